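# Within-population diversity and pairwise differentiation statistics for
# microsatellite genotypes.

# Per-record allele weights in gene copies. A record whose number of
# recorded copies equals the ploidy has known dosage and each copy weighs
# 1; otherwise dosage is unknown and each *distinct* allele receives an
# equal share of the ploidy gene copies (unbiased under ignorance).
#' @keywords internal
record_weights <- function(alleles, ploidy) {
  if (length(alleles) == ploidy) {
    w <- table(alleles)
    stats::setNames(as.numeric(w), names(w))
  } else {
    u <- unique(alleles)
    stats::setNames(rep(ploidy / length(u), length(u)), u)
  }
}

#' Allele frequencies per population and locus
#'
#' @param genotypes An [genotype_table()] object.
#' @param population,locus Optional filters; requesting a combination with
#'   no scored records is an error.
#' @return Tibble with columns `window`, `population`, `locus`, `allele`,
#'   `freq`, `gene_count`. Frequencies sum to 1 within each
#'   population-locus; `gene_count` is ploidy times the number of scored
#'   individuals.
#' @export
allele_frequencies <- function(genotypes, population = NULL, locus = NULL) {
  rec <- genotypes$records
  if (!is.null(population)) rec <- rec[rec$population %in% population, ]
  if (!is.null(locus)) rec <- rec[rec$locus %in% locus, ]
  if (nrow(rec) == 0) stop("no data for the requested population/locus",
                           call. = FALSE)
  ploidy <- genotypes$ploidy
  rec |>
    dplyr::mutate(w = purrr::map(.data$alleles, record_weights, ploidy = ploidy)) |>
    dplyr::mutate(allele = purrr::map(.data$w, names),
                  copies = purrr::map(.data$w, unname)) |>
    dplyr::select("window", "population", "locus", "allele", "copies") |>
    tidyr::unnest(c("allele", "copies")) |>
    dplyr::group_by(.data$window, .data$population, .data$locus) |>
    dplyr::mutate(gene_count = sum(.data$copies)) |>
    dplyr::group_by(.data$allele, .add = TRUE) |>
    dplyr::summarise(freq = sum(.data$copies) / .data$gene_count[1],
                     gene_count = .data$gene_count[1], .groups = "drop")
}

#' Expected heterozygosity per locus
#'
#' Uncorrected `He = 1 - sum(p^2)`; the sample-size-corrected (Nei)
#' estimator multiplies by `n/(n-1)` with `n` the number of sampled gene
#' copies.
#'
#' @param freqs Output of [allele_frequencies()].
#' @param corrected Apply the `n/(n-1)` correction (default `TRUE`).
#' @return Tibble with `window`, `population`, `locus`, `He`.
#' @export
expected_heterozygosity <- function(freqs, corrected = TRUE) {
  out <- freqs |>
    dplyr::group_by(.data$window, .data$population, .data$locus) |>
    dplyr::summarise(He = 1 - sum(.data$freq^2),
                     gene_count = .data$gene_count[1], .groups = "drop")
  if (corrected) {
    if (any(out$gene_count <= 1))
      stop("corrected He undefined for gene_count <= 1", call. = FALSE)
    out$He <- out$He * out$gene_count / (out$gene_count - 1)
  }
  dplyr::select(out, -"gene_count")
}

#' Observed heterozygosity per population
#'
#' An individual-locus record counts as heterozygous when it carries at
#' least two distinct alleles; this definition is dosage-free and applies
#' to both ploidies. The per-locus fractions are averaged (unweighted)
#' over loci.
#'
#' @param genotypes An [genotype_table()] object.
#' @param population Optional filter.
#' @return Tibble with `window`, `population`, `Ho`.
#' @export
observed_heterozygosity <- function(genotypes, population = NULL) {
  rec <- genotypes$records
  if (!is.null(population)) rec <- rec[rec$population %in% population, ]
  if (nrow(rec) == 0) stop("no scored records", call. = FALSE)
  rec |>
    dplyr::mutate(het = purrr::map_int(.data$alleles,
                                       ~ as.integer(length(unique(.x)) >= 2))) |>
    dplyr::group_by(.data$window, .data$population, .data$locus) |>
    dplyr::summarise(Ho_locus = mean(.data$het), .groups = "drop_last") |>
    dplyr::summarise(Ho = mean(.data$Ho_locus), .groups = "drop")
}

#' Inbreeding coefficient
#'
#' `F = 1 - Ho/He`, the classic fixation index; undefined (NA) where
#' `He = 0`.
#'
#' @param Ho,He Observed and expected heterozygosity (vectors, >= 0).
#' @return Numeric vector of F values.
#' @export
inbreeding_coefficient <- function(Ho, He) {
  if (any(Ho < 0, na.rm = TRUE) || any(He < 0, na.rm = TRUE))
    stop("heterozygosities must be >= 0", call. = FALSE)
  ifelse(He > 0, 1 - Ho / He, NA_real_)
}

#' Rarefied allelic richness for one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' `Ar = sum_i [1 - choose(N - N_i, g) / choose(N, g)]`
#' where `N_i` are the allele counts and `N = sum(N_i)`. This makes allele
#' counts comparable across unequal sample sizes.
#'
#' @param counts Allele counts (gene copies) at one locus.
#' @param g Rarefaction sample size in gene copies, `1 <= g <= N`.
#' @return Expected allele count (>= 1 when `g >= 1` and the locus was scored).
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1) stop("g must be >= 1", call. = FALSE)
  if (g > N) stop("g exceeds the available gene count", call. = FALSE)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Shared-allele distance D_PS between two populations
#'
#' `D_PS = 1 -` the proportion of shared alleles, computed on population
#' allele-frequency vectors: per locus the shared proportion is
#' `sum_a min(p_A, p_B)`, and loci are averaged.
#'
#' @param freqsA,freqsB [allele_frequencies()] tibbles for one population
#'   each (any subset covering a common locus set).
#' @return D_PS in `[0, 1]`.
#' @export
pairwise_dps <- function(freqsA, freqsB) {
  shared <- intersect(unique(freqsA$locus), unique(freqsB$locus))
  if (length(shared) == 0) stop("no shared loci", call. = FALSE)
  per_locus <- vapply(shared, function(l) {
    a <- freqsA[freqsA$locus == l, ]
    b <- freqsB[freqsB$locus == l, ]
    pa <- stats::setNames(a$freq, a$allele)
    pb <- stats::setNames(b$freq, b$allele)
    common <- intersect(names(pa), names(pb))
    if (length(common) == 0) 0 else sum(pmin(pa[common], pb[common]))
  }, numeric(1))
  1 - mean(per_locus)
}

#' Hedrick-standardized differentiation G''ST between two populations
#'
#' G''ST standardizes GST by its maximum given the within-population
#' diversity, which makes highly polymorphic microsatellite loci
#' comparable: with `k = 2` populations,
#' `G''ST = k (HT - HS) / ((k HT - HS) (1 - HS))`.
#' Per locus `HS` is the mean within-population gene diversity and `HT`
#' the gene diversity of the pooled (mean) frequency vector; `HS` and `HT`
#' are averaged across loci before the formula is applied once.
#' `corrected = TRUE` applies Nei-Chesser-type sample-size corrections on
#' gene copies: `HS' = ng/(ng-1) HS` and `HT' = HT + HS'/(ng k)` with `ng`
#' the harmonic-mean gene count. Negative estimates are reported, not
#' clamped; the statistic is undefined (NA) when both populations are
#' monomorphic at every locus or mean `HS = 1`.
#'
#' @inheritParams pairwise_dps
#' @param corrected Apply sample-size corrections (default `TRUE`).
#' @return G''ST (<= 1), possibly NA.
#' @export
pairwise_gst_dp <- function(freqsA, freqsB, corrected = TRUE) {
  shared <- intersect(unique(freqsA$locus), unique(freqsB$locus))
  if (length(shared) == 0) stop("no shared loci", call. = FALSE)
  k <- 2
  per_locus <- lapply(shared, function(l) {
    a <- freqsA[freqsA$locus == l, ]
    b <- freqsB[freqsB$locus == l, ]
    alleles <- union(a$allele, b$allele)
    pa <- stats::setNames(rep(0, length(alleles)), alleles)
    pb <- pa
    pa[a$allele] <- a$freq
    pb[b$allele] <- b$freq
    hs_raw <- mean(c(1 - sum(pa^2), 1 - sum(pb^2)))
    pbar <- (pa + pb) / 2
    ht_raw <- 1 - sum(pbar^2)
    if (corrected) {
      ng <- 2 / (1 / a$gene_count[1] + 1 / b$gene_count[1])
      hs <- hs_raw * ng / (ng - 1)
      ht <- ht_raw + hs / (ng * k)
    } else {
      hs <- hs_raw; ht <- ht_raw
    }
    c(hs = hs, ht = ht)
  })
  HS <- mean(vapply(per_locus, `[[`, numeric(1), "hs"))
  HT <- mean(vapply(per_locus, `[[`, numeric(1), "ht"))
  if (HT <= 0 || HS >= 1) return(NA_real_)
  k * (HT - HS) / ((k * HT - HS) * (1 - HS))
}

#' Edge-to-edge distance between two habitat patches
#'
#' Minimum Euclidean distance between the polygon boundaries; 0 when the
#' patches touch or overlap. Coordinates must be planar metres.
#'
#' @param patchA,patchB Two-column vertex matrices of simple polygons.
#' @return Distance in metres.
#' @export
edge_to_edge_distance <- function(patchA, patchB) {
  validate_polygon(patchA, "patchA")
  validate_polygon(patchB, "patchB")
  poly_distance(patchA, patchB)
}

#' Hanski incidence-function connectivity
#'
#' `S_i = sum_{j != i, same window} exp(-alpha d_ij) A_j^b`, with `A_j`
#' the neighbour's population size (flowering-shoot count) and `d_ij` the
#' between-population distance. Larger `S_i` means better connected; the
#' modelling layer uses `isolation = -S_i` so that larger values mean more
#' isolated.
#'
#' @param nodes Tibble with `window`, `population`, `x`, `y`, `size`.
#' @param alpha Inverse distance scale (1/m), > 0. Default 1/1000.
#' @param b Exponent on neighbour size, >= 0. Default 0.5.
#' @param distances Optional tibble `window, pop1, pop2, distance_m` of
#'   precomputed (e.g. edge-to-edge) distances; defaults to centre
#'   distances from `x`, `y`.
#' @return `nodes` with added `connectivity` and `isolation` columns.
#' @export
hanski_connectivity <- function(nodes, alpha = 1/1000, b = 0.5,
                                distances = NULL) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (b < 0) stop("b must be >= 0", call. = FALSE)
  get_d <- function(w, p1, p2) {
    if (is.null(distances)) {
      i <- which(nodes$window == w & nodes$population == p1)
      j <- which(nodes$window == w & nodes$population == p2)
      sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2)
    } else {
      hit <- distances$window == w &
        ((distances$pop1 == p1 & distances$pop2 == p2) |
         (distances$pop1 == p2 & distances$pop2 == p1))
      distances$distance_m[hit][1]
    }
  }
  S <- vapply(seq_len(nrow(nodes)), function(i) {
    w <- nodes$window[i]
    nb <- which(nodes$window == w & nodes$population != nodes$population[i])
    if (length(nb) == 0) return(0)
    sum(vapply(nb, function(j) {
      d <- get_d(w, nodes$population[i], nodes$population[j])
      exp(-alpha * d) * nodes$size[j]^b
    }, numeric(1)))
  }, numeric(1))
  dplyr::mutate(nodes, connectivity = S, isolation = -S)
}

#' Within-population diversity table
#'
#' Per-population allelic richness (hypergeometric rarefaction), expected
#' and observed heterozygosity and the inbreeding coefficient
#' `F = 1 - Ho/He`. Population values are unweighted means over scored
#' loci; loci not scored in a population are simply skipped.
#'
#' @param genotypes An [genotype_table()] object.
#' @param g Rarefaction size in gene copies; defaults to the smallest
#'   per-locus gene count across all populations (so every locus can be
#'   rarefied everywhere).
#' @param corrected Sample-size-corrected He (default `TRUE`).
#' @return Tibble with `window`, `population`, `n_individuals`,
#'   `rarefaction_g`, `Ar`, `He`, `Ho`, `F`.
#' @export
pop_diversity <- function(genotypes, g = NULL, corrected = TRUE) {
  freqs <- allele_frequencies(genotypes)
  if (is.null(g)) g <- min(freqs$gene_count)
  ar <- freqs |>
    dplyr::group_by(.data$window, .data$population, .data$locus) |>
    dplyr::summarise(Ar_locus = allelic_richness(.data$freq * .data$gene_count[1],
                                                 g = g),
                     .groups = "drop_last") |>
    dplyr::summarise(Ar = mean(.data$Ar_locus), .groups = "drop")
  he <- expected_heterozygosity(freqs, corrected = corrected) |>
    dplyr::group_by(.data$window, .data$population) |>
    dplyr::summarise(He = mean(.data$He), .groups = "drop")
  ho <- observed_heterozygosity(genotypes)
  nind <- genotypes$records |>
    dplyr::group_by(.data$window, .data$population) |>
    dplyr::summarise(n_individuals = length(unique(.data$individual)),
                     .groups = "drop")
  nind |>
    dplyr::left_join(ar, by = c("window", "population")) |>
    dplyr::left_join(he, by = c("window", "population")) |>
    dplyr::left_join(ho, by = c("window", "population")) |>
    dplyr::mutate(F = inbreeding_coefficient(.data$Ho, .data$He)) |>
    dplyr::mutate(rarefaction_g = g, .after = "n_individuals")
}

#' Pairwise differentiation table
#'
#' G''ST and D_PS for every within-window population pair, with the
#' geographic distance between them. Pairs sharing fewer than
#' `min_shared_loci` scored loci are reported with NA statistics.
#'
#' @param genotypes An [genotype_table()] object.
#' @param nodes Optional tibble with `window`, `population`, `x`, `y` and
#'   optionally a `patch` list column of polygon matrices; supplies
#'   edge-to-edge (if patches are present) or centre distances.
#' @param corrected Sample-size-corrected G''ST (default `TRUE`).
#' @param min_shared_loci Minimum shared scored loci per pair (default 3).
#' @return Tibble with `window`, `pop1`, `pop2`, `Gst_dp`, `Dps`,
#'   `distance_m`.
#' @export
pop_differentiation <- function(genotypes, nodes = NULL, corrected = TRUE,
                                min_shared_loci = 3L) {
  freqs <- allele_frequencies(genotypes)
  pops <- dplyr::distinct(freqs, .data$window, .data$population)
  out <- list()
  for (w in unique(pops$window)) {
    pw <- pops$population[pops$window == w]
    if (length(pw) < 2) next
    cmb <- utils::combn(sort(pw), 2)
    for (k in seq_len(ncol(cmb))) {
      p1 <- cmb[1, k]; p2 <- cmb[2, k]
      fa <- freqs[freqs$window == w & freqs$population == p1, ]
      fb <- freqs[freqs$window == w & freqs$population == p2, ]
      shared <- intersect(unique(fa$locus), unique(fb$locus))
      if (length(shared) < min_shared_loci) {
        g <- NA_real_; d <- NA_real_
      } else {
        g <- pairwise_gst_dp(fa, fb, corrected = corrected)
        d <- pairwise_dps(fa, fb)
      }
      dist_m <- NA_real_
      if (!is.null(nodes)) {
        i <- which(nodes$window == w & nodes$population == p1)
        j <- which(nodes$window == w & nodes$population == p2)
        if (length(i) == 1 && length(j) == 1) {
          if ("patch" %in% names(nodes) &&
              !is.null(nodes$patch[[i]]) && !is.null(nodes$patch[[j]])) {
            dist_m <- edge_to_edge_distance(nodes$patch[[i]], nodes$patch[[j]])
          } else if (all(c("x", "y") %in% names(nodes))) {
            dist_m <- sqrt((nodes$x[i] - nodes$x[j])^2 +
                           (nodes$y[i] - nodes$y[j])^2)
          }
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        window = w, pop1 = p1, pop2 = p2, Gst_dp = g, Dps = d,
        distance_m = dist_m)
    }
  }
  dplyr::bind_rows(out)
}
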