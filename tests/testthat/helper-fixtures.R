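# Shared fixtures, all built in code.

# A rectangular analysis zone built directly (bypasses buffer/strip
# construction when a test needs exact zone geometry).
rect_zone <- function(xmin, ymin, xmax, ymax, kind = "strip",
                      focus = NULL, axis = c(1, 0)) {
  geom <- agrolandgen:::rect_poly(xmin, ymin, xmax, ymax)
  if (is.null(focus))
    focus <- if (kind == "buffer") c((xmin + xmax) / 2, (ymin + ymax) / 2)
             else rbind(c(xmin, (ymin + ymax) / 2), c(xmax, (ymin + ymax) / 2))
  structure(list(geometry = geom, kind = kind, scale = NA, focus = focus,
                 area_ha = (xmax - xmin) * (ymax - ymin) / 1e4, axis = axis),
            class = "lg_zone")
}

rectp <- function(xmin, ymin, xmax, ymax) {
  agrolandgen:::rect_poly(xmin, ymin, xmax, ymax)
}

# Three-parcel window with hand-computable areas: forest left half,
# arable right-bottom quarter, grass right-top quarter; one road crossing.
toy_window <- function() {
  landscape_window("TOY", c(0, 0, 1000, 1000), tibble::tibble(
    class = c("FOREST", "ARABLE", "GRASS"),
    green_fraction = NA_real_,
    crops = list(NULL, c(`2008` = "RAPE", `2009` = "RAPE", `2010` = "MAIZE",
                         `2011` = "CEREAL", `2012` = "CEREAL",
                         `2013` = "CEREAL", `2014` = "OTHER",
                         `2015` = "OTHER", `2016` = "RAPE",
                         `2017` = "MAIZE"), NULL),
    geometry = list(rectp(0, 0, 500, 1000), rectp(500, 0, 1000, 500),
                    rectp(500, 500, 1000, 1000))),
    tibble::tibble(class = "LROAD",
                   geometry = list(cbind(x = c(100, 900), y = c(500, 500)))))
}

# Random simple polyline within a box.
random_polyline <- function(n_seg = 5, box = c(0, 0, 1000, 1000)) {
  cbind(x = stats::runif(n_seg + 1, box[1], box[3]),
        y = stats::runif(n_seg + 1, box[2], box[4]))
}

# Random convex polygon around a centre (sorted angles on a noisy circle).
random_convex_poly <- function(centre, r_mean = 100) {
  k <- sample(5:9, 1)
  th <- sort(stats::runif(k, 0, 2 * pi))
  r <- stats::runif(k, 0.5 * r_mean, 1.5 * r_mean)
  cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

# Tiny two-population diploid genotype table.
toy_genotypes <- function() {
  genotype_table(tibble::tibble(
    window = "W1",
    population = rep(c("A", "B"), each = 4),
    individual = paste0("i", 1:8),
    locus = rep(c("L1", "L2"), 4),
    allele_1 = c("a", "a", "a", "b", "c", "a", "c", "b"),
    allele_2 = c("b", "a", "a", "b", "c", "b", "c", "b")), ploidy = 2)
}

# Random genotype table with given dimensions.
random_genotypes <- function(n_pops = 3, n_loci = 3, n_ind = 5,
                             n_alleles = 4, ploidy = 2) {
  rows <- expand.grid(population = paste0("P", seq_len(n_pops)),
                      individual = seq_len(n_ind),
                      locus = paste0("L", seq_len(n_loci)),
                      stringsAsFactors = FALSE)
  rows$window <- "W1"
  rows$individual <- paste0(rows$population, "_", rows$individual)
  for (k in seq_len(ploidy))
    rows[[paste0("allele_", k)]] <-
      as.character(sample.int(n_alleles, nrow(rows), replace = TRUE))
  genotype_table(tibble::as_tibble(rows), ploidy = ploidy)
}

# Balanced link-level pair skeleton: `nw` windows, `ppw` populations each,
# all within-window pairs.
pair_skeleton <- function(nw = 4, ppw = 4) {
  out <- list()
  for (w in seq_len(nw)) {
    cmb <- utils::combn(ppw, 2)
    out[[w]] <- tibble::tibble(window = paste0("W", w),
                               pop1 = paste0("P", cmb[1, ]),
                               pop2 = paste0("P", cmb[2, ]))
  }
  dplyr::bind_rows(out)
}

# Independent segment-wise orientation oracle: projects every raw segment
# of every clipped piece onto the reference direction, computed without
# the package's vector algebra (angles via atan2).
orientation_oracle <- function(zone, window, line_class) {
  par_tot <- 0; orth_tot <- 0
  for (i in seq_len(nrow(window$lines))) {
    if (window$lines$class[i] != line_class) next
    pieces <- agrolandgen:::clip_polyline_convex(window$lines$geometry[[i]],
                                                 zone$geometry)
    for (piece in pieces) {
      if (zone$kind == "strip") {
        ref <- atan2(zone$axis[2], zone$axis[1])
      } else {
        mid <- agrolandgen:::polyline_midpoint(piece)
        d <- zone$focus - mid
        ref <- atan2(d[2], d[1])
      }
      for (s in seq_len(nrow(piece) - 1)) {
        dx <- piece[s + 1, 1] - piece[s, 1]
        dy <- piece[s + 1, 2] - piece[s, 2]
        len <- sqrt(dx^2 + dy^2)
        th <- atan2(dy, dx) - ref
        par_tot <- par_tot + len * abs(cos(th))
        orth_tot <- orth_tot + len * abs(sin(th))
      }
    }
  }
  c(parallel = par_tot, orthogonal = orth_tot)
}
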