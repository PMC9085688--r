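# Diversity and differentiation statistics.

test_that("allele frequencies count gene copies, with the tetraploid rule", {
  g1 <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = c("a", "b", "c"),
    locus = "L", allele_1 = "A", allele_2 = "A"), ploidy = 2)
  f1 <- allele_frequencies(g1, "P", "L")
  expect_equal(f1$freq, 1)
  expect_equal(f1$gene_count, 6)
  g2 <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = c("a", "b"),
    locus = "L", allele_1 = c("A", "A"), allele_2 = c("B", "A")), ploidy = 2)
  f2 <- allele_frequencies(g2)
  expect_equal(f2$freq[f2$allele == "A"], 0.75)
  expect_equal(f2$freq[f2$allele == "B"], 0.25)
  # tetraploid with unknown dosage: equal weight over distinct alleles
  g4 <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = "a", locus = "L",
    allele_1 = "A", allele_2 = "B"), ploidy = 4)
  f4 <- allele_frequencies(g4)
  expect_equal(f4$freq, c(0.5, 0.5))
  expect_equal(unique(f4$gene_count), 4)
  expect_error(allele_frequencies(g1, "nope", "L"), "no data")
})

test_that("frequencies sum to one for random tables of both ploidies", {
  set.seed(31)
  for (i in 1:100) {
    ploidy <- if (i %% 2 == 0) 2 else 4
    gt <- random_genotypes(n_pops = 2, n_loci = 2, n_ind = 4, ploidy = ploidy)
    sums <- allele_frequencies(gt) |>
      dplyr::group_by(population, locus) |>
      dplyr::summarise(s = sum(freq), .groups = "drop")
    expect_true(all(abs(sums$s - 1) < 1e-12))
  }
})

test_that("expected heterozygosity with and without correction", {
  gt <- toy_genotypes()
  f <- allele_frequencies(gt)
  # monomorphic population-locus gives zero
  mono <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = c("a", "b"), locus = "L",
    allele_1 = "A", allele_2 = "A"), ploidy = 2)
  expect_equal(expected_heterozygosity(allele_frequencies(mono),
                                       corrected = FALSE)$He, 0)
  # p = (0.5, 0.5) uncorrected -> 0.5; corrected with 10 copies -> 10/9 * 0.5
  ff <- tibble::tibble(window = "W", population = "P", locus = "L",
                       allele = c("A", "B"), freq = 0.5, gene_count = 10)
  expect_equal(expected_heterozygosity(ff, corrected = FALSE)$He, 0.5)
  expect_equal(expected_heterozygosity(ff, corrected = TRUE)$He, 0.55556,
               tolerance = 1e-4)
  ff1 <- dplyr::mutate(ff, gene_count = 1)
  expect_error(expected_heterozygosity(ff1, corrected = TRUE), "undefined")
})

test_that("observed heterozygosity is the share of multi-allele records", {
  het <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = c("a", "b"), locus = "L",
    allele_1 = c("A", "A"), allele_2 = c("B", "C")), ploidy = 2)
  expect_equal(observed_heterozygosity(het)$Ho, 1)
  hom <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = c("a", "b"), locus = "L",
    allele_1 = "A", allele_2 = "A"), ploidy = 2)
  expect_equal(observed_heterozygosity(hom)$Ho, 0)
  half <- genotype_table(tibble::tibble(
    window = "W", population = "P", individual = letters[1:4], locus = "L",
    allele_1 = c("A", "A", "A", "A"), allele_2 = c("B", "B", "A", "A")),
    ploidy = 2)
  expect_equal(observed_heterozygosity(half)$Ho, 0.5)
})

test_that("inbreeding coefficient F = 1 - Ho/He", {
  expect_equal(inbreeding_coefficient(0.4, 0.4), 0)
  expect_equal(inbreeding_coefficient(0, 0.5), 1)
  expect_equal(inbreeding_coefficient(0.6, 0.8), 0.25)
  expect_true(is.na(inbreeding_coefficient(0.1, 0)))
  expect_error(inbreeding_coefficient(-0.1, 0.5), ">= 0")
  # pipeline identity to machine precision
  set.seed(32)
  div <- pop_diversity(random_genotypes(n_pops = 4, n_loci = 4, n_ind = 6))
  ok <- div$He > 0
  expect_equal(div$F[ok], 1 - div$Ho[ok] / div$He[ok], tolerance = 1e-15)
})

test_that("rarefied allelic richness matches enumeration and Monte Carlo", {
  expect_equal(allelic_richness(c(9, 1), 10), 2)
  expect_equal(allelic_richness(c(9, 1), 2), 1.2)
  expect_error(allelic_richness(c(4, 4), 0), ">= 1")
  expect_error(allelic_richness(c(4, 4), 9), "exceeds")
  # exhaustive enumeration oracle for N <= 12
  enum_ar <- function(counts, g) {
    pool <- rep(seq_along(counts), counts)
    subs <- utils::combn(length(pool), g)
    mean(apply(subs, 2, function(ix) length(unique(pool[ix]))))
  }
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    counts <- as.numeric(stats::rmultinom(1, sample(6:12, 1),
                                          rep(1 / k, k)))
    counts <- counts[counts > 0]
    if (length(counts) < 1) next
    g <- sample(seq_len(sum(counts)), 1)
    expect_equal(allelic_richness(counts, g), enum_ar(counts, g),
                 tolerance = 1e-12)
  }
  # monotone non-decreasing in g
  counts <- c(5, 3, 2, 1)
  ar <- vapply(1:11, function(g) allelic_richness(counts, g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  # Monte-Carlo subsampling oracle within 3 MC standard errors
  set.seed(34)
  counts <- c(12, 6, 2); g <- 8
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(1e4, length(unique(sample(pool, g))))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(allelic_richness(counts, g) - mean(draws)), 3 * se)
})

test_that("D_PS is a proper shared-allele distance", {
  f <- function(pop, loci, alleles, freqs)
    tibble::tibble(window = "W", population = pop,
                   locus = rep(loci, lengths(alleles)),
                   allele = unlist(alleles), freq = unlist(freqs),
                   gene_count = 20)
  a <- f("A", "L1", list(c("x", "y")), list(c(0.5, 0.5)))
  b <- f("B", "L1", list("x"), list(1))
  expect_equal(pairwise_dps(a, b), 0.5)
  expect_equal(pairwise_dps(a, a), 0)
  disj <- f("B", "L1", list("z"), list(1))
  expect_equal(pairwise_dps(a, disj), 1)
  expect_error(pairwise_dps(a, f("B", "L9", list("x"), list(1))), "shared")
  # symmetry on random frequency pairs
  set.seed(35)
  for (i in 1:50) {
    pa <- stats::runif(4); pa <- pa / sum(pa)
    pb <- stats::runif(4); pb <- pb / sum(pb)
    fa <- f("A", "L1", list(letters[1:4]), list(pa))
    fb <- f("B", "L1", list(letters[1:4]), list(pb))
    d1 <- pairwise_dps(fa, fb); d2 <- pairwise_dps(fb, fa)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("G''ST hits its identity and fixation endpoints", {
  f <- function(pop, alleles, freqs, gc = 20)
    tibble::tibble(window = "W", population = pop, locus = "L1",
                   allele = alleles, freq = freqs, gene_count = gc)
  a <- f("A", c("x", "y"), c(0.5, 0.5))
  expect_equal(pairwise_gst_dp(a, dplyr::mutate(a, population = "B"),
                               corrected = FALSE), 0)
  fixA <- f("A", "x", 1); fixB <- f("B", "y", 1)
  expect_equal(pairwise_gst_dp(fixA, fixB, corrected = FALSE), 1)
  # HS = 0.4, HT = 0.5 -> 0.2 / 0.36
  p <- (1 + sqrt(0.2)) / 2
  ha <- f("A", c("x", "y"), c(p, 1 - p))
  hb <- f("B", c("x", "y"), c(1 - p, p))
  expect_equal(pairwise_gst_dp(ha, hb, corrected = FALSE), 0.2 / 0.36,
               tolerance = 1e-12)
  # monomorphic in both populations at the same allele: undefined
  mono <- f("A", "x", 1)
  expect_true(is.na(pairwise_gst_dp(mono, dplyr::mutate(mono,
                                                        population = "B"),
                                    corrected = FALSE)))
  # disjoint allele sets at polymorphic loci give exactly 1 (uncorrected)
  set.seed(36)
  for (i in 1:20) {
    pa <- stats::runif(3); pa <- pa / sum(pa)
    pb <- stats::runif(3); pb <- pb / sum(pb)
    fa <- f("A", paste0("a", 1:3), pa)
    fb <- f("B", paste0("b", 1:3), pb)
    expect_equal(pairwise_gst_dp(fa, fb, corrected = FALSE), 1,
                 tolerance = 1e-9)
    expect_equal(pairwise_gst_dp(fa, fb, corrected = FALSE),
                 pairwise_gst_dp(fb, fa, corrected = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hanski connectivity follows the incidence function model", {
  one <- tibble::tibble(window = "W", population = "a", x = 0, y = 0,
                        size = 10)
  expect_equal(hanski_connectivity(one)$connectivity, 0)
  two <- tibble::tibble(window = "W", population = c("a", "b"),
                        x = c(0, 1000), y = 0, size = c(1, 100))
  s <- hanski_connectivity(two, alpha = 0.001, b = 1)
  expect_equal(s$connectivity[1], 100 * exp(-1), tolerance = 1e-9)
  expect_equal(s$isolation, -s$connectivity)
  # additivity over neighbours
  three <- tibble::tibble(window = "W", population = c("a", "b", "c"),
                          x = c(0, 1000, 2000), y = 0, size = c(1, 100, 50))
  s3 <- hanski_connectivity(three, alpha = 0.001, b = 1)
  expect_equal(s3$connectivity[1],
               100 * exp(-1) + 50 * exp(-2), tolerance = 1e-9)
  expect_error(hanski_connectivity(two, alpha = 0), "> 0")
})

test_that("differentiation table pairs populations within windows", {
  set.seed(37)
  gt <- random_genotypes(n_pops = 3, n_loci = 4, n_ind = 5)
  nodes <- tibble::tibble(window = "W1", population = paste0("P", 1:3),
                          x = c(0, 500, 2000), y = 0)
  dt <- pop_differentiation(gt, nodes = nodes)
  expect_equal(nrow(dt), 3)
  expect_equal(sort(dt$distance_m), c(500, 1500, 2000))
  expect_true(all(dt$Dps >= 0 & dt$Dps <= 1))
  expect_true(all(dt$Gst_dp <= 1, na.rm = TRUE))
  # edge-to-edge distance via patches beats centre distance
  nodes$patch <- list(rectp(0, 0, 100, 100), rectp(400, 0, 600, 100),
                      rectp(1900, 0, 2100, 100))
  dtp <- pop_differentiation(gt, nodes = nodes)
  expect_equal(sort(dtp$distance_m), c(300, 1300, 1800))
  # too few shared loci: flagged missing
  dt3 <- pop_differentiation(gt, min_shared_loci = 5)
  expect_true(all(is.na(dt3$Gst_dp)))
})

test_that("GENEPOP import round-trips through the frequency machinery", {
  tmp <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("Toy data", "LocA", "LocB", "Pop",
               "ind1 , 0101 0202", "ind2 , 0102 0202", "Pop",
               "ind3 , 0303 0000"), tmp)
  gt <- read_genepop(tmp, window = "WX")
  expect_equal(gt$ploidy, 2L)
  expect_equal(sort(unique(gt$records$population)), c("pop_1", "pop_2"))
  # the 0000 genotype is an absent record, not a sentinel allele
  expect_equal(nrow(gt$records[gt$records$population == "pop_2", ]), 1)
  f <- allele_frequencies(gt, "pop_1", "LocA")
  expect_equal(f$freq[f$allele == "01"], 0.75)
})
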