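# Scale selection, screening, collinearity reduction, enumeration and
# model averaging.

link_selection_data <- function(n_fam = 3, scales = c("1to3", "1to2"),
                                beta = c(), nw = 4, ppw = 5, s2w = 0.1,
                                s2p = 0.2, s2e = 0.5, metrics = NULL) {
  d <- pair_skeleton(nw, ppw)
  if (is.null(metrics)) metrics <- paste0("M", seq_len(n_fam))
  for (m in metrics) for (s in scales)
    d[[paste0(m, "_", s)]] <- stats::rnorm(nrow(d))
  d$distance_m <- stats::rnorm(nrow(d))
  d$y <- as.numeric(simulate_response(d, beta, s2w, s2p, s2e,
                                      pairs = c("pop1", "pop2")))
  d
}

test_that("enumeration counts subsets and honours marginality", {
  expect_length(enumerate_models(c("a", "b", "c"), 4), 8)
  expect_length(enumerate_models(c("a", "b", "c"), 1), 4)
  # quadratic never appears without its linear term
  terms <- c("a", "a__2", "b")
  subs <- enumerate_models(terms, 4)
  # brute-force filtered oracle
  brute <- Filter(function(s) !("a__2" %in% s) || ("a" %in% s),
                  unlist(lapply(0:3, function(k)
                    utils::combn(terms, k, simplify = FALSE)),
                    recursive = FALSE))
  key <- function(x) paste(sort(unlist(x)), collapse = "+")
  expect_setequal(vapply(subs, key, character(1)),
                  vapply(brute, key, character(1)))
  # interactions require both mains
  subs2 <- enumerate_models(c("a", "b", "a__x__b"), 9)
  keys2 <- vapply(subs2, key, character(1))
  expect_false("a__x__b" %in% keys2)
  expect_true("a+a__x__b+b" %in% keys2)
  expect_error(enumerate_models(paste0("t", 1:25), 9), "subsets")
})

test_that("scale selection picks the informative scale and extras by AICc", {
  set.seed(71)
  d <- link_selection_data(n_fam = 1, beta = c(M1_1to2 = 0.9))
  fam1 <- metric_family("M1", "1to2")
  ch1 <- select_scale(fam1, d, "distance_m", "y",
                      pairs = c("pop1", "pop2"))
  expect_equal(ch1$scale, "1to2")   # single candidate returned
  fam <- metric_family("M1", c("1to3", "1to2"))
  ch <- select_scale(fam, d, "distance_m", "y", pairs = c("pop1", "pop2"))
  expect_equal(ch$scale, "1to2")
  # quadratic kept iff it lowers AICc: verify against exhaustive refits
  dd <- agrolandgen:::ensure_terms(d, c("M1_1to2__2"))
  alts <- list(c("M1_1to2"), c("M1_1to2", "M1_1to2__2"),
               c("M1_1to3"), c("M1_1to3", "M1_1to3__2"))
  dd <- agrolandgen:::ensure_terms(dd, "M1_1to3__2")
  aiccs <- vapply(alts, function(tm)
    fit_mixed(dd, "y", c("distance_m", tm), pairs = c("pop1", "pop2"))$AICc,
    numeric(1))
  expect_equal(sort(ch$terms), sort(alts[[which.min(aiccs)]]))
  expect_equal(ch$aicc, min(aiccs), tolerance = 1e-9)
})

test_that("the true scale is recovered in most replicates", {
  set.seed(72)
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    d <- pair_skeleton(4, 5)   # n = 40
    for (s in c("a", "b", "c")) d[[paste0("M1_", s)]] <- stats::rnorm(40)
    d$y <- as.numeric(simulate_response(d, c(M1_b = 0.5), 0.1, 0.2, 0.6,
                                        pairs = c("pop1", "pop2")))
    ch <- select_scale(metric_family("M1", c("a", "b", "c"),
                                     quadratic = FALSE),
                       d, character(0), "y", pairs = c("pop1", "pop2"))
    if (ch$scale == "b") hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("screening keeps families strictly below the alpha threshold", {
  set.seed(73)
  d <- link_selection_data(n_fam = 1, beta = c(M1_1to2 = 0.8))
  basic <- fit_mixed(d, "y", "distance_m", pairs = c("pop1", "pop2"))
  ch <- select_scale(metric_family("M1", c("1to3", "1to2")), d,
                     "distance_m", "y", pairs = c("pop1", "pop2"))
  sc <- screen_family(ch, basic, alpha = 0.15)
  expect_identical(sc$keep, sc$p.value < 0.15)
  # threshold semantics at the boundary
  expect_true(screen_family(ch, basic, alpha = sc$p.value + 1e-6)$keep)
  expect_false(screen_family(ch, basic, alpha = sc$p.value - 1e-6)$keep)
  other <- fit_mixed(d, "y", "M1_1to3", pairs = c("pop1", "pop2"))
  expect_error(screen_family(ch, other), "nested")
})

test_that("null screening rejects noise metrics near the nominal rate", {
  set.seed(74)
  n_rep <- 200
  kept <- 0L
  for (r in seq_len(n_rep)) {
    d <- link_selection_data(n_fam = 1, scales = "s", beta = c())
    basic <- fit_mixed(d, "y", "distance_m", pairs = c("pop1", "pop2"))
    ch <- select_scale(metric_family("M1", "s", quadratic = FALSE), d,
                       "distance_m", "y", pairs = c("pop1", "pop2"))
    if (screen_family(ch, basic)$keep) kept <- kept + 1L
  }
  # single-scale, single-term null: keep rate should sit near alpha = 0.15
  expect_lt(kept / n_rep, 0.3)
  expect_gt(kept / n_rep, 0.03)
})

test_that("collinear duplicates collapse to a principal-component composite", {
  set.seed(75)
  d <- pair_skeleton(3, 4)
  d$A_s <- stats::rnorm(nrow(d))
  d$B_s <- d$A_s                       # exact duplicate
  d$C_s <- stats::rnorm(nrow(d))      # orthogonal
  d$y <- stats::rnorm(nrow(d))
  mk <- function(m) list(family = metric_family(m, "s"), scale = "s",
                         terms = paste0(m, "_s"), fit = NULL, aicc = 0)
  red <- reduce_collinearity(d, list(mk("A"), mk("B"), mk("C")))
  expect_equal(nrow(red$composites), 2)
  expect_equal(abs(unname(red$composites$loading[1])),
               abs(unname(red$composites$loading[2])), tolerance = 1e-12)
  comp_col <- red$composites$composite[1]
  # sign convention: positive correlation with the first-named member
  expect_gt(stats::cor(red$data[[comp_col]], d$A_s), 0.99)
  # orthogonal member kept untouched
  kept_cols <- vapply(red$kept, agrolandgen:::chosen_col, character(1))
  expect_true("C_s" %in% kept_cols)
  expect_false(any(c("A_s", "B_s") %in% kept_cols))
  # composite scores equal the eigen-decomposition oracle up to sign
  Xm <- scale(cbind(d$A_s, d$B_s))
  ev <- eigen(stats::cov(Xm))$vectors[, 1]
  oracle <- as.numeric(Xm %*% ev)
  oracle <- oracle / stats::sd(oracle)
  if (stats::cor(oracle, d$A_s) < 0) oracle <- -oracle
  expect_equal(red$data[[red$composites$composite[1]]], oracle,
               tolerance = 1e-9)
})

test_that("uncorrelated metrics pass collinearity reduction unchanged", {
  set.seed(76)
  d <- pair_skeleton(3, 4)
  d$A_s <- stats::rnorm(nrow(d)); d$B_s <- stats::rnorm(nrow(d))
  mk <- function(m) list(family = metric_family(m, "s"), scale = "s",
                         terms = paste0(m, "_s"), fit = NULL, aicc = 0)
  red <- reduce_collinearity(d, list(mk("A"), mk("B")))
  expect_length(red$kept, 2)
  expect_equal(nrow(red$composites), 0)
})

test_that("model averaging follows the hand-computed worked case", {
  set.seed(77)
  d <- link_selection_data(n_fam = 2, scales = "s",
                           beta = c(M1_s = 0.5))
  basic <- fit_mixed(d, "y", "distance_m", pairs = c("pop1", "pop2"))
  terms_list <- list(character(0), "M1_s", c("M1_s", "M2_s"))
  fits <- lapply(terms_list, function(tm)
    fit_mixed(d, "y", c("distance_m", tm), pairs = c("pop1", "pop2")))
  avg <- average_models(fits, d, basic, delta = Inf)
  expect_equal(sum(avg$components$weight), 1, tolerance = 1e-12)
  # hand-computed: recompute weights and the full average independently
  aiccs <- vapply(fits, function(f) f$AICc, numeric(1))
  w <- exp(-(aiccs - min(aiccs)) / 2); w <- w / sum(w)
  remls <- lapply(fits, refit_mixed, data = d, method = "REML")
  hand <- sum(vapply(seq_along(remls), function(i) {
    b <- remls[[i]]$coefficients
    w[i] * if ("M1_s" %in% names(b)) b[["M1_s"]] else 0
  }, numeric(1)))
  got <- avg$coefficients$estimate[avg$coefficients$term == "M1_s"]
  expect_equal(got, hand, tolerance = 1e-9)
  # importance = summed weights of the models containing the term
  expect_equal(avg$coefficients$importance[avg$coefficients$term == "M1_s"],
               w[2] + w[3], tolerance = 1e-9)
  expect_equal(avg$coefficients$importance[
    avg$coefficients$term == "distance_m"], 1)
  # dropping a model beyond the delta window changes nothing
  avg2 <- average_models(fits, d, basic, delta = 2)
  in_window <- aiccs - min(aiccs) < 2
  avg3 <- average_models(fits[in_window], d, basic, delta = 2)
  expect_equal(avg2$coefficients, avg3$coefficients, tolerance = 1e-12)
})

test_that("a single qualifying model averages to itself", {
  set.seed(78)
  d <- link_selection_data(n_fam = 1, scales = "s", beta = c(M1_s = 1.5))
  basic <- fit_mixed(d, "y", "distance_m", pairs = c("pop1", "pop2"))
  f1 <- fit_mixed(d, "y", c("distance_m", "M1_s"), pairs = c("pop1", "pop2"))
  f0 <- fit_mixed(d, "y", "distance_m", pairs = c("pop1", "pop2"))
  avg <- average_models(list(f0, f1), d, basic)
  if (nrow(avg$components) == 1) {
    reml <- refit_mixed(f1, d, "REML")
    expect_equal(avg$coefficients$estimate[avg$coefficients$term == "M1_s"],
                 unname(reml$coefficients[["M1_s"]]), tolerance = 1e-9)
    expect_true(all(avg$coefficients$importance == 1))
  }
  expect_equal(sum(avg$components$weight), 1, tolerance = 1e-12)
})

test_that("landscape R2 is the marginal difference with its percentage", {
  lr <- landscape_r2(0.5, 0.2)
  expect_equal(lr$landscape_R2, 0.3)
  expect_equal(lr$pct_landscape, 60)
  # average model equal to the basic model: zero landscape R2
  lr0 <- landscape_r2(0.2, 0.2)
  expect_equal(lr0$landscape_R2, 0)
  # negative differences are reported, not clamped
  lrn <- landscape_r2(0.2, 0.3)
  expect_lt(lrn$landscape_R2, 0)
})

test_that("landscape-only signal attributes most variation to the landscape", {
  set.seed(79)
  pcts <- numeric(20)
  for (r in 1:20) {
    d <- link_selection_data(n_fam = 1, scales = "s", nw = 5, ppw = 5,
                             beta = c(M1_s = 0.8), s2w = 0.05, s2p = 0.1,
                             s2e = 0.3)
    sel <- run_selection(d, "y", "distance_m",
                         list(metric_family("M1", "s", quadratic = FALSE)),
                         pairs = c("pop1", "pop2"),
                         distance_col = "distance_m")
    pcts[r] <- sel$avg$r2$pct_landscape
  }
  expect_gt(stats::median(pcts), 70)
})

test_that("the crop-split comparison reports the better variant", {
  # deterministic comparison semantics (crops preferred on ties)
  expect_identical(if (0.6 >= 0.4) "crops" else "arable", "crops")
  set.seed(80)
  # synthetic RAPE-only effect: the crop-split variant should win mostly
  wins <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    d <- pair_skeleton(4, 5)
    d$RAPE_s <- stats::rnorm(40)
    d$MAIZE_s <- stats::rnorm(40)
    d$CEREAL_s <- stats::rnorm(40)
    d$ARABLE_s <- as.numeric(scale(d$RAPE_s + d$MAIZE_s + d$CEREAL_s +
                                     stats::rnorm(40, 0, 0.5)))
    d$distance_m <- stats::rnorm(40)
    d$y <- as.numeric(simulate_response(d, c(RAPE_s = 0.8), 0.05, 0.1, 0.4,
                                        pairs = c("pop1", "pop2")))
    fams <- function(cs) lapply(if (cs) c("RAPE", "MAIZE", "CEREAL") else
                                  "ARABLE",
                                function(m) metric_family(m, "s",
                                                          quadratic = FALSE))
    r2 <- vapply(c(TRUE, FALSE), function(cs)
      run_selection(d, "y", "distance_m", fams(cs),
                    pairs = c("pop1", "pop2"),
                    distance_col = "distance_m")$avg$r2$marginal, numeric(1))
    if (r2[1] >= r2[2]) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_rep)
})
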