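# Synthetic study scenarios: landscape mosaics, populations and genotypes
# with known ground truth, emulating 5 x 5 km agricultural windows so the
# whole pipeline can be validated closed-loop.
#
# All generators are pure functions of (config, seed); each stage draws
# from its own named substream derived from the scenario seed, so changing
# one stage's draws cannot shift another's.

#' Scenario configuration for the synthetic-data generator
#'
#' The defaults emulate the study conditions: 5 x 5 km windows, up to six
#' populations per window with flowering-shoot counts spanning 15 to
#' 1.2e7, a mosaic dominated by arable land with interspersed forest
#' fragments, grassland and villages, and linear elements at realistic
#' densities (Table-catalog medians: hedgerows ~27 m/ha, water courses
#' ~12, fringes ~3, roads ~16).
#'
#' @param seed Scenario seed (integer).
#' @param n_windows Number of landscape windows.
#' @param window_size_m Window side length (m), default 5000.
#' @param pops_per_window Populations per window (<= 6).
#' @param n_parcels Voronoi parcels per window.
#' @param class_targets Named fractions of window area per land-use class
#'   (must sum to <= 1; remainder goes to OTHER).
#' @param line_density Named m/ha targets per linear-element class.
#' @param kappa,mean_angle Von Mises concentration and mean direction
#'   (radians) of line-segment orientations; `kappa = 0` is isotropic.
#' @param crop_probs Yearly crop-rotation probabilities for arable parcels.
#' @param crop_years Years with crop records.
#' @param size_range Population-size (flowering shoots) range, drawn
#'   log-uniformly.
#' @param min_separation Minimum distance between population centres (m).
#' @param n_loci,n_alleles,n_ind,ploidy Genetic setup: loci, alleles per
#'   locus, individuals sampled per population, ploidy.
#' @param theta_a,theta_b Divergence model: each population's drift level
#'   is `theta = plogis(theta_a + theta_b * driver)`; `theta_b` links
#'   divergence to the landscape driver.
#' @param driver_metric,driver_scale Node-level landscape metric (and
#'   buffer distance) acting as the divergence driver.
#' @param beta,sigma2_w,sigma2_p,sigma2_e Response model: true fixed
#'   effects (named by column) and variance components for
#'   [simulate_response()].
#' @return An `lg_scenario` configuration list.
#' @export
scenario_config <- function(seed = 1L, n_windows = 2L, window_size_m = 5000,
                            pops_per_window = 6L, n_parcels = 80L,
                            class_targets = c(FOREST = 0.12, GRASS = 0.18,
                                              SEMNATGRASS = 0.03,
                                              SEMNATVEG = 0.03,
                                              ARABLE = 0.45, ORCHARD = 0.02,
                                              SETTLE = 0.07),
                            line_density = c(LWOOD = 27, LWATER = 12,
                                             LFRINGE = 3, LROAD = 16),
                            kappa = 0, mean_angle = 0,
                            crop_probs = c(RAPE = 0.10, MAIZE = 0.15,
                                           CEREAL = 0.40, OTHER = 0.35),
                            crop_years = 2008:2017,
                            size_range = c(15, 1.2e7),
                            min_separation = 200,
                            n_loci = 6L, n_alleles = 8L, n_ind = 10L,
                            ploidy = 2L,
                            theta_a = -2.5, theta_b = 0,
                            driver_metric = "FOREST", driver_scale = 1000,
                            beta = c(), sigma2_w = 0.1, sigma2_p = 0.2,
                            sigma2_e = 0.5) {
  stopifnot(sum(class_targets) <= 1 + 1e-9, kappa >= 0,
            pops_per_window <= 6, sigma2_w >= 0, sigma2_p >= 0,
            sigma2_e >= 0, n_alleles >= 2)
  structure(as.list(environment()), class = "lg_scenario")
}

# Deterministic per-stage substream seed (< 2^31).
#' @keywords internal
stage_seed <- function(config, stage, index = 0L) {
  stages <- c(window = 1L, lines = 2L, crops = 3L, pops = 4L,
              genotypes = 5L, response = 6L)
  (as.integer(config$seed) %% 100000L) * 10000L + stages[[stage]] * 1000L +
    as.integer(index)
}

# Von Mises sampler (Best & Fisher rejection method); kappa = 0 falls back
# to uniform angles.
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Generate one synthetic landscape window
#'
#' Builds a seeded land-use mosaic from a Voronoi partition of random
#' points with classes assigned greedily to approach the configured area
#' targets, draws linear elements as random-walk chains whose segment
#' angles follow a von Mises distribution, assigns per-year crops to
#' arable parcels and green fractions (Uniform(0.2, 0.8)) to settlements.
#'
#' @param config An [scenario_config()].
#' @param window_index Window number (1-based); enters the substream seed.
#' @return An [landscape_window()].
#' @export
generate_window <- function(config, window_index = 1L) {
  sz <- config$window_size_m
  set.seed(stage_seed(config, "window", window_index))
  pts <- cbind(stats::runif(config$n_parcels, 0, sz),
               stats::runif(config$n_parcels, 0, sz))
  cells <- voronoi_cells(pts, 0, 0, sz, sz)
  areas <- vapply(cells, poly_area, numeric(1))
  total <- sz^2
  targets <- c(config$class_targets,
               OTHER = max(0, 1 - sum(config$class_targets)))
  assigned <- stats::setNames(rep(0, length(targets)), names(targets))
  ord <- sample.int(length(cells))
  classes <- character(length(cells))
  for (i in ord) {
    deficit <- targets - assigned / total
    cl <- names(which.max(deficit))
    classes[i] <- cl
    assigned[cl] <- assigned[cl] + areas[i]
  }
  realized <- tapply(areas, classes, sum) / total
  if (any(abs(realized - targets[names(realized)]) > 0.10))
    warning("realized class areas deviate > 10 points from targets",
            call. = FALSE)
  green <- ifelse(classes == "SETTLE", stats::runif(length(cells), 0.2, 0.8),
                  NA_real_)
  set.seed(stage_seed(config, "crops", window_index))
  crops <- lapply(seq_along(cells), function(i) {
    if (classes[i] != "ARABLE") return(NULL)
    stats::setNames(sample(names(config$crop_probs), length(config$crop_years),
                           replace = TRUE, prob = config$crop_probs),
                    as.character(config$crop_years))
  })
  parcels <- tibble::tibble(
    class = classes, green_fraction = green, crops = crops,
    geometry = lapply(cells, function(g) {
      colnames(g) <- c("x", "y"); g
    }))
  set.seed(stage_seed(config, "lines", window_index))
  seg_len <- 200
  ext <- rect_poly(0, 0, sz, sz)
  lines <- list()
  for (lc in names(config$line_density)) {
    target_m <- config$line_density[[lc]] * total / 1e4
    n_chains <- max(1L, round(target_m / (10 * seg_len)))
    for (ch in seq_len(n_chains)) {
      p <- c(stats::runif(1, 0, sz), stats::runif(1, 0, sz))
      ang <- rvonmises(10, config$mean_angle, config$kappa)
      coords <- rbind(p)
      for (a in ang) {
        p <- p + seg_len * c(cos(a), sin(a))
        coords <- rbind(coords, p)
      }
      colnames(coords) <- c("x", "y")
      for (piece in clip_polyline_convex(coords, ext))
        lines[[length(lines) + 1L]] <- tibble::tibble(
          class = lc, geometry = list(piece))
    }
  }
  landscape_window(paste0("W", window_index), c(0, 0, sz, sz), parcels,
                   dplyr::bind_rows(lines), validate = FALSE)
}

#' Place populations in a window's forest fragments
#'
#' Selects forest parcels (greedily, honouring a minimum centre
#' separation), puts the population centre at the parcel centroid, keeps
#' the parcel polygon as the habitat patch and draws flowering-shoot
#' counts log-uniformly over the configured range.
#'
#' @param window An [landscape_window()].
#' @param config An [scenario_config()].
#' @return Tibble with `window`, `population`, `x`, `y`, `size` and a
#'   `patch` list column.
#' @export
place_populations <- function(window, config) {
  set.seed(stage_seed(config, "pops",
                      as.integer(sub("^W", "", window$window_id))))
  forest <- which(window$parcels$class == "FOREST")
  if (length(forest) < config$pops_per_window)
    warning("only ", length(forest), " forest parcels; placing fewer ",
            "populations than requested", call. = FALSE)
  forest <- sample(forest)
  centres <- list(); chosen <- integer(0)
  for (i in forest) {
    ctr <- poly_centroid(window$parcels$geometry[[i]])
    if (length(centres) > 0) {
      dmin <- min(vapply(centres, function(c2)
        sqrt(sum((ctr - c2)^2)), numeric(1)))
      if (dmin < config$min_separation) next
    }
    centres[[length(centres) + 1L]] <- ctr
    chosen <- c(chosen, i)
    if (length(chosen) == config$pops_per_window) break
  }
  n <- length(chosen)
  sizes <- exp(stats::runif(n, log(config$size_range[1]),
                            log(config$size_range[2])))
  patches <- lapply(chosen, function(i) window$parcels$geometry[[i]])
  tibble::tibble(
    window = window$window_id,
    population = paste0("P", seq_len(n)),
    x = vapply(centres, `[[`, numeric(1), 1),
    y = vapply(centres, `[[`, numeric(1), 2),
    size = sizes,
    patch = patches)
}

#' Simulate microsatellite genotypes with landscape-driven divergence
#'
#' Per locus, ancestral allele frequencies are drawn from a symmetric
#' Dirichlet(1); each population's frequencies are drawn from
#' `Dirichlet(ancestral * (1 - theta) / theta)` where
#' `theta = plogis(theta_a + theta_b * driver)` sets the population's
#' drift away from the common pool. Individuals are sampled i.i.d. from
#' the population frequencies at the configured ploidy. With
#' `theta_b > 0`, populations with larger driver values diverge more,
#' which raises their pairwise D_PS and G''ST.
#'
#' @param nodes Node tibble from [place_populations()] (all windows bound
#'   together).
#' @param driver Numeric driver value per node row (e.g. a landscape
#'   metric); recycled if length 1.
#' @param config An [scenario_config()].
#' @return An [genotype_table()] object.
#' @export
simulate_genotypes <- function(nodes, driver, config) {
  if (config$n_alleles < 2) stop("need >= 2 alleles per locus", call. = FALSE)
  set.seed(stage_seed(config, "genotypes"))
  driver <- rep_len(driver, nrow(nodes))
  dz <- if (stats::sd(driver) > 0) as.numeric(scale(driver)) else driver * 0
  theta <- stats::plogis(config$theta_a + config$theta_b * dz)
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
  }
  rows <- list()
  for (l in seq_len(config$n_loci)) {
    anc <- rdirichlet1(rep(1, config$n_alleles))
    for (i in seq_len(nrow(nodes))) {
      conc <- anc * (1 - theta[i]) / theta[i]
      p <- rdirichlet1(conc)
      for (ind in seq_len(config$n_ind)) {
        al <- sample(config$n_alleles, config$ploidy, replace = TRUE, prob = p)
        row <- list(window = nodes$window[i], population = nodes$population[i],
                    individual = paste0(nodes$window[i], "_",
                                        nodes$population[i], "_I", ind),
                    locus = paste0("L", l))
        for (k in seq_len(config$ploidy))
          row[[paste0("allele_", k)]] <- sprintf("%03d", al[k])
        rows[[length(rows) + 1L]] <- tibble::as_tibble_row(row)
      }
    }
  }
  genotype_table(dplyr::bind_rows(rows), ploidy = config$ploidy)
}

#' Simulate a response from the mixed-model generative process
#'
#' `y = X beta + window effect + population effects (link level) + noise`,
#' drawn exactly from the model assumed by [fit_mixed()], with the truth
#' recorded in attributes. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param data Data frame holding the predictor columns and grouping
#'   columns.
#' @param beta Named fixed-effect vector (names are columns of `data`;
#'   the name `"(Intercept)"` adds a constant).
#' @param sigma2_w,sigma2_p,sigma2_e Variance components (window,
#'   MLPE population, residual).
#' @param window Window column name.
#' @param pairs `NULL` or `c("pop1", "pop2")`.
#' @return Numeric response vector with attribute `truth`.
#' @export
simulate_response <- function(data, beta, sigma2_w = 0, sigma2_p = 0,
                              sigma2_e = 1, window = "window",
                              pairs = NULL) {
  n <- nrow(data)
  mu <- rep(0, n)
  for (nm in names(beta)) {
    if (nm == "(Intercept)") mu <- mu + beta[[nm]]
    else mu <- mu + beta[[nm]] * data[[nm]]
  }
  wf <- factor(data[[window]])
  bw <- stats::rnorm(nlevels(wf), 0, sqrt(sigma2_w))
  y <- mu + bw[as.integer(wf)]
  if (!is.null(pairs) && sigma2_p > 0) {
    pid <- factor(c(paste(data[[window]], data[[pairs[1]]], sep = "\r"),
                    paste(data[[window]], data[[pairs[2]]], sep = "\r")))
    bp <- stats::rnorm(nlevels(pid), 0, sqrt(sigma2_p))
    y <- y + bp[as.integer(pid[seq_len(n)])] +
      bp[as.integer(pid[n + seq_len(n)])]
  }
  y <- y + stats::rnorm(n, 0, sqrt(sigma2_e))
  attr(y, "truth") <- list(beta = beta, sigma2_w = sigma2_w,
                           sigma2_p = sigma2_p, sigma2_e = sigma2_e)
  y
}

#' Generate a full synthetic scenario
#'
#' Windows, populations and genotypes in one call. The genetic driver is
#' the configured node-level landscape metric (default forest cover in a
#' 1000 m buffer).
#'
#' @param config An [scenario_config()].
#' @return List with `windows` (list of `lg_window`), `nodes` (bound node
#'   tibble with a `driver` column) and `genotypes`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  windows <- lapply(seq_len(config$n_windows), function(i)
    generate_window(config, i))
  nodes <- dplyr::bind_rows(lapply(windows, place_populations, config = config))
  driver <- vapply(seq_len(nrow(nodes)), function(i) {
    w <- windows[[match(nodes$window[i], vapply(windows, `[[`, character(1),
                                                "window_id"))]]
    z <- make_buffer(c(nodes$x[i], nodes$y[i]), config$driver_scale, w)
    percent_cover(z, w, config$driver_metric)
  }, numeric(1))
  nodes$driver <- driver
  genotypes <- simulate_genotypes(nodes, driver, config)
  list(windows = windows, nodes = nodes, genotypes = genotypes,
       config = config)
}
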