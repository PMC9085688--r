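# Three-step multimodel inference: per-metric scale selection, LRT
# screening, collinearity reduction with principal-component composites,
# all-subsets AICc selection and full model averaging.
#
# Derived model terms are encoded in column names: `X__2` is the square of
# column X, `A__x__B` the product of A and B. Marginality (a quadratic
# requires its linear term, an interaction both mains) is enforced from
# these names during enumeration.

#' Describe a landscape-metric family
#'
#' A family is one landscape metric measured at several candidate scales
#' (buffer distances or strip ratios), with flags for the model terms it
#' may contribute: a quadratic term, a conditioning-variable interaction
#' (orientation ratios for linear elements, PROPGREEN for settlement) and,
#' at the link level, an interaction with geographic distance.
#'
#' @param metric Metric base name (e.g. `"FOREST"`).
#' @param scales Character/numeric vector of scale suffixes; data columns
#'   are `metric_scale`.
#' @param quadratic Allow a quadratic term if it lowers AICc.
#' @param conditioning Base name of a conditioning variable measured at the
#'   same scales (e.g. `"OP_LWOOD"`, `"PROPGREEN"`), or `NULL`.
#' @param distance_interaction Allow an interaction with the basic distance
#'   determinant (link level) if it lowers AICc.
#' @return An `lg_family`.
#' @export
metric_family <- function(metric, scales = NA_character_, quadratic = TRUE,
                          conditioning = NULL, distance_interaction = FALSE) {
  stopifnot(length(scales) >= 1)
  structure(list(metric = metric, scales = as.character(scales),
                 quadratic = quadratic, conditioning = conditioning,
                 distance_interaction = distance_interaction),
            class = "lg_family")
}

#' Default metric families for node- or link-level analysis
#'
#' @param level `"node"` or `"link"`.
#' @param crop_split Use RAPE/MAIZE/CEREAL instead of ARABLE.
#' @param scales Scale suffixes present in the metric table.
#' @return List of [metric_family()] objects.
#' @export
default_families <- function(level = c("node", "link"), crop_split = TRUE,
                             scales = NULL) {
  level <- match.arg(level)
  if (is.null(scales))
    scales <- if (level == "node") as.character(BUFFER_DISTANCES) else
      vapply(STRIP_RATIOS, ratio_label, character(1))
  di <- level == "link"
  base <- c("FOREST", "GRASS", "SEMNATGRASS", "SEMNATVEG", "ORCHARD")
  arable <- if (crop_split) c("RAPE", "MAIZE", "CEREAL") else "ARABLE"
  fams <- lapply(c(base, arable), function(m)
    metric_family(m, scales, distance_interaction = di))
  fams <- c(fams, list(
    metric_family("SETTLE", scales, conditioning = "PROPGREEN",
                  distance_interaction = di)))
  fams <- c(fams, lapply(LINE_CLASSES, function(l)
    metric_family(l, scales, conditioning = paste0("OP_", l),
                  distance_interaction = di)))
  c(fams, list(metric_family("SHANNON", scales, distance_interaction = di),
               metric_family("EDGEDEN", scales, distance_interaction = di)))
}

# Data column holding a chosen family's linear metric term.
#' @keywords internal
chosen_col <- function(ch) {
  if (is.null(ch$scale) || is.na(ch$scale)) ch$family$metric
  else paste0(ch$family$metric, "_", ch$scale)
}

# Materialize derived columns (squares, products) needed by `terms`.
#' @keywords internal
ensure_terms <- function(data, terms) {
  for (tm in terms) {
    if (!is.null(data[[tm]])) next
    if (grepl("__x__", tm, fixed = TRUE)) {
      ab <- strsplit(tm, "__x__", fixed = TRUE)[[1]]
      if (is.null(data[[ab[1]]]) || is.null(data[[ab[2]]]))
        stop("cannot build interaction ", tm, call. = FALSE)
      data[[tm]] <- data[[ab[1]]] * data[[ab[2]]]
    } else if (grepl("__2$", tm)) {
      b <- sub("__2$", "", tm)
      if (is.null(data[[b]])) stop("cannot build quadratic ", tm, call. = FALSE)
      data[[tm]] <- data[[b]]^2
    } else stop("unknown term column ", tm, call. = FALSE)
  }
  data
}

#' @keywords internal
term_requirements <- function(tm) {
  if (grepl("__x__", tm, fixed = TRUE))
    strsplit(tm, "__x__", fixed = TRUE)[[1]]
  else if (grepl("__2$", tm)) sub("__2$", "", tm)
  else character(0)
}

#' @keywords internal
obeys_marginality <- function(terms, available = terms) {
  all(vapply(terms, function(tm)
    all(term_requirements(tm) %in% available), logical(1)))
}

#' Step 1: choose a family's most influential scale
#'
#' For every candidate scale, single-metric models (basic determinants +
#' the metric) are fitted by ML; conditioning-variable interactions are
#' always included where the family defines one, while the quadratic term
#' and the distance interaction are kept only when they lower AICc
#' (decided by exhaustive comparison of the 1-4 candidate fits per scale).
#' The scale with the lowest AICc wins; ties break toward the smaller
#' scale and then the simpler model.
#'
#' @param family An [metric_family()].
#' @param data Transformed, standardized data.
#' @param basic_terms Character vector of mandatory basic determinants.
#' @param response,window,pairs Passed to [fit_mixed()].
#' @param distance_col Column for distance interactions (link level).
#' @return List with `family`, `scale`, `terms` (landscape terms only),
#'   `fit` (ML), `aicc`, or `NULL` if every candidate fit failed.
#' @export
select_scale <- function(family, data, basic_terms, response,
                         window = "window", pairs = NULL,
                         distance_col = NULL) {
  best <- NULL
  for (s in family$scales) {
    # NA scale: the metric column carries no scale suffix (composites)
    m <- if (is.na(s)) family$metric else paste0(family$metric, "_", s)
    if (is.null(data[[m]])) next
    if (stats::sd(data[[m]]) < 1e-12) next
    core <- m
    if (!is.null(family$conditioning)) {
      cond <- if (is.na(s)) family$conditioning else
        paste0(family$conditioning, "_", s)
      if (!is.null(data[[cond]]) && stats::sd(data[[cond]]) > 1e-12)
        core <- c(m, cond, paste0(m, "__x__", cond))
    }
    quad_opts <- if (family$quadratic) list(character(0), paste0(m, "__2"))
                 else list(character(0))
    dist_opts <- if (family$distance_interaction && !is.null(distance_col))
      list(character(0), paste0(m, "__x__", distance_col))
    else list(character(0))
    for (q in quad_opts) for (d in dist_opts) {
      terms <- c(core, q, d)
      dat <- ensure_terms(data, terms)
      fit <- tryCatch(
        fit_mixed(dat, response, c(basic_terms, terms), window, pairs,
                  method = "ML"),
        error = function(e) NULL)
      if (is.null(fit)) next
      cand <- list(family = family, scale = s, terms = terms, fit = fit,
                   aicc = fit$AICc)
      if (is.null(best) || cand$aicc < best$aicc - 1e-9 ||
          (abs(cand$aicc - best$aicc) <= 1e-9 &&
           length(cand$terms) < length(best$terms)))
        best <- cand
    }
  }
  best
}

#' Step 1b: screen a chosen single-metric model
#'
#' Likelihood ratio test of the chosen model against the basic model
#' (all metric-related terms dropped jointly); the family is kept when
#' `p < alpha`.
#'
#' @param chosen Result of [select_scale()].
#' @param basic_fit ML fit of the basic model on the same data.
#' @param alpha Screening level (default 0.15).
#' @return List with `keep`, `p.value`, `statistic`, `df`.
#' @export
screen_family <- function(chosen, basic_fit, alpha = 0.15) {
  lr <- lrt(chosen$fit, basic_fit)
  list(keep = lr$p.value < alpha, p.value = lr$p.value,
       statistic = lr$statistic, df = lr$df)
}

#' Step 2: reduce collinearity among kept metrics
#'
#' Pearson correlations among the kept (standardized) metric columns are
#' computed; clusters of metrics connected by `|r| >= r_threshold` are
#' replaced by the standardized first principal-component score of their
#' columns, sign-oriented to correlate positively with the cluster's
#' first-named metric. Clusters listed in `intrinsic` (or all clusters,
#' the default) are composited; for pairs declared non-intrinsic the
#' member with the lower single-metric AICc is kept and the other dropped.
#'
#' @param data Transformed data.
#' @param kept List of [select_scale()] results that passed screening.
#' @param r_threshold Correlation threshold (default 0.7).
#' @param intrinsic `TRUE` to composite every collinear cluster, or a list
#'   of character vectors naming metric columns that belong together;
#'   collinear pairs not covered are resolved by AICc.
#' @return List with `data` (augmented with composite columns), `kept`
#'   (updated chosen list; composites appear as new single-scale
#'   families), and `composites` (tibble of loadings).
#' @export
reduce_collinearity <- function(data, kept, r_threshold = 0.7,
                                intrinsic = TRUE) {
  if (length(kept) < 2)
    return(list(data = data, kept = kept,
                composites = tibble::tibble(composite = character(),
                                            member = character(),
                                            loading = numeric(),
                                            cor_with_pc = numeric())))
  cols <- vapply(kept, chosen_col, character(1))
  cm <- stats::cor(as.matrix(data[cols]))
  adj <- abs(cm) >= r_threshold
  diag(adj) <- FALSE
  # connected components
  comp_id <- seq_along(cols)
  repeat {
    changed <- FALSE
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (adj[i, j] && comp_id[j] != comp_id[i]) {
        comp_id[comp_id == comp_id[j]] <- comp_id[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep_idx <- rep(TRUE, length(cols))
  new_kept <- kept
  comp_rows <- list()
  for (cid in unique(comp_id)) {
    members <- which(comp_id == cid)
    if (length(members) < 2) next
    mcols <- cols[members]
    is_intr <- isTRUE(intrinsic) ||
      (is.list(intrinsic) && any(vapply(intrinsic, function(g)
        all(mcols %in% g), logical(1))))
    if (is_intr) {
      pc <- stats::prcomp(as.matrix(data[mcols]), center = TRUE, scale. = TRUE)
      score <- pc$x[, 1] / pc$sdev[1]
      if (stats::cor(score, data[[mcols[1]]]) < 0) {
        score <- -score
        pc$rotation[, 1] <- -pc$rotation[, 1]
      }
      nm <- paste0("pc_", paste(mcols, collapse = "."))
      data[[nm]] <- score
      comp_rows[[length(comp_rows) + 1L]] <- tibble::tibble(
        composite = nm, member = mcols,
        loading = pc$rotation[, 1],
        cor_with_pc = vapply(mcols, function(m)
          stats::cor(score, data[[m]]), numeric(1)))
      keep_idx[members] <- FALSE
      quad <- any(vapply(kept[members], function(ch) ch$family$quadratic,
                         logical(1)))
      di <- any(vapply(kept[members], function(ch)
        ch$family$distance_interaction, logical(1)))
      new_kept[[length(new_kept) + 1L]] <- list(
        family = metric_family(nm, scales = NA_character_, quadratic = quad,
                               distance_interaction = di),
        scale = NA_character_, terms = nm, fit = NULL, aicc = NA_real_,
        composite = TRUE)
    } else {
      aiccs <- vapply(kept[members], function(ch) ch$aicc, numeric(1))
      drop <- members[-which.min(aiccs)]
      keep_idx[drop] <- FALSE
    }
  }
  new_kept <- c(new_kept[seq_along(kept)][keep_idx],
                new_kept[-seq_along(kept)])
  list(data = data, kept = new_kept,
       composites = if (length(comp_rows)) dplyr::bind_rows(comp_rows) else
         tibble::tibble(composite = character(), member = character(),
                        loading = numeric(), cor_with_pc = numeric()))
}

#' Step 3a: enumerate candidate models
#'
#' All subsets of the global landscape terms that obey marginality and a
#' cap on the number of landscape terms (4 at the node level, 9 at the
#' link level). Every subset keeps the mandatory basic terms.
#'
#' @param terms Character vector of landscape term columns.
#' @param max_terms Cap on landscape terms per model.
#' @return List of character vectors (possibly empty) of landscape terms.
#' @export
enumerate_models <- function(terms, max_terms) {
  n <- length(terms)
  sizes <- 0:min(max_terms, n)
  total <- sum(choose(n, sizes))
  if (total > 1e5)
    stop("enumeration would produce ", total, " subsets; reduce the global ",
         "model or lower max_terms", call. = FALSE)
  out <- list(character(0))
  for (k in sizes[sizes > 0]) {
    cmb <- utils::combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      sub <- terms[cmb[, j]]
      if (obeys_marginality(sub)) out[[length(out) + 1L]] <- sub
    }
  }
  out
}

#' Step 3b: AICc model averaging with importance values
#'
#' Candidate ML fits within `delta` AICc of the best are refit with REML
#' and fully averaged: Akaike weights come from the ML AICc values,
#' coefficients from the REML refits, and a term absent from a component
#' model contributes zero (full averaging). The importance of a term is
#' the summed weight of the component models containing it. The R-squared
#' of the average model is computed on the single best component model
#' containing all important terms.
#'
#' @param fits List of ML `lg_fit` candidates (same data and response).
#' @param data The model data (needed for REML refits).
#' @param basic_fit REML fit of the basic model (for the landscape
#'   R-squared decomposition); if an ML fit is passed it is refit.
#' @param delta AICc window for component models (default 2).
#' @param importance_cutoff Reporting threshold (default 0.5).
#' @return An `lg_avg` object.
#' @export
average_models <- function(fits, data, basic_fit, delta = 2,
                           importance_cutoff = 0.5) {
  aiccs <- vapply(fits, function(f) f$AICc, numeric(1))
  dlt <- aiccs - min(aiccs)
  comp_idx <- which(dlt < delta)
  w <- exp(-dlt[comp_idx] / 2)
  w <- w / sum(w)
  comp <- fits[comp_idx]
  reml <- lapply(comp, refit_mixed, data = data, method = "REML")
  if (basic_fit$method != "REML")
    basic_fit <- refit_mixed(basic_fit, data, "REML")
  all_terms <- unique(unlist(lapply(comp, function(f) f$fixed)))
  basic_terms <- basic_fit$fixed
  avg <- vapply(c("(Intercept)", all_terms), function(tm) {
    sum(vapply(seq_along(reml), function(i) {
      b <- reml[[i]]$coefficients
      w[i] * if (tm %in% names(b)) b[[tm]] else 0
    }, numeric(1)))
  }, numeric(1))
  avg_se <- vapply(c("(Intercept)", all_terms), function(tm) {
    sqrt(sum(vapply(seq_along(reml), function(i) {
      b <- reml[[i]]$coefficients
      s <- reml[[i]]$se
      if (tm %in% names(b)) w[i] * (s[[tm]]^2 + (b[[tm]] - avg[[tm]])^2)
      else w[i] * avg[[tm]]^2
    }, numeric(1))))
  }, numeric(1))
  importance <- vapply(c("(Intercept)", all_terms), function(tm) {
    sum(w[vapply(comp, function(f)
      tm == "(Intercept)" || tm %in% f$fixed, logical(1))])
  }, numeric(1))
  important <- setdiff(names(importance)[importance >= importance_cutoff],
                       "(Intercept)")
  # best component model containing all important terms (refit with
  # exactly those terms if no component holds them all)
  holds_all <- vapply(comp, function(f) all(important %in% f$fixed),
                      logical(1))
  best_fit <- if (any(holds_all)) {
    reml[[which(holds_all)[which.min(aiccs[comp_idx][holds_all])]]]
  } else {
    fit_mixed(ensure_terms(data, important), comp[[1]]$response, important,
              comp[[1]]$window, comp[[1]]$pairs, method = "REML")
  }
  r2_marg <- marginal_r2(best_fit)
  r2_basic <- marginal_r2(basic_fit)
  component_tbl <- tibble::tibble(
    terms = vapply(comp, function(f)
      paste(setdiff(f$fixed, basic_terms), collapse = " + "), character(1)),
    k = vapply(comp, function(f) f$k, numeric(1)),
    logLik = vapply(comp, function(f) f$logLik, numeric(1)),
    AICc = aiccs[comp_idx], delta = dlt[comp_idx], weight = w)
  structure(list(
    components = component_tbl[order(component_tbl$delta), ],
    coefficients = tibble::tibble(
      term = names(avg), estimate = unname(avg),
      std.error = unname(avg_se), importance = unname(importance)),
    basic_terms = basic_terms,
    important_terms = important,
    importance_cutoff = importance_cutoff,
    r2 = list(marginal = r2_marg, basic = r2_basic,
              landscape = r2_marg - r2_basic,
              pct_landscape = if (r2_marg > 0)
                100 * (r2_marg - r2_basic) / r2_marg else NA_real_),
    best_fit = best_fit, basic_fit = basic_fit,
    n_candidates = length(fits)), class = "lg_avg")
}

#' Landscape R-squared decomposition
#'
#' The variation explained uniquely by landscape metrics: the difference
#' between the average model's marginal R-squared and the basic model's
#' (population size/isolation or distance only), plus the share of the
#' marginal R-squared attributable to the landscape. Negative differences
#' are reported, not clamped.
#'
#' @param marginal Marginal R-squared of the average model (or an `lg_avg`,
#'   from which both values are taken).
#' @param basic Marginal R-squared of the basic model.
#' @return List with `landscape_R2` and `pct_landscape`.
#' @export
landscape_r2 <- function(marginal, basic = NULL) {
  if (inherits(marginal, "lg_avg")) {
    basic <- marginal$r2$basic
    marginal <- marginal$r2$marginal
  }
  list(landscape_R2 = marginal - basic,
       pct_landscape = if (marginal != 0) 100 * (marginal - basic) / marginal
                       else NA_real_)
}

#' @export
print.lg_avg <- function(x, ...) {
  cat("<lg_avg> ", nrow(x$components), " component model(s) of ",
      x$n_candidates, " candidates\n", sep = "")
  cat("marginal R2 ", round(x$r2$marginal, 3), ", landscape R2 ",
      round(x$r2$landscape, 3), " (", round(x$r2$pct_landscape, 1),
      "%)\n", sep = "")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Tidy an averaged model
#' @param x An `lg_avg`.
#' @param ... Unused.
#' @method tidy lg_avg
#' @export
tidy.lg_avg <- function(x, ...) x$coefficients

#' One-row summary of an averaged model
#' @param x An `lg_avg`.
#' @param ... Unused.
#' @method glance lg_avg
#' @export
glance.lg_avg <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$components),
                 n_candidates = x$n_candidates,
                 r2_marginal = x$r2$marginal, r2_basic = x$r2$basic,
                 r2_landscape = x$r2$landscape,
                 pct_landscape = x$r2$pct_landscape)
}
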