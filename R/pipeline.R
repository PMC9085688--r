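# End-to-end node- and link-level analyses: popgen statistics, landscape
# metrics, transformation, three-step selection and model averaging, and
# Table-style reporting with effect-shape symbols.

#' Analysis configuration
#'
#' Holds the pipeline's fixed constants. The defaults are the study
#' design's: buffers 125-2000 m, strip ratios 1:7-2:3, LRT screening at
#' alpha = 0.15, collinearity threshold |r| >= 0.7, at most 4 (node) or
#' 9 (link) landscape terms per model, delta-AICc < 2 component models,
#' importance reporting cutoff 0.5.
#'
#' @param buffers Buffer distances (m).
#' @param ratios Strip width-to-length ratios.
#' @param alpha LRT screening level.
#' @param delta AICc window for component models.
#' @param r_threshold Collinearity threshold on |Pearson r|.
#' @param max_terms_node,max_terms_link Landscape-term caps.
#' @param importance_cutoff Reporting threshold on importance values.
#' @param conn_alpha,conn_b Hanski connectivity parameters (1/m, unitless).
#' @param corrected Sample-size-corrected He / G''ST.
#' @param crop_split `"auto"` compares the crop-split and ARABLE variants
#'   and reports the one with the higher marginal R-squared (ties favour
#'   the crop split); `TRUE`/`FALSE` force a variant.
#' @param max_models Budget on the number of candidate models in the
#'   all-subsets step; the weakest-screened families are dropped from the
#'   global model until the enumeration fits the budget.
#' @param seed Seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(buffers = BUFFER_DISTANCES, ratios = STRIP_RATIOS,
                       alpha = 0.15, delta = 2, r_threshold = 0.7,
                       max_terms_node = 4, max_terms_link = 9,
                       importance_cutoff = 0.5,
                       conn_alpha = 1/1000, conn_b = 0.5,
                       corrected = TRUE, crop_split = "auto",
                       max_models = 10000, seed = 1L) {
  stopifnot(alpha > 0, delta > 0, r_threshold > 0, max_terms_node >= 1,
            max_terms_link >= 1, importance_cutoff > 0, conn_alpha > 0)
  structure(list(buffers = buffers, ratios = ratios, alpha = alpha,
                 delta = delta, r_threshold = r_threshold,
                 max_terms_node = max_terms_node,
                 max_terms_link = max_terms_link,
                 importance_cutoff = importance_cutoff,
                 conn_alpha = conn_alpha, conn_b = conn_b,
                 corrected = corrected, crop_split = crop_split,
                 max_models = max_models,
                 seed = as.integer(seed)), class = "run_config")
}

# One response variable through steps 1-3 for a fixed family set.
#' @keywords internal
run_selection <- function(data, response, basic_terms, families,
                          window = "window", pairs = NULL,
                          distance_col = NULL, config = run_config(),
                          intrinsic = TRUE) {
  basic_fit <- fit_mixed(data, response, basic_terms, window, pairs,
                         method = "ML")
  chosen <- list(); screen_tbl <- list()
  for (fam in families) {
    ch <- select_scale(fam, data, basic_terms, response, window, pairs,
                       distance_col)
    if (is.null(ch)) next
    sc <- screen_family(ch, basic_fit, alpha = config$alpha)
    screen_tbl[[length(screen_tbl) + 1L]] <- tibble::tibble(
      metric = fam$metric, scale = ch$scale, p.value = sc$p.value,
      kept = sc$keep)
    if (sc$keep) {
      ch$p.value <- sc$p.value
      chosen[[length(chosen) + 1L]] <- ch
    }
  }
  screen_tbl <- if (length(screen_tbl)) dplyr::bind_rows(screen_tbl) else
    tibble::tibble(metric = character(), scale = character(),
                   p.value = numeric(), kept = logical())
  if (length(chosen) == 0) {
    avg <- average_models(list(basic_fit), data, basic_fit,
                          delta = config$delta,
                          importance_cutoff = config$importance_cutoff)
    return(list(avg = avg, screened = screen_tbl,
                composites = tibble::tibble(), data = data,
                global_terms = character(0)))
  }
  red <- reduce_collinearity(data, chosen, r_threshold = config$r_threshold,
                             intrinsic = intrinsic)
  data <- red$data
  # composites go through scale selection once to settle their extra terms
  kept_terms <- list()
  for (ch in red$kept) {
    if (isTRUE(ch$composite)) {
      ch2 <- select_scale(ch$family, data, basic_terms, response, window,
                          pairs, distance_col)
      if (!is.null(ch2)) ch <- ch2
    }
    kept_terms[[length(kept_terms) + 1L]] <- ch$terms
  }
  cap <- if (is.null(pairs)) config$max_terms_node else config$max_terms_link
  # guard: an over-full global model would make all-subsets enumeration
  # intractable; drop the weakest-screened families until it is feasible
  n_subsets <- function(tl) {
    n <- length(unique(unlist(tl)))
    sum(choose(n, 0:min(cap, n)))
  }
  pvals <- vapply(red$kept, function(ch)
    if (is.null(ch$p.value)) -Inf else ch$p.value, numeric(1))
  budget <- min(config$max_models %||% 10000, 1e5)
  while (length(kept_terms) > 1 && n_subsets(kept_terms) > budget) {
    worst <- which.max(pvals)
    kept_terms <- kept_terms[-worst]
    pvals <- pvals[-worst]
  }
  global_terms <- unique(unlist(kept_terms))
  subsets <- enumerate_models(global_terms, cap)
  data <- ensure_terms(data, global_terms)
  fits <- list()
  for (sub in subsets) {
    f <- tryCatch(fit_mixed(data, response, c(basic_terms, sub), window,
                            pairs, method = "ML"),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  avg <- average_models(fits, data, basic_fit, delta = config$delta,
                        importance_cutoff = config$importance_cutoff)
  list(avg = avg, screened = screen_tbl, composites = red$composites,
       data = data, global_terms = global_terms)
}

# Run one response with the crop-split vs ARABLE comparison.
#' @keywords internal
run_response <- function(data, response, basic_terms, level, scales,
                         window, pairs, distance_col, config,
                         intrinsic = TRUE) {
  keep <- !is.na(data[[response]])
  dat <- data[keep, , drop = FALSE]
  variants <- list()
  want <- if (identical(config$crop_split, "auto")) c(TRUE, FALSE) else
    isTRUE(config$crop_split)
  for (cs in want) {
    fams <- default_families(level, crop_split = cs, scales = scales)
    variants[[if (cs) "crops" else "arable"]] <-
      run_selection(dat, response, basic_terms, fams, window, pairs,
                    distance_col, config, intrinsic)
  }
  if (length(variants) == 1) {
    pick <- names(variants)[1]
  } else {
    r2c <- variants$crops$avg$r2$marginal
    r2a <- variants$arable$avg$r2$marginal
    pick <- if (r2c >= r2a) "crops" else "arable"   # ties favour crop split
  }
  c(variants[[pick]], list(variant = pick, variants = variants))
}

#' @keywords internal
metric_columns <- function(data, id_cols) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], id_cols)
}

#' @keywords internal
transform_model_data <- function(data, exclude = character()) {
  cand <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], exclude)
  dropped <- character(0)
  specs <- list()
  for (cl in cand) {
    x <- data[[cl]]
    if (any(is.na(x)) && all(is.na(x))) { dropped <- c(dropped, cl); next }
    ok <- !is.na(x)
    if (stats::sd(x[ok]) < 1e-10 || sum(ok) < 3) {
      dropped <- c(dropped, cl)
      data[[cl]] <- NULL
      next
    }
    sp <- tryCatch(fit_transform(x[ok]), error = function(e) NULL)
    if (is.null(sp)) { dropped <- c(dropped, cl); data[[cl]] <- NULL; next }
    data[[cl]][ok] <- apply_transform(sp, x[ok])
    specs[[cl]] <- sp
  }
  list(data = data, specs = specs, dropped = dropped)
}

#' Node-level analysis: landscape effects on genetic diversity
#'
#' Runs the full node-level pipeline: within-population diversity (Ar, He,
#' Ho, F), Hanski connectivity, buffer landscape metrics at all configured
#' distances, Box-Cox standardization, and the three-step model selection
#' with full averaging, separately for each diversity response. Both the
#' crop-split and the lumped-ARABLE variants are run; the variant with the
#' higher marginal R-squared is reported.
#'
#' @param windows A single [landscape_window()] or list of them.
#' @param nodes Tibble with `window`, `population`, `x`, `y`, `size`.
#' @param genotypes An [genotype_table()] object.
#' @param config A [run_config()].
#' @param intrinsic Collinearity grouping passed to
#'   [reduce_collinearity()].
#' @return An `lg_result` with one averaged model per response.
#' @export
run_node <- function(windows, nodes, genotypes, config = run_config(),
                     intrinsic = TRUE) {
  if (inherits(windows, "lg_window")) windows <- list(windows)
  div <- pop_diversity(genotypes, corrected = config$corrected)
  if (nrow(div) < 20)
    warning("fewer than 20 usable populations; estimates will be unstable",
            call. = FALSE)
  met <- dplyr::bind_rows(lapply(windows, compute_node_metrics, nodes = nodes,
                                 scales = config$buffers))
  nodes <- hanski_connectivity(nodes, alpha = config$conn_alpha,
                               b = config$conn_b)
  base_cols <- if ("patch" %in% names(nodes))
    nodes[setdiff(names(nodes), "patch")] else nodes
  data <- div |>
    dplyr::inner_join(base_cols, by = c("window", "population")) |>
    dplyr::inner_join(met, by = c("window", "population"))
  tr <- transform_model_data(
    data, exclude = c("x", "y", "n_individuals", "rarefaction_g",
                      "connectivity"))
  responses <- intersect(c("Ar", "He", "Ho", "F"), names(tr$data))
  res <- lapply(responses, function(rv)
    run_response(tr$data, rv, basic_terms = c("size", "isolation"),
                 level = "node", scales = as.character(config$buffers),
                 window = "window", pairs = NULL, distance_col = NULL,
                 config = config, intrinsic = intrinsic))
  names(res) <- responses
  structure(list(level = "node", responses = res, data = tr$data,
                 transforms = tr$specs, dropped = tr$dropped,
                 diversity = div, metrics = met, config = config),
            class = "lg_result")
}

#' Link-level analysis: landscape effects on genetic differentiation
#'
#' Runs the full link-level pipeline: pairwise G''ST and D_PS with
#' edge-to-edge (or centre) distances, strip landscape metrics at all
#' configured width-to-length ratios, Box-Cox standardization, and the
#' three-step selection with MLPE mixed models (population-pair
#' correlation) and full averaging. Windows holding a single population
#' contribute no pairs and are skipped with a warning.
#'
#' @inheritParams run_node
#' @return An `lg_result` with one averaged model per response
#'   (`Gst_dp`, `Dps`).
#' @export
run_link <- function(windows, nodes, genotypes, config = run_config(),
                     intrinsic = TRUE) {
  if (inherits(windows, "lg_window")) windows <- list(windows)
  singles <- nodes |>
    dplyr::count(.data$window) |>
    dplyr::filter(.data$n < 2)
  if (nrow(singles) > 0)
    warning("windows with a single population skipped: ",
            paste(singles$window, collapse = ", "), call. = FALSE)
  diff <- pop_differentiation(genotypes, nodes = nodes,
                              corrected = config$corrected)
  met <- dplyr::bind_rows(lapply(windows, compute_link_metrics, nodes = nodes,
                                 ratios = config$ratios))
  met <- dplyr::select(met, -"distance_m")
  data <- dplyr::inner_join(diff, met, by = c("window", "pop1", "pop2"))
  tr <- transform_model_data(data, exclude = character())
  responses <- intersect(c("Gst_dp", "Dps"), names(tr$data))
  res <- lapply(responses, function(rv)
    run_response(tr$data, rv, basic_terms = "distance_m", level = "link",
                 scales = vapply(config$ratios, ratio_label, character(1)),
                 window = "window", pairs = c("pop1", "pop2"),
                 distance_col = "distance_m", config = config,
                 intrinsic = intrinsic))
  names(res) <- responses
  structure(list(level = "link", responses = res, data = tr$data,
                 transforms = tr$specs, dropped = tr$dropped,
                 differentiation = diff, metrics = met, config = config),
            class = "lg_result")
}

#' @export
print.lg_result <- function(x, ...) {
  cat("<lg_result> ", x$level, "-level analysis, ",
      length(x$responses), " response(s): ",
      paste(names(x$responses), collapse = ", "), "\n", sep = "")
  print(report(x))
  invisible(x)
}

#' Effect-shape code from averaged coefficients
#'
#' `/` and `\` are positive and negative linear effects; `∩`/`∪` unimodal
#' effects whose vertex lies in the central half of the predictor range;
#' `/∩`, `\∩`, `/∪`, `\∪` asymmetric unimodal effects whose overall trend
#' over the range is positive or negative; `X` an effect involving an
#' important interaction.
#'
#' @param beta_l Linear coefficient.
#' @param beta_q Quadratic coefficient or `NA` when no quadratic term is
#'   important.
#' @param xr Range of the (standardized) predictor, `c(min, max)`.
#' @param interactive Any important interaction with the term?
#' @return A single shape string.
#' @export
shape_code <- function(beta_l, beta_q = NA, xr = c(-2, 2),
                       interactive = FALSE) {
  if (interactive) return("X")
  if (is.na(beta_q) || beta_q == 0)
    return(if (beta_l >= 0) "/" else "\\")
  base <- if (beta_q < 0) "∩" else "∪"
  vertex <- -beta_l / (2 * beta_q)
  R <- xr[2] - xr[1]
  central <- c(xr[1] + 0.25 * R, xr[2] - 0.25 * R)
  if (vertex >= central[1] && vertex <= central[2]) return(base)
  f <- function(x) beta_l * x + beta_q * x^2
  trend <- f(xr[2]) - f(xr[1])
  paste0(if (trend >= 0) "/" else "\\", base)
}

#' @keywords internal
pretty_term <- function(tm) {
  tm <- gsub("__x__", " × ", tm, fixed = TRUE)
  tm <- gsub("__2", "²", tm, fixed = TRUE)
  tm <- gsub("OP_", "O:P_", tm, fixed = TRUE)
  gsub("_([0-9])to([0-9])", "_\\1:\\2", tm)
}

#' Report landscape effects in Table style
#'
#' Summarises each response's averaged model: the important landscape
#' terms (importance >= the configured cutoff) grouped by metric with
#' their effect-shape symbol, followed by the R-squared decomposition
#' (marginal, landscape, %Landscape).
#'
#' @param result An `lg_result` from [run_node()] or [run_link()].
#' @return A tibble with columns `response`, `metric`, `shape`,
#'   `importance`, `r2_marginal`, `r2_landscape`, `pct_landscape`; printed
#'   with a text formatter.
#' @export
report <- function(result) {
  out <- list()
  for (rv in names(result$responses)) {
    rr <- result$responses[[rv]]
    avg <- rr$avg
    co <- avg$coefficients
    imp_terms <- avg$important_terms
    land_terms <- setdiff(imp_terms, avg$basic_terms)
    # group important terms by their base (linear) metric column
    bases <- unique(unlist(lapply(land_terms, function(tm) {
      req <- term_requirements(tm)
      if (length(req) == 0) tm else
        setdiff(req, c(avg$basic_terms, "distance_m"))
    })))
    for (b in bases) {
      related <- land_terms[vapply(land_terms, function(tm)
        tm == b || b %in% term_requirements(tm), logical(1))]
      bl <- co$estimate[co$term == b]
      if (length(bl) == 0) bl <- 0
      qn <- paste0(b, "__2")
      bq <- if (qn %in% related) co$estimate[co$term == qn] else NA
      interactive <- any(grepl("__x__", related, fixed = TRUE))
      xr <- if (b %in% names(result$data))
        range(result$data[[b]], na.rm = TRUE) else c(-2, 2)
      out[[length(out) + 1L]] <- tibble::tibble(
        response = rv, metric = pretty_term(b),
        shape = shape_code(bl, bq, xr, interactive),
        importance = max(co$importance[co$term %in% related]),
        r2_marginal = avg$r2$marginal, r2_landscape = avg$r2$landscape,
        pct_landscape = avg$r2$pct_landscape,
        variant = rr$variant)
    }
    if (length(bases) == 0)
      out[[length(out) + 1L]] <- tibble::tibble(
        response = rv, metric = NA_character_, shape = NA_character_,
        importance = NA_real_, r2_marginal = avg$r2$marginal,
        r2_landscape = avg$r2$landscape,
        pct_landscape = avg$r2$pct_landscape, variant = rr$variant)
  }
  dplyr::bind_rows(out)
}

#' Render a report as plain text
#'
#' @param result An `lg_result`.
#' @return Character vector of report lines (invisibly); printed.
#' @export
report_text <- function(result) {
  tb <- report(result)
  lines <- c(sprintf("Landscape effects (%s level)", result$level),
             strrep("-", 46))
  for (rv in unique(tb$response)) {
    sub <- tb[tb$response == rv, ]
    lines <- c(lines, sprintf("%s  [%s variant]", rv, sub$variant[1]))
    for (i in seq_len(nrow(sub))) {
      if (!is.na(sub$metric[i]))
        lines <- c(lines, sprintf("  %-28s %-3s (importance %.2f)",
                                  sub$metric[i], sub$shape[i],
                                  sub$importance[i]))
    }
    lines <- c(lines,
               sprintf("  Marginal R2  %.3f", sub$r2_marginal[1]),
               sprintf("  Landscape R2 %.3f", sub$r2_landscape[1]),
               sprintf("  %% Landscape  %.1f", sub$pct_landscape[1]), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
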