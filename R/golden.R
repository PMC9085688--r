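# Golden regression fixture: a pinned miniature scenario whose end-to-end
# outputs are stored under version control and must reproduce exactly.

#' Configuration of the golden fixture scenario
#'
#' Two 3 x 3 km windows, four populations each, five loci; small enough to
#' run end-to-end in well under a minute, with a real landscape-driven
#' divergence signal (`theta_b = 0.6`).
#'
#' @return An [scenario_config()].
#' @export
golden_config <- function() {
  scenario_config(seed = 42L, n_windows = 2L, window_size_m = 3000,
                  pops_per_window = 4L, n_parcels = 40L,
                  n_loci = 5L, n_alleles = 6L, n_ind = 8L,
                  theta_a = -2.2, theta_b = 0.6, min_separation = 200)
}

#' Run the golden fixture end-to-end
#'
#' Simulates the pinned scenario, runs the link-level pipeline with a
#' reduced strip-ratio set, and collects the outputs that the regression
#' test freezes: the diversity and differentiation tables, the component
#' models, the averaged coefficients with importances, and the R-squared
#' decomposition.
#'
#' @return List of plain tibbles/lists, JSON-serializable.
#' @export
golden_outputs <- function() {
  cfg <- golden_config()
  scn <- simulate_scenario(cfg)
  rc <- run_config(ratios = c("1:3", "1:2"), seed = cfg$seed)
  res <- run_link(scn$windows, scn$nodes, scn$genotypes, config = rc)
  div <- pop_diversity(scn$genotypes)
  list(
    diversity = as.data.frame(div),
    differentiation = as.data.frame(res$differentiation),
    report = as.data.frame(report(res)),
    coefficients = lapply(res$responses, function(r)
      as.data.frame(r$avg$coefficients)),
    r2 = lapply(res$responses, function(r) r$avg$r2))
}

#' Create (or refresh) the stored golden fixture
#'
#' @param path Output JSON path; defaults to the version-controlled copy
#'   under `inst/extdata/golden`.
#' @return The outputs, invisibly.
#' @export
make_golden_fixture <- function(path = NULL) {
  out <- golden_outputs()
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(out)
}

#' @keywords internal
golden_path <- function() {
  system.file("extdata", "golden", "golden.json", package = "agrolandgen")
}

#' Write pipeline outputs to CSV/JSON files
#'
#' Emits the standard output set for an [run_node()]/[run_link()] result:
#' the popgen table (`diversity.csv` or `differentiation.csv`), the metric
#' table (`metrics.csv`), per-response averaged-model JSON summaries and a
#' metadata JSON recording the configuration.
#'
#' @param result An `lg_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  popgen <- if (result$level == "node") result$diversity else
    result$differentiation
  utils::write.csv(popgen,
                   file.path(dir, paste0(
                     if (result$level == "node") "diversity" else
                       "differentiation", ".csv")),
                   row.names = FALSE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (rv in names(result$responses)) {
    rr <- result$responses[[rv]]
    jsonlite::write_json(
      list(variant = rr$variant,
           components = as.data.frame(rr$avg$components),
           coefficients = as.data.frame(rr$avg$coefficients),
           r2 = rr$avg$r2,
           screened = as.data.frame(rr$screened)),
      file.path(dir, paste0("avg_", rv, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  cfg <- result$config
  jsonlite::write_json(
    list(level = result$level, buffers = cfg$buffers, ratios = cfg$ratios,
         alpha = cfg$alpha, delta = cfg$delta,
         r_threshold = cfg$r_threshold,
         importance_cutoff = cfg$importance_cutoff,
         op_stabilizer_m = 1, dropped_columns = result$dropped),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
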