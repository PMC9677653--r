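#' Run manifest
#'
#' Records the settings that produced a set of result files: configuration
#' snapshot, package version, seed and input-file digests, so two runs with
#' identical manifests are identical.
#'
#' @param config Analysis settings list.
#' @param seed Integer seed used for any randomness.
#' @param inputs Character vector of input file paths to digest.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, seed = NA_integer_, inputs = character()) {
  digests <- vapply(inputs, function(p) {
    if (!file.exists(p)) return(NA_character_)
    as.character(tools::md5sum(p))
  }, character(1))
  structure(list(
    package = "dialysisCEA",
    version = as.character(utils::packageVersion("dialysisCEA")),
    seed = seed,
    config = config,
    inputs = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write analysis results to a directory
#'
#' Serialises the deterministic results table (in the published table's
#' layout), and optionally PSA draws, CEAC grid and tornado entries, as CSV
#' plus a JSON summary and the manifest. The deterministic CSV is emitted at
#' presentation precision (nearest USD, two decimals for LY/QALY); all CSVs
#' are deterministic given the manifest.
#'
#' @param results List with any of `deterministic` (from
#'   [deterministic_table()]), `psa` (a `psa_result`), `ceac` (a
#'   `ceac_curve`), `tornado` (a `tornado_result`).
#' @param dir Output directory (created if needed).
#' @param manifest A [run_manifest()].
#' @return Named vector of written file paths, invisibly.
#' @export
emit_results <- function(results, dir, manifest = run_manifest(list())) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(results$deterministic)) {
    det <- results$deterministic
    det$ly <- round(det$ly, 2)
    det$qaly <- round(det$qaly, 2)
    det$lifetime_cost <- round(det$lifetime_cost)
    # derived cells recomputed from the rounded cells so the emitted table
    # is internally consistent at presentation precision
    det <- det |>
      dplyr::group_by(.data$perspective, .data$age) |>
      dplyr::mutate(
        cost_per_ly = round(.data$lifetime_cost / .data$ly),
        icer = dplyr::if_else(
          .data$strategy == "HD",
          round((.data$lifetime_cost[.data$strategy == "HD"] -
                   .data$lifetime_cost[.data$strategy == "PD"]) /
                  (.data$qaly[.data$strategy == "HD"] -
                     .data$qaly[.data$strategy == "PD"])),
          NA_real_)) |>
      dplyr::ungroup()
    p <- file.path(dir, "deterministic.csv")
    utils::write.csv(det, p, row.names = FALSE)
    paths["deterministic"] <- p
  }
  for (nm in c("psa", "ceac", "tornado")) {
    if (!is.null(results[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(results[[nm]]), p, row.names = FALSE)
      paths[nm] <- p
    }
  }
  summary <- list(manifest = unclass(manifest))
  if (!is.null(results$psa)) {
    summary$psa <- as.list(glance(results$psa, boot = 200))
  }
  if (!is.null(results$ceac)) {
    summary$crossover_wtp <- suppressMessages(crossover_wtp(results$ceac))
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["summary"] <- p
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- p
  invisible(paths)
}
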