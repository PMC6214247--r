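# End-to-end orchestration: measures -> time courses -> interpolation ->
# correlations -> significance -> embeddings -> engram, with a JSON config,
# cascading seeds and CSV/JSON outputs.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (null iterations `M = 10000`, confidence level
#' `alpha = 0.05`, power-law acceptance threshold `0.1`, both null models,
#' both correlation types, all 14 measures) and rejects unknown keys and
#' out-of-range values.
#'
#' @param config Path to a JSON config file, a list, or `NULL` for all
#'   defaults.
#' @return A normalized named list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- list(
    M = 10000L, alpha = 0.05, pl_accept = 0.1,
    nulls = c("G", "DP"), corr = c("pearson", "spearman"),
    measures = measure_names(),
    n_realizations = 10L, swap_multiplier = 10L,
    n_bootstrap = 1000L, perturb_fraction = 0.1, sc_repeats = 10L,
    binarize_threshold = 0, seed = 1L)
  user <- if (is.null(config)) list()
          else if (is.character(config))
            jsonlite::fromJSON(config, simplifyVector = TRUE)
          else config
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (cfg$M < 100) stop("M below minimum 100")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (!all(cfg$nulls %in% c("G", "DP"))) stop("nulls must be G and/or DP")
  if (!all(cfg$measures %in% measure_names()))
    stop("unknown measure name(s) in config")
  if (cfg$binarize_threshold < 0) stop("binarize threshold must be >= 0")
  cfg
}

binarize_series <- function(series, threshold = 0) {
  ens <- lapply(series$ensembles, function(e)
    lapply(e, function(cc) if (cc$binary) cc else binarize(cc, threshold)))
  connectome_series(series$step_hours, ens, series$behavioral)
}

#' Run the full analysis pipeline
#'
#' Reads a connectome series, binarizes it, computes the configured measure
#' time courses (per-matrix values averaged per step), builds the
#' correlation/significance summary table against the behavioural signal,
#' embeds the interpolated signals with PCA (z-scored, sign-aligned) and MCE
#' (quantile-normalized), runs the engram analysis, and writes CSV outputs
#' plus a JSON report with a provenance block (config, seed, config hash,
#' package version). Fully reproducible given the config seed.
#'
#' @param manifest Path to a series manifest (see [read_series()]) or a
#'   `connectome_series`.
#' @param config See [validate_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `study_report` with `summary`, `timecourses`,
#'   `embeddings`, `engram`, `provenance`.
#' @export
run_pipeline <- function(manifest, config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  series <- if (inherits(manifest, "connectome_series")) manifest
            else read_series(manifest)
  series <- binarize_series(series, cfg$binarize_threshold)
  seeds <- derive_seeds(cfg$seed, 3L)
  mcfg <- measure_config(cfg$n_realizations, cfg$swap_multiplier,
                         cfg$n_bootstrap, cfg$perturb_fraction,
                         cfg$sc_repeats, seeds[1])
  timecourses <- lapply(cfg$measures, function(mn)
    measure_timecourse(series, mn, mcfg))
  names(timecourses) <- cfg$measures
  summary <- summary_table(series, mcfg, measures = cfg$measures,
                           M = cfg$M, alpha = cfg$alpha, seed = seeds[2],
                           timecourses = timecourses)
  # embeddings on the interpolated signals (topological + behavioural)
  usable <- names(timecourses)[vapply(timecourses, function(tc)
    !anyNA(tc$means) && stats::sd(tc$means) > 0, TRUE)]
  embeddings <- NULL
  if (length(usable) >= 2) {
    sm <- signal_matrix(timecourses[usable], series$step_hours,
                        series$behavioral)
    pca_in <- sign_align(zscore_rows(sm))
    mce_in <- quantile_normalize_rows(pca_in)
    embeddings <- list(pca = pca_embed(pca_in),
                       mce = mce_embed(mce_in),
                       flipped = attr(pca_in, "flipped"))
  }
  engram <- engram_timecourse(series)
  provenance <- list(
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("painmark")),
    n_steps = length(series$step_hours),
    n_matrices_per_step = vapply(series$ensembles, length, 1L))
  report <- structure(list(summary = summary, timecourses = timecourses,
                           embeddings = embeddings, engram = engram,
                           provenance = provenance),
                      class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

config_hash <- function(cfg) {
  payload <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(payload), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a study report to disk
#'
#' Summary table, measure time courses and embedding coordinates as CSV;
#' engram outputs via [write_engram_csv()]; the full report (minus raw
#' matrices) as JSON.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(out_dir, "summary_table.csv"),
                   row.names = FALSE)
  tc <- do.call(rbind, lapply(report$timecourses, function(t)
    data.frame(measure = t$measure_name, hours = t$step_hours,
               mean = t$means, se = t$ses)))
  utils::write.csv(tc, file.path(out_dir, "measure_timecourses.csv"),
                   row.names = FALSE)
  if (!is.null(report$embeddings)) {
    write_embedding_csv(report$embeddings$pca,
                        file.path(out_dir, "embedding_pca.csv"))
    write_embedding_csv(report$embeddings$mce,
                        file.path(out_dir, "embedding_mce.csv"))
  }
  write_engram_csv(report$engram, file.path(out_dir, "engram"))
  payload <- list(
    summary = report$summary,
    region_counts = report$engram$region_counts,
    retained_counts = lapply(report$engram$retained, function(r)
      c(list(interval = r$label), as.list(r$counts))),
    provenance = report$provenance)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d measure rows, %d retained-link intervals, seed %d\n",
              nrow(x$summary), length(x$engram$retained),
              x$provenance$seed))
  if (nrow(x$summary) > 0) {
    top <- x$summary[order(-abs(x$summary$max_correlation)), ]
    cat("  top correlations with the behavioural signal:\n")
    for (i in seq_len(min(3, nrow(top))))
      cat(sprintf("    %-8s max corr %+.3f, max p %.4f\n",
                  top$measure[i], top$max_correlation[i], top$max_p[i]))
  }
  invisible(x)
}
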