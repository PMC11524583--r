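#' Reproduce the reference in vitro/in vivo correlation
#'
#' Recomputes, from the packaged 18-drug dataset, the predicted PS of
#' every drug under both barrier models (mono-culture and triple
#' co-culture), classifies each prediction by the 0.5- to 2-fold
#' criterion, summarizes per model and compares every recomputed PS cell
#' against the published value.
#'
#' @param vsa vascular surface area, cm^2/g (default 150).
#' @param fold_bounds inclusive fold-success interval (default
#'   `c(0.5, 2)`).
#' @return list of class `table1_reproduction`:
#' \describe{
#'   \item{results}{per-drug/model tibble from [run_ivivc()], plus the
#'     published PS and its relative deviation from the recomputed one.}
#'   \item{summary}{per-model success counts and AFE/AAFE from
#'     [summarize_ivivc()].}
#'   \item{failures}{named list of per-model failing drug vectors.}
#'   \item{max_rel_dev}{largest relative deviation between recomputed and
#'     published PS over all 36 cells.}
#' }
#' @export
#' @examples
#' rep <- reproduce_table1()
#' rep$summary
reproduce_table1 <- function(vsa = 150, fold_bounds = c(0.5, 2)) {
  ref <- load_table1()
  results <- run_ivivc(ref$papp, ref$drugs, vsa = vsa,
                       fold_bounds = fold_bounds)
  results <- dplyr::left_join(
    results,
    ref$papp[, c("drug_id", "model_id", "ps_pre_printed")],
    by = c("drug_id", "model_id"))
  results$rel_dev_printed <-
    abs(results$ps_pre - results$ps_pre_printed) / results$ps_pre_printed
  summary <- summarize_ivivc(results)
  failures <- lapply(split(results, results$model_id), failure_set)
  structure(list(results = results, summary = summary,
                 failures = failures,
                 max_rel_dev = max(results$rel_dev_printed)),
            class = "table1_reproduction")
}

#' @export
print.table1_reproduction <- function(x, ...) {
  cat("In vitro/in vivo correlation on the packaged 18-drug dataset\n\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-7s %d/%d predictions within fold bounds (AFE %.2f, AAFE %.2f)\n",
      s$model_id[i], s$n_success[i], s$n_total[i], s$afe[i], s$aafe[i]))
  }
  cat("\n  outside bounds:\n")
  for (m in names(x$failures)) {
    cat(sprintf("    %-7s %s\n", m,
                paste(x$failures[[m]], collapse = ", ")))
  }
  cat(sprintf(
    "\n  max relative deviation from published PS cells: %.3f%%\n",
    100 * x$max_rel_dev))
  invisible(x)
}

#' Run the full assay-to-prediction pipeline
#'
#' Wires the stages together: reads (or accepts) a transport table and a
#' drug reference table, optionally a TEER table, estimates Papp per
#' drug/model with QC, scales to predicted PS and classifies against the
#' observed PS. When `out_dir` is given, all intermediate and final tables
#' plus the effective configuration are written there as CSV/YAML.
#'
#' @param transport transport tibble or CSV path.
#' @param drugs drug reference tibble or CSV path.
#' @param teer optional TEER tibble or CSV path.
#' @param config a [bbb_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `papp`, `ivivc`, `summary`, and (when TEER given)
#'   `teer_summary` and `assay_day`.
#' @export
run_pipeline <- function(transport, drugs, teer = NULL,
                         config = bbb_config(), out_dir = NULL) {
  if (is.character(transport)) {
    transport <- read_transport_table(transport, config)
  }
  if (is.character(drugs)) drugs <- read_drugs_table(drugs)
  if (!nrow(transport)) stop("empty transport table", call. = FALSE)

  out <- list()
  if (!is.null(teer)) {
    if (is.character(teer)) teer <- read_teer_table(teer)
    corrected <- correct_teer_table(teer)
    out$teer_summary <- summarize_teer(corrected)
    out$assay_day <- select_assay_day(out$teer_summary)
  }
  out$papp <- aggregate_papp(transport,
                             sink_threshold = config$sink_threshold,
                             min_replicates = config$min_replicates)
  out$ivivc <- run_ivivc(out$papp, drugs, vsa = config$vsa_cm2_g,
                         fold_bounds = config$fold_bounds)
  out$summary <- summarize_ivivc(out$ivivc)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dg <- config$output_digits
    write_results_table(out$papp, file.path(out_dir, "papp.csv"),
                        digits = max(dg, 8))  # cm/s needs more decimals
    write_results_table(out$ivivc, file.path(out_dir, "ivivc.csv"),
                        digits = max(dg, 8))
    write_results_table(out$summary, file.path(out_dir, "summary.csv"),
                        digits = max(dg, 4))
    if (!is.null(out$teer_summary)) {
      write_results_table(out$teer_summary,
                          file.path(out_dir, "teer_summary.csv"),
                          digits = dg)
    }
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}
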