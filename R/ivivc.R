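#' Scale in vitro permeability to a predicted in vivo PS
#'
#' Converts an apparent permeability coefficient (cm/s) into a predicted
#' permeability-surface-area product (uL/min/g brain):
#' \deqn{PS_{pre} = \frac{P_{app} \times 60 \times VSA \times 1000}{f_{u,brain}}}
#' The factor 60 converts cm/s to cm/min; multiplying by the brain luminal
#' vascular surface area `VSA` (cm^2/g) gives mL/min/g; the factor 1000
#' converts to uL/min/g; dividing by the brain unbound fraction corrects
#' for the fact that only unbound drug equilibrates across the barrier.
#'
#' @param papp apparent permeability, cm/s (vectorized, >= 0).
#' @param fu_brain brain unbound fraction, in (0, 1].
#' @param vsa luminal vascular surface area of brain, cm^2/g (default 150).
#' @return Predicted PS, uL/min/g brain.
#' @export
#' @examples
#' predict_ps(15.24e-6, fu_brain = 0.01)  # 13716
predict_ps <- function(papp, fu_brain, vsa = 150) {
  if (any(fu_brain <= 0) || any(fu_brain > 1)) {
    stop("fu_brain must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(all(papp >= 0), vsa > 0)
  papp * 60 * vsa * 1000 / fu_brain
}

#' Unify a published in vivo permeability to PS
#'
#' Literature brain-uptake values reported per unit capillary surface are
#' unified to a per-gram-of-brain clearance by multiplying by the vascular
#' surface area.
#'
#' @param published_permeability published value, uL/min/cm^2-equivalent
#'   (> 0).
#' @param vsa vascular surface area, cm^2/g (default 150).
#' @return Observed PS, uL/min/g.
#' @export
unify_ps_obs <- function(published_permeability, vsa = 150) {
  stopifnot(all(published_permeability > 0), vsa > 0)
  published_permeability * vsa
}

#' Classify a prediction by the fold criterion
#'
#' Computes the predicted/observed fold ratio and tests it against an
#' inclusive interval, by default [0.5, 2]: a prediction within 0.5- to
#' 2-fold of the observation counts as successful.
#'
#' @param ps_pre predicted PS, uL/min/g (vectorized).
#' @param ps_obs observed PS, uL/min/g (> 0).
#' @param lower,upper inclusive fold bounds (default 0.5 and 2).
#' @return tibble with `fold_ratio` and logical `within_fold`.
#' @export
#' @examples
#' classify_fold(310.22, 116.10)  # ratio 2.67, outside
classify_fold <- function(ps_pre, ps_obs, lower = 0.5, upper = 2) {
  if (any(ps_obs <= 0)) stop("ps_obs must be > 0", call. = FALSE)
  stopifnot(lower > 0, lower < upper)
  ratio <- ps_pre / ps_obs
  tibble::tibble(fold_ratio = ratio,
                 within_fold = ratio >= lower & ratio <= upper)
}

#' Run the in vitro/in vivo correlation over a Papp table
#'
#' Joins per-drug/model Papp estimates with the drug reference table,
#' predicts PS via [predict_ps()] and classifies each prediction via
#' [classify_fold()]. The mean Papp (not per-replicate values) feeds the
#' scaling, so each drug/model yields one prediction.
#'
#' @param papp_tbl tibble with `drug_id`, `model_id`, `papp_mean` (cm/s),
#'   e.g. from [aggregate_papp()] or `load_table1()$papp`.
#' @param drugs tibble with `drug_id`, `fu_brain`, `ps_obs`, e.g. from
#'   [read_drugs_table()] or `load_table1()$drugs`.
#' @param vsa vascular surface area, cm^2/g (default 150).
#' @param fold_bounds inclusive success interval (default `c(0.5, 2)`).
#' @return tibble with one row per drug/model: `ps_pre`, `ps_obs`,
#'   `fold_ratio`, `within_fold`.
#' @export
run_ivivc <- function(papp_tbl, drugs, vsa = 150, fold_bounds = c(0.5, 2)) {
  missing_drugs <- setdiff(papp_tbl$drug_id, drugs$drug_id)
  if (length(missing_drugs)) {
    stop("no reference data for drug(s): ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(papp_tbl, drugs, by = "drug_id")
  joined$ps_pre <- predict_ps(joined$papp_mean, joined$fu_brain, vsa)
  cls <- classify_fold(joined$ps_pre, joined$ps_obs,
                       fold_bounds[1], fold_bounds[2])
  out <- joined[, c("drug_id", "model_id", "papp_mean", "fu_brain",
                    "ps_pre", "ps_obs")]
  out$fold_ratio <- cls$fold_ratio
  out$within_fold <- cls$within_fold
  tibble::as_tibble(out)
}

#' Summarize prediction performance per model
#'
#' Counts successful predictions and computes the standard geometric
#' fold-error metrics:
#' \deqn{AFE = 10^{\mathrm{mean}(\log_{10} r_i)}, \qquad
#'       AAFE = 10^{\mathrm{mean}(|\log_{10} r_i|)}}
#' where \eqn{r_i} is the predicted/observed ratio. AFE measures systematic
#' bias (1 = unbiased, > 1 = overprediction); AAFE measures average spread
#' regardless of direction and is always >= 1.
#'
#' @param results tibble from [run_ivivc()] (any number of models).
#' @return tibble per model: `n_total`, `n_success`, `success_rate`,
#'   `afe`, `aafe`.
#' @export
summarize_ivivc <- function(results) {
  if (!nrow(results)) stop("empty results", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(results, .data$model_id),
    n_total = dplyr::n(),
    n_success = sum(.data$within_fold),
    success_rate = mean(.data$within_fold),
    afe  = 10^mean(log10(.data$fold_ratio)),
    aafe = 10^mean(abs(log10(.data$fold_ratio))),
    .groups = "drop")
}

#' Drugs whose prediction failed the fold criterion
#'
#' @param results tibble from [run_ivivc()] for a single model.
#' @return Character vector of failing `drug_id`s, worst first (largest
#'   absolute log10 fold error).
#' @export
failure_set <- function(results) {
  fails <- results[!results$within_fold, , drop = FALSE]
  if (!nrow(fails)) return(character(0))
  fails$drug_id[order(abs(log10(fails$fold_ratio)), decreasing = TRUE)]
}

#' Brain-to-plasma concentration ratio
#'
#' Elementwise Kp ratio of brain tissue concentration (per g) to plasma
#' concentration (per mL) for in vivo tracer distribution data.
#'
#' @param c_brain brain concentration, amount per g tissue.
#' @param c_plasma plasma concentration, amount per mL (> 0).
#' @return Unitless ratio vector, same length as inputs.
#' @export
brain_plasma_ratio <- function(c_brain, c_plasma) {
  if (any(c_plasma <= 0)) stop("c_plasma must be > 0", call. = FALSE)
  stopifnot(length(c_brain) == length(c_plasma) ||
              length(c_brain) == 1 || length(c_plasma) == 1)
  c_brain / c_plasma
}
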