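#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' Relative expression of a target gene in a sample against a calibrator
#' sample, both normalized to a reference gene:
#' \deqn{\Delta\Delta Ct = (Ct_{target} - Ct_{ref}) -
#'   (Ct_{target,calib} - Ct_{ref,calib}), \qquad FC = 2^{-\Delta\Delta Ct}}
#' Amplification efficiency is assumed to be 2 (perfect doubling per
#' cycle), the comparative method's standard assumption. Technical
#' replicates should be averaged at the Ct level before calling this.
#'
#' @param target_ct,ref_ct Ct of target and reference gene in the sample.
#' @param calib_target_ct,calib_ref_ct Ct of target and reference gene in
#'   the calibrator sample.
#' @return Fold change (vectorized).
#' @export
#' @examples
#' ddct_fold_change(20, 18, 22, 19)  # ddCt = -1 -> 2
ddct_fold_change <- function(target_ct, ref_ct, calib_target_ct,
                             calib_ref_ct) {
  cts <- c(target_ct, ref_ct, calib_target_ct, calib_ref_ct)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be positive and finite", call. = FALSE)
  }
  ddct <- (target_ct - ref_ct) - (calib_target_ct - calib_ref_ct)
  2^(-ddct)
}

#' Average technical qPCR replicates at the Ct level
#'
#' @param ct_tbl tibble with `sample_id`, `gene_id`, `ct`.
#' @return tibble with one mean Ct per sample/gene.
#' @export
average_technical_ct <- function(ct_tbl) {
  dplyr::summarise(dplyr::group_by(ct_tbl, .data$sample_id, .data$gene_id),
                   ct = mean(.data$ct), .groups = "drop")
}

#' Simple linear regression between two variables
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], returning the
#' quantities usually reported alongside a permeability-versus-expression
#' scatter: slope, intercept, r-squared and the two-sided p-value for a
#' non-zero slope.
#'
#' @param x predictor vector (e.g. apparent permeability), length >= 3,
#'   not constant.
#' @param y response vector (e.g. junction-protein expression), same
#'   length.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
#' @examples
#' linear_correlation(0:3, c(1, 3, 5, 7))  # slope 2, intercept 1, r2 = 1
linear_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete points", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("x is constant: slope is undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; the sigma == 0 branch handles them
  sm <- suppressWarnings(summary(fit))
  p <- if (sm$sigma == 0) {
    0  # exact fit: slope infinitely significant
  } else {
    unname(sm$coefficients["x", "Pr(>|t|)"])
  }
  tibble::tibble(
    slope     = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value   = p,
    n         = length(x)
  )
}
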