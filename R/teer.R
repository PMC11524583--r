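#' Blank-correct and area-normalize a TEER reading
#'
#' Converts a raw chopstick-electrode resistance into the conventional
#' ohm.cm^2 scale: `(resistance_raw - blank_mean) * membrane_area`. The
#' blank mean is the average resistance of cell-free inserts measured the
#' same day, which carries the membrane and medium background.
#'
#' Negative corrected values are preserved, not clamped: a reading at or
#' below blank indicates a failed barrier or instrument drift, and clamping
#' would hide it. Use the returned `flag_low_barrier` to spot such inserts.
#'
#' @param resistance_raw raw resistance, ohm (vectorized).
#' @param blank_mean mean blank-insert resistance, ohm (> 0).
#' @param membrane_area insert membrane area, cm^2.
#' @return A tibble with `teer_ohm_cm2` and logical `flag_low_barrier`
#'   (corrected value <= 0).
#' @export
#' @examples
#' normalize_teer(120, blank_mean = 100, membrane_area = 0.33)  # 6.6
normalize_teer <- function(resistance_raw, blank_mean, membrane_area) {
  stopifnot(blank_mean > 0, all(membrane_area > 0),
            all(resistance_raw > 0))
  teer <- (resistance_raw - blank_mean) * membrane_area
  tibble::tibble(teer_ohm_cm2 = teer, flag_low_barrier = teer <= 0)
}

#' Blank-correct a full TEER table
#'
#' Applies [normalize_teer()] to every non-blank row of a TEER table, using
#' the mean of that day's blank inserts (matched on `day` and `area_cm2`,
#' i.e. plate format) as the background. Days without a blank fall back to
#' the mean over all blanks of the same format, with a warning.
#'
#' @param teer_tbl tibble from [read_teer_table()].
#' @return The non-blank rows with `teer_ohm_cm2`, `flag_low_barrier` and
#'   the `blank_mean_ohm` used.
#' @export
correct_teer_table <- function(teer_tbl) {
  blanks <- teer_tbl[teer_tbl$is_blank, , drop = FALSE]
  cells  <- teer_tbl[!teer_tbl$is_blank, , drop = FALSE]
  if (nrow(cells) == 0) stop("no non-blank TEER rows", call. = FALSE)
  if (nrow(blanks) == 0) stop("no blank inserts to correct against",
                              call. = FALSE)
  day_means <- dplyr::summarise(
    dplyr::group_by(blanks, .data$day, .data$area_cm2),
    blank_mean_ohm = mean(.data$resistance_ohm), .groups = "drop")
  fmt_means <- dplyr::summarise(
    dplyr::group_by(blanks, .data$area_cm2),
    blank_mean_fmt = mean(.data$resistance_ohm), .groups = "drop")

  out <- dplyr::left_join(cells, day_means, by = c("day", "area_cm2"))
  if (anyNA(out$blank_mean_ohm)) {
    warning("no same-day blank for some day(s); using format-wide blank mean",
            call. = FALSE)
    out <- dplyr::left_join(out, fmt_means, by = "area_cm2")
    out$blank_mean_ohm <- ifelse(is.na(out$blank_mean_ohm),
                                 out$blank_mean_fmt, out$blank_mean_ohm)
    out$blank_mean_fmt <- NULL
  }
  # same formula as normalize_teer(), with a per-row blank mean
  out$teer_ohm_cm2 <- (out$resistance_ohm - out$blank_mean_ohm) * out$area_cm2
  out$flag_low_barrier <- out$teer_ohm_cm2 <= 0
  tibble::as_tibble(out)
}

#' Summarize a TEER time course
#'
#' Per-model, per-day mean and standard error of corrected TEER values.
#' SEM is the sample standard deviation over inserts divided by sqrt(n);
#' it is 0 when a group holds a single insert.
#'
#' @param corrected tibble with `model_id`, `day` and `teer_ohm_cm2`
#'   columns (e.g. from [correct_teer_table()]).
#' @return tibble `model_id`, `day`, `teer_mean`, `teer_sem`, `n`, ordered
#'   by model then day.
#' @export
summarize_teer <- function(corrected) {
  if (!nrow(corrected)) stop("empty TEER input", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(corrected, .data$model_id, .data$day),
    teer_mean = mean(.data$teer_ohm_cm2),
    teer_sem  = if (dplyr::n() > 1)
      stats::sd(.data$teer_ohm_cm2) / sqrt(dplyr::n()) else 0,
    n = dplyr::n(),
    .groups = "drop")
  dplyr::arrange(out, .data$model_id, .data$day)
}

#' Select the optimal assay day from a TEER time course
#'
#' Returns the day, within a candidate window, on which the mean TEER
#' (averaged across the requested models) is maximal — the day the barrier
#' is tightest and transport assays should be run. Ties go to the earlier
#' day, favoring the shorter culture time.
#'
#' @param timecourse tibble from [summarize_teer()].
#' @param window integer vector of candidate days (default: all days
#'   present).
#' @param model_id optional model to restrict to; default averages over all
#'   models in the table.
#' @return The selected day (integer).
#' @export
select_assay_day <- function(timecourse, window = NULL, model_id = NULL) {
  tc <- timecourse
  if (!is.null(model_id)) tc <- tc[tc$model_id %in% model_id, , drop = FALSE]
  if (is.null(window)) window <- sort(unique(tc$day))
  if (!length(window)) stop("empty day window", call. = FALSE)
  if (!all(window %in% tc$day)) {
    stop("window day(s) absent from the time course: ",
         paste(setdiff(window, tc$day), collapse = ", "), call. = FALSE)
  }
  tc <- tc[tc$day %in% window, , drop = FALSE]
  by_day <- dplyr::summarise(dplyr::group_by(tc, .data$day),
                             m = mean(.data$teer_mean), .groups = "drop")
  by_day <- dplyr::arrange(by_day, .data$day)
  as.integer(by_day$day[which.max(by_day$m)])  # which.max takes first max
}
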