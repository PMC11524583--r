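#' Apparent permeability coefficient from one transport measurement
#'
#' The single-timepoint sink-condition estimator
#' \deqn{P_{app} = \frac{Q / t}{S \cdot C_0}}
#' where `Q = C_receiver * V_receiver` is the amount that reached the
#' receiver chamber by the sampling time `t`, `S` the insert membrane area
#' and `C0` the initial donor concentration. With concentrations in umol/L,
#' volumes in mL (= cm^3), area in cm^2 and time in s, the result is in
#' cm/s with no further conversion.
#'
#' The estimator assumes sink conditions (receiver concentration negligible
#' against donor); as the transported fraction grows, the back-flux makes
#' it a systematic underestimate of the true permeability (see
#' [recover_papp_experiment()] for the exact bias factor).
#'
#' @param C_receiver_uM receiver concentration at `t_sample_s`, umol/L
#'   (vectorized).
#' @param C0_uM initial donor concentration, umol/L (> 0).
#' @param V_receiver_mL receiver chamber volume, mL.
#' @param area_cm2 membrane area, cm^2.
#' @param t_sample_s sampling time, s (default 1800 = 30 min).
#' @return Papp in cm/s.
#' @export
#' @examples
#' compute_papp(0.10, C0_uM = 10, V_receiver_mL = 0.6,
#'              area_cm2 = 0.33)  # 1.0101e-05 cm/s
compute_papp <- function(C_receiver_uM, C0_uM, V_receiver_mL,
                         area_cm2, t_sample_s = 1800) {
  stopifnot(all(t_sample_s > 0), all(area_cm2 > 0), all(V_receiver_mL > 0),
            all(C_receiver_uM >= 0))
  if (any(C0_uM <= 0)) {
    stop("C0_uM must be > 0: permeability is undefined at zero dose",
         call. = FALSE)
  }
  Q <- C_receiver_uM * V_receiver_mL          # nmol (uM * mL)
  (Q / t_sample_s) / (area_cm2 * C0_uM)        # cm/s
}

#' Aggregate replicate transport measurements into a Papp estimate
#'
#' Computes a per-replicate Papp with [compute_papp()] for every row of a
#' transport table, then summarizes per drug/model: mean, SEM (sample SD /
#' sqrt(n)), transported dose fraction, and QC flags.
#'
#' QC flags:
#' * `NON_SINK` — mean fraction of dose transported exceeds
#'   `sink_threshold`; the sink assumption behind the estimator is strained
#'   and Papp is biased low.
#' * `OVER_EQUILIBRIUM` — some replicate's receiver concentration exceeds
#'   the passive-equilibrium bound (cannot arise from diffusion alone).
#' * `LOW_N` — fewer than `min_replicates` replicates.
#'
#' All replicates of a group must share geometry (volumes, area, time);
#' mixed geometry within a drug/model group is an error, since averaging
#' Papp across formats silently mixes assay conditions.
#'
#' @param transport tibble from [read_transport_table()] (or the simulator).
#' @param sink_threshold transported-fraction threshold for `NON_SINK`
#'   (default 0.10).
#' @param min_replicates minimum n before `LOW_N` is flagged (default 3).
#' @return tibble with one row per drug/model: `papp_mean`, `papp_sem`
#'   (cm/s), `n`, `fraction_transported`, logical flag columns and a
#'   semicolon-joined `qc_flags` string.
#' @export
aggregate_papp <- function(transport, sink_threshold = 0.10,
                           min_replicates = 3) {
  if (!nrow(transport)) stop("empty transport table", call. = FALSE)
  geom_cols <- c("t_sample_s", "V_receiver_mL", "V_donor_mL", "area_cm2")
  geo_check <- dplyr::summarise(
    dplyr::group_by(transport, .data$drug_id, .data$model_id),
    n_geom = nrow(unique(dplyr::pick(dplyr::all_of(geom_cols)))),
    .groups = "drop")
  if (any(geo_check$n_geom > 1)) {
    bad <- geo_check[geo_check$n_geom > 1, ]
    stop("mixed insert geometry within group(s): ",
         paste(bad$drug_id, bad$model_id, sep = "/", collapse = ", "),
         call. = FALSE)
  }

  per_rep <- dplyr::mutate(
    transport,
    papp = compute_papp(.data$C_receiver_uM, .data$C0_uM,
                        .data$V_receiver_mL, .data$area_cm2,
                        .data$t_sample_s),
    frac = (.data$C_receiver_uM * .data$V_receiver_mL) /
      (.data$C0_uM * .data$V_donor_mL),
    over_eq = .data$C_receiver_uM >
      .data$C0_uM * .data$V_donor_mL /
      (.data$V_donor_mL + .data$V_receiver_mL)
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$drug_id, .data$model_id),
    papp_mean = mean(.data$papp),
    papp_sem  = if (dplyr::n() > 1) stats::sd(.data$papp) / sqrt(dplyr::n())
                else 0,
    n = dplyr::n(),
    fraction_transported = mean(.data$frac),
    flag_over_equilibrium = any(.data$over_eq),
    .groups = "drop")
  out$flag_non_sink <- out$fraction_transported > sink_threshold
  out$flag_low_n <- out$n < min_replicates
  out$qc_flags <- apply(
    cbind(NON_SINK = out$flag_non_sink,
          OVER_EQUILIBRIUM = out$flag_over_equilibrium,
          LOW_N = out$flag_low_n),
    1, function(f) paste(names(f)[f], collapse = ";"))
  out
}

#' Mass-balance recovery check
#'
#' Fraction of the dosed amount accounted for at the end of the assay:
#' \deqn{recovery = \frac{C_{donor,final} V_{donor} + C_{receiver} V_{receiver}}
#'   {C_0 V_{donor}}}
#' Recovery well below 1 indicates loss to the plastic, the membrane or the
#' cells (binding, metabolism); well above 1 indicates evaporation or a
#' dosing error. Values outside `band` are flagged, never rejected — this
#' is QC, not filtering.
#'
#' @param C_donor_final_uM donor concentration at assay end, umol/L.
#' @param C0_uM initial donor concentration, umol/L.
#' @param C_receiver_uM receiver concentration at assay end, umol/L.
#' @param V_donor_mL,V_receiver_mL chamber volumes, mL.
#' @param band acceptable recovery interval (default `c(0.8, 1.2)`).
#' @return tibble with `recovery` and logical `flag_out_of_band`.
#' @export
recovery_check <- function(C_donor_final_uM, C0_uM, C_receiver_uM,
                           V_donor_mL, V_receiver_mL,
                           band = c(0.8, 1.2)) {
  stopifnot(all(C_donor_final_uM >= 0), all(C0_uM > 0),
            length(band) == 2, band[1] < band[2])
  recovery <- (C_donor_final_uM * V_donor_mL +
                 C_receiver_uM * V_receiver_mL) / (C0_uM * V_donor_mL)
  tibble::tibble(recovery = recovery,
                 flag_out_of_band = recovery < band[1] | recovery > band[2])
}
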