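# Shared fixture builders: everything is generated in code at test time.

# A well-formed transport table: one drug/model, n replicates with the
# given receiver concentrations.
make_transport <- function(C_receiver, drug = "drugA", model = "mono",
                           C0 = 10, Vr = 0.6, Vd = 0.1, area = 0.33,
                           t = 1800) {
  n <- length(C_receiver)
  tibble::tibble(
    drug_id = drug, model_id = model, replicate = seq_len(n),
    t_sample_s = t, C0_uM = C0, C_receiver_uM = C_receiver,
    V_receiver_mL = Vr, V_donor_mL = Vd, area_cm2 = area
  )
}

write_transport_csv <- function(tbl, path = tempfile(fileext = ".csv")) {
  readr::write_csv(tbl, path)
  path
}

# Receiver concentration that makes compute_papp() return exactly `papp`
# under the given geometry (inverts the estimator).
receiver_for_papp <- function(papp, C0 = 10, Vr = 0.6, area = 0.33,
                              t = 1800) {
  papp * t * area * C0 / Vr
}

# TEER profile rising to a peak day then falling, per model.
peak_profile <- function(models = c("mono", "triple"), days = 1:7,
                         peak_day = 6) {
  grid <- expand.grid(model_id = models, day = days,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    model_id = grid$model_id, day = grid$day,
    mean_ohm = 150 + 40 * exp(-(grid$day - peak_day)^2 / 4) +
      ifelse(grid$model_id == "triple", 20, 0),
    sd_ohm = 0
  )
}
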