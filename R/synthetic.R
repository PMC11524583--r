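#' Specify a synthetic Transwell transport experiment
#'
#' Parameterizes the mechanistic two-compartment model of a single insert:
#' a well-mixed donor (apical) and receiver (basolateral) chamber separated
#' by a membrane of permeability `true_papp`, plus multiplicative
#' measurement noise.
#'
#' @param true_papp true membrane permeability, cm/s.
#' @param area_cm2 membrane area, cm^2.
#' @param v_donor_ml,v_receiver_ml chamber volumes, mL.
#' @param c0_um initial donor concentration, umol/L.
#' @param t_grid_s strictly increasing sampling times, s (first >= 0).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise (0 = noiseless).
#' @param seed integer RNG seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(true_papp = 1e-5, area_cm2 = 0.33,
                     v_donor_ml = 0.1, v_receiver_ml = 0.6,
                     c0_um = 10, t_grid_s = c(0, 600, 1200, 1800),
                     noise_cv = 0.05, seed = 1L) {
  stopifnot(true_papp > 0, area_cm2 > 0, v_donor_ml > 0, v_receiver_ml > 0,
            c0_um > 0, noise_cv >= 0, length(t_grid_s) >= 1,
            t_grid_s[1] >= 0, !is.unsorted(t_grid_s, strictly = TRUE))
  structure(list(true_papp = true_papp, area_cm2 = area_cm2,
                 v_donor_ml = v_donor_ml, v_receiver_ml = v_receiver_ml,
                 c0_um = c0_um, t_grid_s = t_grid_s, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Closed-form receiver concentration of the two-compartment diffusion
# model. With k = Papp*S*(1/Vd + 1/Vr), the receiver relaxes to the
# equilibrium concentration C0*Vd/(Vd+Vr) as 1 - exp(-k t).
receiver_closed_form <- function(papp, area_cm2, v_donor_ml, v_receiver_ml,
                                 c0_um, t_s) {
  k <- papp * area_cm2 * (1 / v_donor_ml + 1 / v_receiver_ml)
  c_eq <- c0_um * v_donor_ml / (v_donor_ml + v_receiver_ml)
  c_eq * (1 - exp(-k * t_s))
}

# Multiplicative lognormal noise with unit mean and the requested CV.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a Transwell transport time course
#'
#' Noiseless dynamics follow the closed form of the two-compartment
#' passive-diffusion model: with
#' \eqn{k = P_{app} S (1/V_D + 1/V_R)},
#' \deqn{C_R(t) = C_0 \frac{V_D}{V_D + V_R} (1 - e^{-kt}), \qquad
#'       C_D(t) = C_0 - C_R(t) V_R / V_D.}
#' Mass is conserved exactly at every time. Multiplicative lognormal noise
#' with the spec's CV is applied independently per observation; the noise
#' factors have unit mean so the measurement is unbiased.
#'
#' @param spec a [sim_spec()].
#' @return tibble `t_s`, `C_donor_uM`, `C_receiver_uM` (noisy) and the
#'   noiseless `C_receiver_true_uM`.
#' @export
#' @examples
#' simulate_transport(sim_spec(noise_cv = 0, t_grid_s = c(0, 1800)))
simulate_transport <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  cr_true <- receiver_closed_form(spec$true_papp, spec$area_cm2,
                                  spec$v_donor_ml, spec$v_receiver_ml,
                                  spec$c0_um, spec$t_grid_s)
  cd_true <- spec$c0_um - cr_true * spec$v_receiver_ml / spec$v_donor_ml
  nf_r <- lognormal_factor(length(cr_true), spec$noise_cv)
  nf_d <- lognormal_factor(length(cd_true), spec$noise_cv)
  tibble::tibble(
    t_s = spec$t_grid_s,
    C_donor_uM = cd_true * nf_d,
    C_receiver_uM = cr_true * nf_r,
    C_receiver_true_uM = cr_true
  )
}

#' Estimate Papp from simulated replicates and measure the bias
#'
#' Validation harness for the single-timepoint estimator: simulates
#' `n_reps` independent inserts from `spec`, applies [compute_papp()] to
#' the receiver concentration at `t_sample_s`, aggregates with
#' [aggregate_papp()] and reports the relative bias against the known true
#' permeability.
#'
#' For noiseless data the estimator underestimates by exactly the factor
#' \eqn{(1 - e^{-kt})/(kt)} (< 1 for every kt > 0), the ratio of the
#' realized uptake to the hypothetical linear-flux uptake; the bias
#' vanishes as the transported fraction goes to zero.
#'
#' @param spec a [sim_spec()]; `t_sample_s` must be on its time grid.
#' @param n_reps number of replicate inserts.
#' @param t_sample_s sampling time used by the estimator (default 1800).
#' @return list with `papp` (the one-row [aggregate_papp()] result),
#'   `rel_bias` = (papp_mean - true)/true, and `expected_bias_factor`
#'   = (1 - exp(-kt))/(kt).
#' @export
recover_papp_experiment <- function(spec, n_reps = 4, t_sample_s = 1800) {
  stopifnot(inherits(spec, "sim_spec"), n_reps >= 1)
  if (!t_sample_s %in% spec$t_grid_s) {
    stop("t_sample_s must be on the spec's time grid", call. = FALSE)
  }
  records <- lapply(seq_len(n_reps), function(i) {
    rep_spec <- spec
    rep_spec$seed <- substream_seed(spec$seed, i)
    ts <- simulate_transport(rep_spec)
    row <- ts[ts$t_s == t_sample_s, ]
    tibble::tibble(
      drug_id = "sim", model_id = "sim", replicate = i,
      t_sample_s = t_sample_s, C0_uM = spec$c0_um,
      C_receiver_uM = row$C_receiver_uM,
      V_receiver_mL = spec$v_receiver_ml, V_donor_mL = spec$v_donor_ml,
      area_cm2 = spec$area_cm2
    )
  })
  agg <- aggregate_papp(dplyr::bind_rows(records))
  k <- spec$true_papp * spec$area_cm2 *
    (1 / spec$v_donor_ml + 1 / spec$v_receiver_ml)
  kt <- k * t_sample_s
  list(papp = agg,
       rel_bias = (agg$papp_mean - spec$true_papp) / spec$true_papp,
       expected_bias_factor = (1 - exp(-kt)) / kt)
}

# Deterministic per-unit substream seed: extensible (drug i's stream never
# depends on how many drugs follow it) and kept inside 32-bit range.
substream_seed <- function(root, i) {
  as.integer((as.double(root) * 10007 + as.double(i) * 7919) %% 2147483647)
}

#' Specify a synthetic drug cohort
#'
#' Parameterizes a cohort of hypothetical drugs with dispersed
#' permeability and brain unbound fraction, plus a noisy "observed" in
#' vivo PS around the truth. Defaults reproduce the spread of the packaged
#' 18-drug reference set: Papp spanning roughly 3-40 x 1e-6 cm/s and
#' fu_brain from a few thousandths to near 1.
#'
#' @param n_drugs number of drugs.
#' @param log10_papp_mean,log10_papp_sd log10 of true Papp (cm/s).
#' @param log10_fu_mean,log10_fu_sd log10 of fu_brain; draws above 1 are
#'   truncated to 1.
#' @param ivivc_fold_sd SD (log10 scale) of the prediction error linking
#'   true PS to the noisy observed PS; 0 gives a perfectly predictable
#'   cohort.
#' @param n_replicates transport replicates per drug.
#' @param noise_cv measurement CV for the transport simulation.
#' @param seed root RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_drugs = 18,
                        log10_papp_mean = -4.92, log10_papp_sd = 0.28,
                        log10_fu_mean = -1.15, log10_fu_sd = 0.65,
                        ivivc_fold_sd = 0.25, n_replicates = 4,
                        noise_cv = 0.05, seed = 1L) {
  stopifnot(n_drugs >= 1, log10_papp_sd >= 0, log10_fu_sd >= 0,
            ivivc_fold_sd >= 0, n_replicates >= 1, noise_cv >= 0)
  structure(list(n_drugs = as.integer(n_drugs),
                 log10_papp_mean = log10_papp_mean,
                 log10_papp_sd = log10_papp_sd,
                 log10_fu_mean = log10_fu_mean, log10_fu_sd = log10_fu_sd,
                 ivivc_fold_sd = ivivc_fold_sd,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic drug cohort
#'
#' Samples per-drug true permeability (lognormal) and unbound fraction
#' (lognormal truncated at 1), defines the true PS by the standard scaling
#' (Papp x 60 x VSA x 1000 / fu), and draws a noisy observed PS as
#' \eqn{PS_{obs} = PS_{true} \times 10^\varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} with
#' \eqn{\sigma} = `ivivc_fold_sd`. Optionally emits replicate transport
#' records (via the two-compartment simulator, default assay geometry) in
#' the schema [read_transport_table()] produces, so the full pipeline can
#' run on them.
#'
#' Every drug draws from its own deterministic RNG substream, so
#' extending the cohort does not re-draw earlier drugs.
#'
#' @param spec a [cohort_spec()].
#' @param vsa vascular surface area used for the true PS (default 150).
#' @param config assay geometry for the emitted transport records.
#' @param emit_transport set `FALSE` to skip the per-replicate transport
#'   simulation (fast path for large-cohort statistical checks).
#' @return list with `drugs` (the observed-side table: `drug_id`,
#'   `fu_brain`, `ps_obs`), `transport` (replicate records or `NULL`) and
#'   `truth` (`drug_id`, `papp_true`, `fu_brain`, `ps_true`, `ps_obs`).
#' @export
generate_cohort <- function(spec, vsa = 150, config = bbb_config(),
                            emit_transport = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("drug%04d", seq_len(spec$n_drugs))
  papp_true <- numeric(spec$n_drugs)
  fu <- numeric(spec$n_drugs)
  eps <- numeric(spec$n_drugs)
  for (i in seq_len(spec$n_drugs)) {
    set.seed(substream_seed(spec$seed, i))
    papp_true[i] <- 10^rnorm(1, spec$log10_papp_mean, spec$log10_papp_sd)
    fu[i] <- min(1, 10^rnorm(1, spec$log10_fu_mean, spec$log10_fu_sd))
    eps[i] <- rnorm(1, 0, spec$ivivc_fold_sd)
  }
  ps_true <- predict_ps(papp_true, fu, vsa)
  ps_obs <- ps_true * 10^eps
  truth <- tibble::tibble(drug_id = ids, papp_true = papp_true,
                          fu_brain = fu, ps_true = ps_true, ps_obs = ps_obs)
  drugs <- tibble::tibble(drug_id = ids, fu_brain = fu, ps_obs = ps_obs)

  transport <- NULL
  if (emit_transport) {
    n <- spec$n_drugs * spec$n_replicates
    drug_idx <- rep(seq_len(spec$n_drugs), each = spec$n_replicates)
    rep_idx <- rep(seq_len(spec$n_replicates), times = spec$n_drugs)
    cr_true <- receiver_closed_form(papp_true[drug_idx], config$area_cm2,
                                    config$v_donor_ml, config$v_receiver_ml,
                                    10, config$t_sample_s)
    # per-(drug, replicate) noise from its own substream
    nf <- vapply(seq_len(n), function(j) {
      set.seed(substream_seed(spec$seed,
                              1000L + drug_idx[j] * 100L + rep_idx[j]))
      lognormal_factor(1, spec$noise_cv)
    }, numeric(1))
    transport <- tibble::tibble(
      drug_id = ids[drug_idx], model_id = "sim", replicate = rep_idx,
      t_sample_s = config$t_sample_s, C0_uM = 10,
      C_receiver_uM = cr_true * nf,
      V_receiver_mL = config$v_receiver_ml,
      V_donor_mL = config$v_donor_ml,
      area_cm2 = config$area_cm2
    )
  }
  list(drugs = drugs, transport = transport, truth = truth)
}

#' Generate a synthetic TEER time course
#'
#' Draws Gaussian noise around day-wise mean resistances per model and adds
#' blank (cell-free) inserts, producing the schema [read_teer_table()]
#' reads.
#'
#' @param profiles tibble `model_id`, `day`, `mean_ohm`, `sd_ohm` covering
#'   a common day grid.
#' @param blank_mean_ohm,blank_sd_ohm blank-insert resistance distribution.
#' @param n_inserts inserts per model per day.
#' @param n_blanks blank inserts per day.
#' @param area_cm2 membrane area, cm^2.
#' @param seed RNG seed.
#' @return tibble in the TEER-table schema.
#' @export
generate_teer_course <- function(profiles, blank_mean_ohm = 100,
                                 blank_sd_ohm = 0, n_inserts = 4,
                                 n_blanks = 3, area_cm2 = 0.33, seed = 1L) {
  stopifnot(all(c("model_id", "day", "mean_ohm", "sd_ohm") %in%
                  names(profiles)),
            blank_mean_ohm > 0, blank_sd_ohm >= 0,
            n_inserts >= 1, n_blanks >= 1, area_cm2 > 0)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    tibble::tibble(
      insert_id = sprintf("%s_d%d_r%d", p$model_id, p$day,
                          seq_len(n_inserts)),
      model_id = p$model_id, day = p$day,
      resistance_ohm = rnorm(n_inserts, p$mean_ohm, p$sd_ohm),
      is_blank = FALSE, area_cm2 = area_cm2
    )
  })
  days <- sort(unique(profiles$day))
  blanks <- lapply(days, function(d) {
    tibble::tibble(
      insert_id = sprintf("blank_d%d_r%d", d, seq_len(n_blanks)),
      model_id = "blank", day = d,
      resistance_ohm = rnorm(n_blanks, blank_mean_ohm, blank_sd_ohm),
      is_blank = TRUE, area_cm2 = area_cm2
    )
  })
  out <- dplyr::bind_rows(c(rows, blanks))
  if (any(out$resistance_ohm <= 0)) {
    stop("simulated resistance <= 0; reduce sd or raise means",
         call. = FALSE)
  }
  out
}
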