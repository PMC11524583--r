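#' Read a Transwell transport table
#'
#' Parses and validates a CSV of single-timepoint transport measurements,
#' one row per insert (biological replicate). Expected columns (renameable
#' through `col_map`): `drug_id`, `model_id`, `replicate`, `t_sample_s`,
#' `C0_uM`, `C_receiver_uM`, `V_receiver_mL`, `V_donor_mL`, `area_cm2`.
#' Concentrations are stored in umol/L; `conc_unit = "nmol_per_mL"` is
#' accepted and is numerically identical.
#'
#' Rows whose receiver concentration exceeds the passive-equilibrium bound
#' `C0 * V_donor / (V_donor + V_receiver)` are flagged in
#' `flag_over_equilibrium` (not rejected): such values cannot arise from
#' passive diffusion alone and usually indicate a dosing or dilution error.
#'
#' @param path CSV file path.
#' @param config a [bbb_config()] list; supplies `V_donor_mL` when the
#'   column is absent (with a warning), since some labs record only the
#'   receiver side.
#' @param col_map optional named character vector mapping expected column
#'   names to the names actually present, e.g.
#'   `c(C0_uM = "donor_conc_uM")`.
#' @param conc_unit unit the concentration columns are declared in:
#'   `"uM"` (default) or the equivalent `"nmol_per_mL"`.
#'
#' @return A tibble with one validated row per measurement and a logical
#'   `flag_over_equilibrium` column.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "drug_id,model_id,replicate,t_sample_s,C0_uM,C_receiver_uM,V_receiver_mL,V_donor_mL,area_cm2",
#'   "caffeine,mono,1,1800,10,0.12,0.6,0.1,0.33"), tf)
#' read_transport_table(tf)
read_transport_table <- function(path, config = bbb_config(),
                                 col_map = NULL,
                                 conc_unit = c("uM", "nmol_per_mL")) {
  conc_unit <- match.arg(conc_unit)  # the two are numerically identical
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  required <- c("drug_id", "model_id", "replicate", "t_sample_s",
                "C0_uM", "C_receiver_uM", "V_receiver_mL", "area_cm2")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("transport table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"V_donor_mL" %in% names(raw)) {
    warning("V_donor_mL column absent; using config default ",
            config$v_donor_ml, " mL", call. = FALSE)
    raw$V_donor_mL <- config$v_donor_ml
  }

  num_cols <- c("t_sample_s", "C0_uM", "C_receiver_uM",
                "V_receiver_mL", "V_donor_mL", "area_cm2")
  for (cl in num_cols) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(gsub(",", "", as.character(v))))
      raw[[cl]] <- v
    }
    bad <- which(is.na(raw[[cl]]))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing '%s' in row(s) %s", cl,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_positive <- function(cl, allow_zero = FALSE) {
    bad <- if (allow_zero) which(raw[[cl]] < 0) else which(raw[[cl]] <= 0)
    if (length(bad)) {
      stop(sprintf("invalid '%s' (must be %s) in row(s) %s", cl,
                   if (allow_zero) ">= 0" else "> 0",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_positive("t_sample_s"); check_positive("area_cm2")
  check_positive("V_receiver_mL"); check_positive("V_donor_mL")
  check_positive("C0_uM"); check_positive("C_receiver_uM", allow_zero = TRUE)
  if (any(raw$replicate <= 0 | raw$replicate != round(raw$replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }

  eq_bound <- raw$C0_uM * raw$V_donor_mL / (raw$V_donor_mL + raw$V_receiver_mL)
  out <- tibble::as_tibble(raw[, c("drug_id", "model_id", "replicate",
                                   "t_sample_s", "C0_uM", "C_receiver_uM",
                                   "V_receiver_mL", "V_donor_mL",
                                   "area_cm2")])
  out$flag_over_equilibrium <- raw$C_receiver_uM > eq_bound
  out
}

#' Read a TEER table
#'
#' Parses a CSV of raw transendothelial electrical resistance readings, one
#' row per insert per day. Required columns: `insert_id`, `model_id`, `day`,
#' `resistance_ohm`, `is_blank`, `area_cm2`. Blank inserts (`is_blank` true)
#' carry the membrane-plus-medium background resistance.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_teer_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  required <- c("insert_id", "model_id", "day", "resistance_ohm",
                "is_blank", "area_cm2")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("TEER table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$is_blank <- as.logical(raw$is_blank)
  bad <- which(is.na(raw$resistance_ohm) | raw$resistance_ohm <= 0)
  if (length(bad)) {
    stop("resistance_ohm must be > 0; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(raw$day) | raw$day < 0 | raw$day != round(raw$day))) {
    stop("day must be a non-negative integer", call. = FALSE)
  }
  if (any(is.na(raw$area_cm2) | raw$area_cm2 <= 0)) {
    stop("area_cm2 must be > 0", call. = FALSE)
  }
  if (any(is.na(raw$is_blank))) stop("is_blank must be TRUE/FALSE", call. = FALSE)
  tibble::as_tibble(raw[, required])
}

#' Read a drug reference table
#'
#' Parses a CSV of literature-side drug data: `drug_id`, `fu_brain` (brain
#' unbound fraction, in (0, 1]), `ps_obs_ul_min_g` (observed in vivo
#' permeability-surface-area product, uL/min/g brain) and an optional
#' `source` citation tag.
#'
#' @param path CSV file path.
#' @return A validated tibble with columns `drug_id`, `fu_brain`, `ps_obs`,
#'   `source`.
#' @export
read_drugs_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  required <- c("drug_id", "fu_brain", "ps_obs_ul_min_g")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("drug table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(raw$fu_brain) | raw$fu_brain <= 0 | raw$fu_brain > 1)) {
    stop("fu_brain must lie in (0, 1]", call. = FALSE)
  }
  if (any(is.na(raw$ps_obs_ul_min_g) | raw$ps_obs_ul_min_g <= 0)) {
    stop("ps_obs_ul_min_g must be > 0", call. = FALSE)
  }
  tibble::tibble(
    drug_id  = raw$drug_id,
    fu_brain = raw$fu_brain,
    ps_obs   = raw$ps_obs_ul_min_g,
    source   = if ("source" %in% names(raw)) raw$source else NA_character_
  )
}

# frozen md5 of the packaged 18-drug reference table
TABLE1_MD5 <- "6e2df62713c25fdbb0638e8986949af5"

#' Load the packaged 18-drug reference dataset
#'
#' Returns the bundled reference table of 18 CNS-relevant drugs: brain
#' unbound fraction, observed in vivo PS (in situ brain perfusion,
#' literature-unified to uL/min/g), and mean +/- SEM apparent permeability
#' measured across the endothelial mono-culture and the triple co-culture
#' barrier models, together with the published predicted-PS values for
#' cross-checking. Papp is converted from the table's 1e-6 cm/s display
#' scale to cm/s.
#'
#' The packaged file's md5 checksum is verified on every load so that a
#' corrupted installation fails loudly rather than silently shifting
#' downstream results.
#'
#' @return A list with elements
#' \describe{
#'   \item{drugs}{tibble: `drug_id`, `fu_brain`, `ps_obs` (uL/min/g).}
#'   \item{papp}{long tibble: `drug_id`, `model_id` (`"mono"`/`"triple"`),
#'     `papp_mean` and `papp_sem` (cm/s), `ps_pre_printed` (uL/min/g, the
#'     published predicted PS for that drug/model).}
#' }
#' @export
#' @examples
#' ref <- load_table1()
#' nrow(ref$drugs)  # 18
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "bbbivivc",
                      mustWork = TRUE)
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, TABLE1_MD5)) {
    stop("packaged reference table failed its integrity check (md5 ",
         digest, ")", call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) != 18) {
    stop("reference table must contain exactly 18 drugs", call. = FALSE)
  }
  drugs <- tibble::tibble(
    drug_id  = raw$drug_id,
    fu_brain = raw$fu_brain,
    ps_obs   = raw$ps_obs_ul_min_g
  )
  papp <- dplyr::bind_rows(
    tibble::tibble(
      drug_id = raw$drug_id, model_id = "mono",
      papp_mean = raw$papp_mono_e6_cm_s * 1e-6,
      papp_sem  = raw$papp_mono_sem_e6_cm_s * 1e-6,
      ps_pre_printed = raw$ps_pre_mono_ul_min_g
    ),
    tibble::tibble(
      drug_id = raw$drug_id, model_id = "triple",
      papp_mean = raw$papp_triple_e6_cm_s * 1e-6,
      papp_sem  = raw$papp_triple_sem_e6_cm_s * 1e-6,
      ps_pre_printed = raw$ps_pre_triple_ul_min_g
    )
  )
  list(drugs = drugs, papp = papp)
}

#' Write a results table to CSV
#'
#' Serializes a result tibble with a deterministic column order and fixed
#' decimal precision, so written tables diff cleanly and round-trip through
#' [readr::read_csv()] without loss beyond the stated precision.
#'
#' @param results non-empty data frame.
#' @param path output CSV path.
#' @param digits decimals for numeric columns (default 2, matching the
#'   display convention of the reference dataset).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, digits = 2) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  out <- results[, sort_result_columns(names(results)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# id columns first, then everything else in given order
sort_result_columns <- function(nms) {
  ids <- intersect(c("drug_id", "model_id", "insert_id", "day", "replicate"),
                   nms)
  c(ids, setdiff(nms, ids))
}
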