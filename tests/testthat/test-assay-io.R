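test_that("transport tables parse, validate and preserve row counts", {
  tbl <- make_transport(c(0.10, 0.11, 0.09, 0.12))
  path <- write_transport_csv(tbl)
  got <- read_transport_table(path)
  expect_equal(nrow(got), 4)
  expect_equal(got$C_receiver_uM, tbl$C_receiver_uM)
  expect_false(any(got$flag_over_equilibrium))

  # missing column is named in the error
  bad <- tbl[, setdiff(names(tbl), "C0_uM")]
  expect_error(read_transport_table(write_transport_csv(bad)), "C0_uM")

  # NA receiver concentration cites the offending row
  tbl_na <- tbl
  tbl_na$C_receiver_uM[3] <- NA
  expect_error(read_transport_table(write_transport_csv(tbl_na)), "3")

  # negative concentration rejected
  tbl_neg <- tbl
  tbl_neg$C_receiver_uM[2] <- -1
  expect_error(read_transport_table(write_transport_csv(tbl_neg)), "2")
})

test_that("nmol/mL declarations and column renames are accepted", {
  tbl <- make_transport(0.25)
  names(tbl)[names(tbl) == "C0_uM"] <- "donor_conc"
  path <- write_transport_csv(tbl)
  got <- read_transport_table(path, col_map = c(C0_uM = "donor_conc"),
                              conc_unit = "nmol_per_mL")
  expect_equal(got$C0_uM, 10)           # numerically identical unit
  expect_equal(got$C_receiver_uM, 0.25)
})

test_that("missing donor volume falls back to config with a warning", {
  tbl <- make_transport(0.1)
  tbl$V_donor_mL <- NULL
  path <- write_transport_csv(tbl)
  expect_warning(got <- read_transport_table(path, bbb_config()),
                 "V_donor_mL")
  expect_equal(got$V_donor_mL, 0.1)
})

test_that("over-equilibrium receiver concentrations are flagged, not fatal", {
  # equilibrium bound: 10 * 0.1 / 0.7 = 1.4286 uM
  tbl <- make_transport(c(0.5, 2.0))
  got <- read_transport_table(write_transport_csv(tbl))
  expect_equal(got$flag_over_equilibrium, c(FALSE, TRUE))
})

test_that("packaged 18-drug reference loads with verified content", {
  ref <- load_table1()
  expect_equal(nrow(ref$drugs), 18)
  expect_equal(nrow(ref$papp), 36)
  ama <- ref$drugs[ref$drugs$drug_id == "Amantadine", ]
  expect_equal(ama$fu_brain, 0.1985)
  expect_equal(ama$ps_obs, 116.10)
  gab <- ref$papp[ref$papp$drug_id == "Gabapentin" &
                    ref$papp$model_id == "triple", ]
  expect_equal(gab$papp_mean, 8.78e-6)
  # loading never mutates the packaged file
  expect_identical(unname(tools::md5sum(
    system.file("extdata", "table1.csv", package = "bbbivivc"))),
    bbbivivc:::TABLE1_MD5)
})

test_that("results tables round-trip through write/read at stated precision", {
  res <- tibble::tibble(drug_id = c("a", "b"), model_id = "mono",
                        ps_pre = c(101.046, 13716.004),
                        fold_ratio = c(0.6203, 2.9766))
  path <- tempfile(fileext = ".csv")
  write_results_table(res, path, digits = 2)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$ps_pre, round(res$ps_pre, 2))
  expect_equal(back$fold_ratio, round(res$fold_ratio, 2))
  expect_equal(names(back)[1:2], c("drug_id", "model_id"))

  expect_error(write_results_table(res[0, ], tempfile()), "non-empty")
})

test_that("drug and TEER tables validate their domains", {
  p <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(drug_id = "x", fu_brain = 1.5,
                                  ps_obs_ul_min_g = 10), p)
  expect_error(read_drugs_table(p), "fu_brain")

  readr::write_csv(tibble::tibble(insert_id = "i1", model_id = "mono",
                                  day = 1, resistance_ohm = -5,
                                  is_blank = FALSE, area_cm2 = 0.33), p)
  expect_error(read_teer_table(p), "resistance")
})

test_that("config round-trips through YAML and rejects unknown fields", {
  cfg <- bbb_config(sink_threshold = 0.2, vsa_cm2_g = 100)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(bbb_config(nope = 1), "unknown config")
})
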