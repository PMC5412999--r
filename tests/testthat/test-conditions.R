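test_that("titrant accounting reproduces the documented chloride totals", {
  sc <- load_scenario("fig2_variableCl")
  conds <- build_conditions(sc$schedule, c(2.33, 3.0, 3.18, 3.5, 7.0))
  tot <- setNames(conds$total_Cl_mM, conds$pH)
  expect_equal(unname(tot["3.5"]), 1.27, tolerance = 1e-12)
  expect_equal(unname(tot["7"]), 1.27, tolerance = 1e-12)
  expect_equal(unname(tot["2.33"]), 4.54, tolerance = 1e-9)
  expect_true(all(diff(conds$total_Cl_mM[order(conds$pH)]) <= 0))
  # acid-derived Cl bookkeeping is exact
  v_L <- sc$schedule$volume_mL / 1000
  expect_equal(conds$total_Cl_mM - 1.27,
               conds$acid_added_mmol / v_L, tolerance = 1e-12)
})

test_that("background-only schedules return the background and misuse errors", {
  sch <- titration_schedule(background = c(Na = 0.15, Cl = 0.15),
                            additions = data.frame(acid_added_mmol = c(0, 0),
                                                   base_added_mmol = c(0, 0)))
  conds <- build_conditions(sch, c(4, 8))
  expect_equal(conds$total_Na_mM, c(0.15, 0.15))
  expect_equal(conds$total_Cl_mM, c(0.15, 0.15))
  both <- titration_schedule(additions = data.frame(acid_added_mmol = 1,
                                                    base_added_mmol = 1))
  expect_error(build_conditions(both, 5), class = "ionex_data_error")
  expect_error(build_conditions(sch, c(4, 8, 9)), class = "ionex_data_error")
})

test_that("published offsets shift observations and totals once, reversibly", {
  ds <- envelope_dataset(tibble::tibble(
    pH = c(3, 6, 9), total_Na_mM = 0.15, total_Cl_mM = 0.15,
    gamma_H = c(1.0, 0.0, -0.8), gamma_Cl = c(0.9, 0.1, 0.0)
  ))
  ds2 <- apply_offsets(ds) # defaults: +0.50 H, +0.11 Cl, +0.011 mM Cl
  expect_equal(ds2$gamma_H, c(1.5, 0.5, -0.3))
  expect_equal(ds2$gamma_Cl, c(1.01, 0.21, 0.11))
  expect_equal(ds2$total_Cl_mM, rep(0.161, 3))
  expect_equal(ds2$total_Na_mM, rep(0.15, 3))
  # a second application is refused
  expect_error(apply_offsets(ds2), class = "ionex_contract_error")
  # reversible with negated offsets once the record is cleared
  attr(ds2, "offsets_applied") <- list()
  ds3 <- apply_offsets(ds2, proton_offset = -0.50, ion_offsets = c(Cl = -0.11),
                       total_increments_mM = c(Cl = -0.011))
  expect_equal(ds3$gamma_H, ds$gamma_H)
  expect_equal(ds3$gamma_Cl, ds$gamma_Cl)
  expect_equal(ds3$total_Cl_mM, ds$total_Cl_mM)
  # zero offsets are the identity
  ds0 <- apply_offsets(ds, proton_offset = 0, ion_offsets = c(),
                       total_increments_mM = c())
  expect_equal(ds0$gamma_H, ds$gamma_H)
})

test_that("dataset CSVs round-trip and are validated on read", {
  ds <- envelope_dataset(tibble::tibble(
    condition_id = c("a", "b"), pH = c(3.2, 8.1),
    total_Na_mM = c(0.15, 0.4), total_Cl_mM = c(2.1, 0.15),
    total_L_mM = c(1, 1), gamma_H = c(2.2, -0.1), gamma_L = c(1.4, 1.2)
  ))
  path <- file.path(tempdir(), "ds.csv")
  write_envelope_csv(ds, path, header_comment = "round-trip fixture")
  back <- read_envelope_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  # gamma_Na column absent: loads with Na observations missing
  expect_false("gamma_Na" %in% names(back))

  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("condition_id,pH,gamma_H", "a,3.0,1.0", "b,-2,0.5"), bad)
  expect_error(read_envelope_csv(bad), regexp = "line 3",
               class = "ionex_data_error")
  unk <- file.path(tempdir(), "unk.csv")
  writeLines(c("pH,gamma_Xx", "3,0.1"), unk)
  expect_error(read_envelope_csv(unk), class = "ionex_schema_error")
  expect_error(read_envelope_csv(file.path(tempdir(), "absent.csv")),
               class = "ionex_io_error")
})
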