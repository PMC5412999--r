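test_that("single-datum pK solves reproduce the three calibrated formulations", {
  # one datum: pH 6, 0.5 umol/m2 adsorbed, 1.0 mM total phthalate
  eq6 <- exchange_reaction("S", c(H = 1, L = 0.5), "SOH2L0.5", pK = 0)
  eq7 <- exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = 0, n_soh = 2)
  eq8 <- exchange_reaction("S", c(H = 2, L = 1), "SOH2LH", pK = 0)
  expect_lt(abs(solve_single_point_pk(eq6, 6, 0.5, 1.0, 0.2) - (-7.51)), 0.01)
  expect_lt(abs(solve_single_point_pk(eq7, 6, 0.5, 1.0, 0.2) - (-18.72)), 0.01)
  expect_lt(abs(solve_single_point_pk(eq8, 6, 0.5, 1.0, 0.1) - (-15.02)), 0.01)
  # the returned pK makes the forward prediction pass through the datum
  sc <- load_scenario("fig1_eq7")
  m <- ionex:::set_pks(sc$model,
                       c(S_L_bidentate = solve_single_point_pk(eq7, 6, 0.5,
                                                               1.0, 0.2)))
  sol <- solve_equilibrium(m, list(pH = 6, totals = c(L = 1e-3)))
  expect_equal(unname(sol$adsorbed["L"]), 0.5, tolerance = 1e-6)
})

test_that("infeasible single-datum targets are rejected with the saturation limit", {
  eq7 <- exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = 0, n_soh = 2)
  expect_error(solve_single_point_pk(eq7, 6, 1.2, 1.0, 0.2),
               regexp = "saturation", class = "ionex_domain_error")
})

test_that("the root-solve path agrees with the closed form when chemistry is off", {
  eq7 <- exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = 0, n_soh = 2)
  closed <- solve_single_point_pk(eq7, 6, 0.5, 1.0, 0.2)
  # aqueous protonation barely matters at pH 6 >> pKa2, but the path differs
  rooted <- solve_single_point_pk(eq7, 6, 0.5, 1.0, 0.2,
                                  aqueous_reactions = phthalate_reactions(
                                    na_pair = FALSE))
  expect_equal(rooted, closed, tolerance = 0.01)
})

test_that("R^2 matches its definition and rejects degenerate inputs", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  obs <- c(0.3, 0.9, 1.4, 2.0)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), class = "ionex_domain_error")
  expect_error(r_squared(1, 1), class = "ionex_domain_error")
})

test_that("a staged fit on one datum matches the closed-form solve", {
  sc <- load_scenario("fig1_eq7")
  ds <- envelope_dataset(tibble::tibble(
    condition_id = "d1", pH = 6, total_L_mM = 1.0, gamma_L = 0.5
  ), geometry = iex_geometry(100, 1))
  start <- ionex:::set_pks(sc$model, c(S_L_bidentate = -15))
  fit <- fit_pks(start, ds, fit_plan(fit_stage("S_L_bidentate", ions = "L")))
  expect_equal(fit$model$surface_reactions$pK, -18.72, tolerance = 1e-4)
})

test_that("noiseless synthetic envelopes return the generating pKs", {
  sc <- load_scenario("fig2_variableCl")
  ds <- generate_synthetic_envelope(sc$model, sc$schedule,
                                    pH_grid = seq(2.3, 10.4, length.out = 20),
                                    sigma = 0)
  start <- ionex:::set_pks(sc$model, c(S_Cl = -6.5, S_L = -16))
  fit <- fit_pks(start, ds,
                 fit_plan(fit_stage(c("S_Cl", "S_L"), ions = c("Cl", "L"))))
  pk <- setNames(fit$model$surface_reactions$pK, fit$model$surface_reactions$id)
  expect_equal(unname(pk["S_Cl"]), -8, tolerance = 0.01)
  expect_equal(unname(pk["S_L"]), -18.7, tolerance = 0.01)
  # accepted stages never worsen the objective
  expect_true(all(fit$diagnostics$sse_final <=
                    fit$diagnostics$sse_initial + 1e-12))
})

test_that("recovery error grows with measurement noise", {
  sc <- load_scenario("fig1_eq7") # single free parameter
  sch <- titration_schedule(background = c(Cl = 0.15),
                            fixed_additions = c(L = 1.0), zpt = 3.18)
  rmse_at <- function(sigma, reps) {
    errs <- vapply(seq_len(reps), function(r) {
      ds <- generate_synthetic_envelope(sc$model, sch,
                                        pH_grid = seq(2.5, 10, length.out = 15),
                                        sigma = sigma, seed = 300 + r)
      fit <- fit_pks(sc$model, ds,
                     fit_plan(fit_stage("S_L_bidentate", ions = "L")))
      fit$model$surface_reactions$pK - (-18.72)
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_at(0.02, 6), rmse_at(0.2, 6))
})

test_that("invalid fit plans are rejected", {
  sc <- load_scenario("fig2_fixedCl")
  ds <- envelope_dataset(tibble::tibble(condition_id = "x", pH = 4,
                                        total_L_mM = 1, total_Cl_mM = 4.54,
                                        gamma_L = 0.7),
                         geometry = iex_geometry(100, 1))
  expect_error(fit_pks(sc$model, ds,
                       fit_plan(fit_stage("not_a_reaction", ions = "L"))),
               class = "ionex_contract_error")
  expect_error(fit_pks(sc$model, ds,
                       fit_plan(fit_stage("S_L", window = c(8, 10),
                                          ions = "L"))),
               class = "ionex_data_error")
  expect_error(fit_stage("x", window = c(-1, 3), ions = "L"))
})

test_that("tidy and glance summarize a fit", {
  sc <- load_scenario("fig1_eq7")
  ds <- generate_synthetic_envelope(
    sc$model, titration_schedule(background = c(Cl = 0.15),
                                 fixed_additions = c(L = 1.0), zpt = 3.18),
    pH_grid = seq(3, 9, length.out = 8), sigma = 0.02, seed = 7)
  fit <- fit_pks(sc$model, ds,
                 fit_plan(fit_stage("S_L_bidentate", ions = "L")))
  td <- tidy(fit)
  expect_true(all(c("id", "site", "product", "pK", "delta_G_kJ") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$r2_L > 0.9)
  expect_lte(gl$r2_L, 1)
})
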