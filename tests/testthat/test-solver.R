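test_that("single-reaction solutions match the closed-form quadratic oracle", {
  g100 <- iex_geometry(100, 1)
  for (pK in c(-6, -8, -10)) {
    for (pH in c(3, 4.5, 6)) {
      for (tot in c(5e-4, 1e-3, 4.54e-3)) {
        m <- single_cl_model(pK = pK)
        sol <- solve_equilibrium(m, list(pH = pH, totals = c(Cl = tot)))
        a <- quad_complex_conc(pK, pH, 2e-4, tot)
        expect_equal(unname(sol$adsorbed["Cl"]),
                     ionex:::molar_to_gamma(a, g100), tolerance = 1e-8)
      }
    }
  }
  # the worked example: pK -8, pH 4, 1 mM Cl, 0.2 mM capacity
  sol <- solve_equilibrium(single_cl_model(), list(pH = 4, totals = c(Cl = 1e-3)))
  expect_equal(unname(sol$adsorbed["Cl"]), 1.78301, tolerance = 1e-5)
})

test_that("with no binding the surface stays bare and free equals total", {
  m <- single_cl_model(pK = 30) # K = 1e-30: effectively no reaction
  sol <- solve_equilibrium(m, list(pH = 4, totals = c(Cl = 1e-3)))
  expect_lt(unname(sol$adsorbed["Cl"]), 1e-12)
  expect_equal(unname(sol$free["Cl"]), 1e-3, tolerance = 1e-10)
  expect_equal(sol$surface$conc[sol$surface$species == "SOH"], 2e-4,
               tolerance = 1e-10)
})

test_that("site conservation and component mass balance hold at every solution", {
  sc2 <- load_scenario("fig2_fixedCl")
  sol <- solve_equilibrium(sc2$model, list(pH = 3, totals = c(Cl = 4.54e-3,
                                                              L = 1e-3)))
  expect_lt(max(balance_errors(sc2$model, sol)), 1e-10)

  t2 <- load_scenario("table2_goethite_phthalate")
  conds <- build_conditions(t2$schedule, c(2.5, 4.2, 6.8, 9.7))
  for (i in seq_len(nrow(conds))) {
    sol <- solve_equilibrium(t2$model, conds[i, ])
    expect_lt(max(balance_errors(t2$model, sol)), 1e-10)
  }
})

test_that("anion coadsorption is non-increasing in pH at fixed totals", {
  env <- predict_envelope(single_cl_model(),
                          tibble::tibble(pH = seq(2, 11, 0.5),
                                         total_Cl_mM = 1.0))
  expect_true(all(diff(env$gamma_Cl) <= 1e-12))
})

test_that("adding a competing reaction never increases another ion's adsorption", {
  no_cl <- load_scenario("fig2_noCl")$model
  with_cl <- load_scenario("fig2_fixedCl")$model
  grid <- seq(2, 11, 0.5)
  e0 <- predict_envelope(no_cl, tibble::tibble(pH = grid, total_L_mM = 1.0))
  e1 <- predict_envelope(with_cl, tibble::tibble(pH = grid, total_L_mM = 1.0,
                                                 total_Cl_mM = 4.54))
  expect_true(all(e1$gamma_L <= e0$gamma_L + 1e-12))
  # the fixed-competitor curve is the same shape, vertically scaled: the
  # ratio is flat across the saturated low-pH plateau
  low <- e1$pH <= 3.5
  ratio <- e1$gamma_L[low] / e0$gamma_L[low]
  expect_lt(diff(range(ratio)), 0.01)
  expect_equal(mean(ratio), 0.722 / 1.0, tolerance = 0.01)
})

test_that("predictions are deterministic and duplicated conditions identical", {
  sc <- load_scenario("fig2_fixedCl")
  cond <- tibble::tibble(condition_id = c("a", "b"), pH = 4,
                         total_L_mM = 1, total_Cl_mM = 4.54)
  env <- predict_envelope(sc$model, cond)
  expect_equal(env$gamma_L[1], env$gamma_L[2])
  env2 <- predict_envelope(sc$model, cond)
  expect_identical(env$gamma_L, env2$gamma_L)
})

test_that("derived proton adsorption follows the surface stoichiometry", {
  # 1:1 H:Cl coadsorption
  env <- predict_envelope(single_cl_model(),
                          tibble::tibble(pH = seq(3, 9, 1), total_Cl_mM = 1))
  expect_equal(env$gamma_H, env$gamma_Cl, tolerance = 1e-12)
  # Na+/H+ exchange releases one proton per adsorbed Na
  envna <- predict_envelope(single_na_model(),
                            tibble::tibble(pH = seq(3, 11, 1), total_Na_mM = 1))
  expect_equal(envna$gamma_H, -envna$gamma_Na, tolerance = 1e-12)
  # 2:1 H:L plus 1:1 H:Cl at the competitive plateau
  sol <- solve_equilibrium(load_scenario("fig2_fixedCl")$model,
                           list(pH = 3, totals = c(Cl = 4.54e-3, L = 1e-3)))
  expect_equal(predict_proton_adsorption(sol),
               unname(2 * sol$adsorbed["L"] + sol$adsorbed["Cl"]),
               tolerance = 1e-12)
})

test_that("solver reports conditions and errors usefully", {
  sc <- load_scenario("fig2_fixedCl")
  expect_error(predict_envelope(sc$model, tibble::tibble(pH = numeric())),
               class = "ionex_contract_error")
  expect_error(solve_equilibrium(sc$model, list(pH = 15, totals = c(L = 1e-3))),
               class = "ionex_domain_error")
  m_nog <- iex_model(iex_site("S", 2),
                     exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", -8),
                     components = iex_components()[c(1, 3), ])
  expect_error(solve_equilibrium(m_nog, list(pH = 4, totals = c(Cl = 1e-3))),
               class = "ionex_config_error")
})
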