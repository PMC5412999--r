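test_that("model validation enforces strict charge neutrality and references", {
  s <- iex_site("S", 2.0)
  g <- iex_geometry(100, 1)
  # Cl- alone would leave a charged surface species
  expect_error(
    iex_model(s, exchange_reaction("S", c(Cl = 1), "SOCl", pK = -8),
              geometry = g),
    class = "ionex_charge_error")
  # half a divalent ion balances one proton (fractional stoichiometry)
  expect_silent(
    iex_model(s, exchange_reaction("S", c(H = 1, L = 0.5), "SOH2L0.5",
                                   pK = -7.5), geometry = g))
  # undeclared component
  expect_error(
    iex_model(s, exchange_reaction("S", c(H = 1, Br = 1), "SOH2Br", pK = -8),
              geometry = g),
    class = "ionex_contract_error")
  # undeclared site
  expect_error(
    iex_model(s, exchange_reaction("T", c(H = 1, Cl = 1), "TOH2Cl", pK = -8),
              geometry = g),
    class = "ionex_contract_error")
  expect_error(iex_site("S", 0), class = "ionex_domain_error")
  expect_error(
    iex_model(list(s, iex_site("S", 1)), list(), geometry = g),
    class = "ionex_contract_error")
})

test_that("hydroxide-release rewriting shifts the pK by pKw and is an involution", {
  eq2 <- exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", pK = -8)
  eq3 <- formulation_shift(eq2, "hydroxide-release")
  expect_equal(eq3$pK, -8 + 14)
  expect_equal(unname(eq3$consumed["OH"]), -1) # OH- released
  # Na+/H+ exchange releases a proton; its OH form consumes one hydroxide
  eq4 <- exchange_reaction("S", c(Na = 1, H = -1), "SONa", pK = 8.8)
  eq5 <- formulation_shift(eq4, "hydroxide-release")
  expect_equal(eq5$pK, 8.8 - 14)
  expect_equal(unname(eq5$consumed["OH"]), 1)
  # involution
  back <- formulation_shift(eq3, "hydroxide-release")
  expect_equal(back$pK, eq2$pK)
  expect_equal(back$consumed[order(names(back$consumed))],
               eq2$consumed[order(names(eq2$consumed))])
  no_h <- exchange_reaction("S", c(Na = 1, Cl = 1), "SNaCl", pK = 1)
  expect_error(formulation_shift(no_h, "hydroxide-release"),
               class = "ionex_contract_error")
})

test_that("half-reaction rewriting halves pK and stoichiometry (K_whole = K_half^2)", {
  eq7 <- exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = -18.72,
                           n_soh = 2)
  eq9 <- formulation_shift(eq7, "half-reaction")
  expect_equal(eq9$pK, -9.36)
  expect_equal(eq9$n_soh, 1)
  expect_equal(unname(eq9$consumed[c("H", "L")]), c(1, 0.5))
  expect_equal(eq9$scale, 0.5)
  back <- formulation_shift(eq9, "half-reaction")
  expect_equal(back$pK, eq7$pK)
  expect_equal(back$scale, 1)
  # an odd SOH count cannot be halved into integer site occupation
  odd <- exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", pK = -8)
  expect_error(formulation_shift(odd, "half-reaction"),
               class = "ionex_contract_error")
})

test_that("rewritten models predict identically to the original", {
  sc <- load_scenario("fig2_fixedCl")
  grid <- tibble::tibble(pH = seq(2, 11, by = 0.5), total_L_mM = 1.0,
                         total_Cl_mM = 4.54)
  m_shift <- sc$model |>
    shift_model_reaction("S_Cl", "hydroxide-release") |>
    shift_model_reaction("S_L", "half-reaction")
  e0 <- predict_envelope(sc$model, grid)
  e1 <- predict_envelope(m_shift, grid)
  for (col in c("gamma_H", "gamma_Cl", "gamma_L")) {
    expect_lt(max(abs(e0[[col]] - e1[[col]])), 1e-8)
  }
})

test_that("model YAML and JSON serialization round-trips", {
  sc <- load_scenario("table2_goethite_phthalate")
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("model.", ext))
    write_model(sc$model, path)
    m2 <- read_model(path)
    expect_equal(m2$surface_reactions$pK, sc$model$surface_reactions$pK)
    expect_equal(m2$sites, sc$model$sites)
    expect_equal(m2$aqueous_reactions$logK, sc$model$aqueous_reactions$logK)
    cond <- list(pH = 4, totals = c(Na = 2e-4, Cl = 1e-3, L = 1e-3))
    expect_equal(solve_equilibrium(m2, cond)$adsorbed,
                 solve_equilibrium(sc$model, cond)$adsorbed, tolerance = 1e-10)
  }
  expect_error(read_model(file.path(tempdir(), "nope.yaml")),
               class = "ionex_io_error")
})

test_that("tied pK parameters move together and fixed ones are protected", {
  sc <- load_scenario("table2_goethite_phthalate")
  m2 <- ionex:::set_pks(sc$model, c(L_minor = -19))
  tied <- m2$surface_reactions$pK[m2$surface_reactions$tie_group %in% "L_minor"]
  expect_equal(tied, rep(-19, 3))
  expect_error(ionex:::set_pks(sc$model, c(Sa_Na = 5)),
               class = "ionex_contract_error") # estimated value, fixed
})
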