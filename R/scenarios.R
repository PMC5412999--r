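# Self-contained scenario fixtures -- the in-package simulation and model
# setups used throughout the documentation and tests -- plus a synthetic
# envelope generator for parameter-recovery studies.

#' Scenario names
#'
#' @return Character vector of the shipped scenario names.
#' @export
scenario_names <- function() {
  c("fig1_eq6", "fig1_eq7", "fig1_eq8",
    "fig2_noCl", "fig2_fixedCl", "fig2_variableCl",
    "table1_goethite", "table2_goethite_phthalate")
}

# goethite suspension used for the full four-site models
goethite_geometry <- function() iex_geometry(surface_area = 29.50,
                                             solids_conc = 3.43)

# single-datum optimization setups: one site, one phthalate reaction,
# 1.0 mM total phthalate, no aqueous protonation, 100 m2/L loading
fig1_reactions <- function() {
  list(
    eq6 = exchange_reaction("S", c(H = 1, L = 0.5), "SOH2L0.5", pK = -7.51,
                            n_soh = 1, id = "S_L_half"),
    eq7 = exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = -18.72,
                            n_soh = 2, id = "S_L_bidentate"),
    eq8 = exchange_reaction("S", c(H = 2, L = 1), "SOH2LH", pK = -15.02,
                            n_soh = 1, id = "S_L_monodentate")
  )
}

# anchored interpolation in [H+] between the two printed chloride totals of
# the pH-variable simulation: 1.27 mM at and above pH 3.18, 4.54 mM at
# pH 2.33
fig2_variable_cl_rule <- function(pH) {
  lo <- 10^(-3.18); hi <- 10^(-2.33)
  extra <- (4.54e-3 - 1.27e-3) * (10^(-pH) - lo) / (hi - lo)
  pmax(0, extra)
}

#' Load a shipped scenario
#'
#' Each scenario bundles a fully parameterized model with the conditions
#' (or titration schedule) of a documented simulation or experiment, and
#' needs no external file:
#'
#' * `fig1_eq6` / `fig1_eq7` / `fig1_eq8` — the three alternative phthalate
#'   reaction formulations, each calibrated so the predicted envelope
#'   passes through one datum (pH 6, 0.5 µmol m⁻²) at 1.0 mM total
#'   phthalate; site capacity 0.2 mM (0.1 mM for the two-proton
#'   monodentate form); no aqueous protonation.
#' * `fig2_noCl` / `fig2_fixedCl` / `fig2_variableCl` — the competitive
#'   chloride/phthalate simulation (pK −8 for SOH₂Cl, −18.7 for the
#'   bidentate phthalate complex, capacity 0.2 mM, 1.0 mM phthalate) with
#'   chloride absent, fixed at 4.54 mM, or rising below pH 3.18 from
#'   1.27 mM to 4.54 mM at pH 2.33 as HCl is added.
#' * `table1_goethite` — the four-site H⁺/Na⁺/Cl⁻ exchange model for
#'   goethite (Γ_max 2.2/1.3/0.5/0.4 µmol m⁻², total 4.4).
#' * `table2_goethite_phthalate` — the four-site competitive model with
#'   bidentate phthalate on every site (three minor sites tied to one pK)
#'   and the aqueous phthalate chemistry included.
#'
#' @param name One of [scenario_names()].
#' @return A list of class `iex_scenario`: `name`, `model`, `conditions`
#'   (tibble) and/or `schedule` + `pH_grid`, and for the single-datum
#'   scenarios a `datum` list.
#' @export
load_scenario <- function(name) {
  if (!name %in% scenario_names()) {
    ionex_abort(sprintf("unknown scenario `%s`; see scenario_names()", name),
                "ionex_lookup_error")
  }
  g100 <- iex_geometry(100, 1)
  comps_HL <- iex_components()[c(1, 4), ]   # H, L
  comps_HClL <- iex_components()[c(1, 3, 4), ] # H, Cl, L
  comps_HNaCl <- iex_components()[1:3, ]    # H, Na, Cl

  if (startsWith(name, "fig1")) {
    rx <- fig1_reactions()[[sub("fig1_", "", name)]]
    cap_gamma <- if (name == "fig1_eq8") 1.0 else 2.0
    model <- iex_model(iex_site("S", cap_gamma), list(rx),
                       components = comps_HL, geometry = g100)
    conditions <- tibble(pH = seq(2, 11, by = 0.25), total_L_mM = 1.0)
    return(structure(list(
      name = name, model = model, conditions = conditions,
      datum = list(pH = 6, gamma = 0.5, total_mM = 1.0,
                   capacity_mM = cap_gamma / 10)
    ), class = "iex_scenario"))
  }

  if (startsWith(name, "fig2")) {
    cl_rx <- exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", pK = -8,
                               id = "S_Cl")
    l_rx <- exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = -18.7,
                              n_soh = 2, id = "S_L")
    grid <- seq(2, 11, by = 0.25)
    if (name == "fig2_noCl") {
      model <- iex_model(iex_site("S", 2.0), list(l_rx),
                         components = comps_HL, geometry = g100)
      conditions <- tibble(pH = grid, total_L_mM = 1.0)
      return(structure(list(name = name, model = model,
                            conditions = conditions),
                       class = "iex_scenario"))
    }
    model <- iex_model(iex_site("S", 2.0), list(cl_rx, l_rx),
                       components = comps_HClL, geometry = g100)
    if (name == "fig2_fixedCl") {
      conditions <- tibble(pH = grid, total_L_mM = 1.0, total_Cl_mM = 4.54)
      return(structure(list(name = name, model = model,
                            conditions = conditions),
                       class = "iex_scenario"))
    }
    schedule <- titration_schedule(
      background = c(Cl = 1.27), fixed_additions = c(L = 1.0),
      zpt = 3.18,
      acid_rule = fig2_variable_cl_rule,
      base_rule = function(pH) rep(0, length(pH))
    )
    return(structure(list(name = name, model = model, schedule = schedule,
                          conditions = build_conditions(schedule, grid)),
                     class = "iex_scenario"))
  }

  if (name == "table1_goethite") {
    sites <- list(iex_site("Sa", 2.2), iex_site("Sb", 1.3),
                  iex_site("Sc", 0.5), iex_site("Sd", 0.4))
    rx <- list(
      exchange_reaction("Sa", c(H = 1, Cl = 1), "SaOH2Cl", pK = -5.6, id = "Sa_Cl"),
      exchange_reaction("Sa", c(Na = 1, H = -1), "SaONa", pK = 8.8, id = "Sa_Na",
                        fixed = TRUE), # estimated, never optimized
      exchange_reaction("Sb", c(H = 1, Cl = 1), "SbOH2Cl", pK = -6.6, id = "Sb_Cl"),
      exchange_reaction("Sb", c(Na = 1, H = -1), "SbONa", pK = 8.8, id = "Sb_Na",
                        fixed = TRUE),
      exchange_reaction("Sc", c(H = 1, Cl = 1), "ScOH2Cl", pK = -8.7, id = "Sc_Cl"),
      exchange_reaction("Sc", c(Na = 1, H = -1), "ScONa", pK = 6.8, id = "Sc_Na"),
      exchange_reaction("Sd", c(H = 1, Cl = 1), "SdOH2Cl", pK = -10.5, id = "Sd_Cl"),
      exchange_reaction("Sd", c(Na = 1, H = -1), "SdONa", pK = 2.8, id = "Sd_Na")
    )
    model <- iex_model(sites, rx, components = comps_HNaCl,
                       geometry = goethite_geometry())
    schedule <- titration_schedule(background = c(Na = 0.15, Cl = 0.15),
                                   zpt = 6.41)
    return(structure(list(name = name, model = model, schedule = schedule,
                          pH_grid = default_ph_grid()),
                     class = "iex_scenario"))
  }

  # table2_goethite_phthalate
  sites <- list(iex_site("Sa", 2.2), iex_site("Sb", 1.3),
                iex_site("Sc", 0.5), iex_site("Sd", 0.4))
  rx <- list(
    exchange_reaction("Sa", c(H = 1, Cl = 1), "SaOH2Cl", pK = -6.6, id = "Sa_Cl"),
    exchange_reaction("Sa", c(Na = 1, H = -1), "SaONa", pK = 8.8, id = "Sa_Na",
                      fixed = TRUE),
    exchange_reaction("Sa", c(H = 2, L = 1), "(SaOH2)2L", pK = -17.4,
                      n_soh = 2, id = "Sa_L"),
    exchange_reaction("Sb", c(H = 1, Cl = 1), "SbOH2Cl", pK = -6.6, id = "Sb_Cl"),
    exchange_reaction("Sb", c(Na = 1, H = -1), "SbONa", pK = 8.8, id = "Sb_Na",
                      fixed = TRUE),
    exchange_reaction("Sb", c(H = 2, L = 1), "(SbOH2)2L", pK = -20.8,
                      n_soh = 2, id = "Sb_L", tie_group = "L_minor"),
    exchange_reaction("Sc", c(H = 1, Cl = 1), "ScOH2Cl", pK = -8.7, id = "Sc_Cl"),
    exchange_reaction("Sc", c(Na = 1, H = -1), "ScONa", pK = 8.8, id = "Sc_Na"),
    exchange_reaction("Sc", c(H = 2, L = 1), "(ScOH2)2L", pK = -20.8,
                      n_soh = 2, id = "Sc_L", tie_group = "L_minor"),
    exchange_reaction("Sd", c(H = 1, Cl = 1), "SdOH2Cl", pK = -10.5, id = "Sd_Cl"),
    exchange_reaction("Sd", c(Na = 1, H = -1), "SdONa", pK = 5.4, id = "Sd_Na"),
    exchange_reaction("Sd", c(H = 2, L = 1), "(SdOH2)2L", pK = -20.8,
                      n_soh = 2, id = "Sd_L", tie_group = "L_minor")
  )
  model <- iex_model(sites, rx, aqueous_reactions = phthalate_reactions(),
                     geometry = goethite_geometry())
  schedule <- titration_schedule(background = c(Na = 0.15, Cl = 0.15),
                                 fixed_additions = c(L = 1.0), zpt = 3.18)
  structure(list(name = name, model = model, schedule = schedule,
                 pH_grid = default_ph_grid()),
            class = "iex_scenario")
}

#' @export
print.iex_scenario <- function(x, ...) {
  cat(sprintf("<iex_scenario> %s\n", x$name))
  print(x$model)
  invisible(x)
}

# 28 points over the experimental span
default_ph_grid <- function() seq(2.3, 10.4, length.out = 28)

#' Generate a synthetic adsorption-envelope dataset
#'
#' Builds conditions from a titration schedule, forward-predicts the
#' envelope with the supplied (true) model, and adds iid Gaussian
#' measurement noise per ion.  With `sigma = 0` the observations equal the
#' predictions exactly; a fixed `seed` makes the draw reproducible.  The
#' generating pK values are carried in the `true_pk` attribute for
#' parameter-recovery studies.
#'
#' @param model The generating [iex_model()].
#' @param schedule A [titration_schedule()].
#' @param pH_grid Equilibrium pH values (default 28 points over 2.3–10.4).
#' @param sigma Noise sd in µmol m⁻²; scalar, or named per ion
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @param geometry [iex_geometry()] override.
#' @return An [envelope_dataset()] whose `gamma_<ion>` columns are noisy
#'   observations of the model's predictions.
#' @export
generate_synthetic_envelope <- function(model, schedule,
                                        pH_grid = default_ph_grid(),
                                        sigma = 0.05, seed = NULL,
                                        geometry = NULL) {
  stopifnot(inherits(model, "iex_model"))
  assert_nonnegative(unlist(sigma), "sigma")
  geometry <- geometry %||% model$geometry
  conditions <- build_conditions(schedule, pH_grid)
  pred <- predict_envelope(model, conditions, geometry = geometry)
  pred <- pred[match(conditions$condition_id, pred$condition_id), ]
  if (!is.null(seed)) set.seed(seed)
  out <- conditions
  gcols <- grep("^gamma_", names(pred), value = TRUE)
  sig <- function(ion) {
    s <- as_named_numeric(if (length(sigma) == 1 && is.null(names(sigma))) {
      stats::setNames(sigma, "ALL")
    } else sigma, "sigma")
    unname(s[ion] %|na|% s["ALL"] %|na|% 0)
  }
  for (col in gcols) {
    ion <- sub("^gamma_", "", col)
    out[[col]] <- pred[[col]] + stats::rnorm(nrow(out), 0, sig(ion))
  }
  ds <- envelope_dataset(out, geometry = geometry %||% model$geometry)
  sr <- model$surface_reactions
  attr(ds, "true_pk") <- stats::setNames(sr$pK, sr$id)
  attr(ds, "sigma") <- sigma
  attr(ds, "seed") <- seed
  ds
}
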