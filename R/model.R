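# Domain types for a strict charge-neutral ion-exchange model: aqueous
# components, aqueous formation reactions, surface sites and charge-neutral
# exchange reactions, assembled into an `iex_model`.
#
# Conventions:
#   * equilibrium constants are on a concentration (molar) basis;
#   * surface reactions are written as formations of a neutral surface
#     complex: n_soh SOH + sum(consumed_i ion_i) = product, with
#     K = {product} / ({SOH}^n_soh * prod [ion_i]^consumed_i), pK = -log10 K.
#     A negative `consumed` coefficient places the ion on the product side
#     (e.g. the proton released by Na+/H+ exchange).
#   * `scale` < 1 marks a fractional ("half-reaction") writing of the same
#     physical complex: all stoichiometric coefficients and the pK are the
#     whole reaction's times `scale`.  The solver always works with the
#     whole-reaction (canonical) form, so scaled variants predict
#     identically by construction.

#' Standard aqueous components
#'
#' The four components of the goethite H⁺/Na⁺/Cl⁻/phthalate system.
#' Phthalate is tracked as its fully deprotonated dianion `L`.
#'
#' @param extra Optional tibble with columns `name`, `charge` to append.
#' @return A tibble with columns `name`, `charge`.
#' @export
iex_components <- function(extra = NULL) {
  out <- tibble(name = c("H", "Na", "Cl", "L"),
                charge = c(1, 1, -1, -2))
  if (!is.null(extra)) out <- bind_rows(out, as_tibble(extra))
  if (anyDuplicated(out$name)) {
    ionex_abort("component names must be unique", "ionex_contract_error")
  }
  out
}

#' Aqueous formation reaction
#'
#' Formation of one aqueous species from the components, e.g.
#' `aqueous_reaction("HL", c(H = 1, L = 1), logK = 4.9)` for the first
#' protonation of phthalate.  `logK` is the log10 formation constant on a
#' concentration basis, so \[HL⁻\] = 10^4.9 \[H⁺\]\[L²⁻\].
#'
#' @param species Name of the species formed.
#' @param stoich Named numeric: components consumed (signed).
#' @param logK log10 formation constant.
#' @return A list of class `iex_aqueous_reaction`.
#' @export
aqueous_reaction <- function(species, stoich, logK) {
  stoich <- as_named_numeric(stoich, "stoich")
  if (length(stoich) == 0) {
    ionex_abort("`stoich` must be nonempty", "ionex_contract_error")
  }
  stopifnot(is.character(species), length(species) == 1, is.finite(logK))
  structure(list(species = species, stoich = stoich, logK = logK),
            class = "iex_aqueous_reaction")
}

#' Phthalate aqueous chemistry
#'
#' The protonation reactions of the phthalate dianion (pKa 2.95 and 4.9;
#' formation logK of HL⁻ is 4.9 and of H₂L is 2.95 + 4.9 = 7.85) and,
#' optionally, the weak Na-phthalate ion pair (formation logK 0.7, i.e.
#' pK −0.7).
#'
#' @param na_pair Include the NaL⁻ ion pair? Default `TRUE`.
#' @param pKa1,pKa2 Acid dissociation constants of H₂L and HL⁻.
#' @param logK_NaL log10 formation constant of NaL⁻.
#' @return List of [aqueous_reaction()]s.
#' @export
phthalate_reactions <- function(na_pair = TRUE, pKa1 = 2.95, pKa2 = 4.9,
                                logK_NaL = 0.7) {
  out <- list(
    aqueous_reaction("HL", c(H = 1, L = 1), logK = pKa2),
    aqueous_reaction("H2L", c(H = 2, L = 1), logK = pKa1 + pKa2)
  )
  if (na_pair) {
    out <- c(out, list(aqueous_reaction("NaL", c(Na = 1, L = 1), logK_NaL)))
  }
  out
}

#' Surface site
#'
#' @param name Site identifier (e.g. `"Sa"`).
#' @param gamma_max Site density Γ_max, µmol m⁻² (> 0).
#' @return A list of class `iex_site`.
#' @export
iex_site <- function(name, gamma_max) {
  stopifnot(is.character(name), length(name) == 1)
  assert_positive(gamma_max, "gamma_max")
  structure(list(name = name, gamma_max = gamma_max), class = "iex_site")
}

#' Charge-neutral surface exchange reaction
#'
#' @param site Site the reaction occurs on.
#' @param consumed Named numeric: aqueous components consumed per product
#'   unit (H⁺ included; negative values are released; `OH` allowed for the
#'   hydroxide-release writing).  May be fractional.
#' @param product Name of the neutral surface complex formed.
#' @param pK −log10 of the formation constant.
#' @param n_soh Bare SOH groups consumed per product unit (default 1).
#' @param id Reaction identifier; defaults to `<site>_<product>`.
#' @param scale Fraction of the whole physical reaction this writing
#'   represents (1 = whole reaction, 1/2 = half-reaction form).
#' @param tie_group Optional label; reactions sharing a label are optimized
#'   as one parameter.
#' @param fixed If `TRUE` the pK is never optimized.
#' @return A list of class `iex_reaction`.
#' @examples
#' # SOH + H+ + Cl- = SOH2Cl, pK -8
#' exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", pK = -8)
#' # 2 SOH + 2 H+ + L2- = (SOH2)2L, pK -18.7
#' exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = -18.7, n_soh = 2)
#' @export
exchange_reaction <- function(site, consumed, product, pK, n_soh = 1,
                              id = NULL, scale = 1, tie_group = NA_character_,
                              fixed = FALSE) {
  consumed <- as_named_numeric(consumed, "consumed")
  stopifnot(is.character(site), length(site) == 1,
            is.character(product), length(product) == 1,
            is.finite(pK), is.finite(n_soh), n_soh > 0,
            is.finite(scale), scale > 0, scale <= 1,
            is.logical(fixed))
  if (length(consumed) == 0) {
    ionex_abort("`consumed` must name at least one aqueous component",
                "ionex_contract_error")
  }
  structure(list(
    id = id %||% paste(site, product, sep = "_"),
    site = site, consumed = consumed, product = product,
    n_soh = n_soh, occupancy = n_soh, scale = scale,
    pK = pK, tie_group = as.character(tie_group), fixed = fixed
  ), class = "iex_reaction")
}

#' Assemble an ion-exchange model
#'
#' Bundles sites, surface exchange reactions, aqueous reactions, the
#' component table and the suspension geometry into one validated model.
#' Validation enforces the strict charge-neutral theory: every surface
#' complex must have net charge exactly zero, and every reaction must
#' reference declared sites and components.
#'
#' @param sites List of [iex_site()]s.
#' @param surface_reactions List of [exchange_reaction()]s.
#' @param aqueous_reactions List of [aqueous_reaction()]s (water
#'   self-ionization is always implied and need not be listed).
#' @param components Component tibble, see [iex_components()].
#' @param geometry Default [iex_geometry()] for capacity conversions.
#' @param temperature Kelvin; only used by [gibbs_free_energy()] reporting.
#' @param pKw Water self-ionization pK (default 14.00, 20 °C convention).
#' @return An object of class `iex_model`.
#' @export
iex_model <- function(sites, surface_reactions, aqueous_reactions = list(),
                      components = iex_components(), geometry = NULL,
                      temperature = 293.15, pKw = 14) {
  if (inherits(sites, "iex_site")) sites <- list(sites)
  if (inherits(surface_reactions, "iex_reaction")) {
    surface_reactions <- list(surface_reactions)
  }
  if (inherits(aqueous_reactions, "iex_aqueous_reaction")) {
    aqueous_reactions <- list(aqueous_reactions)
  }
  model <- structure(list(
    components = as_tibble(components),
    sites = tibble(
      site = map_chr(sites, "name"),
      gamma_max = map_dbl(sites, "gamma_max")
    ),
    surface_reactions = tibble(
      id = map_chr(surface_reactions, "id"),
      site = map_chr(surface_reactions, "site"),
      product = map_chr(surface_reactions, "product"),
      n_soh = map_dbl(surface_reactions, "n_soh"),
      occupancy = map_dbl(surface_reactions, "occupancy"),
      scale = map_dbl(surface_reactions, "scale"),
      pK = map_dbl(surface_reactions, "pK"),
      tie_group = map_chr(surface_reactions, "tie_group"),
      fixed = map_lgl(surface_reactions, "fixed"),
      consumed = map(surface_reactions, "consumed")
    ),
    aqueous_reactions = tibble(
      species = map_chr(aqueous_reactions, "species"),
      logK = map_dbl(aqueous_reactions, "logK"),
      stoich = map(aqueous_reactions, "stoich")
    ),
    geometry = geometry,
    temperature = temperature,
    pKw = pKw
  ), class = "iex_model")
  validate_iex_model(model)
  model
}

component_charges <- function(model) {
  # OH- is always available (water); charge -1
  stats::setNames(c(model$components$charge, -1),
                  c(model$components$name, "OH"))
}

validate_iex_model <- function(model) {
  comp <- model$components
  if (anyDuplicated(comp$name)) {
    ionex_abort("component names must be unique", "ionex_contract_error")
  }
  if (any(comp$name == "OH")) {
    ionex_abort("`OH` is reserved for water self-ionization", "ionex_contract_error")
  }
  if (anyDuplicated(model$sites$site)) {
    ionex_abort("site names must be unique", "ionex_contract_error")
  }
  assert_positive(model$sites$gamma_max, "gamma_max")
  if (anyDuplicated(model$surface_reactions$id)) {
    ionex_abort("surface reaction ids must be unique", "ionex_contract_error")
  }
  charges <- component_charges(model)
  for (i in seq_len(nrow(model$surface_reactions))) {
    r <- model$surface_reactions[i, ]
    nu <- r$consumed[[1]]
    unknown <- setdiff(names(nu), names(charges))
    if (length(unknown) > 0) {
      ionex_abort(sprintf("reaction `%s` uses undeclared component(s): %s",
                          r$id, paste(unknown, collapse = ", ")),
                  "ionex_contract_error")
    }
    if (!r$site %in% model$sites$site) {
      ionex_abort(sprintf("reaction `%s` references undeclared site `%s`",
                          r$id, r$site), "ionex_contract_error")
    }
    # strict charge neutrality: SOH is neutral, so the product charge is the
    # stoichiometric sum of consumed ion charges; it must vanish exactly
    q <- sum(nu * charges[names(nu)])
    if (abs(q) > 1e-9) {
      ionex_abort(sprintf(
        "reaction `%s` forms a charged surface species (net charge %+g); only charge-neutral surface complexes are allowed",
        r$id, q), "ionex_charge_error")
    }
    if (abs(r$occupancy - r$n_soh) > 1e-12) {
      ionex_abort(sprintf("reaction `%s`: occupancy must equal n_soh", r$id),
                  "ionex_contract_error")
    }
  }
  for (i in seq_len(nrow(model$aqueous_reactions))) {
    a <- model$aqueous_reactions[i, ]
    unknown <- setdiff(names(a$stoich[[1]]), comp$name)
    if (length(unknown) > 0) {
      ionex_abort(sprintf("aqueous species `%s` uses undeclared component(s): %s",
                          a$species, paste(unknown, collapse = ", ")),
                  "ionex_contract_error")
    }
  }
  invisible(model)
}

#' @export
print.iex_model <- function(x, ...) {
  cat(sprintf("<iex_model> %d site(s), %d surface reaction(s), %d aqueous reaction(s)\n",
              nrow(x$sites), nrow(x$surface_reactions), nrow(x$aqueous_reactions)))
  cat(sprintf("  sites: %s (sum %.3g umol/m2)\n",
              paste(sprintf("%s=%.3g", x$sites$site, x$sites$gamma_max),
                    collapse = ", "),
              sum(x$sites$gamma_max)))
  print(reaction_table(x), n = Inf)
  invisible(x)
}

#' Surface-reaction summary table
#'
#' One row per surface reaction: id, site, product, pK, ΔG° (kJ mol⁻¹ at
#' the model temperature), tie group and fixed flag.
#'
#' @param model An `iex_model`.
#' @return A tibble.
#' @export
reaction_table <- function(model) {
  model$surface_reactions |>
    mutate(delta_G_kJ = gibbs_free_energy(.data$pK / .data$scale,
                                          model$temperature)) |>
    select("id", "site", "product", "n_soh", "scale", "pK", "delta_G_kJ",
           "tie_group", "fixed")
}

# replace pK values by parameter name (tie_group when present, else id);
# fixed reactions are never touched
set_pks <- function(model, values) {
  values <- as_named_numeric(values, "values")
  sr <- model$surface_reactions
  par <- ifelse(is.na(sr$tie_group), sr$id, sr$tie_group)
  known <- par %in% names(values) & !sr$fixed
  bad <- setdiff(names(values), par[!sr$fixed])
  if (length(bad) > 0) {
    ionex_abort(sprintf("unknown or fixed pK parameter(s): %s",
                        paste(bad, collapse = ", ")), "ionex_contract_error")
  }
  sr$pK[known] <- unname(values[par[known]])
  model$surface_reactions <- sr
  model
}

pk_parameters <- function(model) {
  sr <- model$surface_reactions
  unique(ifelse(is.na(sr$tie_group), sr$id, sr$tie_group)[!sr$fixed])
}

#' Rewrite an exchange reaction in a mathematically equivalent form
#'
#' Two rewritings leave every model prediction unchanged:
#'
#' * `"hydroxide-release"` swaps consumed H⁺ for released OH⁻ (or back),
#'   shifting the pK by the swapped proton coefficient times pKw, since
#'   \[OH⁻\] = Kw / \[H⁺\] is fixed at any pH.
#' * `"half-reaction"` halves every stoichiometric coefficient and the pK
#'   (K_whole = K_half²); applying it to a half form doubles it back.
#'
#' @param reaction An [exchange_reaction()].
#' @param variant `"hydroxide-release"` or `"half-reaction"`.
#' @param pKw Water pK (default 14).
#' @return The transformed `iex_reaction`.
#' @examples
#' eq2 <- exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", pK = -8)
#' formulation_shift(eq2, "hydroxide-release")$pK # -8 + 14 = 6
#' @export
formulation_shift <- function(reaction,
                              variant = c("hydroxide-release", "half-reaction"),
                              pKw = 14) {
  stopifnot(inherits(reaction, "iex_reaction"))
  variant <- match.arg(variant)
  r <- reaction
  if (variant == "hydroxide-release") {
    nu_h <- r$consumed["H"]
    nu_oh <- r$consumed["OH"]
    if (!is.na(nu_h) && nu_h != 0) {
      # H+ form -> OH- form: consumed nu_h H+ becomes released nu_h OH-
      r$consumed <- r$consumed[names(r$consumed) != "H"]
      r$consumed["OH"] <- (if (is.na(nu_oh)) 0 else unname(nu_oh)) - unname(nu_h)
      r$pK <- r$pK + unname(nu_h) * pKw
    } else if (!is.na(nu_oh) && nu_oh != 0) {
      # OH- form -> H+ form
      r$consumed <- r$consumed[names(r$consumed) != "OH"]
      r$consumed["H"] <- -unname(nu_oh)
      r$pK <- r$pK + unname(nu_oh) * pKw
    } else {
      ionex_abort("hydroxide-release shift needs a nonzero H+ or OH- coefficient",
                  "ionex_contract_error")
    }
    r$consumed <- r$consumed[r$consumed != 0]
  } else { # half-reaction
    if (r$scale == 1) {
      if (abs(r$n_soh %% 2) > 1e-12) {
        ionex_abort("half-reaction form needs an even number of SOH per product",
                    "ionex_contract_error")
      }
      r$n_soh <- r$n_soh / 2
      r$occupancy <- r$n_soh
      r$consumed <- r$consumed / 2
      r$pK <- r$pK / 2
      r$scale <- 1 / 2
    } else if (abs(r$scale - 0.5) < 1e-12) {
      r$n_soh <- r$n_soh * 2
      r$occupancy <- r$n_soh
      r$consumed <- r$consumed * 2
      r$pK <- r$pK * 2
      r$scale <- 1
    } else {
      ionex_abort("half-reaction shift only toggles between scale 1 and 1/2",
                  "ionex_contract_error")
    }
  }
  r
}

#' Apply a formulation shift to one reaction inside a model
#'
#' @param model An `iex_model`.
#' @param id Reaction id to rewrite.
#' @param variant Passed to [formulation_shift()].
#' @return The model with the reaction replaced (predictions unchanged).
#' @export
shift_model_reaction <- function(model, id, variant) {
  sr <- model$surface_reactions
  i <- match(id, sr$id)
  if (is.na(i)) {
    ionex_abort(sprintf("no surface reaction with id `%s`", id),
                "ionex_contract_error")
  }
  r <- structure(as.list(sr[i, , drop = FALSE]), class = "iex_reaction")
  r$consumed <- sr$consumed[[i]]
  r2 <- formulation_shift(r, variant, pKw = model$pKw)
  sr$n_soh[i] <- r2$n_soh
  sr$occupancy[i] <- r2$occupancy
  sr$scale[i] <- r2$scale
  sr$pK[i] <- r2$pK
  sr$consumed[[i]] <- r2$consumed
  model$surface_reactions <- sr
  validate_iex_model(model)
  model
}
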