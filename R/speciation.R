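# Aqueous-phase equilibrium speciation at fixed pH.  Uses the same
# log-scale Newton tableau as the surface solver (with no site unknowns),
# so arbitrary species sets -- protonation ladders, ion pairs -- are handled
# uniformly even where a closed form exists.

#' Aqueous speciation at fixed pH
#'
#' Distributes the component totals over the free ions and the declared
#' aqueous complexes (e.g. HL⁻, H₂L, NaL⁻) at a fixed \[H⁺\] = 10^−pH.
#' Mass action holds for every species and mass balance holds for every
#' component to a relative 1e-12.
#'
#' @param totals Named numeric, component totals in mol/L (protons excluded;
#'   the pH fixes them).
#' @param pH Solution pH in \[0, 14\].
#' @param reactions List of [aqueous_reaction()]s, e.g.
#'   [phthalate_reactions()].
#' @param components Component table (default [iex_components()]).
#' @param pKw Water self-ionization pK.
#' @return An `iex_speciation`: list with `free` (named, mol/L), `species`
#'   tibble (`species`, `conc`), and `fractions` tibble (`component`,
#'   `species`, `fraction`) where each component's fractions sum to 1.
#' @examples
#' sp <- speciate(c(L = 1e-3), pH = 3.5, phthalate_reactions(na_pair = FALSE))
#' sp$fractions # about H2L 0.213, HL 0.757, L 0.030
#' @export
speciate <- function(totals, pH, reactions, components = iex_components(),
                     pKw = 14) {
  totals <- as_named_numeric(totals, "totals")
  assert_nonnegative(totals, "totals")
  if (pH < 0 || pH > 14) {
    ionex_abort("pH must lie in [0, 14]", "ionex_domain_error")
  }
  # an aqueous-only model reuses the coupled solver's tableau machinery;
  # the placeholder site never exchanges and is dropped from the outputs
  model <- iex_model(
    sites = iex_site(".none", 1),
    surface_reactions = list(),
    aqueous_reactions = reactions,
    components = components,
    pKw = pKw
  )
  cm <- compile_model(model)
  pt <- solve_point(cm, pH, totals, capacities = 1e-9)
  is_free <- pt$type == "free"
  is_aq <- pt$type == "aqueous"
  free <- stats::setNames(numeric(length(cm$comps)), cm$comps)
  free[pt$name[is_free]] <- pt$conc[is_free]
  species <- tibble(species = pt$name[is_aq], conc = pt$conc[is_aq])
  # per-component fractions over that component's species (free included)
  frac <- list()
  for (comp in names(totals)[totals > 0]) {
    nu_free <- tibble(species = comp, nu = 1, conc = free[[comp]])
    in_aq <- which(is_aq & pt$name != "OH")
    nus <- map_dbl(pt$idx[in_aq], function(i) {
      a <- cm$aq$A[i, , drop = TRUE]
      if (comp %in% names(a)) a[[comp]] else 0
    })
    keep <- nus != 0
    rows <- bind_rows(
      nu_free,
      tibble(species = pt$name[in_aq][keep], nu = nus[keep],
             conc = pt$conc[in_aq][keep])
    )
    frac[[comp]] <- rows |>
      mutate(component = comp,
             fraction = .data$nu * .data$conc / totals[[comp]]) |>
      select("component", "species", "conc", "fraction")
  }
  structure(list(
    pH = pH, totals = totals, free = free, species = species,
    fractions = bind_rows(frac), residual_norm = pt$residual
  ), class = "iex_speciation")
}

#' @export
print.iex_speciation <- function(x, ...) {
  cat(sprintf("<iex_speciation> pH %.3g\n", x$pH))
  print(x$fractions)
  invisible(x)
}

#' Speciation fractions over a pH grid
#'
#' Tidy long table of species fractions per component across pH, ready for
#' plotting or CSV export.
#'
#' @inheritParams speciate
#' @param pH Numeric vector of pH values.
#' @return A tibble: `pH`, `component`, `species`, `conc`, `fraction`.
#' @export
speciation_profile <- function(totals, pH, reactions,
                               components = iex_components(), pKw = 14) {
  purrr::map(pH, function(p) {
    sp <- speciate(totals, p, reactions, components, pKw)
    mutate(sp$fractions, pH = p, .before = 1)
  }) |> bind_rows()
}
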