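# Coupled surface + solution equilibrium at fixed (measured) pH.
#
# The problem is posed as a classical speciation tableau.  Unknowns are the
# natural logs of the free concentrations of every non-proton component with
# a positive total, plus ln{SOH} for every site.  Every species k has
#   ln c_k = lnK*_k + sum_j A[k, j] * u_j
# where lnK* folds in the (fixed) proton and hydroxide terms, and A holds
# the stoichiometric exponents with respect to the unknowns.  The residuals
# are the relative errors of the component mass balances and the site
# balances; because A >= 0 for every unknown the Jacobian
#   J_ij = sum_k A_ki A_kj c_k / T_i
# is well conditioned and a damped Newton iteration converges from the
# standard start (free = totals, {SOH} = capacity).

#' @keywords internal
compile_model <- function(model) {
  comps <- setdiff(model$components$name, "H")
  aq <- model$aqueous_reactions
  n_aq <- nrow(aq)
  aqA <- matrix(0, n_aq, length(comps), dimnames = list(aq$species, comps))
  aq_h <- numeric(n_aq)
  for (i in seq_len(n_aq)) {
    nu <- aq$stoich[[i]]
    aq_h[i] <- if ("H" %in% names(nu)) nu[["H"]] else 0
    rest <- nu[setdiff(names(nu), "H")]
    aqA[i, names(rest)] <- rest
  }
  sr <- model$surface_reactions
  n_sr <- nrow(sr)
  srA <- matrix(0, n_sr, length(comps), dimnames = list(sr$id, comps))
  sr_h <- sr_oh <- sr_n <- sr_pk <- numeric(n_sr)
  for (i in seq_len(n_sr)) {
    s <- sr$scale[i]
    nu <- sr$consumed[[i]] / s # canonical whole-reaction coefficients
    sr_pk[i] <- sr$pK[i] / s
    sr_n[i] <- sr$n_soh[i] / s
    sr_h[i] <- if ("H" %in% names(nu)) nu[["H"]] else 0
    sr_oh[i] <- if ("OH" %in% names(nu)) nu[["OH"]] else 0
    rest <- nu[setdiff(names(nu), c("H", "OH"))]
    srA[i, names(rest)] <- rest
  }
  list(comps = comps, pKw = model$pKw,
       aq = list(species = aq$species, A = aqA, h = aq_h, logK = aq$logK),
       sr = list(id = sr$id, site = sr$site, product = sr$product, A = srA,
                 h = sr_h, oh = sr_oh, n = sr_n, pk = sr_pk,
                 h_coef = sr_h - sr_oh),
       sites = model$sites)
}

# Damped Newton on the log-scale tableau. A: n_species x n_unknowns,
# lnk: species log constants, totals: per-unknown totals (all > 0).
newton_tableau <- function(A, lnk, totals, u0, tol = 1e-12, maxit = 200L) {
  nuk <- length(totals)
  eval_state <- function(u) {
    conc <- exp(lnk + drop(A %*% u))
    b <- drop(crossprod(A, conc))
    list(u = u, conc = conc, r = (b - totals) / totals)
  }
  st <- eval_state(u0)
  iter <- 0L
  while (iter < maxit) {
    rn <- max(abs(st$r))
    if (is.finite(rn) && rn < tol) {
      return(list(u = st$u, conc = st$conc, resid = rn, iter = iter,
                  converged = TRUE))
    }
    iter <- iter + 1L
    J <- crossprod(A, A * st$conc) / totals
    delta <- tryCatch(solve(J, -st$r), error = function(e) NULL)
    lam <- 1e-10 * max(abs(diag(J)), 1)
    while (is.null(delta) && lam < 1e12) {
      delta <- tryCatch(solve(J + diag(lam, nuk), -st$r),
                        error = function(e) NULL)
      lam <- lam * 1e3
    }
    if (is.null(delta) || any(!is.finite(delta))) break
    m <- max(abs(delta))
    if (m > 6) delta <- delta * (6 / m) # trust region in ln units
    alpha <- 1
    repeat {
      cand <- eval_state(st$u + alpha * delta)
      ok <- all(is.finite(cand$r)) && max(abs(cand$r)) < max(abs(st$r))
      if (ok || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (!ok) break # stalled; fall through to derivative-free rescue
    st <- cand
  }
  # bounded derivative-free rescue (rarely reached): minimize the squared
  # relative residuals, then re-check
  obj <- function(u) {
    r <- eval_state(u)$r
    if (any(!is.finite(r))) return(1e300)
    sum(r^2)
  }
  opt <- stats::optim(st$u, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  st2 <- eval_state(opt$par)
  if (max(abs(st2$r)) < max(abs(st$r))) st <- st2
  # one last run of Newton from the polished point
  for (k in seq_len(50L)) {
    if (max(abs(st$r)) < tol) break
    J <- crossprod(A, A * st$conc) / totals
    delta <- tryCatch(solve(J, -st$r), error = function(e) NULL)
    if (is.null(delta)) break
    cand <- eval_state(st$u + delta)
    if (!all(is.finite(cand$r)) || max(abs(cand$r)) >= max(abs(st$r))) break
    st <- cand
  }
  list(u = st$u, conc = st$conc, resid = max(abs(st$r)), iter = iter,
       converged = max(abs(st$r)) < tol)
}

# Assemble and solve one condition. totals: named mol/L over non-H
# components (missing = 0). Returns raw species concentrations.
solve_point <- function(cm, pH, totals, capacities, tol = 1e-12,
                        maxit = 200L, condition_id = NULL) {
  if (pH < 0 || pH > 14) {
    ionex_abort(sprintf("pH %.3g outside [0, 14]", pH), "ionex_domain_error")
  }
  h <- 10^(-pH)
  ln_oh <- -cm$pKw * log(10) - log(h)
  comps <- cm$comps
  tot <- stats::setNames(numeric(length(comps)), comps)
  tot[names(totals)[names(totals) %in% comps]] <-
    totals[names(totals) %in% comps]
  assert_nonnegative(tot, "totals")
  active <- comps[tot > 0]
  sites <- cm$sites$site
  if (any(capacities <= 0)) {
    ionex_abort("zero or negative site capacity", "ionex_config_error")
  }

  # species rows: free components, aqueous complexes, bare SOH, surface
  # complexes; species needing an inactive component have zero concentration
  # and are dropped from the tableau (reported as 0)
  unknowns <- c(active, sites)
  nu <- length(unknowns)
  rows <- list(); lnk <- numeric(0); meta <- list()
  add_row <- function(a, k, type, name, site = NA_character_, idx = NA_integer_) {
    rows[[length(rows) + 1L]] <<- a
    lnk[length(lnk) + 1L] <<- k
    meta[[length(meta) + 1L]] <<- list(type = type, name = name, site = site,
                                       idx = idx)
  }
  basis <- function(name) {
    a <- numeric(nu); a[match(name, unknowns)] <- 1; a
  }
  for (c0 in active) add_row(basis(c0), 0, "free", c0)
  # hydroxide (for bookkeeping/output only; no unknown involvement)
  add_row(numeric(nu), ln_oh, "aqueous", "OH")
  for (i in seq_along(cm$aq$species)) {
    need <- comps[cm$aq$A[i, ] != 0]
    if (length(setdiff(need, active)) > 0) next
    a <- numeric(nu)
    a[match(need, unknowns)] <- cm$aq$A[i, need]
    add_row(a, cm$aq$logK[i] * log(10) + cm$aq$h[i] * log(h),
            "aqueous", cm$aq$species[i], idx = i)
  }
  for (s in sites) add_row(basis(s), 0, "soh", paste0(s, "_SOH"), site = s)
  for (i in seq_along(cm$sr$id)) {
    need <- comps[cm$sr$A[i, ] != 0]
    if (length(setdiff(need, active)) > 0) next
    a <- numeric(nu)
    a[match(need, unknowns)] <- cm$sr$A[i, need]
    a[match(cm$sr$site[i], unknowns)] <- cm$sr$n[i]
    add_row(a, -cm$sr$pk[i] * log(10) + cm$sr$h[i] * log(h) +
              cm$sr$oh[i] * ln_oh,
            "surface", cm$sr$id[i], site = cm$sr$site[i], idx = i)
  }
  A <- do.call(rbind, rows)
  targets <- c(tot[active], stats::setNames(capacities, sites))
  u0 <- log(targets)
  sol <- newton_tableau(A, lnk, unname(targets), u0, tol = tol, maxit = maxit)
  if (!sol$converged) {
    ionex_abort(sprintf(
      "equilibrium solver did not converge%s (max relative residual %.3g after %d iterations)",
      if (is.null(condition_id)) "" else sprintf(" for condition `%s`", condition_id),
      sol$resid, sol$iter),
      "ionex_solver_error", residual = sol$resid, last_u = sol$u)
  }
  type <- map_chr(meta, "type")
  list(unknowns = unknowns, u = sol$u, conc = sol$conc, type = type,
       name = map_chr(meta, "name"), site = map_chr(meta, "site"),
       idx = map(meta, "idx"), residual = sol$resid, iter = sol$iter,
       active = active, totals = tot, pH = pH)
}

#' Solve the coupled surface/solution equilibrium for one condition
#'
#' Solves all mass-action and mass-balance equations of a strict
#' charge-neutral ion-exchange model at a fixed, measured equilibrium pH.
#' The proton is never a solved unknown: \[H⁺\] = 10^−pH, and the reported
#' proton adsorption is the stoichiometric sum of proton co-adsorption over
#' the surface complexes (see [predict_proton_adsorption()]).
#'
#' @param model An [iex_model()].
#' @param condition A list or one-row data frame with `pH` and totals,
#'   either as a named `totals` vector in mol/L or as `total_<comp>_mM`
#'   columns in mmol/L; an optional `id`.
#' @param geometry [iex_geometry()] override (defaults to the model's).
#' @param tol Relative residual tolerance (default 1e-12).
#' @param maxit Maximum Newton iterations (default 200).
#' @return An `iex_solution`: list with tibbles `free` (mol/L), `aqueous`
#'   (mol/L), `surface` (per-site complexes, mol/L and µmol m⁻²), a named
#'   `adsorbed` vector (µmol m⁻², including derived `H`), `residual_norm`
#'   and `iterations`.
#' @examples
#' m <- iex_model(
#'   sites = iex_site("S", 2.0),
#'   surface_reactions = exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl",
#'                                         pK = -8),
#'   components = iex_components()[c(1, 3), ],
#'   geometry = iex_geometry(100, 1)
#' )
#' sol <- solve_equilibrium(m, list(pH = 4, totals = c(Cl = 1e-3)))
#' sol$adsorbed["Cl"] # about 1.783 umol/m2
#' @export
solve_equilibrium <- function(model, condition, geometry = NULL,
                              tol = 1e-12, maxit = 200L) {
  stopifnot(inherits(model, "iex_model"))
  geometry <- geometry %||% model$geometry
  if (is.null(geometry)) {
    ionex_abort("no geometry: supply `geometry` or set it on the model",
                "ionex_config_error")
  }
  cond <- parse_condition(condition)
  cm <- compile_model(model)
  capacities <- gamma_to_molar(model$sites$gamma_max, geometry)
  pt <- solve_point(cm, cond$pH, cond$totals, capacities, tol = tol,
                    maxit = maxit, condition_id = cond$id)
  build_solution(pt, cm, model, geometry, cond$id)
}

parse_condition <- function(condition) {
  condition <- as.list(condition)
  if (is.null(condition$pH)) {
    ionex_abort("condition needs a `pH`", "ionex_contract_error")
  }
  totals <- condition$totals
  if (is.null(totals)) {
    nm <- grep("^total_.*_mM$", names(condition), value = TRUE)
    totals <- stats::setNames(unlist(condition[nm]) * 1e-3,
                              sub("^total_(.*)_mM$", "\\1", nm))
  }
  totals <- as_named_numeric(totals, "totals")
  totals[is.na(totals)] <- 0
  list(pH = condition$pH, totals = totals,
       id = condition$id %||% condition$condition_id %||% NA_character_)
}

build_solution <- function(pt, cm, model, geometry, condition_id = NA) {
  is_free <- pt$type == "free"
  is_aq <- pt$type == "aqueous"
  is_soh <- pt$type == "soh"
  is_surf <- pt$type == "surface"
  free <- stats::setNames(numeric(length(cm$comps)), cm$comps)
  free[pt$name[is_free]] <- pt$conc[is_free]
  surf_idx <- unlist(pt$idx[is_surf])
  surface <- bind_rows(
    tibble(site = pt$site[is_soh], species = "SOH", reaction = NA_character_,
           conc = pt$conc[is_soh]),
    tibble(site = pt$site[is_surf],
           species = cm$sr$product[surf_idx],
           reaction = cm$sr$id[surf_idx],
           conc = pt$conc[is_surf])
  ) |>
    mutate(gamma = molar_to_gamma(.data$conc, geometry)) |>
    arrange(.data$site)

  ions <- cm$comps[colSums(abs(cm$sr$A)) > 0]
  surfA <- cm$sr$A[surf_idx, , drop = FALSE]
  surf_conc <- pt$conc[is_surf]
  adsorbed <- stats::setNames(numeric(length(ions) + 1), c("H", ions))
  adsorbed["H"] <- molar_to_gamma(
    sum(cm$sr$h_coef[surf_idx] * surf_conc), geometry)
  for (ion in ions) {
    adsorbed[ion] <- molar_to_gamma(sum(surfA[, ion] * surf_conc), geometry)
  }
  structure(list(
    condition_id = condition_id,
    pH = pt$pH,
    free = free,
    aqueous = tibble(species = pt$name[is_aq], conc = pt$conc[is_aq]),
    surface = surface,
    adsorbed = adsorbed,
    residual_norm = pt$residual,
    iterations = pt$iter,
    totals = pt$totals,
    geometry = geometry
  ), class = "iex_solution")
}

#' @export
print.iex_solution <- function(x, ...) {
  cat(sprintf("<iex_solution> pH %.3g  (residual %.2g, %d iterations)\n",
              x$pH, x$residual_norm, x$iterations))
  cat("  adsorbed (umol/m2):",
      paste(sprintf("%s=%.4g", names(x$adsorbed), x$adsorbed), collapse = "  "),
      "\n")
  invisible(x)
}

#' Derived proton adsorption of a solved condition
#'
#' Γ_H is not an independently solved quantity: it is the stoichiometric sum
#' of proton co-adsorption over all surface complexes.  Chloride-type
#' complexes (SOH₂Cl) contribute +1 proton each, bidentate phthalate
#' complexes contribute +2, and sodium exchange (SOH + Na⁺ → SONa + H⁺)
#' contributes −1.  Positive values mean net proton uptake (low pH),
#' negative mean net proton release.  Bare SOH is the Γ_H = 0 reference.
#'
#' @param result An `iex_solution` from [solve_equilibrium()].
#' @param model The model it was solved with.
#' @return Γ_H in µmol m⁻².
#' @export
predict_proton_adsorption <- function(result, model) {
  stopifnot(inherits(result, "iex_solution"))
  unname(result$adsorbed["H"])
}

#' Predict an adsorption envelope
#'
#' Solves the model at every condition and returns one row per condition,
#' ordered by pH: derived Γ_H, Γ per ion (µmol m⁻²) and the free
#' concentrations (mol L⁻¹).
#'
#' @param model An [iex_model()].
#' @param conditions Data frame with columns `pH`, optional `condition_id`,
#'   and totals as `total_<comp>_mM` columns (mmol/L), e.g. from
#'   [build_conditions()]; or a list of condition lists.
#' @param geometry [iex_geometry()] override.
#' @inheritParams solve_equilibrium
#' @return A tibble of class `iex_envelope` with columns `condition_id`,
#'   `pH`, `gamma_H`, `gamma_<ion>` and `free_<comp>`.
#' @export
predict_envelope <- function(model, conditions, geometry = NULL,
                             tol = 1e-12, maxit = 200L) {
  stopifnot(inherits(model, "iex_model"))
  geometry <- geometry %||% attr(conditions, "geometry") %||% model$geometry
  if (is.null(geometry)) {
    ionex_abort("no geometry: supply `geometry` or set it on the model",
                "ionex_config_error")
  }
  if (is.data.frame(conditions)) {
    conds <- purrr::map(seq_len(nrow(conditions)),
                        \(i) as.list(conditions[i, , drop = FALSE])) |>
      purrr::map(parse_condition)
  } else {
    conds <- purrr::map(conditions, parse_condition)
  }
  if (length(conds) == 0) {
    ionex_abort("`conditions` is empty", "ionex_contract_error")
  }
  cm <- compile_model(model)
  capacities <- gamma_to_molar(model$sites$gamma_max, geometry)
  ions <- cm$comps[colSums(abs(cm$sr$A)) > 0]
  n <- length(conds)
  ids <- map_chr(seq_len(n), function(i) {
    if (is.na(conds[[i]]$id)) as.character(i) else as.character(conds[[i]]$id)
  })
  area <- area_per_litre(geometry)
  gam <- matrix(0, n, 1 + length(ions),
                dimnames = list(NULL, paste0("gamma_", c("H", ions))))
  fre <- matrix(0, n, length(cm$comps),
                dimnames = list(NULL, paste0("free_", cm$comps)))
  resid <- numeric(n)
  for (i in seq_len(n)) {
    pt <- tryCatch(
      solve_point(cm, conds[[i]]$pH, conds[[i]]$totals, capacities,
                  tol = tol, maxit = maxit, condition_id = ids[i]),
      ionex_error = function(e) {
        ionex_abort(sprintf("condition `%s`: %s", ids[i], conditionMessage(e)),
                    class(e)[1], parent = e)
      })
    is_surf <- pt$type == "surface"
    is_free <- pt$type == "free"
    sidx <- unlist(pt$idx[is_surf])
    sconc <- pt$conc[is_surf]
    gam[i, 1] <- sum(cm$sr$h_coef[sidx] * sconc) * 1e6 / area
    for (k in seq_along(ions)) {
      gam[i, 1 + k] <- sum(cm$sr$A[sidx, ions[k]] * sconc) * 1e6 / area
    }
    fre[i, match(paste0("free_", pt$name[is_free]), colnames(fre))] <-
      pt$conc[is_free]
    resid[i] <- pt$residual
  }
  out <- bind_cols(tibble(condition_id = ids,
                          pH = map_dbl(conds, "pH")),
                   as_tibble(gam), as_tibble(fre),
                   tibble(residual_norm = resid)) |>
    arrange(.data$pH)
  structure(out, class = c("iex_envelope", class(out)),
            geometry = geometry, ions = ions)
}
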