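# pK estimation: exact single-datum solves, staged/tied bounded
# least-squares over envelope data, and goodness-of-fit reporting.

#' Solve a pK from a single datum point
#'
#' For a single exchange reaction at a fixed pH, the mass-action and
#' mass-balance equations can be inverted in closed form: the target
#' adsorption fixes the surface-complex concentration, the site balance
#' fixes \{SOH\}, the component balance fixes the free ion, and the pK
#' follows directly.  When aqueous reactions are supplied (so the free ion
#' is no longer total − adsorbed) a bounded 1-D root solve on the forward
#' prediction is used instead.
#'
#' @param reaction An [exchange_reaction()].
#' @param pH Datum pH.
#' @param gamma_target Target adsorption of the datum ion, µmol m⁻².
#' @param total_mM Total concentration of the datum ion, mmol/L.
#' @param capacity_mM Site capacity, mmol/L.
#' @param geometry [iex_geometry()] used to relate µmol m⁻² and mol/L
#'   (default a 100 m² L⁻¹ loading, under which 2.0 µmol m⁻² ≡ 0.2 mmol/L).
#' @param ion Datum ion; default the single non-proton component consumed.
#' @param totals_mM Named totals of any other consumed ions, mmol/L.
#' @param aqueous_reactions Optional list of [aqueous_reaction()]s; forces
#'   the root-solve path.
#' @param bounds pK search interval for the root-solve path.
#' @return The pK such that the predicted envelope passes through the datum.
#' @examples
#' eq7 <- exchange_reaction("S", c(H = 2, L = 1), "(SOH2)2L", pK = 0, n_soh = 2)
#' solve_single_point_pk(eq7, pH = 6, gamma_target = 0.5,
#'                       total_mM = 1.0, capacity_mM = 0.2) # -18.72
#' @export
solve_single_point_pk <- function(reaction, pH, gamma_target, total_mM,
                                  capacity_mM,
                                  geometry = iex_geometry(100, 1),
                                  ion = NULL, totals_mM = c(),
                                  aqueous_reactions = NULL,
                                  bounds = c(-40, 20)) {
  stopifnot(inherits(reaction, "iex_reaction"))
  assert_positive(total_mM, "total_mM")
  assert_positive(capacity_mM, "capacity_mM")
  assert_nonnegative(gamma_target, "gamma_target")
  nu <- reaction$consumed / reaction$scale
  n <- reaction$n_soh / reaction$scale
  ions_in <- setdiff(names(nu), c("H", "OH"))
  ion <- ion %||% if (length(ions_in) == 1) ions_in else {
    ionex_abort("reaction consumes several ions; name the datum `ion`",
                "ionex_contract_error")
  }
  area <- area_per_litre(geometry)
  ads <- gamma_target * 1e-6 * area # mol/L of adsorbed datum ion
  P <- ads / nu[[ion]] # surface-complex concentration
  cap <- capacity_mM * 1e-3
  soh <- cap - n * P
  gamma_sat <- molar_to_gamma(cap * nu[[ion]] / n, geometry)
  if (soh <= 0) {
    ionex_abort(sprintf(
      "target %.4g umol/m2 exceeds the form's saturation limit of %.4g umol/m2",
      gamma_target, gamma_sat), "ionex_domain_error")
  }
  totals_mM <- as_named_numeric(totals_mM, "totals_mM")
  totals_mM[ion] <- total_mM

  if (is.null(aqueous_reactions) || length(aqueous_reactions) == 0) {
    # closed form: free = total - adsorbed for every consumed ion
    h <- 10^(-pH)
    oh <- 10^(pH - 14)
    lnK <- log(P) - n * log(soh)
    if ("H" %in% names(nu)) lnK <- lnK - nu[["H"]] * log(h)
    if ("OH" %in% names(nu)) lnK <- lnK - nu[["OH"]] * log(oh)
    for (cp in setdiff(names(nu), c("H", "OH"))) {
      free <- totals_mM[[cp]] * 1e-3 - nu[[cp]] * P
      if (free <= 0) {
        ionex_abort(sprintf("target uses more `%s` than is present", cp),
                    "ionex_domain_error")
      }
      lnK <- lnK - nu[[cp]] * log(free)
    }
    pk_canonical <- -lnK / log(10)
    return(pk_canonical * reaction$scale)
  }

  # with aqueous chemistry: 1-D root solve on the forward prediction
  gamma_cap <- site_capacity_areal(capacity_mM, geometry)
  predict_at <- function(pk) {
    r <- reaction; r$pK <- pk
    m <- iex_model(iex_site(reaction$site, gamma_cap), list(r),
                   aqueous_reactions = aqueous_reactions,
                   geometry = geometry)
    sol <- solve_equilibrium(m, list(pH = pH, totals = totals_mM * 1e-3))
    unname(sol$adsorbed[ion])
  }
  f <- function(pk) predict_at(pk) - gamma_target
  flo <- f(bounds[1]); fhi <- f(bounds[2])
  if (sign(flo) == sign(fhi)) {
    ionex_abort("datum not reachable within the pK bounds", "ionex_domain_error")
  }
  stats::uniroot(f, bounds, tol = 1e-10)$root
}

#' Staged optimization plan
#'
#' A `fit_plan` is an ordered list of stages.  Each stage frees one or more
#' pK parameters (reaction ids, or tie-group labels for parameters shared
#' across reactions), restricts the objective to a pH window and to the
#' listed ions, and holds every other pK at its incoming value.  Reactions
#' marked `fixed` are never optimized.
#'
#' @param ... [fit_stage()] objects (or one list of them).
#' @param bounds Length-2 numeric, the pK box for every freed parameter
#'   (default c(-30, 15)).
#' @return A list of class `iex_fit_plan`.
#' @export
fit_plan <- function(..., bounds = c(-30, 15)) {
  stages <- list(...)
  if (length(stages) == 1 && !inherits(stages[[1]], "iex_fit_stage")) {
    stages <- stages[[1]]
  }
  stopifnot(all(map_lgl(stages, inherits, "iex_fit_stage")),
            length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(stages = stages, bounds = bounds), class = "iex_fit_plan")
}

#' @rdname fit_plan
#' @param free Character: reaction ids / tie groups freed in this stage.
#' @param window pH interval (within \[0, 14\]) of the data used.
#' @param ions Ions whose residuals enter the stage objective (e.g.
#'   `c("H", "Cl")`).
#' @export
fit_stage <- function(free, window = c(0, 14), ions) {
  stopifnot(is.character(free), length(free) >= 1,
            length(window) == 2, window[1] <= window[2],
            window[1] >= 0, window[2] <= 14,
            is.character(ions), length(ions) >= 1)
  structure(list(free = free, window = window, ions = ions),
            class = "iex_fit_stage")
}

#' Coefficient of determination
#'
#' R² = 1 − SSE / SStot with SStot about the observed mean.  Can be
#' negative when the model is worse than the mean; it is capped above by 1.
#'
#' @param observed,predicted Equal-length numeric vectors (n ≥ 2).
#' @return R² as a plain number.
#' @export
r_squared <- function(observed, predicted) {
  keep <- is.finite(observed) & is.finite(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (length(observed) < 2 || length(observed) != length(predicted)) {
    ionex_abort("need at least two paired finite values", "ionex_domain_error")
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    ionex_abort("R^2 is undefined: observations are all identical",
                "ionex_domain_error")
  }
  1 - sum((observed - predicted)^2) / sstot
}

#' Fit pK values to an envelope dataset
#'
#' Minimizes, stage by stage, the unweighted sum of squared residuals
#' (µmol m⁻²) between observed and predicted adsorption for the stage's
#' ions inside its pH window, holding all other pKs at their incoming
#' values.  Tied reactions move as one parameter.  Stages with one free
#' parameter use golden-section search; multi-parameter stages use
#' Nelder-Mead on a logistic rescaling of the pK box, started at the
#' incoming values.  Deterministic for fixed data and plan.
#'
#' @param model Starting [iex_model()].
#' @param dataset An [envelope_dataset()] with `gamma_<ion>` observations
#'   (offsets already applied where applicable).
#' @param plan A [fit_plan()].
#' @param geometry [iex_geometry()] override.
#' @param weights Optional named per-ion weights for the residuals
#'   (default all 1).
#' @param report_window Optional pH interval over which the final per-ion
#'   R² is computed (default: all data).
#' @return An `iex_fit`: list with the fitted `model`, `pk_table`,
#'   per-ion `r_squared`, per-stage `diagnostics`, and a `residuals` tibble.
#' @export
fit_pks <- function(model, dataset, plan, geometry = NULL, weights = NULL,
                    report_window = NULL) {
  stopifnot(inherits(model, "iex_model"), inherits(plan, "iex_fit_plan"))
  dataset <- as_tibble(dataset)
  geometry <- geometry %||% attr(dataset, "geometry") %||% model$geometry
  pars_all <- pk_parameters(model)
  weights <- as_named_numeric(weights %||% c(ALL = 1), "weights")
  get_w <- function(ion) unname(weights[ion] %|na|% weights["ALL"] %|na|% 1)

  current_pks <- function(m, pars) {
    sr <- m$surface_reactions
    key <- ifelse(is.na(sr$tie_group), sr$id, sr$tie_group)
    stats::setNames(sr$pK[match(pars, key)], pars)
  }

  diagnostics <- list()
  for (si in seq_along(plan$stages)) {
    stage <- plan$stages[[si]]
    unknown <- setdiff(stage$free, pars_all)
    if (length(unknown) > 0) {
      ionex_abort(sprintf("stage %d frees unknown/fixed parameter(s): %s",
                          si, paste(unknown, collapse = ", ")),
                  "ionex_contract_error")
    }
    rows <- dataset |>
      filter(.data$pH >= stage$window[1], .data$pH <= stage$window[2])
    obs_cols <- paste0("gamma_", stage$ions)
    obs_cols <- obs_cols[obs_cols %in% names(rows)]
    if (nrow(rows) == 0 || length(obs_cols) == 0) {
      ionex_abort(sprintf("stage %d has no usable observations", si),
                  "ionex_data_error")
    }
    evals <- 0L
    objective <- function(pk_vec) {
      evals <<- evals + 1L
      m2 <- set_pks(model, stats::setNames(pk_vec, stage$free))
      pred <- predict_envelope(m2, rows, geometry = geometry)
      sse <- 0
      for (col in obs_cols) {
        ion <- sub("^gamma_", "", col)
        if (!col %in% names(pred)) next
        d <- rows[[col]] - pred[[col]][match(rows$condition_id,
                                             pred$condition_id)]
        sse <- sse + get_w(ion) * sum(d^2, na.rm = TRUE)
      }
      sse
    }
    p0 <- current_pks(model, stage$free)
    sse0 <- objective(unname(p0))
    lo <- plan$bounds[1]; hi <- plan$bounds[2]
    if (length(stage$free) == 1) {
      opt <- stats::optimize(objective, c(lo, hi), tol = 1e-7)
      best <- opt$minimum; sse1 <- opt$objective
    } else {
      eps <- 1e-6 * (hi - lo)
      th0 <- stats::qlogis((pmin(pmax(p0, lo + eps), hi - eps) - lo) / (hi - lo))
      obj_t <- function(th) objective(lo + (hi - lo) * stats::plogis(th))
      opt <- stats::optim(th0, obj_t, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      best <- lo + (hi - lo) * stats::plogis(opt$par)
      sse1 <- opt$value
    }
    if (!is.finite(sse1) || sse1 > sse0 + 1e-12) {
      # never accept a step that worsens the objective
      best <- unname(p0); sse1 <- sse0
    }
    model <- set_pks(model, stats::setNames(best, stage$free))
    par_label <- paste(stage$free, collapse = ",")
    diagnostics[[si]] <- tibble(
      stage = si, parameters = par_label,
      n_points = nrow(rows), sse_initial = sse0, sse_final = sse1,
      evaluations = evals
    )
  }

  pred_full <- predict_envelope(model, dataset, geometry = geometry)
  pred_full <- pred_full[match(dataset$condition_id, pred_full$condition_id), ]
  rep_rows <- if (is.null(report_window)) rep(TRUE, nrow(dataset)) else {
    dataset$pH >= report_window[1] & dataset$pH <= report_window[2]
  }
  obs_ions <- sub("^gamma_", "",
                  grep("^gamma_", names(dataset), value = TRUE))
  r2 <- list(); resid <- list()
  for (ion in obs_ions) {
    col <- paste0("gamma_", ion)
    if (!col %in% names(pred_full)) next
    o <- dataset[[col]][rep_rows]; p <- pred_full[[col]][rep_rows]
    keep <- is.finite(o) & is.finite(p)
    if (sum(keep) >= 2 && stats::var(o[keep]) > 0) {
      r2[[ion]] <- r_squared(o[keep], p[keep])
    }
    resid[[ion]] <- tibble(condition_id = dataset$condition_id,
                           pH = dataset$pH, ion = ion,
                           observed = dataset[[col]],
                           predicted = pred_full[[col]]) |>
      mutate(residual = .data$observed - .data$predicted)
  }
  structure(list(
    model = model,
    pk_table = reaction_table(model),
    r_squared = unlist(r2),
    diagnostics = bind_rows(diagnostics),
    residuals = bind_rows(resid),
    report_window = report_window
  ), class = "iex_fit")
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' @export
print.iex_fit <- function(x, ...) {
  cat("<iex_fit>\n")
  print(x$pk_table, n = Inf)
  if (length(x$r_squared) > 0) {
    cat("R^2:", paste(sprintf("%s=%.3f", names(x$r_squared), x$r_squared),
                      collapse = "  "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted ion-exchange model
#'
#' @param x An `iex_fit`.
#' @param ... Unused.
#' @return One row per surface reaction: id, site, product, pK, ΔG°,
#'   tie group and fixed flag.
#' @export
tidy.iex_fit <- function(x, ...) x$pk_table

#' One-row fit summary
#'
#' @param x An `iex_fit`.
#' @param ... Unused.
#' @return A one-row tibble: total SSE, number of residual points, and one
#'   `r2_<ion>` column per observed ion.
#' @export
glance.iex_fit <- function(x, ...) {
  out <- tibble(
    n_points = sum(is.finite(x$residuals$observed)),
    sse = sum(x$residuals$residual^2, na.rm = TRUE),
    n_stages = nrow(x$diagnostics)
  )
  for (ion in names(x$r_squared)) {
    out[[paste0("r2_", ion)]] <- unname(x$r_squared[ion])
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
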