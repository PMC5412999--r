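# Independent oracles and small model builders shared across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# closed-form diprotic acid fractions (H2A / HA- / A2-)
alpha_diprotic <- function(pH, pKa1 = 2.95, pKa2 = 4.9) {
  h <- 10^(-pH)
  ka1 <- 10^(-pKa1)
  ka2 <- 10^(-pKa2)
  d <- h^2 + h * ka1 + ka1 * ka2
  list(H2L = h^2 / d, HL = h * ka1 / d, L = ka1 * ka2 / d)
}

# closed-form single-site, single-reaction SOH + H+ + X- = SOH2X:
# a = K h (cap - a)(T - a); smaller root of K h a^2 - (K h (cap+T) + 1) a
# + K h cap T = 0 is the physical one
quad_complex_conc <- function(pK, pH, capacity_molar, total_molar) {
  kh <- 10^(-pK) * 10^(-pH)
  a <- kh
  b <- -(kh * (capacity_molar + total_molar) + 1)
  cc <- kh * capacity_molar * total_molar
  (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# one site, one Cl coadsorption reaction, 100 m2/L loading
single_cl_model <- function(pK = -8, gamma_max = 2.0) {
  iex_model(
    iex_site("S", gamma_max),
    exchange_reaction("S", c(H = 1, Cl = 1), "SOH2Cl", pK = pK, id = "S_Cl"),
    components = iex_components()[c(1, 3), ],
    geometry = iex_geometry(100, 1)
  )
}

single_na_model <- function(pK = 8.8, gamma_max = 2.0) {
  iex_model(
    iex_site("S", gamma_max),
    exchange_reaction("S", c(Na = 1, H = -1), "SONa", pK = pK, id = "S_Na"),
    components = iex_components()[1:2, ],
    geometry = iex_geometry(100, 1)
  )
}

# relative mass-balance / site-balance audit of one solved condition
balance_errors <- function(model, solution) {
  geometry <- solution$geometry
  cm <- ionex:::compile_model(model)
  errs <- c()
  for (comp in names(solution$totals)) {
    tot <- solution$totals[[comp]]
    if (tot == 0) next
    aq <- solution$aqueous
    in_aq <- vapply(aq$species, function(s) {
      i <- match(s, cm$aq$species)
      if (is.na(i)) 0 else cm$aq$A[i, comp]
    }, numeric(1))
    surf <- solution$surface
    in_surf <- vapply(seq_len(nrow(surf)), function(i) {
      if (is.na(surf$reaction[i])) return(0)
      j <- match(surf$reaction[i], cm$sr$id)
      cm$sr$A[j, comp]
    }, numeric(1))
    lhs <- solution$free[[comp]] + sum(in_aq * aq$conc) +
      sum(in_surf * surf$conc)
    errs[comp] <- abs(lhs - tot) / tot
  }
  for (s in model$sites$site) {
    cap <- ionex:::gamma_to_molar(
      model$sites$gamma_max[model$sites$site == s], geometry)
    rows <- solution$surface[solution$surface$site == s, ]
    occ <- vapply(seq_len(nrow(rows)), function(i) {
      if (is.na(rows$reaction[i])) return(1) # bare SOH
      j <- match(rows$reaction[i], cm$sr$id)
      cm$sr$n[j]
    }, numeric(1))
    errs[paste0("site_", s)] <- abs(sum(occ * rows$conc) - cap) / cap
  }
  errs
}
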