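# Conjugate-ion titrant accounting and envelope-dataset I/O.
#
# A batch pH series cannot be made with a strong acid or base without also
# introducing the conjugate ion: HCl additions raise total Cl-, NaOH
# additions raise total Na+.  `build_conditions()` turns a titration
# schedule into per-condition total concentrations (per final volume), and
# `apply_offsets()` applies the constant measurement corrections that align
# raw adsorption data with the bare-SOH proton reference.

#' Titration schedule for a batch adsorption-envelope experiment
#'
#' @param background Named numeric, background electrolyte totals in mmol/L
#'   (e.g. `c(Na = 0.15, Cl = 0.15)` for 0.15 mM NaCl).
#' @param fixed_additions Named numeric, totals added to every condition in
#'   mmol/L (e.g. `c(L = 1.0)` for 1 mM phthalate).
#' @param acid,base Lists `list(component =, stock_M =)` describing the
#'   titrants; defaults HCl 0.020 M and NaOH 0.024 M.
#' @param volume_mL Final sample volume (default 35 mL).
#' @param zpt Zero point of titration: acid is added below it, base above.
#' @param acid_rule,base_rule Optional functions `pH -> mol/L` of
#'   titrant-derived conjugate ion in the final volume.  The defaults use
#'   the strong-acid/strong-base estimate
#'   `max(0, 10^-pH - 10^-zpt)` (and its hydroxide mirror), i.e. the
#'   minimum titrant needed in the absence of buffering.
#' @param additions Optional data frame with per-condition
#'   `acid_added_mmol` / `base_added_mmol`, overriding the rules (one row
#'   per condition, in pH order of the `pH` argument to
#'   [build_conditions()]).
#' @return A list of class `iex_schedule`.
#' @export
titration_schedule <- function(background = c(Na = 0.15, Cl = 0.15),
                               fixed_additions = c(),
                               acid = list(component = "Cl", stock_M = 0.020),
                               base = list(component = "Na", stock_M = 0.024),
                               volume_mL = 35, zpt = 6.41,
                               acid_rule = NULL, base_rule = NULL,
                               additions = NULL) {
  background <- as_named_numeric(background, "background")
  fixed_additions <- as_named_numeric(fixed_additions, "fixed_additions")
  assert_nonnegative(background, "background")
  assert_nonnegative(fixed_additions, "fixed_additions")
  assert_positive(volume_mL, "volume_mL")
  structure(list(
    background = background, fixed_additions = fixed_additions,
    acid = acid, base = base, volume_mL = volume_mL, zpt = zpt,
    acid_rule = acid_rule %||% function(pH) pmax(0, 10^(-pH) - 10^(-zpt)),
    base_rule = base_rule %||% function(pH) pmax(0, 10^(pH - 14) - 10^(zpt - 14)),
    additions = additions
  ), class = "iex_schedule")
}

#' Build per-condition totals from a titration schedule
#'
#' Totals are background + fixed additions + the conjugate ion introduced
#' by the titrant (Cl⁻ from HCl below the ZPT, Na⁺ from NaOH above it),
#' all expressed in the final sample volume.  Acid and base are never both
#' added to one condition.
#'
#' @param schedule An [iex_schedule][titration_schedule()].
#' @param pH Numeric vector: one measured equilibrium pH per condition.
#' @return A conditions tibble: `condition_id`, `pH`, `acid_added_mmol`,
#'   `base_added_mmol` and one `total_<comp>_mM` column per component.
#' @export
build_conditions <- function(schedule, pH) {
  stopifnot(inherits(schedule, "iex_schedule"))
  if (any(pH < 0 | pH > 14)) {
    ionex_abort("pH values must lie in [0, 14]", "ionex_data_error")
  }
  n <- length(pH)
  v_L <- schedule$volume_mL / 1000
  if (!is.null(schedule$additions)) {
    add <- as_tibble(schedule$additions)
    if (nrow(add) != n) {
      ionex_abort("`additions` must have one row per condition",
                  "ionex_data_error")
    }
    acid_mmol <- add$acid_added_mmol %||% rep(0, n)
    base_mmol <- add$base_added_mmol %||% rep(0, n)
  } else {
    acid_mmol <- schedule$acid_rule(pH) * v_L * 1000
    base_mmol <- schedule$base_rule(pH) * v_L * 1000
  }
  assert_nonnegative(acid_mmol, "acid_added_mmol")
  assert_nonnegative(base_mmol, "base_added_mmol")
  if (any(acid_mmol > 0 & base_mmol > 0)) {
    ionex_abort("acid and base must never both be added to one condition",
                "ionex_data_error")
  }
  comps <- unique(c(names(schedule$background), names(schedule$fixed_additions),
                    schedule$acid$component, schedule$base$component))
  totals <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  for (cp in names(schedule$background)) {
    totals[, cp] <- totals[, cp] + schedule$background[[cp]]
  }
  for (cp in names(schedule$fixed_additions)) {
    totals[, cp] <- totals[, cp] + schedule$fixed_additions[[cp]]
  }
  totals[, schedule$acid$component] <-
    totals[, schedule$acid$component] + acid_mmol / v_L # mmol / L = mM
  totals[, schedule$base$component] <-
    totals[, schedule$base$component] + base_mmol / v_L
  if (any(totals < 0)) {
    ionex_abort("negative computed total concentration", "ionex_data_error")
  }
  out <- tibble(
    condition_id = sprintf("c%02d", seq_len(n)),
    pH = pH,
    acid_added_mmol = acid_mmol,
    base_added_mmol = base_mmol
  )
  for (cp in comps) out[[paste0("total_", cp, "_mM")]] <- totals[, cp]
  out
}

#' Envelope dataset
#'
#' A conditions tibble plus measured adsorbed amounts (`gamma_<ion>`
#' columns, µmol m⁻², `NA` allowed) and a record of applied corrections.
#'
#' @param data Data frame with at least `condition_id`, `pH`, the
#'   `total_<comp>_mM` columns and any `gamma_<ion>` observation columns.
#' @param geometry An [iex_geometry()], carried as an attribute.
#' @return A tibble of class `iex_dataset`.
#' @export
envelope_dataset <- function(data, geometry = NULL) {
  data <- as_tibble(data)
  required <- c("pH")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    ionex_abort(sprintf("dataset is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "ionex_schema_error")
  }
  if (!"condition_id" %in% names(data)) {
    data <- mutate(data, condition_id = sprintf("c%02d", dplyr::row_number()),
                   .before = 1)
  }
  bad <- which(data$pH < 0 | data$pH > 14)
  if (length(bad) > 0) {
    ionex_abort(sprintf("invalid pH at data row %s", bad[1]),
                "ionex_data_error")
  }
  structure(data, class = c("iex_dataset", class(data)),
            geometry = geometry,
            offsets_applied = attr(data, "offsets_applied") %||% list())
}

#' Apply the published measurement offsets to an envelope dataset
#'
#' Constant offsets are *added* to the raw observed surface densities so
#' that the corrected proton curve crosses zero at the point of zero salt
#' effect, and the named component totals are incremented in every
#' condition (e.g. autochthonous chloride already on the solid).  The
#' correction record makes the operation refuse a second application; it is
#' reversible with negated offsets after clearing that record.
#'
#' @param dataset An [envelope_dataset()].
#' @param proton_offset Added to `gamma_H`, µmol m⁻² (default 0.50).
#' @param ion_offsets Named numeric added to `gamma_<ion>` columns,
#'   µmol m⁻² (default `c(Cl = 0.11)`).
#' @param total_increments_mM Named numeric added to `total_<comp>_mM`
#'   columns (default `c(Cl = 0.011)`).
#' @return The corrected `iex_dataset`.
#' @export
apply_offsets <- function(dataset, proton_offset = 0.50,
                          ion_offsets = c(Cl = 0.11),
                          total_increments_mM = c(Cl = 0.011)) {
  stopifnot(inherits(dataset, "iex_dataset"))
  rec <- attr(dataset, "offsets_applied")
  if (length(rec) > 0) {
    ionex_abort("offsets have already been applied to this dataset",
                "ionex_contract_error")
  }
  offs <- c(stats::setNames(proton_offset, "H"),
            as_named_numeric(ion_offsets, "ion_offsets"))
  if (any(!is.finite(offs))) {
    ionex_abort("offsets must be finite", "ionex_domain_error")
  }
  for (ion in names(offs)) {
    col <- paste0("gamma_", ion)
    if (col %in% names(dataset)) {
      dataset[[col]] <- dataset[[col]] + offs[[ion]]
    }
  }
  incs <- as_named_numeric(total_increments_mM, "total_increments_mM")
  for (cp in names(incs)) {
    col <- paste0("total_", cp, "_mM")
    if (!col %in% names(dataset)) {
      ionex_abort(sprintf("no `%s` column to increment", col),
                  "ionex_schema_error")
    }
    dataset[[col]] <- dataset[[col]] + incs[[cp]]
  }
  attr(dataset, "offsets_applied") <- list(
    proton_offset = proton_offset, ion_offsets = ion_offsets,
    total_increments_mM = incs, applied = TRUE
  )
  dataset
}

DATASET_COLUMNS <- c("condition_id", "pH", "acid_added_mmol", "base_added_mmol",
                     "total_Na_mM", "total_Cl_mM", "total_L_mM",
                     "gamma_H", "gamma_Cl", "gamma_L", "gamma_Na")

#' Read / write an envelope dataset CSV
#'
#' The canonical dialect is UTF-8, comma separated, `"."` decimal, header
#' row, optional leading `#` comment lines.  Recognised columns:
#' `condition_id, pH, acid_added_mmol, base_added_mmol, total_Na_mM,
#' total_Cl_mM, total_L_mM, gamma_H, gamma_Cl, gamma_L, gamma_Na`; the
#' observation and titrant columns are optional.  Read and write round-trip
#' losslessly.
#'
#' @param path File path.
#' @param geometry Optional [iex_geometry()] attached to the result.
#' @return An [envelope_dataset()].
#' @export
read_envelope_csv <- function(path, geometry = NULL) {
  if (!file.exists(path)) {
    ionex_abort(sprintf("file not found: %s", path), "ionex_io_error")
  }
  data <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) {
      ionex_abort(sprintf("malformed CSV `%s`: %s", path, conditionMessage(e)),
                  "ionex_parse_error")
    })
  unknown <- setdiff(grep("^gamma_", names(data), value = TRUE),
                     grep("^gamma_", DATASET_COLUMNS, value = TRUE))
  if (length(unknown) > 0) {
    ionex_abort(sprintf("unknown ion column(s): %s",
                        paste(unknown, collapse = ", ")),
                "ionex_schema_error")
  }
  prob <- readr::problems(data)
  if (nrow(prob) > 0) {
    ionex_abort(sprintf("malformed value at line %d of %s", prob$row[1] + 1L,
                        path), "ionex_parse_error")
  }
  if (!"pH" %in% names(data)) {
    ionex_abort("dataset CSV needs a `pH` column", "ionex_schema_error")
  }
  bad <- which(!is.finite(data$pH) | data$pH < 0 | data$pH > 14)
  if (length(bad) > 0) {
    # +1 for the header row
    ionex_abort(sprintf("invalid pH at line %d of %s", bad[1] + 1L, path),
                "ionex_data_error")
  }
  envelope_dataset(data, geometry = geometry)
}

#' @rdname read_envelope_csv
#' @param dataset An [envelope_dataset()] (or plain data frame).
#' @param header_comment Optional character vector written as leading
#'   `# `-prefixed comment lines.
#' @export
write_envelope_csv <- function(dataset, path, header_comment = NULL) {
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    readr::write_csv(as_tibble(as.data.frame(dataset)), path, append = TRUE,
                     col_names = TRUE)
  } else {
    readr::write_csv(as_tibble(as.data.frame(dataset)), path)
  }
  invisible(path)
}
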