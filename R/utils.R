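#' @importFrom rlang %||% .data abort
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_lgl imap pmap map2
NULL

# consistent condition classes so callers can distinguish user error,
# data error and solver failure
ionex_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ionex_error"), ...)
}

assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    ionex_abort(sprintf("`%s` must be finite and > 0.", what),
                "ionex_domain_error")
  }
  invisible(x)
}

assert_nonnegative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    ionex_abort(sprintf("`%s` must be finite and >= 0.", what),
                "ionex_domain_error")
  }
  invisible(x)
}

# named-numeric helper: coerce a (possibly empty) named list/vector
as_named_numeric <- function(x, what = "value") {
  if (is.null(x) || length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- unlist(x)
  if (!is.numeric(out) || is.null(names(out)) || any(names(out) == "")) {
    ionex_abort(sprintf("`%s` must be a named numeric vector.", what),
                "ionex_contract_error")
  }
  out
}
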