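# Equivalent annual cost of capital investments.
#
# A one-time outlay P spread over an equipment lifetime of n years at yearly
# discount rate r costs P / a(r, n) per year, where a(r, n) is the annuity
# factor a = (1 - (1+r)^-n) / r (limit a = n as r -> 0).

#' Annuity parameters
#'
#' @param discount_rate yearly discount rate as a fraction (>= 0).
#' @param lifetime_years equipment lifetime in whole years (>= 1).
#' @return an `annuity_params` object.
#' @examples
#' annuity_params(0.03, 5)
#' @export
annuity_params <- function(discount_rate = 0.03, lifetime_years = 5) {
  if (!is.numeric(discount_rate) || length(discount_rate) != 1 ||
      is.na(discount_rate) || discount_rate < 0)
    abort_config("discount_rate must be a single nonnegative number")
  if (!is.numeric(lifetime_years) || length(lifetime_years) != 1 ||
      is.na(lifetime_years) || lifetime_years < 1 ||
      lifetime_years != round(lifetime_years))
    abort_config("lifetime_years must be a whole number >= 1")
  structure(list(discount_rate = discount_rate,
                 lifetime_years = as.integer(lifetime_years)),
            class = "annuity_params")
}

#' Annuity factor
#'
#' @param params an [annuity_params()] object.
#' @return the annuity factor in years-equivalent.
#' @examples
#' annuity_factor(annuity_params(0.03, 5)) # 4.5797
#' @export
annuity_factor <- function(params) {
  stopifnot(inherits(params, "annuity_params"))
  r <- params$discount_rate
  n <- params$lifetime_years
  if (r == 0) return(as.numeric(n))
  (1 - (1 + r)^(-n)) / r
}

#' Equivalent annual cost of an investment
#'
#' @param present_value investment outlay (EUR, >= 0).
#' @param params an [annuity_params()] object.
#' @param round if `TRUE`, round half-up to whole euros for table display.
#' @return EUR per year.
#' @examples
#' annualize(16511, annuity_params(0.03, 5), round = TRUE) # 3605
#' @export
annualize <- function(present_value, params, round = FALSE) {
  stopifnot(inherits(params, "annuity_params"))
  if (any(is.na(present_value)) || any(present_value < 0))
    abort_data("present_value must be nonnegative")
  out <- present_value / annuity_factor(params)
  if (round) round_half_up(out) else out
}

#' @export
print.annuity_params <- function(x, ...) {
  cat(sprintf("annuity: %.1f%% discount over %d years (factor %.4f)\n",
              100 * x$discount_rate, x$lifetime_years, annuity_factor(x)))
  invisible(x)
}
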