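# Component-based service costing.
#
# A cost configuration lists priced items (equipment, rent, personnel,
# prorated per-consultation items) tagged with a category, a site, the
# alternative they belong to, and the payer who bears them. Investments are
# annuitized to an equivalent annual cost; recurring items enter at their
# annual amount; per-consultation items scale linearly with the yearly
# consultation volume.

COST_CATEGORIES   <- c("investment", "recurring_annual", "per_consultation")
COST_SITES        <- c("hospital", "remote_center")
COST_ALTERNATIVES <- c("standard", "telemedicine_A", "telemedicine_B", "shared")
COST_PAYERS       <- c("health_sector", "patient", "production")
ARM_ALTERNATIVES  <- setdiff(COST_ALTERNATIVES, "shared")

#' Build a cost-component table
#'
#' @param name,amount,category,site,alternative,payer parallel vectors; amounts
#'   are EUR (per year for `recurring_annual`, per consultation for
#'   `per_consultation`, the outlay for `investment`).
#' @return a `data.frame` with class `cost_components`.
#' @export
cost_components <- function(name, amount, category, site, alternative, payer) {
  df <- data.frame(name = as.character(name), amount = as.numeric(amount),
                   category = as.character(category), site = as.character(site),
                   alternative = as.character(alternative),
                   payer = as.character(payer), stringsAsFactors = FALSE)
  validate_components(df)
}

validate_components <- function(df) {
  need <- c("name", "amount", "category", "site", "alternative", "payer")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_config("cost components missing column(s): %s",
                 paste(miss, collapse = ", "))
  if (any(is.na(df$amount)) || any(df$amount < 0))
    abort_config("component amounts must be nonnegative")
  bad <- function(col, allowed) unique(df[[col]][!df[[col]] %in% allowed])
  for (spec in list(c("category", "COST_CATEGORIES"),
                    c("site", "COST_SITES"),
                    c("alternative", "COST_ALTERNATIVES"),
                    c("payer", "COST_PAYERS"))) {
    b <- bad(spec[1], get(spec[2]))
    if (length(b))
      abort_config("unknown %s tag(s): %s", spec[1], paste(b, collapse = ", "))
  }
  class(df) <- c("cost_components", "data.frame")
  df
}

#' Read a cost configuration (YAML)
#'
#' The file carries the currency conversion, the annuity assumptions, the
#' reference yearly volume that per-consultation unit costs were derived at,
#' and the component list. Amounts given in NOK (`amount_nok`) are converted
#' to EUR at load time and never downstream.
#'
#' @param path YAML file; see the bundled `table2_components.yaml`.
#' @return list with `components`, `annuity`, `reference_volume`,
#'   `nok_per_eur`.
#' @export
read_cost_config <- function(path) {
  if (!file.exists(path)) abort_config("cost config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components)) abort_config("cost config has no components")
  rows <- lapply(cfg$components, function(cmp) {
    amount <- cmp$amount
    if (is.null(amount) && !is.null(cmp$amount_nok)) {
      if (is.null(cfg$nok_per_eur))
        abort_config("component '%s' priced in NOK but nok_per_eur missing",
                     cmp$name %||% "?")
      amount <- cmp$amount_nok / cfg$nok_per_eur
    }
    data.frame(name = cmp$name %||% NA_character_,
               amount = as.numeric(amount %||% NA_real_),
               category = cmp$category %||% NA_character_,
               site = cmp$site %||% NA_character_,
               alternative = cmp$alternative %||% NA_character_,
               payer = cmp$payer %||% "health_sector",
               stringsAsFactors = FALSE)
  })
  comp <- validate_components(do.call(rbind, rows))
  ann <- cfg$annuity %||% list()
  list(components = comp,
       annuity = annuity_params(ann$discount_rate %||% 0.03,
                                ann$lifetime_years %||% 5),
       reference_volume = cfg$reference_volume %||% 300,
       nok_per_eur = cfg$nok_per_eur %||% NA_real_)
}

components_for <- function(components, alternative) {
  if (!alternative %in% ARM_ALTERNATIVES)
    abort_config("unknown alternative '%s'", alternative)
  keep <- components$alternative == alternative
  if (alternative != "standard")
    keep <- keep | components$alternative == "shared"
  components[keep, , drop = FALSE]
}

sum_by_payer <- function(amount, payer) {
  out <- c(health_sector = 0, patient = 0, production = 0)
  if (length(amount)) {
    s <- tapply(amount, factor(payer, levels = COST_PAYERS), sum)
    out[names(s)][!is.na(s)] <- s[!is.na(s)]
  }
  out
}

#' Annual service cost of one alternative
#'
#' Fixed annual cost = annuitized investments + recurring annual items;
#' per-consultation items scale with `volume`. Shared components count toward
#' both telemedicine alternatives but not toward standard care.
#'
#' @param components a [cost_components()] table.
#' @param alternative one of `"standard"`, `"telemedicine_A"`,
#'   `"telemedicine_B"`.
#' @param volume consultations per year (>= 1).
#' @param params an [annuity_params()] object.
#' @return an `arm_cost_summary`: fixed annual cost, per-consultation variable
#'   cost split by payer, and the total annual cost at `volume`.
#' @export
aggregate_annual_cost <- function(components, alternative, volume,
                                  params = annuity_params()) {
  if (!is.numeric(volume) || length(volume) != 1 || is.na(volume) || volume < 1)
    abort_data("volume must be >= 1")
  cmp <- components_for(components, alternative)
  inv <- cmp[cmp$category == "investment", , drop = FALSE]
  rec <- cmp[cmp$category == "recurring_annual", , drop = FALSE]
  per <- cmp[cmp$category == "per_consultation", , drop = FALSE]
  fixed_by_payer <- sum_by_payer(annualize(inv$amount, params), inv$payer) +
    sum_by_payer(rec$amount, rec$payer)
  var_by_payer <- sum_by_payer(per$amount, per$payer)
  arm_cost_summary(alternative = alternative,
                   fixed_annual = fixed_by_payer,
                   variable_per_consultation = var_by_payer,
                   volume_assumed = volume,
                   total_investment = sum(inv$amount))
}

#' Arm cost summary
#'
#' @param alternative label of the costed alternative.
#' @param fixed_annual named numeric (by payer) or scalar EUR/year.
#' @param variable_per_consultation named numeric (by payer) or scalar EUR per
#'   consultation.
#' @param volume_assumed consultations per year the summary was built at.
#' @param total_investment undiscounted investment outlay (bookkeeping only).
#' @return an `arm_cost_summary` object.
#' @export
arm_cost_summary <- function(alternative, fixed_annual,
                             variable_per_consultation, volume_assumed,
                             total_investment = NA_real_) {
  as_payer_vec <- function(x) {
    if (is.null(names(x))) {
      stopifnot(length(x) == 1)
      x <- c(health_sector = unname(x), patient = 0, production = 0)
    }
    out <- c(health_sector = 0, patient = 0, production = 0)
    out[names(x)] <- x
    if (any(out < 0)) abort_data("cost summary components must be >= 0")
    out
  }
  structure(list(alternative = alternative,
                 fixed_annual = as_payer_vec(fixed_annual),
                 variable_per_consultation = as_payer_vec(variable_per_consultation),
                 volume_assumed = volume_assumed,
                 total_investment = total_investment),
            class = "arm_cost_summary")
}

#' @export
print.arm_cost_summary <- function(x, ...) {
  cat(sprintf("<arm_cost_summary: %s>\n", x$alternative))
  cat(sprintf("  fixed annual     : %.2f EUR (health %.2f / patient %.2f / production %.2f)\n",
              sum(x$fixed_annual), x$fixed_annual[["health_sector"]],
              x$fixed_annual[["patient"]], x$fixed_annual[["production"]]))
  cat(sprintf("  per consultation : %.2f EUR (health %.2f / patient %.2f / production %.2f)\n",
              sum(x$variable_per_consultation),
              x$variable_per_consultation[["health_sector"]],
              x$variable_per_consultation[["patient"]],
              x$variable_per_consultation[["production"]]))
  cat(sprintf("  total annual at %d consultations: %.2f EUR\n",
              as.integer(x$volume_assumed),
              total_annual_cost(x, x$volume_assumed)))
  invisible(x)
}

#' Total annual cost of a summary at a volume
#'
#' @param summary an `arm_cost_summary`.
#' @param volume consultations per year.
#' @param persp a [perspective()]; defaults to societal.
#' @return EUR per year (unrounded).
#' @export
total_annual_cost <- function(summary, volume,
                              persp = perspective("societal")) {
  pay <- persp$payers
  sum(summary$fixed_annual[pay]) +
    volume * sum(summary$variable_per_consultation[pay])
}

#' Published-style annual cost table for one alternative
#'
#' Reproduces the investment / annualized / additional-cost layout of the
#' service-cost table: total investment, its equivalent annual cost,
#' alternative-specific recurring costs, the shared additional costs (rent,
#' remote-site nurse, prorated second consultations at the reference volume),
#' and the total annual cost. Values are rounded half-up to whole euros at
#' this final step only.
#'
#' @param components a [cost_components()] table.
#' @param alternative `"telemedicine_A"` or `"telemedicine_B"`.
#' @param params an [annuity_params()] object.
#' @param reference_volume yearly volume at which per-consultation items are
#'   displayed (default 300).
#' @return named list of rounded EUR values plus the unrounded total.
#' @export
service_cost_table <- function(components, alternative,
                               params = annuity_params(),
                               reference_volume = 300) {
  cmp <- components_for(components, alternative)
  inv <- cmp[cmp$category == "investment", , drop = FALSE]
  rec_specific <- cmp[cmp$category == "recurring_annual" &
                        cmp$alternative == alternative, , drop = FALSE]
  rec_shared <- cmp[cmp$category == "recurring_annual" &
                      cmp$alternative == "shared", , drop = FALSE]
  per <- cmp[cmp$category == "per_consultation", , drop = FALSE]
  total_investment <- sum(inv$amount)
  annualized <- annualize(total_investment, params)
  subtotal <- annualized + sum(rec_specific$amount)
  additional <- sum(rec_shared$amount) + sum(per$amount) * reference_volume
  total <- subtotal + additional
  list(alternative = alternative,
       total_investment = round_half_up(total_investment),
       annualized_investment = round_half_up(annualized),
       subtotal = round_half_up(subtotal),
       additional_costs = round_half_up(additional),
       total_annual = round_half_up(total),
       total_annual_unrounded = total)
}
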