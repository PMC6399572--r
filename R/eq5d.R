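# EQ-5D-3L utility scoring and QALY outcomes.
#
# A health state is five dimension levels (mobility, self-care, usual
# activities, pain/discomfort, anxiety/depression), each 1-3. A country
# tariff maps a state to a utility anchored at 1 (full health, state 11111)
# and 0 (dead): u = 1 - c - sum(dimension decrements) - n3, where c is a
# constant subtracted once for any dysfunction and n3 an extra decrement if
# any dimension is at level 3. The bundled default is the UK time-trade-off
# value set the study used. QALYs gained = (u_followup - u_baseline) x
# duration of the health state.

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Read an EQ-5D-3L tariff (CSV)
#'
#' Format: columns `term,value`; terms are `constant_any_dysfunction`,
#' `any_level3`, and `<dimension>_L2` / `<dimension>_L3` decrements for the
#' five dimensions. The bundled UK TTO set lives at
#' `telecea_file("eq5d_uk_tto.csv")`; [eq5d_tariff_checksum()] gives its MD5.
#'
#' @param path CSV tariff file.
#' @return an `eq5d_tariff` object.
#' @export
read_eq5d_tariff <- function(path) {
  if (!file.exists(path)) abort_config("tariff file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "value") %in% names(df)))
    abort_config("tariff file needs columns term,value: %s", path)
  val <- stats::setNames(df$value, df$term)
  need <- c("constant_any_dysfunction", "any_level3",
             paste0(rep(EQ5D_DIMENSIONS, each = 2), c("_L2", "_L3")))
  miss <- setdiff(need, names(val))
  if (length(miss))
    abort_config("tariff missing term(s): %s", paste(miss, collapse = ", "))
  dec <- matrix(val[paste0(rep(EQ5D_DIMENSIONS, each = 2), c("_L2", "_L3"))],
                nrow = 5, byrow = TRUE,
                dimnames = list(EQ5D_DIMENSIONS, c("L2", "L3")))
  eq5d_tariff(constant = val[["constant_any_dysfunction"]],
              n3 = val[["any_level3"]], decrements = dec)
}

#' EQ-5D-3L tariff coefficients
#'
#' @param constant decrement applied once when any dimension is above level 1.
#' @param n3 decrement applied once when any dimension is at level 3.
#' @param decrements 5 x 2 matrix of level-2/level-3 decrements, rows in
#'   dimension order.
#' @return an `eq5d_tariff` object (utility of 11111 is exactly 1).
#' @export
eq5d_tariff <- function(constant, n3, decrements) {
  stopifnot(is.matrix(decrements), nrow(decrements) == 5,
            ncol(decrements) == 2)
  if (constant < 0 || n3 < 0 || any(decrements < 0))
    abort_config("tariff decrements must be >= 0")
  if (any(decrements[, 2] < decrements[, 1]))
    abort_config("level-3 decrements must be >= level-2 decrements")
  structure(list(constant = constant, n3 = n3, decrements = decrements),
            class = "eq5d_tariff")
}

#' MD5 checksum of the bundled tariff file
#' @return named character, the MD5 of `eq5d_uk_tto.csv`.
#' @export
eq5d_tariff_checksum <- function() {
  unname(tools::md5sum(telecea_file("eq5d_uk_tto.csv")))
}

#' Score EQ-5D-3L states
#'
#' @param states a data.frame/matrix with the five dimension columns (levels
#'   1-3), or a character vector of 5-digit states like `"11212"`.
#' @param tariff an [eq5d_tariff()]; default the bundled UK TTO set.
#' @return numeric utilities; `NA` for incomplete states (any missing
#'   dimension), which are never imputed.
#' @examples
#' score_eq5d("11111") # 1
#' score_eq5d("33333") # -0.594 under the bundled UK tariff
#' @export
score_eq5d <- function(states, tariff = default_tariff()) {
  if (is.character(states)) {
    m <- do.call(rbind, lapply(strsplit(states, ""), function(ch) {
      if (length(ch) != 5) abort_data("EQ-5D state must have 5 digits")
      as.integer(ch)
    }))
  } else {
    states <- as.data.frame(states)
    cols <- if (all(EQ5D_DIMENSIONS %in% names(states))) EQ5D_DIMENSIONS
            else names(states)[seq_len(5)]
    m <- as.matrix(states[, cols])
    storage.mode(m) <- "integer"
  }
  if (any(!is.na(m) & !(m %in% 1:3)))
    abort_data("EQ-5D levels must be 1, 2 or 3")
  complete <- rowSums(is.na(m)) == 0
  u <- rep(NA_real_, nrow(m))
  if (any(complete)) {
    mm <- m[complete, , drop = FALSE]
    dec2 <- tariff$decrements[, 1]
    dec3 <- tariff$decrements[, 2]
    dims <- sweep((mm == 2) * 1, 2, dec2, `*`) +
      sweep((mm == 3) * 1, 2, dec3, `*`)
    any_dys <- rowSums(mm > 1) > 0
    any_l3 <- rowSums(mm == 3) > 0
    u[complete] <- 1 - tariff$constant * any_dys - rowSums(dims) -
      tariff$n3 * any_l3
  }
  u
}

default_tariff_cache <- new.env(parent = emptyenv())

#' Bundled default tariff (UK TTO)
#' @return an `eq5d_tariff` object.
#' @export
default_tariff <- function() {
  if (is.null(default_tariff_cache$tariff))
    default_tariff_cache$tariff <- read_eq5d_tariff(telecea_file("eq5d_uk_tto.csv"))
  default_tariff_cache$tariff
}

#' All 243 EQ-5D-3L states
#' @return data.frame of the full 3^5 level grid plus the `state` label.
#' @export
all_eq5d_states <- function() {
  g <- expand.grid(mobility = 1:3, self_care = 1:3, usual_activities = 1:3,
                   pain_discomfort = 1:3, anxiety_depression = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$mobility, g$self_care, g$usual_activities, g$pain_discomfort,
               g$anxiety_depression), ]
  g$state <- do.call(paste0, g[EQ5D_DIMENSIONS])
  rownames(g) <- NULL
  g
}

#' QALYs gained from a utility change
#'
#' @param u0,u1 baseline and follow-up utilities.
#' @param duration duration of the health state in years (default 1, the
#'   trial horizon; no discounting is applied at horizons <= 1 year).
#' @return `(u1 - u0) * duration`; `NA` where either utility is missing.
#' @export
qaly_gain <- function(u0, u1, duration = 1) {
  if (any(duration < 0)) abort_data("duration must be >= 0")
  (u1 - u0) * duration
}

#' Mean QALY gain over complete pairs
#'
#' @param gains numeric vector of per-patient QALY gains (may contain `NA`
#'   for incomplete baseline/follow-up pairs, which are dropped).
#' @return list with `mean`, `sd`, `n` (complete pairs only).
#' @export
arm_mean_qaly <- function(gains) {
  g <- gains[!is.na(gains)]
  if (!length(g))
    abort_data("no complete baseline/follow-up utility pairs")
  list(mean = mean(g), sd = if (length(g) > 1) stats::sd(g) else 0,
       n = length(g))
}

#' Patient-level QALY records from a patient table
#'
#' Scores baseline and follow-up EQ-5D responses (columns `eq5d_<dim>` and
#' `eq5d_fu_<dim>`) and computes per-patient QALY gains. Utilities are scored
#' only for complete five-dimension responses.
#'
#' @param patients patient-level data.frame.
#' @param tariff an [eq5d_tariff()].
#' @param duration years (default 1).
#' @return data.frame with `patient_id`, `arm`, `utility_baseline`,
#'   `utility_followup`, `qaly_gain`.
#' @export
qaly_records <- function(patients, tariff = default_tariff(), duration = 1) {
  base_cols <- paste0("eq5d_", EQ5D_DIMENSIONS)
  fu_cols <- paste0("eq5d_fu_", EQ5D_DIMENSIONS)
  miss <- setdiff(c(base_cols, fu_cols), names(patients))
  if (length(miss))
    abort_data("patient table missing column(s): %s", paste(miss, collapse = ", "))
  u0 <- score_eq5d(stats::setNames(patients[base_cols], EQ5D_DIMENSIONS), tariff)
  u1 <- score_eq5d(stats::setNames(patients[fu_cols], EQ5D_DIMENSIONS), tariff)
  data.frame(patient_id = patients$patient_id, arm = patients$arm,
             utility_baseline = u0, utility_followup = u1,
             duration = duration, qaly_gain = qaly_gain(u0, u1, duration),
             stringsAsFactors = FALSE)
}
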