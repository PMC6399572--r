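#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Published cost tables round 0.5 up, whereas base [round()] rounds half to
#' even. All table-facing output uses this helper; internal arithmetic stays
#' unrounded.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up (half away from zero for negatives).
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Condition helpers: the CLI maps these classes to distinct exit codes
# (config = 2, data = 3, numerical = 4).
abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("teleCEA_config_error", "teleCEA_error")))
}

abort_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("teleCEA_data_error", "teleCEA_error")))
}

abort_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("teleCEA_numeric_error", "teleCEA_error")))
}

assert_flag01 <- function(x, name) {
  if (any(!x %in% c(0, 1, NA)))
    abort_data("column '%s' must be 0/1", name)
  as.integer(x)
}

#' Path to a bundled fixture
#'
#' @param file file name under `extdata/`; with no argument, lists them.
#' @return absolute path (or vector of available file names).
#' @export
telecea_file <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "teleCEA")))
  p <- system.file("extdata", file, package = "teleCEA")
  if (!nzchar(p)) abort_config("no bundled file '%s'", file)
  p
}
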