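# Between-arm comparisons: two-sample t tests (pooled by default), Pearson
# chi-square on transport/usage proportions, and - for consultation-level
# binary outcomes repeated within patients - generalized estimating
# equations with a logit link, exchangeable working correlation and robust
# (sandwich) variance. No estimating-equations package is available in the
# target environment, so the GEE solver is implemented here and checked
# against its singleton-cluster GLM limit.

comparison_result <- function(statistic, p_value, method, n, df = NA_real_,
                              estimate = NA_real_, std_error = NA_real_,
                              clusters = NA_integer_, alpha = NA_real_,
                              converged = NA) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, df = df, estimate = estimate, std_error = std_error,
                 clusters = clusters, working_correlation = alpha,
                 converged = converged),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = " + ")))
  invisible(x)
}

#' Two-sample t test
#'
#' Pooled-variance by default (the published analysis does not state Welch);
#' Welch available by flag. Degenerate case (both groups constant and equal)
#' returns p = 1 by convention.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return a `comparison_result`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    abort_data("each group needs at least 2 observations")
  t_test_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), var_equal)
}

#' Two-sample t test from summary statistics
#'
#' Same test as [two_sample_t()] but from published means, SDs and group
#' sizes.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param var_equal pooled variance if `TRUE`.
#' @return a `comparison_result`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) abort_data("each group needs n >= 2")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  delta <- mean1 - mean2
  if (se == 0) {
    stat <- if (delta == 0) 0 else Inf * sign(delta)
    p <- if (delta == 0) 1 else 0
  } else {
    stat <- delta / se
    p <- 2 * stats::pt(-abs(stat), df)
  }
  comparison_result(stat, p, if (var_equal) "t_test" else "t_test_welch",
                    n = c(n1, n2), df = df, estimate = delta, std_error = se)
}

#' Pearson chi-square test on a 2 x k count table
#'
#' No continuity correction (matching the published tests); warns when any
#' expected cell count is below 5.
#'
#' @param counts 2 x k matrix of nonnegative integer counts.
#' @return a `comparison_result`.
#' @export
chi_square_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_data("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort_data("chi-square undefined: zero row or column margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("expected cell count below 5; chi-square approximation is weak")
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  comparison_result(stat, stats::pchisq(stat, df, lower.tail = FALSE),
                    "chi_square", n = rowSums(counts), df = df)
}

#' GEE for a clustered binary outcome
#'
#' Logistic marginal model `outcome ~ group` estimated by generalized
#' estimating equations with an exchangeable working correlation and robust
#' sandwich standard errors; reports the Wald test of the group effect.
#' With singleton clusters the fit collapses to ordinary logistic
#' regression. Non-convergence is reported, never silently swallowed.
#'
#' @param outcome 0/1 vector, one element per consultation.
#' @param group two-level factor (or coercible), e.g. the arm.
#' @param cluster cluster identifier (the patient).
#' @param tol convergence tolerance on the coefficient change.
#' @param maxit maximum Fisher-scoring iterations.
#' @return a `comparison_result` with the group log-odds estimate, robust
#'   SE, estimated working correlation, and cluster count.
#' @export
gee_binary <- function(outcome, group, cluster, tol = 1e-8, maxit = 100) {
  y <- assert_flag01(outcome, "outcome")
  g <- factor(group)
  if (nlevels(g) != 2) abort_data("group must have exactly 2 levels")
  keep <- !is.na(y) & !is.na(g) & !is.na(cluster)
  y <- y[keep]; g <- g[keep]; cluster <- as.character(cluster)[keep]
  for (lv in levels(g)) {
    cl <- unique(cluster[g == lv])
    if (length(cl) < 2) abort_data("need >= 2 clusters per group")
    if (length(unique(y[g == lv])) < 2)
      warning(sprintf("outcome is constant in group '%s' (separation risk)", lv))
  }
  X <- cbind(1, as.numeric(g == levels(g)[2]))
  beta <- stats::coef(stats::glm.fit(X, y, family = stats::binomial()))
  idx <- split(seq_along(y), cluster)
  p <- ncol(X)
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    r <- (y - mu) / sqrt(mu * (1 - mu))
    phi <- sum(r^2) / (length(y) - p)
    num <- 0; den <- 0
    for (ii in idx) {
      ni <- length(ii)
      if (ni > 1) {
        num <- num + (sum(r[ii])^2 - sum(r[ii]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- if (den > p) num / (phi * (den - p)) else 0
    alpha <- max(min(alpha, 0.99), -0.99)
    U <- numeric(p); H <- matrix(0, p, p); M <- matrix(0, p, p)
    for (ii in idx) {
      ni <- length(ii)
      Ai <- mu[ii] * (1 - mu[ii])          # variance = d mu / d eta for logit
      Di <- X[ii, , drop = FALSE] * Ai
      Rinv <- solve_exchangeable(ni, alpha)
      Vinv <- (Rinv / sqrt(Ai)) / rep(sqrt(Ai), each = ni) / phi
      DtV <- crossprod(Di, Vinv)
      U <- U + DtV %*% (y[ii] - mu[ii])
      H <- H + DtV %*% Di
      ui <- DtV %*% (y[ii] - mu[ii])
      M <- M + tcrossprod(ui)
    }
    step <- tryCatch(solve(H, U), error = function(e) NA_real_)
    if (any(!is.finite(step))) {
      warning("GEE scoring step is numerically unstable; stopping early")
      break
    }
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GEE did not converge in %d iterations", maxit))
  # robust (sandwich) covariance
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  U <- NULL
  H <- matrix(0, p, p); M <- matrix(0, p, p)
  r <- (y - mu) / sqrt(mu * (1 - mu))
  phi <- sum(r^2) / (length(y) - p)
  for (ii in idx) {
    ni <- length(ii)
    Ai <- mu[ii] * (1 - mu[ii])
    Di <- X[ii, , drop = FALSE] * Ai
    Rinv <- solve_exchangeable(ni, alpha)
    Vinv <- (Rinv / sqrt(Ai)) / rep(sqrt(Ai), each = ni) / phi
    DtV <- crossprod(Di, Vinv)
    H <- H + DtV %*% Di
    ui <- DtV %*% (y[ii] - mu[ii])
    M <- M + tcrossprod(ui)
  }
  Hinv <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  vb <- Hinv %*% M %*% Hinv
  se <- sqrt(vb[2, 2])
  z <- beta[2] / se
  comparison_result(z, 2 * stats::pnorm(-abs(z)), "gee_exchangeable_logit",
                    n = as.vector(table(g)), estimate = beta[2],
                    std_error = se, clusters = length(idx), alpha = alpha,
                    converged = converged)
}

# inverse of the exchangeable correlation matrix (1-a) I + a J
solve_exchangeable <- function(n, alpha) {
  if (n == 1) return(matrix(1, 1, 1))
  d <- 1 / (1 - alpha)
  off <- -alpha / ((1 - alpha) * (1 + (n - 1) * alpha))
  m <- matrix(off, n, n)
  diag(m) <- d + off
  m
}

#' Descriptive arm-comparison report
#'
#' "mean (SD)" and "n (%)" cells with p values, mirroring the descriptive
#' table layout of trial reports: continuous variables by pooled t test,
#' binary consultation-level variables by chi-square and (cluster-aware) GEE
#' side by side.
#'
#' @param trial output of [generate_trial()].
#' @return data.frame with one row per compared variable.
#' @export
describe_arms <- function(trial) {
  con <- trial$consultations
  pat <- trial$patients
  arms <- c("standard", "telemedicine")
  fmt_mean <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                  stats::sd(x[!is.na(x)]))
  fmt_prop <- function(x) sprintf("%d (%.1f)", sum(x, na.rm = TRUE),
                                  100 * mean(x, na.rm = TRUE))
  rows <- list()
  cont <- list(age = pat$age, travel_time_min = con$travel_time_min,
               distance_km = con$distance_km)
  cont_src <- list(pat$arm, con$arm, con$arm)
  for (i in seq_along(cont)) {
    x <- cont[[i]]; src <- cont_src[[i]]
    tt <- two_sample_t(x[src == arms[1]], x[src == arms[2]])
    rows[[length(rows) + 1]] <- data.frame(
      variable = names(cont)[i], standard = fmt_mean(x[src == arms[1]]),
      telemedicine = fmt_mean(x[src == arms[2]]),
      p_value = tt$p_value, p_value_gee = NA_real_, stringsAsFactors = FALSE)
  }
  bins <- list(companion = con$companion, extra_transport = con$extra_transport,
               bus_main = as.integer(con$main_mode == "bus"),
               private_car_main = as.integer(con$main_mode == "private_car"))
  for (i in seq_along(bins)) {
    x <- bins[[i]]
    tab <- vapply(arms, function(a)
      c(sum(x[con$arm == a], na.rm = TRUE),
        sum(!is.na(x[con$arm == a])) - sum(x[con$arm == a], na.rm = TRUE)),
      numeric(2))
    cs <- chi_square_2xk(t(tab))
    gee <- tryCatch(gee_binary(x, con$arm, con$patient_id),
                    warning = function(w) NULL, error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      variable = names(bins)[i],
      standard = fmt_prop(x[con$arm == arms[1]]),
      telemedicine = fmt_prop(x[con$arm == arms[2]]),
      p_value = cs$p_value,
      p_value_gee = if (is.null(gee)) NA_real_ else gee$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
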