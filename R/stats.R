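## Validation statistics: Monte-Carlo chi-square goodness of fit, 3-sigma
## control charts with run rules, replicate homogeneity.

#' Chi-square goodness of fit with a Monte-Carlo p-value
#'
#' Pearson statistic against expected proportions, with the p-value obtained
#' by simulating multinomial tables under the expected proportions -- the
#' appropriate correction when event counts are small.  The Monte-Carlo
#' p-value uses the add-one correction \code{(1 + #\{simulated >= observed\})
#' / (n_mc + 1)} and is therefore never exactly zero.
#'
#' @param observed vector of observed counts.
#' @param expected vector of expected proportions (summing to 1).
#' @param n_mc number of Monte-Carlo tables.
#' @param zero_expected how to handle zero expected cells: \code{"merge"}
#'   pools each into the smallest neighbouring cell, \code{"error"} stops.
#' @return a \code{gof_result}: list with \code{statistic}, \code{df},
#'   \code{p_asymptotic}, \code{p_montecarlo}, \code{n_mc}.
#' @export
chisq_gof_mc <- function(observed, expected, n_mc = 2000,
                         zero_expected = c("merge", "error")) {
  zero_expected <- match.arg(zero_expected)
  if (n_mc < 1) stop("n_mc must be at least 1")
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (abs(sum(expected) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  total <- sum(observed)
  if (total <= 0) stop("observed total must be positive")

  while (any(expected == 0)) {
    if (zero_expected == "error") stop("zero expected cell")
    z <- which(expected == 0)[1]
    nb <- c(z - 1, z + 1)
    nb <- nb[nb >= 1 & nb <= length(expected)]
    tgt <- nb[which.min(expected[nb])]
    observed[tgt] <- observed[tgt] + observed[z]
    observed <- observed[-z]; expected <- expected[-z]
  }

  E <- total * expected
  stat <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  sims <- stats::rmultinom(n_mc, size = total, prob = expected)
  sim_stat <- colSums((sims - E)^2 / E)
  p_mc <- (1 + sum(sim_stat >= stat)) / (n_mc + 1)
  structure(list(statistic = stat, df = df,
                 p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE),
                 p_montecarlo = p_mc, n_mc = n_mc),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f (df %d), asymptotic p = %.4f, MC p = %.4f (%d sims)\n",
              x$statistic, x$df, x$p_asymptotic, x$p_montecarlo, x$n_mc))
  invisible(x)
}

#' 3-sigma control chart against replicate simulations
#'
#' For each data point, replicate simulations give a mean and (sample,
#' \code{n-1} denominator) SD; the control limits are mean +/- 3 SD.  The
#' simulation is judged acceptable if the observed points fall inside the
#' limits and the signs of (observed - mean) look random: no same-sign run
#' longer than 6 points.  Ties (observed equal to the mean) carry sign zero
#' and break runs; at points where the replicate SD is zero the observation
#' counts as inside only if it equals the mean exactly.
#'
#' @param replicate_series replicate x point matrix of simulated values.
#' @param observed vector of observed values, one per point.
#' @return a \code{control_chart_result}: per-point \code{mean}, \code{sd},
#'   \code{lower}/\code{upper} limits, logical \code{outside}, \code{sign}
#'   (-1/0/1), and \code{run_violations} (start and length of every same-sign
#'   run of length >= 7).
#' @export
control_chart <- function(replicate_series, observed) {
  replicate_series <- as.matrix(replicate_series)
  if (nrow(replicate_series) < 2) stop("need at least 2 replicates")
  if (ncol(replicate_series) != length(observed))
    stop("observed length must match the number of points")
  m <- colMeans(replicate_series)
  s <- apply(replicate_series, 2, stats::sd)
  lower <- m - 3 * s
  upper <- m + 3 * s
  outside <- ifelse(s == 0, observed != m,
                    observed < lower | observed > upper)
  sgn <- sign(observed - m)
  run_violations <- find_sign_runs(sgn, min_length = 7)
  structure(list(mean = m, sd = s, lower = lower, upper = upper,
                 observed = observed, outside = outside, sign = sgn,
                 run_violations = run_violations),
            class = "control_chart_result")
}

find_sign_runs <- function(sgn, min_length = 7) {
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bad <- which(r$values != 0 & r$lengths >= min_length)
  data.frame(start = starts[bad], length = r$lengths[bad],
             sign = r$values[bad])
}

#' @export
print.control_chart_result <- function(x, ...) {
  cat(sprintf("control chart: %d points, %d outside the 3-sigma limits, %d run violation(s)\n",
              length(x$mean), sum(x$outside), nrow(x$run_violations)))
  invisible(x)
}

#' Plot a 3-sigma control chart
#'
#' @param x a \code{control_chart_result}.
#' @param ... passed to \code{plot}.
#' @export
plot.control_chart_result <- function(x, ...) {
  n <- length(x$mean)
  ylim <- range(c(x$lower, x$upper, x$observed), finite = TRUE)
  graphics::plot(seq_len(n), x$mean, type = "l", ylim = ylim,
                 xlab = "point", ylab = "value", ...)
  graphics::lines(seq_len(n), x$lower, lty = 2)
  graphics::lines(seq_len(n), x$upper, lty = 2)
  graphics::points(seq_len(n), x$observed,
                   pch = ifelse(x$outside, 19, 1),
                   col = ifelse(x$outside, 2, 1))
  invisible(x)
}

#' Replicate homogeneity chi-square
#'
#' Standard r x c homogeneity test across replicate count tables (replicates
#' as rows, flattened table cells as columns), with a Monte-Carlo p-value
#' simulated under the pooled cell proportions.
#'
#' @param tables list of count tables (equal shapes).
#' @param n_mc Monte-Carlo tables.
#' @return a \code{gof_result} (with \code{df = (r-1)(c-1)} after dropping
#'   all-zero columns).
#' @export
replicate_homogeneity <- function(tables, n_mc = 2000) {
  if (length(tables) < 2) stop("need at least 2 replicate tables")
  shape <- dim(as.matrix(tables[[1]]))
  for (t in tables)
    if (!identical(dim(as.matrix(t)), shape)) stop("table shape mismatch")
  X <- t(vapply(tables, function(t) as.numeric(t), numeric(prod(shape))))
  X <- X[, colSums(X) > 0, drop = FALSE]
  if (ncol(X) < 2) {
    # degenerate: all events in one cell; trivially homogeneous
    return(structure(list(statistic = 0, df = 0L, p_asymptotic = 1,
                          p_montecarlo = 1, n_mc = n_mc),
                     class = "gof_result"))
  }
  stat <- homogeneity_stat(X)
  df <- (nrow(X) - 1L) * (ncol(X) - 1L)
  p_cells <- colSums(X) / sum(X)
  row_tot <- rowSums(X)
  sim_stat <- vapply(seq_len(n_mc), function(i) {
    S <- t(vapply(row_tot, function(n)
      as.numeric(stats::rmultinom(1, n, p_cells)), numeric(ncol(X))))
    homogeneity_stat(S)
  }, 0)
  p_mc <- (1 + sum(sim_stat >= stat)) / (n_mc + 1)
  structure(list(statistic = stat, df = df,
                 p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE),
                 p_montecarlo = p_mc, n_mc = n_mc),
            class = "gof_result")
}

homogeneity_stat <- function(X) {
  E <- outer(rowSums(X), colSums(X)) / sum(X)
  ok <- E > 0
  sum((X[ok] - E[ok])^2 / E[ok])
}
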