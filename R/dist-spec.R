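# Distribution specifications: the sampleable description of one
# characterization parameter, either normal or piecewise-uniform empirical.

#' Normal distribution specification
#'
#' Describes a parameter whose field measurements showed significant normal
#' distribution characteristics, so that new instances are drawn from
#' N(mu, sigma^2).
#'
#' @param mu Mean, in the units of the parameter (degrees, mm or count).
#' @param sigma Standard deviation, same units; must be >= 0.
#' @return An object of class \code{dist_spec} with \code{kind = "normal"}.
#' @seealso [dist_empirical()], [sample_parameter()]
#' @export
#' @examples
#' sp <- dist_normal(100, 10)
#' sample_parameter(sp, n = 3)
dist_normal <- function(mu, sigma) {
  spec <- structure(list(kind = "normal", mu = as.numeric(mu),
                         sigma = as.numeric(sigma)),
                    class = "dist_spec")
  validate_spec(spec)
  spec
}

#' Piecewise-uniform empirical distribution specification
#'
#' Describes a parameter without a significant parametric distribution by a
#' set of intervals and their probabilities. Sampling selects an interval by
#' the cumulative probabilities and then draws uniformly within it
#' (inverse-CDF interval sampling).
#'
#' @param intervals Two-column numeric matrix (or list of length-2 vectors)
#'   of closed interval bounds \code{[a_i, b_i]}, sorted by \code{a_i} and
#'   non-overlapping.
#' @param probs Numeric vector of interval probabilities; must be >= 0 and
#'   sum to 1 within 1e-6.
#' @return An object of class \code{dist_spec} with \code{kind = "empirical"}.
#' @export
#' @examples
#' # The printed Zaodabai creeping-root initial axial angle distribution:
#' sp <- dist_empirical(
#'   intervals = cbind(c(70, 86, 101, 116, 131, 146),
#'                     c(85, 100, 115, 130, 145, 160)),
#'   probs = c(0.12, 0.36, 0.14, 0.16, 0.16, 0.06))
#' sample_parameter(sp, n = 5)
dist_empirical <- function(intervals, probs) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2,
                      dimnames = list(NULL, c("a", "b")))
  spec <- structure(list(kind = "empirical", intervals = intervals,
                         probs = as.numeric(probs)),
                    class = "dist_spec")
  validate_spec(spec)
  spec
}

#' Validate a distribution specification
#'
#' Checks the structural invariants of a \code{dist_spec}: for normal specs,
#' \code{sigma >= 0}; for empirical specs, matching lengths, \code{a_i <= b_i},
#' sorted non-overlapping intervals, nonnegative probabilities summing to 1
#' within 1e-6.
#'
#' @param spec A \code{dist_spec}.
#' @return The spec, invisibly; errors with a message on violation.
#' @export
validate_spec <- function(spec) {
  if (!inherits(spec, "dist_spec"))
    stop("not a dist_spec object", call. = FALSE)
  if (identical(spec$kind, "normal")) {
    if (!is.finite(spec$mu) || !is.finite(spec$sigma))
      stop("normal spec: mu and sigma must be finite", call. = FALSE)
    if (spec$sigma < 0)
      stop("normal spec: sigma must be >= 0, got ", spec$sigma, call. = FALSE)
  } else if (identical(spec$kind, "empirical")) {
    iv <- spec$intervals
    p <- spec$probs
    if (!is.matrix(iv) || ncol(iv) != 2 || nrow(iv) < 1)
      stop("empirical spec: intervals must be an n x 2 matrix", call. = FALSE)
    if (nrow(iv) != length(p))
      stop("empirical spec: ", nrow(iv), " intervals but ", length(p),
           " probabilities", call. = FALSE)
    if (any(!is.finite(iv)) || any(!is.finite(p)))
      stop("empirical spec: non-finite interval bound or probability",
           call. = FALSE)
    if (any(iv[, 1] > iv[, 2]))
      stop("empirical spec: interval with a_i > b_i", call. = FALSE)
    if (is.unsorted(iv[, 1]))
      stop("empirical spec: intervals must be sorted by lower bound",
           call. = FALSE)
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("empirical spec: overlapping intervals", call. = FALSE)
    if (any(p < 0))
      stop("empirical spec: negative probability", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-6)
      stop("empirical spec: probabilities sum to ", format(sum(p)),
           ", not 1", call. = FALSE)
  } else {
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$kind == "normal") {
    cat(sprintf("<dist_spec> normal(mu = %g, sigma = %g)\n", x$mu, x$sigma))
  } else {
    cat("<dist_spec> empirical,", nrow(x$intervals), "intervals:\n")
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  [%g, %g]  p = %g\n",
                  x$intervals[i, 1], x$intervals[i, 2], x$probs[i]))
  }
  invisible(x)
}

#' Draw samples from a distribution specification
#'
#' Normal specs are drawn with [stats::rnorm()]. Empirical specs use
#' inverse-CDF interval sampling: a uniform \code{u} on \[0, 1\] selects
#' interval \code{i} with \code{u} in \code{(cum_{i-1}, cum_i]} (where
#' \code{cum_0 = 0}), and the value is then uniform on \code{[a_i, b_i]}.
#' Randomness comes from the R session RNG, so results are reproducible
#' under [set.seed()].
#'
#' @param spec A validated \code{dist_spec}.
#' @param n Number of draws.
#' @param nonneg If \code{TRUE}, negative draws are rejected and resampled
#'   (up to 100 rounds), then clamped to 0; used for physically nonnegative
#'   parameters such as radii, lengths, depths and counts.
#' @return Numeric vector of length \code{n}.
#' @export
sample_parameter <- function(spec, n = 1, nonneg = FALSE) {
  validate_spec(spec)
  draw <- function(m) {
    if (spec$kind == "normal") {
      stats::rnorm(m, mean = spec$mu, sd = spec$sigma)
    } else {
      i <- select_interval(spec$probs, stats::runif(m))
      stats::runif(m, min = spec$intervals[i, 1], max = spec$intervals[i, 2])
    }
  }
  x <- draw(n)
  if (nonneg) {
    for (attempt in seq_len(100)) {
      bad <- which(x < 0)
      if (!length(bad)) break
      x[bad] <- draw(length(bad))
    }
    x[x < 0] <- 0
  }
  x
}

# Inverse-CDF interval selection: index i such that u lies in
# (cum_{i-1}, cum_i], with cum_0 = 0; u == 0 maps to the first interval.
select_interval <- function(probs, u) {
  cum <- cumsum(probs)
  cum[length(cum)] <- 1  # guard rounding in the final cumulative sum
  i <- findInterval(u, c(0, cum), left.open = TRUE)
  i[i < 1L] <- 1L
  i
}

#' Mean of a distribution specification
#'
#' The theoretical mean: \code{mu} for normal specs, the probability-weighted
#' interval midpoints for empirical specs.
#'
#' @param spec A \code{dist_spec}.
#' @return Numeric scalar.
#' @export
spec_mean <- function(spec) {
  validate_spec(spec)
  if (spec$kind == "normal") spec$mu
  else sum(spec$probs * rowMeans(spec$intervals))
}

#' Probability mass of a spec over a closed interval
#'
#' Integrates the spec's density over \code{[lower, upper]}. Used to compare
#' refitted empirical distributions against a ground truth binned on
#' different interval boundaries.
#'
#' @param spec A \code{dist_spec}.
#' @param lower,upper Interval bounds, \code{lower <= upper}.
#' @return Probability in \[0, 1\].
#' @export
spec_interval_prob <- function(spec, lower, upper) {
  validate_spec(spec)
  stopifnot(lower <= upper)
  if (spec$kind == "normal") {
    if (spec$sigma == 0) return(as.numeric(spec$mu >= lower & spec$mu <= upper))
    return(stats::pnorm(upper, spec$mu, spec$sigma) -
             stats::pnorm(lower, spec$mu, spec$sigma))
  }
  total <- 0
  for (i in seq_along(spec$probs)) {
    a <- spec$intervals[i, 1]; b <- spec$intervals[i, 2]
    if (b == a) {                       # degenerate interval: a point mass
      if (a >= lower && a <= upper) total <- total + spec$probs[i]
    } else {
      ov <- max(0, min(b, upper) - max(a, lower))
      total <- total + spec$probs[i] * ov / (b - a)
    }
  }
  unname(total)
}
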