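# Fitting distribution specs from measurements: normality-based model
# selection (normal where not rejected, piecewise-uniform empirical
# otherwise), and assembly of whole parameter databases.

#' Fit a distribution specification to a sample
#'
#' Model selection follows the survey's statistical workflow: a parameter
#' whose sample is consistent with normality is stored as a normal spec with
#' the sample mean and standard deviation; otherwise its distribution is
#' expressed empirically as equal-width intervals with relative-frequency
#' probabilities. Normality is tested with the Shapiro-Wilk test.
#'
#' Empirical binning uses Sturges' rule, k = ceiling(1 + log2(n)) equal-width
#' bins over the sample range; empty bins are merged into their right
#' neighbour (the last into its left) so every stored interval has positive
#' probability. A zero-variance sample falls back to a single degenerate
#' interval with probability 1.
#'
#' @param samples Numeric vector, at least 8 finite values.
#' @param alpha Significance level of the normality test (default 0.05);
#'   normality is rejected when p < alpha.
#' @return A \code{dist_spec}.
#' @export
#' @examples
#' set.seed(1)
#' fit_distribution(rnorm(200, 100, 10))       # -> normal spec
#' fit_distribution(c(rnorm(100, 75, 3), rnorm(100, 140, 3)))  # -> empirical
fit_distribution <- function(samples, alpha = 0.05) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  n <- length(samples)
  if (n < 8)
    stop("need at least 8 samples to fit a distribution (got ", n,
         "); supply an explicit dist_spec instead", call. = FALSE)
  rng <- range(samples)
  if (rng[1] == rng[2])  # constant sample: degenerate point mass
    return(dist_empirical(matrix(rng, ncol = 2), 1))
  # Shapiro-Wilk is defined for 3 <= n <= 5000; thin large samples evenly
  sw <- samples
  if (n > 5000) sw <- sort(samples)[round(seq(1, n, length.out = 5000))]
  p <- stats::shapiro.test(sw)$p.value
  if (p >= alpha)
    return(dist_normal(mean(samples), stats::sd(samples)))
  k <- ceiling(1 + log2(n))
  # few distinct values (integer counts, coarse readings): represent the
  # distribution exactly as point masses instead of distorting it with
  # equal-width bins full of gaps
  uv <- sort(unique(samples))
  if (length(uv) <= k) {
    freq <- vapply(uv, function(v) mean(samples == v), numeric(1))
    return(dist_empirical(cbind(uv, uv), freq))
  }
  breaks <- seq(rng[1], rng[2], length.out = k + 1)
  counts <- graphics::hist(samples, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  # merge empty bins into the following bin (last empty bin into previous)
  while (any(counts == 0) && length(counts) > 1) {
    i <- which(counts == 0)[1]
    if (i < length(counts)) {
      lo[i + 1] <- lo[i]
      lo <- lo[-i]; hi <- hi[-i]; counts <- counts[-i]
    } else {
      hi[i - 1] <- hi[i]
      lo <- lo[-i]; hi <- hi[-i]; counts <- counts[-i]
    }
  }
  dist_empirical(cbind(lo, hi), counts / sum(counts))
}

#' Build a parameter database from a measurement table
#'
#' Fits one distribution spec per (organ class, parameter) present in the
#' table via [fit_distribution()]. Counts (number of roots per class, number
#' of tubers) are fitted over the per-plant integer counts recorded in the
#' table. A parameter required for a present organ class but absent from the
#' table is an error naming the pair; organ classes wholly absent from the
#' table are permitted (the resulting database covers only the measured
#' classes and a warning lists the missing ones — model generation requires
#' a complete database).
#'
#' @param table A measurement table (see [validate_measurements()]).
#' @param alpha Normality-test level passed to [fit_distribution()].
#' @param variety Variety name or code for the database.
#' @return A \code{parameter_db}.
#' @export
build_database <- function(table, alpha = 0.05, variety = "unknown") {
  validate_measurements(table)
  if (!nrow(table))
    stop("measurement table is empty", call. = FALSE)
  organs <- list()
  for (cls in intersect(ORGAN_CLASSES, unique(table$organ_class))) {
    sub <- table[table$organ_class == cls, , drop = FALSE]
    specs <- list()
    for (par in required_parameters(cls)) {
      vals <- sub$value[sub$parameter == par]
      if (length(vals) < 8)
        stop("cannot fit (", cls, ", ", par, "): ", length(vals),
             " value(s) in table, need at least 8", call. = FALSE)
      specs[[par]] <- fit_distribution(vals, alpha = alpha)
    }
    organs[[cls]] <- specs
  }
  absent <- setdiff(ORGAN_CLASSES, names(organs))
  if (length(absent))
    warning("no measurements for organ class(es): ",
            paste(absent, collapse = ", "),
            "; database is incomplete for model generation", call. = FALSE)
  new_parameter_db(variety, organs)
}
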