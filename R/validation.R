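# Model validation: relative root mean square error (RRMSE) between
# measured and simulated root depths, the four-level accuracy scale, and
# the end-to-end measured-vs-simulated comparison workflow.

#' Relative root mean square error
#'
#' \code{RRMSE = 100 * sqrt(mean((obs - sim)^2)) / mean(obs)}, in percent.
#' The smaller the RRMSE, the closer the simulation is to the measurements.
#' Undefined (error) when the observed mean is not positive.
#'
#' @param obs Numeric vector of measured values (mm).
#' @param sim Numeric vector of simulated values, same length.
#' @return RRMSE in percent.
#' @export
#' @examples
#' rrmse(c(100), c(90))   # 10
rrmse <- function(obs, sim) {
  obs <- as.numeric(obs); sim <- as.numeric(sim)
  if (!length(obs) || length(obs) != length(sim))
    stop("obs and sim must be non-empty vectors of equal length",
         call. = FALSE)
  if (any(!is.finite(obs)) || any(!is.finite(sim)))
    stop("obs and sim must be finite", call. = FALSE)
  m <- mean(obs)
  if (m <= 0)
    stop("mean of observed values must be > 0 (relative scale undefined)",
         call. = FALSE)
  100 * sqrt(mean((obs - sim)^2)) / m
}

#' RRMSE accuracy levels
#' @export
RRMSE_LEVELS <- c("extremely_significant", "significant", "general", "poor")

#' Classify an RRMSE value on the four-level accuracy scale
#'
#' Below 10 percent the consistency between simulated and measured values is
#' extremely significant; 10-20 percent significant; 20-30 percent general;
#' above 30 percent the simulation is poor. Boundary values are assigned to
#' the worse (higher) class.
#'
#' @param value RRMSE in percent, >= 0.
#' @return One of [RRMSE_LEVELS].
#' @export
#' @examples
#' classify_rrmse(6.81)   # "extremely_significant"
#' classify_rrmse(15.32)  # "significant"
classify_rrmse <- function(value) {
  if (!is.finite(value) || value < 0)
    stop("RRMSE must be a nonnegative number", call. = FALSE)
  if (value < 10) "extremely_significant"
  else if (value < 20) "significant"
  else if (value < 30) "general"
  else "poor"
}

# Rank pairing of two depth samples: sort both; when sizes differ, the
# simulated sample is reduced to the observed sample's plotting-position
# quantiles. This compares the distributions without inventing a
# plant-by-plant correspondence.
rank_pair <- function(obs, sim) {
  obs <- sort(obs)
  n <- length(obs)
  if (length(sim) == n) {
    sim <- sort(sim)
  } else {
    sim <- as.numeric(stats::quantile(sim, probs = (seq_len(n) - 0.5) / n,
                                      type = 7, names = FALSE))
  }
  list(obs = obs, sim = sim)
}

#' Validate a parameter database against measured root depths
#'
#' Simulates \code{n_plants} plants from the database with [build_plant()],
#' collects the trajectory depth ([axis_depth()]) of every simulated root
#' per class, and compares it with the measured depths
#' (\code{parameter == "depth_mm"}) in the table. Measured and simulated
#' depths are rank-paired (both sorted; quantile-matched when sizes differ)
#' and scored with [rrmse()] and [classify_rrmse()]. Simulated depths come
#' from the growth trajectories, not from the fitted depth distribution, so
#' validation is a genuine end-to-end test of the growth model. Root
#' classes absent from either side are skipped with a warning.
#'
#' @param db A complete \code{parameter_db}.
#' @param measured A measurement table with depth rows for the root classes.
#' @param n_plants Number of plants to simulate (>= 1).
#' @param seed Optional integer seed.
#' @param l_unit Growth-unit length for the simulated axes, mm.
#' @return An object of class \code{validation_report}: per root class the
#'   RRMSE (percent), accuracy level, sample size and the paired
#'   observed/simulated vectors.
#' @export
validate_model <- function(db, measured, n_plants = 50, seed = NULL,
                           l_unit = 1) {
  validate_db(db, complete = TRUE)
  validate_measurements(measured)
  if (!is.numeric(n_plants) || n_plants < 1)
    stop("n_plants must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim_depths <- stats::setNames(vector("list", length(ROOT_CLASSES)),
                                ROOT_CLASSES)
  for (i in seq_len(n_plants)) {
    # tuber/stem count mismatches are irrelevant to depth validation
    plant <- withCallingHandlers(
      build_plant(db, l_unit = l_unit),
      warning = function(w) {
        if (grepl("dropping", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    for (nd in plant$nodes) {
      if (nd$organ_class %in% ROOT_CLASSES)
        sim_depths[[nd$organ_class]] <-
          c(sim_depths[[nd$organ_class]], axis_depth(nd$axis))
    }
  }
  results <- list()
  for (cls in ROOT_CLASSES) {
    obs <- measured$value[measured$organ_class == cls &
                            measured$parameter == "depth_mm"]
    sim <- sim_depths[[cls]]
    if (!length(obs) || !length(sim)) {
      warning("skipping ", cls, ": no ",
              if (!length(obs)) "measured" else "simulated",
              " depths available", call. = FALSE)
      next
    }
    pr <- rank_pair(obs, sim)
    val <- rrmse(pr$obs, pr$sim)
    results[[cls]] <- list(rrmse_percent = val, level = classify_rrmse(val),
                           n = length(pr$obs), obs = pr$obs, sim = pr$sim)
  }
  structure(list(variety = db$variety, n_plants = n_plants, seed = seed,
                 classes = results),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> variety:", x$variety, "-", x$n_plants,
      "simulated plants\n")
  for (cls in names(x$classes)) {
    r <- x$classes[[cls]]
    cat(sprintf("  %-14s RRMSE %6.2f %%  (%s, n = %d)\n",
                cls, r$rrmse_percent, r$level, r$n))
  }
  invisible(x)
}

#' Scatter plot of measured vs simulated depths
#'
#' One panel per root class with the 1:1 line; the usual visual check of the
#' depth validation.
#'
#' @param x A \code{validation_report}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.validation_report <- function(x, ...) {
  ncls <- length(x$classes)
  if (!ncls) stop("empty validation report", call. = FALSE)
  old <- graphics::par(mfrow = c(1, ncls))
  on.exit(graphics::par(old))
  for (cls in names(x$classes)) {
    r <- x$classes[[cls]]
    lim <- range(c(r$obs, r$sim))
    graphics::plot(r$obs, r$sim, xlab = "measured depth (mm)",
                   ylab = "simulated depth (mm)",
                   main = sprintf("%s (RRMSE %.1f%%)", cls, r$rrmse_percent),
                   xlim = lim, ylim = lim, ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Write a validation report
#'
#' JSON carries the full report (per class RRMSE, level, n, paired vectors,
#' seed); the CSV is the summary table, one row per (variety, root class)
#' with the RRMSE in percent.
#'
#' @param report A \code{validation_report}.
#' @param json_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the summary data frame.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  summary_df <- do.call(rbind, lapply(names(report$classes), function(cls) {
    r <- report$classes[[cls]]
    data.frame(variety = report$variety, organ_class = cls,
               rrmse_percent = r$rrmse_percent, level = r$level, n = r$n,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(variety = report$variety,
                              n_plants = report$n_plants,
                              seed = report$seed,
                              classes = report$classes),
                         json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  if (!is.null(csv_path))
    utils::write.csv(summary_df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(summary_df)
}
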