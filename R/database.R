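# Parameter database: per-variety, per-organ-class collection of
# distribution specs for every characterization parameter.

#' Organ classes of the tuber-root system
#'
#' The six organ classes of the model: the seed potato, the underground
#' (main) stem, the three root classes (seminal roots, creeping roots,
#' creeping stems/stolons) and the daughter tubers. Fibrous roots are
#' excluded from the model because they are too slim to influence
#' soil-tuber-root mechanics.
#'
#' @format Character vectors.
#' @export
ORGAN_CLASSES <- c("seed_potato", "underground_stem", "seminal_root",
                   "creeping_root", "creeping_stem", "tuber")

#' @rdname ORGAN_CLASSES
#' @export
ROOT_CLASSES <- c("seminal_root", "creeping_root", "creeping_stem")

#' Variety codes
#'
#' Numeric codes for the three early-maturing varieties:
#' 1 = Zaodabai, 2 = Helanshiwu, 3 = Fujin.
#' @export
VARIETY_CODES <- c(Zaodabai = 1L, Helanshiwu = 2L, Fujin = 3L)

#' Required characterization parameters per organ class
#'
#' Root classes carry the full root parameter set (initial axial and radial
#' angles in degrees, initial and tip radii, length, depth and distance to
#' the seed potato in mm, total deflection angle in degrees, and a per-plant
#' count). Tubers carry their three dimensions and a count; the underground
#' stem its bottom/top radii and height; the seed potato its dimensions and
#' burial depth.
#'
#' @param organ_class One of [ORGAN_CLASSES].
#' @return Character vector of parameter names (units suffixed).
#' @export
required_parameters <- function(organ_class) {
  switch(organ_class,
    seed_potato = c("length_mm", "width_mm", "height_mm", "burial_depth_mm"),
    underground_stem = c("bottom_radius_mm", "top_radius_mm", "height_mm"),
    seminal_root = ,
    creeping_root = ,
    creeping_stem = c("axial_angle_deg", "radial_angle_deg",
                      "initial_radius_mm", "tip_radius_mm", "length_mm",
                      "depth_mm", "total_deflection_deg", "count",
                      "distance_to_seed_mm"),
    tuber = c("length_mm", "width_mm", "height_mm", "count"),
    stop("unknown organ class: ", organ_class, call. = FALSE)
  )
}

# Angles (including deflections) may be sampled on the full real line; every
# other parameter is physically nonnegative and sampled with rejection.
is_nonneg_parameter <- function(parameter) {
  !grepl("angle|deflection", parameter)
}

parameter_units <- function(parameter) {
  as.character(ifelse(grepl("_deg$", parameter), "deg",
                      ifelse(parameter == "count", "count", "mm")))
}

#' Construct a parameter database
#'
#' @param variety Variety name ("Zaodabai", "Helanshiwu", "Fujin") or its
#'   numeric code 1/2/3; other names are accepted for user databases.
#' @param organs Named list: organ class -> named list of
#'   parameter -> \code{dist_spec}.
#' @return An object of class \code{parameter_db}.
#' @export
new_parameter_db <- function(variety, organs) {
  variety <- resolve_variety(variety)
  db <- structure(list(variety = variety, organs = organs),
                  class = "parameter_db")
  validate_db(db)
  db
}

resolve_variety <- function(variety) {
  if (is.numeric(variety)) {
    code <- as.integer(variety)
    if (!code %in% VARIETY_CODES)
      stop("unknown variety code: ", variety,
           " (valid codes: 1 = Zaodabai, 2 = Helanshiwu, 3 = Fujin)",
           call. = FALSE)
    return(names(VARIETY_CODES)[match(code, VARIETY_CODES)])
  }
  as.character(variety)
}

#' Validate a parameter database
#'
#' Checks that every organ class is known, that every spec validates, and
#' that parameter names are drawn from the required set for their class.
#'
#' @param db A \code{parameter_db}.
#' @param complete If \code{TRUE}, additionally require that all six organ
#'   classes are present and each carries its full parameter set (as model
#'   generation does).
#' @return \code{db}, invisibly.
#' @export
validate_db <- function(db, complete = FALSE) {
  if (!inherits(db, "parameter_db"))
    stop("not a parameter_db object", call. = FALSE)
  if (!length(db$organs))
    stop("parameter database has no organ classes", call. = FALSE)
  for (cls in names(db$organs)) {
    if (!cls %in% ORGAN_CLASSES)
      stop("unknown organ class in database: '", cls, "'", call. = FALSE)
    req <- required_parameters(cls)
    for (par in names(db$organs[[cls]])) {
      if (!par %in% req)
        stop("unknown parameter '", par, "' for organ class '", cls, "'",
             call. = FALSE)
      tryCatch(validate_spec(db$organs[[cls]][[par]]),
               error = function(e) stop("organ '", cls, "', parameter '", par,
                                        "': ", conditionMessage(e),
                                        call. = FALSE))
    }
  }
  if (complete) {
    for (cls in ORGAN_CLASSES) {
      if (is.null(db$organs[[cls]]))
        stop("database is missing organ class '", cls, "'", call. = FALSE)
      miss <- setdiff(required_parameters(cls), names(db$organs[[cls]]))
      if (length(miss))
        stop("database is missing spec for ", cls, ": ",
             paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(db)
}

#' @export
print.parameter_db <- function(x, ...) {
  cat("<parameter_db> variety:", x$variety, "\n")
  for (cls in names(x$organs)) {
    kinds <- vapply(x$organs[[cls]], function(s) s$kind, character(1))
    cat(sprintf("  %-17s %d parameters (%d normal, %d empirical)\n",
                cls, length(kinds), sum(kinds == "normal"),
                sum(kinds == "empirical")))
  }
  invisible(x)
}

spec_to_list <- function(spec) {
  if (spec$kind == "normal") {
    list(kind = "normal", mu = spec$mu, sigma = spec$sigma)
  } else {
    list(kind = "empirical",
         intervals = lapply(seq_len(nrow(spec$intervals)),
                            function(i) as.numeric(spec$intervals[i, ])),
         probs = as.numeric(spec$probs))
  }
}

spec_from_list <- function(x, where) {
  kind <- x$kind
  if (is.null(kind))
    stop("missing 'kind' at ", where, call. = FALSE)
  res <- tryCatch({
    if (kind == "normal") {
      dist_normal(x$mu, x$sigma)
    } else if (kind == "empirical") {
      iv <- x$intervals
      if (is.list(iv)) iv <- do.call(rbind, lapply(iv, as.numeric))
      dist_empirical(iv, as.numeric(x$probs))
    } else stop("unknown kind '", kind, "'", call. = FALSE)
  }, error = function(e) {
    stop("invalid spec at ", where, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Save / load a parameter database as JSON
#'
#' The on-disk dialect is
#' \code{{"variety": "...", "organs": {"creeping_root":
#' {"axial_angle_deg": {"kind": "empirical", "intervals": [[70,85], ...],
#' "probs": [0.12, ...]}, ...}, ...}}}. Truth configurations
#' (see [default_truth()]) additionally carry \code{n_plants} and
#' \code{seed}. Load validates the schema and reports the JSON path of the
#' first offending field.
#'
#' @param db A \code{parameter_db} (or \code{truth_config}).
#' @param path File path of the JSON document.
#' @return \code{save_database} returns \code{path} invisibly;
#'   \code{load_database} returns the database.
#' @export
save_database <- function(db, path) {
  validate_db(db)
  out <- list(variety = db$variety,
              organs = lapply(db$organs, function(org) lapply(org, spec_to_list)))
  if (!is.null(db$n_plants)) out$n_plants <- db$n_plants
  if (!is.null(db$seed)) out$seed <- db$seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$variety))
    stop("schema violation at $.variety: missing", call. = FALSE)
  if (is.null(x$organs) || !length(x$organs))
    stop("schema violation at $.organs: missing or empty", call. = FALSE)
  organs <- list()
  for (cls in names(x$organs)) {
    if (!cls %in% ORGAN_CLASSES)
      stop("schema violation at $.organs.", cls, ": unknown organ class",
           call. = FALSE)
    specs <- list()
    for (par in names(x$organs[[cls]])) {
      if (!par %in% required_parameters(cls))
        stop("schema violation at $.organs.", cls, ".", par,
             ": unknown parameter", call. = FALSE)
      specs[[par]] <- spec_from_list(x$organs[[cls]][[par]],
                                     paste0("$.organs.", cls, ".", par))
    }
    organs[[cls]] <- specs
  }
  db <- new_parameter_db(x$variety, organs)
  if (!is.null(x$n_plants) || !is.null(x$seed)) {
    db$n_plants <- if (!is.null(x$n_plants)) as.integer(x$n_plants)
    db$seed <- if (!is.null(x$seed)) as.integer(x$seed)
    class(db) <- c("truth_config", class(db))
  }
  db
}

db_equal <- function(a, b, tol = 1e-12) {
  isTRUE(all.equal(unclass(a)[c("variety", "organs")],
                   unclass(b)[c("variety", "organs")], tolerance = tol))
}
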