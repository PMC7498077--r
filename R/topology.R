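# Plant topology: the tuber-root system as a tree of organ nodes stored in
# child-chain (child-sibling) notation. The tree has three structural parts:
# seed potato -> seminal roots; seed potato -> underground stem -> creeping
# stems -> tubers; and underground stem -> creeping roots. Levels: seed
# potato 1; seminal roots and underground stem 2; creeping roots/stems 3;
# tubers 4.

new_organ_node <- function(id, organ_class, level, parent = NA_integer_,
                           params = list(), axis = NULL, dims = NULL,
                           center = NULL, attach_h = NA_real_) {
  list(id = as.integer(id), organ_class = organ_class,
       level = as.integer(level), parent = as.integer(parent),
       first_child = NA_integer_, next_sibling = NA_integer_,
       params = params, axis = axis, dims = dims, center = center,
       attach_h = attach_h)
}

# Append child to parent's child chain (after existing siblings).
link_child <- function(nodes, parent_id, child_id) {
  if (is.na(nodes[[parent_id]]$first_child)) {
    nodes[[parent_id]]$first_child <- child_id
  } else {
    sib <- nodes[[parent_id]]$first_child
    while (!is.na(nodes[[sib]]$next_sibling)) sib <- nodes[[sib]]$next_sibling
    nodes[[sib]]$next_sibling <- child_id
  }
  nodes
}

sample_count <- function(spec) {
  max(0L, as.integer(round(sample_parameter(spec, 1, nonneg = TRUE))))
}

sample_root_params <- function(specs) {
  p <- list(
    axial_angle_deg = sample_parameter(specs$axial_angle_deg, 1),
    radial_angle_deg = sample_parameter(specs$radial_angle_deg, 1),
    initial_radius_mm = sample_parameter(specs$initial_radius_mm, 1, nonneg = TRUE),
    tip_radius_mm = sample_parameter(specs$tip_radius_mm, 1, nonneg = TRUE),
    length_mm = sample_parameter(specs$length_mm, 1, nonneg = TRUE),
    total_deflection_deg = sample_parameter(specs$total_deflection_deg, 1),
    distance_to_seed_mm = sample_parameter(specs$distance_to_seed_mm, 1, nonneg = TRUE)
  )
  # roots taper: tip radius cannot exceed the initial radius
  p$tip_radius_mm <- min(p$tip_radius_mm, p$initial_radius_mm)
  if (p$length_mm <= 0) p$length_mm <- 1  # degenerate draw: minimal stub
  p
}

#' Build a plant model from a parameter database
#'
#' Samples the full tuber-root system of one plant: seed potato dimensions
#' and burial depth; the underground stem; per-class root counts; each
#' root's initial angles, radii, length, deflection and (for creeping roots
#' and stems) rooting distance along the stem, clamped to the stem height;
#' and tuber counts and dimensions. Root axes are generated with the growth
#' model. Seminal roots start at the seed potato center \code{(0, 0, z0)};
#' creeping roots and stems start on the underground-stem axis at their
#' sampled distance above the seed; each tuber sits at the terminal node of
#' a creeping stem (when fewer tubers than stems are drawn, the longest
#' stems receive them; excess tubers beyond the stem count are dropped with
#' a warning).
#'
#' @param db A complete \code{parameter_db} (all six organ classes).
#' @param seed Optional integer seed for reproducible builds.
#' @param l_unit Growth-unit length in mm (default 1).
#' @return An object of class \code{plant_model}.
#' @export
build_plant <- function(db, seed = NULL, l_unit = 1) {
  validate_db(db, complete = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sp <- db$organs$seed_potato
  st <- db$organs$underground_stem

  z0 <- sample_parameter(sp$burial_depth_mm, 1, nonneg = TRUE)
  seed_dims <- c(L = sample_parameter(sp$length_mm, 1, nonneg = TRUE),
                 W = sample_parameter(sp$width_mm, 1, nonneg = TRUE),
                 H = sample_parameter(sp$height_mm, 1, nonneg = TRUE))
  h_j <- sample_parameter(st$height_mm, 1, nonneg = TRUE)
  r_j0 <- sample_parameter(st$bottom_radius_mm, 1, nonneg = TRUE)
  r_j1 <- sample_parameter(st$top_radius_mm, 1, nonneg = TRUE)
  r_j1 <- min(r_j1, r_j0)

  nodes <- list()
  nodes[[1]] <- new_organ_node(1, "seed_potato", 1,
                               params = list(burial_depth_mm = z0),
                               dims = seed_dims, center = c(0, 0, z0))
  # underground stem: vertical axis from the seed upward toward the surface
  stem_axis <- generate_axis(start = c(0, 0, z0), axial_angle = 0,
                             radial_angle = 0, total_length = h_j,
                             l_unit = max(l_unit, h_j / 64),
                             r0 = r_j0, r_tip = r_j1)
  nodes[[2]] <- new_organ_node(2, "underground_stem", 2, parent = 1,
                               params = list(height_mm = h_j,
                                             bottom_radius_mm = r_j0,
                                             top_radius_mm = r_j1),
                               axis = stem_axis, attach_h = 0)
  nodes <- link_child(nodes, 1L, 2L)

  add_root <- function(nodes, cls, parent_id, level) {
    p <- sample_root_params(db$organs[[cls]])
    if (cls == "seminal_root") {
      h_g <- 0
      start <- c(0, 0, z0)
    } else {
      h_g <- min(max(p$distance_to_seed_mm, 0), h_j)
      start <- c(0, 0, z0 - h_g)  # on the stem axis, h_g above the seed
    }
    ax <- generate_axis(start = start, axial_angle = p$axial_angle_deg,
                        radial_angle = p$radial_angle_deg,
                        total_length = p$length_mm, l_unit = l_unit,
                        total_deflection = p$total_deflection_deg,
                        r0 = p$initial_radius_mm, r_tip = p$tip_radius_mm)
    id <- length(nodes) + 1L
    nodes[[id]] <- new_organ_node(id, cls, level, parent = parent_id,
                                  params = p, axis = ax, attach_h = h_g)
    link_child(nodes, parent_id, id)
  }

  n_sem <- sample_count(db$organs$seminal_root$count)
  for (i in seq_len(n_sem)) nodes <- add_root(nodes, "seminal_root", 1L, 2L)
  n_cr <- sample_count(db$organs$creeping_root$count)
  for (i in seq_len(n_cr)) nodes <- add_root(nodes, "creeping_root", 2L, 3L)
  n_cs <- sample_count(db$organs$creeping_stem$count)
  stem_ids <- integer(0)
  for (i in seq_len(n_cs)) {
    nodes <- add_root(nodes, "creeping_stem", 2L, 3L)
    stem_ids <- c(stem_ids, length(nodes))
  }

  tb <- db$organs$tuber
  n_k <- sample_count(tb$count)
  if (n_k > length(stem_ids)) {
    warning(n_k, " tubers drawn but only ", length(stem_ids),
            " creeping stems; dropping ", n_k - length(stem_ids),
            " tuber(s)", call. = FALSE)
    n_k <- length(stem_ids)
  }
  if (n_k > 0) {
    stem_len <- vapply(stem_ids, function(i) nodes[[i]]$params$length_mm,
                       numeric(1))
    chosen <- stem_ids[order(stem_len, decreasing = TRUE)][seq_len(n_k)]
    chosen <- sort(chosen)  # keep child order stable
    for (sid in chosen) {
      dims <- sort(c(sample_parameter(tb$length_mm, 1, nonneg = TRUE),
                     sample_parameter(tb$width_mm, 1, nonneg = TRUE),
                     sample_parameter(tb$height_mm, 1, nonneg = TRUE)),
                   decreasing = TRUE)
      names(dims) <- c("L", "W", "H")
      term <- nodes[[sid]]$axis$points[nrow(nodes[[sid]]$axis$points), ]
      id <- length(nodes) + 1L
      nodes[[id]] <- new_organ_node(id, "tuber", 4, parent = sid,
                                    params = list(),
                                    dims = dims, center = as.numeric(term))
      nodes <- link_child(nodes, sid, id)
    }
  }
  structure(list(variety = db$variety, seed = seed, l_unit = l_unit,
                 nodes = nodes, root = 1L),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  classes <- vapply(x$nodes, function(n) n$organ_class, character(1))
  cat("<plant_model> variety:", x$variety, "-", length(x$nodes), "organ nodes\n")
  print(table(factor(classes, levels = ORGAN_CLASSES)))
  invisible(x)
}

#' Traverse a plant model
#'
#' Walks the child-sibling links, visiting every node exactly once.
#' Preorder visits a node before its child chain; level order groups nodes
#' by tree level (1 seed potato .. 4 tubers). A cycle in the links raises a
#' structural error.
#'
#' @param plant A \code{plant_model}.
#' @param order \code{"preorder"} or \code{"levelorder"}.
#' @return List of organ nodes in visit order.
#' @export
traverse <- function(plant, order = c("preorder", "levelorder")) {
  order <- match.arg(order)
  nodes <- plant$nodes
  n <- length(nodes)
  seen <- logical(n)
  visit_count <- 0L
  check <- function(id) {
    if (seen[id]) stop("cycle detected in child-sibling links at node ", id,
                       call. = FALSE)
    visit_count <<- visit_count + 1L
    if (visit_count > n) stop("cycle detected in child-sibling links",
                              call. = FALSE)
    seen[id] <<- TRUE
  }
  out <- vector("list", n)
  k <- 0L
  if (order == "preorder") {
    stack <- plant$root
    while (length(stack)) {
      id <- stack[1]; stack <- stack[-1]
      check(id)
      k <- k + 1L; out[[k]] <- nodes[[id]]
      push <- c()
      if (!is.na(nodes[[id]]$first_child)) push <- nodes[[id]]$first_child
      if (!is.na(nodes[[id]]$next_sibling)) push <- c(push, nodes[[id]]$next_sibling)
      # first child is explored before the next sibling (preorder)
      stack <- c(push, stack)
    }
  } else {
    queue <- plant$root
    while (length(queue)) {
      id <- queue[1]; queue <- queue[-1]
      check(id)
      k <- k + 1L; out[[k]] <- nodes[[id]]
      child <- nodes[[id]]$first_child
      while (!is.na(child)) {
        queue <- c(queue, child)
        child <- nodes[[child]]$next_sibling
      }
    }
  }
  out[seq_len(k)]
}

axis_to_list <- function(ax) {
  if (is.null(ax)) return(NULL)
  list(points = lapply(seq_len(nrow(ax$points)),
                       function(i) as.numeric(ax$points[i, ])),
       l_unit = ax$l_unit, gamma = as.numeric(ax$gamma),
       theta = as.numeric(ax$theta), axial_angle = ax$axial_angle,
       radial_angle = ax$radial_angle, r0 = ax$r0, r_tip = ax$r_tip)
}

axis_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  structure(list(points = do.call(rbind, lapply(x$points, as.numeric)),
                 l_unit = x$l_unit, gamma = as.numeric(x$gamma),
                 theta = as.numeric(x$theta), axial_angle = x$axial_angle,
                 radial_angle = x$radial_angle, r0 = x$r0, r_tip = x$r_tip),
            class = "root_axis")
}

#' Save / load a plant model as JSON
#'
#' Serializes the child-sibling tree: one record per organ node with its id,
#' class, level, parent / first-child / next-sibling links, sampled
#' parameters, axis polyline (roots and stems) or dimensions and center
#' (seed potato, tubers). The build seed is embedded.
#'
#' @param plant A \code{plant_model}.
#' @param path JSON file path.
#' @return \code{save_plant} returns \code{path} invisibly;
#'   \code{load_plant} the plant model.
#' @export
save_plant <- function(plant, path) {
  nodes <- lapply(plant$nodes, function(nd) {
    list(id = nd$id, organ_class = nd$organ_class, level = nd$level,
         parent = nd$parent, first_child = nd$first_child,
         next_sibling = nd$next_sibling, params = nd$params,
         axis = axis_to_list(nd$axis),
         dims = if (!is.null(nd$dims)) as.list(nd$dims),
         center = if (!is.null(nd$center)) as.numeric(nd$center),
         attach_h = nd$attach_h)
  })
  jsonlite::write_json(list(variety = plant$variety, seed = plant$seed,
                            l_unit = plant$l_unit, root = plant$root,
                            nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname save_plant
#' @export
load_plant <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_int_na <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  nodes <- lapply(x$nodes, function(nd) {
    node <- new_organ_node(nd$id, nd$organ_class, nd$level,
                           parent = as_int_na(nd$parent),
                           params = lapply(nd$params, as.numeric),
                           axis = axis_from_list(nd$axis),
                           dims = if (!is.null(nd$dims))
                             unlist(lapply(nd$dims, as.numeric)),
                           center = if (!is.null(nd$center))
                             as.numeric(unlist(nd$center)),
                           attach_h = if (is.null(nd$attach_h)) NA_real_
                                      else as.numeric(nd$attach_h))
    node$first_child <- as_int_na(nd$first_child)
    node$next_sibling <- as_int_na(nd$next_sibling)
    node
  })
  structure(list(variety = x$variety,
                 seed = if (!is.null(x$seed)) as.integer(x$seed),
                 l_unit = as.numeric(x$l_unit),
                 nodes = nodes, root = as.integer(x$root)),
            class = "plant_model")
}

#' Per-class node counts of a plant
#' @param plant A \code{plant_model}.
#' @return Named integer vector over [ORGAN_CLASSES].
#' @export
plant_counts <- function(plant) {
  classes <- vapply(plant$nodes, function(n) n$organ_class, character(1))
  table(factor(classes, levels = ORGAN_CLASSES))
}
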