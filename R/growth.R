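# Root growth trajectories: curved axes generated by iterated unit-length
# steps, each deflected by a rotation of gamma degrees about the local Z
# axis (radial deflection) and theta degrees about the local X axis (axial
# deflection). In the local frame the undeflected step is +Y.
#
# Conventions (world frame): right-handed, z is soil depth, positive
# downward, soil surface at z = 0; the seed potato center sits at
# (0, 0, z0). The initial axial angle is measured from the upward
# underground-stem direction, so 180 deg points straight down and 90 deg is
# horizontal. The initial radial angle is measured from +Y in the
# horizontal plane.

deg2rad <- function(deg) deg * pi / 180

#' Deflection rotation matrix
#'
#' The 3x3 rotation applied to a row vector: \code{gamma} degrees about Z
#' followed by \code{theta} degrees about X, so that the undeflected local
#' step \code{(0, l, 0)} maps to
#' \code{l * (-cos(theta) sin(gamma), cos(theta) cos(gamma), sin(theta))}.
#'
#' @param gamma Radial deflection, degrees (about Z).
#' @param theta Axial deflection, degrees (about X).
#' @return 3x3 rotation matrix (row-vector convention: \code{v \%*\% R}).
#' @export
deflection_rotation <- function(gamma, theta) {
  g <- deg2rad(gamma); t <- deg2rad(theta)
  matrix(c(cos(g),           sin(g),           0,
           -cos(t) * sin(g), cos(t) * cos(g),  sin(t),
           sin(t) * sin(g),  -sin(t) * cos(g), cos(t)),
         nrow = 3, byrow = TRUE)
}

#' Advance a root tip by one growth unit
#'
#' One step of the tip-growth recurrence: in the tip's local frame the root
#' grows a unit length \code{l} along +Y and is deflected by
#' \code{gamma} (about Z) and \code{theta} (about X). The orientation state
#' accumulates the deflections so successive steps bend smoothly; from the
#' identity orientation a single step reproduces the homogeneous-transform
#' product (translation by \code{(0, l, 0)} then rotation) exactly.
#'
#' @param point Numeric length-3, current tip position (mm).
#' @param orientation 3x3 rotation, the accumulated local-to-world frame
#'   (row-vector convention); identity for a fresh axis.
#' @param l Growth-unit length, mm; must be > 0.
#' @param gamma,theta Deflection angles for this step, degrees.
#' @return List with \code{point} (new tip) and \code{orientation} (updated
#'   frame).
#' @export
#' @examples
#' growth_step(c(1, 2, 3), diag(3), l = 5, gamma = 0, theta = 0)$point # (1,7,3)
growth_step <- function(point, orientation = diag(3), l, gamma = 0, theta = 0) {
  if (!is.numeric(l) || length(l) != 1 || l <= 0)
    stop("growth-unit length l must be a positive scalar", call. = FALSE)
  R <- deflection_rotation(gamma, theta)
  disp <- c(0, l, 0) %*% R %*% orientation
  list(point = as.numeric(point + disp), orientation = R %*% orientation)
}

#' Generate a curved root axis
#'
#' Builds the axis as \code{N = round(total_length / l_unit)} growth steps in
#' a canonical frame (first step along +Y), deflecting each step by
#' \code{total_deflection / N} degrees axially (and
#' \code{radial_deflection / N} radially) — the bending of a root is treated
#' as a uniform change over its length. Optionally each step's deflections
#' can instead be drawn from distribution specs, or jittered around the
#' uniform split. The finished polyline is then rigidly rotated to the
#' initial axial angle (from the upward stem direction, about X) and radial
#' angle (about the vertical axis) and translated to the rooting point.
#'
#' @param start Numeric length-3 rooting point, world mm.
#' @param axial_angle Initial axial angle, degrees from the upward
#'   underground-stem direction (180 = straight down, 90 = horizontal).
#' @param radial_angle Initial radial angle, degrees from +Y in the
#'   horizontal plane.
#' @param total_length Root length, mm (> 0).
#' @param l_unit Growth-unit length, mm (default 1; smaller values give
#'   smoother, more realistic axes).
#' @param total_deflection Total axial deflection over the root, degrees.
#' @param radial_deflection Total radial deflection, degrees (default 0).
#' @param r0,r_tip Initial and tip radius, mm (r0 >= r_tip >= 0); carried on
#'   the axis for tube meshing.
#' @param jitter_sd Standard deviation (degrees) of optional zero-mean
#'   normal jitter added to each step's deflections (default 0, off).
#' @param step_sampler Optional function(n) returning an n x 2 matrix of
#'   per-step (gamma, theta) deflections drawn from a database, overriding
#'   the uniform split.
#' @return An object of class \code{root_axis}: \code{points}
#'   ((N+1) x 3 matrix), \code{l_unit}, per-step \code{gamma}/\code{theta},
#'   \code{axial_angle}, \code{radial_angle}, \code{r0}, \code{r_tip}.
#' @export
generate_axis <- function(start = c(0, 0, 0), axial_angle = 180,
                          radial_angle = 0, total_length, l_unit = 1,
                          total_deflection = 0, radial_deflection = 0,
                          r0 = 0, r_tip = 0, jitter_sd = 0,
                          step_sampler = NULL) {
  if (total_length <= 0) stop("total_length must be > 0", call. = FALSE)
  if (l_unit <= 0) stop("l_unit must be > 0", call. = FALSE)
  if (r0 < r_tip || r_tip < 0)
    stop("radii must satisfy r0 >= r_tip >= 0", call. = FALSE)
  if (l_unit > total_length) {
    warning("l_unit exceeds total_length; producing a single-step axis",
            call. = FALSE)
    l_unit <- total_length
  }
  n <- max(1L, as.integer(round(total_length / l_unit)))
  if (!is.null(step_sampler)) {
    gt <- step_sampler(n)
    gammas <- gt[, 1]; thetas <- gt[, 2]
  } else {
    gammas <- rep(radial_deflection / n, n)
    thetas <- rep(total_deflection / n, n)
  }
  if (jitter_sd > 0) {
    gammas <- gammas + stats::rnorm(n, 0, jitter_sd)
    thetas <- thetas + stats::rnorm(n, 0, jitter_sd)
  }
  pts <- matrix(0, nrow = n + 1L, ncol = 3)
  if (is.null(step_sampler) && jitter_sd == 0) {
    # uniform bending: the orientation after i steps is R^i, so the i-th
    # displacement is d_{i} = d_{i-1} %*% R with d_0 = (0, l, 0) %*% R
    R <- deflection_rotation(gammas[1], thetas[1])
    d <- c(0, l_unit, 0)
    for (i in seq_len(n)) {
      d <- as.numeric(d %*% R)
      pts[i + 1L, ] <- pts[i, ] + d
    }
  } else {
    state <- list(point = c(0, 0, 0), orientation = diag(3))
    for (i in seq_len(n)) {
      state <- growth_step(state$point, state$orientation, l_unit,
                           gammas[i], thetas[i])
      pts[i + 1L, ] <- state$point
    }
  }
  # rigid placement: tilt the canonical +Y axis to the initial axial angle
  # (measured from upward = -z), then swing by the radial angle about the
  # vertical axis, then translate to the rooting point
  place <- deflection_rotation(0, axial_angle - 90) %*%
    deflection_rotation(radial_angle, 0)
  pts <- pts %*% place
  pts <- sweep(pts, 2, as.numeric(start), "+")
  structure(list(points = pts, l_unit = l_unit, gamma = gammas,
                 theta = thetas, axial_angle = axial_angle,
                 radial_angle = radial_angle, r0 = r0, r_tip = r_tip),
            class = "root_axis")
}

#' @export
print.root_axis <- function(x, ...) {
  cat(sprintf(paste0("<root_axis> %d growth units of %g mm, axial %g deg,",
                     " radial %g deg, depth %.1f mm\n"),
              nrow(x$points) - 1L, x$l_unit, x$axial_angle, x$radial_angle,
              axis_depth(x)))
  invisible(x)
}

#' Maximum soil depth reached by an axis
#'
#' Depth is the z coordinate (positive downward); the axis depth is the
#' maximum over all trajectory points, the simulated counterpart of the
#' measured root depth used in validation.
#'
#' @param axis A \code{root_axis}.
#' @return Depth in mm.
#' @export
axis_depth <- function(axis) {
  if (!inherits(axis, "root_axis")) stop("not a root_axis", call. = FALSE)
  if (!nrow(axis$points)) stop("empty axis", call. = FALSE)
  max(axis$points[, 3])
}

#' Total polyline length of an axis
#' @param axis A \code{root_axis}.
#' @return Length in mm (sum of segment lengths).
#' @export
axis_length <- function(axis) {
  d <- diff(axis$points)
  sum(sqrt(rowSums(d^2)))
}
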