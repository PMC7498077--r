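# Procedural organ geometry: triangle meshes for the semi-ellipsoid seed
# potato, the stitched-frustum underground stem, linearly tapering root
# tubes swept along curved axes, and ellipsoidal tubers. Meshes are plain
# lists of vertices (n x 3, mm) and faces (m x 3 integer, 1-based), wound
# counterclockwise seen from outside so divergence-theorem volumes come out
# positive.

new_mesh <- function(vertices, faces) {
  structure(list(vertices = vertices,
                 faces = matrix(as.integer(faces), ncol = 3)),
            class = "organ_mesh")
}

#' @export
print.organ_mesh <- function(x, ...) {
  cat(sprintf("<organ_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Validate a triangle mesh
#'
#' Checks face index bounds, finiteness of coordinates, and that no face has
#' area below the degeneracy tolerance.
#'
#' @param mesh An \code{organ_mesh}.
#' @param min_area Degeneracy tolerance in mm^2 (default 1e-12).
#' @return The mesh, invisibly.
#' @export
validate_mesh <- function(mesh, min_area = 1e-12) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(!is.finite(v))) stop("mesh has non-finite vertices", call. = FALSE)
  if (any(f < 1L) || any(f > nrow(v)))
    stop("mesh face index out of bounds", call. = FALSE)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))  # twice the triangle area
  if (any(area2 / 2 <= min_area))
    stop("mesh contains degenerate (zero-area) faces", call. = FALSE)
  invisible(mesh)
}

#' Signed volume and surface area of a mesh
#'
#' Volume by the divergence theorem (sum of signed tetrahedron volumes);
#' positive for a closed, outward-wound surface. Area is the sum of triangle
#' areas.
#'
#' @param mesh An \code{organ_mesh}.
#' @return Volume in mm^3 / area in mm^2.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Translate a mesh
#' @param mesh An \code{organ_mesh}.
#' @param offset Numeric length-3 translation in mm.
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}

merge_meshes <- function(meshes) {
  offs <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + offs
    offs <- offs + nrow(m$vertices)
  }
  new_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

# Lat-long triangulation of a full ellipsoid, semi-axes (a, b, c), centered
# at the origin. resolution = number of latitude bands; 2*resolution
# longitudes.
ellipsoid_mesh <- function(a, b, c, center = c(0, 0, 0), resolution = 24) {
  if (a <= 0 || b <= 0 || c <= 0)
    stop("ellipsoid semi-axes must be > 0", call. = FALSE)
  n_lat <- max(3L, as.integer(resolution))
  n_lon <- 2L * n_lat
  th <- pi * seq_len(n_lat - 1L) / n_lat       # polar angle, poles excluded
  ph <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  grid <- expand.grid(ph = ph, th = th)
  verts <- rbind(c(0, 0, c),                                    # north pole
                 cbind(a * sin(grid$th) * cos(grid$ph),
                       b * sin(grid$th) * sin(grid$ph),
                       c * cos(grid$th)),
                 c(0, 0, -c))                                   # south pole
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  south <- nrow(verts)
  faces <- list()
  # pole fans (outward winding for +z pole: pole, ring j, ring j+1 is CCW
  # from outside when traversed pole -> j+1 -> j on a right-handed frame)
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(n_lat - 2L)) for (j in seq_len(n_lon)) {
    v00 <- idx(i, j); v01 <- idx(i, j + 1L)
    v10 <- idx(i + 1L, j); v11 <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(v00, v10, v11)
    faces[[length(faces) + 1L]] <- c(v00, v11, v01)
  }
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(south, idx(n_lat - 1L, j + 1L),
                                     idx(n_lat - 1L, j))
  m <- new_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]  # enforce outward
  translate_mesh(m, center)
}

# Triangulated flat disc fan: ring of existing vertices closed around a new
# center vertex; `flip` controls winding.
fan_faces <- function(center_idx, ring_idx, flip = FALSE) {
  center_idx <- as.integer(center_idx)
  ring_idx <- as.integer(ring_idx)
  n <- length(ring_idx)
  f <- t(vapply(seq_len(n), function(j) {
    c(center_idx, ring_idx[j], ring_idx[(j %% n) + 1L])
  }, integer(3)))
  if (flip) f[, c(1, 3, 2)] else f
}

# Side wall between two rings of equal resolution.
wall_faces <- function(ring0, ring1) {
  ring0 <- as.integer(ring0)
  ring1 <- as.integer(ring1)
  n <- length(ring0)
  do.call(rbind, lapply(seq_len(n), function(j) {
    jn <- (j %% n) + 1L
    rbind(c(ring0[j], ring1[j], ring1[jn]),
          c(ring0[j], ring1[jn], ring0[jn]))
  }))
}

#' Seed potato mesh (semi-ellipsoid)
#'
#' The spent seed tuber at maturity is approximated as a half ellipsoid with
#' the flat face up: semi-axes LS/2 and WS/2 horizontally and dome height HS
#' pointing down into the soil (depth-positive z). The mesh is centered on
#' the flat face; the surface is closed by a triangulated cap.
#'
#' @param LS,WS Length and width of the seed potato, mm.
#' @param HS Height of the dome, mm.
#' @param resolution Latitude bands of the dome (>= 4 recommended; 32 keeps
#'   the volume within 2 percent of the closed form).
#' @param center Position of the flat-face center, world mm.
#' @return An \code{organ_mesh}.
#' @export
seed_potato_mesh <- function(LS, WS, HS, resolution = 24, center = c(0, 0, 0)) {
  if (LS <= 0 || WS <= 0 || HS <= 0)
    stop("seed potato dimensions must be > 0", call. = FALSE)
  a <- LS / 2; b <- WS / 2
  n_lat <- max(2L, as.integer(resolution))
  n_lon <- 4L * n_lat
  th <- pi / 2 * seq_len(n_lat) / n_lat  # 0 (pole) .. pi/2 (equator rim)
  ph <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  grid <- expand.grid(ph = ph, th = th)
  # dome points down: +z is depth
  verts <- rbind(c(0, 0, HS),
                 cbind(a * sin(grid$th) * cos(grid$ph),
                       b * sin(grid$th) * sin(grid$ph),
                       HS * cos(grid$th)))
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  if (n_lat > 1L) for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_lon)) {
    v00 <- idx(i, j); v01 <- idx(i, j + 1L)
    v10 <- idx(i + 1L, j); v11 <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(v00, v10, v11)
    faces[[length(faces) + 1L]] <- c(v00, v11, v01)
  }
  # flat cap at z = 0 (the upward face)
  verts <- rbind(verts, c(0, 0, 0))
  cap_center <- nrow(verts)
  rim <- vapply(seq_len(n_lon), function(j) idx(n_lat, j), integer(1))
  faces[[length(faces) + 1L]] <- fan_faces(cap_center, rim)
  m <- new_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  translate_mesh(m, center)
}

#' Underground stem mesh (stitched frusta)
#'
#' The main stem is a stack of \code{n_segments} cone frusta whose centers
#' are not collinear: each interior ring center is offset laterally by a
#' uniform jitter in \code{[-jitter, +jitter]^2}, imitating the rough,
#' irregular surface of a real underground stem. The cross-section radius
#' tapers linearly from \code{RD} at the base to \code{RD * (1 - rD)} at the
#' top. Built in local coordinates with the base ring center at the origin
#' and the stem along -z (upward, depth-positive convention); both ends are
#' capped.
#'
#' @param HD Stem height, mm (> 0).
#' @param RD Initial (bottom) radius, mm (> 0).
#' @param rD Radius change rate, dimensionless in \[0, 1): top radius is
#'   \code{RD * (1 - rD)}.
#' @param n_segments Number of stacked frusta (>= 1).
#' @param jitter Lateral jitter half-range in mm (0 disables; default 5
#'   percent of RD). Draws come from the session RNG.
#' @param ring_resolution Vertices per cross-section ring.
#' @param base World position of the base ring center.
#' @return An \code{organ_mesh}.
#' @export
underground_stem_mesh <- function(HD, RD, rD = 0.2, n_segments = 8,
                                  jitter = 0.05 * RD, ring_resolution = 16,
                                  base = c(0, 0, 0)) {
  if (HD <= 0 || RD <= 0) stop("HD and RD must be > 0", call. = FALSE)
  if (rD < 0 || rD >= 1)
    stop("radius change rate rD must be in [0, 1); rD >= 1 would give a ",
         "nonpositive top radius", call. = FALSE)
  if (n_segments < 1) stop("n_segments must be >= 1", call. = FALSE)
  n_seg <- as.integer(n_segments)
  nr <- max(3L, as.integer(ring_resolution))
  ph <- 2 * pi * (seq_len(nr) - 1L) / nr
  verts <- NULL
  rings <- list()
  for (k in 0:n_seg) {
    t <- k / n_seg
    r_k <- RD * (1 - rD * t)           # global linear taper
    off <- if (jitter > 0 && k > 0 && k < n_seg)
      stats::runif(2, -jitter, jitter) else c(0, 0)
    ring <- cbind(off[1] + r_k * cos(ph), off[2] + r_k * sin(ph), -HD * t)
    rings[[k + 1L]] <- nrow(verts %||% matrix(nrow = 0, ncol = 3)) +
      seq_len(nr)
    verts <- rbind(verts, ring)
  }
  faces <- list()
  for (k in seq_len(n_seg))
    faces[[length(faces) + 1L]] <- wall_faces(rings[[k]], rings[[k + 1L]])
  # caps
  # base ring is CCW viewed from +z; the base cap faces +z (downward,
  # outward), the top cap faces -z
  verts <- rbind(verts, c(0, 0, 0))
  bottom_c <- nrow(verts)
  faces[[length(faces) + 1L]] <- fan_faces(bottom_c, rings[[1L]])
  top_off <- colMeans(verts[rings[[n_seg + 1L]], , drop = FALSE])
  verts <- rbind(verts, top_off)
  faces[[length(faces) + 1L]] <- fan_faces(nrow(verts), rings[[n_seg + 1L]],
                                           flip = TRUE)
  m <- new_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  translate_mesh(m, base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a tuber shape
#'
#' Tubers are spherical, ellipsoidal or elongated depending on their aspect
#' ratio \code{rho = L / W} (dimensions sorted \code{L >= W >= H}):
#' \code{rho < 1.15} spherical, \code{1.15 <= rho < 1.8} ellipsoid,
#' \code{rho >= 1.8} elongated. The cutoffs separate the three archetypes
#' and are configurable.
#'
#' @param L,W,H Tuber dimensions in mm, sorted \code{L >= W >= H > 0}.
#' @param thresholds Length-2 numeric, the spherical/ellipsoid and
#'   ellipsoid/elongated aspect-ratio cutoffs.
#' @return One of \code{"spherical"}, \code{"ellipsoid"}, \code{"elongated"}.
#' @export
classify_tuber <- function(L, W, H, thresholds = c(1.15, 1.8)) {
  if (L <= 0 || W <= 0 || H <= 0)
    stop("tuber dimensions must be > 0", call. = FALSE)
  if (L < W || W < H)
    stop("tuber dimensions must be sorted L >= W >= H", call. = FALSE)
  rho <- L / W
  if (rho < thresholds[1]) "spherical"
  else if (rho < thresholds[2]) "ellipsoid"
  else "elongated"
}

#' Tuber mesh (ellipsoid)
#'
#' A tuber is an ellipsoid with semi-axes LK/2, WK/2, HK/2 centered at PK.
#' By default the long axis lies horizontal (along x), the natural lie of a
#' stolon-end tuber.
#'
#' @param PK Center, world mm.
#' @param LK,WK,HK Tuber length, width, height in mm.
#' @param resolution Latitude bands (32 keeps volume within 2 percent of
#'   \code{(pi/6) LK WK HK}).
#' @return An \code{organ_mesh}.
#' @export
tuber_mesh <- function(PK = c(0, 0, 0), LK, WK, HK, resolution = 24) {
  if (LK <= 0 || WK <= 0 || HK <= 0)
    stop("tuber dimensions must be > 0", call. = FALSE)
  ellipsoid_mesh(LK / 2, WK / 2, HK / 2, center = PK, resolution = resolution)
}

# Parallel-transport frames along a polyline: returns list of (normal,
# binormal) pairs per vertex, rotated minimally between segments to avoid
# twisting at curvature.
transport_frames <- function(points) {
  n <- nrow(points)
  tang <- diff(points)
  tang <- tang / sqrt(rowSums(tang^2))
  # vertex tangents: average of adjacent segment tangents
  vt <- rbind(tang[1, , drop = FALSE],
              if (n > 2) (tang[-nrow(tang), , drop = FALSE] +
                          tang[-1, , drop = FALSE]) / 2,
              tang[nrow(tang), , drop = FALSE])
  vt <- vt / sqrt(rowSums(vt^2))
  frames <- vector("list", n)
  t0 <- vt[1, ]
  ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  nrm <- ref - sum(ref * t0) * t0
  nrm <- nrm / sqrt(sum(nrm^2))
  bin <- c(t0[2] * nrm[3] - t0[3] * nrm[2],
           t0[3] * nrm[1] - t0[1] * nrm[3],
           t0[1] * nrm[2] - t0[2] * nrm[1])
  frames[[1]] <- list(normal = nrm, binormal = bin)
  for (i in 2:n) {
    t_prev <- vt[i - 1, ]; t_cur <- vt[i, ]
    axis <- c(t_prev[2] * t_cur[3] - t_prev[3] * t_cur[2],
              t_prev[3] * t_cur[1] - t_prev[1] * t_cur[3],
              t_prev[1] * t_cur[2] - t_prev[2] * t_cur[1])
    s <- sqrt(sum(axis^2))
    cth <- sum(t_prev * t_cur)
    if (s < 1e-12) {            # parallel tangents: carry the frame over
      frames[[i]] <- frames[[i - 1]]
    } else {
      axis <- axis / s
      rot <- function(v) {      # Rodrigues rotation about `axis` by angle
        v * cth + c(axis[2] * v[3] - axis[3] * v[2],
                    axis[3] * v[1] - axis[1] * v[3],
                    axis[1] * v[2] - axis[2] * v[1]) * s +
          axis * sum(axis * v) * (1 - cth)
      }
      frames[[i]] <- list(normal = rot(frames[[i - 1]]$normal),
                          binormal = rot(frames[[i - 1]]$binormal))
    }
  }
  frames
}

#' Root tube mesh (tapered sweep along an axis)
#'
#' Sweeps a circular cross-section along the axis polyline with
#' parallel-transport frames (no twisting at curvature). The radius
#' interpolates linearly from \code{r0} at the rooting point to
#' \code{r_tip} at the tip. Ends are capped; a zero tip radius produces a
#' cone tip (single apex vertex, no degenerate faces).
#'
#' @param axis A \code{root_axis} with at least 2 points and
#'   \code{r0 >= r_tip >= 0}, \code{r0 > 0}.
#' @param ring_resolution Vertices per cross-section ring (default 12).
#' @param caps Close the ends (default TRUE).
#' @return An \code{organ_mesh}.
#' @export
root_tube_mesh <- function(axis, ring_resolution = 12, caps = TRUE) {
  if (!inherits(axis, "root_axis")) stop("not a root_axis", call. = FALSE)
  pts <- axis$points
  if (nrow(pts) < 2) stop("axis must have at least 2 points", call. = FALSE)
  r0 <- axis$r0; r_tip <- axis$r_tip
  if (r0 <= 0) stop("root initial radius must be > 0 to mesh", call. = FALSE)
  if (r0 < r_tip || r_tip < 0)
    stop("radii must satisfy r0 >= r_tip >= 0", call. = FALSE)
  n <- nrow(pts)
  nr <- max(3L, as.integer(ring_resolution))
  ph <- 2 * pi * (seq_len(nr) - 1L) / nr
  # linear taper in arc length (equal-length segments: linear in index)
  radii <- r0 + (r_tip - r0) * (seq_len(n) - 1L) / (n - 1L)
  frames <- transport_frames(pts)
  cone_tip <- r_tip == 0
  n_rings <- if (cone_tip) n - 1L else n
  verts <- matrix(0, nrow = n_rings * nr, ncol = 3)
  rings <- vector("list", n_rings)
  for (i in seq_len(n_rings)) {
    fr <- frames[[i]]
    ring <- pts[rep(i, nr), ] +
      radii[i] * (cos(ph) %o% fr$normal + sin(ph) %o% fr$binormal)
    rows <- (i - 1L) * nr + seq_len(nr)
    verts[rows, ] <- ring
    rings[[i]] <- rows
  }
  faces <- list()
  for (i in seq_len(n_rings - 1L))
    faces[[length(faces) + 1L]] <- wall_faces(rings[[i]], rings[[i + 1L]])
  if (cone_tip) {
    verts <- rbind(verts, pts[n, ])
    faces[[length(faces) + 1L]] <- fan_faces(nrow(verts), rings[[n_rings]],
                                             flip = TRUE)
  } else if (caps) {
    verts <- rbind(verts, pts[n, ])
    faces[[length(faces) + 1L]] <- fan_faces(nrow(verts), rings[[n_rings]],
                                             flip = TRUE)
  }
  if (caps) {
    verts <- rbind(verts, pts[1, ])
    faces[[length(faces) + 1L]] <- fan_faces(nrow(verts), rings[[1L]])
  }
  m <- new_mesh(verts, do.call(rbind, faces))
  if (caps && mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Meshes for every organ of a plant model
#'
#' Produces one named mesh per organ node, placed in world coordinates:
#' the seed potato semi-ellipsoid at its burial depth, the stitched-frustum
#' underground stem, tapered tubes for every root, and ellipsoidal tubers at
#' the creeping-stem termini.
#'
#' @param plant A \code{plant_model}.
#' @param resolution Ellipsoid latitude bands / ring resolutions.
#' @param stem_jitter Lateral jitter of the stem frusta, mm (default 5
#'   percent of its bottom radius).
#' @return Named list of \code{organ_mesh} (names like
#'   \code{"seminal_root_3"}).
#' @export
plant_meshes <- function(plant, resolution = 16, stem_jitter = NULL) {
  out <- list()
  for (nd in plant$nodes) {
    nm <- paste0(nd$organ_class, "_", nd$id)
    m <- switch(nd$organ_class,
      seed_potato = seed_potato_mesh(nd$dims[["L"]], nd$dims[["W"]],
                                     nd$dims[["H"]], resolution = resolution,
                                     center = nd$center),
      underground_stem = {
        jit <- stem_jitter %||% (0.05 * nd$params$bottom_radius_mm)
        rD <- 1 - nd$params$top_radius_mm / nd$params$bottom_radius_mm
        underground_stem_mesh(HD = nd$params$height_mm,
                              RD = nd$params$bottom_radius_mm,
                              rD = max(0, min(rD, 0.95)),
                              n_segments = 8, jitter = jit,
                              ring_resolution = resolution,
                              base = nd$axis$points[1, ])
      },
      tuber = tuber_mesh(nd$center, nd$dims[["L"]], nd$dims[["W"]],
                         nd$dims[["H"]], resolution = resolution),
      {  # root classes
        ax <- nd$axis
        if (ax$r0 <= 0) ax$r0 <- 0.5  # guard a degenerate radius draw
        root_tube_mesh(ax, ring_resolution = max(8L, resolution %/% 2))
      })
    out[[nm]] <- m
  }
  out
}
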