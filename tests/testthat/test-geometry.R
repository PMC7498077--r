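test_that("mesh volumes converge to the closed forms", {
  r <- 20
  hemi <- seed_potato_mesh(2 * r, 2 * r, r, resolution = 32)
  expect_equal(mesh_volume(hemi), (2 / 3) * pi * r^3, tolerance = 0.02)
  sphere <- tuber_mesh(c(0, 0, 0), 2 * r, 2 * r, 2 * r, resolution = 32)
  expect_equal(mesh_volume(sphere), (4 / 3) * pi * r^3, tolerance = 0.02)
  fr <- underground_stem_mesh(100, 10, rD = 0.5, n_segments = 1, jitter = 0,
                              ring_resolution = 32)
  expect_equal(mesh_volume(fr), pi * 100 / 3 * (100 + 50 + 25),
               tolerance = 0.02)
  # doubling the resolution reduces the volume error (order check)
  err <- vapply(c(16, 32), function(res) {
    abs(mesh_volume(tuber_mesh(c(0, 0, 0), 40, 40, 40, resolution = res)) -
          (4 / 3) * pi * 20^3) / ((4 / 3) * pi * 20^3)
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("minimal and degenerate geometry inputs behave", {
  m <- seed_potato_mesh(10, 8, 4, resolution = 4)
  expect_no_error(validate_mesh(m))
  expect_gt(mesh_volume(m), 0)
  expect_error(seed_potato_mesh(0, 8, 4), "> 0")
  expect_error(tuber_mesh(c(0, 0, 0), -1, 8, 4), "> 0")
  expect_error(underground_stem_mesh(100, 10, rD = 1), "rD")
  expect_error(underground_stem_mesh(-1, 10), "> 0")
  # a cylinder: rD = 0 keeps all ring radii equal
  cyl <- underground_stem_mesh(50, 5, rD = 0, n_segments = 4, jitter = 0,
                               ring_resolution = 16)
  rad <- sqrt(rowSums(cyl$vertices[seq_len(5 * 16), 1:2]^2))
  expect_equal(rad, rep(5, 80), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stem jitter is reproducible and offsets interior rings", {
  set.seed(8)
  a <- underground_stem_mesh(100, 10, 0.3, n_segments = 8, jitter = 1)
  set.seed(8)
  b <- underground_stem_mesh(100, 10, 0.3, n_segments = 8, jitter = 1)
  expect_identical(a$vertices, b$vertices)
  centers <- t(vapply(0:8, function(k)
    colMeans(a$vertices[k * 16 + seq_len(16), ]), numeric(3)))
  expect_true(any(abs(centers[2:8, 1:2]) > 1e-6))  # not collinear
  expect_no_error(validate_mesh(a))
})

test_that("tubers are classified by aspect ratio", {
  expect_identical(classify_tuber(50, 50, 50), "spherical")
  expect_identical(classify_tuber(60, 50, 45), "ellipsoid")   # rho = 1.2
  expect_identical(classify_tuber(90, 50, 45), "elongated")   # rho = 1.8
  expect_identical(classify_tuber(57, 50, 45), "spherical")   # rho = 1.14
  expect_error(classify_tuber(50, 60, 45), "sorted")
  expect_error(classify_tuber(50, 0, 0), "> 0")
})

test_that("tuber meshes are translation-equivariant", {
  m <- tuber_mesh(c(10, 0, 0), 40, 30, 20, resolution = 16)
  expect_equal(colMeans(m$vertices), c(10, 0, 0), tolerance = 1e-9)
  expect_equal(mesh_volume(m), pi / 6 * 40 * 30 * 20, tolerance = 0.02)
})

test_that("root tubes sweep with the right area, caps and vertex counts", {
  ax <- generate_axis(axial_angle = 90, total_length = 100, l_unit = 1,
                      r0 = 3, r_tip = 3)
  side <- root_tube_mesh(ax, ring_resolution = 64, caps = FALSE)
  expect_equal(mesh_area(side), 2 * pi * 3 * 100, tolerance = 0.02)
  capped <- root_tube_mesh(ax, ring_resolution = 12)
  expect_identical(nrow(capped$vertices), 101L * 12L + 2L)
  expect_no_error(validate_mesh(capped))
  expect_gt(mesh_volume(capped), 0)
  # a zero tip radius gives a cone apex without degenerate faces
  ax2 <- generate_axis(axial_angle = 135, total_length = 60, l_unit = 1,
                       total_deflection = 40, r0 = 2, r_tip = 0)
  cone <- root_tube_mesh(ax2, ring_resolution = 12)
  expect_no_error(validate_mesh(cone))
  expect_error(root_tube_mesh(structure(list(points = matrix(0, 1, 3),
                                             r0 = 1, r_tip = 0),
                                        class = "root_axis")),
               "at least 2")
})

test_that("randomized organ meshes pass validity checks", {
  set.seed(21)
  for (i in 1:100) {
    dims <- sort(runif(3, 5, 120), decreasing = TRUE)
    expect_no_error(validate_mesh(
      tuber_mesh(runif(3, -50, 50), dims[1], dims[2], dims[3],
                 resolution = sample(4:20, 1))))
    expect_no_error(validate_mesh(
      underground_stem_mesh(runif(1, 20, 150), runif(1, 2, 12),
                            rD = runif(1, 0, 0.9),
                            n_segments = sample(1:10, 1),
                            jitter = runif(1, 0, 1))))
    r0 <- runif(1, 0.5, 4)
    ax <- generate_axis(axial_angle = runif(1, 45, 180),
                        radial_angle = runif(1, 0, 360),
                        total_length = runif(1, 10, 200), l_unit = 2,
                        total_deflection = runif(1, -60, 60),
                        r0 = r0, r_tip = runif(1, 0, r0))
    expect_no_error(validate_mesh(root_tube_mesh(ax)))
  }
})

test_that("whole-plant scenes export to OBJ and PLY and read back", {
  plant <- build_plant(make_degenerate_db(), seed = 3)
  meshes <- plant_meshes(plant, resolution = 8)
  expect_identical(length(meshes), length(plant$nodes))
  for (m in meshes) expect_no_error(validate_mesh(m))
  obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(meshes, obj)
  back <- read_obj(obj)
  expect_identical(names(back), names(meshes))
  for (nm in names(meshes)) {
    expect_equal(back[[nm]]$vertices, meshes[[nm]]$vertices,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_identical(back[[nm]]$faces, meshes[[nm]]$faces)
  }
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(meshes, ply)
  head <- readLines(ply, n = 9)
  expect_identical(head[1], "ply")
  total_v <- sum(vapply(meshes, function(m) nrow(m$vertices), numeric(1)))
  expect_identical(head[3], paste("element vertex", total_v))
})
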