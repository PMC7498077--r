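test_that("degenerate counts produce the expected eight-node plant", {
  # 2 + N_seminal + N_creeping_root + N_creeping_stem + N_tuber
  db <- make_degenerate_db(n_sem = 2, n_cr = 2, n_cs = 1, n_k = 1)
  plant <- build_plant(db, seed = 1)
  counts <- plant_counts(plant)
  expect_identical(length(plant$nodes), 8L)
  expect_equal(unname(counts[c("seed_potato", "underground_stem",
                               "seminal_root", "creeping_root",
                               "creeping_stem", "tuber")]),
               c(1, 1, 2, 2, 1, 1), ignore_attr = TRUE)
  # structural placement
  for (nd in plant$nodes) {
    if (nd$organ_class == "underground_stem")
      expect_identical(nd$parent, 1L)
    if (nd$organ_class == "seminal_root")
      expect_identical(nd$parent, 1L)
    if (nd$organ_class %in% c("creeping_root", "creeping_stem"))
      expect_identical(plant$nodes[[nd$parent]]$organ_class,
                       "underground_stem")
    if (nd$organ_class == "tuber") {
      par <- plant$nodes[[nd$parent]]
      expect_identical(par$organ_class, "creeping_stem")
      # tuber sits at the terminal node of its creeping stem
      expect_equal(nd$center, par$axis$points[nrow(par$axis$points), ],
                   tolerance = 1e-9)
    }
  }
  # levels: seed 1; stem + seminal 2; creeping 3; tuber 4
  lv <- vapply(plant$nodes, function(n) n$level, integer(1))
  cls <- vapply(plant$nodes, function(n) n$organ_class, character(1))
  expect_true(all(lv[cls == "seed_potato"] == 1))
  expect_true(all(lv[cls %in% c("underground_stem", "seminal_root")] == 2))
  expect_true(all(lv[cls %in% c("creeping_root", "creeping_stem")] == 3))
  expect_true(all(lv[cls == "tuber"] == 4))
})

test_that("zero counts leave just the seed potato and underground stem", {
  db <- make_degenerate_db(n_sem = 0, n_cr = 0, n_cs = 0, n_k = 0)
  plant <- build_plant(db, seed = 1)
  expect_identical(length(plant$nodes), 2L)
  expect_identical(vapply(plant$nodes, function(n) n$organ_class,
                          character(1)),
                   c("seed_potato", "underground_stem"))
})

test_that("excess tubers are dropped with a warning", {
  db <- make_degenerate_db(n_cs = 1, n_k = 3)
  expect_warning(plant <- build_plant(db, seed = 1), "dropping")
  expect_equal(sum(vapply(plant$nodes, function(n)
    n$organ_class == "tuber", logical(1))), 1)
})

test_that("builds are deterministic under a fixed seed", {
  cfg <- default_truth(1)
  p1 <- build_plant(cfg, seed = 99)
  p2 <- build_plant(cfg, seed = 99)
  expect_identical(length(p1$nodes), length(p2$nodes))
  for (i in seq_along(p1$nodes))
    expect_identical(p1$nodes[[i]]$axis$points, p2$nodes[[i]]$axis$points)
})

test_that("traversals agree with an adjacency-list oracle on random plants", {
  cfg <- default_truth(1)
  for (s in 1:5) {
    plant <- suppressWarnings(build_plant(cfg, seed = s))
    n <- length(plant$nodes)
    # oracle: explicit children lists from parent ids, in id order (the
    # order children were attached)
    children <- lapply(seq_len(n), function(i) integer(0))
    for (nd in plant$nodes[-1])
      children[[nd$parent]] <- c(children[[nd$parent]], nd$id)
    ref_pre <- integer(0)
    dfs <- function(id) {
      ref_pre <<- c(ref_pre, id)
      for (ch in children[[id]]) dfs(ch)
    }
    dfs(1L)
    ref_bfs <- integer(0); queue <- 1L
    while (length(queue)) {
      id <- queue[1]; queue <- queue[-1]
      ref_bfs <- c(ref_bfs, id)
      queue <- c(queue, children[[id]])
    }
    pre <- vapply(traverse(plant, "preorder"), function(x) x$id, integer(1))
    bfs <- vapply(traverse(plant, "levelorder"), function(x) x$id,
                  integer(1))
    expect_identical(pre, ref_pre)
    expect_identical(bfs, ref_bfs)
    expect_identical(length(pre), n)  # every node exactly once
    # level order is grouped by nondecreasing level
    lv <- vapply(traverse(plant, "levelorder"), function(x) x$level,
                 integer(1))
    expect_true(all(diff(lv) >= 0))
    # node-count identity
    cnt <- plant_counts(plant)
    expect_equal(n, 2 + sum(cnt[c("seminal_root", "creeping_root",
                                  "creeping_stem", "tuber")]),
                 ignore_attr = TRUE)
    # creeping organs root within the stem height
    h_j <- plant$nodes[[2]]$params$height_mm
    for (nd in plant$nodes)
      if (nd$organ_class %in% c("creeping_root", "creeping_stem")) {
        expect_gte(nd$attach_h, 0)
        expect_lte(nd$attach_h, h_j)
      }
  }
  # preorder visits the seed potato first and the underground stem second
  plant <- build_plant(make_degenerate_db(), seed = 1)
  pre <- traverse(plant, "preorder")
  expect_identical(pre[[1]]$organ_class, "seed_potato")
  expect_identical(pre[[2]]$organ_class, "underground_stem")
})

test_that("a cycle in the links is detected as a structural error", {
  plant <- build_plant(make_degenerate_db(), seed = 1)
  plant$nodes[[3]]$next_sibling <- 2L  # stem <-> sibling loop
  expect_error(traverse(plant, "preorder"), "cycle")
})

test_that("plant models round-trip through JSON", {
  plant <- suppressWarnings(build_plant(default_truth(1), seed = 17))
  path <- withr::local_tempfile(fileext = ".json")
  save_plant(plant, path)
  back <- load_plant(path)
  expect_identical(length(back$nodes), length(plant$nodes))
  expect_identical(back$variety, plant$variety)
  expect_identical(back$seed, 17L)
  for (i in seq_along(plant$nodes)) {
    a <- plant$nodes[[i]]; b <- back$nodes[[i]]
    expect_identical(b$organ_class, a$organ_class)
    expect_identical(b$first_child, a$first_child)
    expect_identical(b$next_sibling, a$next_sibling)
    if (!is.null(a$axis))
      expect_equal(b$axis$points, a$axis$points, tolerance = 1e-12,
                   ignore_attr = TRUE)
    if (!is.null(a$dims))
      expect_equal(unname(b$dims), unname(a$dims), tolerance = 1e-12)
  }
  pre_a <- vapply(traverse(plant), function(x) x$id, integer(1))
  pre_b <- vapply(traverse(back), function(x) x$id, integer(1))
  expect_identical(pre_a, pre_b)
})
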