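test_that("rrmse matches a naive loop oracle on random vectors", {
  naive_rrmse <- function(obs, sim) {
    n <- length(obs)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (obs[i] - sim[i])^2
    100 * sqrt(acc / n) / (sum(obs) / n)
  }
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:80, 1)
    obs <- runif(n, 10, 200)
    sim <- obs + rnorm(n, 0, 15)
    expect_equal(rrmse(obs, sim), naive_rrmse(obs, sim),
                 tolerance = 1e-12)
  }
})

test_that("rrmse reproduces hand-computed values and identities", {
  expect_equal(rrmse(c(100), c(90)), 10)
  obs <- c(94, 98, 133, 80)
  sim <- c(96.87, 90.52, 127.64, 86.38)
  expect_equal(rrmse(obs, sim),
               100 * sqrt(mean((obs - sim)^2)) / mean(obs))
  expect_equal(rrmse(obs, sim), 5.71, tolerance = 0.001)
  expect_equal(rrmse(obs, obs), 0)
  # scale invariance
  for (c in c(0.001, 1, 7.3, 1e6))
    expect_equal(rrmse(c * obs, c * sim), rrmse(obs, sim),
                 tolerance = 1e-12)
  # degenerate simulation at the observed mean: population SD over mean
  simc <- rep(mean(obs), 4)
  sd_pop <- sqrt(mean((obs - mean(obs))^2))
  expect_equal(rrmse(obs, simc), 100 * sd_pop / mean(obs),
               tolerance = 1e-12)
  expect_error(rrmse(c(-5, 5), c(0, 0)), "mean")
  expect_error(rrmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rrmse(c(1, 2), c(1)), "equal length")
})

test_that("the four-level accuracy scale classifies with worse-class bounds", {
  expect_identical(classify_rrmse(6.81), "extremely_significant")
  expect_identical(classify_rrmse(15.32), "significant")
  expect_identical(classify_rrmse(0), "extremely_significant")
  expect_identical(classify_rrmse(10), "significant")
  expect_identical(classify_rrmse(20), "general")
  expect_identical(classify_rrmse(25), "general")
  expect_identical(classify_rrmse(30), "poor")
  expect_identical(classify_rrmse(55), "poor")
  expect_error(classify_rrmse(-1), "nonnegative")
})

test_that("rank pairing sorts and quantile-matches unequal samples", {
  rp <- tuberoot:::rank_pair(c(3, 1, 2), c(30, 10, 20))
  expect_equal(rp$obs, c(1, 2, 3))
  expect_equal(rp$sim, c(10, 20, 30))
  rp2 <- tuberoot:::rank_pair(c(1, 2), seq(0, 100, by = 1))
  expect_identical(length(rp2$sim), 2L)
  expect_lt(rp2$sim[1], rp2$sim[2])
})

test_that("self-validation of a database is consistent", {
  cfg <- default_truth(1)
  tab <- generate_measurements(cfg, n_plants = 50, seed = 404)
  rep <- validate_model(cfg, tab, n_plants = 50, seed = 405)
  expect_setequal(names(rep$classes), ROOT_CLASSES)
  for (cls in ROOT_CLASSES) {
    expect_lt(rep$classes[[cls]]$rrmse_percent, 30)
    expect_gt(rep$classes[[cls]]$n, 0)
    expect_identical(length(rep$classes[[cls]]$obs),
                     length(rep$classes[[cls]]$sim))
  }
  # report writers round-trip
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  summary_df <- write_report(rep, json_path = jp, csv_path = cp)
  expect_identical(nrow(summary_df), 3L)
  csv <- utils::read.csv(cp)
  expect_equal(csv$rrmse_percent,
               vapply(rep$classes, function(x) x$rrmse_percent, numeric(1)),
               tolerance = 1e-6, ignore_attr = TRUE)
  js <- jsonlite::read_json(jp)
  expect_identical(js$variety, "Zaodabai")
})

test_that("validation rejects empty runs and skips absent classes", {
  cfg <- default_truth(1)
  tab <- generate_measurements(cfg, n_plants = 10, seed = 3)
  expect_error(validate_model(cfg, tab, n_plants = 0), "n_plants")
  no_sem <- tab[tab$organ_class != "seminal_root", ]
  expect_warning(rep <- validate_model(cfg, no_sem, n_plants = 3, seed = 1),
                 "seminal_root")
  expect_false("seminal_root" %in% names(rep$classes))
})
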