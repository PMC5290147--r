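test_that("medians per contact time use the midpoint rule", {
  ds <- as.data.frame(rbind(
    data.frame(cell_id = paste0("c", 1:3), condition = "x", contact_time_s = 5,
               adhesion_force_N = c(1, 2, 3) * 1e-9),
    data.frame(cell_id = paste0("c", 1:4), condition = "y", contact_time_s = 5,
               adhesion_force_N = c(1, 2, 3, 4) * 1e-9)))
  expect_equal(unname(median_forces(ds, "x")), 2e-9)
  expect_equal(unname(median_forces(ds, "y")), 2.5e-9)
  expect_error(median_forces(ds, "z"), "unknown condition")
  # simulator condition with small noise: medians monotone in t
  cfg <- simulation_config(conditions = list(tiny_condition("m", 2e-9, 40,
                                                            cell_sd_rel = 0.1,
                                                            meas_sd = 2e-11)),
                           n_cells = 10, seed = 3)
  med <- median_forces(simulate_adhesion_dataset(cfg), "m")
  expect_true(all(diff(med) > 0))
})

test_that("Mann-Whitney p-values match brute-force enumeration", {
  # canonical fully-separated case: U = 0, exact p = 2/20
  mw <- mann_whitney_medians(c(1, 2, 3), c(10, 11, 12))
  expect_identical(unname(mw$U), 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$p_value, enumerate_mw_p(c(1, 2, 3), c(10, 11, 12)))
  # random tie-free small samples against the enumeration oracle
  set.seed(5)
  for (i in 1:20) {
    a <- round(runif(sample(2:6, 1), 0, 100), 6)
    b <- round(runif(sample(2:6, 1), 0, 100), 6)
    expect_equal(mann_whitney_medians(a, b)$p_value, enumerate_mw_p(a, b))
  }
  # identical samples: p = 1 under the tie-corrected approximation
  expect_gte(mann_whitney_medians(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_error(mann_whitney_medians(numeric(), 1), "empty")
})

test_that("Mann-Whitney type-I error is near nominal on generator draws", {
  set.seed(77)
  cond <- tiny_condition(meas_sd = 2e-10)
  rej <- mean(replicate(2000, {
    a <- sample_cell_adhesion(cond, 50, 1, n = 10)
    b <- sample_cell_adhesion(cond, 50, 1, n = 10)
    mann_whitney_medians(a, b)$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("discrete and average slopes match hand arithmetic", {
  expect_equal(discrete_slope(1e-9, 2.5e-9, 5, 20), 1e-10)
  expect_identical(discrete_slope(1e-9, 1e-9, 5, 20), 0)
  expect_equal(discrete_slope(2.5e-9, 1e-9, 20, 5),
               -discrete_slope(1e-9, 2.5e-9, 5, 20))
  expect_error(discrete_slope(1, 2, 5, 5), "differ")

  med <- c("5" = 1e-9, "20" = 2.5e-9, "50" = 4e-9, "120" = 6e-9)
  expect_equal(average_slope(med), mean(c(0.1, 0.05, 2 / 70)) * 1e-9)
  expect_identical(average_slope(c("5" = 1e-9, "120" = 1e-9)), 0)
  # exactly linear force series: average slope equals the ratio on any grid
  tt <- c(3, 11, 47, 60, 118)
  expect_equal(average_slope(setNames(4e-12 * tt, tt)), 4e-12)
  expect_error(average_slope(c("5" = 1e-9)), "undefined")
})

test_that("cell bootstrap keeps whole force-time profiles", {
  cfg <- simulation_config(conditions = list(tiny_condition("x", 2e-9, 40)),
                           n_cells = 10, seed = 2)
  ds <- simulate_adhesion_dataset(cfg)
  bs <- bootstrap_resample(ds, "x", size = 10, seed = 1)
  expect_identical(length(unique(bs$cell_id)), 10L)
  expect_true(all(sub("^b\\d+\\.", "", bs$cell_id) %in% ds$cell_id))
  # each drawn cell keeps its complete, paired time profile
  for (cid in unique(bs$cell_id)) {
    orig <- sub("^b\\d+\\.", "", cid)
    expect_identical(bs$adhesion_force_N[bs$cell_id == cid],
                     ds$adhesion_force_N[ds$cell_id == orig])
  }
  expect_error(bootstrap_resample(ds, "x", 11), "between 1")
  # multinomial oracle: over many resamples every cell appears ~ 1/n per draw
  set.seed(9)
  counts <- table(unlist(lapply(1:1000, function(i)
    sub("^b\\d+\\.", "", unique(bootstrap_resample(ds, "x", 10)$cell_id)))))
  expected <- 1000 * 10 / 10
  s3 <- 3 * sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < s3))
})

test_that("slope test: self-comparison is null, determinism holds", {
  cfg <- simulation_config(conditions = list(tiny_condition("x", 2e-9, 40)),
                           n_cells = 10, seed = 4)
  ds <- simulate_adhesion_dataset(cfg)
  st <- slope_difference_test(ds, ds, B = 100, seed = 6)
  expect_gte(st$p_value, 0.99)
  st2 <- slope_difference_test(ds, ds, B = 100, seed = 6)
  expect_identical(serialize(st, NULL), serialize(st2, NULL))
  # p-values invariant to record order
  perm <- ds[sample(nrow(ds)), ]
  class(perm) <- class(ds)
  st3 <- slope_difference_test(perm, perm, B = 100, seed = 6)
  expect_equal(st3$p_value, st$p_value)
  expect_error(slope_difference_test(ds, ds, B = 5), ">= 10")
})

test_that("epsilon matches hand arithmetic and is A/B symmetric", {
  expect_identical(interaction_epsilon(2, 0.2, 1.5, 1.8), 2 + 0.2 - 1.5 - 1.8)
  expect_equal(interaction_epsilon(2e-9, 2e-10, 1.5e-9, 1.8e-9), -1.1e-9)
  expect_identical(interaction_epsilon(2, 0.2, 1.5, 1.8),
                   interaction_epsilon(2, 0.2, 1.8, 1.5))
  # additive null: zero (to rounding)
  expect_equal(interaction_epsilon(1.5 + 1.8 - 0.2, 0.2, 1.5, 1.8), 0)
})

test_that("interaction test guards inputs and is deterministic", {
  ds <- simulate_adhesion_dataset(additive_config(seed = 12))
  cmap <- c(ab = "AB", a = "A", b = "B", zero = "ctrl")
  it <- interaction_test(ds, cmap, B = 100, seed = 3)
  expect_identical(dim(it$boot_epsilon), c(100L, 4L))
  expect_true(all(it$p_time >= 0 & it$p_time <= 1))
  expect_true(all(it$sign %in% c("positive", "negative", "none")))
  it2 <- interaction_test(ds, cmap, B = 100, seed = 3)
  expect_identical(serialize(it, NULL), serialize(it2, NULL))
  expect_error(interaction_test(ds, c(ab = "AB", a = "A", b = "B",
                                      zero = "nope"), B = 100),
               "missing condition.*nope")
  expect_error(interaction_test(ds, cmap, B = 1), ">= 10")
})

test_that("under the additive generative null, observed epsilon centres at 0", {
  eps <- vapply(1:500, function(i) {
    ds <- simulate_adhesion_dataset(additive_config(seed = 5000 + i))
    m <- vapply(c("AB", "ctrl", "A", "B"),
                function(cc) median_forces(ds, cc)[["120"]], 0)
    m[1] + m[2] - m[3] - m[4]
  }, 0)
  expect_lt(abs(mean(eps)), 3 * sd(eps) / sqrt(length(eps)))
})

test_that("Pratt signed-rank agrees with the classical test when zero-free", {
  set.seed(13)
  x <- rnorm(50, 0.3)
  p_pkg <- scfskit:::wilcoxon_signed_rank_pratt(x)
  p_ref <- wilcox.test(x, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  expect_identical(scfskit:::wilcoxon_signed_rank_pratt(numeric(10)), 1)
})
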