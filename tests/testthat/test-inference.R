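test_that("subgroup tests pick the right procedure and adjust pairwise", {
  d <- tibble::tibble(value = c(1:6, 1:6), grp = rep(c("a", "b"), each = 6))
  r <- subgroup_tests(d, "value", "grp")
  expect_equal(r$omnibus$test, "wilcoxon")
  expect_gt(r$omnibus$p, 0.9) # identical groups

  d3 <- tibble::tibble(value = c(1:5, 11:15, 21:25),
                       grp = rep(c("a", "b", "c"), each = 5))
  r3 <- subgroup_tests(d3, "value", "grp")
  expect_equal(r3$omnibus$test, "kruskal-wallis")
  expect_lt(r3$omnibus$p, 0.05)
  expect_equal(nrow(r3$pairwise), 3)
  expect_equal(r3$pairwise$p_bonferroni,
               pmin(1, r3$pairwise$p_raw * 3))

  tiny <- tibble::tibble(value = c(1, 2, 3, 4, 9),
                         grp = c("a", "a", "b", "b", "c"))
  expect_warning(rt <- subgroup_tests(tiny, "value", "grp"), "n < 2")
  expect_equal(rt$omnibus$test, "wilcoxon")
})

test_that("Kruskal-Wallis agrees with the rank definition and exact enumeration", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- stats::kruskal.test(x, factor(g))
  expect_equal(unname(kw$statistic), kw_statistic_direct(x, g),
               tolerance = 1e-12)
  # fully separated groups: only the 3! relabellings achieve the maximal
  # statistic, so the exact permutation p is 6/1680
  expect_equal(kw_exact_p(x, g), 6 / 1680)

  # agreement with the direct statistic on random tied data, n <= 10
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:10, 1)
    xs <- sample(1:4, n, replace = TRUE) # heavy ties
    gs <- sample(c("a", "b", rep(c("a", "b", "c"), length.out = n - 2)))
    kw2 <- stats::kruskal.test(xs, factor(gs))
    expect_equal(unname(kw2$statistic), kw_statistic_direct(xs, gs),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment in the model matches the step-up definition", {
  # the worked step-up example: (0.01, 0.02, 0.04) -> (0.03, 0.03, 0.04)
  expect_equal(bh_stepup_direct(c(0.01, 0.02, 0.04)),
               c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(sample(3:20, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup_direct(p),
                 tolerance = 1e-12)
  }
})

test_that("the mixed model nails a zero-noise, zero-random-effect design", {
  sim <- simulate_design_rows(n_participants = 12, n_days = 2,
                              re_sd = 0, resid_sd = 1e-3, seed = 2)
  fit <- suppressWarnings(suppressMessages(
    fit_exposure_model(sim$design, adjustment = "none", p_method = "normal",
                       emm = FALSE)))
  est <- fit$coefficients$estimate[match(names(sim$truth),
                                         fit$coefficients$term)]
  expect_equal(est, unname(sim$truth), tolerance = 1e-2)
  # BH column is the adjustment of the non-intercept p-values
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_equal(co$p_bh, stats::p.adjust(co$p, "BH"))
  expect_true(all(co$p_bh >= co$p - 1e-15))
})

test_that("indoor-stratum slope adds main effect and interaction", {
  tab <- tibble::tibble(term = c("(Intercept)", "pm25_idw",
                                 "ioindoor:pm25_idw"),
                        estimate = c(8.5, 0.279, -0.168))
  expect_equal(indoor_slope(tab), 0.111)
  tab0 <- tab; tab0$estimate[3] <- 0
  expect_equal(indoor_slope(tab0), tab$estimate[2])
  expect_error(indoor_slope(tab[1:2, ]), "interaction")
})

test_that("EMMs reduce to group means on balanced designs and differences
           equal coefficient differences", {
  # fully balanced factorial: every landuse level appears with every
  # combination of the other terms
  cells <- tidyr::expand_grid(
    landuse = c("other", "industrial", "office"),
    io = c("outdoor", "indoor"),
    season = c("spring", "winter"),
    hour = c("h00", "h12"),
    pm25_idw = c(4, 8),
    studyid = c("P001", "P002"))
  set.seed(9)
  design <- cells |>
    dplyr::mutate(
      landuse = factor(.data$landuse,
                       levels = c("other", "industrial", "office")),
      io = factor(.data$io, levels = c("outdoor", "indoor")),
      season = factor(.data$season, levels = c("spring", "winter")),
      hour = factor(.data$hour, levels = c("h00", "h12")),
      conc = 5 + 2 * (landuse == "industrial") - 3 * (landuse == "office") +
        0.5 * (io == "indoor") + 0.3 * pm25_idw + rnorm(dplyr::n(), 0, 0.2))
  fit <- suppressWarnings(suppressMessages(
    fit_exposure_model(design, adjustment = "none", p_method = "normal")))
  emm_lu <- fit$emms[fit$emms$variable == "landuse", ]
  grp_means <- tapply(design$conc, design$landuse, mean)
  expect_equal(emm_lu$emm, as.numeric(grp_means[emm_lu$level]),
               tolerance = 1e-8)
  # no interaction involves landuse, so EMM differences = coefficient diffs
  co <- fit$coefficients
  expect_equal(
    emm_contrast(fit$emms, "landuse", "industrial", "office"),
    co$estimate[co$term == "landuseindustrial"] -
      co$estimate[co$term == "landuseoffice"],
    tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly, naming aliased columns", {
  sim <- simulate_design_rows(n_participants = 6, n_days = 2, seed = 3)
  d <- sim$design
  d$season <- d$io # perfectly aliased factor
  levels(d$season) <- c("spring", "winter")
  expect_error(
    suppressMessages(fit_exposure_model(d, adjustment = "none", emm = FALSE)),
    "aliased")
})

test_that("variance components: ICC limits behave", {
  set.seed(4)
  # identical participants: between-variance 0 (singular) -> ICC 0, flagged
  d0 <- tibble::tibble(participant_id = rep(sprintf("P%02d", 1:10), each = 50),
                       conc = rnorm(500))
  r0 <- variance_components_icc(d0)
  expect_true(r0$singular)
  expect_equal(r0$icc, 0)

  # residual -> 0 limit: ICC -> 1
  b <- rnorm(10, 0, 2)
  d1 <- tibble::tibble(participant_id = rep(sprintf("P%02d", 1:10), each = 50),
                       conc = rep(b, each = 50) + rnorm(500, 0, 1e-4))
  expect_gt(variance_components_icc(d1)$icc, 0.999)
})

test_that("land-use entropy has its closed forms", {
  one <- tibble::tibble(microenv = rep("residential", 50))
  expect_equal(landuse_entropy(one)$entropy, 0)
  uni <- tibble::tibble(microenv = rep(microenv_levels(), each = 10))
  expect_equal(landuse_entropy(uni)$entropy, log(8), tolerance = 1e-12)
  half <- tibble::tibble(microenv = rep(c("residential", "office"), 25))
  expect_equal(landuse_entropy(half)$entropy, log(2), tolerance = 1e-12)
  # vehicle exclusion shrinks the class set
  expect_equal(landuse_entropy(uni, include_vehicle = FALSE)$entropy, log(7),
               tolerance = 1e-12)
  expect_error(landuse_entropy(one[0, ]), "no labelled minutes")
})

test_that("spatiotemporal coefficients are robust to demographic adjustment
           when demographic effects are null", {
  sim <- simulate_design_rows(n_participants = 30, n_days = 2,
                              rows_per_hour = 2, seed = 5)
  ns <- suppressWarnings(suppressMessages(
    sensitivity_nested(sim$design, p_method = "normal")))
  tab <- ns$table
  spat <- grepl("landuse|season|hour|io|pm25_idw", tab$term)
  dev <- abs(tab$estimate_model3[spat] - tab$estimate_model1[spat])
  expect_true(all(dev < 2 * tab$se_model1[spat]))
})

test_that("leave-one-group-out is deterministic and tightens with n", {
  sim_small <- simulate_design_rows(n_participants = 15, n_days = 2, seed = 6)
  sim_big <- simulate_design_rows(n_participants = 60, n_days = 2, seed = 6)
  l1 <- suppressWarnings(suppressMessages(
    sensitivity_logo(sim_small$design, seed = 11, adjustment = "none",
                     p_method = "normal")))
  l1b <- suppressWarnings(suppressMessages(
    sensitivity_logo(sim_small$design, seed = 11, adjustment = "none",
                     p_method = "normal")))
  expect_identical(l1$partition, l1b$partition)
  l2 <- suppressWarnings(suppressMessages(
    sensitivity_logo(sim_big$design, seed = 11, adjustment = "none",
                     p_method = "normal")))
  shared <- intersect(l1$ranges$term, l2$ranges$term)
  r1 <- l1$ranges$range[match(shared, l1$ranges$term)]
  r2 <- l2$ranges$range[match(shared, l2$ranges$term)]
  expect_lt(median(r2), median(r1))
})
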