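half_eq <- conversion_equation("half", "region", "R", "linear",
                               list(m = 0.5, b = 0))

test_that("residual validation: zero, shifted, and symmetric residuals", {
  som <- seq(10, 60, length.out = 20)
  # residuals identically zero
  d0 <- data.frame(region = "R", som = som, oc = 0.5 * som)
  r0 <- validate_equation_on_region(half_eq, d0)
  expect_false(r0$different_from_zero)
  expect_equal(r0$central_tendency, 0)

  # residuals ~ N(5, 1): power ~ 1 at n = 50
  set.seed(31)
  som50 <- runif(50, 10, 60)
  d5 <- data.frame(region = "R", som = som50,
                   oc = 0.5 * som50 + rnorm(50, 5, 1))
  r5 <- validate_equation_on_region(half_eq, d5)
  expect_true(r5$different_from_zero)
  expect_equal(r5$central_tendency, 5, tolerance = 0.5)

  # alternating +/-1 residuals: bimodal, so the Wilcoxon path fires and
  # perfect symmetry keeps p high
  dalt <- data.frame(region = "R", som = som,
                     oc = 0.5 * som + rep(c(1, -1), 10))
  ralt <- validate_equation_on_region(half_eq, dalt)
  expect_identical(ralt$test_used, "wilcoxon_signed_rank")
  expect_gt(ralt$p_value, 0.5)
  expect_false(ralt$different_from_zero)
  expect_equal(ralt$central_tendency, 0)

  expect_error(validate_equation_on_region(half_eq,
                                           d0[1:2, ]), "at least 3")
})

test_that("validation summary arithmetic and its identity", {
  reps <- data.frame(region = c("A", "B", "C"),
                     central_tendency = c(1, -1, 2),
                     different_from_zero = c(FALSE, FALSE, TRUE))
  s <- summarize_validation(reps, "demo")
  expect_equal(s$abs_sum, 4)
  expect_equal(s$abs_mean, 4 / 3)
  expect_equal(s$n_not_different_from_zero, 2)
  expect_identical(s$abs_mean * s$n_regions, s$abs_sum)

  zero <- data.frame(region = c("A", "B"), central_tendency = c(0, 0),
                     different_from_zero = c(FALSE, FALSE))
  sz <- summarize_validation(zero)
  expect_equal(c(sz$abs_sum, sz$abs_mean), c(0, 0))

  # 17 central tendencies summing (in absolute value) to 14.43
  set.seed(8)
  ct <- runif(17)
  ct <- ct / sum(ct) * 14.43 * sample(c(-1, 1), 17, replace = TRUE)
  r17 <- data.frame(region = paste0("R", 1:17), central_tendency = ct,
                    different_from_zero = rep(FALSE, 17))
  s17 <- summarize_validation(r17)
  expect_equal(s17$abs_sum, 14.43)
  expect_equal(s17$abs_mean, 14.43 / 17)

  expect_error(summarize_validation(rbind(reps, reps[1, ])), "duplicate")
})

test_that("sedimentary t-test behaves at the null and under separation", {
  d <- make_two_region_samples()
  # identical (non-constant) groups -> t = 0
  same <- data.frame(som = rep(c(10, 20, 30), 2),
                     oc = rep(c(4, 9, 15), 2),
                     sedimentary = rep(c("carbonate", "terrigenous"),
                                       each = 3))
  expect_equal(compare_sedimentary(same)$t, 0)

  # groups emulating the carbonate/terrigenous contrast
  set.seed(77)
  n1 <- 300; n2 <- 150
  rat <- c(rnorm(n1, 0.46, 0.07), rnorm(n2, 0.32, 0.12))
  dd <- data.frame(som = rep(20, n1 + n2), oc = 20 * rat,
                   sedimentary = rep(c("carbonate", "terrigenous"),
                                     c(n1, n2)))
  res <- compare_sedimentary(dd)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$df, n1 + n2 - 2)
  expect_gt(res$group_stats$mean[res$group_stats$group == "carbonate"],
            res$group_stats$mean[res$group_stats$group == "terrigenous"])

  expect_error(compare_sedimentary(
    data.frame(som = 1:3, oc = c(0.3, 0.4, 0.5) * 1:3,
               sedimentary = c("carbonate", "carbonate", "terrigenous"))),
    "n >= 2")
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  d <- make_two_region_samples()
  d$ces <- d$sedimentary  # two groups under the ANOVA interface
  tt <- compare_sedimentary(d)
  av <- compare_ces(d)
  expect_equal(av$F, tt$t^2, tolerance = 1e-8)
  expect_equal(av$df[2], tt$df)
})

test_that("CES ANOVA separates shifted groups and letters behave", {
  set.seed(13)
  n <- 25
  d <- data.frame(som = rep(20, 3 * n),
                  oc = 20 * c(rnorm(n, 0.2, 0.01), rnorm(n, 0.45, 0.01),
                              rnorm(n, 0.7, 0.01)),
                  ces = rep(c("TD", "CE", "XX"), each = n))
  res <- compare_ces(d)
  expect_lt(res$p_value, 1e-10)
  expect_true(all(res$tukey$p_adj < 0.05))
  expect_equal(length(unique(res$letters)), 3)

  # a single common distribution: no separation in most replicates
  set.seed(14)
  null_ok <- replicate(20, {
    d0 <- data.frame(som = rep(20, 4 * n),
                     oc = 20 * rnorm(4 * n, 0.4, 0.05),
                     ces = rep(c("A", "B", "C", "D"), each = n))
    res0 <- compare_ces(d0)
    res0$p_value > 0.05 && length(unique(res0$letters)) == 1
  })
  expect_gte(mean(null_ok), 0.75)

  expect_error(compare_ces(data.frame(som = 1:4, oc = (1:4) * 0.4,
                                      ces = rep("A", 4))),
               "at least two")
})

test_that("latitude regressions on exact, shuffled and degenerate data", {
  su <- data.frame(region = paste0("R", 1:8),
                   latitude = seq(24, 31, 1))
  su$slope <- 0.9 - 0.02 * su$latitude
  su$mean_som <- 200 - 6 * su$latitude
  lr <- suppressWarnings(latitude_regressions(su))
  expect_equal(lr$slope_vs_latitude$r_squared, 1)
  expect_equal(lr$slope_vs_latitude$coefficients$m, -0.02)
  expect_equal(lr$mean_som_vs_latitude$coefficients$m, -6)

  # subsetting restricts the fit
  lr2 <- suppressWarnings(latitude_regressions(su, subset = paste0("R", 1:4)))
  expect_equal(lr2$slope_vs_latitude$n, 4)

  # shuffling latitudes destroys the association
  set.seed(21)
  su$latitude <- sample(su$latitude)
  su$slope <- 0.9 - 0.02 * seq(24, 31, 1) + rnorm(8, 0, 1e-6)
  lr3 <- latitude_regressions(su)
  expect_lt(lr3$slope_vs_latitude$r_squared, 0.5)

  su$latitude <- 25
  expect_error(latitude_regressions(su), "zero variance")
})

test_that("binned latitudinal trends recover built-in effects", {
  # latitude-independent generator: average slope compatible with zero
  specs <- default_region_specs()[1:8, ]
  d0 <- generate_dataset(specs, seed = 99)
  d0$oc <- 0.45 * d0$som + rnorm(nrow(d0), 0, 1)  # common slope everywhere
  d0$oc <- pmin(pmax(d0$oc, 0.01 * d0$som), 0.99 * d0$som)
  tr0 <- binned_latitude_trends(d0)
  expect_false(is.null(tr0$bins))
  expect_lt(abs(tr0$avg_slope_all), 0.02)

  # single populated bin
  d1 <- data.frame(region = rep(c("A", "B", "C"), each = 4),
                   som = runif(12, 20, 29),
                   latitude = rep(c(24, 27, 30), each = 4))
  d1$oc <- 0.4 * d1$som
  tr1 <- suppressWarnings(binned_latitude_trends(d1))
  expect_equal(nrow(tr1$bins), 1)
  expect_equal(tr1$bins$bin, "[20,30)")
})
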