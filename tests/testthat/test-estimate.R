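reg <- load_builtin_registry()

test_that("selection hierarchy returns the highest applicable tier", {
  s1 <- select_equation(reg, list(region = "Tampa Bay"))
  expect_identical(s1$tier, "regional")
  expect_equal(s1$equation$coefficients$m, 0.427)

  s2 <- select_equation(reg, list(ces = "TD"))
  expect_identical(s2$tier, "ces")
  expect_equal(s2$equation$coefficients$m, 0.287)

  s3 <- select_equation(reg, list())
  expect_identical(s3$tier, "general")
  expect_identical(s3$equation$id, "general_linear")
  s3q <- select_equation(reg, list(), general_form = "quadratic")
  expect_identical(s3q$equation$id, "general_quadratic")

  s4 <- select_equation(reg, list(sedimentary = "carbonate"))
  expect_identical(s4$tier, "sedimentary")
  expect_identical(s4$equation$form, "quadratic")

  # carbonate lagoon contexts map to the carbonate open coast equation
  s5 <- select_equation(reg, list(ces = "CL"))
  expect_identical(s5$equation$id, "ces_coc")

  # an unknown region falls through to the next tier
  s6 <- select_equation(reg, list(region = "Nowhere", ces = "CE"))
  expect_identical(s6$tier, "ces")

  expect_error(select_equation(reg, list(planet = "Mars")), "unknown context")
})

test_that("tier priority is monotone in added context", {
  tier_rank <- c(regional = 1, ces = 2, sedimentary = 3, general = 4,
                 slope_from_mean_som = 5)
  contexts <- list(
    list(),
    list(sedimentary = "terrigenous"),
    list(ces = "TL", sedimentary = "terrigenous"),
    list(region = "Merritt Island", ces = "TL", sedimentary = "terrigenous"))
  ranks <- vapply(contexts, function(ctx)
    tier_rank[[select_equation(reg, ctx)$tier]], numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("slope-from-mean-SOM tier builds a zero-intercept equation", {
  su <- data.frame(region = letters[1:5], mean_som = c(5, 15, 30, 50, 70))
  su$slope <- 0.1 * su$mean_som^0.4
  sf <- fit_slope_vs_mean_som(su)
  sel <- select_equation(reg, list(regional_mean_som = 40), slope_fit = sf,
                         tiers = "slope_from_mean_som")
  expect_identical(sel$tier, "slope_from_mean_som")
  expect_equal(sel$equation$coefficients$b, 0)
  expect_equal(sel$equation$coefficients$m, 0.1 * 40^0.4, tolerance = 1e-6)
})

test_that("OC predictions clamp, flag and propagate uncertainty", {
  ce <- registry_get(reg, "ces_ce")
  p0 <- estimate_oc(ce, 0)
  expect_equal(p0$oc_raw, -1.7)
  expect_equal(p0$oc, 0)
  expect_true(p0$clamped)

  # strongly negative intercept clamps at low SOM
  lg <- registry_find(reg, "region", "Laguna Gandoca")[[1]]
  p5 <- estimate_oc(lg, 5)
  expect_lt(p5$oc_raw, 0)
  expect_equal(p5$oc, 0)

  noerr <- conversion_equation("e0", "region", "x", "linear",
                               list(m = 0.5, b = 0),
                               coefficient_se = list(m = 0, b = 0))
  p40 <- estimate_oc(noerr, 40)
  expect_equal(p40$oc, 20)
  expect_equal(p40$oc_se, 0)

  # linear error propagation sqrt(som^2 se_m^2 + se_b^2)
  pse <- estimate_oc(ce, 40)
  expect_equal(pse$oc_se, sqrt(40^2 * 0.005^2 + 0.3^2))
})

test_that("dataset prediction uses measured OC first, then the hierarchy", {
  d <- data.frame(som = c(30, 30, 30),
                  oc = c(12, NA, NA),
                  region = c(NA, "Tampa Bay", NA))
  out <- predict_dataset_oc(d, reg)
  expect_identical(out$tier, c("measured", "regional", "general"))
  expect_equal(out$oc_est[1], 12)
  expect_equal(out$oc_est[2], 0.427 * 30 - 0.2)
  expect_equal(out$oc_est[3], 0.511 * 30 - 2.497)
})

test_that("stock computation: worked example, additivity, homogeneity", {
  one <- data.frame(depth_top = 0, depth_bottom = 100, oc = 10,
                    bulk_density = 0.5)
  expect_equal(compute_stock(one)$stock, 500)
  expect_equal(compute_stock(transform(one, oc = 0))$stock, 0)

  # two half-depth intervals equal one full interval
  halves <- data.frame(depth_top = c(0, 50), depth_bottom = c(50, 100),
                       oc = 10, bulk_density = 0.5)
  expect_equal(compute_stock(halves)$stock, compute_stock(one)$stock)

  # homogeneous of degree 1 in bulk density
  expect_equal(compute_stock(transform(one, bulk_density = 1.5))$stock,
               3 * compute_stock(one)$stock)

  # straddling intervals are pro-rated; gaps reported
  deep <- data.frame(depth_top = c(0, 80), depth_bottom = c(50, 120),
                     oc = 10, bulk_density = 0.5)
  res <- compute_stock(deep, depth_limit = 100)
  expect_equal(res$stock, (50 + 20) * 0.10 * 0.5 * 100)
  expect_equal(res$gap_fraction, 0.3)

  overlap <- data.frame(depth_top = c(0, 40), depth_bottom = c(50, 90),
                        oc = 10, bulk_density = 0.5)
  expect_error(compute_stock(overlap), "overlapping")
})

test_that("per-core stock table splits on core_id", {
  d <- data.frame(core_id = rep(c("c1", "c2"), each = 2),
                  depth_top = c(0, 50, 0, 50),
                  depth_bottom = c(50, 100, 50, 100),
                  oc_est = c(10, 10, 20, 20),
                  bulk_density = 0.5)
  st <- compute_stocks(d)
  expect_equal(st$stock[st$core_id == "c1"], 500)
  expect_equal(st$stock[st$core_id == "c2"], 1000)
})

test_that("paired stock comparison: null, shifted, and degenerate input", {
  a <- seq(50, 340, by = 10)
  same <- compare_stock_estimates(a, a)
  expect_equal(same$p_value, 1)

  shifted <- compare_stock_estimates(a, a * 1.5)
  expect_lt(shifted$p_value, 0.01)
  expect_equal(shifted$summary$median[2], median(a) * 1.5)

  expect_error(compare_stock_estimates(1, 2), "at least 5")
  expect_error(compare_stock_estimates(a, a[-1]), "paired")
})

test_that("matched regional equations beat the general equation on
           synthetic regions (accuracy ordering)", {
  specs <- default_region_specs()
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- generate_dataset(specs, seed = 1000 + r)
    su <- region_summaries(d)
    gen <- registry_get(reg, "general_linear")
    reg_abs <- 0; gen_abs <- 0
    for (rg in su$region) {
      ds <- d[d$region == rg, ]
      own <- registry_find(reg, "region", rg)
      if (!length(own)) next
      reg_abs <- reg_abs +
        abs(mean(ds$oc - as.numeric(evaluate_equation(own[[1]], ds$som))))
      gen_abs <- gen_abs +
        abs(mean(ds$oc - as.numeric(evaluate_equation(gen, ds$som))))
    }
    if (reg_abs < gen_abs) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})
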