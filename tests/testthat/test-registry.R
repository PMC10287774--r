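test_that("built-in registry has the published structure and values", {
  reg <- load_builtin_registry()
  lv <- vapply(reg$equations, `[[`, character(1), "scope_level")
  expect_identical(sum(lv == "region"), 17L)
  expect_identical(sum(lv == "ces"), 6L)
  expect_identical(sum(lv == "sedimentary"), 2L)
  expect_identical(sum(lv == "general_mangrove"), 2L)
  expect_identical(sum(lv == "literature_ecosystem"), 5L)
  expect_identical(sum(lv == "literature_regional"), 14L)

  ce <- registry_find(reg, "ces", "CE")[[1]]
  expect_equal(ce$coefficients$m, 0.506)
  expect_equal(ce$coefficients$b, -1.7)

  swe <- registry_find(reg, "region", "Southwest Everglades")[[1]]
  expect_equal(swe$coefficients$m, 0.515)
  expect_equal(swe$coefficients$b, -2.2)
  expect_identical(swe$n, 543L)
  expect_equal(swe$r_squared, 0.93)

  # interceptless published equations are stored without b
  tb_lit <- registry_find(reg, "literature_regional", "Tampa Bay, FL USA")[[1]]
  expect_null(tb_lit$coefficients$b)
})

test_that("regional and CES slopes span the published ranges", {
  reg <- load_builtin_registry()
  reg_m <- vapply(registry_find(reg, "region"),
                  function(e) e$coefficients$m, numeric(1))
  expect_equal(range(reg_m), c(0.240, 0.687))
  ces_m <- vapply(registry_find(reg, "ces"),
                  function(e) e$coefficients$m, numeric(1))
  expect_equal(range(ces_m), c(0.250, 0.506))
  lin <- Filter(function(e) e$form == "linear", reg$equations)
  m <- vapply(lin, function(e) e$coefficients$m, numeric(1))
  expect_true(all(m > 0 & m < 1))
})

test_that("intercept unit conversion scales by 100 and round-trips", {
  expect_equal(convert_intercept_units(10, "percent", "fraction"), 0.10)
  expect_equal(convert_intercept_units(0.01, "fraction", "percent"), 1.0)
  expect_equal(convert_intercept_units(0, "percent", "fraction"), 0)
  expect_equal(convert_intercept_units(5, "percent", "percent"), 5)
  # bit-exact where binary representation allows; 1e-12 relative in general
  for (b in c(-15.5, -4.5, -0.25, 0, 10, 100)) {
    expect_identical(
      convert_intercept_units(
        convert_intercept_units(b, "percent", "fraction"),
        "fraction", "percent"),
      b)
  }
  set.seed(2)
  b <- runif(100, -20, 20)
  expect_equal(convert_intercept_units(
    convert_intercept_units(b, "percent", "fraction"),
    "fraction", "percent"), b, tolerance = 1e-12)
})

test_that("evaluate_equation handles all three forms", {
  reg <- load_builtin_registry()
  # global mangrove power form: OC:SOM 0.25 at 5% SOM and 0.36 at 90%
  pw <- registry_get(reg, "eco_mangrove_ouyang")
  expect_equal(round(as.numeric(evaluate_equation(pw, 5)) / 5, 2), 0.25)
  expect_equal(round(as.numeric(evaluate_equation(pw, 90)) / 90, 2), 0.36)

  lin <- conversion_equation("half", "region", "x", "linear",
                             list(m = 0.5, b = 0))
  expect_equal(as.numeric(evaluate_equation(lin, 50)), 25)

  swe <- registry_find(reg, "region", "Southwest Everglades")[[1]]
  expect_equal(as.numeric(evaluate_equation(swe, 60)), 0.515 * 60 - 2.2)

  expect_error(evaluate_equation(lin, 120), "0, 100")
})

test_that("every built-in linear equation equals its intercept at SOM = 0", {
  reg <- load_builtin_registry()
  lin <- Filter(function(e) e$form == "linear", reg$equations)
  for (e in lin) {
    b <- if (is.null(e$coefficients$b)) 0 else e$coefficients$b
    expect_equal(as.numeric(evaluate_equation(e, 0)), b, info = e$id)
  }
})

test_that("a quadratic with a2 = 0 reduces to the linear evaluation", {
  q <- conversion_equation("q0", "region", "x", "quadratic",
                           list(a2 = 0, a1 = 0.4, a0 = -1.2))
  l <- conversion_equation("l0", "region", "x", "linear",
                           list(m = 0.4, b = -1.2))
  som <- seq(0, 100, by = 2.5)
  expect_equal(as.numeric(evaluate_equation(q, som)),
               as.numeric(evaluate_equation(l, som)))
})

test_that("extrapolation outside the validity range is flagged", {
  e <- conversion_equation("v", "region", "x", "linear",
                           list(m = 0.5, b = 0),
                           som_validity_range = c(10, 60))
  out <- evaluate_equation(e, c(5, 30, 80))
  expect_identical(attr(out, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("constructor rejects malformed equations", {
  expect_error(conversion_equation("x", "region", "k", "linear",
                                   list(a = 1, p = 2)),
               "not valid")
  expect_error(conversion_equation("x", "region", "k", "power",
                                   list(a = 0.2)),
               "requires")
  expect_error(equation_registry(list(
    conversion_equation("dup", "region", "k", "linear", list(m = 0.5)),
    conversion_equation("dup", "region", "k2", "linear", list(m = 0.4)))),
    "duplicate")
})

test_that("registry round-trips exactly through delimited text and YAML", {
  reg <- load_builtin_registry()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, tsv)
  expect_identical(read_registry(tsv), reg)

  yml <- withr::local_tempfile(fileext = ".yml")
  write_registry_yaml(reg, yml)
  expect_identical(read_registry_yaml(yml), reg)

  # fitted (full-precision double) coefficients survive the round-trip too
  set.seed(3)
  f <- fit_linear(runif(20, 5, 70), runif(20, 2, 30))
  reg2 <- equation_registry(list(as_conversion_equation(
    f, "fitted_demo", "region", "Demo")))
  write_registry(reg2, tsv)
  expect_identical(read_registry(tsv), reg2)
})
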