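# Log-log OLS power-law fitting, exponent algebra with quadrature SEs, and
# agreement with a brute-force grid-search oracle.

# independent oracle: minimise log10-space squared error over a refined
# exponent grid, with the intercept profiled out analytically
grid_search_power_law <- function(x, y, lo = -3, hi = 3) {
  lx <- log10(x); ly <- log10(y)
  sse <- function(b) {
    a <- mean(ly - b * lx)
    sum((ly - a - b * lx)^2)
  }
  for (step in c(1e-2, 1e-4, 1e-6)) {
    bs <- seq(lo, hi, by = step)
    best <- bs[which.min(vapply(bs, sse, numeric(1)))]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  a <- mean(ly - best * lx)
  list(coefficient = 10^a, exponent = best)
}

test_that("noiseless power laws are recovered exactly", {
  x <- c(1, 2, 4, 8, 16)
  fit <- fit_power_law(x, 2 * x^0.5)
  expect_equal(fit$coefficient, 2, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$se_exponent, 1e-10)
  expect_lt(fit$se_log_coefficient, 1e-10)
  expect_identical(fit$n, 5L)
})

test_that("fitting validates its inputs and names offending records", {
  x <- c(1, 2, -3, 4)
  expect_error(fit_power_law(x, x), "offending record\\(s\\): 3")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_law(c(1, 2, 3), c(1, 0, 2)), "positive")
  expect_error(fit_power_law(data.frame(a = 1:3, b = 1:3)), "columns")
})

test_that("fit is scale-equivariant in the predictor", {
  d <- generate_power_law(5, 1.3, 0.25, n = 40, x_range = c(0.1, 100),
                          seed = 11)
  f1 <- fit_power_law(d$x, d$y)
  k <- 250
  f2 <- fit_power_law(k * d$x, d$y)
  expect_equal(f2$exponent, f1$exponent)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_equal(f2$se_exponent, f1$se_exponent)
  expect_equal(f2$coefficient, f1$coefficient * k^(-f1$exponent))
})

test_that("fit agrees with the brute-force grid-search minimiser", {
  for (seed in c(3, 17)) {
    d <- generate_power_law(12, 0.7, 0.3, n = 15, x_range = c(0.5, 500),
                            seed = seed)
    fit <- fit_power_law(d$x, d$y)
    oracle <- grid_search_power_law(d$x, d$y)
    expect_equal(fit$exponent, oracle$exponent, tolerance = 1e-4)
    expect_equal(fit$coefficient, oracle$coefficient, tolerance = 1e-3)
  }
})

test_that("noisy fits report honest standard errors and r-squared", {
  d <- generate_power_law(7586, 0.82, 0.3, n = 60, x_range = c(0.1, 1e3),
                          seed = 5)
  fit <- fit_power_law(d)
  expect_lt(abs(fit$exponent - 0.82), 2 * fit$se_exponent)
  expect_gt(fit$r_squared, 0.5)
  expect_gt(fit$se_exponent, 0)
})

test_that("exponent algebra adds/subtracts and combines SEs in quadrature", {
  # growth V^0.97 (SE 0.04) over bacterial division time V^-0.17 (SE 0.11):
  # biomass accumulation scales as V^1.14 with SE 0.12
  comb <- combine_exponents(c(0.97, 0.04), "divide", c(-0.17, 0.11))
  expect_equal(comb$exponent, 1.14)
  expect_equal(comb$se, sqrt(0.04^2 + 0.11^2))
  expect_equal(round(comb$se, 2), 0.12)
  # eukaryotes: division time rises as V^0.13, giving V^0.84 per cell
  expect_equal(combine_exponents(c(0.97, 0.04), "divide", 0.13)$exponent, 0.84)
  # identity element
  id <- combine_exponents(c(0.7, 0.05), "multiply", c(0, 0))
  expect_equal(id$exponent, 0.7)
  expect_equal(id$se, 0.05)
  expect_error(combine_exponents(c(1, -0.1), "multiply", 0), ">= 0")
})

test_that("exponent algebra accepts fitted objects directly", {
  x <- c(1, 2, 4, 8, 16, 32)
  fit <- fit_power_law(x, 3 * x^0.25)
  comb <- combine_exponents(fit, "multiply", c(0.5, 0))
  expect_equal(comb$exponent, 0.75, tolerance = 1e-9)
})

test_that("predict evaluates coefficient * x^exponent", {
  x <- c(1, 2, 4, 8)
  fit <- fit_power_law(x, 2 * x^0.5)
  expect_equal(predict(fit, 4), 4, tolerance = 1e-9)
  expect_equal(predict(fit, 1), fit$coefficient)
  # the mitochondrial area law: 3.0 V^0.99 passes through 3.0 at V = 1
  mito <- structure(list(coefficient = 3.0, exponent = 0.99),
                    class = "power_law_fit")
  expect_equal(predict(mito, 1), 3.0)
  expect_error(predict(fit, -2), "positive")
})

test_that("scaling datasets and fit reports round-trip through files", {
  d <- generate_power_law(2, 1.1, 0.1, n = 10, x_range = c(1, 50), seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_scaling_dataset(path)
  expect_equal(back$x, d$x)
  expect_equal(back$y, d$y)
  rep <- fit_report(fit_power_law(back$x, back$y), "demo")
  expect_identical(names(rep)[1:3], c("trait", "coefficient", "exponent"))
  expect_identical(nrow(rep), 1L)
})
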