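# Geometry closed forms against numerical integration, inner:outer
# extrapolation, and apportionment of the growth budget across membranes.

# numeric surface-of-revolution oracle: S = int 2 pi y(x) sqrt(1 + y'^2) dx
# evaluated piecewise for a profile y(x), with derivative supplied
revolution_area <- function(pieces) {
  sum(vapply(pieces, function(p) {
    integrate(function(x) 2 * pi * p$y(x) * sqrt(1 + p$dy(x)^2),
              p$lower, p$upper, rel.tol = 1e-10)$value
  }, numeric(1)))
}

sphere_pieces <- function(r, eps = 1e-9) {
  list(list(y = function(x) sqrt(pmax(r^2 - x^2, 0)),
            dy = function(x) -x / sqrt(pmax(r^2 - x^2, 1e-300)),
            lower = -r + eps * r, upper = r - eps * r))
}

test_that("sphere closed forms match the revolution-integral oracle", {
  set.seed(21)
  for (r in runif(4, 0.2, 3)) {
    g <- cell_geometry("sphere", radius = r)
    expect_equal(surface_area(g), 4 * pi * r^2)
    expect_equal(cell_volume(g), 4 / 3 * pi * r^3)
    expect_equal(surface_area(g), revolution_area(sphere_pieces(r)),
                 tolerance = 1e-6)
  }
})

test_that("spherocylinder closed forms match the oracle and degenerate to a sphere", {
  g <- cell_geometry("spherocylinder", radius = 0.5, length = 2)
  expect_equal(surface_area(g), 2 * pi * 0.5 * 2 + 4 * pi * 0.25)
  expect_equal(signif(surface_area(g), 4), 9.425)
  expect_equal(cell_volume(g), pi * 0.25 * 2 + 4 / 3 * pi * 0.125)
  set.seed(22)
  for (i in 1:3) {
    r <- runif(1, 0.2, 2); L <- runif(1, 0.1, 5)
    gc <- cell_geometry("spherocylinder", radius = r, length = L)
    pieces <- c(sphere_pieces(r),
                list(list(y = function(x) rep(r, length(x)),
                          dy = function(x) rep(0, length(x)),
                          lower = 0, upper = L)))
    expect_equal(surface_area(gc), revolution_area(pieces), tolerance = 1e-6)
  }
  degen <- cell_geometry("spherocylinder", radius = 0.8, length = 0)
  expect_equal(surface_area(degen),
               surface_area(cell_geometry("sphere", radius = 0.8)))
  expect_equal(cell_volume(degen),
               cell_volume(cell_geometry("sphere", radius = 0.8)))
})

test_that("ellipsoid area matches sphere and prolate-spheroid closed forms", {
  ball <- cell_geometry("ellipsoid", semi_axes = c(1.3, 1.3, 1.3))
  expect_equal(surface_area(ball), 4 * pi * 1.3^2, tolerance = 1e-8)
  expect_equal(cell_volume(ball), 4 / 3 * pi * 1.3^3)
  # prolate spheroid a > b = c: S = 2 pi b^2 (1 + (a/(b e)) asin(e))
  a <- 2; b <- 1
  e <- sqrt(1 - b^2 / a^2)
  closed <- 2 * pi * b^2 * (1 + a / (b * e) * asin(e))
  pro <- cell_geometry("ellipsoid", semi_axes = c(a, b, b))
  expect_equal(surface_area(pro), closed, tolerance = 1e-8)
  expect_error(cell_geometry("ellipsoid", semi_axes = c(1, 2)), "length 3")
  expect_error(cell_geometry("sphere", radius = 0), "positive")
})

test_that("total mitochondrial area extrapolates from the outer membrane", {
  expect_identical(total_mito_area(10, 4.6), 56)
  expect_identical(total_mito_area(0), 0)
  # mean of the four individually measured inner:outer ratios, available
  # for sensitivity analysis against the default 4.6
  measured <- reference_constants$inner_outer_ratios_measured
  expect_equal(mean(measured), 3.775)
  expect_equal(total_mito_area(10, mean(measured)), 47.75)
  expect_error(total_mito_area(10, 0.5), ">= 1")
  expect_error(total_mito_area(-1), "non-negative")
})

test_that("membrane budget shares are non-negative and sum to one", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(2:6, 1)
    areas <- setNames(runif(n, 0, 50),
                      c("plasma", paste0("organelle", seq_len(n - 1))))
    mb <- membrane_budget_table(areas, volume = runif(1, 0.5, 500))
    expect_true(all(mb$table$share >= 0))
    expect_equal(sum(mb$table$share), 1, tolerance = 1e-9)
  }
})

test_that("membrane budget is additive under compartment splitting", {
  areas <- c(plasma = 10, mitochondria = 6, er = 4)
  split_areas <- c(plasma = 10, mitochondria = 6, er_a = 2.5, er_b = 1.5)
  a <- membrane_budget_table(areas, volume = 44)
  b <- membrane_budget_table(split_areas, volume = 44)
  expect_equal(a$total_fraction, b$total_fraction)
  expect_equal(a$internal_share, b$internal_share)
  expect_equal(sum(b$table$share[3:4]), a$table$share[3])
})

test_that("single-compartment inventories get the whole share", {
  mb <- membrane_budget_table(c(mitochondria = 3.0), volume = 1,
                              mean_lipid_cost = 440)
  expect_equal(mb$table$share, 1)
  expect_equal(mb$internal_share, 1)
  expect_equal(round(mb$total_fraction, 2), 0.15)
})

test_that("zero-area inventories warn and report zeros", {
  expect_warning(mb <- membrane_budget_table(c(plasma = 0, er = 0), volume = 1),
                 "zero")
  expect_equal(mb$total_fraction, 0)
  expect_equal(mb$table$cost_atp, c(0, 0))
})

test_that("published budget shares yield the printed internal-membrane splits", {
  ref <- membrane_budget_reference
  # mammalian (Ss) cell: 96% of membrane costs internal, ~29% of the budget
  ss <- ref[ref$species == "Ss", ]
  s <- membrane_share_summary(ss$membrane_fraction, ss$plasma)
  expect_equal(round(100 * s$internal_share), 96)
  expect_equal(round(100 * s$internal_fraction_of_total), 29)
  # Ostreococcus: even the smallest eukaryote keeps 44% of membrane
  # costs internal
  ot <- ref[ref$species == "Ot", ]
  expect_equal(round(100 * (1 - ot$plasma)), 44)
  # compartment shares as published sum to 1 per species
  shares <- as.matrix(ref[, c("plasma", "mitochondria", "nucleus",
                              "er_golgi", "vesicles_vacuoles")])
  expect_equal(unname(rowSums(shares)), rep(1, 4), tolerance = 0.01)
})

test_that("membrane inventories round-trip through TSV", {
  tab <- data.frame(
    species = c("sp1", "sp1", "sp2"),
    compartment = c("plasma", "mitochondria", "plasma"),
    area_um2 = c(12, 5, 3),
    mean_lipid_cost = c(143, 155, 123))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  inv <- read_membrane_inventory(path)
  expect_named(inv, c("sp1", "sp2"))
  expect_equal(unname(inv$sp1["mitochondria"]), 5)
  mb <- membrane_budget_table(inv$sp1, volume = 44,
                              mean_lipid_cost = attr(inv$sp1, "mean_lipid_cost"))
  expect_false(mb$generic_costs)
  expect_equal(sum(mb$table$share), 1)
})
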