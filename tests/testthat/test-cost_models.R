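# Lipid cost formulas, species overrides, composition averaging, and the
# ATP-vs-redox share arithmetic.

test_that("total lipid cost matches the published linear coefficients", {
  expect_identical(lipid_cost_total(16, 0, "bacteria"), 320)
  expect_identical(lipid_cost_total(16, 0, "eukaryote"), 340)
  expect_identical(lipid_cost_total(18, 1, "bacteria"), 320 + 38 * 2 + 6)
  # vectorised over chain length
  expect_equal(lipid_cost_total(c(16, 18), c(0, 1), "bacteria"), c(320, 402))
})

test_that("reduced lipid cost matches the published linear coefficients", {
  expect_identical(lipid_cost_reduced(16, 0, "bacteria"), 110)
  expect_identical(lipid_cost_reduced(16, 0, "eukaryote"), 120)
  expect_identical(lipid_cost_reduced(22, 6, "eukaryote"), 120 + 9 * 6 + 6 * 6)
})

test_that("lipid cost formulas reject and warn outside their domain", {
  expect_error(lipid_cost_total(0, 0, "bacteria"), "positive")
  expect_error(lipid_cost_total(-3, 0, "eukaryote"), "positive")
  expect_error(lipid_cost_total(16, -1, "bacteria"), "non-negative")
  expect_warning(lipid_cost_total(9, 0, "eukaryote"), "extrapolat")
  # very short chains push the bacterial total cost below zero
  expect_error(suppressWarnings(lipid_cost_total(5, 0, "bacteria")),
               "domain of validity")
})

test_that("cost surfaces are monotone, ordered, and in the published range", {
  grid <- expand.grid(NL = 14:22, NU = 0:6)
  for (domain in c("bacteria", "eukaryote")) {
    tot <- lipid_cost_total(grid$NL, grid$NU, domain)
    red <- lipid_cost_reduced(grid$NL, grid$NU, domain)
    # reduced (direct) cost is always below the full evolutionary cost
    expect_true(all(red < tot))
    # strictly increasing in each argument
    expect_true(all(lipid_cost_total(grid$NL + 1, grid$NU, domain) > tot))
    expect_true(all(lipid_cost_total(grid$NL, grid$NU + 1, domain) > tot))
    expect_true(all(lipid_cost_reduced(grid$NL + 1, grid$NU, domain) > red))
  }
  # eukaryotic synthesis is dearer at equal composition
  expect_true(all(lipid_cost_total(grid$NL, grid$NU, "eukaryote") >=
                    lipid_cost_total(grid$NL, grid$NU, "bacteria")))
  # brute-force enumeration over the membrane-lipid grid: totals span the
  # published ~200-600 ATP band, exactly [244, 616] at the grid corners
  all_tot <- c(lipid_cost_total(grid$NL, grid$NU, "bacteria"),
               lipid_cost_total(grid$NL, grid$NU, "eukaryote"))
  expect_identical(range(all_tot), c(244, 616))
})

test_that("species overrides take precedence and cardiolipin ships with them", {
  cl <- cardiolipin()
  expect_identical(species_cost(cl), 640)
  expect_identical(species_cost(cl, reduced = TRUE), 240)
  plain <- lipid_species("POPC-like", "bacteria", 16, 0)
  expect_identical(species_cost(plain), 320)
  expect_identical(species_cost(plain, reduced = TRUE), 110)
})

test_that("lipid_species validates its overrides", {
  expect_error(lipid_species("x", "bacteria", 16, 0, total_cost_override = -1),
               "positive")
  expect_error(lipid_species("x", "bacteria", 16, 0,
                             total_cost_override = 100,
                             reduced_cost_override = 200),
               "cannot exceed")
  expect_error(lipid_species("x", "bacteria", chain_length = 0), ">= 1")
})

test_that("mean membrane cost is the mole-fraction weighted mean", {
  one <- membrane_composition(list(lipid_species("a", "eukaryote", 18.5, 0)), 1)
  expect_equal(mean_membrane_cost(one), 340 + 40 * 2.5)
  mix <- membrane_composition(
    list(lipid_species("a", "bacteria", 16, 0),
         lipid_species("b", "bacteria", 16, 0, total_cost_override = 400)),
    c(0.5, 0.5))
  expect_equal(mean_membrane_cost(mix), 360)
  expect_error(membrane_composition(list(), numeric(0)), "at least one")
  expect_error(
    membrane_composition(list(lipid_species("a", "bacteria")), 0.9),
    "sum to 1")
})

test_that("lipid composition tables round-trip through TSV", {
  tab <- data.frame(
    name = c("lipidA", "cardiolipin"),
    domain = c("eukaryote", "eukaryote"),
    chain_length = c(18, 18),
    unsaturations = c(1, 2),
    fraction = c(0.8, 0.2),
    total_cost_override = c(NA, 640),
    reduced_cost_override = c(NA, 240))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- read_lipid_composition(path)
  expect_s3_class(comp, "membrane_composition")
  expect_equal(mean_membrane_cost(comp),
               0.8 * (340 + 40 * 2 + 6) + 0.2 * 640)
})

test_that("ATP hydrolysis share follows 1/(1 + r k) and is monotone", {
  expect_equal(atp_hydrolysis_share(1.5, 3), 1 / 5.5)
  expect_equal(atp_hydrolysis_share(2, 3), 1 / 7)
  expect_identical(atp_hydrolysis_share(0, 3), 1)
  r <- seq(0, 5, by = 0.25)
  shares <- atp_hydrolysis_share(r)
  expect_true(all(shares > 0 & shares <= 1))
  expect_true(all(diff(shares) < 0))
  expect_error(atp_hydrolysis_share(-1), "non-negative")
  expect_error(atp_hydrolysis_share(1, 0), "positive")
})

test_that("monomer cost table carries validated defaults", {
  tab <- monomer_cost_table()
  expect_equal(tab$amino_acid_cost, 30)
  expect_equal(tab$nucleotide_cost, 50)
  expect_equal(tab$atp_equiv_per_redox, 3)
  expect_error(monomer_cost_table(amino_acid_cost = 0), "positive")
})
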