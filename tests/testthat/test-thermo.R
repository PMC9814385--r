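# fixed random property table over the library for the oracle comparisons
.thermo_fixture <- function(seed = 77) {
  generate_thermo_table(rxn_library(), seed = seed)
}

test_that("species Gibbs energy honours both sign conventions", {
  expect_identical(gibbs_of_species(1.0, 0, 300), 1.0)
  expect_equal(gibbs_of_species(0, 0.5 / 300, 300, "standard"), -0.5)
  expect_equal(gibbs_of_species(0, 0.5 / 300, 300, "published"), 0.5)
  expect_error(gibbs_of_species(1, 1, -5), class = "rxnvae_thermo_error")
  # agreement with a one-line recomputation on random tables
  set.seed(12)
  H <- rnorm(50); S <- runif(50, 1e-4, 3e-3); T_K <- runif(50, 200, 400)
  expect_equal(gibbs_of_species(H, S, T_K), H - T_K * S, tolerance = 1e-12)
  expect_equal(gibbs_of_species(H, S, T_K, "published"), H + T_K * S, tolerance = 1e-12)
})

test_that("reaction aggregates are zero on identity, antisymmetric, homogeneous", {
  tab <- .thermo_fixture()
  id <- "O=C=O + 2[H][H] >> 2[H][H] + O=C=O"
  expect_identical(reaction_gibbs(id, tab), 0)
  expect_identical(reaction_entropy_diff(id, tab), 0)
  expect_identical(reaction_dipole_diff(id, tab), 0)

  fwd <- "2[H][H] + O=O >> 2O"
  rev <- "2O >> 2[H][H] + O=O"
  dbl <- "4[H][H] + 2O=O >> 4O"
  expect_equal(reaction_gibbs(fwd, tab), -reaction_gibbs(rev, tab))
  expect_equal(reaction_entropy_diff(fwd, tab), -reaction_entropy_diff(rev, tab))
  expect_equal(reaction_dipole_diff(fwd, tab), -reaction_dipole_diff(rev, tab))
  expect_equal(reaction_gibbs(dbl, tab), 2 * reaction_gibbs(fwd, tab))
  expect_equal(reaction_entropy_diff(dbl, tab), 2 * reaction_entropy_diff(fwd, tab))

  expect_error(reaction_gibbs("C >> C#C", data.frame(
    canonical_smiles = "C", H_eV = 0, S_eV_per_K = 0, dipole_debye = 0
  )), class = "rxnvae_thermo_error", regexp = "missing")
})

test_that("reaction aggregates match a brute-force weighted-sum oracle", {
  tab <- .thermo_fixture()
  lut <- function(canon, col) tab[[col]][match(canon, tab$canonical_smiles)]
  corpus <- generate_corpus(generator_config(n_equations = 50, seed = 55))$lines
  for (line in corpus[1:25]) {
    eq <- parse_reaction_string(line)
    w <- function(side, col) {
      sum(vapply(side, function(tm) {
        tm$coefficient * lut(tm$species$canonical_smiles, col)
      }, 0))
    }
    T_K <- 298.15
    g_oracle <- (w(eq$products, "H_eV") - T_K * w(eq$products, "S_eV_per_K")) -
      (w(eq$reactants, "H_eV") - T_K * w(eq$reactants, "S_eV_per_K"))
    expect_equal(reaction_gibbs(eq, tab), g_oracle, tolerance = 1e-12)
    expect_equal(reaction_entropy_diff(eq, tab),
                 w(eq$products, "S_eV_per_K") - w(eq$reactants, "S_eV_per_K"),
                 tolerance = 1e-12)
    expect_equal(reaction_dipole_diff(eq, tab),
                 w(eq$products, "dipole_debye") - w(eq$reactants, "dipole_debye"),
                 tolerance = 1e-12)
  }
})

test_that("planted hydrogen-combustion thermodynamics are recovered exactly", {
  tab <- generate_thermo_table(seed = 3)
  # planted: H2 (0 eV, 1e-3 eV/K), O2 (0, 2e-3), H2O (-2.5, 1.5e-3)
  T_K <- 298.15
  hand <- 2 * (-2.5 - T_K * 1.5e-3) - (2 * (0 - T_K * 1e-3) + (0 - T_K * 2e-3))
  expect_equal(reaction_gibbs("2[H][H] + O=O >> 2O", tab, T_K), hand,
               tolerance = 1e-12)
  expect_equal(reaction_entropy_diff("2[H][H] + O=O >> 2O", tab),
               2 * 1.5e-3 - (2 * 1e-3 + 2e-3), tolerance = 1e-15)
  expect_equal(reaction_dipole_diff("2[H][H] + O=O >> 2O", tab),
               2 * 1.85, tolerance = 1e-12)
})

test_that("dipole moment is a charge-weighted position sum", {
  two <- data.frame(element = c("H", "H"), q = c(1, -1),
                    x = c(1, -1), y = 0, z = 0)
  d <- dipole_moment(two)
  expect_equal(d$vector, c(2, 0, 0))
  expect_equal(d$magnitude, 2)

  one <- data.frame(element = "H", q = 1, x = 0, y = 0, z = 0)
  expect_equal(dipole_moment(one, origin = "none")$vector, c(0, 0, 0))

  # naive-summation oracle on random 50-atom sets
  set.seed(9)
  for (rep in 1:5) {
    atoms <- data.frame(
      element = sample(c("H", "C", "N", "O"), 50, replace = TRUE),
      q = rnorm(50), x = rnorm(50), y = rnorm(50), z = rnorm(50)
    )
    got <- dipole_moment(atoms, origin = "none")
    want <- c(sum(atoms$q * atoms$x), sum(atoms$q * atoms$y), sum(atoms$q * atoms$z))
    expect_equal(got$vector, want, tolerance = 1e-12)
    expect_equal(got$magnitude, sqrt(sum(want^2)), tolerance = 1e-12)
  }
})

test_that("dipole vector is translation-invariant exactly for neutral sets", {
  set.seed(21)
  atoms <- data.frame(element = sample(c("H", "O"), 10, replace = TRUE),
                      q = rnorm(10), x = rnorm(10), y = rnorm(10), z = rnorm(10))
  neutral <- atoms
  neutral$q <- neutral$q - mean(neutral$q)  # total charge 0
  shift <- function(df) { df$x <- df$x + 3.7; df$y <- df$y - 1.2; df }
  expect_equal(dipole_moment(neutral, "none")$vector,
               dipole_moment(shift(neutral), "none")$vector, tolerance = 1e-12)
  expect_gt(sum(abs(dipole_moment(atoms, "none")$vector -
                    dipole_moment(shift(atoms), "none")$vector)), 1e-6)
  # charge-center origin removes the dependence on the coordinate frame origin
  expect_equal(dipole_moment(atoms, "charge_center")$vector,
               dipole_moment(shift(atoms), "charge_center")$vector,
               tolerance = 1e-12)
})

test_that("stability filter keeps the boundary and matches a counting oracle", {
  expect_true(stability_filter(5.0))
  expect_false(stability_filter(5.0001))
  expect_true(stability_filter(0))
  set.seed(31)
  dg <- runif(1000, -8, 8)
  kept <- stability_filter(dg)
  expect_identical(sum(kept), sum(abs(dg) <= 5))
  expect_identical(kept, abs(dg) <= 5)
})

test_that("property table IO enforces the unit-labelled schema", {
  tab <- .thermo_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write_thermo_table(tab, f)
  back <- read_thermo_table(f)
  expect_equal(back$H_eV, tab$H_eV, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,H,S,mu", "O,1,2,3"), bad)
  expect_error(read_thermo_table(bad), class = "rxnvae_thermo_error")
})
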