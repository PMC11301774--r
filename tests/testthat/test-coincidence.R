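test_that("enumeration over a two-residue alphabet matches brute force", {
  sets <- enumerate_compositions(150, alphabet = c("G", "A"),
                                 mod_table = NULL)
  expect_identical(nrow(sets), 5L)
  expect_setequal(sets$composition, c("G", "A", "G+G", "A+G", "A+A"))
  expect_equal(sort(sets$mass),
               c(57.02146, 71.03711, 114.04293, 128.05858, 142.07422),
               tolerance = 1e-4)
})

test_that("a bound below the lightest residue yields nothing", {
  expect_identical(nrow(enumerate_compositions(50, mod_table = NULL)), 0L)
})

test_that("full enumeration to 200 Da keeps N and GG as distinct sets", {
  sets <- enumerate_compositions(200)
  expect_true("N" %in% sets$composition)
  expect_true("G+G" %in% sets$composition)
  m_n <- sets$mass[sets$composition == "N"]
  m_gg <- sets$mass[sets$composition == "G+G"]
  expect_lt(abs(m_n - m_gg), 1e-6)
  # modified tokens are enumerated alongside the plain ones; fixed
  # carbamidomethyl replaces bare C entirely
  expect_true(any(grepl("Oxidation", sets$composition)))
  expect_false("C" %in% sets$composition)
  expect_true("C[Carbamidomethyl]" %in% sets$composition)
  # at most one N-terminal pyro-Glu token per composition
  n_pyro <- vapply(strsplit(sets$composition, "+", fixed = TRUE),
                   function(x) sum(grepl("pyro", x)), integer(1))
  expect_true(all(n_pyro <= 1L))
})

test_that("greedy mass merging is chained, not radius-based", {
  expect_identical(count_unique_masses(c(57.02, 71.04, 114.04, 114.04),
                                       0.01), 3L)
  # chained merging: adjacent gaps within precision collapse the run even
  # though the extremes differ by more than the precision
  expect_identical(count_unique_masses(c(100.00, 100.009, 100.018), 0.01),
                   1L)
  m <- c(57.02146, 71.03711, 99.06841, 113.08406)
  expect_identical(count_unique_masses(m, 0), 4L)
})

test_that("greedy merge equals the pairwise-merge oracle", {
  withr::local_seed(11)
  for (rep in 1:25) {
    masses <- sort(runif(sample(2:12, 1), 50, 60))
    prec <- runif(1, 0, 0.5)
    expect_identical(count_unique_masses(masses, prec),
                     oracle_groups(masses, prec))
  }
  # and on a real enumeration over a 4-residue alphabet up to 300 Da
  sets <- enumerate_compositions(300, alphabet = c("G", "A", "S", "N"),
                                 mod_table = NULL)
  for (prec in c(0, 0.005, 0.02, 0.05, 0.5)) {
    expect_identical(count_unique_masses(sets$mass, prec),
                     oracle_groups(sets$mass, prec))
  }
})

test_that("survival fraction is monotone and collapses known coincidences", {
  grid <- survival_curve(c(0, 0.005, 0.02, 0.04, 0.1),
                         c(115, 150, 200, 250))
  expect_true(all(grid$fraction > 0 & grid$fraction <= 1))
  for (mm in unique(grid$max_mass)) {
    fr <- grid$fraction[grid$max_mass == mm]
    expect_true(all(diff(fr) <= 1e-12))  # non-increasing in precision
  }
  # non-increasing in the mass bound throughout the accumulation regime
  # (>= 150 Da, where multi-residue coincidences pile up faster than new
  # well-separated compositions appear)
  for (pr in unique(grid$precision)) {
    fr <- grid$fraction[grid$precision == pr & grid$max_mass >= 150]
    expect_true(all(diff(fr) <= 1e-12))
  }
  # GG = N collapses even at precision 0 once the bound admits them
  at0 <- grid[grid$precision == 0 & grid$max_mass == 115, ]
  expect_lt(at0$fraction, 1)
})

test_that("K/Q merge at 0.04 Da precision but not at 0.02 Da", {
  sets <- enumerate_compositions(150, alphabet = c("K", "Q"),
                                 mod_table = NULL)
  kq <- sets$mass[sets$length == 1L]
  expect_identical(count_unique_masses(kq, 0.02), 2L)
  expect_identical(count_unique_masses(kq, 0.04), 1L)
})

test_that("a lone residue alphabet survives any sub-gap precision", {
  grid <- survival_curve(0.01, 120, alphabet = "G", mod_table = NULL)
  expect_identical(grid$fraction, 1)
})
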