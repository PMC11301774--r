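test_that("the substitution table holds exactly the mass-silent pairs", {
  tab <- isobaric_substitution_table()
  expect_true(all(c("N", "GG") %in% tab$from))
  expect_true(any(tab$from == "N" & tab$to == "GG"))
  expect_true(any(tab$from == "Q" & tab$to %in% c("GA", "AG")))
  expect_true(any(tab$from == "AS" & tab$to %in% c("GT", "TG")))
  # every pair is exactly mass-silent and never a pure I/L respelling
  for (i in seq_len(nrow(tab))) {
    expect_lt(mass_difference(tab$from[i], tab$to[i]), 1e-6)
  }
  expect_false(any(tab$from == "I" & tab$to == "L"))
  # cross-check against the coincidence enumeration: both sides of every
  # pair sit in the same exact-mass group
  sets <- enumerate_compositions(2 * max(residue_masses()),
                                 mod_table = NULL)
  grp <- cumsum(c(TRUE, diff(sets$mass) > 1e-6))
  key <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "+")
  for (i in sample(nrow(tab), 10)) {
    ga <- grp[match(key(tab$from[i]), sets$composition)]
    gb <- grp[match(key(tab$to[i]), sets$composition)]
    expect_identical(ga, gb)
  }
})

test_that("zero error rates give exact substrings of the truth", {
  spec <- fixture_spec(seed = 41, rotation_rate = 0, isobaric_rate = 0)
  gen <- generate_reads(spec)
  for (i in seq_len(nrow(gen$reads))) {
    chain <- gen$placements$chain[i]
    expect_true(grepl(gen$reads$sequence[i], spec$truth[[chain]],
                      fixed = TRUE))
    # the recorded placement is where the read came from
    start <- gen$placements$start[i]
    expect_identical(substr(spec$truth[[chain]], start + 1,
                            start + nchar(gen$reads$sequence[i])),
                     gen$reads$sequence[i])
  }
})

test_that("rotation rate one yields exactly one adjacent transposition", {
  spec <- fixture_spec(seed = 43, rotation_rate = 1, isobaric_rate = 0)
  gen <- generate_reads(spec)
  rotated <- which(gen$placements$error == "rotation")
  expect_gt(length(rotated), 0.9 * nrow(gen$reads))
  for (i in rotated[1:20]) {
    read <- strsplit(gen$reads$sequence[i], "")[[1]]
    chain <- gen$placements$chain[i]
    start <- gen$placements$start[i]
    truth <- strsplit(substr(spec$truth[[chain]], start + 1,
                             start + length(read)), "")[[1]]
    diff_pos <- which(read != truth)
    expect_identical(length(diff_pos), 2L)
    expect_identical(diff(diff_pos), 1L)
    expect_identical(read[diff_pos], truth[rev(diff_pos)])
  }
})

test_that("isobaric injections are mass-silent against the truth", {
  spec <- fixture_spec(seed = 47, rotation_rate = 0, isobaric_rate = 1)
  gen <- generate_reads(spec)
  iso <- which(gen$placements$error == "isobaric")
  expect_gt(length(iso), 0)
  for (i in iso[seq_len(min(20, length(iso)))]) {
    chain <- gen$placements$chain[i]
    start <- gen$placements$start[i]
    read <- gen$reads$sequence[i]
    truth_all <- spec$truth[[chain]]
    # the substitution may change the read length by one; the read's
    # total mass equals the mass of the truth window it was cut from
    ok <- any(vapply(nchar(read) + (-1:1), function(L0) {
      win <- substr(truth_all, start + 1, start + L0)
      nchar(win) == L0 &&
        abs(sequence_mass(read) - sequence_mass(win)) < 1e-6
    }, logical(1)))
    expect_true(ok)
    expect_false(identical(read, substr(truth_all, start + 1,
                                        start + nchar(read))))
  }
})

test_that("identical seeds reproduce identical fixtures", {
  s1 <- fixture_spec(seed = 7); s2 <- fixture_spec(seed = 7)
  expect_identical(s1$truth, s2$truth)
  g1 <- generate_reads(s1); g2 <- generate_reads(s2)
  expect_identical(g1$reads$sequence, g2$reads$sequence)
  expect_identical(g1$reads$alc, g2$reads$alc)
  expect_identical(g1$reads$local_confidence, g2$reads$local_confidence)
  expect_identical(g1$placements, g2$placements)
  sp1 <- generate_spectra("GAISK", seed = 3)
  sp2 <- generate_spectra("GAISK", seed = 3)
  expect_identical(sp1, sp2)
  expect_false(identical(fixture_spec(seed = 8)$truth, s1$truth))
})

test_that("ALC tracks the injected error count", {
  spec <- fixture_spec(seed = 53, rotation_rate = 0.5, isobaric_rate = 0.3)
  gen <- generate_reads(spec)
  has_err <- gen$placements$error != "none"
  expect_gt(min(gen$reads$alc[!has_err]), max(50, 85))
  expect_lt(mean(gen$reads$alc[has_err]), mean(gen$reads$alc[!has_err]))
})

test_that("the fixture bundle doubles as reader input", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 61, coverage_depth = 1)
  paths <- write_fixture_bundle(spec, dir)
  expect_true(all(file.exists(paths)))
  back <- read_peaks_csv(paths[["reads"]])
  gen <- generate_reads(spec)
  expect_identical(back$reads$sequence, gen$reads$sequence)
  expect_identical(back$reads$alc, gen$reads$alc)
  tpl <- read_templates_fasta(paths[["templates"]])
  expect_identical(tpl, spec$templates)
  spectra <- read_mgf(paths[["spectra"]])
  expect_length(spectra, nrow(gen$reads))
})
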