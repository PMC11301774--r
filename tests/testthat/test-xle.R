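test_that("fragment series follow standard offsets", {
  y <- theoretical_fragments("GG", 1, "y")
  expect_equal(y$neutral_mass, 57.02146 + 18.01056, tolerance = 1e-5)
  bz <- theoretical_fragments("PEPTIDE", 2, c("b", "y", "c", "z"))
  expect_identical(nrow(bz), 4L * 6L * 2L)
  # monotone within a series at fixed charge
  b1 <- bz[bz$type == "b" & bz$charge == 1, ]
  expect_true(all(diff(b1$mz) > 0))
  # c = b + NH3; z = y - NH3 + H
  b <- bz[bz$type == "b" & bz$charge == 1, ]
  cc <- bz[bz$type == "c" & bz$charge == 1, ]
  expect_equal(cc$neutral_mass - b$neutral_mass, rep(17.02655, 6),
               tolerance = 1e-4)
  expect_identical(nrow(theoretical_fragments("PEPTIDE", 1,
                                              character(0))), 0L)
  expect_error(theoretical_fragments("PEZTIDE"), "Z")
})

test_that("satellite losses carry the nominal 15/29/43 Da masses", {
  losses <- satellite_losses()
  expect_identical(round(unname(losses)), c(15, 29, 43))
  expect_equal(unname(losses), c(15.0235, 29.0391, 43.0548),
               tolerance = 1e-4)
  # w-ion of a z-ion ending in L sits 43.0548 below the z mass
  z <- theoretical_fragments("GLK", 1, "z")
  z2 <- z$neutral_mass[z$index == 2]  # spans L-K
  w <- z2 - losses[["L_C3H7"]]
  expect_equal(z2 - w, 43.0548, tolerance = 1e-4)
})

test_that("peak matching respects the ppm tolerance", {
  th <- theoretical_fragments("PEPTIDE", 1, c("b", "y"))
  sp <- list(mz = th$mz, intensity = rep(100, nrow(th)))
  ann <- match_peaks(sp, th, tolerance = 20)
  expect_true(all(!is.na(ann$peak_mz)))
  expect_true(all(abs(ann$delta) < 1e-9))
  # a peak 25 ppm off stays unmatched at 20 ppm
  one <- th[1, ]
  off <- list(mz = one$mz * (1 + 25e-6), intensity = 1)
  expect_true(is.na(match_peaks(off, one, 20)$peak_mz))
  expect_false(is.na(match_peaks(off, one, 30)$peak_mz))
})

test_that("satellite evidence drives the I/L call", {
  # GALSK: one Xle site, L at 0-based position 2
  sp_l <- generate_spectra("GALSK", satellite_probability = 1, seed = 3)
  calls <- assign_xle("GALSK", sp_l)
  expect_identical(calls$call[calls$position == 2], "L")
  expect_identical(calls$basis[calls$position == 2], "satellite")

  sp_i <- generate_spectra("GAISK", xle_truth = "GAISK",
                           satellite_probability = 1, seed = 4)
  calls_i <- assign_xle("GAISK", sp_i)
  expect_identical(calls_i$call[calls_i$position == 2], "I")
  expect_true(grepl("I_", calls_i$matched_losses[calls_i$position == 2]))
})

test_that("without satellites the germline/L fallback applies", {
  calls <- assign_xle("GALSK", spectrum = NULL, germline = "GAISK")
  expect_identical(calls$call, "I")
  expect_identical(calls$basis, "germline")
  # germline residue is not I/L: default to L
  calls2 <- assign_xle("GALSK", spectrum = NULL, germline = "GAVSK")
  expect_identical(calls2$call, "L")
  expect_identical(calls2$basis, "default_L")
  # no germline supplied at all
  calls3 <- assign_xle("GAISK", spectrum = NULL)
  expect_identical(calls3$call, "L")
  expect_identical(calls3$basis, "default_L")
})

test_that("calls never contradict their matched losses", {
  withr::local_seed(9)
  aa <- setdiff(names(residue_masses()), c("I", "L"))
  for (rep in 1:15) {
    chars <- sample(aa, 8, TRUE)
    pos <- sample(2:7, 2)
    chars[pos] <- sample(c("I", "L"), 2, TRUE)
    pep <- paste(chars, collapse = "")
    sp <- generate_spectra(pep, satellite_probability = 1,
                           noise_peaks = 30, seed = rep)
    calls <- assign_xle(pep, sp)
    for (i in seq_len(nrow(calls))) {
      ml <- strsplit(calls$matched_losses[i], ",")[[1]]
      if (calls$basis[i] == "satellite" && calls$call[i] == "I") {
        expect_true(any(startsWith(ml, "I_")))
      }
      if (calls$basis[i] == "satellite" && calls$call[i] == "L") {
        expect_true(any(startsWith(ml, "L_")))
      }
    }
  }
})

test_that("round-trip recovery on satellite-bearing synthetic spectra", {
  withr::local_seed(17)
  aa <- setdiff(names(residue_masses()), c("I", "L"))
  n_pos <- 0L; n_correct <- 0L
  for (rep in 1:40) {
    chars <- sample(aa, sample(7:12, 1), TRUE)
    k <- sample(seq_along(chars)[-1], sample(1:3, 1))
    chars[k] <- sample(c("I", "L"), length(k), TRUE)
    pep <- paste(chars, collapse = "")
    sp <- generate_spectra(pep, satellite_probability = 1,
                           noise_peaks = 25, seed = rep * 7L)
    calls <- assign_xle(pep, sp)
    truth <- chars[calls$position + 1L]
    n_pos <- n_pos + nrow(calls)
    n_correct <- n_correct + sum(calls$call == truth)
  }
  expect_gte(n_correct / n_pos, 0.99)
})

test_that("spectra without satellites reproduce the fallback rule exactly", {
  withr::local_seed(23)
  pep <- "KASILGNTLK"
  germ <- "KASLLGNILK"
  sp <- generate_spectra(pep, satellite_probability = 0,
                         noise_peaks = 10, seed = 5)
  calls <- assign_xle(pep, sp, germline = germ)
  gchars <- strsplit(germ, "")[[1]]
  for (i in seq_len(nrow(calls))) {
    g <- gchars[calls$position[i] + 1L]
    expect_identical(calls$call[i], if (g %in% c("I", "L")) g else "L")
    expect_true(calls$basis[i] %in% c("germline", "default_L"))
  }
})

test_that("MGF round-trips spectra", {
  sp <- generate_spectra("GAISK", satellite_probability = 1,
                         noise_peaks = 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(sp), path)
  back <- read_mgf(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$mz, sp$mz, tolerance = 1e-7)
  expect_equal(back[[1]]$intensity, sp$intensity, tolerance = 1e-5)
  expect_identical(back[[1]]$title, sp$title)
  expect_identical(back[[1]]$precursor_charge, sp$precursor_charge)
})
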