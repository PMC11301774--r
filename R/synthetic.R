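# Seeded synthetic fixtures: ground-truth antibody chains derived from the
# shipped mini germline set, error-injected peptide reads emulating the
# four categories of MS-based sequencing errors, and fragmentation spectra
# with satellite ions for I/L positions. All randomness flows from the
# fixture seed through R's default RNG, so identical seeds give identical
# fixtures.

#' Shipped synthetic germline template set
#'
#' A small, hand-composed germline-like V/J/C segment set for heavy and
#' light chains (clearly synthetic, not derived from any germline
#' database), shipped as `extdata/templates_synthetic.fasta`.
#'
#' @return Template data.frame (see [read_templates_fasta()]).
#' @export
synthetic_templates <- function() {
  read_templates_fasta(system.file("extdata", "templates_synthetic.fasta",
                                   package = "massalign", mustWork = TRUE))
}

#' Exact-composition isobaric substitution table
#'
#' Enumerates all pairs of residue-sequence spellings up to `max_len`
#' residues whose masses coincide exactly (same elemental composition)
#' but whose residue multisets differ -- the substitutions a mass
#' spectrometer cannot see (N = GG, Q = GA, AS = GT and their
#' rearrangements). I/L swaps are excluded (their own error category).
#'
#' @param max_len Maximum spelling length per side (default 2).
#' @return data.frame with columns `from`, `to`.
#' @export
isobaric_substitution_table <- function(max_len = 2L) {
  aa <- setdiff(names(residue_masses()), character(0))
  spellings <- aa
  cur <- aa
  for (len in seq_len(max_len)[-1]) {
    cur <- as.vector(outer(cur, aa, paste0))
    spellings <- c(spellings, cur)
  }
  mass <- vapply(spellings, sequence_mass, numeric(1))
  comp <- vapply(strsplit(spellings, ""), function(x) {
    paste(sort(x), collapse = "")
  }, character(1))
  ord <- order(mass)
  spellings <- spellings[ord]; mass <- mass[ord]; comp <- comp[ord]
  grp <- cumsum(c(TRUE, diff(mass) > 1e-6))
  out <- list()
  for (g in split(seq_along(spellings), grp)) {
    if (length(g) < 2L) next
    for (i in g) for (j in g) {
      if (i == j || comp[i] == comp[j]) next
      # exclude pure I/L respellings (category-1, not category-2)
      if (chartr("I", "L", comp[i]) == chartr("I", "L", comp[j])) next
      out[[length(out) + 1L]] <- data.frame(
        from = spellings[i], to = spellings[j], stringsAsFactors = FALSE)
    }
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Specification of a synthetic antibody fixture
#'
#' Bundles the ground truth and all generation parameters. The truth
#' chains are built from the shipped germline set by somatic-hypermutation
#' style substitutions in V and J plus a randomly drawn CDRH3 junction, so
#' the truth differs from the templates the way a mature antibody differs
#' from its germline precursor.
#'
#' @param seed Integer seed fixing all downstream randomness.
#' @param n_mutations_v,n_mutations_j Substitutions introduced into each
#'   V (default 8) and J (default 1) segment.
#' @param cdrh3_len Length of the random CDRH3 core between the V-encoded
#'   `AR` and the J-proximal `FDY` (default 11, giving a 15-residue
#'   junction, the typical human CDRH3 length).
#' @param read_length Integer range of read lengths (default 8:18; long
#'   enough that anchored reads can reach the middle of a 15-residue
#'   CDRH3 junction).
#' @param coverage_depth Mean per-position read depth (default 6).
#' @param rotation_rate,isobaric_rate Per-read probabilities of injecting
#'   one adjacent-transposition, respectively one exact-mass substitution
#'   (category-2 errors; defaults 0.05 + 0.05 = 10% of reads).
#' @param near_isobaric_rate Per-read probability of a K<->Q swap
#'   (category 3; default 0).
#' @param deamidation_rate Per-read probability of N->D / Q->E
#'   (category 4; default 0).
#' @param il_swap_rate Per-read probability of an I<->L swap
#'   (category 1; default 0).
#' @param satellite_probability Probability that a spectrum carries the
#'   w-ions for an I/L position (default 1).
#' @param templates Template set (default [synthetic_templates()]).
#' @return A `fixture_spec` list, including `truth` (named character
#'   vector, one sequence per chain) and `cdrh3` (the planted junction).
#' @export
fixture_spec <- function(seed = 1L, n_mutations_v = 8L, n_mutations_j = 1L,
                         cdrh3_len = 11L, read_length = 8:18,
                         coverage_depth = 6, rotation_rate = 0.05,
                         isobaric_rate = 0.05, near_isobaric_rate = 0,
                         deamidation_rate = 0, il_swap_rate = 0,
                         satellite_probability = 1,
                         templates = synthetic_templates()) {
  rates <- c(rotation_rate, isobaric_rate, near_isobaric_rate,
             deamidation_rate, il_swap_rate, satellite_probability)
  stopifnot(all(rates >= 0), all(rates <= 1),
            sum(rotation_rate, isobaric_rate, near_isobaric_rate,
                deamidation_rate, il_swap_rate) <= 1)
  set.seed(seed)
  aa <- names(residue_masses())
  mutate <- function(seq, n) {
    ch <- strsplit(seq, "")[[1]]
    if (n > 0L) {
      idx <- sample(length(ch), min(n, length(ch)))
      for (i in idx) {
        ch[i] <- sample(setdiff(aa, ch[i]), 1L)
      }
    }
    paste(ch, collapse = "")
  }
  truth <- character(0)
  cdrh3 <- character(0)
  for (chain in unique(templates$chain)) {
    segs <- templates[templates$chain == chain, , drop = FALSE]
    pick <- function(cls) {
      s <- segs[segs$segment_class == cls, , drop = FALSE]
      if (nrow(s)) s$sequence[1] else ""
    }
    v <- mutate(pick("V"), n_mutations_v)
    j <- mutate(pick("J"), n_mutations_j)
    jx <- if (chain == "heavy") {
      core <- paste(sample(setdiff(aa, c("C", "X")), cdrh3_len,
                           replace = TRUE), collapse = "")
      paste0("D", core, "FDY")
    } else {
      ""  # light CDR3 is fully V/J encoded
    }
    truth[chain] <- paste0(v, jx, j, pick("C"))
    cdrh3[chain] <- jx
  }
  structure(list(seed = seed, templates = templates, truth = truth,
                 cdrh3 = cdrh3, read_length = read_length,
                 coverage_depth = coverage_depth,
                 rotation_rate = rotation_rate,
                 isobaric_rate = isobaric_rate,
                 near_isobaric_rate = near_isobaric_rate,
                 deamidation_rate = deamidation_rate,
                 il_swap_rate = il_swap_rate,
                 satellite_probability = satellite_probability),
            class = "fixture_spec")
}

inject_category2 <- function(chars, kind, subs_table) {
  # returns list(chars, window = c(start, end) on the modified read, or NULL)
  n <- length(chars)
  if (kind == "rotation") {
    cand <- which(chars[-n] != chars[-1])
    if (!length(cand)) return(NULL)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    chars[c(i, i + 1L)] <- chars[c(i + 1L, i)]
    return(list(chars = chars, window = c(i, i + 1L)))
  }
  # isobaric substitution: find occurrences of any 'from' spelling
  seq <- paste(chars, collapse = "")
  hits <- list()
  for (r in seq_len(nrow(subs_table))) {
    from <- subs_table$from[r]
    starts <- gregexpr(from, seq, fixed = TRUE)[[1]]
    if (starts[1] > 0) {
      for (s in starts) {
        hits[[length(hits) + 1L]] <- list(start = s, from = from,
                                          to = subs_table$to[r])
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- hits[[if (length(hits) == 1L) 1L else sample(length(hits), 1L)]]
  pre <- if (h$start > 1L) chars[seq_len(h$start - 1L)] else character(0)
  post_start <- h$start + nchar(h$from)
  post <- if (post_start <= n) chars[post_start:n] else character(0)
  new <- c(pre, strsplit(h$to, "")[[1]], post)
  list(chars = new, window = c(h$start, h$start + nchar(h$to) - 1L))
}

#' Generate error-injected peptide reads from a fixture
#'
#' Tiles seeded reads over each truth chain and injects per-read errors
#' at the configured rates: adjacent transpositions (rotations), exact
#' isobaric substitutions drawn from [isobaric_substitution_table()],
#' K/Q near-isobaric swaps, deamidation (N->D, Q->E) and I/L swaps. The
#' ALC is assigned inversely to the number of injected errors, and the
#' local confidence is depressed inside the error window.
#'
#' @param spec A [fixture_spec()].
#' @return list: `reads` (a `peptide_reads` table) and `placements`
#'   (data.frame with the true chain, start (0-based) and error
#'   bookkeeping per read).
#' @export
generate_reads <- function(spec) {
  set.seed(spec$seed + 1L)
  subs <- isobaric_substitution_table()
  reads_seq <- character(0); alc <- numeric(0); area <- numeric(0)
  conf <- list(); sref <- character(0)
  pl_chain <- character(0); pl_start <- integer(0); pl_err <- character(0)
  for (chain in names(spec$truth)) {
    truth <- strsplit(spec$truth[[chain]], "")[[1]]
    n <- length(truth)
    n_reads <- ceiling(spec$coverage_depth * n / mean(spec$read_length))
    for (k in seq_len(n_reads)) {
      len <- min(n, sample(spec$read_length, 1L))
      # windows may overhang either terminus and are clipped to the chain
      # (to a minimum of 6 residues), mimicking the short terminal
      # peptides of a real digest; interior tiling alone would leave the
      # chain ends systematically under-covered
      lo <- -(len - 6L); hi <- n - 6L
      start <- sample(lo:hi, 1L)
      a <- max(0L, start); b <- min(n, start + len)
      start <- a
      chars <- truth[(a + 1L):b]
      u <- stats::runif(1)
      err <- "none"; window <- NULL
      thresholds <- cumsum(c(spec$rotation_rate, spec$isobaric_rate,
                             spec$near_isobaric_rate,
                             spec$deamidation_rate, spec$il_swap_rate))
      if (u < thresholds[1]) {
        res <- inject_category2(chars, "rotation", subs)
        if (!is.null(res)) {
          chars <- res$chars; window <- res$window; err <- "rotation"
        }
      } else if (u < thresholds[2]) {
        res <- inject_category2(chars, "isobaric", subs)
        if (is.null(res)) res <- inject_category2(chars, "rotation", subs)
        if (!is.null(res)) {
          chars <- res$chars; window <- res$window; err <- "isobaric"
        }
      } else if (u < thresholds[3]) {
        cand <- which(chars %in% c("K", "Q"))
        if (length(cand)) {
          i <- if (length(cand) == 1L) cand else sample(cand, 1L)
          chars[i] <- if (chars[i] == "K") "Q" else "K"
          window <- c(i, i); err <- "near_isobaric"
        }
      } else if (u < thresholds[4]) {
        cand <- which(chars %in% c("N", "Q"))
        if (length(cand)) {
          i <- if (length(cand) == 1L) cand else sample(cand, 1L)
          chars[i] <- if (chars[i] == "N") "D" else "E"
          window <- c(i, i); err <- "deamidation"
        }
      } else if (u < thresholds[5]) {
        cand <- which(chars %in% c("I", "L"))
        if (length(cand)) {
          i <- if (length(cand) == 1L) cand else sample(cand, 1L)
          chars[i] <- if (chars[i] == "I") "L" else "I"
          window <- c(i, i); err <- "il_swap"
        }
      }
      n_err <- as.integer(err != "none")
      lc <- round(stats::runif(length(chars), 93, 99))
      if (!is.null(window)) {
        w <- window[1]:window[2]
        lc[w] <- round(stats::runif(length(w), 40, 70))
      }
      reads_seq <- c(reads_seq, paste(chars, collapse = ""))
      alc <- c(alc, max(50, min(99, round(97 - 10 * n_err -
                                            stats::runif(1, 0, 4)))))
      area <- c(area, round(10^stats::runif(1, 3, 5)))
      conf[[length(conf) + 1L]] <- lc
      sref <- c(sref, paste0(chain, "_scan_", k))
      pl_chain <- c(pl_chain, chain)
      pl_start <- c(pl_start, start)
      pl_err <- c(pl_err, err)
    }
  }
  reads <- peptide_reads(reads_seq, alc = alc, local_confidence = conf,
                         area = area, spectrum_ref = sref,
                         source_format = "synthetic")
  list(reads = reads,
       placements = data.frame(chain = pl_chain, start = pl_start,
                               error = pl_err, stringsAsFactors = FALSE))
}

#' Generate a synthetic fragmentation spectrum with satellite ions
#'
#' Builds the c/z fragment ladder of a peptide at charge 1 and, for every
#' I/L position, adds the w-ion peaks consistent with the planted truth
#' (losses of 15.0235 and 29.0391 Da for I, 43.0548 Da for L) with the
#' given emission probability. Seeded low-intensity noise peaks are
#' added on top; their intensity stays well below the fragment peaks.
#'
#' @param peptide Residue string (the read's spelling).
#' @param xle_truth True residue string (same length; its I/L states
#'   drive which satellites are emitted), or `NULL` to use `peptide`.
#' @param satellite_probability Emission probability per Xle position.
#' @param noise_peaks Number of random noise peaks.
#' @param seed Seed for emission and noise randomness.
#' @return A spectrum list (`title`, `precursor_mz`, `precursor_charge`,
#'   `mz`, `intensity`).
#' @export
generate_spectra <- function(peptide, xle_truth = NULL,
                             satellite_probability = 1, noise_peaks = 0,
                             seed = 1L) {
  set.seed(seed)
  if (is.null(xle_truth)) xle_truth <- peptide
  truth_chars <- strsplit(xle_truth, "")[[1]]
  syms <- strsplit(peptide, "")[[1]]
  stopifnot(length(truth_chars) == length(syms))
  n <- length(syms)
  frag <- theoretical_fragments(peptide, charge_max = 1L,
                                ion_types = c("c", "z"))
  mz <- frag$mz
  int <- round(stats::runif(length(mz), 200, 1000))
  losses <- satellite_losses()
  for (p in which(truth_chars %in% c("I", "L")) - 1L) {
    if (stats::runif(1) > satellite_probability) next
    k <- n - p
    z_neutral <- if (k <= n - 1L) {
      frag$neutral_mass[frag$type == "z" & frag$index == k][1]
    } else {
      sequence_mass(peptide) + WATER_MASS -
        composition_mass(c(N = 1, H = 3)) + ELEMENT_MASS[["H"]]
    }
    wl <- if (truth_chars[p + 1L] == "I") {
      losses[c("I_CH3", "I_C2H5")]
    } else {
      losses["L_C3H7"]
    }
    mz <- c(mz, unname(z_neutral - wl + PROTON_MASS))
    int <- c(int, round(stats::runif(length(wl), 50, 500)))
  }
  if (noise_peaks > 0L) {
    mz <- c(mz, stats::runif(noise_peaks, 100, max(mz) + 50))
    int <- c(int, round(stats::runif(noise_peaks, 1, 10)))
  }
  o <- order(mz)
  list(title = paste0("synthetic_", peptide),
       precursor_mz = (sequence_mass(peptide) + WATER_MASS +
                         2 * PROTON_MASS) / 2,
       precursor_charge = 2L,
       mz = mz[o], intensity = int[o])
}

#' Write a complete fixture bundle to disk
#'
#' Emits the fixture's reads as PEAKS-dialect CSV, the truth and template
#' sequences as FASTA, and per-read spectra as MGF, so generated fixtures
#' double as reader tests.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_reads(spec)
  paths <- c(
    reads = file.path(dir, "reads_peaks.csv"),
    truth = file.path(dir, "truth.fasta"),
    templates = file.path(dir, "templates.fasta"),
    spectra = file.path(dir, "spectra.mgf"))
  write_peaks_csv(gen$reads, paths[["reads"]])
  writeLines(as.vector(rbind(paste0(">", names(spec$truth)),
                             unname(spec$truth))), paths[["truth"]])
  with_tpl <- spec$templates
  writeLines(as.vector(rbind(
    paste0(">", with_tpl$species, "|", with_tpl$chain, "|",
           with_tpl$segment_class, "|", with_tpl$name),
    with_tpl$sequence)), paths[["templates"]])
  spectra <- lapply(seq_len(nrow(gen$reads)), function(i) {
    sp <- generate_spectra(gen$reads$sequence[i],
                           satellite_probability =
                             spec$satellite_probability,
                           seed = spec$seed + i)
    sp$title <- gen$reads$spectrum_ref[i]
    sp
  })
  write_mgf(spectra, paths[["spectra"]])
  paths
}
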