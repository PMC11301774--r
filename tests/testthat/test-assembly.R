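toy_reads <- function() {
  peptide_reads(c("QVQLVQSGAE", "GAEVKKPGAS", "PGASVKVSCK"),
                alc = c(90, 95, 99))
}

test_that("ALC filtering keeps order and respects the bounds", {
  reads <- toy_reads()
  expect_identical(nrow(filter_reads(reads, 0)), 3L)
  kept <- filter_reads(reads, 95)
  expect_identical(kept$sequence, c("GAEVKKPGAS", "PGASVKVSCK"))
  expect_identical(nrow(filter_reads(reads, 100)), 0L)
  expect_error(filter_reads(reads, -1))
})

test_that("peptide_reads enforces the confidence-length invariant", {
  expect_error(peptide_reads("GAS", local_confidence = list(c(90, 90))),
               "length")
  r <- peptide_reads("GAS", alc = 80)
  expect_identical(r$local_confidence[[1]], rep(80, 3))
  expect_identical(r$area, 1)
})

test_that("template FASTA headers parse into segment annotations", {
  tpl <- synthetic_templates()
  expect_setequal(unique(tpl$chain), c("heavy", "light"))
  expect_setequal(unique(tpl$segment_class), c("V", "J", "C"))
  expect_false(any(grepl("X", tpl$sequence)))
})

test_that("wildcard extension appends the requested X run", {
  tpl <- synthetic_templates()[3, ]
  expect_identical(extend_with_wildcards(tpl, 0)$sequence, tpl$sequence)
  ext <- extend_with_wildcards(tpl, 12, "C")
  expect_identical(nchar(ext$sequence), nchar(tpl$sequence) + 12L)
  expect_true(endsWith(ext$sequence, strrep("X", 12)))
  extn <- extend_with_wildcards(tpl, 5, "N")
  expect_true(startsWith(extn$sequence, "XXXXX"))
  # overhanging read residues land on the X positions during alignment
  a <- mba_align("VSSARD", extend_with_wildcards(
    data.frame(sequence = "TLVTVSS"), 3, "C")$sequence)
  expect_identical(a$template_end, 10L)
})

test_that("enforce_unique keeps placements within the best-score ratio", {
  templates <- data.frame(
    name = c("t1", "t2", "far"),
    species = "syn", chain = "heavy", segment_class = "V",
    sequence = c("QVQLVQSGAEVKKPGA",   # exact region
                 "QVQLVESGAEVKKPGA",   # one substitution
                 "WWWWYYYYFFFFHHHH"),
    stringsAsFactors = FALSE)
  reads <- peptide_reads("QVQLVQSGAEVK", alc = 95)
  placed_loose <- match_to_templates(reads, templates,
                                     enforce_unique = 0.9)
  expect_setequal(placed_loose$template_name, c("t1", "t2"))
  placed_strict <- match_to_templates(reads, templates,
                                      enforce_unique = 0.99)
  expect_identical(placed_strict$template_name, "t1")
  # an 8-residue exact match clears the default cutoff of 5 easily
  short <- match_to_templates(peptide_reads("QVQLVQSG"), templates[1, ],
                              score_cutoff = 5)
  expect_identical(nrow(short), 1L)
  # reads matching nowhere are simply unplaced
  none <- match_to_templates(peptide_reads("PPPPPPPP"), templates[3, ],
                             score_cutoff = 30)
  expect_identical(nrow(none), 0L)
})

test_that("consensus weighting follows confidence x area", {
  template <- list(name = "t", sequence = "QVQLVQ")
  # two conflicting reads, equal confidence, areas 10 vs 1
  reads <- peptide_reads(c("QVELVQ", "QVQLVQ"), alc = c(90, 90),
                         area = c(10, 1))
  placed <- match_to_templates(reads, data.frame(
    name = "t", species = "s", chain = "h", segment_class = "V",
    sequence = "QVQLVQ", stringsAsFactors = FALSE))
  cons <- build_consensus(placed, template)
  expect_identical(cons$chosen[3], "E")  # area-10 read wins
  # weight conservation at the contested position
  w <- cons$options[[3]]
  expect_equal(sum(w), 0.9 * 10 + 0.9 * 1)
  expect_identical(cons$depth[3], 2L)
  # single full-confidence read reproduces itself over its span
  one <- build_consensus(placed[2, ], template)
  expect_identical(one$sequence, "QVQLVQ")
})

test_that("uncovered positions fall back to the template and are flagged", {
  template <- list(name = "t", sequence = "QVQLVQSGAEVKKPGA")
  reads <- peptide_reads("QVQLVQ")
  placed <- match_to_templates(reads, data.frame(
    name = "t", species = "s", chain = "h", segment_class = "V",
    sequence = template$sequence, stringsAsFactors = FALSE))
  cons <- build_consensus(placed, template)
  expect_identical(cons$sequence, template$sequence)
  expect_true(all(cons$template_only[7:16]))
  expect_true(all(!cons$template_only[1:6]))
  expect_true(all(cons$depth[7:16] == 0L))
})

test_that("CDRH3 overhangs merge at the best overlap", {
  j <- reconstruct_cdrh3("ARDGY", "DGYFDY")
  expect_true(j$joined)
  expect_identical(j$sequence, "ARDGYFDY")
  expect_identical(j$overlap, 3L)
  # empty overhangs cannot join
  expect_false(reconstruct_cdrh3("", "DGYFDY")$joined)
  expect_false(reconstruct_cdrh3("ARDGY", "")$joined)
  # disjoint overhangs score below the cutoff and stay unjoined
  expect_false(reconstruct_cdrh3("AAAAA", "WWWWW")$joined)
})

test_that("identity and coverage arithmetic", {
  truth <- strrep("QVQLVASGAEVK", 10)  # 120 residues
  expect_equal(identity_and_coverage(truth, truth)$identity, 1)
  wrong1 <- paste0(substr(truth, 1, 59), "W", substr(truth, 61, 120))
  expect_equal(identity_and_coverage(wrong1, truth)$identity, 119 / 120,
               tolerance = 1e-12)
})

test_that("error-free reads assemble to the exact truth", {
  spec <- fixture_spec(seed = 301, rotation_rate = 0, isobaric_rate = 0)
  gen <- generate_reads(spec)
  tpl <- synthetic_templates()
  heavy <- gen$reads[gen$placements$chain == "heavy", , drop = FALSE]
  asm <- assemble_chain(heavy, tpl[tpl$chain == "heavy", , drop = FALSE])
  ic <- identity_and_coverage(asm$consensus, spec$truth[["heavy"]])
  expect_identical(ic$identity, 1)
  expect_identical(ic$coverage, 1)
  expect_true(asm$cdrh3$joined)
  expect_identical(asm$cdrh3$sequence, spec$cdrh3[["heavy"]])
})

test_that("the light chain assembles without a junction", {
  spec <- fixture_spec(seed = 302, rotation_rate = 0, isobaric_rate = 0)
  gen <- generate_reads(spec)
  tpl <- synthetic_templates()
  light <- gen$reads[gen$placements$chain == "light", , drop = FALSE]
  asm <- assemble_chain(light, tpl[tpl$chain == "light", , drop = FALSE])
  ic <- identity_and_coverage(asm$consensus, spec$truth[["light"]])
  expect_gte(ic$identity, 0.99)
})

test_that("consensus weight totals equal the contributed read weights", {
  spec <- fixture_spec(seed = 303)
  gen <- generate_reads(spec)
  tpl <- synthetic_templates()
  heavy <- gen$reads[gen$placements$chain == "heavy", , drop = FALSE]
  v <- extend_with_wildcards(
    tpl[tpl$chain == "heavy" & tpl$segment_class == "V", , drop = FALSE][1, ],
    15, "C")
  placed <- match_to_templates(heavy, v)
  cons <- build_consensus(placed, as.list(v))
  total_weight <- sum(unlist(cons$options))
  # recompute independently from the alignments
  expected <- 0
  tchars <- strsplit(v$sequence, "")[[1]]
  for (k in seq_len(nrow(placed))) {
    aln <- placed$alignment[[k]]
    span <- tchars[seq(aln$template_start + 1, aln$template_end)]
    if (all(span == "X")) next  # unanchored, excluded from consensus
    conf <- placed$local_confidence[[k]]
    ri <- aln$read_start
    for (s in seq_len(nrow(aln$steps))) {
      lr <- aln$steps$len_read[s]; lt <- aln$steps$len_template[s]
      kind <- aln$steps$kind[s]
      if (kind %in% c("match", "mismatch")) {
        expected <- expected + conf[ri + 1] / 100 * placed$area[k]
      } else if (kind %in% c("rotation", "isobaric")) {
        expected <- expected +
          lt * mean(conf[(ri + 1):(ri + lr)]) / 100 * placed$area[k]
      }
      ri <- ri + lr
    }
  }
  expect_equal(total_weight, expected, tolerance = 1e-9)
})
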