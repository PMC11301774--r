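mtx <- set_score_matrix()

test_that("set pair scores follow the rotation/isobaric constants", {
  expect_identical(set_step_score(mtx, "AS", "SA"),
                   list(kind = "rotation", score = 6L))
  expect_identical(set_step_score(mtx, "N", "GG"),
                   list(kind = "isobaric", score = 4L))
  expect_identical(set_step_score(mtx, "GG", "N"),
                   list(kind = "isobaric", score = 4L))
  expect_identical(set_step_score(mtx, "GA", "Q")$score, 4L)
  expect_identical(set_step_score(mtx, "AS", "GT")$score, 4L)
  a_match <- set_step_score(mtx, "A", "A")
  expect_identical(a_match$kind, "match")
  expect_identical(a_match$score, modified_blosum62()["A", "A"])
})

test_that("rotation and isobaric scores stay below any direct match", {
  entries <- build_set_matrix(
    mtx, alphabet = c("G", "A", "S", "T", "N", "Q", "I", "L", "V", "K"))
  special <- entries[entries$kind %in% c("rotation", "isobaric"), ]
  expect_gt(nrow(special), 0)
  diag_min <- min(diag(modified_blosum62()))
  len <- pmax(nchar(special$set_a), nchar(special$set_b))
  expect_true(all(special$score < diag_min * len))
  # rotations only between equal-length permutations, score 3/residue
  rot <- special[special$kind == "rotation", ]
  expect_true(all(nchar(rot$set_a) == nchar(rot$set_b)))
  expect_true(all(rot$score == 3L * nchar(rot$set_a)))
  expect_true(all(nchar(rot$set_a) >= 2L))
  # isobaric score 2 x max length, pairs are not permutations
  iso <- special[special$kind == "isobaric", ]
  expect_true(all(iso$score ==
                    2L * pmax(nchar(iso$set_a), nchar(iso$set_b))))
  sorted <- function(s) vapply(strsplit(s, ""), function(x)
    paste(sort(x), collapse = ""), character(1))
  expect_true(all(sorted(iso$set_a) != sorted(iso$set_b)))
})

test_that("the set matrix is symmetric and round-trips through TSV", {
  entries <- build_set_matrix(mtx, alphabet = c("G", "A", "S", "N", "T"))
  key <- paste(entries$set_a, entries$set_b)
  rev_key <- paste(entries$set_b, entries$set_a)
  m <- match(rev_key, key)
  expect_false(anyNA(m))
  expect_identical(entries$score, entries$score[m])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_set_matrix(entries, path)
  expect_identical(read_set_matrix(path), entries)
})

test_that("an oversized set enumeration is rejected with advice", {
  expect_error(build_set_matrix(set_score_matrix(max_set_len = 3),
                                entry_budget = 10),
               "smaller max_set_len")
})

test_that("modified BLOSUM62 treats I/L as a direct match", {
  b <- modified_blosum62()
  expect_identical(b["I", "L"], min(b["I", "I"], b["L", "L"]))
  expect_identical(b["A", "R"], -1L)  # untouched elsewhere
})

test_that("mass-based alignment absorbs the canonical coincidences", {
  a <- mba_align("GG", "N")
  expect_identical(a$raw_score, 4L)
  expect_identical(a$steps$kind, "isobaric")
  expect_identical(a$steps$len_template, 1L)
  expect_identical(a$steps$len_read, 2L)

  b <- mba_align("PEPSATIDE", "PEPASTIDE")
  expect_identical(sum(b$steps$kind == "rotation"), 1L)
  expect_gt(b$raw_score, swa_align("PEPSATIDE", "PEPASTIDE")$raw_score)

  ident <- mba_align("QVQLVQ", "QVQLVQ")
  expect_true(all(ident$steps$kind == "match"))
  diag_sum <- sum(diag(modified_blosum62())[
    match(strsplit("QVQLVQ", "")[[1]], rownames(modified_blosum62()))])
  expect_identical(ident$raw_score, diag_sum)
  expect_equal(ident$normalized_score, diag_sum / 6)
})

test_that("step lengths sum to the aligned spans", {
  withr::local_seed(5)
  aa <- names(residue_masses())
  for (rep in 1:20) {
    r <- paste(sample(aa, sample(4:9, 1), TRUE), collapse = "")
    t <- paste(sample(aa, sample(4:9, 1), TRUE), collapse = "")
    a <- mba_align(r, t)
    expect_identical(sum(a$steps$len_template),
                     a$template_end - a$template_start)
    expect_identical(sum(a$steps$len_read), a$read_end - a$read_start)
    expect_identical(sum(a$steps$score), a$raw_score)
    expect_gte(a$raw_score, 0L)
  }
})

test_that("the DP equals the exhaustive path oracle and dominates SWA", {
  withr::local_seed(42)
  aa <- names(residue_masses())
  for (rep in 1:60) {
    r <- paste(sample(aa, sample(2:6, 1), TRUE), collapse = "")
    t <- paste(sample(aa, sample(2:6, 1), TRUE), collapse = "")
    mba <- mba_align(r, t)$raw_score
    expect_identical(mba, enumerate_paths_oracle(r, t),
                     info = paste(r, t))
    expect_gte(mba, swa_align(r, t)$raw_score)
  }
  expect_error(enumerate_paths_oracle(strrep("A", 11), "GG"), "10")
})

test_that("SWA cannot bridge GG = N and scores strictly lower there", {
  s <- swa_align("GG", "N")
  m <- mba_align("GG", "N")
  expect_lt(s$raw_score, m$raw_score)
  expect_false(any(s$steps$kind %in% c("rotation", "isobaric")))
})

test_that("identical inputs give identical alignments", {
  a1 <- mba_align("GGNAST", "NAATSG")
  a2 <- mba_align("GGNAST", "NAATSG")
  expect_identical(a1[setdiff(names(a1), "read")],
                   a2[setdiff(names(a2), "read")])
})

test_that("wildcard template positions accept any residue at +2", {
  a <- mba_align("ARDGY", "XXXXX")
  expect_identical(a$raw_score, 5L * mtx$wildcard_score)
  expect_true(all(a$steps$kind == "match"))
  # X never joins rotation/isobaric sets: GG aligns to the N alone
  b <- mba_align("GG", "XN")
  ti <- b$template_start
  tchars <- strsplit("XN", "")[[1]]
  for (s in seq_len(nrow(b$steps))) {
    lt <- b$steps$len_template[s]
    if (b$steps$kind[s] %in% c("rotation", "isobaric") && lt > 0) {
      expect_false(any(tchars[(ti + 1):(ti + lt)] == "X"))
    }
    ti <- ti + lt
  }
  expect_identical(b$raw_score, 4L)
})

test_that("empty sequences are rejected", {
  expect_error(mba_align("", "PEPTIDE"), "non-empty")
  expect_error(swa_align("PEPTIDE", ""), "non-empty")
})
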