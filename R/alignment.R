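# Mass-based local alignment (MBA) and the classic Smith-Waterman baseline
# (SWA). MBA extends the SWA step set (match/mismatch/insertion/deletion)
# with rotation and isobaric steps of up to N residues on each side, so
# that mass-coincidence sequencing errors (AS = SA, AS = GT, GG = N) align
# with a positive score instead of mismatches and gaps.

ALPHABET <- c(names(RESIDUE_COMPOSITION), "X")
KIND_LEVELS <- c("match", "rotation", "isobaric", "mismatch",
                 "gap_in_read", "gap_in_template")

#' Modified BLOSUM62 base matrix
#'
#' BLOSUM62 restricted to the 20 canonical residues, with the I/L
#' off-diagonal entries raised to the diagonal (match) score: I and L have
#' identical masses and are indistinguishable in MS-derived peptide reads,
#' so they are treated as a direct match during placement. Override by
#' passing any 20x20 integer matrix with residue dimnames.
#'
#' @return Integer matrix with residue row/column names.
#' @export
modified_blosum62 <- function() {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  aa <- names(RESIDUE_COMPOSITION)
  m <- b62[aa, aa]
  m["I", "L"] <- m["L", "I"] <- min(m["I", "I"], m["L", "L"])
  storage.mode(m) <- "integer"
  m
}

#' Set-to-set scoring scheme for mass-based alignment
#'
#' Bundles the parameters from which every residue-set pair score is
#' determined: the single-residue base matrix (top-left of the conceptual
#' two-dimensional score array), the maximum set length N, the isobaric
#' mass tolerance, and the step-score constants. Rotations (permuted sets
#' of equal length >= 2) score `rotation_per_residue` per residue involved;
#' isobaric pairs (different composition, equal mass within tolerance)
#' score `isobaric_per_residue` per the maximum number of residues
#' involved. Both are strictly below any direct match on the base matrix.
#'
#' @param base_matrix Single-residue substitution matrix
#'   ([modified_blosum62()] by default).
#' @param max_set_len Maximum residues per side in a rotation/isobaric
#'   step (N; default 3).
#' @param isobaric_tolerance Mass tolerance in Da for isobaric steps. The
#'   default `1e-6` admits only exact composition-level coincidences;
#'   raise it (e.g. to 0.05) to also absorb near-coincidences such as
#'   K vs Q (0.036 Da) on low-precision data.
#' @param wildcard_score Score for aligning any residue against the
#'   template wildcard X (default 2; below any direct match, enough to
#'   extend paths). X never joins rotation/isobaric sets.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend` (defaults -12, -1).
#' @param rotation_per_residue,isobaric_per_residue Step-score constants
#'   (defaults 3 and 2).
#' @return An object of class `set_score_matrix`.
#' @export
set_score_matrix <- function(base_matrix = modified_blosum62(),
                             max_set_len = 3L,
                             isobaric_tolerance = 1e-6,
                             wildcard_score = 2L,
                             gap_open = -12L, gap_extend = -1L,
                             rotation_per_residue = 3L,
                             isobaric_per_residue = 2L) {
  stopifnot(max_set_len >= 1L, isobaric_tolerance >= 0)
  structure(list(base_matrix = base_matrix,
                 max_set_len = as.integer(max_set_len),
                 isobaric_tolerance = isobaric_tolerance,
                 wildcard_score = as.integer(wildcard_score),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 rotation_per_residue = as.integer(rotation_per_residue),
                 isobaric_per_residue = as.integer(isobaric_per_residue)),
            class = "set_score_matrix")
}

#' @export
print.set_score_matrix <- function(x, ...) {
  cat("Set-to-set scoring scheme (mass-based alignment)\n",
      "  max set length N: ", x$max_set_len, "\n",
      "  isobaric tolerance: ", x$isobaric_tolerance, " Da\n",
      "  rotation/isobaric constants: ", x$rotation_per_residue, " / ",
      x$isobaric_per_residue, "\n",
      "  gaps: open ", x$gap_open, ", extend ", x$gap_extend, "\n",
      sep = "")
  invisible(x)
}

#' Score of a single residue-set pair
#'
#' Classifies and scores one residue-set pair under a scoring scheme:
#' direct match/mismatch for single residues, rotation for permuted equal-
#' length sets, isobaric for mass-coincident sets of different composition
#' (possibly different lengths), `none` otherwise.
#'
#' @param matrix A [set_score_matrix()].
#' @param set_a,set_b Residue strings of length 1..N.
#' @return list with `kind` and `score`.
#' @export
#' @examples
#' set_step_score(set_score_matrix(), "AS", "SA")  # rotation, 6
#' set_step_score(set_score_matrix(), "N", "GG")   # isobaric, 4
set_step_score <- function(matrix, set_a, set_b) {
  la <- nchar(set_a); lb <- nchar(set_b)
  stopifnot(la >= 1, lb >= 1, la <= matrix$max_set_len,
            lb <= matrix$max_set_len)
  if (la == 1L && lb == 1L) {
    if (set_a == set_b) {
      return(list(kind = "match",
                  score = matrix$base_matrix[set_a, set_b]))
    }
    base <- matrix$base_matrix[set_a, set_b]
    if (abs(sequence_mass(set_a) - sequence_mass(set_b)) <=
        matrix$isobaric_tolerance) {
      # isobaric single residues (I/L; K/Q at loose tolerance): keep the
      # higher-scoring of the base entry and the isobaric step score
      # (modified BLOSUM62 already scores I/L as a direct match)
      iso <- matrix$isobaric_per_residue
      if (iso >= base) return(list(kind = "isobaric", score = iso))
    }
    return(list(kind = "mismatch", score = base))
  }
  ca <- sort(strsplit(set_a, "")[[1]]); cb <- sort(strsplit(set_b, "")[[1]])
  if (identical(set_a, set_b)) return(list(kind = "none", score = 0L))
  if (la == lb && identical(ca, cb)) {
    return(list(kind = "rotation",
                score = matrix$rotation_per_residue * la))
  }
  if (abs(sequence_mass(set_a) - sequence_mass(set_b)) <=
      matrix$isobaric_tolerance) {
    return(list(kind = "isobaric",
                score = matrix$isobaric_per_residue * max(la, lb)))
  }
  list(kind = "none", score = 0L)
}

#' Materialize the set-to-set score matrix
#'
#' Enumerates every residue-set pair up to N residues per side that has a
#' defined score: all single-residue pairs (the base matrix), every
#' rotation pair and every isobaric pair. Intended for inspection and TSV
#' export; the aligner computes the same scores on the fly.
#'
#' @param matrix A [set_score_matrix()].
#' @param alphabet Residue alphabet to enumerate over.
#' @param entry_budget Maximum number of emitted entries before the
#'   enumeration is rejected with advice to lower N.
#' @return data.frame with columns `set_a`, `set_b`, `kind`, `score`.
#' @export
build_set_matrix <- function(matrix = set_score_matrix(),
                             alphabet = names(residue_masses()),
                             entry_budget = 2e6) {
  N <- matrix$max_set_len
  seqs <- character(0)
  cur <- alphabet
  for (len in seq_len(N)) {
    seqs <- c(seqs, cur)
    if (len < N) cur <- as.vector(outer(cur, alphabet, paste0))
  }
  mass <- vapply(seqs, sequence_mass, numeric(1))
  # only pairs in the same exact-mass neighbourhood can score as
  # rotation/isobaric; bucket by mass to avoid the full cross product
  ord <- order(mass)
  seqs <- seqs[ord]; mass <- mass[ord]
  grp <- cumsum(c(TRUE, diff(mass) > matrix$isobaric_tolerance + 1e-9))
  out <- vector("list", 0)
  n_entries <- 0L
  emit <- function(df) {
    n_entries <<- n_entries + nrow(df)
    if (n_entries > entry_budget) {
      stop("set matrix enumeration exceeds the entry budget (",
           format(entry_budget, scientific = FALSE),
           "); use a smaller max_set_len", call. = FALSE)
    }
    out[[length(out) + 1L]] <<- df
  }
  # base matrix block (all single-residue pairs)
  singles <- expand.grid(set_a = alphabet, set_b = alphabet,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sc <- mapply(function(a, b) set_step_score(matrix, a, b),
               singles$set_a, singles$set_b, SIMPLIFY = FALSE)
  singles$kind <- vapply(sc, `[[`, character(1), "kind")
  singles$score <- vapply(sc, function(s) as.integer(s$score), integer(1))
  emit(singles)
  # rotation / isobaric entries from mass buckets
  for (g in split(seq_along(seqs), grp)) {
    if (length(g) < 2L) next
    for (ia in g) for (ib in g) {
      a <- seqs[ia]; b <- seqs[ib]
      if (a == b || (nchar(a) == 1L && nchar(b) == 1L)) next
      s <- set_step_score(matrix, a, b)
      if (s$kind %in% c("rotation", "isobaric")) {
        emit(data.frame(set_a = a, set_b = b, kind = s$kind,
                        score = as.integer(s$score),
                        stringsAsFactors = FALSE))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export / import a materialized set matrix as TSV
#'
#' @param entries data.frame from [build_set_matrix()].
#' @param path File path.
#' @return `write_set_matrix` returns the path invisibly;
#'   `read_set_matrix` returns the entries data.frame.
#' @export
write_set_matrix <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_set_matrix
#' @export
read_set_matrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = character(0))  # "NA" = Asn+Ala
}

encode_seq <- function(s) {
  codes <- match(strsplit(s, "")[[1]], ALPHABET)
  if (anyNA(codes)) {
    bad <- strsplit(s, "")[[1]][which(is.na(codes))[1]]
    stop("unknown residue symbol: '", bad, "'", call. = FALSE)
  }
  as.integer(codes - 1L)
}

base_matrix_padded <- function(base) {
  aa <- names(RESIDUE_COMPOSITION)
  m <- matrix(0L, 21L, 21L)
  m[1:20, 1:20] <- base[aa, aa]
  m
}

alignment_from_cpp <- function(raw, read, template) {
  steps <- data.frame(kind = KIND_LEVELS[raw$kind + 1L],
                      len_template = raw$len_template,
                      len_read = raw$len_read,
                      score = raw$step_score,
                      stringsAsFactors = FALSE)
  span <- raw$template_end - raw$template_start
  structure(list(
    read = read, template = template,
    template_start = raw$template_start, template_end = raw$template_end,
    read_start = raw$read_start, read_end = raw$read_end,
    steps = steps, raw_score = raw$score,
    normalized_score = if (span > 0) raw$score / span else 0
  ), class = "mba_alignment")
}

#' Mass-based local alignment of a read against a template
#'
#' Dynamic-programming local alignment over the extended step set:
#' match/mismatch (single residues, base matrix), rotation and isobaric
#' steps of up to N residues per side, and affine gaps. At every cell the
#' highest scoring of the possible steps is chosen; ties prefer
#' match > rotation > isobaric > mismatch > gaps and shorter steps.
#' Template positions holding the wildcard X accept any read residue at
#' the configured wildcard score.
#'
#' @param read,template Non-empty residue strings (template may contain X).
#' @param matrix A [set_score_matrix()].
#' @return An `mba_alignment`: 0-based half-open spans on both sequences,
#'   the ordered step list, `raw_score` and `normalized_score`
#'   (raw score / aligned template length).
#' @export
#' @examples
#' mba_align("GG", "N")$raw_score   # 4, one isobaric step
mba_align <- function(read, template, matrix = set_score_matrix()) {
  if (!nzchar(read) || !nzchar(template)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  raw <- mba_align_cpp(encode_seq(template), encode_seq(read),
                       base_matrix_padded(matrix$base_matrix),
                       c(unname(RESIDUE_MASS), 0),
                       matrix$max_set_len, matrix$isobaric_tolerance,
                       matrix$wildcard_score, matrix$gap_open,
                       matrix$gap_extend, 20L,
                       matrix$rotation_per_residue,
                       matrix$isobaric_per_residue)
  alignment_from_cpp(raw, read, template)
}

#' Smith-Waterman local alignment baseline
#'
#' Classic local alignment restricted to single-residue match/mismatch and
#' affine gaps, using the same base matrix, wildcard and gap settings as
#' the mass-based aligner. Its step set is a strict subset of
#' [mba_align()]'s, so its raw score never exceeds the MBA score for the
#' same pair.
#'
#' @inheritParams mba_align
#' @return An `mba_alignment` object.
#' @export
swa_align <- function(read, template, matrix = set_score_matrix()) {
  if (!nzchar(read) || !nzchar(template)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  raw <- mba_align_cpp(encode_seq(template), encode_seq(read),
                       base_matrix_padded(matrix$base_matrix),
                       c(unname(RESIDUE_MASS), 0),
                       1L, -1, matrix$wildcard_score, matrix$gap_open,
                       matrix$gap_extend, 20L,
                       matrix$rotation_per_residue,
                       matrix$isobaric_per_residue)
  alignment_from_cpp(raw, read, template)
}

#' @export
print.mba_alignment <- function(x, ...) {
  cat("Local alignment: raw score ", x$raw_score,
      " (normalized ", round(x$normalized_score, 3), ")\n",
      "  template [", x$template_start, ", ", x$template_end, ") vs read [",
      x$read_start, ", ", x$read_end, ")\n", sep = "")
  if (nrow(x$steps)) {
    cat("  steps: ", paste(x$steps$kind, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Exhaustive best-path oracle for short sequences
#'
#' Independent reference for [mba_align()]: explores every decomposition of
#' the two sequences into alignment steps by top-down recursion over
#' (template position, read position, gap state), maximizing the summed
#' step score with the local-alignment convention (start and stop
#' anywhere). Capped at 10 residues per side.
#'
#' @inheritParams mba_align
#' @return Best raw score (integer).
#' @export
enumerate_paths_oracle <- function(read, template,
                                   matrix = set_score_matrix()) {
  n <- nchar(template); m <- nchar(read)
  if (n > 10L || m > 10L) {
    stop("oracle is limited to sequences of at most 10 residues",
         call. = FALSE)
  }
  N <- matrix$max_set_len
  memo <- new.env(hash = TRUE, parent = emptyenv())
  tchars <- strsplit(template, "")[[1]]
  rchars <- strsplit(read, "")[[1]]
  step_score <- function(i, la, j, lb) {
    a <- paste(tchars[(i + 1):(i + la)], collapse = "")
    b <- paste(rchars[(j + 1):(j + lb)], collapse = "")
    if (grepl("X", a, fixed = TRUE) || grepl("X", b, fixed = TRUE)) {
      if (la == 1L && lb == 1L) return(matrix$wildcard_score)
      return(NA_integer_)
    }
    s <- set_step_score(matrix, a, b)
    if (s$kind == "none") NA_integer_ else as.integer(s$score)
  }
  # best score of a path starting at template position i / read position j
  # (0-based, residues consumed so far), in the given gap state
  best_from <- function(i, j, state) {
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0L  # stop here
    if (state != "y" && i < n) {
      gap <- if (state == "x") matrix$gap_extend else
        matrix$gap_open + matrix$gap_extend
      best <- max(best, gap + best_from(i + 1L, j, "x"))
    }
    if (state != "x" && j < m) {
      gap <- if (state == "y") matrix$gap_extend else
        matrix$gap_open + matrix$gap_extend
      best <- max(best, gap + best_from(i, j + 1L, "y"))
    }
    for (la in 1:N) for (lb in 1:N) {
      if (i + la > n || j + lb > m) next
      sc <- step_score(i, la, j, lb)
      if (is.na(sc)) next
      best <- max(best, sc + best_from(i + la, j + lb, "m"))
    }
    memo[[key]] <- best
    best
  }
  best <- 0L
  for (i in 0:(n - 1L)) for (j in 0:(m - 1L)) {
    best <- max(best, best_from(i, j, "m"))
  }
  best
}
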