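# Readers for de novo peptide sequencing output dialects (PEAKS CSV,
# Casanovo mzTab, Novor.Cloud CSV, pNovo text, MaxNovo table, FASTA, plain
# text), all normalized into the peptide_reads representation. Column names
# drift between vendor versions, so each reader accepts a mapping that
# overrides the defaults.

#' Default column mappings per input dialect
#'
#' @return Named list of per-format field-to-column mappings, each
#'   overridable in the corresponding reader.
#' @export
default_format_mappings <- function() {
  list(
    peaks = list(peptide = "Peptide", alc = "ALC (%)",
                 local_confidence = "local confidence (%)",
                 area = "Area", scan = "Scan"),
    novor = list(peptide = "peptide", score = "score",
                 aa_score = "aaScore", scan = "scanNum"),
    maxnovo = list(peptide = "Sequence", score = "Score",
                   scan = "Scan number"),
    pnovo = list(title = 1L, peptide = 2L, score = 3L),
    mztab = list(peptide = "sequence", score = "search_engine_score[1]",
                 aa_scores = "opt_ms_run[1]_aa_scores",
                 spectra_ref = "spectra_ref")
  )
}

#' Parse a peptide string with inline modification notation
#'
#' Accepts both delta style (`"M(+15.99)"`) and name style
#' (`"M[Oxidation]"`). Deltas are resolved against the modification table
#' by nearest mass within 0.01 Da.
#'
#' @param s Peptide string.
#' @param mod_table Modification table.
#' @return list with `sequence` (plain residues) and `mods` (data.frame
#'   `position` (1-based), `name`).
#' @export
parse_peptide_string <- function(s, mod_table = default_modifications()) {
  seq_chars <- character(0)
  mods <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      j <- regexpr(")", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced '(' in peptide '", s, "'", call. = FALSE)
      token <- substr(s, i + 1L, i + j - 2L)
      delta <- suppressWarnings(as.numeric(sub("^\\+", "", token)))
      if (is.na(delta)) {
        stop("cannot parse modification '", token, "' in '", s, "'",
             call. = FALSE)
      }
      d <- abs(mod_table$delta_mass - delta)
      k <- which.min(d)
      if (d[k] > 0.01) {
        stop("no known modification within 0.01 Da of ", delta,
             " in '", s, "'", call. = FALSE)
      }
      mods[[length(mods) + 1L]] <- data.frame(
        position = length(seq_chars), name = mod_table$name[k],
        stringsAsFactors = FALSE)
      i <- i + j
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced '[' in peptide '", s, "'", call. = FALSE)
      nm <- substr(s, i + 1L, i + j - 2L)
      if (!nm %in% mod_table$name) {
        stop("unknown modification '", nm, "' in '", s, "'", call. = FALSE)
      }
      mods[[length(mods) + 1L]] <- data.frame(
        position = length(seq_chars), name = nm, stringsAsFactors = FALSE)
      i <- i + j
    } else if (ch %in% names(RESIDUE_MASS)) {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    } else if (ch %in% c(" ", ".", "-")) {
      i <- i + 1L
    } else {
      stop("unknown residue symbol: '", ch, "' in '", s, "'",
           call. = FALSE)
    }
  }
  list(sequence = paste(seq_chars, collapse = ""),
       mods = if (length(mods)) do.call(rbind, mods) else
         data.frame(position = integer(0), name = character(0)))
}

reader_result <- function(reads, skipped, source_format) {
  structure(list(reads = reads, skipped = skipped,
                 source_format = source_format),
            class = "reader_result")
}

#' @export
print.reader_result <- function(x, ...) {
  cat("Reader result (", x$source_format, "): ", nrow(x$reads),
      " reads, ", nrow(x$skipped), " skipped\n", sep = "")
  invisible(x)
}

finalize_reads <- function(peptides, alc, local_confidence, area,
                           spectrum_ref, source_format, skipped,
                           mod_table = default_modifications()) {
  parsed <- lapply(peptides, parse_peptide_string, mod_table = mod_table)
  seqs <- vapply(parsed, `[[`, character(1), "sequence")
  reads <- peptide_reads(seqs, alc = alc,
                         local_confidence = local_confidence,
                         area = area, spectrum_ref = spectrum_ref,
                         source_format = source_format)
  reads$mods <- lapply(parsed, `[[`, "mods")
  reader_result(reads, skipped, source_format)
}

empty_skipped <- function() {
  data.frame(row = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Read a PEAKS de novo export (CSV)
#'
#' Expects the PEAKS columns `Peptide`, `ALC (%)`, `local confidence (%)`
#' (space- or comma-separated per-residue values), `Area` and `Scan`;
#' override names via `mapping`. Rows whose confidence vector length does
#' not match the residue count are skipped with a reason.
#'
#' @param path CSV file path.
#' @param mapping Column mapping (see [default_format_mappings()]).
#' @param mod_table Modification table for inline notation.
#' @return A `reader_result`.
#' @export
read_peaks_csv <- function(path, mapping = default_format_mappings()$peaks,
                           mod_table = default_modifications()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(mapping$peptide, mapping$alc)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("PEAKS csv missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  skipped <- empty_skipped()
  keep <- rep(TRUE, nrow(df))
  lc <- vector("list", nrow(df))
  seq_len_of <- function(p) {
    nchar(parse_peptide_string(p, mod_table)$sequence)
  }
  has_lc <- !is.null(mapping$local_confidence) &&
    mapping$local_confidence %in% names(df)
  for (i in seq_len(nrow(df))) {
    if (has_lc) {
      vals <- suppressWarnings(as.numeric(
        strsplit(trimws(df[[mapping$local_confidence]][i]),
                 "[ ,]+")[[1]]))
      nres <- tryCatch(seq_len_of(df[[mapping$peptide]][i]),
                       error = function(e) -1L)
      if (nres < 0L) {
        keep[i] <- FALSE
        skipped <- rbind(skipped, data.frame(
          row = i, reason = "unparseable peptide string"))
        next
      }
      if (anyNA(vals) || length(vals) != nres) {
        keep[i] <- FALSE
        skipped <- rbind(skipped, data.frame(
          row = i,
          reason = "confidence vector length != residue count"))
        next
      }
      lc[[i]] <- vals
    } else {
      lc[i] <- list(NULL)
    }
  }
  df <- df[keep, , drop = FALSE]
  lc <- lc[keep]
  if (!nrow(df)) {
    return(reader_result(peptide_reads(character(0)), skipped, "peaks"))
  }
  area <- if (!is.null(mapping$area) && mapping$area %in% names(df)) {
    as.numeric(df[[mapping$area]])
  } else NULL
  scan <- if (!is.null(mapping$scan) && mapping$scan %in% names(df)) {
    as.character(df[[mapping$scan]])
  } else NA_character_
  if (!has_lc) lc <- NULL
  finalize_reads(df[[mapping$peptide]], as.numeric(df[[mapping$alc]]),
                 lc, area, scan, "peaks", skipped, mod_table)
}

#' Read an mzTab PSM section (Casanovo-style)
#'
#' Parses `PSH`/`PSM` rows; the search engine score (0-1) is scaled to
#' the 0-99 ALC range, and the optional per-residue `aa_scores` column
#' (comma-separated, 0-1) becomes the local confidence.
#'
#' @inheritParams read_peaks_csv
#' @return A `reader_result`.
#' @export
read_mztab <- function(path, mapping = default_format_mappings()$mztab,
                       mod_table = default_modifications()) {
  lines <- readLines(path)
  psh <- grep("^PSH\\t", lines, value = TRUE)
  psm <- grep("^PSM\\t", lines, value = TRUE)
  if (!length(psh)) {
    stop("mzTab file has no PSH header line: ", path, call. = FALSE)
  }
  header <- strsplit(psh[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- lapply(psm, function(x) strsplit(x, "\t", fixed = TRUE)[[1]][-1])
  col <- function(nm) match(nm, header)
  if (is.na(col(mapping$peptide))) {
    stop("mzTab PSH lacks the '", mapping$peptide, "' column",
         call. = FALSE)
  }
  peptides <- vapply(rows, `[[`, character(1), col(mapping$peptide))
  score <- if (!is.na(col(mapping$score))) {
    as.numeric(vapply(rows, `[[`, character(1), col(mapping$score)))
  } else rep(NA_real_, length(rows))
  alc <- pmin(round(score * 100), 99)
  alc[is.na(alc)] <- 90
  lc <- NULL
  if (!is.na(col(mapping$aa_scores))) {
    lc <- lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(
        strsplit(r[[col(mapping$aa_scores)]], ",")[[1]]))
      v * 100
    })
  }
  sref <- if (!is.na(col(mapping$spectra_ref))) {
    vapply(rows, `[[`, character(1), col(mapping$spectra_ref))
  } else NA_character_
  finalize_reads(peptides, alc, lc, NULL, sref, "mztab",
                 empty_skipped(), mod_table)
}

#' Read a Novor.Cloud CSV export
#'
#' Uses the `peptide`, `score` (0-100) and dash-separated `aaScore`
#' columns; `#` comment lines are ignored.
#'
#' @inheritParams read_peaks_csv
#' @return A `reader_result`.
#' @export
read_novor_csv <- function(path, mapping = default_format_mappings()$novor,
                           mod_table = default_modifications()) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        strip.white = TRUE, stringsAsFactors = FALSE)
  if (!mapping$peptide %in% names(df)) {
    stop("Novor csv missing mandatory column: ", mapping$peptide,
         call. = FALSE)
  }
  alc <- if (mapping$score %in% names(df)) {
    pmin(as.numeric(df[[mapping$score]]), 99)
  } else NULL
  lc <- if (mapping$aa_score %in% names(df)) {
    lapply(strsplit(as.character(df[[mapping$aa_score]]), "-", fixed = TRUE),
           as.numeric)
  } else NULL
  scan <- if (mapping$scan %in% names(df)) {
    as.character(df[[mapping$scan]])
  } else NA_character_
  finalize_reads(df[[mapping$peptide]], alc, lc, NULL, scan, "novor",
                 empty_skipped(), mod_table)
}

#' Read a pNovo text result
#'
#' Tab-separated lines: spectrum title, peptide, score.
#'
#' @inheritParams read_peaks_csv
#' @return A `reader_result`.
#' @export
read_pnovo_txt <- function(path, mapping = default_format_mappings()$pnovo,
                           mod_table = default_modifications()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("pNovo line ", bad[1], " is not tab-separated title/peptide: '",
         lines[bad[1]], "'", call. = FALSE)
  }
  title <- vapply(parts, `[[`, character(1), mapping$title)
  peptides <- vapply(parts, `[[`, character(1), mapping$peptide)
  score <- vapply(parts, function(p) {
    if (length(p) >= mapping$score) as.numeric(p[[mapping$score]])
    else NA_real_
  }, numeric(1))
  alc <- pmin(round(score), 99)
  alc[is.na(alc)] <- 90
  finalize_reads(peptides, alc, NULL, NULL, title, "pnovo",
                 empty_skipped(), mod_table)
}

#' Read a MaxNovo (MaxQuant-style) result table
#'
#' Tab-separated with `Sequence`, `Score` and `Scan number` columns.
#'
#' @inheritParams read_peaks_csv
#' @return A `reader_result`.
#' @export
read_maxnovo_table <- function(path,
                               mapping = default_format_mappings()$maxnovo,
                               mod_table = default_modifications()) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!mapping$peptide %in% names(df)) {
    stop("MaxNovo table missing mandatory column: ", mapping$peptide,
         call. = FALSE)
  }
  alc <- if (mapping$score %in% names(df)) {
    pmin(round(as.numeric(df[[mapping$score]])), 99)
  } else NULL
  scan <- if (mapping$scan %in% names(df)) {
    as.character(df[[mapping$scan]])
  } else NA_character_
  finalize_reads(df[[mapping$peptide]], alc, NULL, NULL, scan, "maxnovo",
                 empty_skipped(), mod_table)
}

#' Read peptide reads from FASTA
#'
#' Record names become spectrum references; confidence and area take the
#' format-free defaults.
#'
#' @param path FASTA file path.
#' @param mod_table Modification table.
#' @return A `reader_result`.
#' @export
read_fasta_reads <- function(path, mod_table = default_modifications()) {
  seqs <- Biostrings::readAAStringSet(path)
  finalize_reads(as.character(seqs), NULL, NULL, NULL, names(seqs),
                 "fasta", empty_skipped(), mod_table)
}

#' Read peptide reads from plain text (one peptide per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @inheritParams read_fasta_reads
#' @return A `reader_result`.
#' @export
read_plain_text <- function(path, mod_table = default_modifications()) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  finalize_reads(lines, NULL, NULL, NULL, NA_character_, "plain",
                 empty_skipped(), mod_table)
}

# ---- writers (round-trip counterparts, also used by the fixture
# generator so fixtures double as reader tests) ----

#' Write reads in each supported dialect
#'
#' Writers mirroring the readers, used for round-trip testing and for
#' emitting synthetic fixtures.
#'
#' @param reads A `peptide_reads` table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_peaks_csv <- function(reads, path) {
  df <- data.frame(
    "Peptide" = reads$sequence,
    "ALC (%)" = reads$alc,
    "local confidence (%)" = vapply(reads$local_confidence, paste,
                                    character(1), collapse = " "),
    "Area" = reads$area,
    "Scan" = ifelse(is.na(reads$spectrum_ref), "", reads$spectrum_ref),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
write_mztab <- function(reads, path) {
  hdr <- c("MTD\tmzTab-version\t1.0.0",
           paste("PSH", "sequence", "PSM_ID", "search_engine_score[1]",
                 "spectra_ref", "opt_ms_run[1]_aa_scores", sep = "\t"))
  rows <- vapply(seq_len(nrow(reads)), function(i) {
    paste("PSM", reads$sequence[i], i,
          format(reads$alc[i] / 100, digits = 6),
          ifelse(is.na(reads$spectrum_ref[i]), "null",
                 reads$spectrum_ref[i]),
          paste(format(reads$local_confidence[[i]] / 100, digits = 6,
                       trim = TRUE), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
write_novor_csv <- function(reads, path) {
  df <- data.frame(
    scanNum = seq_len(nrow(reads)),
    score = reads$alc,
    peptide = reads$sequence,
    aaScore = vapply(reads$local_confidence, paste, character(1),
                     collapse = "-"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
write_pnovo_txt <- function(reads, path) {
  title <- ifelse(is.na(reads$spectrum_ref),
                  paste0("spectrum_", seq_len(nrow(reads))),
                  reads$spectrum_ref)
  writeLines(paste(title, reads$sequence, reads$alc, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
write_maxnovo_table <- function(reads, path) {
  df <- data.frame(
    "Sequence" = reads$sequence,
    "Score" = reads$alc,
    "Scan number" = ifelse(is.na(reads$spectrum_ref),
                           seq_len(nrow(reads)), reads$spectrum_ref),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
write_reads_fasta <- function(reads, path) {
  nm <- ifelse(is.na(reads$spectrum_ref),
               paste0("read_", seq_len(nrow(reads))), reads$spectrum_ref)
  writeLines(as.vector(rbind(paste0(">", nm), reads$sequence)), path)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
write_plain_text <- function(reads, path) {
  writeLines(reads$sequence, path)
  invisible(path)
}
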