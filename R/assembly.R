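# Template-based assembly: place de novo peptide reads on germline V/J/C
# segments, build a weighted consensus, reconstruct the CDRH3 junction from
# wildcard-extended V/J overhangs, and run the second (recombined)
# template-matching pass.

#' Construct a table of peptide reads
#'
#' One row per de novo sequenced peptide, normalized across input formats:
#' a plain residue string, the aggregate confidence (ALC, 0-99), the
#' per-residue local confidence vector (0-100), the abundance (area) and
#' provenance fields. Missing areas default to 1 (confidence-only
#' weighting); missing local confidence defaults to the ALC spread
#' uniformly over the residues.
#'
#' @param sequence Character vector of residue strings.
#' @param alc Aggregate confidence per read (0-99).
#' @param local_confidence List of numeric vectors (one per read, length
#'   equal to the residue count), or `NULL`.
#' @param area Numeric abundances, or `NULL`.
#' @param spectrum_ref Optional source-scan identifiers.
#' @param source_format Provenance tag.
#' @return A `peptide_reads` data.frame.
#' @export
peptide_reads <- function(sequence, alc = NULL, local_confidence = NULL,
                          area = NULL, spectrum_ref = NA_character_,
                          source_format = "manual") {
  n <- length(sequence)
  if (n == 0L) {
    out <- data.frame(sequence = character(0), alc = numeric(0),
                      area = numeric(0), spectrum_ref = character(0),
                      source_format = character(0),
                      stringsAsFactors = FALSE)
    out$local_confidence <- list()
    class(out) <- c("peptide_reads", "data.frame")
    return(out)
  }
  if (is.null(alc)) alc <- rep(90, n)
  if (is.null(area)) area <- rep(1, n)
  area[is.na(area)] <- 1
  if (is.null(local_confidence)) {
    local_confidence <- lapply(seq_len(n), function(i) {
      rep(alc[i], nchar(sequence[i]))
    })
  }
  bad <- which(lengths(local_confidence) != nchar(sequence))
  if (length(bad)) {
    stop("local_confidence length must equal sequence length (read ",
         bad[1], ")", call. = FALSE)
  }
  out <- data.frame(sequence = sequence, alc = alc, area = area,
                    spectrum_ref = spectrum_ref,
                    source_format = source_format,
                    stringsAsFactors = FALSE)
  out$local_confidence <- local_confidence
  class(out) <- c("peptide_reads", "data.frame")
  out
}

#' Filter reads on aggregate confidence
#'
#' @param reads A `peptide_reads` table.
#' @param alc_cutoff Minimum ALC (0-99); reads with `alc >= alc_cutoff`
#'   are kept in their original order.
#' @return Filtered `peptide_reads`.
#' @export
filter_reads <- function(reads, alc_cutoff) {
  stopifnot(alc_cutoff >= 0, alc_cutoff <= 100)
  reads[!is.na(reads$alc) & reads$alc >= alc_cutoff, , drop = FALSE]
}

#' Read germline template segments from FASTA
#'
#' Headers follow the convention `species|chain|segment_class|name`
#' (e.g. `synthetic|heavy|V|IGHV-syn1`). Wildcard X characters never occur
#' in source FASTA; they are introduced only by [extend_with_wildcards()].
#'
#' @param path FASTA file path.
#' @return data.frame with columns `name`, `species`, `chain`,
#'   `segment_class`, `sequence`.
#' @export
read_templates_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop("template header not in 'species|chain|class|name' form: '",
         names(seqs)[bad[1]], "'", call. = FALSE)
  }
  data.frame(
    name = vapply(parts, `[[`, character(1), 4),
    species = vapply(parts, `[[`, character(1), 1),
    chain = vapply(parts, `[[`, character(1), 2),
    segment_class = vapply(parts, `[[`, character(1), 3),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
}

#' Extend a template with wildcard residues
#'
#' Appends (C terminus) or prepends (N terminus) `n_x` wildcard X
#' characters to each template sequence, so overhanging reads can extend
#' the consensus into regions the germline does not cover (CDRH3).
#'
#' @param templates Template data.frame (or a single row).
#' @param n_x Number of X characters (>= 0).
#' @param end `"C"` or `"N"`.
#' @return The templates with extended sequences.
#' @export
extend_with_wildcards <- function(templates, n_x, end = c("C", "N")) {
  end <- match.arg(end)
  stopifnot(n_x >= 0)
  pad <- strrep("X", n_x)
  templates$sequence <- if (end == "C") {
    paste0(templates$sequence, pad)
  } else {
    paste0(pad, templates$sequence)
  }
  templates
}

#' Place reads on template segments
#'
#' Aligns every read against every template and keeps placements whose raw
#' alignment score reaches `score_cutoff`. With `enforce_unique = r`, a
#' read is only placed on templates scoring at least `r` times its best
#' raw score across all templates, suppressing ambiguous multi-template
#' placements.
#'
#' @param reads A `peptide_reads` table.
#' @param templates Template data.frame.
#' @param matrix A [set_score_matrix()].
#' @param score_cutoff Minimum raw alignment score (default 5).
#' @param enforce_unique Best-score ratio threshold in \[0, 1\]
#'   (default 0.9).
#' @param aligner `"mba"` or `"swa"`.
#' @return data.frame of placements: read columns plus `read_index`,
#'   `template_name`, `raw_score`, `normalized_score`, `accepted`, and a
#'   list column `alignment`.
#' @export
match_to_templates <- function(reads, templates, matrix = set_score_matrix(),
                               score_cutoff = 5, enforce_unique = 0.9,
                               aligner = c("mba", "swa")) {
  aligner <- match.arg(aligner)
  stopifnot(nrow(templates) > 0)
  align_fun <- if (aligner == "mba") mba_align else swa_align
  rows <- list()
  for (ri in seq_len(nrow(reads))) {
    alns <- lapply(templates$sequence, function(tpl) {
      align_fun(reads$sequence[ri], tpl, matrix)
    })
    scores <- vapply(alns, `[[`, numeric(1), "raw_score")
    keep <- scores >= score_cutoff &
      scores >= enforce_unique * max(scores)
    for (ti in which(keep)) {
      rows[[length(rows) + 1L]] <- list(
        read_index = ri, template_name = templates$name[ti],
        raw_score = scores[ti],
        normalized_score = alns[[ti]]$normalized_score,
        alignment = alns[[ti]])
    }
  }
  if (!length(rows)) {
    out <- reads[integer(0), , drop = FALSE]
    out$read_index <- integer(0); out$template_name <- character(0)
    out$raw_score <- numeric(0); out$normalized_score <- numeric(0)
    out$accepted <- logical(0); out$alignment <- list()
    return(out)
  }
  idx <- vapply(rows, `[[`, integer(1), "read_index")
  out <- reads[idx, , drop = FALSE]
  out$read_index <- idx
  out$template_name <- vapply(rows, `[[`, character(1), "template_name")
  out$raw_score <- vapply(rows, `[[`, numeric(1), "raw_score")
  out$normalized_score <- vapply(rows, `[[`, numeric(1), "normalized_score")
  out$accepted <- TRUE
  out$alignment <- lapply(rows, `[[`, "alignment")
  rownames(out) <- NULL
  class(out) <- c("placed_reads", "data.frame")
  out
}

set_label <- function(residues) paste0("{", residues, "}")

#' Build a weighted consensus over one template
#'
#' Each placed read residue contributes `local_confidence / 100 * area` to
#' its aligned template position. Reads spanning rotation or isobaric
#' steps contribute the spanned read residues as a *set option* (the order
#' or spelling is not mass-supported), preserving the ambiguity. The
#' chosen residue per position is the weight argmax; where a set option
#' wins, the mass-equivalent template spelling is used and the position is
#' flagged ambiguous. Positions covered by no read fall back to the
#' template residue and are flagged template-only.
#'
#' @param placed_reads Placements from [match_to_templates()], all on the
#'   same template.
#' @param template One template row (or a list with `sequence`).
#' @return A `consensus_sequence` object.
#' @export
build_consensus <- function(placed_reads, template) {
  tpl_seq <- strsplit(template$sequence, "")[[1]]
  np <- length(tpl_seq)
  options <- vector("list", np)
  depth <- integer(np)
  for (k in seq_len(nrow(placed_reads))) {
    aln <- placed_reads$alignment[[k]]
    # a placement lying entirely inside the wildcard extension is
    # positionally unanchored (every X offset scores the same); it carries
    # no placement information and is excluded from the consensus
    span <- tpl_seq[seq(aln$template_start + 1L, aln$template_end)]
    if (length(span) && all(span == "X")) next
    conf <- placed_reads$local_confidence[[k]]
    area <- placed_reads$area[k]
    rchars <- strsplit(placed_reads$sequence[k], "")[[1]]
    ti <- aln$template_start; ri <- aln$read_start
    st <- aln$steps
    for (s in seq_len(nrow(st))) {
      lt <- st$len_template[s]; lr <- st$len_read[s]
      kind <- st$kind[s]
      if (kind %in% c("match", "mismatch")) {
        w <- conf[ri + 1] / 100 * area
        key <- rchars[ri + 1]
        p <- ti + 1
        options[[p]][key] <- sum(options[[p]][key], w, na.rm = TRUE)
        depth[p] <- depth[p] + 1L
      } else if (kind %in% c("rotation", "isobaric")) {
        win <- rchars[(ri + 1):(ri + lr)]
        w <- mean(conf[(ri + 1):(ri + lr)]) / 100 * area
        key <- set_label(paste(win, collapse = ""))
        for (p in (ti + 1):(ti + lt)) {
          options[[p]][key] <- sum(options[[p]][key], w, na.rm = TRUE)
          depth[p] <- depth[p] + 1L
        }
      }
      ti <- ti + lt; ri <- ri + lr
    }
  }
  chosen <- character(np)
  template_only <- logical(np)
  ambiguous <- logical(np)
  for (p in seq_len(np)) {
    opt <- options[[p]]
    if (is.null(opt) || !length(opt)) {
      chosen[p] <- tpl_seq[p]
      template_only[p] <- TRUE
      next
    }
    # argmax by weight; ties prefer single residues, then the template
    # spelling, then lexicographic order (deterministic)
    top <- names(opt)[opt >= max(opt) - 1e-12]
    singles <- top[!startsWith(top, "{")]
    pick <- if (length(singles)) {
      if (tpl_seq[p] %in% singles) tpl_seq[p] else sort(singles)[1]
    } else sort(top)[1]
    if (startsWith(pick, "{")) {
      # a mass-equivalent set carries no positional spelling; keep the
      # template's spelling and surface the ambiguity
      chosen[p] <- tpl_seq[p]
      ambiguous[p] <- TRUE
    } else {
      chosen[p] <- pick
    }
  }
  structure(list(
    template = template,
    options = options,
    depth = depth,
    chosen = chosen,
    template_only = template_only,
    ambiguous = ambiguous,
    sequence = paste(chosen, collapse = "")
  ), class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("Consensus over template '", x$template$name %||% "?", "' (",
      length(x$chosen), " positions, mean depth ",
      round(mean(x$depth), 2), ")\n", x$sequence, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export per-position consensus detail as TSV
#'
#' @param consensus A `consensus_sequence`.
#' @param path File path.
#' @export
write_consensus_tsv <- function(consensus, path) {
  rows <- lapply(seq_along(consensus$chosen), function(p) {
    opt <- consensus$options[[p]]
    data.frame(position = p, template = strsplit(
                 consensus$template$sequence, "")[[1]][p],
               chosen = consensus$chosen[p], depth = consensus$depth[p],
               template_only = consensus$template_only[p],
               options = if (length(opt)) {
                 paste(sprintf("%s:%.4g", names(opt), opt), collapse = ";")
               } else "",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

consensus_overhang <- function(consensus, side = c("C", "N")) {
  side <- match.arg(side)
  tpl <- strsplit(consensus$template$sequence, "")[[1]]
  xpos <- which(tpl == "X")
  if (!length(xpos)) return("")
  covered <- consensus$depth[xpos] >= 1L
  if (side == "C") {
    # contiguous covered run from the start of the X tail
    n <- match(FALSE, covered, nomatch = length(covered) + 1L) - 1L
    if (n == 0L) return("")
    paste(consensus$chosen[xpos[seq_len(n)]], collapse = "")
  } else {
    rev_cov <- rev(covered)
    n <- match(FALSE, rev_cov, nomatch = length(covered) + 1L) - 1L
    if (n == 0L) return("")
    paste(consensus$chosen[xpos[(length(xpos) - n + 1L):length(xpos)]],
          collapse = "")
  }
}

#' Reconstruct the CDRH3 junction from V/J overhangs
#'
#' Takes the read-derived consensus overhangs that extend the V segment
#' (C-terminal X region) and the J segment (N-terminal X region), aligns
#' the V-side suffix against the J-side prefix at every possible overlap
#' length, and merges at the best-scoring overlap. If no overlap reaches
#' `cutoff` (or an overhang is empty), the fragments are returned
#' unjoined.
#'
#' @param v_consensus,j_consensus `consensus_sequence` objects built on
#'   X-extended V and J templates (or plain overhang strings).
#' @param matrix A [set_score_matrix()].
#' @param cutoff Minimum overlap alignment score (default 5).
#' @return list with `joined` (logical), `sequence` (merged junction when
#'   joined), `v_overhang`, `j_overhang`, `overlap`, `score`.
#' @export
#' @examples
#' reconstruct_cdrh3("ARDGY", "DGYFDY")$sequence  # "ARDGYFDY"
reconstruct_cdrh3 <- function(v_consensus, j_consensus,
                              matrix = set_score_matrix(), cutoff = 5) {
  v_ov <- if (is.character(v_consensus)) v_consensus else
    consensus_overhang(v_consensus, "C")
  j_ov <- if (is.character(j_consensus)) j_consensus else
    consensus_overhang(j_consensus, "N")
  if (!nzchar(v_ov) || !nzchar(j_ov)) {
    return(list(joined = FALSE, sequence = NULL, v_overhang = v_ov,
                j_overhang = j_ov, overlap = 0L, score = NA_real_,
                reason = "empty overhang"))
  }
  best <- list(score = -Inf, k = 0L)
  for (k in seq_len(min(nchar(v_ov), nchar(j_ov)))) {
    tail_v <- substr(v_ov, nchar(v_ov) - k + 1L, nchar(v_ov))
    head_j <- substr(j_ov, 1L, k)
    sc <- overlap_score(tail_v, head_j, matrix)
    if (sc > best$score || (sc == best$score && k > best$k)) {
      best <- list(score = sc, k = k)
    }
  }
  if (best$score < cutoff) {
    return(list(joined = FALSE, sequence = NULL, v_overhang = v_ov,
                j_overhang = j_ov, overlap = 0L, score = best$score,
                reason = "no overlap above cutoff"))
  }
  merged <- paste0(v_ov, substr(j_ov, best$k + 1L, nchar(j_ov)))
  list(joined = TRUE, sequence = merged, v_overhang = v_ov,
       j_overhang = j_ov, overlap = best$k, score = best$score)
}

# end-anchored score of two equal-length overlap windows: position-wise
# base-matrix scores plus rotation/isobaric credit for mass-coincident
# windows (a local alignment would reward shifted internal matches and
# misjudge the overlap length)
overlap_score <- function(a, b, matrix) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  valid <- ca != "X" & cb != "X"
  if (!any(valid)) return(0L)
  direct <- sum(matrix$base_matrix[cbind(ca[valid], cb[valid])]) +
    matrix$wildcard_score * sum(!valid)
  if (all(valid) && a != b) {
    s <- set_step_score_window(a, b, matrix)
    if (!is.na(s)) return(max(direct, s))
  }
  direct
}

# rotation/isobaric score for whole windows of any length (the DP's
# per-step cap on N does not apply to the junction overlap check)
set_step_score_window <- function(a, b, matrix) {
  ca <- sort(strsplit(a, "")[[1]]); cb <- sort(strsplit(b, "")[[1]])
  if (identical(ca, cb)) return(matrix$rotation_per_residue * nchar(a))
  if (abs(sequence_mass(a) - sequence_mass(b)) <=
      matrix$isobaric_tolerance) {
    return(matrix$isobaric_per_residue * max(nchar(a), nchar(b)))
  }
  NA_integer_
}

#' Identity and coverage of a consensus against a known truth
#'
#' Identity is the fraction of exactly matching positions over the aligned
#' truth length, using the mass-based aligner to place the consensus on
#' the truth; coverage is the fraction of consensus positions supported by
#' at least one placed read. Wildcard X positions left unfilled are
#' stripped before the identity alignment.
#'
#' @param consensus A `consensus_sequence` (or a plain string, in which
#'   case coverage is `NA`).
#' @param truth Known-truth residue string.
#' @param matrix A [set_score_matrix()].
#' @return Named list: `identity`, `coverage`, `template_only_fraction`.
#' @export
identity_and_coverage <- function(consensus, truth,
                                  matrix = set_score_matrix()) {
  if (is.character(consensus)) {
    seq <- consensus
    coverage <- NA_real_
    tmpl_frac <- NA_real_
  } else {
    seq <- consensus$sequence
    coverage <- mean(consensus$depth >= 1L)
    tmpl_frac <- mean(consensus$template_only)
  }
  seq <- gsub("X", "", seq)
  if (!nzchar(seq)) {
    return(list(identity = 0, coverage = coverage,
                template_only_fraction = tmpl_frac))
  }
  aln <- mba_align(seq, truth, matrix)
  tchars <- strsplit(truth, "")[[1]]
  schars <- strsplit(seq, "")[[1]]
  ti <- aln$template_start; ri <- aln$read_start
  n_match <- 0L
  st <- aln$steps
  for (s in seq_len(nrow(st))) {
    if (st$kind[s] == "match" &&
        tchars[ti + 1] == schars[ri + 1]) {
      n_match <- n_match + 1L
    }
    ti <- ti + st$len_template[s]; ri <- ri + st$len_read[s]
  }
  span <- aln$template_end - aln$template_start
  list(identity = if (span > 0) n_match / span else 0,
       coverage = coverage, template_only_fraction = tmpl_frac)
}

#' Second template-matching pass on recombined chain templates
#'
#' Concatenates the recombined segment consensus sequences into one
#' chain-level template, re-places all reads on it and rebuilds the
#' consensus, as in the final assembly step.
#'
#' @param chain_template Character: the recombined V-CDR3-J(-C) sequence.
#' @param reads All reads (not only the first-pass placements).
#' @param matrix A [set_score_matrix()].
#' @param score_cutoff Placement cutoff for the second pass (default 5).
#' @param enforce_unique Ratio threshold as in [match_to_templates()].
#' @param aligner `"mba"` or `"swa"`.
#' @param name Template name for the recombined chain.
#' @return A `consensus_sequence` on the recombined template.
#' @export
recombine_and_rematch <- function(chain_template, reads,
                                  matrix = set_score_matrix(),
                                  score_cutoff = 5, enforce_unique = 0.9,
                                  aligner = c("mba", "swa"),
                                  name = "recombined") {
  aligner <- match.arg(aligner)
  tpl <- data.frame(name = name, species = "recombined", chain = name,
                    segment_class = "chain", sequence = chain_template,
                    stringsAsFactors = FALSE)
  placed <- match_to_templates(reads, tpl, matrix, score_cutoff,
                               enforce_unique, aligner)
  build_consensus(placed, as.list(tpl[1, ]))
}

#' Full template-based assembly of one antibody chain
#'
#' Runs the complete pipeline for one chain: ALC filtering, first-pass
#' placement on X-extended V and J plus C segments, per-segment consensus,
#' CDRH3 reconstruction from the V/J overhangs, construction of the
#' recombined chain template, and the second template-matching pass.
#' Where several templates of one segment class are supplied (e.g. V
#' alleles), the one accumulating the highest total placement score is
#' used.
#'
#' @param reads A `peptide_reads` table.
#' @param templates Template data.frame for one chain (segment classes V,
#'   J and optionally C).
#' @param matrix A [set_score_matrix()].
#' @param alc_cutoff ALC filter (default 0 = keep all).
#' @param score_cutoff Template-matching score cutoff (default 5).
#' @param recombine_cutoff CDRH3 overlap score cutoff (default 5).
#' @param enforce_unique Ratio threshold (default 0.9).
#' @param n_x Wildcard extension length on V (C-terminal) and J
#'   (N-terminal), default 15.
#' @param aligner `"mba"` or `"swa"`.
#' @return list: `consensus` (final chain `consensus_sequence`),
#'   `chain_template`, `cdrh3`, per-segment first-pass results, and the
#'   number of unplaced reads.
#' @export
assemble_chain <- function(reads, templates, matrix = set_score_matrix(),
                           alc_cutoff = 0, score_cutoff = 5,
                           recombine_cutoff = 5, enforce_unique = 0.9,
                           n_x = 15, aligner = c("mba", "swa")) {
  aligner <- match.arg(aligner)
  reads <- filter_reads(reads, alc_cutoff)
  if (!nrow(reads)) stop("no reads left after ALC filtering", call. = FALSE)
  stopifnot(all(c("V", "J") %in% templates$segment_class))
  ext <- templates
  is_v <- ext$segment_class == "V"
  is_j <- ext$segment_class == "J"
  ext[is_v, ] <- extend_with_wildcards(ext[is_v, , drop = FALSE], n_x, "C")
  ext[is_j, ] <- extend_with_wildcards(ext[is_j, , drop = FALSE], n_x, "N")

  placed <- match_to_templates(reads, ext, matrix, score_cutoff,
                               enforce_unique, aligner)
  n_unplaced <- nrow(reads) - length(unique(placed$read_index))

  segment_consensus <- list()
  for (cls in intersect(c("V", "J", "C"), ext$segment_class)) {
    cand <- ext[ext$segment_class == cls, , drop = FALSE]
    totals <- vapply(cand$name, function(nm) {
      sum(placed$raw_score[placed$template_name == nm])
    }, numeric(1))
    bestn <- cand$name[which.max(totals)]
    sub <- placed[placed$template_name == bestn, , drop = FALSE]
    segment_consensus[[cls]] <-
      build_consensus(sub, as.list(cand[cand$name == bestn, ]))
  }

  cdrh3 <- reconstruct_cdrh3(segment_consensus$V, segment_consensus$J,
                             matrix, recombine_cutoff)
  v_core <- core_consensus(segment_consensus$V)
  j_core <- core_consensus(segment_consensus$J)
  junction <- if (cdrh3$joined) cdrh3$sequence else
    paste0(cdrh3$v_overhang, "XXX", cdrh3$j_overhang)
  c_part <- if (!is.null(segment_consensus$C))
    segment_consensus$C$sequence else ""
  chain_template <- paste0(v_core, junction, j_core, c_part)

  final <- recombine_and_rematch(chain_template, reads, matrix,
                                 score_cutoff, enforce_unique, aligner)
  list(consensus = final, chain_template = chain_template, cdrh3 = cdrh3,
       segment_consensus = segment_consensus, placed = placed,
       n_unplaced = n_unplaced)
}

# consensus over the non-wildcard part of an X-extended template
core_consensus <- function(consensus) {
  tpl <- strsplit(consensus$template$sequence, "")[[1]]
  paste(consensus$chosen[tpl != "X"], collapse = "")
}

#' Export a consensus as FASTA
#'
#' @param consensus A `consensus_sequence` (or named character vector).
#' @param path File path.
#' @param name Record name.
#' @export
write_consensus_fasta <- function(consensus, path, name = "consensus") {
  seq <- if (is.character(consensus)) consensus else consensus$sequence
  writeLines(c(paste0(">", name), seq), path)
  invisible(path)
}
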