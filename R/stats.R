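# Binomial sequence-accuracy model and the evaluation summaries behind the
# alignment benchmarks (length-normalized score by ALC bin).

#' Probability of an exact number of sequencing errors
#'
#' Under the per-residue binomial accuracy model: with accuracy `a` and
#' sequence length `T`, the probability of exactly `k` wrong residues is
#' the binomial pmf `choose(T, k) a^(T-k) (1-a)^k`. The raw product
#' `a^C (1-a)^(T-C)` (the probability of one *specific* pattern of
#' errors, without the combinatorial factor) is available via
#' `p_error_pattern()`; the two coincide at `k = 0`.
#'
#' @param a Per-residue accuracy in \[0, 1\].
#' @param T Sequence length in residues.
#' @param k_errors Number of errors, `0 <= k <= T`.
#' @return Probability.
#' @export
#' @examples
#' p_zero_errors(0.99, 120)  # 0.299
p_exact_errors <- function(a, T, k_errors) {
  if (any(a < 0 | a > 1)) stop("accuracy must lie in [0, 1]", call. = FALSE)
  stopifnot(T >= 1, all(k_errors >= 0), all(k_errors <= T))
  stats::dbinom(k_errors, size = T, prob = 1 - a)
}

#' @rdname p_exact_errors
#' @param C Number of correct residues.
#' @export
p_error_pattern <- function(a, T, C) {
  if (any(a < 0 | a > 1)) stop("accuracy must lie in [0, 1]", call. = FALSE)
  stopifnot(T >= 1, all(C >= 0), all(C <= T))
  a^C * (1 - a)^(T - C)
}

#' @rdname p_exact_errors
#' @export
p_zero_errors <- function(a, T) {
  p_exact_errors(a, T, 0L)
}

#' Per-residue accuracy required for an error-free sequence
#'
#' Solves `a^T = p_target` for the accuracy: `a = p_target^(1/T)`.
#'
#' @param p_target Target probability of zero errors, in (0, 1\].
#' @param T Sequence length in residues.
#' @return Required accuracy.
#' @export
#' @examples
#' required_accuracy(0.99, 120)  # > 0.9999
required_accuracy <- function(p_target, T) {
  if (any(p_target <= 0) || any(p_target > 1)) {
    stop("p_target must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(T >= 1)
  p_target^(1 / T)
}

#' Length-normalized alignment score by ALC bin
#'
#' Groups placements by the reads' ALC and reports the mean and standard
#' deviation of the normalized alignment score (raw score divided by the
#' aligned template length) per bin.
#'
#' @param placed_reads Placements from [match_to_templates()] (needs
#'   `alc` and `normalized_score` columns).
#' @param bin_width ALC bin width (default 1 = per ALC value).
#' @return data.frame: `bin`, `mean_normalized_score`, `sd`, `n`.
#' @export
alc_binned_scores <- function(placed_reads, bin_width = 1) {
  stopifnot(nrow(placed_reads) > 0)
  bin <- floor(placed_reads$alc / bin_width) * bin_width
  agg <- lapply(split(placed_reads$normalized_score, bin), function(x) {
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
      n = length(x))
  })
  out <- data.frame(bin = as.numeric(names(agg)),
                    mean_normalized_score = vapply(agg, `[[`, 0, "mean"),
                    sd = vapply(agg, `[[`, 0, "sd"),
                    n = vapply(agg, `[[`, 0, "n"))
  rownames(out) <- NULL
  out[order(out$bin), , drop = FALSE]
}
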