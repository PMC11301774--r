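# Mass-coincidence survival analysis: enumerate all modified residue
# combinations up to a mass bound and ask what fraction can be told apart at
# a given mass precision.

#' Token alphabet for coincidence enumeration
#'
#' Expands a residue alphabet against a modification table: fixed
#' modifications replace the unmodified token (e.g. C is always
#' carbamidomethylated), variable modifications add a modified variant
#' alongside the unmodified one. N-terminal-only modifications yield tokens
#' flagged `nterm`, of which at most one may occur per composition.
#'
#' @param alphabet Character vector of residue symbols (default all 20).
#' @param mod_table Modification table ([default_modifications()]), or
#'   `NULL` for the bare alphabet.
#' @return data.frame with columns `token`, `mass`, `nterm`.
#' @export
composition_alphabet <- function(alphabet = names(residue_masses()),
                                 mod_table = default_modifications()) {
  base <- residue_masses()[alphabet]
  tokens <- data.frame(token = alphabet, mass = unname(base),
                       nterm = FALSE, stringsAsFactors = FALSE)
  if (is.null(mod_table) || nrow(mod_table) == 0L) return(tokens)
  for (i in seq_len(nrow(mod_table))) {
    tg <- intersect(strsplit(mod_table$targets[i], ",")[[1]], alphabet)
    if (!length(tg)) next
    lab <- paste0(tg, "[", mod_table$name[i], "]")
    add <- data.frame(token = lab,
                      mass = unname(base[tg]) + mod_table$delta_mass[i],
                      nterm = mod_table$terminus[i] == "N",
                      stringsAsFactors = FALSE)
    if (mod_table$fixed[i]) {
      tokens <- tokens[!tokens$token %in% tg, , drop = FALSE]
    }
    tokens <- rbind(tokens, add)
  }
  tokens[order(tokens$mass), , drop = FALSE]
}

#' Enumerate residue compositions up to a mass bound
#'
#' Generates every multiset of (optionally modified) residue tokens with
#' total mass at most `max_mass`. Multisets are used because sequences that
#' are permutations of one another coincide trivially in mass ("without
#' rotations"); each combination appears exactly once, as a canonical
#' sorted token tuple. N-terminal-only modifications (pyro-Glu) contribute
#' at most one token per composition.
#'
#' @param max_mass Upper mass bound in Da.
#' @param alphabet Residue alphabet.
#' @param mod_table Modification table or `NULL`.
#' @return data.frame with columns `composition` (tokens joined by `+`),
#'   `mass` (Da) and `length` (residue count), sorted by mass.
#' @export
#' @examples
#' enumerate_compositions(150, alphabet = c("G", "A"), mod_table = NULL)
enumerate_compositions <- function(max_mass,
                                   alphabet = names(residue_masses()),
                                   mod_table = default_modifications()) {
  tok <- composition_alphabet(alphabet, mod_table)
  ntok <- nrow(tok)
  out_comp <- character(0); out_mass <- numeric(0); out_len <- integer(0)
  # Depth-first over tokens in non-decreasing index order (multisets),
  # pruning by remaining mass. Token masses are sorted ascending, so once a
  # token no longer fits neither does any later one.
  recurse <- function(start, tokens, mass, n_nterm) {
    if (length(tokens)) {
      out_comp[length(out_comp) + 1L] <<-
        paste(sort(tokens), collapse = "+")
      out_mass[length(out_mass) + 1L] <<- mass
      out_len[length(out_len) + 1L] <<- length(tokens)
    }
    for (i in start:ntok) {
      if (i > ntok) break
      new_mass <- mass + tok$mass[i]
      if (new_mass > max_mass + 1e-9) {
        if (tok$mass[i] > 0) break else next
      }
      if (tok$nterm[i] && n_nterm >= 1L) next
      recurse(i, c(tokens, tok$token[i]), new_mass,
              n_nterm + as.integer(tok$nterm[i]))
    }
  }
  if (ntok > 0L && any(tok$mass <= max_mass)) {
    recurse(1L, character(0), 0, 0L)
  }
  res <- data.frame(composition = out_comp, mass = out_mass,
                    length = out_len, stringsAsFactors = FALSE)
  res[order(res$mass, res$composition), , drop = FALSE]
}

#' Count mass-distinguishable groups at a given precision
#'
#' Sorts the masses ascending and walks the list, greedily merging each
#' entry into the current group whenever it lies within `precision` of the
#' *previous* entry (chained merging, not a radius from the group's first
#' member). Returns the number of groups.
#'
#' @param masses Numeric vector of masses (Da), or a data.frame with a
#'   `mass` column as returned by [enumerate_compositions()].
#' @param precision Merge precision in Da (>= 0).
#' @return Integer group count.
#' @export
#' @examples
#' count_unique_masses(c(57.02, 71.04, 114.04, 114.04), 0.01)  # 3
count_unique_masses <- function(masses, precision) {
  if (is.data.frame(masses)) masses <- masses$mass
  stopifnot(precision >= 0)
  if (!length(masses)) return(0L)
  m <- sort(masses)
  # a new group starts wherever the gap to the previous mass exceeds the
  # precision (floating-point slack covers composition-identical masses
  # summed in different orders)
  sum(diff(m) > precision + 1e-9) + 1L
}

#' Mass-coincidence survival curve
#'
#' For every combination of precision and upper mass bound, enumerates all
#' modified residue combinations up to the bound and reports the fraction
#' that are distinguishable by mass at that precision (the "survival"
#' fraction, or specificity).
#'
#' @param precisions Numeric vector of precisions in Da.
#' @param max_masses Numeric vector of upper mass bounds in Da.
#' @param alphabet Residue alphabet.
#' @param mod_table Modification table or `NULL`.
#' @return data.frame with columns `precision`, `max_mass`, `n_sets`,
#'   `n_groups`, `fraction`.
#' @export
survival_curve <- function(precisions, max_masses,
                           alphabet = names(residue_masses()),
                           mod_table = default_modifications()) {
  stopifnot(length(precisions) > 0, length(max_masses) > 0)
  all_sets <- enumerate_compositions(max(max_masses), alphabet, mod_table)
  grid <- expand.grid(precision = precisions, max_mass = max_masses,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    sub <- all_sets$mass[all_sets$mass <= grid$max_mass[k] + 1e-9]
    n <- length(sub)
    g <- if (n) count_unique_masses(sub, grid$precision[k]) else 0L
    data.frame(precision = grid$precision[k], max_mass = grid$max_mass[k],
               n_sets = n, n_groups = g,
               fraction = if (n) g / n else NA_real_)
  })
  do.call(rbind, res)
}
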