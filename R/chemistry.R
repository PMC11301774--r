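# Monoisotopic mass bookkeeping for residues, modifications and sequences.
#
# All residue masses are derived from elemental compositions and the
# monoisotopic atomic masses below, so that exact composition-level
# coincidences (GG = N, GA = Q, AS = GT) hold to floating-point accuracy.

# Monoisotopic atomic masses in Da (CODATA 2018 / IUPAC 2021 atomic mass
# evaluation, >= 6 decimal places).
ELEMENT_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706912
)

PROTON_MASS <- 1.0072764669
WATER_MASS  <- 2 * ELEMENT_MASS[["H"]] + ELEMENT_MASS[["O"]]

# Elemental compositions of the 20 canonical amino acid *residues*
# (i.e. amino acid minus water, the form they take inside a peptide chain).
RESIDUE_COMPOSITION <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

composition_mass <- function(comp) {
  sum(ELEMENT_MASS[names(comp)] * comp)
}

# Named vector of residue monoisotopic masses, computed once at load.
RESIDUE_MASS <- vapply(RESIDUE_COMPOSITION, composition_mass, numeric(1))

#' Canonical residue monoisotopic masses
#'
#' Monoisotopic masses (Da) of the 20 canonical amino acid residues on the
#' residue-mass scale (amino acid minus water). Masses are derived from
#' elemental compositions, so isobaric identities such as L = I and
#' composition-level coincidences (GG = N) are exact.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
#' @examples
#' residue_masses()[["G"]]  # 57.02146
residue_masses <- function() RESIDUE_MASS

#' Default modification set
#'
#' The shipped set of post-translational and artefactual modifications:
#' Carbamidomethyl (fixed on C), Oxidation (variable on W/H/M), Deamidated
#' (variable on N/Q), Glu->pyro-Glu (variable, N-terminal E) and
#' Gln->pyro-Glu (variable, N-terminal Q). Pyro-Glu modifications carry
#' negative deltas (loss of water, respectively ammonia) and apply only at
#' the N terminus.
#'
#' @return A data.frame with columns `name`, `delta_mass` (Da), `targets`
#'   (comma separated residue symbols), `terminus` (`"N"` or `""`) and
#'   `fixed` (logical).
#' @export
default_modifications <- function() {
  data.frame(
    name = c("Carbamidomethyl", "Oxidation", "Deamidated",
             "Glu->pyro-Glu", "Gln->pyro-Glu"),
    delta_mass = c(
      composition_mass(c(C = 2, H = 3, N = 1, O = 1)),   # +C2H3NO
      ELEMENT_MASS[["O"]],                                # +O
      composition_mass(c(O = 1)) - composition_mass(c(N = 1, H = 1)), # +O -NH
      -WATER_MASS,                                        # -H2O
      -composition_mass(c(N = 1, H = 3))                  # -NH3
    ),
    targets = c("C", "W,H,M", "N,Q", "E", "Q"),
    terminus = c("", "", "", "N", "N"),
    fixed = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

mod_targets <- function(mods) strsplit(mods$targets, ",", fixed = TRUE)

#' Residue monoisotopic mass with modifications
#'
#' @param symbol One-letter code of a canonical residue.
#' @param modifications Character vector of modification names to apply
#'   (from the active modification table), or `NULL`.
#' @param mod_table Modification table, defaults to
#'   [default_modifications()].
#' @return Mass in Da (residue scale, no water term).
#' @export
#' @examples
#' residue_mass("G")                 # 57.02146
#' residue_mass("M", "Oxidation")    # 147.03540
residue_mass <- function(symbol, modifications = NULL,
                         mod_table = default_modifications()) {
  if (length(symbol) != 1L || !symbol %in% names(RESIDUE_MASS)) {
    stop("unknown residue symbol: '", symbol, "'", call. = FALSE)
  }
  m <- RESIDUE_MASS[[symbol]]
  for (mod in modifications) {
    i <- match(mod, mod_table$name)
    if (is.na(i)) stop("unknown modification: '", mod, "'", call. = FALSE)
    tg <- strsplit(mod_table$targets[i], ",", fixed = TRUE)[[1]]
    if (!symbol %in% tg) {
      stop("modification '", mod, "' is not applicable to residue '",
           symbol, "'", call. = FALSE)
    }
    m <- m + mod_table$delta_mass[i]
  }
  m
}

#' Sequence mass on the residue scale
#'
#' Sum of residue monoisotopic masses plus any modification deltas; no water
#' term is included (peptide neutral mass = sequence mass + 18.01056 Da,
#' applied only when computing fragment or precursor masses).
#'
#' @param sequence Residue string, e.g. `"GG"`. May be empty.
#' @param modifications Optional modifications: a character vector of
#'   modification names applied once each to the sequence, or a list of such
#'   vectors (one element per modified position).
#' @param mod_table Modification table.
#' @return Mass in Da.
#' @export
#' @examples
#' sequence_mass("GG") - sequence_mass("N")  # 0 (exact coincidence)
sequence_mass <- function(sequence, modifications = NULL,
                          mod_table = default_modifications()) {
  if (nchar(sequence) == 0L) return(0)
  syms <- strsplit(sequence, "")[[1]]
  bad <- setdiff(syms, names(RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown residue symbol: '", bad[[1]], "'", call. = FALSE)
  }
  total <- sum(RESIDUE_MASS[syms])
  if (!is.null(modifications)) {
    if (!is.list(modifications)) modifications <- list(modifications)
    for (k in seq_along(modifications)) {
      for (mod in modifications[[k]]) {
        i <- match(mod, mod_table$name)
        if (is.na(i)) stop("unknown modification: '", mod, "'", call. = FALSE)
        total <- total + mod_table$delta_mass[i]
      }
    }
  }
  total
}

#' Absolute mass difference between two (modified) sequences
#'
#' @param seq_a,seq_b Residue strings.
#' @param mods_a,mods_b Modifications for each sequence, as in
#'   [sequence_mass()].
#' @param mod_table Modification table.
#' @return Absolute difference in Da.
#' @export
#' @examples
#' mass_difference("M", "F", mods_a = "Oxidation")  # 0.033
mass_difference <- function(seq_a, seq_b, mods_a = NULL, mods_b = NULL,
                            mod_table = default_modifications()) {
  abs(sequence_mass(seq_a, mods_a, mod_table) -
      sequence_mass(seq_b, mods_b, mod_table))
}

#' Read a plain-text modification definition file
#'
#' Tab-separated with columns `name`, `delta_mass`, `targets`, `terminus`,
#' `fixed`; `#` lines are comments. The format round-trips the shipped
#' default set via [write_modifications()].
#'
#' @param path File path.
#' @return Modification table (same shape as [default_modifications()]).
#' @export
read_modifications <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "delta_mass", "targets", "terminus", "fixed")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("modification file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$terminus[is.na(df$terminus)] <- ""
  df$fixed <- as.logical(df$fixed)
  df[need]
}

#' Write a modification table to the plain-text definition format
#'
#' @param mods Modification table.
#' @param path File path.
#' @export
write_modifications <- function(mods, path) {
  utils::write.table(mods, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
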