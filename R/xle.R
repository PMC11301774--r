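# Satellite-ion (w-ion) based isoleucine/leucine disambiguation.
#
# Electron-based fragmentation (ETD/EThcD) produces c/z backbone fragments;
# secondary fragmentation of z-ions cleaves the side chain at the beta
# carbon, giving w-ions whose loss mass distinguishes I from L: losses of
# CH3 (15.0235 Da) or C2H5 (29.0391 Da) for isoleucine, C3H7 (43.0548 Da)
# for leucine.

#' Satellite-ion side-chain losses
#'
#' Exact monoisotopic masses (Da) of the side-chain fragments lost when a
#' z-ion undergoes secondary cleavage at an I/L residue; the literature's
#' nominal 15/29/43 Da.
#'
#' @return Named numeric vector: `I_CH3`, `I_C2H5`, `L_C3H7`.
#' @export
satellite_losses <- function() {
  c(I_CH3  = composition_mass(c(C = 1, H = 3)),
    I_C2H5 = composition_mass(c(C = 2, H = 5)),
    L_C3H7 = composition_mass(c(C = 3, H = 7)))
}

#' Theoretical fragment ions of a peptide
#'
#' Computes b/y/c/z series neutral masses and m/z values. Conventions
#' (residue-mass scale): b = prefix residue sum; y = suffix residue sum +
#' water; c = b + NH3; z = y - NH3 + H (the z-radical species observed in
#' electron-based dissociation). w-ions are derived from z-ions by
#' [assign_xle()] and [generate_spectra()].
#'
#' @param peptide Residue string.
#' @param charge_max Maximum fragment charge (>= 1).
#' @param ion_types Subset of `c("b", "y", "c", "z")`.
#' @return data.frame: `ion` (label like `"z3"`), `type`, `index`,
#'   `charge`, `neutral_mass`, `mz`.
#' @export
#' @examples
#' theoretical_fragments("GG", 1, "y")$neutral_mass  # y1 = 75.03202
theoretical_fragments <- function(peptide, charge_max = 1L,
                                  ion_types = c("c", "z")) {
  stopifnot(charge_max >= 1L)
  if (length(ion_types)) {
    ion_types <- match.arg(ion_types, c("b", "y", "c", "z"),
                           several.ok = TRUE)
  }
  syms <- strsplit(peptide, "")[[1]]
  bad <- setdiff(syms, names(RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown residue symbol: '", bad[[1]], "'", call. = FALSE)
  }
  n <- length(syms)
  if (n < 2L || !length(ion_types)) {
    return(data.frame(ion = character(0), type = character(0),
                      index = integer(0), charge = integer(0),
                      neutral_mass = numeric(0), mz = numeric(0)))
  }
  res_mass <- unname(RESIDUE_MASS[syms])
  prefix <- cumsum(res_mass)[-n]           # b_i, i = 1..n-1
  suffix <- rev(cumsum(rev(res_mass)))[-1] # residue sum of y_i, i = n-1..1
  nh3 <- composition_mass(c(N = 1, H = 3))
  h <- ELEMENT_MASS[["H"]]
  series <- list(
    b = prefix,
    y = suffix + WATER_MASS,
    c = prefix + nh3,
    z = suffix + WATER_MASS - nh3 + h
  )
  idx <- list(b = seq_len(n - 1L), y = (n - 1L):1L,
              c = seq_len(n - 1L), z = (n - 1L):1L)
  out <- list()
  for (tp in ion_types) {
    for (z in seq_len(charge_max)) {
      out[[length(out) + 1L]] <- data.frame(
        ion = paste0(tp, idx[[tp]],
                     if (z > 1L) paste0("^", z) else ""),
        type = tp, index = idx[[tp]], charge = z,
        neutral_mass = series[[tp]],
        mz = (series[[tp]] + z * PROTON_MASS) / z,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match theoretical fragments against spectrum peaks
#'
#' Each theoretical m/z is matched to the nearest peak within tolerance;
#' a single peak may annotate several ions.
#'
#' @param spectrum A spectrum list with `mz` and `intensity` vectors (see
#'   [read_mgf()]).
#' @param theoretical data.frame from [theoretical_fragments()] (any
#'   data.frame with an `mz` column).
#' @param tolerance Match tolerance; interpreted as ppm when
#'   `unit = "ppm"` (default 20), as Da when `unit = "da"`.
#' @param unit `"ppm"` or `"da"`.
#' @return The theoretical table with `peak_mz`, `peak_intensity`,
#'   `delta` columns (`NA` where unmatched).
#' @export
match_peaks <- function(spectrum, theoretical, tolerance = 20,
                        unit = c("ppm", "da")) {
  unit <- match.arg(unit)
  stopifnot(tolerance > 0)
  mzs <- spectrum$mz
  theoretical$peak_mz <- NA_real_
  theoretical$peak_intensity <- NA_real_
  theoretical$delta <- NA_real_
  if (!length(mzs)) return(theoretical)
  for (i in seq_len(nrow(theoretical))) {
    tmz <- theoretical$mz[i]
    tol <- if (unit == "ppm") tmz * tolerance * 1e-6 else tolerance
    d <- abs(mzs - tmz)
    j <- which.min(d)
    if (d[j] <= tol) {
      theoretical$peak_mz[i] <- mzs[j]
      theoretical$peak_intensity[i] <- spectrum$intensity[j]
      theoretical$delta[i] <- mzs[j] - tmz
    }
  }
  theoretical
}

#' Assign I/L identities from satellite ions
#'
#' For every I/L (Xle) position of the peptide, searches the spectrum for
#' w-ion peaks at the mass of the z-ion spanning that position minus each
#' candidate side-chain loss (15.0235 / 29.0391 Da for I, 43.0548 Da for
#' L). The call follows the matched evidence; when both I- and L-type
#' satellites match, the larger summed intensity wins (tie: undetermined,
#' fall back). Without satellite evidence the call falls back to the
#' germline residue when the germline carries I or L at that position, or
#' to L otherwise.
#'
#' @param peptide Residue string containing at least one I or L.
#' @param spectrum Spectrum list (`mz`, `intensity`), or `NULL` (all
#'   positions fall back).
#' @param tolerance Match tolerance in ppm (default 20).
#' @param germline Optional germline residue string aligned to the
#'   peptide (same length), or a vector of single residues per position.
#' @param charge_max Maximum satellite charge searched.
#' @return data.frame: `position` (0-based), `peptide_residue`, `call`,
#'   `basis` (`satellite`/`germline`/`default_L`), `i_intensity`,
#'   `l_intensity`, `matched_losses`.
#' @export
assign_xle <- function(peptide, spectrum, tolerance = 20, germline = NULL,
                       charge_max = 1L) {
  syms <- strsplit(peptide, "")[[1]]
  pos <- which(syms %in% c("I", "L")) - 1L
  if (!length(pos)) {
    stop("peptide contains no I/L position", call. = FALSE)
  }
  if (!is.null(germline) && length(germline) == 1L) {
    germline <- strsplit(germline, "")[[1]]
  }
  losses <- satellite_losses()
  n <- length(syms)
  zfr <- if (!is.null(spectrum)) {
    theoretical_fragments(peptide, charge_max = 1L, ion_types = "z")
  } else NULL
  rows <- lapply(pos, function(p) {
    i_int <- 0; l_int <- 0; matched <- character(0)
    # the z-ion whose N-terminal residue is position p covers residues
    # p..n-1, i.e. z_{n-p}; secondary cleavage of that residue's side
    # chain yields the w-ion (for p = 0 the full-length z species is used)
    k <- n - p
    if (!is.null(spectrum)) {
      z_neutral <- if (k <= n - 1L) {
        zfr$neutral_mass[zfr$index == k][1]
      } else {
        sequence_mass(peptide) + WATER_MASS -
          composition_mass(c(N = 1, H = 3)) + ELEMENT_MASS[["H"]]
      }
      for (ln in names(losses)) {
        for (z in seq_len(charge_max)) {
          w_mz <- (z_neutral - losses[[ln]] + z * PROTON_MASS) / z
          tol <- w_mz * tolerance * 1e-6
          d <- abs(spectrum$mz - w_mz)
          if (length(d) && min(d) <= tol) {
            j <- which.min(d)
            matched <- union(matched, ln)
            if (startsWith(ln, "I")) {
              i_int <- i_int + spectrum$intensity[j]
            } else {
              l_int <- l_int + spectrum$intensity[j]
            }
          }
        }
      }
    }
    if (i_int > l_int) {
      call <- "I"; basis <- "satellite"
    } else if (l_int > i_int) {
      call <- "L"; basis <- "satellite"
    } else {
      g <- if (!is.null(germline) && length(germline) > p) {
        germline[p + 1L]
      } else NA_character_
      if (!is.na(g) && g %in% c("I", "L")) {
        call <- g; basis <- "germline"
      } else {
        call <- "L"; basis <- "default_L"
      }
    }
    data.frame(position = p, peptide_residue = syms[p + 1L], call = call,
               basis = basis, i_intensity = i_int, l_intensity = l_int,
               matched_losses = paste(matched, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-position I/L calls as TSV
#'
#' @param calls data.frame from [assign_xle()].
#' @param path File path.
#' @export
write_xle_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an MGF peak list
#'
#' Minimal Mascot Generic Format reader: BEGIN IONS / END IONS blocks with
#' TITLE, PEPMASS, CHARGE headers and mz/intensity peak lines.
#'
#' @param path File path.
#' @return List of spectra; each a list with `title`, `precursor_mz`,
#'   `precursor_charge`, `mz`, `intensity` (peaks sorted by m/z).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pmz <- NA_real_; pz <- NA_integer_
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pmz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), " ")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          pz <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
          xs <- strsplit(ln, "[ \t]+")[[1]]
          mz <- c(mz, as.numeric(xs[1]))
          int <- c(int, as.numeric(xs[2]))
        }
        i <- i + 1L
      }
      o <- order(mz)
      spectra[[length(spectra) + 1L]] <-
        list(title = title, precursor_mz = pmz, precursor_charge = pz,
             mz = mz[o], intensity = int[o])
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra as MGF
#'
#' @param spectra List of spectrum lists (as from [read_mgf()]).
#' @param path File path.
#' @export
write_mgf <- function(spectra, path) {
  out <- character(0)
  for (sp in spectra) {
    out <- c(out, "BEGIN IONS",
             paste0("TITLE=", sp$title %||% "spectrum"),
             if (!is.null(sp$precursor_mz) && !is.na(sp$precursor_mz))
               paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)),
             if (!is.null(sp$precursor_charge) &&
                 !is.na(sp$precursor_charge))
               paste0("CHARGE=", sp$precursor_charge, "+"),
             paste(format(sp$mz, digits = 10, trim = TRUE),
                   format(sp$intensity, digits = 6, trim = TRUE)),
             "END IONS", "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Annotated-spectrum JSON export
#'
#' Serializes a spectrum with its matched fragment annotations for
#' downstream rendering.
#'
#' @param spectrum Spectrum list.
#' @param annotations data.frame from [match_peaks()].
#' @param path File path.
#' @export
write_annotated_spectrum_json <- function(spectrum, annotations, path) {
  jsonlite::write_json(
    list(title = spectrum$title,
         precursor_mz = spectrum$precursor_mz,
         precursor_charge = spectrum$precursor_charge,
         peaks = data.frame(mz = spectrum$mz,
                            intensity = spectrum$intensity),
         annotations = annotations[!is.na(annotations$peak_mz), ,
                                   drop = FALSE]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
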