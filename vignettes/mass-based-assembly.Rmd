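---
title: "Mass-coincidence-aware assembly of de novo peptide reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-coincidence-aware assembly of de novo peptide reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massalign)
```

## The problem

Bottom-up proteomics can sequence an antibody directly from the secreted
protein: peptides from a proteolytic digest are sequenced de novo from
fragmentation spectra and assembled against germline V/J/C gene-segment
templates into full heavy- and light-chain consensus sequences. The
limiting factor is not the assembly but the error structure of de novo
peptide sequencing, which is dominated by *mass coincidences*:

1. isoleucine and leucine have identical residue masses;
2. sets of consecutive residues can be isobaric as a group — rotations
   (`AS` = `SA`), equal-length recompositions (`AS` = `GT`) and
   different-length recompositions (`GG` = `N`, `GA` = `Q`) — whenever
   the fragment ions separating them are missing;
3. some residues are near-isobaric within instrument precision
   (K vs Q: 0.036 Da; oxidized M vs F: 0.033 Da);
4. sample handling introduces deamidation (N→D, Q→E), a real chemical
   change of exactly +0.98402 Da.

`massalign` implements a template-based assembler whose alignment engine
understands category 2 explicitly, together with the surrounding
machinery: a survival analysis quantifying how fast mass coincidences
accumulate, satellite-ion (w-ion) disambiguation of I/L, a binomial
accuracy model for whole-domain error probabilities, readers for common
de novo output formats, a variant graph for polyclonal mixtures, and a
seeded synthetic-fixture generator used throughout the test suite.

## Mass bookkeeping

All residue masses derive from elemental compositions and monoisotopic
atomic masses (CODATA/IUPAC values, at least six decimals), on the
*residue-mass* scale (amino acid minus water). Water (18.01056 Da) is
added only when fragment or precursor neutral masses are formed. Because
`GG` and `N` share the elemental formula C4H6N2O2, composition-level
coincidences are exact to floating-point accuracy; the internal
"exact" tolerance of 1e-6 Da absorbs summation-order effects only.

The shipped modification set is Carbamidomethyl (fixed on C), Oxidation
(variable on W/H/M, one delta for all three targets), Deamidated
(variable on N/Q) and the two pyro-Glu modifications, modelled as
N-terminal-only variable modifications with negative deltas (loss of
water from E, of ammonia from Q). A plain-text definition format
(`read_modifications()` / `write_modifications()`) lets users extend the
set; it round-trips the defaults.

## The coincidence survival analysis

`enumerate_compositions()` generates every multiset of (modified)
residue tokens up to a mass bound — multisets, because permutations
coincide trivially ("not counting rotations"). Variable modifications
multiply the token alphabet; fixed modifications replace the unmodified
token; N-terminal-only tokens occur at most once per multiset.
Enumeration is a depth-first walk in non-decreasing token order with
mass pruning; no length cap is applied beyond the mass bound itself.

`count_unique_masses()` implements the grouping rule as a chained greedy
merge: sort by mass and merge each entry with its predecessor whenever
the gap is within the precision. On a sorted list this equals the
connected components of the pairwise within-precision graph, which the
tests verify against a union-find oracle.

One property deserves a caveat. The distinguishable fraction is
guaranteed non-increasing in the precision (merging can only coarsen),
and it falls with the mass bound throughout the accumulation regime
(bounds of 150 Da and up at every precision we test). It is *not*
globally monotone in the bound: between 115 and 150 Da the fraction
rises slightly (0.750 to 0.760 with the default modification set),
because that interval adds proportionally more well-separated
compositions than collisions. The tests assert exactly what holds.

## Mass-based alignment

The aligner is a local dynamic program over an extended step set. To the
classic Smith–Waterman steps (single-residue match/mismatch scored by a
modified BLOSUM62, affine gaps) it adds two families of multi-residue
steps of up to N residues per side:

* **rotation** — the two windows are permutations of each other
  (equal length ≥ 2, different spelling): score 3 per residue involved;
* **isobaric** — the windows differ in composition but agree in mass
  within the isobaric tolerance (lengths may differ): score 2 × the
  larger window length.

Both constants sit strictly below the smallest BLOSUM62 diagonal entry
(4) per residue, so a direct match always wins where one exists; the
coincidence steps only rescue windows that would otherwise be mismatches
and gaps. At every cell the highest-scoring available step is chosen.

Default parameters, and why:

| parameter | default | rationale |
|---|---|---|
| N (max set length) | 3 | covers all the canonical category-2 coincidences (lengths 1–3) while keeping the step set small; configurable |
| isobaric tolerance | 1e-6 Da | exact composition level; raise to ~0.05 Da to absorb category-3 near-coincidences on low-precision (ion-trap) data |
| base matrix | BLOSUM62 with I/L raised to the match score | I/L are mass-indistinguishable in reads, so an I/L "mismatch" carries no evidence against a placement |
| gap open / extend | −12 / −1 | conventional affine penalties for short-read placement; a gap of length L costs −12 − L |
| wildcard X score | +2 | below any direct match but positive, so overhanging reads extend into the X region without X ever joining a rotation/isobaric set |

Tie-breaks are deterministic: match > rotation > isobaric > mismatch >
gap-in-read > gap-in-template, shorter steps first, and the first
maximal cell in row-major order anchors the traceback. Rotation and
isobaric steps may chain without an intervening match. Coordinates are
0-based half-open internally.

The DP core is compiled (Rcpp); an independent memoized-recursion
oracle (`enumerate_paths_oracle()`) explores every step decomposition
for sequences up to 10 residues, and the tests require exact score
agreement on hundreds of seeded random pairs, plus the structural
guarantee that the Smith–Waterman score (the same engine restricted to
single-residue steps) never exceeds the mass-based score.

## Template-based assembly

Reads are filtered on ALC, aligned to every template, and placed when
the raw score reaches the cutoff (default 5, also the recombination
default). `enforce_unique` (default 0.9) is interpreted as a best-score
ratio: a read is placed only on templates scoring at least 0.9 × its
best raw score — the parameter's exact semantics are not published, and
this reading reproduces its evident purpose (suppressing ambiguous
multi-template placements) with a single number.

The consensus weighs each read residue by
`local_confidence / 100 × area` (product — the combination rule is not
published either; missing areas default to 1, missing confidences to
the ALC). Reads spanning rotation/isobaric steps contribute their
residue window as a *set option* over the spanned template positions:
the read supports the mass, not the spelling. Where a set option wins
the argmax, the template's (mass-equivalent) spelling is kept and the
position flagged ambiguous. Uncovered positions fall back to the
template residue, flagged template-only. Placements lying entirely
inside the wildcard extension are excluded: every X offset scores the
same, so such placements carry no positional information (and in
practice they smear the junction consensus).

CDRH3 cannot be templated (the D segment is too short and variable), so
the V and J templates are extended with wildcard X runs (default 15,
user-configurable), overhanging reads fill them, and the two read-derived
overhangs are merged at the best-scoring overlap. The overlap score is
end-anchored and position-wise (base matrix, plus whole-window
rotation/isobaric credit): a local alignment must not be used here,
because it happily rewards a shifted internal match and then reports the
wrong overlap length. If no overlap reaches the recombination cutoff the
fragments are reported unjoined. The recombined V–CDRH3–J(–C) chain then
serves as the template for a second, chain-level matching pass that
produces the final consensus.

Identity against a known truth counts exactly matching positions over
the aligned truth span (mass-based alignment of consensus to truth);
coverage is the fraction of positions with read support.

## I/L disambiguation from satellite ions

Electron-based fragmentation yields c/z backbone ions; secondary
cleavage of a z-ion's N-terminal side chain at the beta carbon produces
w-ions. The lost fragment differs between the isomers — CH3 (15.0235 Da)
or C2H5 (29.0391 Da) from isoleucine, C3H7 (43.0548 Da) from leucine —
so a matched w-ion identifies the residue. For each Xle position the
package searches for peaks at the spanning z-ion mass minus each
candidate loss (exact masses, 20 ppm default tolerance; the nominal
15/29/43 are rounded values). Conflicting evidence resolves by summed
matched intensity; a tie falls through to the fallback: the germline
residue where it is I or L, otherwise L. d-ions (the analogous a-ion
satellites) are implemented symmetrically but off by default — the
mechanism of record is w-ions from ETD-type spectra. When several
spectra cover one position, intensity-weighted votes are summed.

## The synthetic fixture generator

`fixture_spec()` defines the study conditions; all randomness flows
from its seed. Ground truth is built from a shipped, hand-composed
germline-like template set (clearly synthetic; no germline database is
bundled): 8 substitutions in each V and 1 in each J emulate somatic
hypermutation, and a random 15-residue CDRH3 junction (the typical
human length) joins the heavy chain. Reads of 9–14 residues tile each
chain at mean depth 6; windows may overhang the termini and are clipped
to ≥ 6 residues, because interior-only tiling under-covers chain ends
about two-fold, which real digests (short terminal peptides) do not.

Errors are injected per read: 5% adjacent transpositions plus 5% exact
isobaric substitutions — the 10% category-2 condition — drawn only from
the exact-composition coincidence table, so planted errors are truly
mass-silent; optional K/Q swaps, deamidation and I/L swaps cover the
other categories and default to 0. ALC is assigned inversely to the
injected error count (clean reads 93–97, error reads 83–87) and local
confidence is depressed inside the error window. Synthetic spectra
carry the c/z ladder, the truth-consistent w-ions with configurable
emission probability, and low-intensity noise peaks (intensity an order
of magnitude below the satellites, so a noise collision cannot outvote
real evidence).

What the generator does *not* emulate: realistic intensity and
chromatography models, correlated errors within a read, chimeric
spectra, and the long tail of low-quality reads in real PEAKS exports.
Passing the end-to-end tests therefore demonstrates the assembler's
tolerance to mass-coincidence errors under controlled conditions, not
the full error profile of experimental data.

## Evaluation choices

The end-to-end comparison between the mass-based and Smith–Waterman
aligners is stochastic (it depends on where the tiling drops reads and
errors), so the test evaluates it over five replicate fixtures and
compares mean identities: the mass-based consensus must average ≥ 0.99
identity, never fall below the Smith–Waterman consensus on any
replicate, and beat it strictly on the mean. A single replicate of a
strict inequality would be a coin-flip over seeds; the mean over a
small panel is the property actually worth asserting. Problem sizes
throughout the suite (chains of ~140 residues, ~130 reads per fixture,
oracle pairs up to 10 residues, enumeration bounds up to 300 Da) were
chosen so the whole suite exercises every code path at desk scale.

The binomial accuracy model exposes both the plain pattern probability
`a^C (1−a)^(T−C)` and the proper pmf with the binomial coefficient;
the two coincide in the zero-error case used for the headline numbers
(P = 0.002 at a = 0.95 and P = 0.299 at a = 0.99 for T = 120, and
a > 0.9999 needed for P > 0.99). Error-count curves use the pmf: the
probability of *some* k errors must sum to one over k.

## Known limitations

* Polyclonal mixtures: the variant graph surfaces co-occurring variants,
  but no automatic clone separation is attempted.
* The junction merge assumes the two overhangs genuinely overlap; with a
  coverage gap inside CDRH3 the fragments are reported unjoined (or, if
  a short spurious overlap clears the cutoff, merged short — the
  ambiguity is visible in the reported overlap score).
* Identity at the extreme chain termini depends on local-alignment
  clipping: a mutated first or last residue supported by a single read
  may be dropped in favour of the template spelling.
* Only substitution-style somatic hypermutation is modelled in fixtures;
  insertions/deletions relative to germline are handled by the aligner
  but not planted by the generator.
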