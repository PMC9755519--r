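---
title: "Methods: assay models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assay models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartchar)
```

smartchar implements the computational half of the standard biochemical
characterization assays for compact RNA-guided nucleases. This vignette
documents the model behind each pipeline, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate — i.e., what a passing test suite does and does not show
about real data.

## PAM discovery from a randomized-library cleavage assay

The assay ligates sequencing adapters onto the blunted cleavage products of
an 8N PAM plasmid library, so every read has the architecture

```
adapter | protospacer remnant (d nt) | PAM (8 nt) | backbone anchor (14-24 nt)
```

in one of the two orientations. The pipeline:

1. **Quality filter.** Reads with mean Phred score strictly greater than
   `min_mean_q = 20` are retained. A per-read mean is used rather than a
   per-base or windowed rule: the downstream exact-match step already
   rejects reads with errors in the anchor or adapter, so the scalar filter
   only needs to remove globally bad reads. Exposed as `min_mean_q`.
2. **Anchor location** (`locate_anchor`). The 14–24 nt backbone anchor is
   matched **exactly**, first forward then on the reverse complement;
   leftmost match wins. Exact matching (0 mismatches) mirrors the assay's
   exclusion of reads without an exact reference/adapter match; with a 16 nt
   anchor, the chance of a spurious hit in a random 100-mer is ~2×10⁻⁸.
3. **Observation extraction** (`extract_observations`). The `pam_length`
   bases on the protospacer side of the anchor are the putative PAM; the cut
   distance is the number of bases between the end of the ligated adapter
   and the PAM-proximal edge (0 = adapter flush against the PAM). Reads
   whose adapter cannot be found upstream of the PAM in the same orientation
   signal chimeric or undigested molecules and are tallied per reason in a
   `discards` attribute, so `n_raw − n_retained` is fully accounted.
4. **Cut-site filter** (`build_profile`). The modal cut distance is computed
   jointly over all observations (a single mode, not per-PAM; ties break
   toward the smaller, PAM-proximal distance, a deterministic choice
   favouring the biologically expected geometry), and only observations
   within ±2 of the mode enter the profile.
5. **PFM, information, consensus.** Each PFM cell receives a pseudocount of
   0.5 before row normalization (Laplace-style smoothing keeps logarithms
   finite at depths where a base may be unobserved). Information content is
   `2 + Σ_b f log2 f` bits; logo heights are `f × I`.

**Consensus threshold.** `call_consensus` includes a base at a position when
its frequency is at least `include_threshold = 0.2`; if all four bases
qualify, or none does, the position is `N`. The threshold sits deliberately
*below* the uniform expectation of 0.25: at an uninformative position the
four observed frequencies scatter tightly around 0.25 (binomial sd ≈ 0.004
at 10⁴ reads), so with any threshold at or above 0.25 roughly half the bases
would drop out by chance and the position would be mis-called as partially
informative. At 0.2, all four bases qualify at uninformative positions
(collapsing to `N`, many sds above the threshold), while a base that is
genuinely absent from a degenerate position sits near 0 and a true member of
even a three-base degenerate set sits at ≥ 1/3. Any threshold in roughly
(0.26, 0.32) would *invert* this failure mode for three-base codes; 0.2 is
the stable choice for the full IUPAC code space.

**Overhang calling** (`infer_overhang`). The retained cut distances are
non-target-strand (NTS) cleavage positions; the target-strand (TS) cut
position comes from an independent experiment (typically Sanger run-off
sequencing) and is supplied by the user. Offsets `NTS − TS` that are all
positive give a 5′ overhang, all negative a 3′ overhang, all zero blunt;
mixed signs raise an error rather than a silent majority call. Lengths are
reported as magnitudes with the sign carried by the type.

## Mismatch-tolerance mapping

The interference assay transforms nuclease/guide-expressing *E. coli* with
a library of target plasmids — one perfect protospacer match plus single
mismatches tiling the spacer — and sequences the survivors. Cleaved
plasmids kill their host, so variants the enzyme still cuts are depleted
and variants at positions that require base pairing are relatively
enriched.

Enrichment is a log2 relative-frequency ratio with pseudocount 1 (so a
variant absent from one library remains finite); relative frequencies make
the statistic invariant to sequencing depth. The exact invariances (zero
under equal proportions, exact scale invariance) hold in the
pseudocount-free form; with the default pseudocount they hold to
`O(pc/depth)`, which at the assay's typical 10³–10⁴ per-variant depths is
below 0.02 log2 units.

Per-position calls average enrichment over the one-to-three alternate-base
variants at that position and compare against the **perfect-match spacer's
own enrichment**, which anchors the "fully cut" baseline and absorbs global
composition shifts between libraries: tolerated within `margin` (default 1
log2 unit), intolerant beyond `2 × margin`, indeterminate between. The calls
are effect-size thresholds, not p-values, matching the qualitative readout
of the assay; no multiple-testing machinery is attached. Reads are assigned
to variants only by exact protospacer match between the constant flanks —
variants differ by single substitutions, so Hamming-nearest assignment
could never be ambiguous, but a read failing exactness is counted
`unassigned` rather than force-assigned.

## Protein feature screening

Candidate ORFs are screened for the signature of small arginine-rich
nuclease systems:

* **Composition deviation.** Observed residue fractions are regressed on a
  packaged background composition (Swiss-Prot release averages,
  renormalized; any 20-residue table can be substituted) by OLS with slope
  and intercept across the 20 points. Residuals are standardized by the
  fit's residual sd; `arg_lys_enriched` requires both R and K above
  `+sigma` (default 2) and `met_depleted` requires M below `−sigma`. The
  2-sigma default operationalizes "deviates from the linear trend" as a
  conventional outlier rule; it is exposed because the underlying
  comparison is graphical in origin, not inferential.
* **Motif grammar.** Patterns use fixed residues, `X` (any), `X(m,n)` or
  `X(m-n)` bounded gaps (the two spellings are treated identically), and
  `[A/B]` alternation — enough for RRXRR, the zinc-ribbon spacings
  CX(2-4)C / CX(2-4)H / HX(2-4)C, and the composite Zn-finger
  CX(2,4)CX(27,31)CX(2,4)[C/H]. All match starts are reported (overlaps
  allowed — a conservative deterministic count); at each start the shortest
  match is taken, with variable gaps resolved leftmost-minimally, which
  prevents double counting of nested gap choices. The scanner is
  regex-compiled with lazy quantifiers and is checked in the test suite
  against an independent brute-force enumerator.
* **Charge and pI.** Henderson–Hasselbalch per ionizable group (D, E, C, Y,
  H, K, R, termini) with the EMBOSS pKa set (N-term 8.6, C-term 3.6, C 8.5,
  D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1). Net charge is strictly
  decreasing in pH, so bisection on [0, 14] converges to the unique root;
  the interval is shrunk to 10⁻⁶ pH units so the residual charge stays
  below 0.01 elementary charges even for proteins whose charge changes by
  ~100 per pH unit.
* **Verdict.** "SMART-like" = length within `size_band` (default 400–1050
  aa, the envelope of the class) ∧ `arg_lys_enriched` ∧ (≥1 RRXRR ∨ ≥2
  zinc-ribbon motifs). Motif counts across protein families are reported as
  raw counts; cross-family significance testing would require a reference
  effector panel and is out of scope.

## sgRNA scaffold construction

The repeat:anti-repeat duplex is identified by a Smith–Waterman local
alignment of the repeat against the reversed tracrRNA in which
complementary pairs (and G:U wobble, switchable) score +1, mismatches −2,
and each gapped base −3; ties resolve toward the repeat's 3′ end, where the
duplex sits. This is a deliberate substitution of a complementarity
alignment for thermodynamic folding: the task is deterministic scaffold
construction, not ΔG prediction, and the duplex of interest is near-perfect,
so the result is insensitive to the exact scores (the test suite verifies
equality with exhaustive enumeration over all monotone pairings). A
structure computed elsewhere (e.g. an MFE fold) can be injected via
`duplex_model()`, which validates Watson–Crick/wobble pairing and
antiparallel monotonicity.

Designs concatenate `spacer + trimmed repeat + GAAA + trimmed anti-repeat +
tracr tail` over the cartesian product of trim levels, spacer lengths, and
tracr termination points. Trimming removes pairs from the tetraloop-proximal
end symmetrically on both strands (the trimmed helix stays a helix); spacers
truncate from the 5′ (PAM-distal) end, the standard guide-truncation
convention. Combinations that would leave fewer than `min_duplex` pairs or
overrun the supplied spacer are skipped with a warning, never silently
emitted. Sequences are computed on the DNA alphabet and emitted as RNA.
For in vitro transcription, prepend a T7 promoter to the emitted FASTA; the
package does not design IVT templates.

## Edit quantification

Reads are globally aligned to the amplicon reference with affine gaps
(match 2, mismatch −3, gap open −8, gap extend −1; a gap of length L costs
`open + L × extend`). Alignments below 60% identity are rejected as
off-target amplicons or primer dimers; both the scores and the threshold
are exposed since the upstream tools this mirrors treat them as
configuration. Tie-breaking is deterministic — mismatch over gap, deletion
over insertion — so outputs are stable across runs and platforms.

Substitutions are counted per position independently (marginal
frequencies, no haplotype phasing), matching the per-position heatmap
readout; `conversion_table()` numbers positions within the protospacer as
in the standard base-editor figures. The indel fraction counts reads with
at least one insertion or deletion overlapping the editing window — the
nuclease readout — with `whole_amplicon = TRUE` as the override. Base
qualities are not used to mask calls by default (`min_base_q`-style masking
would change denominators; the simulators emit constant Q37, and with real
data the 60% identity gate plus the quality filter upstream carry that
role).

## Synthetic data: what is and is not emulated

Every generator is bit-reproducible under a fixed seed and attaches a
machine-readable truth manifest consumed directly by the tests.

* `simulate_pam_reads` draws uniform 8-mers, cleaves matching molecules
  with `cleave_prob_match` (non-matching with `cleave_prob_nonmatch`),
  assembles `adapter + remnant + PAM + anchor` reads with substitution
  errors and an orientation mix. Only cleaved molecules emit reads — the
  enrichment-style design of the assay (a depletion-mode assay is not
  modelled). `n` is the number of *emitted reads* (molecules are generated
  until `n` are cleaved), which keeps the recovery regime independent of
  how restrictive the planted PAM is; the molecule count is recorded in
  the manifest.
* `simulate_mismatch_counts` works at the count level: multinomial input,
  Bernoulli survival per molecule (`1 − cleave_p`). Default cleavage
  probabilities 0.99 (tolerated/perfect) vs 0.05 (intolerant) and depth
  10,000 per variant reflect a strongly active, strongly specific enzyme;
  the preset truth pattern `seed13_except9` (intolerant at PAM-proximal
  positions 1–13 except 9) encodes the canonical long-seed profile of this
  enzyme class.
* `simulate_amplicon_reads` applies each planted substitution independently
  at its fraction, then the indel, then substitution-only sequencing error.
* `simulate_protein` draws i.i.d. residues from a boosted background and
  overwrites windows with planted literal motifs.

Deliberate simplifications, and hence the limits of what recovery tests
demonstrate: sequencing error is substitution-only (no error-model indels —
this keeps the alignment oracle exact), qualities are constant rather than
position-dependent, there is no PCR amplification bias or duplication, no
paired-end structure, and protein sequences are i.i.d. rather than
domain-structured. Passing recovery on these fixtures validates the
*estimators* (filters, counting, alignment, calling) under the assays'
idealized generative models; it does not validate robustness to
instrument-specific artifacts, which should be assessed on real runs.

## Problem sizes and numerical choices

The test suite and the acceptance script use 10⁴ reads for PAM and amplicon
recovery, depth 10⁴ per variant for the 24+1 mismatch library, 10³ random
proteins for the motif-oracle comparison, and exhaustive-enumeration oracles
at sizes where enumeration is complete (alignment paths ≤7 nt, duplex
pairings ≤8 nt, ungapped duplex offsets ≤30 nt) — sizes at which every
binomial 3σ recovery band in the suite is a fraction of the planted effect,
chosen so the checks are sharp rather than merely fast. Degenerate inputs
are errors, not guesses: empty observation sets, mixed-sign overhangs,
zero-depth libraries, and all-rejected alignments raise with the tally that
explains them.
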