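# smartchar

Analysis toolkit for the biochemical characterization of compact RNA-guided
nucleases — Cas9-like effectors and the HEARO/IscB family of small,
arginine-rich ("SMART") systems. The package implements the computational
side of the standard wet-lab characterization assays:

* **PAM/TAM discovery** from deep sequencing of cleavage products of a
  randomized (8N) PAM plasmid library, including cut-site distance profiling
  and staggered-overhang calling;
* **guide mismatch-tolerance mapping** from plasmid-interference survivor
  counts of a single-mismatch target library;
* **protein feature screening** of candidate ORFs for the SMART signature
  (arginine/lysine composition deviation, RRXRR and zinc-ribbon motif
  grammar, isoelectric point and net charge);
* **sgRNA scaffold construction** from a CRISPR repeat and tracrRNA by
  repeat:anti-repeat duplex identification, helix trimming, and GAAA
  tetraloop fusion;
* **base-edit and indel quantification** from amplicon sequencing
  (per-position conversion percentages, window-overlapping indel fraction);
* **synthetic-data generators** with known ground truth for every assay, so
  each stage is verifiable end to end by parameter recovery.

It is aimed at groups characterizing novel programmable nucleases who want a
reproducible, scriptable alternative to one-off analysis notebooks.

## The statistics at the core

**PAM recovery.** Each cleavage-product read has the layout
`adapter + protospacer-remnant + PAM + backbone-anchor`. After a mean-Phred
quality filter (Q > 20) the known backbone anchor is located by exact match
in either orientation, the adjacent 8 bp are the putative PAM, and the
distance between the ligated adapter and the PAM-proximal edge is the cut
distance. Observations are filtered to the modal cut distance ±2, then a
position frequency matrix `f` with Laplace pseudocounts gives per-position
information content

    I_i = 2 + sum_b f_ib log2 f_ib   (bits),

logo heights `f_ib * I_i`, and an IUPAC consensus (a base joins the
consensus set when `f_ib >= 0.2`, just under the uniform expectation of
0.25; all four or none → N).

**Mismatch tolerance.** For variant `v` of `V` with survivor counts `out`
and input counts `in`, enrichment is the pseudocounted log2
relative-frequency ratio

    e(v) = log2[ ((out_v + 1)/(Out + V)) / ((in_v + 1)/(In + V)) ].

A position is *intolerant* (base pairing required) when the mean enrichment
of its mismatch variants exceeds the perfect-match spacer's enrichment by
≥ 2 margins (default margin 1 log2 unit), *tolerated* within 1 margin.

**Edit quantification.** Reads are globally aligned to the amplicon with
affine gap penalties (match 2, mismatch −3, gap open −8, extend −1; <60%
identity rejected); the per-position edit fraction and the fraction of reads
with an indel overlapping the editing window are reported, per conversion
(e.g. A→G for adenine base editors) on the percent scale.

## Worked example

Simulate a 10,000-read NGG cleavage library (1% base-call error, cut sites
5–7 nt from the PAM) and recover every planted parameter:

```r
library(smartchar)

layout <- assay_layout(adapter = "ACGCTCTTCCGATCT", anchor = "GTCGCCAGTTGACCTA")
truth  <- pam_truth("NGG", cut_dist = c("5" = 0.55, "6" = 0.30, "7" = 0.15),
                    error_rate = 0.01)
reads  <- simulate_pam_reads(truth, layout, n = 10000, seed = 7)

profile <- build_profile(extract_observations(quality_filter(reads), layout))
profile
#> <pam_profile>
#>   consensus: NGGNNNNN
#>   modal cut: 5  retained: 7335 / 7335 reads
#>   information (bits): 0.00 1.92 1.92 0.00 0.00 0.00 0.00 0.00

infer_overhang(ts_cut = 3, profile)
#> <overhang_call> five_prime (TS cut 3 | NTS 5,6,7 | lengths 2,3,4 )
```

The planted `NGG` comes back exactly (positions 2–3 carry ~1.92 of the
maximal 2 bits each; all other positions are uninformative), the modal cut
distance is the planted 5, and combining the non-target-strand cut distances
5–7 with a target-strand cut at position 3 calls a 5′ overhang of 2–4 nt —
the staggered-cut geometry these enzymes produce. Roughly a quarter of the
simulated reads are dropped before profiling because a 1% per-base error
rate leaves ~73% of reads with an exact anchor and adapter match, mirroring
the exact-match filtering of the original assay.

Every result object has `tidy()`, `glance()`, and `autoplot()` methods, so
results drop straight into dplyr/ggplot2 workflows.

A command-line wrapper is installed at `exec/smartchar` exposing the same
pipelines (`simulate`, `pam-discover`, `mismatch-map`, `protein-screen`,
`guide-design`, `edit-quant`) with TSV/JSON outputs and a reproducibility
manifest per run.

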