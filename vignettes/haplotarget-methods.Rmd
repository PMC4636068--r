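---
title: "Methods: targeted proximity-ligation haplotyping in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted proximity-ligation haplotyping in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and algorithms:
what is simulated, what is estimated, which parameters matter, and where
genuinely open design choices were resolved.

## The problem

A diploid individual carries two versions (homologs) of each locus.
Phasing assigns every heterozygous allele to its homolog. Proximity
ligation supplies long-range phase evidence because a chimeric ligation
product joins two genomic windows that were spatially close — almost
always on the same chromosome copy. Capture enrichment with probes tiled
around restriction cut sites restricts sequencing to one target locus
(MHC- or KIR-scale) at a fraction of whole-genome cost. The package
simulates this design end to end and assembles and evaluates the
haplotypes.

Coordinates are 0-based half-open everywhere internally; VCF output is
1-based; BED input/output is 0-based half-open. One convention internally
eliminates off-by-one drift between modules.

## Probe design

Targets are the symmetric `flank` = 400 bp windows on each side of every
restriction cut site (HindIII `A^AGCTT` by default; palindromic motifs
are scanned on one strand, non-palindromic motifs on both with the
reverse-strand cut mirrored). Repeat intervals — from a BED and from
soft-masked (lower-case) FASTA stretches — are subtracted, and
`probe_length` = 120 nt probes are tiled from each interval start at step
`probe_length / tiling_density` (30 nt at 4X), with a final probe placed
flush with the interval end so 3' ends are not left uncovered. Intervals
shorter than one probe are skipped for cut-site targets but *padded* to
one probe length (centered, slid off repeats if needed) for exon targets:
genic regions are targeted deliberately and must not vanish because an
exon is short. Flanks are centered on the cut position, not the motif
start, for symmetry. Identical probe intervals arising from both sources
are deduplicated. The design is deterministic: identical inputs give
byte-identical BED output.

Out of scope by design: probe thermodynamics (Tm/GC filtering,
cross-hybridization), which belongs to vendor design software.

## The generative model

`sim_config()` bundles every parameter. The two profiles are the study
conditions the package is calibrated around:

| parameter | paper | fast | meaning |
|---|---|---|---|
| `locus_length` | 3.5 Mb | 1 Mb | diploid target locus |
| `snv_density` | 9400/3.5e6 | 2700/1e6 | het SNVs per bp (~2.7/kb) |
| `n_fragments` | 1.0e6 | 2.7e5 | pre-capture fragment count |
| `read_length` | 100 bp | 100 bp | per-anchor read |
| `decay_exponent` α | 1.08 | 1.08 | contact-span power law |
| `min_span` | 2 kb | 2 kb | lower truncation of the span law |
| `htrans_rate` τ | 0.02 | 0.02 | inter-homolog ligation probability |
| `enrichment_fold` F | 50 | 50 | capture retention odds |
| `seq_error` ε | 0.005 | 0.005 | per-observation allele error |
| `lfr_length`, `lfr_n` | 10 kb, 10x cov. | 10 kb, 10x cov. | long-fragment companion data |
| `planted_error_fraction` | 0 (0.1 in QC runs) | — | reported-truth flips in dense windows |

Variant positions are uniform without replacement; truth phase bits are
fair coins; the *density flag* marks variants in 2 kb windows whose SNV
count reaches the top decile of window counts ("high variant density" has
no published threshold; the decile is configurable). Fragment anchors:
anchor 1 uniform; span s from the truncated power law p(s) ∝ s^(−α) on
[`min_span`, `locus_length`] via the closed-form inverse CDF; anchor 2 at
that span in a uniform direction, reflected at the locus bounds
(reflection can make the two reads overlap, in which case the first end's
observation of a variant wins — a fragment observes a variant once). The
homolog of anchor 1 is a fair coin; with probability τ anchor 2 reads the
*other* homolog. Each observed allele is flipped independently with
probability ε; base qualities are the Phred equivalent of ε (capped at
Q40) so MEC weighting stays interpretable. α = 1.08 with a 2 kb lower
cutoff is the canonical intra-chromosomal contact decay; the data source
this package emulates does not state its contact model, so the law is
exposed as configuration.

Capture retains a fragment with certainty when at least one read overlaps
at least one probe, otherwise with probability 1/F. LFR fragments are
contiguous single molecules reading one homolog end to end — they can
carry allele errors but *cannot* be h-trans, which is exactly why they
work as an orthogonal phase witness. Planted truth errors flip the
reported phase of density-flagged variants with probability
`planted_error_fraction`, emulating the local phasing mistakes short-read
trio truth sets accumulate in complex regions; the generative truth and
the flipped index set are kept separately so filter recall/precision can
be scored.

The fragment-count defaults are calibrated so the median number of
informative (≥2-observation) fragments per variant after capture is
about 5 — the intended operating coverage. The primary simulator output
is allele-level fragment files; a SAM emitter exists to exercise the
alignment-consuming path (`extract_fragments()`), reflecting allele-level
errors in the read bases. Read-level realism beyond that (PCR duplicates,
chimeric re-ligation, mappability bias, indels) is deliberately not
modeled, so passing tests say nothing about those failure modes on real
libraries.

## Haplotype assembly

Fragments with ≥2 observations induce a variant graph: an edge per
co-covered pair, weighted by quality-weighted cis-minus-trans votes.
Connected components bound the achievable blocks. Per component the
phase is optimized in three stages:

1. **Max-cut local search** (C++): best-improvement single flips on the
   signed graph, from a BFS spanning-tree initialization (restart 1; it
   recovers the exact optimum on noise-free, balanced components) and 19
   random restarts. The winning restart is chosen by the *exact* MEC
   score, never the cut surrogate.
2. **Exact-MEC polishing** (C++): single members and contiguous runs of
   up to `prune_max_segment` = 8 members are flipped while that lowers
   the true MEC objective Σ_f min(m_f, k_f − m_f). This matters because
   the cut objective over-credits correlated votes: one multi-SNV read
   yields several observation pairs but only one independent error.
3. **Confidence pruning**: at the optimum, any run whose flip would
   change the MEC by less than `prune_min_margin` = 2 observations is
   released to unresolved — its phase rests on at most one observation
   of evidence, and a single erroneous or h-trans ligation can phase a
   small stretch confidently wrong. Pruning engages only when the
   component shows conflicting evidence (MEC > 0) and is larger than
   twice the segment scale, so noise-free data and small worked examples
   are reported whole. The margin of the global flip is 0 by symmetry
   and is never treated as prunable.

Numerical conventions: zero-gain flips are rejected (no plateau walking);
the exhaustive oracle `brute_force_phase()` (components ≤ 16 variants)
breaks ties to the lexicographically smallest phase vector; block
orientation is canonicalized so the first member has phase 0; block ids
are the smallest member index, and the VCF `PS` tag is that member's
1-based position. Degenerate inputs — no informative fragments, empty
matrices, single-variant components — yield empty/unresolved results
rather than errors.

**LCP refinement.** Variants no fragment links are phased against a
reference panel by a one-pass haplotype-copying vote: for each unresolved
variant, the `window` = 10 nearest members of the scaffold (the largest
assembled block) are consulted; panel haplotypes matching the scaffold at
≥ 80% of those anchors vote with their allele at the variant; a winning
fraction ≥ `vote_threshold` = 0.9 assigns the variant to the scaffold
block with `source = "lcp"`, else it stays unresolved. Newly assigned
variants never serve as scaffold (no chaining). This is a deliberately
simplified conditional-copying vote, not a Li–Stephens HMM with a genetic
map; it preserves the testable contract (panel-consistent variants join
the scaffold, orientation-invariantly) and is labeled in the output VCF
via an `LCP` INFO flag. The simulated panel is a switch-and-mutation
mosaic of the truth haplotypes (defaults: 20 haplotypes, 1% mutation,
~5 switches), a caricature of strong local LD that ignores population
structure and allele-frequency spectra.

## Evaluation layer

*Resolution* is the fraction of all het SNVs phased into the single
largest block — the locus-spanning haplotype structure; other blocks are
reported but do not count unless `largest_block_only = FALSE`.
*Per-variant accuracy* orients each block to the truth by majority vote
and scores every variant independently — the worst-case convention, in
contrast to *switch error*, which charges a flipped stretch only at its
boundaries; both are computed, both invariant to global block flips.
When a blacklist is supplied, those variants leave both numerator and
denominator of accuracy.

*H-trans diagnostics.* Every within-fragment observation pair is
classified cis or h-trans against a reported truth; the report carries
the overall ratio, the fraction of h-trans pairs whose two observations
come from one read end (a contiguous read cannot be a genuine
inter-homolog ligation, so same-end h-trans points at the truth set),
and ratios per variant-density decile (a pair is binned by the denser of
its variants). The *concordance filter* blacklists a variant when both
data types independently find it h-trans: the majority of its pairs are
h-trans in the proximity-ligation data *and* in the LFR data, with at
least `min_lfr_support` = 2 distinct LFR molecules showing the
inter-haplotype pairing. Majority status is the load-bearing choice:
scattered allele errors never reach a majority at a covered variant, and
genuine chemistry h-trans cannot appear in LFR at all, so joint majority
isolates reported-truth phase errors. (A same-end-pair precondition was
considered and rejected: it needs a second het within one read length,
which a large fraction of dense-region variants lack, and it lets stray
LFR errors count as confirmation — measured on the package's own
simulations it costs roughly half the recall at a fraction of the
precision.)

*Enrichment fold.* A naive on/off per-base read-density ratio is
structurally biased far below F in a locus-only simulation: the
off-target mate of every on-target read is retained with it, and targets
are a large fraction of the locus, so mate rescue dominates the
off-target denominator. The estimator therefore works at the fragment
level, normalized by expectation: fragments are classified on-target by
the same predicate capture uses (≥1 read overlapping a probe), and
fold = (n_on / E[share on]) / (n_off / E[share off]), with the expected
shares 1 − (1 − c)² and (1 − c)² computed from the read-length-padded
probe footprint fraction c under uniform anchors. This returns 1 for
uniform pre-capture data, F after capture at fold F, and an infinity
sentinel when nothing is off-target. Probe sensitivity is reported
against size-matched, seeded "virtual probes" placed near cut sites but
outside the real footprint.

*Contact concordance.* Paired anchors are binned (100 kb — matching the
enrichment binning; the profile-comparison binning is otherwise
unstated), fragments counted per bin pair i ≤ j, and r² is the squared
Pearson correlation of log10(1 + count) over bin pairs nonzero in either
dataset; fewer than two such pairs is an error, and a dataset against
itself gives exactly 1.

*Genotyping.* Capture sequencing is blind to genotype, so allele depths
at candidate sites support de novo calls. The caller is a frequency
threshold with an explicit ambiguous zone: `no_call` below `min_depth`
= 8; `het` when the minor allele reaches 20% of depth and ≥2 reads;
homozygous when the minor fraction is ≤ 5%; in between, `no_call` rather
than a guess — hom calls are intrinsically the fragile ones here, since
a couple of stray observations can masquerade as heterozygosity. A
likelihood-based caller was deliberately not built; the thresholds are
arguments. `simulate_site_counts()` provides base-level multinomial
counts under the standard substitution model (errors go to each of the
three other bases uniformly, so the expected `other` fraction at a het
site is 2ε/3) for calibrating the caller.

## Problem sizes and determinism

The test suite runs everything at desk scale: oracle comparisons on ≤8
variants × ≤30 fragments (exhaustive enumeration over 2^(n−1)
phasings), noise-free and noisy phasing at the 1 Mb fast profile, span
law checks at n = 50,000 draws against the closed-form CDF, and
binomial-CI checks sized so three-sigma bounds are meaningful. The
acceptance script runs the 3.5 Mb profile over three seeds plus three
fast-profile seeds, about a minute on one CPU. Every stochastic step
takes an explicit seed, derived stage offsets keep streams distinct, and
the pipeline is byte-deterministic: same config, same files.

## Known limitations

* The simulator's uniform-anchor, single-exponent contact model has no
  domain structure (TADs, compartments), no restriction-fragment
  boundary effects, and no coverage bias beyond capture itself.
* Allele errors are independent per observation; real base errors
  correlate along reads and with sequence context, which would make the
  concordance filter's job harder than simulated.
* LCP is a local vote, not an HMM; with weak panels it abstains rather
  than degrades, but its accuracy ceiling is the panel's local fidelity.
* Biallelic SNVs only; indels and multiallelics are rejected on input.
* Single-contig loci; whole-genome multi-contig phasing is out of scope.
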