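# haplotarget

Targeted capture proximity-ligation haplotyping of megabase-scale loci, in R.

Immune loci such as the MHC (~3.5 Mb, with the HLA genes) and the KIR
cluster carry dense, strongly linked heterozygous variation, and many of
their clinical applications — transplantation matching, compound
heterozygosity, disease association — need the *haplotype*: which alleles
sit together on one chromosome copy. Short-read sequencing cannot link
variants more than a fragment length apart. Proximity ligation (Hi-C)
can: crosslinked chromatin is digested with a restriction enzyme (HindIII
here) and re-ligated, producing chimeric fragments that join loci tens of
kilobases to megabases apart but almost always on the *same* chromosome
copy. Enriching such a library with capture probes tiled around the
restriction cut sites of one target locus concentrates that long-range
phase information exactly where it is wanted.

`haplotarget` implements the complete in-silico side of this design for
people who want to study, calibrate or extend it without wet-lab data:

* **probe design** — 120-nt probes tiled at 4X density over the
  non-repetitive ±400 bp flanks of restriction cut sites, plus exonic
  targets;
* **simulation** — a diploid locus with ~2.7 het SNVs/kb, proximity-ligation
  fragments with a truncated power-law contact-span law
  p(s) ∝ s^(−α) (α = 1.08), a small homologous-trans (h-trans) rate τ,
  capture enrichment fold F, per-base allele error ε, a long-fragment-read
  (LFR) companion dataset, and planted phase errors in the reported truth
  set concentrated in high-variant-density windows;
* **haplotype assembly** — minimum-error-correction (MEC) phasing: over the
  fragment matrix M (fragments × variants with entries 0/1/–), find the
  phase vector h minimizing Σ_f min(d(M_f, h), d(M_f, h̄)), via a max-cut
  local search over the fragment-induced variant graph with multiple
  restarts, exact-MEC polishing, confidence pruning, and a local
  conditional phasing (LCP) step that places residual variants using a
  reference haplotype panel;
* **evaluation** — completeness / resolution / per-variant ("worst-case")
  accuracy and switch error, h-trans diagnostics (same-end fraction,
  density stratification), the LFR concordance filter that detects
  truth-set phase errors, capture enrichment fold, binned contact-profile
  r², and de novo genotype calling from allele depths.

## Worked example

Simulate a 1 Mb locus end to end (design → simulate → capture → phase →
QC → genotype) and print the run summary:

```r
library(haplotarget)
cfg <- sim_config("fast", seed = 7, planted_error_fraction = 0.1)
out <- run_pipeline(cfg, "ht_demo")
cat(out$summary_lines, sep = "\n")
```

```
targeted proximity-ligation haplotyping summary
profile: fast  locus: 1000000 bp  variants: 2700  seed: 7
probes: 5596  enrichment fold (measured): 50.0
resolution (largest block): 98.56%
accuracy vs reported truth: 97.48% pre-blacklist, 99.73% post-blacklist (60 blacklisted)
h-trans ratio: 0.0751  same-end fraction: 0.453
MEC score: 180
genotyping: call rate 90.33%, het accuracy 100.00%
```

Reading this: of 2,700 heterozygous SNVs, 98.6% were phased into one
locus-spanning haplotype block. Measured against the *reported* truth set
— into which the simulator planted phase flips at 10% of high-density
variants — the apparent per-variant error is 2.5%; the h-trans/LFR
concordance filter blacklists 60 suspect variants and the error drops to
0.27%, illustrating that most of the apparent error was in the truth set,
not the phasing. The measured capture enrichment matches the configured
50-fold, and genotypes called de novo from allele depths are correct at
every called het site. `ht_demo/` holds the probe BEDs, truth and phased
VCFs (with `PS` phase-set tags), fragment files and QC tables.

The building blocks are ordinary functions — `design_probes()`,
`simulate_dataset()`, `max_cut_phase()`, `lcp_refine()`,
`evaluate_phasing()`, `htrans_report()`, `concordance_filter()` — and an
optional shell front-end lives at `inst/scripts/haplotarget`. The methods
vignette (`vignettes/haplotarget-methods.Rmd`) documents the generative
model, the phasing algorithm and every tunable parameter.

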