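# ejcsplice

Transcriptome-wide characterisation of splicing events that depend on the
exon junction complex (EJC).

The EJC (eIF4A3, Magoh, Y14, MLN51) is deposited ~24 nt upstream of
exon–exon junctions during splicing and links splicing to mRNA export,
translation and nonsense-mediated decay (NMD). Knocking down EJC components
changes the inclusion of many cassette exons; characterising *which* exons
respond, and how they differ in sequence and EJC binding from unaffected
exons, is the analysis this package implements — for computational
biologists working with differential-splicing calls, CLIP coverage and
knockdown mRNA-seq, or anyone who wants a fully synthetic, seeded testbed
of that analysis.

## What it computes

* **Event catalog** — parses differential-splicing calls in two caller
  dialects (per-replicate MISO-like; replicate-aware DiffSplice-like),
  applies the standard filter (|ΔΨ| > 0.1, evidence score > 5, inclusion
  and skipping reads > 10, sum > 20; all strict), intersects replicates,
  takes the cross-caller union deduplicated by cassette-exon coordinates,
  and classifies events by direction (ΔΨ = Ψ_control − Ψ_KD; "+" =
  skipping up in knockdown) and annotation status (ALT/CON), with matched
  control sets (Ctr: |ΔΨ| < 0.03, Ψ ∈ (0.1, 0.9); CtrCON: triplets of
  successive constitutive exons) and an expression filter
  (coverage = read length × reads / transcript length ≥ 10).
* **Sequence features** — flanking intron lengths; donor (9-mer) and
  acceptor (23-mer) splice-site strength in bits from trainable
  per-position log-odds models; splicing-regulatory-element frequencies
  (ESE/ESS/ISE hexamers, ISS decamers; overlapping matches per nt) with
  100-shuffle permutation z-scores; Mann–Whitney group comparisons.
* **RNA splicing maps** — per-category CLIP-binding profiles over 100-nt
  exon-border windows, normalised per position by mRNA coverage (masked at
  zero), averaged by the number of contributing exons, and scaled to a
  maximum of 1.
* **NMD flags** — the 50-nt rule (a stop > 50 nt upstream of the last
  junction is premature) on both isoforms of each event, and AS-NMD
  candidates (PTC-bearing plus fold change > 1.5 in an EJC knockdown).
* **Synthetic data** — a seeded generator for annotation (GTF), genome
  (FASTA), event tables (TSV), stranded coverage (bedGraph) and gene
  counts with known ground truth: binomial inclusion reads at set true Ψ,
  and CLIP peaks planted at −24 nt from every exon's 3′ border.

## Worked example

```r
library(ejcsplice)

cfg <- pipeline_config(sim = sim_config(n_genes = 60, seed = 7),
                       n_ctr = 50, n_ctr_con = 50)
rep <- run_pipeline(cfg)
rep$summary
#>   direction anno_class count      pct
#> 1         -        ALT     2 11.76471
#> 2         +        ALT    15 88.23529
profile_argmax(rep$exon_map, "+")
#> [1] -24
max(rep$exon_map$height)
#> [1] 1
```

17 of this run's simulated cassette events survive the filters and
classification: 15 with increased skipping upon EJC knockdown ("+") and 2
with increased inclusion ("−"), all at annotated alternative exons. The
splicing-map profile of the "+" category peaks at relative position −24 —
the canonical EJC deposition site planted by the generator — and is scaled
so its maximum is exactly 1. `rep$nmd` carries per-event PTC and AS-NMD
flags, `rep$group_tests` the feature comparisons against the Ctr control
set (raw and BH-adjusted p-values), and `rep$log` the exact predicate text
of every filter applied.

The same analysis, written out step by step with intermediate files, is in
`analysis/01_simulate.R` … `analysis/06_report.R`; each script reads the
previous one's outputs under `results/` and narrates what it finds.

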