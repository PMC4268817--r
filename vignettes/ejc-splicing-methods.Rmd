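---
title: "Methods: characterising EJC-dependent splicing events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising EJC-dependent splicing events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

The exon junction complex (EJC: eIF4A3, Magoh, Y14, MLN51) is deposited
about 24 nt upstream of exon–exon junctions during splicing and couples
splicing to downstream mRNA fate, including nonsense-mediated decay (NMD).
`ejcsplice` implements the downstream analysis of a knockdown mRNA-seq
splicing study of this complex: given differential-splicing calls from two
callers, an annotation, a genome, CLIP and mRNA coverage, and gene counts,
it produces a categorised event catalog, per-event sequence features,
positional CLIP-binding profiles ("RNA splicing maps"), and PTC/AS-NMD
flags. A seeded generator produces all of these inputs synthetically with
known ground truth, so the full pipeline runs and is tested with no
external data.

Everything is driven by inclusion levels. For a cassette exon, Ψ (percent
spliced in) is the fraction of transcripts that include the exon, and the
package uses the sign convention

    ΔΨ = Ψ_control − Ψ_knockdown,

so ΔΨ > 0 means increased *skipping* upon knockdown ("+" events) and
ΔΨ < 0 increased inclusion ("−"). The same convention applied to intron
inclusion makes ΔΨ < 0 increased retention. This convention is used
consistently; caller dialects are converted on parsing.

## Event catalog

MISO-dialect calls are per-replicate, per-contrast rows carrying Ψ
estimates, an evidence score ("Bayes factor") and informative read counts.
The filter retains a row iff

    |ΔΨ| > 0.1  AND  score > 5  AND  skipping reads > 10
    AND inclusion reads > 10  AND  inclusion + skipping > 20,

all strict inequalities (a row at exactly a threshold is dropped).
Replicates are then intersected: an event survives only if called in both
replicates at identical cassette-exon coordinates with the same ΔΨ sign;
the reported ΔΨ, Ψ and counts are replicate means (keeping the larger
replicate instead was the other defensible choice; averaging is symmetric
and was fixed once). DiffSplice-dialect calls are replicate-aware and
filtered at |ΔΨ| > 0.1 only.

The merged catalog is the union of the MISO intersection and the filtered
DiffSplice calls, deduplicated by (chromosome, strand, cassette start,
cassette end) per contrast — coordinates are the only identity the two
callers share. Where both call an event, the MISO Ψ estimates take
precedence and the source is recorded as `both`; coordinate-equal calls
with opposite signs are discordant and go to an audit table instead of the
catalog.

Classification aggregates contrasts: an event is "+" if ΔΨ > 0.1 in at
least one of the three EJC contrasts (eIF4A3, Y14, MLN51 — the union,
not the intersection), "−" if ΔΨ < −0.1; the Upf1 contrast never decides
direction. The annotation class is ALT when the cassette exon is annotated
alternative and CON when it is an annotated exon with no alternative
annotation. Events are excluded (with an audit reason) when the cassette
exon is not in the annotation, when either flanking exon is missing or
annotated alternative, when two events' cassette exons overlap (complex
splicing patterns), or when EJC contrasts disagree in direction.

Two control sets are built, restricted to expressed genes:

* **Ctr** — annotated alternative events with |ΔΨ| < 0.03 in *every* EJC
  contrast and all Ψ estimates inside the open interval (0.1, 0.9),
  sampled without replacement to the requested size;
* **CtrCON** — triplets of three successive constitutive exons, excluding
  each transcript's first and last exon, at most one triplet per gene
  (chosen at random among a gene's eligible windows, seeded).

The control-set sizes are parameters, not constants. The expression filter
retains a gene iff its coverage `C = read_length × reads / transcript
length` is at least 10 in the control condition and in at least one
knockdown; this threshold is deliberately *inclusive* so that the worked
value C = 51·200/1020 = 10 passes, while the event filters are strict as
printed above.

## Sequence features

Flanking intron lengths are strand-aware coordinate gaps; "upstream" always
means the transcript 5′ side. Splice-site strength uses a trainable
independent per-position nucleotide model: the donor window is a 9-mer (last
3 exonic + first 6 intronic nt), the acceptor a 23-mer (last 20 intronic +
first 3 exonic nt), and the score is the summed log2 odds (bits) of the
position model against a background composition, so a model equal to its
background scores exactly 0. Published maximum-entropy score tables can be
loaded instead (`load_maxent_tables()`, a k-mer → score lookup); none are
bundled, and the package is fully functional without them. Training uses an
additive pseudocount (default 0.5) so all scores are finite.

Splicing-regulatory elements are fixed-length motif sets — ESE/ESS/ISE
hexamers and ISS decamers. Frequency is the number of sliding-window
matches (overlapping occurrences all counted — the counting unit was open;
counting all is the simplest rule and is oracle-tested) divided by the
sequence length; exonic sets are counted over exons, intronic sets over the
*full* flanking introns, with no sub-window. The enrichment z-score
compares the observed frequency to the same sequence shuffled `n = 100`
times:

    z = (f_obs − mean(f_shuffled)) / sd(f_shuffled).

The shuffle unit was an open choice: the default is a uniform permutation
of nucleotides (mononucleotide composition preserved), with a
dinucleotide-block shuffle behind a flag. When every shuffle yields the
same count (sd = 0, e.g. near-homopolymers) the z-score is reported as the
`NA` sentinel with a `degenerate` flag and excluded from downstream
summaries rather than imputed.

The bundled motif files under `inst/extdata/` are deterministic *synthetic*
stand-ins with the published catalogue sizes (238 ESE, 176 ESS, 199 ISE
hexamers; 102 ISS decamers) and a coarse compositional caricature (ESE
purine-rich, ESS/ISS pyrimidine-rich); the real screens are not
redistributed. Analyses of real data should load the published lists with
`read_motif_set()`.

Group comparisons use the two-sided Mann–Whitney–Wilcoxon test (exact for
small tie-free samples, normal approximation otherwise); family-level
results report raw p-values plus Benjamini–Hochberg adjustment — the
adjusted column is supplementary transparency, not a change to any
decision rule. The intron-length/expression association is a Spearman
correlation with tie-corrected ranks.

## RNA splicing maps

Profiles are built over two 100-nt coordinate frames per region, anchored
at the 5′ and 3′ borders of the upstream, cassette and downstream exon
(intron maps anchor the same frames on the intronic sides). Exons shorter
than 200 nt keep both frames, which then overlap — short exons are not
discarded. Relative positions are transcript-oriented: +1 is the first base
inside a 5′ border, −1 the last base before a 3′ border, so the canonical
EJC site is −24.

Normalisation order is declared, because the source wording permits
several orders:

1. per exon and position, `c′(p) = CLIP(p) / mRNA(p)`, with positions of
   zero mRNA coverage masked (excluded from sums *and* from the exon count
   `n(p)`; a pseudocount is available behind a flag, masking avoids
   unbounded ratios);
2. per relative position, the mean over contributing exons,
   `H_raw(p) = Σ c′(p) / n(p)` (n counted after masking);
3. the whole category profile divided by its maximum over the analysed
   region, so the maximum is exactly 1 when any signal is present.

This order makes profiles invariant to global CLIP scaling, to per-gene
expression level, and to category size — the three invariances the tests
assert.

## NMD flags

A stop codon is premature iff it lies strictly more than 50 nt upstream of
the *last* exon–exon junction, in spliced-transcript coordinates (distance
exactly 50 is not premature; single-exon transcripts are never PTC+). The
last junction suffices because it is the 3′-most, and the classifier is
tested for exact agreement with a reference that scans all junctions. The
skipping isoform's ORF is derived by removing the cassette exon from the
inclusion isoform and re-scanning from the first ATG to the first in-frame
stop. An event is an AS-NMD candidate iff either isoform is PTC+ and the
gene's fold change (library-size-normalised count ratio, knockdown over
control) exceeds 1.5 — strictly — in at least one EJC contrast; events
without fold-change records are "undetermined", never silently dropped.

## The synthetic generator

The generator emulates the statistical structure the analysis consumes,
not the biology that produced it:

* genes of 3 + Poisson(5) exons, lognormal exon (median 150 nt) and intron
  (median 1.5 kb, human-like) lengths, random strand, one reference
  transcript per gene;
* a configurable fraction (default 0.2) of internal exons flagged as
  cassette exons; 30% of cassette events truly change upon EJC knockdown,
  65% of those toward skipping (matching the observed skew of
  EJC-dependent exons), with |ΔΨ| = 0.3 between Ψ = 0.85 and 0.55; changes
  are shared by all three EJC contrasts and absent in Upf1, emulating the
  finding that most EJC-dependent changes are NMD-independent;
* event reads: total ~ Poisson(depth 100), inclusion ~ Binomial(total, Ψ),
  per condition and replicate, so Ψ̂ is an unbiased binomial estimator; no
  overdispersion by default;
* the MISO-like evidence score is the proxy `2·|ΔΨ̂|·√(total reads)` — a
  monotone function of effect and depth under which the conventional
  threshold of 5 separates the planted changes from null events at the
  default depth; the caller's actual Bayesian machinery is out of scope,
  only the filter semantics matter. The DiffSplice-like score is the
  Jensen–Shannon divergence of the two estimated inclusion distributions;
* mRNA coverage: uniform per exon at a lognormal per-gene level with
  Poisson noise; introns get 10% of the exonic level (pre-mRNA signal) so
  that intron windows remain normalisable after mRNA masking;
* CLIP coverage: Poisson background (1×) plus a Gaussian peak of height 20
  and width σ = 1 nt centred 24 nt upstream of every exon's 3′ border.
  The narrow width is a calibration requirement, not an aesthetic choice:
  the generator must make the planted peak's position recoverable as the
  per-exon argmax, and a broad peak under Poisson noise shifts the argmax
  off-centre;
* splice-site contexts at every exon border are sampled from the bundled
  donor/acceptor position models (GT/AG-consistent consensus), which
  double as the known ground truth for model-recovery tests.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: isoform-resolution read generation and mapping
(FASTQ/alignment are out of scope), overdispersion between replicates,
correlated expression and binding, realistic codon structure (ORFs scanned
from random sequence almost always hit an early stop, so PTC flags on
fully synthetic genes are near-universal; the classifier itself is
validated against an exhaustive reference on controlled isoforms), and
caller-specific biases of the two splicing callers, whose outputs are
inputs here.

## Numerical and size choices

Coordinates are 0-based half-open internally; GTF is 1-based inclusive at
the boundary, bedGraph 0-based half-open, one file per strand. All
randomness flows through explicit integer seeds; a fixed seed gives
byte-identical files. Degenerate inputs (sd = 0 shuffles, constant
correlation vectors, empty categories, all-masked frames, undersized
control pools) return documented sentinels or warnings, never silent
drops or infinities.

Test and acceptance runs use deliberately compact problem sizes — the
catalog oracle runs on ~1,000 events from 850 genes with 300-nt-median
introns (intron length does not enter the catalog logic), splicing-map
recovery on 20 seeded runs of 25 genes (≥ 50 peak-bearing exons each),
site-model recovery on 10,000 training sites, z-score calibration on
500 × 100 shuffles, and the PTC reference on 1,000 random isoforms. The
`analysis/` scripts run a 120-gene study at the generator defaults.

## Known limitations

Only cassette-exon and intron-retention events are modelled (no A5SS/A3SS);
one reference transcript per gene; the trainable site model is an
independent per-position model, not a maximum-entropy fit with marginal
constraints; PTC prediction considers the two event isoforms only; and the
bundled motif sets are synthetic stand-ins, as above.
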