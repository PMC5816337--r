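---
title: "Methods: differential intron retention from coverage and junction evidence"
author: "dirseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential intron retention from coverage and junction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirseq)
```

## The problem

Intron retention (IR) is the dominant mode of alternative splicing in
plants: a mature transcript keeps one of its introns instead of splicing it
out. Abiotic stresses (drought, salt, heat, cold) shift the degree of
retention of specific introns — *differential intron retention* (DIR) — in a
stress- and tissue-dependent way. `dirseq` quantifies retention from
short-read evidence, calls DIR events between treatment and control, places
them in the wider context of alternative-splicing (AS) classes observed in
long-read isoform models, clusters co-regulated retention profiles across
conditions, and quantifies isoform-ratio switches from droplet digital PCR
(ddPCR) counts.

All genomic intervals are 0-based half-open internally. GFF/GTF (1-based
inclusive) and BED (already half-open) are converted at the I/O boundary; a
single internal convention prevents off-by-one drift between modules.

## Retention measure

For an intron $i$ in one library, the *relative IR score* is

$$ r_i = \frac{\bar d_i}{J_i}, $$

where $\bar d_i$ is the average per-base read depth over the intron and
$J_i$ is the number of reads supporting that intron's spliced junction —
its exact donor–acceptor pair, not the sum over neighbouring junctions.
Read this as retention:splicing odds: if a fraction $\psi$ of transcripts
retains the intron, $r_i$ estimates $\psi/(1-\psi)$. Two degenerate cases
are handled explicitly: positive intronic depth with zero junction reads
uses a unit pseudo-denominator and is flagged `no_splice_support`
(a fully retained intron is signal, not an error); zero depth *and* zero
junction reads leave the intron unscored (`NA`). The *splicing ratio
difference* for a control/treatment pair is
$\Delta r = \bar r_{\mathrm{control}} - \bar r_{\mathrm{treatment}}$
(replicate means), so increased retention under treatment appears as a
negative $\Delta r$.

## The DIR statistic

The effect measure is a pseudo-count-adjusted log-fold change of intron
coverage. For a pseudo-count $c$ on a grid (default $\{1,2,4,8,16,32\}$),

$$ \mathrm{aLFC}(c) =
   \frac{\log_2\!\big((m_t + c)/(m_c + c)\big)}{\mathrm{SE}(c)}, $$

with $m_t, m_c$ the replicate means of normalized intron depth and
$\mathrm{SE}(c)$ the pooled standard error of the replicate
$\log_2(\mathrm{depth}+c)$ values, floored at $\varepsilon = 0.05$ so the
statistic stays finite when replicates are (nearly) identical. The reported
statistic is the $\mathrm{aLFC}$ of *minimal absolute value* over the grid
together with its $c$ — the most conservative stabilized effect. Raw
$|\log_2((a+c)/(b+c))|$ is non-increasing in $c$ for fixed $a \neq b$, so
the grid's upper end bounds the shrinkage. The sign of the selected aLFC
sets the call direction (positive = increased IR under treatment).

Significance comes from a separate replicate-level test, by default a
two-sided Welch *t*-test on

$$ v = \log_2 \frac{\bar d_i + 1}{\bar e_g + 1}, $$

the within-sample log-ratio of intron depth to the host gene's mean exonic
depth. Because both terms come from the same library, library scale cancels
exactly in $v$; the ratio moves only when retention changes relative to
transcription, which is precisely the quantity of interest. An exact
label-permutation test on the mean difference is available as an
alternative (`method = "permutation"`, requiring at least 6 exchangeable
units); with fewer than 2 replicates per side the Welch path returns `NA`
rather than a sham p-value. P-values are Benjamini–Hochberg adjusted
*within each (tissue, stress, phase) comparison*, mirroring per-treatment
reporting, and calls use $P_{adj} < \alpha$ with $\alpha = 0.05$.

Two filters precede testing. Genes whose expression changes more than
fivefold (in either direction) between the conditions are excluded, so
transcription bursts are not misread as retention shifts. Exon gaps
shorter than 20 nt (configurable) are treated as alignment artifacts and
never scored.

### Normalization

Depths are library-size normalized with *median-of-ratios* size factors
computed from per-gene mean exonic depths (each sample's factor is the
median ratio of its gene depths to the per-gene geometric mean across
samples). Total-count scaling was considered and rejected: a minority of
strongly regulated genes shifts the library total, which biases every
normalized depth in the sample and can pull a genuinely >5-fold gene under
the expression filter. Median-of-ratios is robust to such composition
effects as long as most genes are stably expressed, the standard assumption
in expression analysis. The test statistic $v$ is additionally
normalization-free by construction, so mis-estimated size factors cannot
inflate the test; they only affect the reported aLFC magnitudes.

## AS event classification from long-read isoforms

Aligned long-read transcript models are collapsed into unique isoforms:
multi-exon models with an identical (chromosome, strand, junction chain)
merge into one isoform taking the outermost observed ends (5′ truncation
noise in long reads shortens terminal exons but leaves junction chains
intact); single-exon models merge by same-strand overlap. Collapse is
idempotent and order-independent.

Each isoform is classified against the reference transcript of its gene
sharing the most junctions (ties: longest exonic length, then lexicographic
id — the comparison baseline must be stable and testable). With donors and
acceptors defined in transcript orientation:

* **IR** — a reference intron fully contained in one isoform exon;
* **Alt5** (alternative donor) — isoform junction shares its acceptor but
  not its donor with a reference junction;
* **Alt3** (alternative acceptor) — shares the donor, differs at the
  acceptor;
* **ES** — one or more complete reference exons fall inside the gap of a
  single isoform junction;
* **MXE** — an internal isoform exon overlapping no reference exon whose
  flanking junctions skip exactly one reference exon: one exon swapped for
  another. MXE is reported with both exon intervals and folded into ES in
  summaries, as a coordinated-ES subcategory.

Compound isoforms yield one event per local difference; there is no
priority suppression beyond the MXE rule (which absorbs the two junction
differences that constitute it). Terminal-exon end differences are not
events. Because the denominator of a class distribution is ambiguous when
one isoform carries several events, summaries report both tallies: events
per class, and isoforms counted once per class they exhibit.

Isoforms overlapping no annotated gene span are grouped into strand-aware
overlap clusters (*novel transcribed regions*); a region shows AS when at
least two member isoforms differ in junction chain, and its coding capacity
is called from the longest open reading frame across its spliced sequences
(default threshold 100 codons — a conservative conventional floor for a
protein-coding ORF).

## Junction handling

Junction records are keyed by intron coordinates (first and one-past-last
intronic base). Donor/acceptor motifs are the first and last two intronic
nucleotides read strand-aware; unstranded records are tried in both
orientations and adopt the orientation yielding a whitelisted motif
(GT/AG, GC/AG, AT/AC), with ties left unstranded as `other`. Instead of a
trained false-positive classifier, filtering uses transparent configurable
rules — motif whitelist, minimum read count 2, minimum anchor overhang
8 nt — which capture the intent of learned junction filters while remaining
auditable. Novelty is an exact-coordinate match against the annotation's
distinct introns: a 1 nt shift is novel. Multi-mapping reads (NH > 1) are
excluded at BAM extraction so that only uniquely aligned evidence counts.

## Co-regulation clustering

Significant DIRs form an intron × condition matrix of $\Delta r$ values;
rows observed in fewer than half the conditions are dropped. Rows are
z-scored and clustered hierarchically with correlation distance
($1 - \rho$) and average linkage, cutting the tree at height 0.3 (members
correlate at roughly $\geq 0.7$); singletons are discarded. These choices
are stated stand-ins — no specific algorithm is canonical for this task —
and every knob is exposed. Cluster coherence is the mean pairwise Pearson
correlation of member profiles; its significance comes from independently
permuting each member row's condition labels, which preserves marginals
while destroying coordination, with the add-one estimator
$p = (1 + \#\{\text{null} \geq \text{obs}\})/(1 + B)$. The permutation
seed is required and stamped into outputs so reports are bit-reproducible.

## ddPCR quantification

Template molecules distribute over droplets as a Poisson process, so from
the positive-droplet fraction $\hat p$ the mean copies per droplet is
$\hat\lambda = -\ln(1-\hat p)$ and the concentration is
$\hat\lambda / V_{\text{droplet}}$ (default droplet volume 0.85 nL, the
QX200-class figure) times the dilution factor. Replicate wells of one
target/condition are pooled *before* correction — pooling droplet counts
preserves the Poisson likelihood, averaging concentrations does not.
Saturated wells (all droplets positive) are an error, not an estimate. The
retention ratio of a condition is $100 \times$ retained/spliced copies; a
*switch* is flagged when, relative to baseline, the spliced copy number and
the retention ratio move to opposite sides of 1 — the signature of
stress-coupled isoform-ratio switching. Log-normal confidence intervals on
$\lambda$ are reported but never used for gating.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
a scale where the truth is enumerable:

* random multi-exon genes (default 20; 3–8 exons of 80–300 nt; introns
  80–400 nt) with strand-aware boundary motifs drawn at 0.90/0.08/0.02 for
  GT/AG, GC/AG, AT/AC — the qualitative mix seen in plant genomes;
* a study design of 3 tissues × 4 stresses × 2 phases × 3 replicates plus
  per-tissue controls, the shape of a multi-tissue stress survey at toy
  scale;
* per-base exonic depth NB(mean $= E \cdot 100$, dispersion 0.1;
  variance $\mu + \mu^2\phi$), the common transcriptomics parameterization;
* each intron's reads partition by an inclusion level $\psi$ (default
  0.15 — a realistic baseline retention for constitutively spliced plant
  introns) into retained depth (mean $\psi E d$) and a Binomial spliced
  junction count; $\psi = 0$ yields exact zeros, no noise on absent signal;
* 10% of introns seeded as DIRs with $|\Delta\psi| = 0.3$ in a random
  subset of stress×phase conditions; 10% of genes given an 8-fold
  expression change to exercise the expression filter;
* long-read models per gene: the reference isoform plus one single-event
  alternative isoform (types cycling IR/Alt5/Alt3/ES/MXE as structure
  allows), 3–8 reads each with uniform 5′ truncation up to 30 nt (never
  crossing a junction); five intergenic loci, two with a second
  donor-shifted isoform;
* droplet counts Binomial$(N, 1-e^{-\lambda})$.

Everything is deterministic given the seed; fixtures are plain text
(FASTA, GFF3, bedGraph, TSV, BED12, JSON manifest) and the manifest fully
determines the expected output of every stage, which is what the test
suite exploits.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: read-level alignment error and mapping
ambiguity, fragment-length and positional coverage biases, overlapping and
nested gene models, correlated biological replicate variation beyond NB
counting noise, partial (5′/3′-biased) long-read degradation, and ddPCR
rain/threshold ambiguity. Results on real alignments inherit whatever
systematic error the upstream aligner introduces.

## Validation scales and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) uses: a
1000-intron null with 20 replicate simulations for type-I error and FDR of
the full filter→test→BH pipeline; a 500-intron design with 100 seeded
DIRs and five simulations for power and direction accuracy; 500
single-event isoforms for classifier precision/recall; 100-replicate
depth-500 simulations for the $\psi/(1-\psi)$ identity; 200 null and 40
coherent clusters for permutation calibration and power; 100 simulated
wells at 20,000 droplets for the Poisson round trip; and two full
toy-design pipeline runs compared byte-for-byte. These sizes were chosen so
each check has enough Monte-Carlo resolution for its acceptance band while
the whole suite completes in minutes.

Numerical conventions: SE floor 0.05 in the aLFC; `NA` (never 0 or 1) for
untestable introns; BH within comparison families; permutation p-values
via the add-one rule; correlation distance on pairwise-complete
observations with uncorrelatable pairs treated as maximally distant;
degenerate Welch inputs (zero pooled variance) give $p = 1$ for equal
means and $p \to 0$ otherwise.

## Known limitations

* The Welch test at 3 replicates is slightly conservative (observed null
  rejection ≈ 0.04 at nominal 0.05); the permutation path is exact but
  granular at small designs.
* DIRs are defined on the per-gene union of distinct annotated introns;
  introns private to unannotated isoforms are only reachable through the
  novel-junction path.
* The per-intron mean-of-ratio estimate $r_i$ is noisy at low junction
  counts; $\Delta r$ therefore uses replicate means, and the odds identity
  only holds in expectation.
* Event classification is reference-relative: a compound isoform whose
  best-matching reference transcript is itself unusual can legitimately
  yield a different event decomposition than intuition expects.
* MXE detection requires the alternative exon to lie fully inside a
  reference intron; exotic overlapping MXE arrangements fold into
  Alt5/Alt3 plus ES calls.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(list(out_dir = "toy_run", seed = 1))
# toy_run/ now holds junctions.tsv, as_events.tsv, as_summary.tsv,
# dir_results.tsv, dir_summary.tsv, coreg_clusters.tsv, ddpcr_ratios.tsv,
# each stamped with the config hash and seed; rerunning with the same seed
# reproduces every file byte-for-byte.
```
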