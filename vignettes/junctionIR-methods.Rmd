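---
title: "Junction-based intron retention analysis: models and methods"
author: "junctionIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-based intron retention analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionIR)
```

# The quantity being estimated

When splicing is impaired — for instance after depleting a factor needed
for spliceosomal snRNA pseudouridylation — unspliced pre-mRNA accumulates.
`junctionIR` quantifies this from aligned RNA-seq reads using only reads
that directly span splice boundaries:

* a read whose contiguous alignment crosses an **exon–intron boundary**
  (with a minimum anchor on each side) is evidence of an unspliced
  molecule (count $a$);
* a read whose split alignment gap matches an annotated intron **exactly**
  is evidence of a spliced molecule (count $b$).

The **IR ratio** of a gene in a sample is the ratio of summed counts over
the gene's junctions,

$$\mathrm{IR} = \frac{\sum_j (a^{donor}_j + a^{acceptor}_j)}{\sum_j b_j},$$

a single coefficient per gene reflecting the magnitude of pre-mRNA
accumulation. Summing before dividing (rather than averaging per-junction
ratios) keeps the estimate stable when individual junctions carry few
reads; the per-junction tallies remain available for inspection. Knockdown
versus control comparison proceeds on two levels:

* **per gene**: IR is computed per replicate, averaged within condition,
  and the fold $\mathrm{IR}_{kd}/\mathrm{IR}_{ctrl}$ is compared with a
  threshold of 1.15 (strict inequality); only increases are flagged as
  aberrant retention, decreases are reported unflagged;
* **globally**: the two per-gene IR vectors are compared with the
  two-sample two-sided Kolmogorov–Smirnov test (asymptotic p-value); a
  rightward shift of the knockdown ECDF means the knockdown distribution
  is stochastically larger, i.e. genome-wide pre-mRNA accumulation.

Analysis is restricted to **high-confidence genes**: at least 10 total
junction reads ($a+b$) and RPKM $\ge$ 100, both as averages over the
control replicates and both inclusive thresholds. RPKM uses the merged
(union) exon length of the gene as its kilobase denominator and the total
primary mapped read count as its per-million denominator; the numerator
counts *mature* reads — reads overlapping the gene's exons but none of its
annotated introns, which includes split reads whose gaps match the gene's
junctions.

# The junction catalog

Junctions are derived from the union of annotated introns over all
transcripts of each gene (the annotation does not dictate a transcript
choice, and any annotated intron defines a measurable splicing event),
deduplicated by (gene, intron coordinates). Junctions with identical
coordinates in different genes are kept separately but flagged ambiguous.

A boundary is masked (non-measurable) when any of its first `overhang`
intronic bases are exonic in an overlapping transcript of any gene: a read
crossing such a boundary could be an ordinary exonic read of the other
isoform, so it must not be counted as retention evidence. Masked
boundaries never accumulate counts; their junction still contributes
spliced evidence.

Internally all intervals are `GRanges` (1-based, closed), the native
Bioconductor convention; the catalog TSV export writes BED-style 0-based
half-open intron coordinates, and GTF input (1-based, closed) is converted
at the boundary. Donor/acceptor are defined in transcript orientation: on
the minus strand the donor is the right genomic boundary.

# Read classification rules

With anchor `overhang` $h$ (default 6 nt, applied to both read classes):

* **SPLICED**: a CIGAR N gap equal to the intron, with $\ge h$ aligned nt
  on each side. Near-miss gaps (offset by even 1 nt) are ignored, not
  counted — the catalog defines the events of interest and novel-junction
  discovery is out of scope.
* **DONOR/ACCEPTOR**: a contiguous aligned block covering the $h$ exonic
  and $h$ intronic bases around a measurable boundary.

Only primary, non-duplicate, non-supplementary alignments with mapping
quality $\ge$ 10 are used (the source protocols do not pin these down;
the values are declared defaults, all configurable). Counting is
strand-agnostic since library strandedness is typically unknown for
total-RNA protocols; mates of a pair are counted as independent events.
A read may generate events on several junctions but at most one event per
junction; for the rare contiguous read that spans a whole short intron
(crossing both boundaries) the donor event is kept, a deterministic
tie-break.

# The simulator and what "recovery" demonstrates

`simulateDataset()` generates a single synthetic chromosome (uniform
random A/C/G/T), one transcript per gene, and uniform reads from a mixture
of molecule isoforms: each molecule retains each intron independently with
probability $\theta$ (one $\theta$ per gene, shared by its introns, so the
gene-level expectation has a closed form). Reads from spliced molecules
that cross a junction are written as split SAM alignments whose N gap
equals the intron exactly; unspliced-molecule reads are contiguous.

Under uniform placement, a junction offers $L - 2h + 1$ anchored
placements for its exon–exon read and each of the two exon–intron
boundaries of a retained intron offers the same number, hence

$$E[\mathrm{IR}] \to \frac{2\theta}{1-\theta},$$

which `expectedGeneIR()` returns and the test suite verifies by
simulation (the geometry check in `simConfig()` — minimum exon length
$\ge L - h$ — guarantees every placement exists, so the identity is exact
rather than approximate).

Default conditions emulate a knockdown design: two conditions with two
replicates, $\theta_{ctrl} \sim U(0.05, 0.2)$, and a $+0.1$ shift planted
in 80% of genes — matching the magnitude of widespread retention reported
for splicing-factor depletion, where roughly four fifths of expressed
genes gain retention. The generator deliberately omits sequencing error,
GC bias, fragment-length variation, paired-end structure and isoform
switching: the IR statistic is driven by position counts alone, so these
factors would add realism without changing what recovery tests can show.
Consequently, passing tests demonstrate the *estimator and pipeline
logic* are correct; they do not certify behaviour under alignment
artefacts or biased coverage in real data.

Problem sizes used by the checks: gene-level recovery runs 500
single-intron genes at roughly 1,800 junction reads per gene (deep
coverage, so that the fold threshold of 1.15 separates cleanly from
counting noise); KS calibration uses 2,000 Monte-Carlo null replicates of
500-gene cohorts, where the asymptotic two-sample test rejects at 5.0% at
$\alpha = 0.05$; the end-to-end pipeline checks run ~50–150 genes.

# The expression screen

`screenUpregulated()` reproduces a case/control microarray screen: fold
change as the difference of group means in log2 space, an unpaired
two-sided t-test per gene, and selection by strict thresholds
(fold > 1.5, p < 0.01, no multiple-testing correction — selection is on
raw p-values by design). The Welch test is the default, the safer choice
under the heavily unbalanced group sizes such screens often have
(e.g. 117 tumours vs 7 controls). The pooled-variance test is exposed as
`var_equal = TRUE` because the selected-gene count genuinely depends on
the choice: at 20 cases vs 5 controls with planted effects of 1.5 log2
units ($\sigma = 0.5$), the Welch test misses ~10% of planted genes (the
small control group leaves it very few degrees of freedom) while the
pooled test misses under 2%. The recovery checks therefore use the pooled
variant; on balanced designs the two agree closely. Genes with zero
variance in both groups have no defined t statistic and are reported
unselected with a warning.

# The branch-site scanner

`scanBranchSite()` slides an IUPAC consensus (default `UCCUGNC`, branch
position 6) over the final `window` nt (default 100) of an intron given
in transcript orientation, scoring placements by match count. Simple
match-count scoring, not a position weight matrix, is deliberate: the
motif of interest is a single literal element and transparency matters
more than sensitivity; PWM scoring is a natural extension point. The
branch position is configurable because which motif position carries the
branchpoint can be ambiguous in annotations. Placements whose branch
nucleotide lies in the last 3 nt before the 3' splice site are excluded
(branch points do not abut the 3'SS); ties are broken towards the 3'SS,
where mammalian branch points cluster (−18..−40). A branch nucleotide
other than A is flagged noncanonical — the configuration where splicing
is expected to depend on U2 snRNA pseudouridine stabilising the weaker
G/C pairing, which is the biological motivation for the scan.

# Numerical and degenerate-input conventions

* IR with $b = 0, a > 0$ is flagged infinite, excluded from folds and KS
  vectors, and reported separately; $a = b = 0$ is undefined. No
  pseudocounts are added anywhere.
* The aberrant fraction is reported over all high-confidence genes;
  excluded genes are listed with reasons.
* `ks.test` is always called with `exact = FALSE`; ties in IR vectors
  (ratios of small integers) would make "exact" p-values invalid anyway.
* The filter, fold, and screen thresholds follow their verbal
  definitions exactly: "at least"/">=" inclusive, "more than" strict.
* Empty alignment files count successfully to all-zero tables with
  RPKM reported as `NA` (the RPKM denominator is undefined).
* All simulator randomness derives from the required `seed` field;
  identical configs give byte-identical output files.

# Known limitations

* The catalog is annotation-version-dependent; junction and gene counts
  from different annotation builds are not comparable.
* Exon–intron evidence is counted per boundary and summed; tools that
  count retention per intron pair will differ on partially masked
  junctions.
* No per-gene significance test accompanies the differential fold (the
  analysis applies a fold threshold by design); counting-noise false
  positives near the 1.15 threshold are controlled by depth, not by a
  test.
* The simulator's uniform single-end reads cannot exercise
  duplicate-marking, pairing or strandedness options.
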