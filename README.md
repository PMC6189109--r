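# junctionIR

Junction-based quantification of intron retention (IR) from aligned
RNA-seq, for studying global splicing impairment — e.g. after knocking
down a splicing factor — together with the surrounding analyses such a
study needs: a differential-retention caller, a global ECDF shift test, a
case/control expression screen, a branch-point motif scanner, and a
ground-truth read simulator that makes every stage verifiable at desk
scale.

## The statistic

Only reads that directly span splice boundaries are used. Reads whose
contiguous alignment crosses an exon–intron boundary (with ≥ 6 nt anchored
on each side) count as unspliced evidence *a*; reads whose split-alignment
gap exactly matches an annotated intron count as spliced evidence *b*.
Per gene and sample,

    IR = Σ(a_donor + a_acceptor) / Σ b

over the gene's junctions. Analysis is restricted to high-confidence
genes (mean ≥ 10 junction reads and RPKM ≥ 100 in the control
replicates). A gene is called **aberrant retention** when
IR_kd / IR_ctrl > 1.15 (strict), and the global shift of the IR
distribution is tested with the two-sample Kolmogorov–Smirnov statistic:
a rightward ECDF shift in the knockdown means genome-wide pre-mRNA
accumulation. Details and design rationale are in
`vignettes/junctionIR-methods.Rmd`.

## Worked example

Simulate a knockdown experiment with known per-gene retention fractions
(θ_ctrl ~ U(0.05, 0.2); 80% of genes shifted by +0.1 in the knockdown),
then run the pipeline:

```r
library(junctionIR)

sim <- runSimulate(tempfile("ex"), seed = 11, n_genes = 30, lambda = 5)
models  <- readGeneModels(sim$gtf)
catalog <- buildJunctionCatalog(models, overhang = 6)
catalog
#> JunctionCatalog with 61 junctions in 30 genes (overhang 6 nt)
#>   measurable boundaries: 61 donor / 61 acceptor; 0 ambiguous

cs  <- countJunctions(sim$sam, catalog, models = models)
tab <- geneIRTable(cs, catalog)
head(tab[tab$sample_id == "ctrl_rep1",
         c("gene_id", "a_total", "b_total", "ir", "rpkm")], 4)
#>   gene_id a_total b_total        ir     rpkm
#> 1   g0001     157     552 0.2844203 80890.21
#> 2   g0002      84     592 0.1418919 83279.15
#> 3   g0003      51     298 0.1711409 60154.66
#> 4   g0004      33     321 0.1028037 70015.54

tab <- filterHighConfidence(tab, c("ctrl_rep1", "ctrl_rep2"))
res <- differentialIR(tab, c("ctrl_rep1", "ctrl_rep2"),
                      c("kd_rep1", "kd_rep2"))
head(res$table, 4)
#>   gene_id    ir_ctrl     ir_kd  ir_fold aberrant
#> 1   g0001 0.25919455 0.4897627 1.889556     TRUE
#> 2   g0002 0.13312211 0.1490206 1.119428    FALSE
#> 3   g0003 0.15886037 0.4538153 2.856693     TRUE
#> 4   g0004 0.09561956 0.3494422 3.654506     TRUE
str(res$summary)
#> List of 4
#>  $ n_high_confidence: int 30
#>  $ n_evaluated      : int 30
#>  $ n_aberrant       : int 25
#>  $ fraction_aberrant: num 0.833

ksShift(res$table$ir_ctrl, res$table$ir_kd)[c("statistic", "p.value")]
#> $statistic 0.667   $p.value 3.24e-06
```

The estimated aberrant fraction (0.833 of 30 genes) recovers the planted
fraction (0.8); per-gene `ir` tracks the closed form `expectedGeneIR(θ) =
2θ/(1−θ)` recorded in `sim$truth`. The KS test rejects decisively, as it
should for a global +0.1 θ shift.

Other entry points: `screenUpregulated()` (case/control log2 matrix →
genes with fold > 1.5 at p < 0.01), `scanBranchSite()` /
`scanCatalogBranchSites()` (branch-point consensus scan of intron 3'
ends, flagging non-adenosine branch nucleotides), `splicingEfficiency()`
and `ddct()` (ratio statistics for RT-PCR readouts). Every stage is also
available as a shell subcommand via the thin `exec/junctionIR` script
(`simulate`, `catalog`, `count`, `ir`, `diff`, `screen`, `branch`), each
writing a JSON run manifest next to its outputs.

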