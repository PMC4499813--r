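# blockProc

Differential and coherent processing analysis of small RNAs from
multi-sample short RNA-seq read profiles.

## The problem

Mapped short RNA reads pile up at a locus in characteristic stacks
("blocks"); the set of blocks at one locus in one sample is its *read
profile* (or *block group*) and reflects how the host transcript is
post-transcriptionally processed.  MicroRNA **arm switching** — the mature
miRNA being produced from the 5p arm in some tissues and the 3p arm in
others — is the canonical example of what this package calls *differential
processing*; a profile that looks the same in every sample is *coherently
processed*.  Both are statements about profile shape, independent of
expression level, so they complement ordinary differential-expression
analysis.  The package is aimed at anyone with replicated small RNA-seq
across several cell lines or tissues (BED/BAM mapped reads) who wants
locus-level calls of either kind.

## The method

Per locus, after profiling (reads < 50 nt apart share a locus; Gaussian-peak
block detection; ≥ 10 reads per locus; blocks ≥ 10% of the locus total) and
cross-sample harmonization, all profile pairs are aligned to a similarity
score *S* ∈ [0, 1].  The *n* × *n* score matrix is clustered
(1 − Pearson correlation, average linkage) with multiscale-bootstrap
approximately-unbiased support, and each supported cluster *k*
(p < 0.05) is scored

&nbsp;&nbsp;&nbsp;&nbsp;*X*<sub>k</sub> = max(0, S̄<sub>in</sub>(k) − S̄<sub>out</sub>(k)),&nbsp;&nbsp;&nbsp;&nbsp;*X* = mean<sub>k</sub> *X*<sub>k</sub>,

the margin by which profiles agree better inside the cluster than across
its boundary.  Loci with *X* ≥ 0.15 are candidate **differentially
processed loci (DPL)** and are validated depth-independently: block counts
are normalized by median-of-ratios size factors
*s*<sub>j</sub> = median<sub>i</sub> *k*<sub>ij</sub> / (∏<sub>m</sub> *k*<sub>im</sub>)<sup>1/m</sup>,
all sample pairs are compared with m×2 Fisher's exact tests, and a locus
passes iff in some supported cluster more than half the in-cluster samples
are significant against every out-of-cluster sample.  Loci whose mean
pairwise *S* is ≥ 0.8 are **coherently processed loci (CPL)**; single-block
profiles with read-start entropy ≤ 2 bits and span ≤ 40 nt are classified
*short and precise*.  Genomic context comes from a binomial dart-throwing
enrichment model and strand-aware TSS metaprofiles.

A built-in simulator generates replicated multi-sample read datasets with
known truth (arm switching, arm loss, coherent and noise loci, variable
depth), so the entire pipeline is testable without any external data.  See
`vignettes/differential-processing.Rmd` for the full model description.

## Worked example

```r
library(blockProc)

scen <- c(replicate(2, locusScenario("arm_switch"), simplify = FALSE),
          replicate(2, locusScenario("coherent_one_block"), simplify = FALSE),
          list(locusScenario("noise")))
ds  <- simulateDataset(scen, seed = 42)   # 9 cell lines x 2 replicates
res <- runPipeline(ds$readsBySample, ds$replicateMap, mode = "combined",
                   nBoot = 500, seed = 43)
#> profiling 18 sample(s)
#> 5 common locus/loci selected
print(res)
#> ProcessingResult: 5 locus/loci | 2 candidate, 2 validated DPL, 2 CPL
res$summary[, c("locus", "n_consensus_blocks", "X", "candidate", "dpl",
                "mean_S", "cpl")]
#>   locus n_consensus_blocks      X candidate   dpl mean_S   cpl
#> 1     1                  2 0.3244      TRUE  TRUE  0.575 FALSE
#> 2     2                  3 0.3146      TRUE  TRUE  0.629 FALSE
#> 3     3                  1 0.0302     FALSE FALSE  0.925  TRUE
#> 4     4                  1 0.0311     FALSE FALSE  0.932  TRUE
#> 5     5                  3 0.1313     FALSE FALSE  0.588 FALSE
```

Reading the table: the two arm-switch loci separate cleanly (cluster score
*X* ≈ 0.32, well over the 0.15 candidate threshold) and survive the
depth-independent Fisher validation (`dpl = TRUE`), while their mean
alignment score (~0.6) keeps them far from the coherent call.  The two
single-block loci are the mirror image: no cluster structure (*X* ≈ 0.03)
but near-identical profiles everywhere (mean *S* ≈ 0.93 ≥ 0.8 →
`cpl = TRUE`).  The noise locus is neither: its scattered read starts
depress the mean score, but no sample subset forms a supported,
validated cluster.

A thin command-line wrapper over the same functions ships in
`inst/scripts/blockproc.R` (`simulate` and `run` subcommands).

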