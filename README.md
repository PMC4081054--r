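# nbcnv

Rare copy number variant (CNV) detection from whole-exome read-depth
data, for cohorts of samples sequenced on one platform — including
family trios. `nbcnv` is aimed at statistical geneticists and
bioinformaticians who have a targets file and per-sample read counts (or
BAM files) and want deletion/duplication calls with quality scores,
integer copy numbers, and trio transmission / de novo analysis, all
testable offline through a built-in cohort simulator.

## The model

Read counts $K_{ij}$ at capture target $i$ in sample $j$ are modelled as
negative binomial, $K_{ij} \sim \mathrm{NB}(\mu_{ij}, \sigma^2_{ij})$,
with moments estimated from reference samples:

* reference samples are normalized to the test sample's aggregate count,
  then weighted by non-negative least squares regression of the test
  sample on the references — samples sharing the test sample's batch
  biases get the weight;
* $\mu_{ij}$ and $\sigma^2_{ij}$ are the weighted mean and (unbiased,
  reliability-weighted) variance across references, with a floor
  $\max(\mu_{ij}, s^2_{ij})$ where $s^2_{ij}$ comes from an additive
  penalized-spline regression of variance on mean depth and GC content;
* a 3-state HMM (deletion / diploid / duplication) with NB emissions
  (mean and size scaled by copy/2) and distance-attenuated transitions
  ($p = 10^{-8}$, $T = 6$ targets, $D = 70$ kb) is decoded by Viterbi;
* every call gets Phred-scaled qualities
  $SQ = -10\log_{10}P_\text{none}$ and $NQ = -10\log_{10}(1 -
  P_\text{none})$ from constrained forward passes, plus an integer copy
  number in {0, 1, 3, 4, 5, 6} chosen by likelihood ratio (non-baseline
  states require LR > 1000; copy 0 uses a Poisson(0.2) background);
* samples with more than 50 calls are filtered out, and an
  inverse-covariance MDS diagnostic (`mds_batches()`, `plot()`) shows
  the cohort's batch structure.

For trios, a parental call is transmitted when the child's SQ over the
region exceeds the child's NQ; a child call is de novo at threshold $t$
when its SQ and both parents' NQ exceed $t$. The median per-pair
transmission ratio converging to 50% as quality rises is the package's
built-in specificity instrument.

See the methods vignette (`vignettes/methods.Rmd`) for assumptions,
parameter rationale, and limitations.

## Worked example

```r
library(nbcnv)

# a simulated 30-sample cohort with one spiked heterozygous deletion
sim <- simulate_cohort(n_samples = 30, n_targets = 400, depth = 100, seed = 42)
set.seed(99)
sim <- spike_cnvs(sim, data.frame(sample = "S007", first_target = 120,
                                  last_target = 124, copy = 1))

fit <- nbcnv(sim$counts, sim$targets)
fit
#> Cohort CNV calls (negative binomial HMM)
#>   samples: 30   targets: 400
#>   calls: 1 (1 DEL, 0 DUP)
calls(fit)
#>   sample type chrom  start    end first_target last_target n_targets SQ NQ copy_number
#> 1   S007  DEL  chr1 493100 504354          120         124         5 99  0           1
```

The spiked 5-target deletion — and nothing else — is recovered in the
right sample with SQ at the 99 cap (overwhelming evidence *for* the
event), NQ ≈ 0 (no evidence the region is diploid) and copy number 1
(heterozygous). `write_calls(calls(fit), "calls.tsv")` writes the call
table; `format = "vcf"` emits VCF 4.2 with symbolic `<DEL>`/`<DUP>`
alleles.

Real data enter the same way: `read_targets("targets.bed")`,
`gc_content(targets, "ref.fa")`, `count_reads_from_bam("s1.bam",
targets)` per sample (or `read_count_matrix()` for a precomputed
table), then `nbcnv(counts, targets)`. For trios, build the pedigree
with `read_pedigree()`, pass
`exclude_references = pedigree_exclusions(ped)` to `nbcnv()` so family
members stay out of each other's reference panels, and use
`trio_transmission()`, `transmission_ratio()`, `trio_de_novo()` and
`size_binned_inheritance()`.

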