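# crossqc

Curation of SNP genotypes from two-generation experimental crosses.

## The problem

Genetic mapping in an F2 intercross or N2 backcross starts from raw SNP
allele calls delivered by an array genotyping service (e.g. the MiniMUGA
mouse array, as Illumina-style long-format files). Before those calls can be
used for QTL mapping they must be converted into genotypes coded relative to
the two parental strains (`A` = homozygous parent 1, `H` = heterozygous,
`B` = homozygous parent 2) — and they must be cleaned. Defective assays,
annotation errors and parent/offspring allele inconsistencies produce
genotypes that mimic recombination: the genetic map estimated from the cross
expands to thousands of centimorgans, permutation-based LOD thresholds
explode, and spurious single-marker linkage peaks appear.

`crossqc` is for geneticists running two-generation crosses who want an
automated, reproducible path from raw allele calls to an analysis-ready
R/qtl cross file. It implements a cascade of simple, genetically motivated
filters over a per-marker ledger (the *marker table*), plus a synthetic
cross simulator used to validate every filter against known ground truth.

## The method

For each marker the package records the alleles observed in the offspring,
the parental alleles (consensus over replicate samples of each strain), and
the genotype-class counts. Filters then flag markers:

1. **match** — marker not genotyped in both parents and offspring, or not
   placed on the genetic map by the annotation;
2. **allele** — parent/offspring allele inconsistencies: both parental
   alleles missing; parents sharing one allele while two segregate in the
   offspring; offspring homozygous for a base carried by neither parent;
   backcross homozygotes for the non-recurrent allele; optionally (strict
   mode) any marker with a missing or heterozygous parent. A single missing
   parental allele is otherwise imputed from the offspring;
3. **na** — more than 50% missing genotypes (configurable);
4. **poly** — no polymorphism among genotyped offspring;
5. **prop** — departure from Mendelian segregation, either as a minimum
   proportion per genotype class (default 10%; expectations 1:2:1 for an F2,
   1:1 for an N2) or as a chi-square goodness-of-fit test
   (χ² = Σ (O−E)²/E) at a configurable α;
6. **estmap** — map sanity: the recombination fraction r between each pair
   of adjacent retained markers is estimated (direct recombinant proportion
   in a backcross; pairwise EM over the two-locus genotype classes in an
   intercross) and converted to distance with the Haldane map function
   d = −50 ln(1 − 2r). A marker whose estimated distance to *every* neighbor
   exceeds a threshold (default 100 cM) is genotyping noise, not biology,
   and is dropped.

Retained markers are exported as an R/qtl `"csv"` cross file; the full
marker table, with every flag and exclusion reason, is exported as a TSV
report.

## Worked example

Simulate a 176-individual F2 on a 19-chromosome map with a mix of injected
error markers, build parental consensus genotypes, and run the cascade in
chi-square mode:

```r
library(crossqc)

cfg <- sim_config(n_individuals = 176, map = sim_map(19, 30, 2), seed = 2025,
                  error_spec = c(random_call = 3,
                                 parent_monomorphic_sgipoly = 3,
                                 nonpolymorphic = 20, high_missing = 3))
sim     <- simulate_cross(cfg)
parents <- parental_alleles(consensus_strains(sim$parents, sim$strain_of),
                            "P1", "P2")
res <- run_pipeline(sim$geno, sim$map, parents, cross_type("F2"),
                    filter_config(prop_mode = "chi2"))
res
#> Curation of a F2 cross: 498/570 markers retained
#>    step n_in n_excluded n_out                         params
#>  import  570          0   570
#>   match  570          0   570
#>  allele  570          3   567             parNH_strict=FALSE
#>      na  567          3   564                     na_max=0.5
#>    poly  564         20   544
#>    prop  544         46   498 mode=chi2 alpha=0.05 x_min=0.1
#>  estmap  498          0   498               threshold_cM=100
```

Reading the log: the 3 markers whose parents were set identical while the
offspring segregate are caught by the allele filter, the 3 high-missingness
markers by the NA filter, the 20 monomorphic markers by the polymorphism
filter, and the proportion step removes the 3 random-call markers plus the
expected ~5% of clean markers that a chi-square test at α = 0.05 rejects by
construction. The curated map is no longer expanded:

```r
map_length_ratio(estimate_map(res$encoded))
#> [1] 1.013
```

Per-marker segregation can be tested directly; a marker with genotype
counts 40:40:20 against the 1:2:1 expectation gives

```r
mendelian_chi2(c(n_p1p1 = 40, n_het = 40, n_p2p2 = 20), cross_type("F2"))
#> $statistic
#> [1] 12
#> $p_value
#> [1] 0.002478752
```

Finally `write_rqtl(res$encoded, pheno, "cross.csv")` writes the R/qtl cross
file and `write_marker_report(res$table, "markers.tsv")` the audit trail.

The same pipeline is scriptable from a shell via
`inst/cli/crossqc.R {simulate|curate|report}` (see `cmd_curate()` and
friends).

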