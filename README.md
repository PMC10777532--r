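# coloclust

Colocalization-first partitioning of GWAS risk variants into pathway
clusters, with partitioned polygenic risk scores and Mendelian-
randomization directionality tests.

## The problem

Risk variants for a heterogeneous disease such as type 2 diabetes act
through different biological pathways — adiposity, lipid metabolism,
insulin secretion. Grouping variants by the *other* traits they move is a
powerful way to expose that structure, but naive grouping by shared
significance is confounded by linkage disequilibrium: two traits can show
overlapping association peaks driven by different causal variants.
`coloclust` addresses this by demanding Bayesian colocalization evidence
(a shared causal variant) before a variant–trait association enters the
clustering at all, then:

1. **Harmonizes** per-trait GWAS summary statistics over 1 Mbp regions
   around disease lead variants (allele reconciliation, orientation to
   the effect-increasing allele, removal of ambiguous palindromic
   variants with LD-proxy substitution for leads).
2. **Colocalizes** with a staged workflow: Wakefield approximate Bayes
   factors feed a multi-trait regional/alignment posterior
   (accepted when `P_R * P_A > 0.60` with a per-trait association gate of
   `p < 1e-5`); multi-signal regions are fine-mapped with a
   sum-of-single-effects model and tested credible-set by credible-set
   (`PP.H4 > 0.6`); a single-causal-variant enumeration is the fallback.
3. **Clusters** the significance-gated, sparse variant-by-trait z matrix:
   Pearson correlations between variant profiles, the highest edge
   cutoff that keeps every vertex connected, and spinglass community
   detection scored by weighted modularity
   `Q = sum_c [w_c/W - (d_c/2W)^2]`.
4. **Scores** individuals with per-cluster polygenic risk scores
   (dosage-weighted, standardized) and tests outcome associations with
   covariates and Bonferroni correction.
5. **Orients** cluster–trait relationships with two-sample MR: IVW and
   Egger regression plus the Steiger test comparing instrument
   `r² = z²/(z²+n−2)` between exposure and outcome.

A synthetic-data module generates LD matrices, multi-trait summary
statistics with planted colocalization and cluster structure, and
individual-level cohorts, so the whole pipeline runs and is tested end to
end without any external downloads.

## Worked example

Generate the default synthetic scenario — an index disease trait plus six
metabolic traits, 12 regions of 150 variants, three planted pathway
clusters, two null regions — and run the pipeline:

```r
library(coloclust)

dir <- file.path(tempdir(), "demo")
make_scenario(default_scenario(seed = 42), dir)
res <- run_pipeline(dir, ccfg = cluster_config(n_restarts = 10, seed = 42))

events_table(res$events)[, .(region_id, method, traits, lead, pr, pa, pp_h4)]
#>     region_id     method      traits     lead        pr        pa     pp_h4
#>  1:         1 multitrait     bmi,t2d  rs1_075 0.9814499 0.9985745        NA
#>  2:         2 multitrait bmi,t2d,vat  rs2_075 0.9999908 0.9999999        NA
#>  3:         3 multitrait bmi,t2d,vat  rs3_075 0.9999990 0.9999999        NA
#>  4:         4      susie     t2d,bmi  rs4_075        NA        NA 0.9999988
#>  5:         4      susie     t2d,vat  rs4_075        NA        NA 1.0000000
#>  6:         5 multitrait      t2d,tg  rs5_075 0.9999172 0.9989776        NA
#>  7:         6 multitrait  hdl,t2d,tg  rs6_075 0.9998481 0.9999999        NA
#>  8:         7 multitrait  hdl,t2d,tg  rs7_075 0.9996857 0.9999999        NA
#>  9:         8 multitrait      fg,t2d  rs8_075 1.0000000 0.9990010        NA
#> 10:         9 multitrait  fg,hba,t2d  rs9_075 0.9996619 0.9999999        NA
#> 11:        10 multitrait  fg,hba,t2d rs10_075 0.9999707 0.9999999        NA
```

All ten planted colocalized regions are detected (each event names the
trait set sharing the causal variant and the lead SNP; region 4, which
carries two independent disease signals, went through the fine-mapping
route) and the two null regions are quiet. The network stage then
recovers the planted clusters:

```r
c(cutoff = res$cutoff, Q = res$solution$modularity, k = res$solution$k)
#> cutoff     Q      k
#>  0.678 0.635      3

res$signatures[cluster == 1]
#>    cluster trait   mean_z
#> 1:       1   bmi 7.648798
#> 2:       1    fg 0.000000
#> 3:       1   hba 0.000000
#> 4:       1   hdl 0.000000
#> 5:       1    tg 0.000000
#> 6:       1   vat 5.932360
```

The edge cutoff (0.678) is the highest correlation threshold at which
every variant keeps at least one edge; modularity 0.635 over `k = 3`
emergent communities; the first cluster's signature (positive mean z on
BMI and visceral fat only) is the planted adiposity pathway. From here,
`build_prs()` + `test_association()` score and test per-cluster risk
scores in a cohort, and `mr_report()` runs IVW/Egger/Steiger between a
cluster's traits — `experiment_end_to_end()` wires all of it together
and scores the run against the scenario's truth table.

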