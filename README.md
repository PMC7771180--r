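# trophiq

Quantitative diet analysis and trophic-niche comparison from DNA
metabarcoding read tables, built around Barcode Index Numbers (BINs) as
prey-item units. The package targets the study design used in molecular
diet work on cryptic insectivorous bats — two species sampled across
allopatric and sympatric regions, with fine-scale syntopic/allotopic
classification — but every stage operates on plain tables and applies to
any predator–prey metabarcoding data set with a 2-primer × 2-PCR-replicate
run structure.

## What it computes

* **Quality filtering** of long-format read tables: low-read (singleton)
  removal with a morphology-calibrated threshold, the 10× blank
  contamination rule (extraction blanks scoped by batch, sequencing blanks
  by run and primer), additive and conservative PCR-replicate consensus
  (conservative mode requires >100 reads in all four runs), and primer
  union — with a full removal audit trail.
* **Diet metrics**: weighted percent of occurrence
  (`wPOO_i = (1/S) Σ_s c_i(s)/n(s)` — an item found among 10 items
  contributes 1/10 of a sole item), POO, RRA; at BIN, order, or
  functional-category level; Levins' standardized niche breadth
  `B_A = (1/Σp² − 1)/(n − 1)`.
* **Niche overlap**: Pianka's
  `O_jk = Σ p_j p_k / √(Σ p_j² · Σ p_k²)` with RA1–RA4 randomization null
  models (RA3 default: reshuffle each species' utilization values across
  resource states), two-tailed add-one-corrected p-values; Jaccard
  distances and ANOSIM; stratified overlap (allopatric/sympatric,
  allotopic/syntopic) and pairwise between-site overlap tables.
* **Functional profiling**: volancy classification (non-volant / not
  actively volant / nocturnally volant; most-specific rule wins) and the
  per-sample fraction of prey that is not nocturnally volant — a gleaning
  proxy.
* **Prey selection**: site-level diet-minus-availability wPOO behind a 20%
  representativeness gate, with cross-site quartiles, bootstrap CIs and
  over/under/neutral flags.
* **Synthetic studies with ground truth** (`generate_study()`): full read
  tables, metadata, taxonomy, functional rules, morphology counts and
  blanks with known prey-use vectors, true per-stratum overlap, planted
  contaminants, detection biases, calibration optima and selection
  effects — the basis of the package's parameter-recovery test suite.

## Worked example

```r
library(trophiq)

st <- generate_study(generator_config(seed = 1))
f  <- filter_study(st$reads, st$meta, min_reads = 2, blank_factor = 10)
dropping <- st$meta$sample_id[st$meta$sample_type == "dropping"]
comp <- f$composition[f$composition$sample_id %in% dropping, ]

stratified_overlap(comp, st$meta, scale = "fine", n_iter = 1000, seed = 1)
#> $allotopic
#> Pianka niche overlap null-model test (RA3)
#>   observed O_jk = 0.5405
#>   null mean = 0.4021 (1000 iterations)
#>   Pr(null >= obs) = 0.0170, Pr(null <= obs) = 0.9840
#>
#> $syntopic
#> Pianka niche overlap null-model test (RA3)
#>   observed O_jk = 0.4704
#>   null mean = 0.4117 (1000 iterations)
#>   Pr(null >= obs) = 0.1868, Pr(null <= obs) = 0.8142

true_overlap(st, "syntopic")
#> [1] 0.5127449
```

The two species' diets overlap more than the RA3 null expects in allotopic
sites (O_jk = 0.54, p_high = 0.017) and the syntopic estimate sits close
to the generator's true overlap of 0.513; with a planted `syntopic_shift`
the syntopic overlap drops below the allotopic one. Order-level wPOO per
species comes from `compute_wpoo(comp, level = "order", taxonomy =
st$taxonomy, groups = ...)` — for this seed *M. escalerai*'s diet is led
by Diptera (34.0%), Lepidoptera (16.3%) and Coleoptera (14.0%).

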