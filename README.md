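# coevomotif

Mapping the specificity landscape of an enzyme family from its multiple
sequence alignment.

Large glycoside hydrolase / phosphorylase families such as CAZy family GH65
contain thousands of sequences but only a handful of experimentally
characterised members, and overall sequence similarity is a poor guide to
substrate specificity. `coevomotif` implements the alternative strategy of
reading specificity off a small set of co-evolving alignment positions:
columns whose residues are conserved within each substrate specificity but
switch together across specificity boundaries. The package

1. **curates** a family alignment (greedy redundancy reduction at an
   identity threshold, removal of sequences lacking the catalytic acid,
   trimming of gap-rich columns),
2. **detects correlated mutations**: for columns *i*, *j* it computes a
   weighted normalized mutual information
   `NMI(i,j) = MI(i,j) / min(H(i), H(j)) ∈ [0, 1]`
   with Henikoff position-based sequence weights and pairwise-complete gap
   handling (Rcpp kernel for full matrices),
3. **selects specificity-determining positions** with a two-stage rule: at
   least one score above 0.9 and at least two correlation partners at or
   above 0.8,
4. **extracts per-subgroup fingerprint motifs** (weighted residue
   frequencies, Schneider–Stephens information content, consensus tokens
   like `K`, `[MF]`, `x`) and **classifies query sequences** against a
   packaged fingerprint table, including a phosphorylase-vs-hydrolase
   mechanism call from phosphate-binding positions,
5. **annotates the family phylogeny** (clade-homogeneity subgroup
   assignment, iTOL COLORSTRIP ring export in the RasMol color scheme), and
6. **fits Michaelis–Menten kinetics** `v = Vmax·S/(KM+S)` of candidate
   enzymes by bounded Levenberg–Marquardt least squares, with
   `kcat = Vmax·MW/60` (Vmax in U/mg, MW in kDa) and catalytic efficiency
   `kcat/KM`.

A synthetic-family generator plants subgroup-coupled columns with known
ground truth, so the whole pipeline is testable without any downloads.

## Worked example

Generate the GH65-analog synthetic family (22 subgroups × 50 sequences, 600
columns, 24 planted co-evolving positions) and run the correlation stage:

```r
library(coevomotif)

fam <- generate_family(gh65_analog_spec())
w   <- henikoff_weights(fam$alignment)
cr  <- cma_matrix(fam$alignment, w, reference_id = "CsKP_synthetic")
net <- build_network(cr, edge_threshold = 0.8)
select_positions(net, cr, strong_threshold = 0.9, min_partners = 2)
#> # A tibble: 6 × 4
#>   position column max_score n_partners
#>      <int>  <int>     <dbl>      <int>
#> 1       64     64     0.931         20
#> 2      392    392     0.948         20
#> 3      394    394     0.948         20
#> 4      402    402     0.944         20
#> 5      416    416     0.941         20
#> 6      585    585     0.942         20
```

Exactly the six planted positions pass the two-stage rule, each with 20
partners at the hub-anchored coupling; 24 positions in total reach a score
of 0.8 somewhere in the matrix. Classify the four uncharacterised query
motifs against the packaged fingerprint table:

```r
classify_sequence(c(TbGP = "TRIGPP", ChGP = "FAITQA",
                    HoGP = "EEAPWS", CaGP = "DQGQDE"),
                  gh65_fingerprints())
#> # A tibble: 4 × 4
#>   query_id label   match_score detail
#>   <chr>    <chr>         <dbl> <list>
#> 1 TbGP     TP                1 <tibble>
#> 2 ChGP     oligoNP           1 <tibble>
#> 3 HoGP     KP                1 <tibble>
#> 4 CaGP     T6PP              1 <tibble>
```

`EEAPWS` hits the kojibiose-phosphorylase motif `EEAPxx` on all four of its
informative positions (`x` wildcards are excluded from the denominator).
Finally, simulate a triplicate initial-rate experiment at 3 % multiplicative
noise and fit it:

```r
dat <- generate_mm_data(K_M = 0.77, k_cat = 9.9, noise_cv = 0.03,
                        replicates = 3, seed = 42)
fit_michaelis_menten(dat)
#> <mm_fit> Michaelis-Menten fit
#>   KM   = 0.7329 mM (se 0.039)
#>   Vmax = 7.979 U/mg (se 0.11)
#>   kcat = 9.801 s^-1 (MW 73.7 kDa); kcat/KM = 13.37 mM^-1 s^-1
```

The recovered constants sit within one standard error of the generating
values (KM 0.77 mM, kcat 9.9 s⁻¹), and the efficiency rounds to
13 mM⁻¹ s⁻¹ at two significant figures. `tidy()`, `glance()` and
`autoplot()` methods are available for fitted objects, and
`run_pipeline()` chains every stage from a YAML config into a run manifest.

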