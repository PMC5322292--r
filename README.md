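# tina: interaction-adjusted indices of community similarity

Classical β-diversity indices (Jaccard, Bray–Curtis, Morisita–Horn, …)
treat taxa as independent: two samples that share no taxa are maximally
dissimilar, no matter how ecologically interchangeable their taxa are.
`tina` implements a family of indices that instead quantify community
similarity as the **average association strength between the taxa of two
samples**, read off a taxa interaction network:

- **TINA** (Taxa INteraction-Adjusted) uses a co-occurrence association
  network inferred from the count table itself (SparCC, Spearman,
  taxa-wise Bray–Curtis or taxa-wise weighted Jaccard);
- **PINA** (Phylogenetic INteraction-Adjusted) uses cophenetic
  similarities on a phylogenetic tree.

The package also provides the classical and phylogenetic indices the
family is benchmarked against (JCI, JCW, Chao's JCC, BC, MH, unweighted
and weighted UniFrac), the multivariate statistics used to evaluate them
(PERMANOVA, PCoA, distance–gradient rank correlations), and a
generalized Lotka–Volterra simulation toolkit for generating
habitat-structured benchmark communities with known ground-truth
interactions.

## The indices

Let `p_Ai = n_Ai / n_A` be relative abundances and `C` an association
matrix on [0, 1] obtained by correlating taxa by their association
profiles (rows of a raw interaction matrix `I`) and rescaling:

    C_ij = (1 + pearson(I_i*, I_j*)) / 2

so `C` scales from 0 (avoidance) through 0.5 (neutral) to 1 (complete
association). The unweighted index averages associations between the
`N_A` taxa observed in A and the `N_B` taxa observed in B:

    TU(A,B) = (1 / N_A N_B) Σ_{i∈A} Σ_{j∈B} C_ij

and the weighted index is the abundance-weighted association, scaled by
the geometric mean of the within-sample weighted associations:

    TW(A,B) = Σ_ij p_Ai p_Bj C_ij / sqrt( Σ_ij p_Ai p_Aj C_ij · Σ_ij p_Bi p_Bj C_ij )

`TW(A,A) = 1` exactly; for samples sharing no taxa both indices tend to
0.5 under neutral associations, to 0 under avoidance, and up to 1 under
complete association. PU/PW are the same formulas with the phylogenetic
association matrix Φ.

## Worked example

Simulate a 60-taxa, 30-sample two-habitat community with habitat
preference but neutral interactions, then ask each index how well it
separates the habitats:

```r
library(tina)

sc <- make_benchmark_scenario("habitat_only", n_taxa = 60, n_samples = 30, seed = 7)
sc$counts
#> Count table: 60 taxa x 30 samples, 148,853 individuals

run_benchmark(sc$counts, sc$labels,
              indices = c("jci", "bc", "mh", "tu", "tw"),
              network_method = "sparcc", n_perm = 999, seed = 7)
#>   index network            F        R2     p
#> 1   jci    <NA> 1.219698e+02 0.8132958 0.001
#> 2    bc    <NA> 1.691363e+02 0.8579663 0.001
#> 3    mh    <NA> 1.376214e+03 0.9800600 0.001
#> 4    tu  sparcc 3.033327e+02 0.9154928 0.001
#> 5    tw  sparcc 5.802618e+07 0.9999995 0.001
```

Every index detects the habitat split (p = 0.001 with 999 permutations),
but the pseudo-F for weighted TINA is orders of magnitude above the
count-based indices: habitat preference alone induces strong
co-occurrence structure, which the interaction-adjusted index reads
directly. Individual steps are available as separate functions:

```r
d <- distance_matrix(sc$counts, "bc")
permanova(d, sc$labels, n_perm = 999, seed = 1)
#> PERMANOVA (999 free permutations)
#>      term df     SS      F    R2     p
#>    groups  1 6.5542 169.14 0.858 0.001
#>  Residual 28 1.0850     NA 0.142    NA
#>     Total 29 7.6392     NA 1.000    NA
```

plus `infer_cooccurrence()` / `sparcc_correlations()` /
`transform_association()` for networks, `phylo_association()` for trees,
`pcoa()` and `gradient_correlation()` for ordination and gradient tests,
and `glv_simulate()`, `shuffle_counts()`, `rarefy()` and friends for
simulation. A thin command-line wrapper over these functions ships in
`inst/scripts/csim.R`.

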