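# mutpatterns

Sequence-context models of germline mutation rates by **IUPAC pattern
partition**, with a gene-level engine that turns a fitted rate model into
expected counts of functional mutation classes, burden p-values and
loss-of-function constraint scores.

## Who this is for

Statistical and population geneticists who want context-dependent mutation
rate models (point mutations *and* short indels) trained from observed de
novo mutations, and who need per-gene expectations calibrated well enough to
test for mutation burden in disease cohorts or to score selective
constraint.

## The method

Estimating one rate per k-mer breaks down for k ≥ 5: most contexts hold too
few mutations. Instead, the space of k-mers is partitioned by IUPAC
ambiguity patterns — each k-mer matched by exactly one pattern — and all
k-mers in a pattern share a rate. Given per-k-mer mutated/unmutated counts
(m_j, u_j), a partition {p_1, …, p_n} is scored by the penalized binomial
deviance

    loss = Σ_i [ −2( M_i log r_i + U_i log(1 − r_i) ) + c ],
    r_i  = (M_i + α) / (M_i + U_i + α/μ),

with M_i, U_i the pattern's summed counts, μ the class mean rate, c a
per-pattern complexity penalty and α a pseudo count shrinking rates toward
μ (at c = 2, α = 0 the loss is the binomial AIC). The optimal partition is
found by exact dynamic programming over all 15^k patterns via recursive
code two-partitions, or by a greedy heuristic for large k; α and c are
fitted by repeated 2-fold cross-validation with hypergeometric table
splits. Held-out fit is reported as Nagelkerke's pseudo r².

Indels get the same treatment through breakpoint context k-mers, with the
placement ambiguity of each event resolved by seeded random choice among
all equivalent breakpoints, and both strands covered by counting each
context with its reverse complement.

The gene engine enumerates every possible SNV in a transcript (plus indel
opportunities per breakpoint), classifies each as synonymous / missense /
nonsense / start loss / stop loss / essential splice / in-frame /
frameshift, rescales rates to per-generation units (genome-wide means
1.28e-8 for SNVs, 0.68e-9 for indels), applies the cohort-size scaling
r_scaled = 1 − (1 − r)^(2·n_gen), and tests observed counts against the
Poisson-binomial null by Monte Carlo. Constraint is reported as the LoF
observed/expected ratio and a conservative variant using the lower bound of
the 90% interval of the expected count.

## Worked example

Simulate a 300 kb genome whose C→T mutations follow a known 4-pattern truth
(NCG 0.02, TCH 0.008, VCT 0.004, VCM 0.001), count 3-mer contexts, pick
hyperparameters by cross-validation and fit the exact partition:

```r
library(mutpatterns)

sim  <- simulate_genome(3e5, gc_content = 0.41, seed = 42)
muts <- simulate_mutations(sim$genome, sim$mask, default_snv_truth(), seed = 42)
tabs <- count_snv_kmers(muts, sim$genome, sim$mask, k = 3)

cv  <- grid_search(tabs$`C>T`,
                   cv_config(alpha_grid = c(0.5, 2, 10),
                             c_grid = c(1, 10, 100), n_repeats = 5, seed = 42))
fit <- optimal_partition(tabs$`C>T`, cv$selected$alpha, cv$selected$c_penalty)
tidy(fit)
#> # A tibble: 4 × 5
#>   pattern mutated background    rate rel_rate
#>   <chr>     <dbl>      <dbl>   <dbl>    <dbl>
#> 1 NMG         508      24934 0.0198     2.81
#> 2 TMH         207      28700 0.00716    1.01
#> 3 VMT         112      25450 0.00441    0.624
#> 4 VMM          43      43152 0.00104    0.146
```

The fit recovers the true four patterns (the central M code is the
strand-collapsed {A,C}; only the C half carries counts here) with rates
close to truth. `glance(fit)` summarizes the model; `autoplot(fit)` draws
the pattern rates relative to the mean. Held-out evaluation:

```r
folds <- split_table(tabs$`C>T`, seed = 7)
m <- optimal_partition(folds[[1]], cv$selected$alpha, cv$selected$c_penalty)
evaluate_models(list(`C>T` = m), list(`C>T` = folds[[2]]))
#> # A tibble: 2 × 5
#>   mut_class    l_M    l_0     n     r2
#>   <chr>      <dbl>  <dbl> <dbl>  <dbl>
#> 1 C>T       -2397. -2588. 61553 0.0768
#> 2 joint     -2397. -2588. 61553 0.0768
```

A pseudo r² of 0.077 on 61 553 held-out sites: context explains a real but
bounded share of where mutations land, as expected for an intrinsically
stochastic process. From a fitted model set, `scale_snv_models()`,
`transcript_site_table()`, `gene_burden_test()` and `constraint_scores()`
take over for per-gene analyses (see the vignette). A command-line front
end over the same functions is installed at `inst/scripts/mutpatterns`.

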