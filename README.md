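# stt — spatial transition tensors for multistable single-cell dynamics

Single-cell RNA velocity, as usually practiced, assumes every gene relaxes
toward one global splicing equilibrium. Developing and transitioning tissues
do not look like that: cell populations sit in several coexisting attractors
(stable cell states) and individual cells hop between their basins. `stt`
is for analysts with joint unspliced/spliced count matrices — from standard
scRNA-seq or from spatial transcriptomics with per-spot coordinates — who
want attractor-aware dynamics: which states exist, which genes support the
multistability, which cells are committed versus transitional, and along
which paths transitions flow.

## The model in brief

For each gene, kinetics near attractor `c` follow

    dU/dt = alpha_c − beta U,     dS/dt = beta U − gamma S,   gamma ≡ 1,

with a state-dependent transcription rate `alpha_c` and shared splicing rate
`beta`. Given fuzzy attractor memberships `rho` (cells × K, rows on the
simplex), the regularized weighted least-squares loss has a closed-form
minimizer (`estimate_params()`), yielding a 4-D **transition tensor**
`v[cell, {u,s}, attractor, gene]`. The membership-averaged tensor drives an
inner-product **velocity kernel** `exp(V_u·ΔU + V_s·ΔS)`, mixed with an
expression-similarity kernel and (when coordinates exist) a spatial kernel
into one row-stochastic cellular random walk

    P = w1 P^v + w2 P^c + (1 − w1 − w2) P^s .

**GPCCA** (generalized Perron cluster cluster analysis) fuzzily coarse-grains
P into K attractors, returning memberships, per-cell transitional entropy
`−Σ rho ln rho`, and a K×K coarse chain. Kinetics and memberships are
refined alternately with per-gene **multistability scores**
`1 − J/(N_C(Var U + Var S))` filtering genes on a held-out fold, until the
memberships stop moving. Downstream: transition path theory (committors,
reactive flux, ranked paths) on the coarse chain, a Gaussian-mixture
dynamical manifold `phi(y) = −ln P(y)`, cosine-kernel streamline projection,
and pathway-level tensor-similarity clustering from GMT gene sets. Two
stochastic benchmark circuits ship with the package: a bistable toggle
switch and a seven-gene EMT cascade whose signal sweep passes through a
tristable epithelial/intermediate/mesenchymal window.

See the methods vignette (`vignettes/transition-tensor-methods.Rmd`) for
formulas, defaults and design rationale.

## Worked example

```r
library(stt)

sim <- simulate_toggle_switch(n_cells = 2000, seed = 1)
round(sim$fixed_points, 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 2.097 0.198 2.097 0.198
#> [2,] 0.198 2.097 0.198 2.097

fit <- stt_fit(sim$dataset, seed = 1)
fit
#> <stt_fit> 2000 cells, K = 2 attractors, 2/2 genes selected
#>   4 rounds, delta = 6.66e-04, converged

tidy(fit$params)
#> # A tibble: 2 × 4
#>   gene    beta alpha_1 alpha_2
#>   <chr>  <dbl>   <dbl>   <dbl>
#> 1 gene_x 0.961   1.96    0.233
#> 2 gene_y 0.967   0.243   1.99

fit$chain
#> <stt_chain> 2 attractors
#>        [,1]   [,2]
#> [1,] 0.9996 0.0004
#> [2,] 0.0004 0.9996

transition_paths(fit$chain, source = 1, target = 2)
#> <stt_tpt> 1 -> 2, rate 0.0002004
#>   path 1 -> 2  fraction 1.000
```

Reading the numbers: the two rows of `fixed_points` are the circuit's
stable states (each gene dominant in one). The fit recovers the splicing
rates (`beta ≈ 0.96` against a true value of 1, the residual bias coming
from snapshot noise) and attractor-specific transcription rates
(`alpha ≈ 2` where the gene is active, `≈ 0.2` basal elsewhere, matching
the simulated Hill kinetics). The coarse-grained chain is strongly
metastable — per-step hop probability ~4e-4 — and all transition flux from
attractor 1 to 2 flows along the single direct path. Per-cell results
(`tidy(fit)`) carry memberships, entropy and hard assignments; cells near
the saddle show entropy near `ln 2`.

On the EMT benchmark, `simulate_emt_circuit()` pools seven TGFB-like signal
levels; fitting with K = 3 and running `transition_paths()` between the
epithelial-like and mesenchymal-like attractors routes the dominant path
through the intermediate state.

A command-line wrapper is included:

```sh
Rscript inst/cli/stt.R simulate --circuit toggle --n-cells 2000 --seed 1 --out toggle.h5
Rscript inst/cli/stt.R fit --in toggle.h5 --out run --seed 1
Rscript inst/cli/stt.R dynamics --in toggle.h5 --out run --seed 1
```

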