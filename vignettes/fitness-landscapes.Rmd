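---
title: "Combinatorial fitness landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial fitness landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscape)
```

# The scientific setting

`fitscape` analyses combinatorial active-site mutagenesis experiments of the
kind used to study how an enzyme acquires a new activity: a handful of
active-site residues are randomised simultaneously with degenerate codons,
variants are selected for the new activity (here, detoxification of an
antibiotic by a bacterial nitroreductase expressed in its native host), and
every possible intermediate between wild type and a top selected variant is
then synthesised and measured. The resulting data form a *combinatorial
fitness landscape*: a map from each subset of the variant's `n` substitutions
to a fitness proxy, the fold-improvement in EC50 (the drug concentration
producing half-maximal growth inhibition) over wild type.

The package covers the five computational stages of such a study, plus a
synthetic-data generator that stands in for the raw measurements so that
every analysis is testable end to end.

# Degenerate library statistics

A degenerate codon such as NDT is the Cartesian product of IUPAC ambiguity
sets (N = ACGT, D = AGT, T), and its amino-acid repertoire follows from
translating the expansion: NDT encodes 12 amino acids once each, NHT another
12, and VNG 11 (with arginine encoded by two codons). Library diversity is
the product of per-site counts: six NDT sites, one NHT and one VNG give
`12^8 = 429,981,696` gene variants and `12^7 x 11 = 394,149,888` proteins.

**Expected coverage.** Given `L` transformants sampled independently from
the library, the expected number of distinct protein variants is
`sum_j k_j (1 - (1 - p_j)^L)`, where variants are grouped into classes of
equal sampling probability `p_j` (the product of per-site codon
multiplicities over the product of per-site expansion sizes) with `k_j`
variants per class. Grouping by multiplicity keeps the sum to a handful of
terms even at 10^8-scale diversity. A Poisson approximation
(`1 - exp(-L p_j)`) is provided and agrees with the exact sum to well under
0.1% at library scale; the exact grouped-binomial form is the default. Both
are evaluated with `log1p`/`expm1` so that probabilities of order 1e-9 do
not lose precision. For the eight-codon design at 398 million transformants
the exact form gives about 246.5 million distinct proteins; published
coverage estimates from proprietary calculators can differ by a few percent,
and no attempt is made to match them beyond reporting the computed value.

# Landscape representation

Substitutions are written `wt + position + mut` (`"S41Y"`), genotypes as
`"+"`-joined substitution sets sorted by ascending position, with `"WT"` for
the empty set. Internally a genotype is a bitmask over the landscape's
ordered substitution list, making subset-lattice operations O(1) per lookup.
The wild type anchors the fold scale at exactly 1: raw EC50 replicate tables
are converted on ingest by pairing each measurement with the wild-type
control of its batch (per-batch ratios, then averaged), which is why the
wild-type row carries no residual error of its own. Incomplete landscapes
are rejected by lattice operations (trajectory counting, greedy paths,
networks) rather than silently skipped, because a missing genotype corrupts
path counts.

# Trajectory accessibility

A trajectory is one of the `n!` orders in which the substitutions can be
acquired one at a time. A step is *improving* when the fold-improvement
rises by strictly more than a relative threshold, 16% by default — the
average relative error of the EC50 measurements, so that gains within
measurement error do not count. The threshold applies to mean folds only;
measurement error is not re-entered at this stage because the threshold
already encodes it. A trajectory is *accessible* when all `n` steps improve.

Counting accessible trajectories does not require visiting all `n!`
orderings: the count equals the number of monotone improving paths through
the subset lattice, computed by a dynamic program over the `2^n` subsets in
O(n 2^n). The permutation iterator (lexicographic, constant memory) is
retained both as the user-facing enumeration contract and as the brute-force
oracle that the dynamic program is tested against for n <= 5. Accessible
orderings are only materialised on request.

**Greedy most-plausible path.** At each step the remaining substitution
yielding the highest resulting-genotype fitness is chosen. This single
argmax rule covers both regimes of interest — take the biggest improvement
when one exists, otherwise the smallest decrease — and ties are broken by
lowest residue position for determinism. Exact-threshold steps and ties are
declared conventions, not inferred ones: strict inequality at the threshold,
lowest-position tie-break.

**Mutation networks.** The Hasse diagram of the subset lattice (2^n nodes,
`n 2^(n-1)` edges, substitution gains only — reversions are out of scope) is
exported via igraph to GraphML or DOT, or to a flat edge CSV
(`from,to,delta,improving,on_greedy_path`) that round-trips through
`import_edge_csv()`. Node attributes carry the substitution-count layer and
the fold-improvement for styling; drawing is left to graph tools.

# Epistasis statistics

The multiplicative null for a genotype with single-substitution folds
`X_1..X_k` is `R = prod(X_i)` with propagated error
`dR = R sqrt(sum((dX_i/X_i)^2))` — the k-term generalisation of the
three-variable product rule. The wild-type error is deliberately not added
as an extra term: every fold is already a ratio to wild type, and the
three-term form is followed literally. Deviation is scored on the natural
log scale, `epsilon = ln(observed/R)`, which is symmetric in over- and
under-performance and additive across interactions.

Pairwise classification uses the standard definitions: *magnitude* epistasis
when `|epsilon|` exceeds a tolerance but no effect changes direction; *sign*
epistasis when exactly one substitution's effect reverses between
backgrounds; *reciprocal sign* when both do. The tolerance separating
"none" from epistasis defaults to `|epsilon| <= 0.05`; the underlying
studies classify qualitatively, so a numeric tolerance had to be declared
here, and 0.05 (a 5% deviation on the fold scale) sits well below the 16%
measurement error.

Group comparisons use an unpaired two-sample t-test computed from summary
statistics (mean, SD, n), pooled-variance Student by default with Welch
available, since landscapes store summaries rather than raw replicates; it
is verified against `stats::t.test` on raw data to 1e-10. Star labels use
`<=` thresholds at 0.05/0.01/0.001. No multiple-testing correction is
applied, matching the analysis style the package reproduces.

# Dose-response fitting

Percent growth inhibition is `100 (1 - dOD_challenged / dOD_control)` with
`dOD` the OD600 increase over the 4 h challenge; a non-growing control is an
assay failure and is rejected. EC50s come from the four-parameter variable
slope model in log10 concentration,
`y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 x) hill))`,
fitted by Levenberg–Marquardt least squares with a deterministic
initialisation (top = max response, bottom = min response, hill = 1, logEC50
at the concentration nearest the half-height). Parameters are unconstrained
by default, with optional physical bounds `bottom >= 0`, `top <= 100` for
percent-inhibition data. Non-convergence and EC50s outside the tested
concentration range are flagged on the fit object, never silently returned.
Technical-replicate EC50s are averaged within each biological replicate
first; the biological replicates then give the final mean, SD and n.

A point worth knowing when designing assays: with a shallow curve
(hill near 1) a 1.5-fold dilution series never reaches either plateau, and
the unconstrained four-parameter fit then leaves the EC50 only weakly
identified (linearised analysis gives a relative EC50 SD above 10% even at
5% response noise). Steeper curves — typical of growth-collapse endpoints —
or the physical 0–100 bounds restore identifiability; this is why the
synthetic generator's default hill slope is 2.

# The synthetic-data generator

`simulate_landscape()` draws replicate fold measurements from a known ground
truth: `log fold = sum(expressed single effects) + sum(active interaction
terms)`, where an optional *gating* substitution scales all other single
effects by a masking factor while absent (masking 0 = full gating, 1 = plain
multiplicativity), and interaction terms activate when all their member
substitutions are present (pairs or higher order). Replicate noise is
lognormal and mean-preserving, so folds stay positive, the expected
replicate mean equals the true fold, and the coefficient of variation equals
the specified CV exactly. Seeds are explicit arguments and the caller's RNG
state is restored.

The default specification mirrors the study conditions the package is
aimed at: seven substitutions (128 genotypes), single fold effects
1.9, 0.9, 1.4, 0.85, 1.2, 2.9 and 1.3 so that the full variant sits near
9-fold improvement and measured folds span roughly 0.25–11; the 2.9-fold
substitution at position 225 is the gate (masking 0.15), reproducing the
observation that variants retaining the native residue average ~1.0-fold
while those substituting it average ~4-fold; a compensated interaction
(H215C+K222V at 0.3x, restored when S224R joins) injects sign-epistatic
valleys; 4 replicates per genotype at CV 0.16, the stated average EC50
error. With these defaults no ordering has all seven steps improving —
matching the finding that no exclusively-upward path to the top variants
exists — while relaxing the deleterious tail effects immediately opens
gate-first paths.

What the generator deliberately does *not* emulate: batch-to-batch drift of
the wild-type control (folds are drawn directly), non-lognormal outliers,
plate position effects, and genotype-dependent measurement error. Passing
recovery tests on synthetic data therefore demonstrates correctness of the
estimators under the declared noise model, not robustness to every artefact
of real plate data.

# Numerical conventions and problem sizes

* Trajectory enumeration is guarded at n <= 12 (factorial growth); the
  materialising convenience wrapper at n <= 8; landscape bitmasks at n <= 20.
* Coverage sums use `log1p`/`expm1`; accessible-path counts are exact
  doubles (max 12! ~ 4.8e8, well within integer-exact range).
* Property-style tests run at deliberately modest sizes chosen to exercise
  the mathematics, not the hardware: brute-force trajectory oracles at
  n <= 5, Monte-Carlo coverage oracles at V = 44 with 10^4 replicates,
  error-propagation resampling at 10^5 draws, EC50 recovery over 100–200
  seeds, and CV calibration at 10^4 replicates.

# Known limitations

* Landscapes carry at most one alternative residue per position; the
  nucleotide level (and hence codon accessibility of each amino-acid
  substitution) is out of scope.
* Trajectory analysis is combinatorial, not population-genetic: no fixation
  probabilities, clonal interference or reversions.
* The completeness estimate assumes independent uniform sampling of
  transformants; real libraries carry synthesis and cloning bias, which is
  one reason observed coverage can deviate by a few percent from any
  closed-form estimate.
* Higher-order epistasis is injected and recovered term by term; no global
  decomposition (Walsh/Fourier) is provided.
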