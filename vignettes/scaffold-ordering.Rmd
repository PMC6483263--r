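---
title: "Ordering genomic scaffolds from low-coverage mapping populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering genomic scaffolds from low-coverage mapping populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scafmap builds pseudo-chromosomes from genetic segregation data: it orders
and orients genomic scaffolds along chromosomes by maximizing the likelihood
of low-coverage genotyping data from an experimental mapping population (F2,
F3 or recombinant inbred lines), and compares maps across crosses to detect
structural variation such as inversions. This vignette is the package's
account of the model, its assumptions, the tunable parameters, and the
numerical choices behind the implementation.

## The data and the marker model

The input is a sparse table of per-individual read counts at
parent-diagnostic SNPs: reads matching parent A versus parent B, keyed by
scaffold and position. Such data come from reduced-representation sequencing
(RAD-seq / multiplexed shotgun genotyping), where each individual is
sequenced at a large number of tag sites but at very low depth — often one
or two reads per tag.

Because single low-depth SNP calls are unreliable, markers are *windows*:
all diagnostic reads falling in a 100 kb span of a scaffold are aggregated
(`define_windows()`, `build_call_matrix()`). The terminal sub-window
remainder of each scaffold forms its own marker, so the windows partition
`[0, L)` exactly; a `merge_remainder_below` option merges tiny remainders
into the previous window instead, since a 2 kb remainder marker is almost
always `NN` and harmless either way. The window call is a hard-threshold
rule (`call_window()`): with fewer than `min_depth = 6` reads the call is
`NN` (no call); otherwise the fraction of A reads decides — strictly above
0.95 gives `AA`, strictly below 0.05 gives `BB`, inside the closed band
[0.25, 0.75] gives `AB`, and anything between the bands falls to `NN`. The
strict/inclusive reading of the boundaries is the conservative choice: a
19:1 window (fraction exactly 0.95) is a no-call rather than a homozygote.
Window-level ambiguity has two main causes — mis-mapped reads and true
crossovers inside the window — and scoring both as `NN` is appropriate
because the hidden Markov model recovers the genotype from flanking markers.

SNP-level filters (`filter_snps()`) run before aggregation: each parental
allele must be seen in at least 5 carriers and 2.5% of scored individuals,
and a SNP whose per-individual allele-ratio categories disagree with the
rest of its window in more than half of informative individuals is dropped.
The neighbor-consistency statistic is a reconstruction (the original
pipeline's exact SNP filters are not published in the main text), so both
filters are configurable and report what they removed. A per-marker
chi-square against the design's expected genotype frequencies
(`flag_marker_distortion()`, default alpha `1e-6`) flags distorted markers
without dropping them.

## The hidden Markov model

For one individual, the hidden chain is the true genotype (AA, AB, BB) along
the marker sequence induced by a candidate map; the observed states are the
putative window calls. The chain is non-homogeneous: the transition between
adjacent markers depends on the recombination fraction `r` of that specific
interval. For an F2, the transition matrix is the product of two independent
gametes (`transition_matrix()`): from AA the probabilities are
`((1-r)^2, 2r(1-r), r^2)`, from AB they are
`(r(1-r), (1-r)^2 + r^2, r(1-r))`. F3 and RIL matrices are computed exactly
by propagating the ten two-locus diplotype states through the required
number of selfing meioses and conditioning on the first-locus genotype; the
one-generation special case reproduces the closed-form F2 matrix, and all
three designs are validated against brute-force meiosis simulation in the
test suite. RIL designs use a finite number of selfing generations (default
8) counted from the F1, so residual heterozygosity `0.5^g` is retained
rather than forced to zero; `r` is always the per-meiosis recombination
fraction, and map lengths are reported as the sum of Haldane-transformed `r`
values in cM so that comparisons across designs are explicit.

Emissions carry per-individual genotyping error rates: a true homozygote is
called heterozygous with probability `e0` and as the opposite homozygote
with probability `e1` (errors to either alternative homozygote are taken as
equally likely), and a true heterozygote is called homozygous with total
probability `e2`, split equally. `NN` has emission probability 1 under every
hidden state — missingness is already encoded upstream and needs no separate
rate. Likelihoods use a scaled (not log-space) forward recursion with
per-step normalization, numerically safe for chromosomes with tens of
thousands of markers; posteriors come from the scaled forward × backward
product.

## Staged estimation

Estimation is deliberately staged rather than joint:

1. **Error rates** (`estimate_error_rates()`): per individual, `(e0, e1, e2)`
   are estimated by maximizing the product of chain likelihoods over that
   individual's scaffolds with recombination fixed proportional to physical
   distance — 5.0 cM/Mb for F2 populations, 10.0 cM/Mb for F3/RIL, applied
   to midpoint-to-midpoint distances (the same midpoint convention as the
   interval-rate extraction; whether the original used midpoints or edges is
   unstated, and the difference for 100 kb windows is negligible). The
   optimizer is bounded L-BFGS-B inside `[1e-6, 0.2]` with three restarts;
   box bounds were preferred over a logit transform because boundary
   solutions then land exactly on the bound and can be flagged as such. The
   floor avoids `log(0)`, the ceiling prevents the label-swap degeneracy in
   which errors masquerade as genotype flips. One identifiability subtlety:
   an individual with no heterozygous calls leaves `e2` essentially
   unidentified — the likelihood is flat except for a sliver gained by
   re-explaining a terminal marker as a miscall — so a rate is kept above
   the floor only when it improves that individual's log-likelihood by more
   than 0.01 units, a likelihood-ratio support rule that resolves the flat
   directions to the parsimonious floor. Individuals with no
   informative calls are flagged for culling (`cull_individuals()`).

2. **Intra-scaffold rates** (`estimate_intra_rates()`): with error rates
   fixed, the likelihood of each scaffold is maximized over the `r` values
   between its adjacent markers, summed across individuals. An intra rate
   far above the genomic average over a single window length (default
   threshold 0.2, roughly 400 times a 5 cM/Mb average) indicates a
   mis-assembled scaffold spanning a structural breakpoint;
   `flag_split_candidates()` / `split_scaffolds()` cut such scaffolds into
   independent pieces that re-enter the pipeline.

3. **Map search** (`order_scaffolds()`): a genetic algorithm over scaffold
   orders and orientations. The fitness of a candidate map is its chain
   log-likelihood after optimizing only the `L - 1` junction rates, with the
   `K` intra-scaffold rates held at stage-2 estimates. A bad join cannot be
   hidden: the junction MLE rises toward 0.5 and the likelihood pays for it.

4. **Final fit** (`finalize_map()`): all `L - 1 + K` rates are re-estimated
   jointly for the chosen order and genotype posteriors are emitted.
   Posterior hard calls (`hard_calls()`) assign the genotype whose posterior
   strictly exceeds 0.95, otherwise missing.

All rate optimizations use cyclic coordinate-wise Brent ascent rather than a
full quasi-Newton step: each `r` enters exactly one chain step, so with the
forward variables advanced under already-updated left-hand rates and
backward variables computed under current right-hand rates, each
one-dimensional step maximizes the true profile likelihood and the sweep is
monotone. Sweeps repeat (at least two, at most eight) until a full cycle
improves the log-likelihood by less than `1e-4`. Each rate is confined to
`[1e-6, 0.5]`; interior Brent optima are compared against both endpoints so
perfect linkage lands exactly on the floor.

For the genetic algorithm, fitness evaluations use an algebraically
identical but much faster representation: with intra rates and emissions
fixed, each oriented scaffold collapses into one 3×3 transfer operator per
individual (the product of its transition and emission matrices, with a
stored log scale factor), so a candidate map is a chain over `L` scaffold
nodes instead of `M` markers. The equality of the two routes is asserted in
the tests at `1e-10`.

## The genetic algorithm

Maps are coded as permutations of scaffolds with orientations. Each
generation the best `E = 4` maps pass unchanged (elitism, which makes the
best-fitness trace provably non-decreasing); the remaining slots are filled
by children of rank-selected parent pairs (selection weight linear in
fitness rank). Children are built by order crossover — a contiguous block of
one parent kept in place, the rest following the other parent's relative
order — and mutated by orientation flips, segment reversal-with-flip (an
in-map inversion, an involution), single-scaffold relocation, and pairwise
swaps. The operator set and the population defaults (N = 48, at most 200
generations, stop after 20 generations without a 1e-3 improvement) are this
package's own choices, sized for desk-scale convergence; only elitism with
E = 4 and rank selection are taken as fixed conventions. Fitness values are
memoized on a canonical signature shared by a map and its full reversal
(the chain likelihood is reversal-invariant, which the tests assert at
1e-8), and ties between equal-likelihood maps are broken by the
lexicographically smallest signature so a given seed yields one defined
answer. After stagnation, a greedy first-improvement local search (flips,
adjacent swaps, reversals of up to four scaffolds, short-range relocations)
polishes the best map; this memetic step is cheap under the evaluation cache
and substantially improves the chance of reaching the global optimum when
the search starts from a completely random scramble rather than a
nearly-correct draft order.

Two degeneracies are expected and tolerated rather than fought: the
orientation of a single-marker scaffold is unidentifiable (its emission
sequence is unchanged by flipping), and scaffolds inside a
non-recombining region can be permuted without changing the likelihood when
no individual recombines there. In both cases the search returns *a* map of
maximal likelihood; equality of likelihood, not equality of order, is the
meaningful statement.

## Comparing maps across crosses

`delta_loglik()` imposes one cross's optimized map on another cross's data
and re-estimates **all** rates under the imposed order, so the resulting
ΔlnLk reflects order and orientation alone, never rate differences. A
ΔlnLk of 77.1 corresponds to a likelihood ratio of order 10^33.
`pairwise_delta()` assembles the ordered-pair matrix and per-chromosome
sums (a flag collapses to unordered pairs, since either reading of "summed
pairwise" is defensible). Scaffolds present in only one map are dropped
pairwise with a warning; below 50% overlap the comparison is refused.
Self-imposition returns ΔlnLk = 0 (tested at 1e-6), and a home map
materially worse than an imposed one flags under-convergence of the search
rather than being silently accepted.

Two structural-variant screens build on this. `detect_suppression()` scans
a reference marker ordering for spans of at least 10 markers whose summed
genetic length is under 1 cM in one cross while exceeding 5 cM in another —
the signature of a segregating inversion suppressing recombination in
heterokaryotypic crosses. `detect_reversal()` finds contiguous blocks whose
scaffold order is reversed and orientations flipped between two maps, the
expected pattern between crosses homokaryotypic for opposite arrangements;
both maps are canonicalized first so a whole-map reversal (which is
map-equivalent) is never reported. `end_matching` of scaffolds into linkage
groups (`assign_linkage_groups()`) uses two-point recombination estimates
between scaffold-end markers, joining ends with `r < 0.2`, LOD > 6 and at
least 20 jointly scored individuals — a documented reconstruction, as the
original end-matching criteria are not published.

`extract_interval_rates()` converts a final map into per-marker local
recombination rates over the midpoint-to-midpoint interval around each
interior marker (200 kb for standard windows); scaffold-end markers and
junction gaps are excluded because the interceding DNA is unknown, and an
exclusion mask lets the caller drop inversion-suppressed regions.
`weighted_mean_rates()` standardizes each cross's interval rates by its
total map length and combines crosses by reciprocal-variance weights
(weights are accepted as inputs; `default_cross_weights()` ships the
five-cross worked-example values).

## The simulator and what it does (not) emulate

`simulate_mapping_experiment()` wires together the generator primitives into
a complete benchmark with known truth: tags placed as a hard-core renewal
process (at most one per kb, expected density as configured), a smooth
recombination map with a Gaussian pericentromeric dip, gametes formed by
no-interference (Poisson) crossovers so that recombinant fractions follow
the Haldane map function, optional achiasmatic male meiosis (the paternal F2
gamete carries a single parental haplotype), negative-binomial read depth
per tag with binomial — or beta-binomial, to emulate heterozygote allele
dropout — allele sampling, random fracturing of the chromosome into
scaffolds at inter-tag midpoints, and a uniformly scrambled input map.

The default study conditions are one ~20 Mb chromosome at 0.25 tags/kb, a
1 Morgan female map with a 90% pericentromeric dip, 200 F2 individuals with
achiasmatic fathers, mean depth 2 with dispersion 1, per-read error 0.005,
and 30 random breaks (31 scaffolds). These sizes keep a full pipeline run in
minutes on one core while preserving the qualitative regime of real MSG
experiments: roughly one detectable crossover per individual per
chromosome, window depths of tens of reads, and a low-recombination interior
where scaffold order is only weakly identifiable.

Two caveats about what passing tests show. First, the simulator draws reads
at diagnostic sites directly — there is no sequence, no alignment, no
mis-mapping; real data add error modes (reference bias, paralogy) that
enter here only through the error-rate parameters. Second, with achiasmatic
males the true genotype process is a mixture over the constant paternal
allele and is not Markov, so the F2 HMM is knowingly misspecified for these
data — exactly as in the original benchmark design. A consequence worth
stating plainly: at finite sample size the maximum-likelihood map under the
misspecified model can score slightly *above* the true order, so the
meaningful success criterion is that the search reaches at least the true
map's likelihood, not that it stops exactly there.

## Numerical choices and limitations

* Coordinates are 0-based, half-open throughout.
* Error-rate bounds `[1e-6, 0.2]`; rate bounds `[1e-6, 0.5]`; Brent
  tolerance `1e-5` on `r`; coordinate-ascent stopping tolerance `1e-4`
  lnLk; GA progress tolerance `1e-3` lnLk.
* Randomness flows from a single `set.seed()` stream consumed in a fixed
  order (R has no splittable generator in base), which still gives
  byte-identical outputs for identical seed and configuration.
* Designs are limited to F2/F3/selfing-RIL; outbred pedigrees and
  sex-specific maps are out of scope. Non-recombining regions cannot be
  ordered by any segregation-based method; the likelihood says so honestly
  (equal-likelihood alternatives) rather than pretending to resolve them.
* QTL interval mapping itself is not implemented; `hard_calls()` produces
  the genotype matrix such a package consumes.

## A worked micro-example

```{r, eval = FALSE}
library(scafmap)

sim <- simulate_mapping_experiment(seed = 1, n_individuals = 100,
                                   chrom_length_bp = 5e6, n_breaks = 9)
design <- cross_design("F2")
windows <- define_windows(sim$scaffold_lengths)
calls  <- build_call_matrix(sim$counts, windows)
errors <- estimate_error_rates(calls, design)
intra  <- estimate_intra_rates(calls, errors, design)

search <- order_scaffolds(sim$input_map, calls, errors, design, intra,
                          seed = 2)
final  <- finalize_map(search$best_map, calls, errors, design, intra)

glance(final)
tidy(final)
autoplot(search)            # monotone lnLk ascent
plot_map_comparison(final, fit_map(sim$true_map, calls, errors, design, intra))
```

The test suite (`tests/testthat/`) carries the quantitative claims: oracle
equivalence of the forward-backward likelihood against exhaustive path
enumeration, transition matrices against brute-force meiosis simulation,
parameter recovery for error rates and recombination fractions, the
symmetry and elitism invariants, and the structural-variant screens'
detection and false-positive rates.
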