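---
title: "Mutation accumulation in birth-death processes: model, theory and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation accumulation in birth-death processes: model, theory and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutburden)
```

## The model

`mutburden` simulates and analyses neutral mutation accumulation in a growing
clonal population — the baseline dynamics against which tumour sequencing
data are commonly interpreted. Time is discrete: at step $i$ one uniformly
chosen cell divides with probability $\beta$ or dies with probability
$\delta = 1-\beta$, so the population size $N_i$ performs a random walk on
$\{0, 1, 2, \dots\}$ with an absorbing state at 0. Only the growing case
$\beta > \delta$ is supported. The process is equivalently a growing rooted
binary tree: the root is a single mutation-free progenitor, leaves are
living cells, and a death prunes a leaf.

When a cell divides, each daughter inherits all parental mutations and
acquires $U_1, U_2 \sim \mathrm{Pois}(\mu)$ new ones, independent between
daughters, under the infinite-sites approximation (every new mutation is
globally unique). The mutation model is pluggable — degenerate, geometric
and arbitrary finite-table models with the same mean are available — which
matters for the robustness question discussed at the end.

All expectations in the package are conditioned on survival of the whole
population, implemented by rejection: a realisation that hits $N = 0$ before
its stopping rule fires is discarded and restarted with fresh randomness,
and the number of discarded attempts is reported. For a supercritical
process started from one cell the extinction probability is $\delta/\beta$,
which the discard fraction estimates directly.

Three single-population summary statistics are maintained, all derived from
the dynamical genotype matrix $Y_i$ (cells in rows, mutations in columns,
binary incidence; `genotype_matrix()`):

* the **site frequency spectrum** $\{S_{j,i}\}$ — the number of mutations
  carried by exactly $j$ living cells (per-mutation abundances);
* the **division distribution** $\{D_{\ell,i}\}$ — the number of living
  cells whose lineage contains exactly $\ell$ divisions (leaf depths);
* the **mutational burden distribution** $\{B_{k,i}\}$ — the number of
  living cells carrying exactly $k$ mutations.

The MBD and DD partition the population size and the SFS partitions the
number of unique mutations $M_i$, and every realisation obeys the exact
occurrence identity $\sum_j j S_{j,i} = \sum_k k B_{k,i}$ (the number of
1-entries of $Y_i$), which `mutational_occurrences()` verifies on every
call. Columns of $Y_i$ are grouped into *division blocks*: all mutations one
daughter acquired in one division share a block (and hence one incidence
pattern); a division that contributed no mutations still owns a placeholder
all-zero column, so the block registry records the full division history and
row sums of the block-membership matrix reproduce the DD.

## Expected distributions

**Pure birth ($\delta = 0$).** Here $N_i = i + 1$ deterministically, and the
law of total expectation yields recurrences solved exactly by closed forms:

* SFS: $\mathbb{E}[S_{j,i}] = \dfrac{2\mu (i+1)}{j (j+1)}$, exact for
  $j \le i$. For $j > i$ the true expectation is zero while the closed form
  is positive, so `sfs_recurrence()` (the forward iteration) is treated as
  authoritative there and the closed form as an asymptotic tail.
* DD: $\mathbb{E}[D_{\ell,i}] = \genfrac[]{0pt}{}{i}{\ell} 2^\ell / i!$,
  with $\genfrac[]{0pt}{}{i}{\ell}$ the unsigned Stirling numbers of the
  first kind — the classical leaf-depth law of the Yule process /
  random binary increasing trees.
* MBD: a cell with $\ell$ divisions carries a $\mathrm{Pois}(\ell\mu)$
  burden, so
  $\mathbb{E}[B_{k,i}] = \sum_\ell \genfrac[]{0pt}{}{i}{\ell}
  \frac{2^\ell}{i!} e^{-\ell\mu} \frac{(\ell\mu)^k}{k!}$ — the Poisson
  mixture of the expected DD (`expected_mbd_pure_birth()`, built on
  `dd_to_mbd()`).
* The mean burden is a rescaled harmonic number,
  $\mu \cdot 2 (H_{i+1} - 1)$: logarithmic growth in the step count.

**With death ($0 < \delta < \beta$).** $N_i$ is random, and ratios such as
$\mathbb{E}[S_{j,i}/N_i]$ are expanded to first order,
$\mathbb{E}[A/B] \simeq \mathbb{E}[A]/\mathbb{E}[B]$, valid in the low-death
and large-population limits. This gives

* SFS: $\mathbb{E}[S_{j,i}] \simeq \sum_{j'\ge 0}
  \frac{2\mu\,(\delta/\beta)^{j'}}{(j+j')(j+j'+1)} \,\mathbb{E}[N_i]$,
  a geometric series truncated when a term drops below a relative tolerance
  (default $10^{-12}$; the ratio $\delta/\beta < 1$ guarantees convergence);
* DD: $\mathbb{E}[D_{\ell,i}] \simeq \dfrac{f(i,\ell)}{\sum_{\ell'}
  f(i,\ell')}\, \mathbb{E}[N_i]$ with
  $f(i,\ell) = \genfrac[]{0pt}{}{i}{\ell}\, 2^\ell (1-\delta/\beta)^{-\ell}$,
  normalised by log-sum-exp so the fractions sum to one by construction.

Both reduce termwise to the pure-birth forms at $\delta = 0$. The factor
$\mathbb{E}[N_i]$ defaults to the numerically exact survival-conditioned
value: `expected_popsize_conditioned()` forward-propagates the finite-state
chain with an absorbing 0 state and renormalises over the non-absorbed mass.
The linear approximation $(\beta-\delta) i + 1$ is returned alongside
(accurate for low death; at $\beta = 2/3$ it undershoots the conditioned
value by a few percent at moderate $i$). When an ensemble is stopped at a
fixed final size $N$, that known $N$ should be passed as `popsize` instead —
that is how the package reproduces fixed-size experiments.

## Numerical choices

* **Stirling numbers.** Magnitudes reach $i!$, so
  $\genfrac[]{0pt}{}{i}{\ell} 2^\ell/i!$ overflows/underflows
  catastrophically if assembled naively. All expectation formulas are
  assembled in log space (`stirling_log_row()` runs the defining recurrence
  with log-add-exp) and exponentiated last. `stirling1()` returns exact
  values as doubles and refuses once any value in the triangle exceeds
  $2^{53}$. For exact identity checks beyond that range the package carries
  a minimal arbitrary-precision integer helper (base $10^9$ digit vectors
  supporting addition, small-scalar multiplication and power-of-two shifts),
  with which the row identity
  $\sum_\ell \genfrac[]{0pt}{}{i}{\ell} 2^\ell = (i+1)!$ is verified exactly
  and the log tables are validated to $10^{-12}$ relative accuracy.
* **Recurrence cross-checks.** The DD recurrence can be iterated in log
  space (`dd_recurrence(log = TRUE)`), which keeps the deep tails
  ($\sim 2^i/i!$, far below double underflow at $i = 200$) comparable with
  the closed form at full relative precision.
* **Truncations.** The burden support of the Poisson mixture is truncated at
  mean $+\,10$ standard deviations of the widest component, with the mass
  defect tracked and kept below $10^{-8}$; mixture components carrying less
  than $10^{-14}$ of the DD mass are dropped only when their total is
  negligible. The conditioned-chain state space is capped at
  $20(\beta-\delta) i_{\max} + 50$ with an error raised if boundary mass
  accumulates.
* **Degenerate inputs.** $\mu = 0$ collapses the MBD onto $k = 0$;
  `mbd_to_dd()` refuses $\mu = 0$ (non-invertible); theory functions refuse
  $\delta \ge \beta$ and the recurrences refuse $\delta > 0$ where only the
  pure-birth case is exact.

## The inverse transform

`mbd_to_dd()` bins burden $k$ into division class $\ell = \mathrm{round}(k/\mu)$
— boundaries at half-integer multiples of $\mu$, ties to even. This is the
maximum-likelihood class assignment for a $\mathrm{Pois}(\ell\mu)$
observation when components are well separated, and it conserves mass
exactly. It is deliberately simple: when neighbouring components overlap
(component standard deviation $\sqrt{\ell\mu}$ comparable to the bin
half-width $\mu/2$, i.e. $\ell \gtrsim \mu/4$), mass spills into adjacent
classes and the inversion is only approximate. Formal deconvolution is out
of scope.

## Simulation design

* **Two tracking modes.** `track = "full"` stores per-cell mutation-id sets,
  the division-block registry and an incrementally maintained per-mutation
  abundance vector (needed for the SFS and the genotype matrix);
  `track = "compact"` keeps only per-cell (burden, divisions) counters for
  large ensembles. Both consume the random stream identically, so one seed
  yields one realisation in either mode — a property the tests assert.
* **Reproducibility.** One master seed per ensemble; per-replicate seeds are
  derived deterministically, and restarts after extinction continue the same
  stream, so ensembles are bit-reproducible including their discard tallies.
* **Stopping rules.** Fixed final population size (fires at the first step
  with $N_i = N$) and fixed step count are both supported; the theory
  formulas are indexed by step, fixed-size experiments use the known $N$ as
  the population factor.
* **Initial conditions.** $N_0 > 1$ is allowed in the simulator (progenitors
  mutation-free, zero divisions); the closed forms all assume $N_0 = 1$ and
  are not applied elsewhere.

## What the generator emulates, and what passing tests show

The synthetic ensembles reproduce the idealised neutral process: no
selection or clonal competition, no sequencing noise, no sampling — real
single-cell data add all three. Agreement between simulation and theory here
validates the mathematics and the implementation, not the applicability of
the neutral model to any particular dataset.

Default experiment sizes were chosen to keep Monte-Carlo error small enough
for 3-standard-error bin-wise comparisons while remaining quick on a single
CPU: 200 surviving replicates per ensemble (as in the reference
experiments), final sizes $N = 10^3$ for the DD overlay and the test suite,
$N = 10^4$ with $\mu = 10$ for the conversion experiment in the acceptance
script, and $\ge 10^4$ attempts for the extinction-fraction check.

## How far "only the mean matters" goes

The Poisson-mixture construction of the MBD from the DD uses only the
mutational mean $\mu$, and the package's simulations confirm a strong and a
weak half of the robustness claim:

* **Distribution-free (exact):** the mean map. For any per-division
  mutational distribution with mean $\mu$, the mean of the MBD is $\mu$
  times the mean of the DD. Poisson, degenerate and geometric models with
  equal means reproduce the same mean burden within Monte-Carlo error, and
  they share the identical division structure by construction.
* **Not distribution-free (bin-wise):** the full shape. A degenerate model
  (`fixed`) concentrates every burden on exact multiples of $\mu$ — a comb
  that no smooth mixture can match bin by bin — and a geometric model
  (per-division variance $\mu(1+\mu)$ instead of $\mu$) measurably widens
  the MBD at 200-replicate resolution. The Poisson-kernel conversion
  reproduces the simulated MBD bin-wise (3 SE) only when the per-division
  variance is itself Poisson-like, because the class-$\ell$ component of the
  true MBD is the $\ell$-fold convolution of the mutational distribution,
  with variance $\ell\sigma^2$ against the kernel's $\ell\mu$. The burden
  spread contributed by division-count stochasticity,
  $\mu^2 \mathrm{Var}(\ell)$, dominates as $\mu$ grows, which is why the
  distributions *look* alike at coarse resolution even when bin-wise tests
  distinguish them.

The test suite encodes both halves: the Poisson experiment must pass the
bin-wise comparison, the degenerate model must pass the mean map and the
exact division-binned recovery of its DD, and must *fail* the bin-wise
comparison — the failure is a theorem, not a bug.

## Known limitations

* Birth-death expectations are first-order approximations; at
  $\delta/\beta = 1/2$ they are still accurate at the resolutions tested
  here (the SFS series matches a 200-replicate ensemble at $N = 10^3$ within
  3 SE for small $j$), but no error bound is provided.
* The exact survival-conditioned population size is computed numerically by
  chain propagation, not in closed form.
* Conditioning by rejection matches conditioning on survival at the
  observation step; comparisons at intermediate steps of a longer run would
  require re-conditioning and are not offered.
* Continuous-time (exponential waiting time) simulation, selection,
  type-dependent rates, sampling and sequencing noise are out of scope.
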