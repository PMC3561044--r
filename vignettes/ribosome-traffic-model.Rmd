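---
title: "A two-state ribosome traffic model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state ribosome traffic model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraffic)
```

## The model

`ribotraffic` simulates translation of one mRNA as an exclusion process
of extended particles on a codon lattice. A ribosome is labelled by the
codon under its A site and occludes `footprint` = 9 codons, enforced as
a minimum A-site gap. Each ribosome cycles through two internal states:

1. **tRNA capture.** At codon *i* the ribosome waits for its cognate
   tRNA, arriving at a codon-specific rate $k_i$ (s$^{-1}$).
2. **Translocation.** Once tRNA-bound it advances one codon at the
   codon-independent rate $\gamma = 35\,\mathrm{s}^{-1}$, provided the
   gap to the ribosome ahead allows it; from the last codon it instead
   terminates at rate $\beta$ (= $\gamma$ by default).

Ribosomes initiate at rate $\alpha$ whenever the first `footprint`
codons are clear. The defining feature is that a sterically *blocked*
ribosome **retains its captured tRNA**: when space opens it advances at
the fast rate $\gamma$ rather than redrawing the full capture +
translocation step. A collapsed one-state comparator (a plain
codon-dependent TASEP whose single exponential step has mean
$1/k_i + 1/\gamma$) is available via `sim_config(one_state = TRUE)`;
at high initiation the two models differ measurably (see the test
suite), because queueing is common and tRNA retention speeds queue
dissolution.

Two steady-state observables summarise a run: the **current** $J$
(terminations per second = protein production rate) and the **density**
$\rho$ (time-averaged ribosome count per codon, the model's proxy for
polysome size).

## Codon rates from a tRNA census

`build_rate_table()` sets $k_c \propto \sum_t n_t \, w(c, t)$ over
anticodons $t$ with gene copy number $n_t$, where $w$ is 1 for a
Watson–Crick third-position pair, a wobble penalty (default 0.5) for
G:U/U:G and inosine-like readings, and 0 otherwise; Watson–Crick
pairing is required at codon positions 1–2 and, by default, anticodons
only serve codons of their own amino acid. The proportionality constant
is calibrated so the usage-weighted mean of $k_c$ equals a target
(default 10 s$^{-1}$), which fixes the absolute time scale.

## Simulation and the exact oracle

The simulator (`simulate_steady_state()`) is an exact continuous-time
Monte Carlo (Gillespie) implemented in C++, using R's RNG so runs are
reproducible from `sim_config(seed = )`. After a burn-in, $J$ is the
termination count over the measurement window and $\rho$ the average of
density samples taken every `sample_interval` seconds; standard errors
come from batch means (default 10 batches).

For small lattices `exact_steady_state()` builds the full
continuous-time Markov chain — every admissible ribosome configuration
times every combination of internal states — as a sparse generator and
solves for the stationary distribution directly. On one codon the model
is a renewal process and both routes reproduce the closed form
$J = (1/\alpha + 1/k + 1/\beta)^{-1}$:

```{r closed-form}
prof <- structure(list(gene_id = "single", codons = "AAA", k = 10),
                  class = "rate_profile")
cfg <- sim_config(footprint = 1, burn_in_time = 100, measure_time = 2000,
                  sample_interval = 0.5, seed = 1)
c(formula = 1 / (1 / 1 + 1 / 10 + 1 / 35),
  exact = exact_steady_state(prof, 1, cfg)$J,
  simulated = simulate_steady_state(prof, 1, cfg)$J)
```

The package's acceptance experiments (`experiment_oracle_agreement()`)
check simulator/oracle agreement on random small instances within
Monte-Carlo error.

## Response curves and smoothing

`sweep_alpha()` simulates a grid of initiation rates (default: 60
log-spaced points in $[10^{-3}, 5]$ plus 20 linear points in
$[0.01, 1]$, concentrating resolution where physiological rates lie)
and smooths both series with a 10-point running average. Two numerical
choices matter:

- **Saturation values.** $J_\max$ and $\rho_\max$ are the means of the
  last five *raw* grid points — the elongation-limited plateau.
- **Smoothed abscissa.** A running average over a log-spaced grid
  estimates the curve at the window's *arithmetic-mean* $\alpha$, which
  exceeds the grid point. All interpolation, inversion and slope
  estimates therefore pair the smoothed ordinates with the equally
  smoothed abscissa `alpha_s`. Skipping this pairing biases recovered
  initiation rates low by roughly 8–9% on the default grid.

## Inferring physiological initiation rates

Given an experimentally observed density $\rho_{\exp}$ (ribosomes per
codon; `density_per_codon()` converts per-mRNA counts),
`infer_alpha()` solves $\rho_{\text{smooth}}(\alpha) = \rho_{\exp}$ on
the piecewise-linear interpolant. Densities above the simulated range
are flagged `SATURATED` (pinned at the grid maximum), below it
`BELOW_GRID`; if noise leaves several crossings the smallest root is
returned and the estimate marked ambiguous — a conservative choice
reflecting the low-$\alpha$ physiological prior.
`infer_genomewide()` applies this per gene, adds the translation
efficiency $T_e = J(\alpha_{\mathrm{ph}})$, the gearing factor
$K = \mathrm{d}J/\mathrm{d}\alpha|_{\alpha_{\mathrm{ph}}}$
(responsiveness of protein output to initiation changes), saturation
values and a traffic-class label, and reports unmatched gene ids
instead of dropping them.

## Smooth, abrupt and hybrid transcripts

A slow-codon cluster in the body of an ORF lets a queue form once
$\alpha$ exceeds a sequence-specific threshold: the density jumps and
$J(\alpha)$ kinks sharply into its plateau. The same cluster at the 5′
edge cannot support an upstream queue and the curve saturates smoothly.
`curve_features()` extracts three shape features (kink height,
saturation sharpness, density jump) and `classify_curves()` z-scores
them and runs 2-means with a deterministic initialisation; genes whose
assignment margin falls below a band (default 0.2) are called HYBRID.

```{r dichotomy, eval = FALSE}
# a mid-body vs 5'-edge bottleneck pair (several minutes of simulation)
res <- experiment_bottleneck_dichotomy(n_pairs = 2, seed = 1)
res$labels
```

## Synonymous shuffling: arrangement vs usage

`shuffle_synonymous()` permutes the codon multiset within each
amino-acid family, leaving the protein, the codon composition, the CAI
(`cai()`, geometric mean of reference weights, excluding AUG/UGG/stops,
with a 0.5 pseudo-count for unobserved reference codons) and the mean
capture rate exactly invariant — while the current of a bottlenecked
ORF varies strongly with the *arrangement* alone
(`shuffle_ensemble_currents()`). This separates what usage indices can
and cannot predict about protein output.

## Synthetic data scope

All fixtures are generated in code and clearly synthetic:
`synthetic_rate_table()` assigns a fast background rate and designated
slow codons; `make_synthetic_orf()` builds ORFs with controlled
bottleneck windows; `make_synthetic_density()` forward-simulates
densities at known initiation rates for recovery tests. They are design
parameters, not derived from any organism's tRNA census, and the
package makes no claim that synthetic panels reproduce genome-wide
statistics of a real organism — applying the pipeline to real data
requires user-supplied ORF FASTA, tRNA copy-number, density and
abundance tables (see the CLI in `exec/ribotraffic`).

## Problem sizes and runtime

Defaults are sized so every experiment runs in minutes on one core:
ORFs of 200–300 codons, 50–80-point $\alpha$ grids, sweeps at 300 s
burn-in + 1500 s measurement per point, forward density simulations at
the full 2000 s + 8000 s (density noise, not sweep noise, limits
recovery accuracy), shuffle ensembles of 50 variants at 2000 s. The
exact oracle is practical up to roughly $10^5$ states (e.g. L ≈ 20 at
footprint 9, or L ≈ 8 at footprint 1).

## Limitations

- Elongation uses one codon-independent translocation rate; only tRNA
  capture is codon specific. Termination is a single fast step.
- The exact oracle is exponential in lattice size and is a validation
  tool, not a production solver.
- Inversion assumes the smoothed density response is monotone over the
  grid; Monte-Carlo dips are handled by flagging, not re-simulation.
- The classifier's margin band is a package choice; class fractions on
  real genomes depend on it and on sweep noise.
- Initiation is memoryless and sequence-independent apart from the
  footprint-clearance rule; 5′ UTR structure, uORFs and reinitiation
  are out of scope.
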