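# ribotraffic

Stochastic simulation of mRNA translation as ribosome traffic, and the
machinery to infer per-transcript initiation rates genome-wide from
ribosome-density data.

Ribosomes are modelled as extended particles (9-codon footprint) on a
codon lattice with a **two-state** elongation cycle: at codon *i* a
ribosome first captures its cognate tRNA at a codon-specific rate
*k<sub>i</sub>* (set by tRNA gene copy numbers with wobble-pairing
corrections), then translocates at a fast codon-independent rate
γ = 35 s⁻¹ when steric exclusion allows. A blocked ribosome keeps its
captured tRNA — which makes dense traffic measurably faster than a
plain codon-dependent TASEP. From simulated response curves
*J*(α), ρ(α) (current and density versus initiation rate α) the package:

- inverts experimentally observed ribosome densities to physiological
  initiation rates α_ph, with explicit SATURATED / BELOW_GRID /
  ambiguous flags;
- computes translation efficiency *T*<sub>e</sub> = *J*(α_ph), gearing
  *K* = d*J*/dα, and the saturation values *J*<sub>max</sub>, ρ<sub>max</sub>;
- classifies transcripts into SMOOTH / ABRUPT / HYBRID traffic regimes
  driven by the *position* of slow-codon clusters;
- runs synonymous-shuffle ensembles that hold codon usage (CAI, mean
  capture rate) exactly fixed while the arrangement — and hence the
  current — varies;
- predicts protein abundance as *T*<sub>e</sub>·*m* (optionally
  ·*F* for polysome-loaded fractions).

A C++ Gillespie core gives exact stochastic dynamics; an exact
master-equation solver for small lattices serves as a validation
oracle. All fixtures are synthetic and generated in code, so the whole
pipeline is testable offline; real analyses need user-supplied ORF
FASTA, tRNA, density and abundance tables.

## Worked example

Two synthetic 300-codon ORFs with identical codon composition, differing
only in where a 5-codon slow cluster (k = 1 s⁻¹ vs background
20 s⁻¹) sits: mid-body vs 5′ edge.

```r
library(ribotraffic)

mid  <- make_synthetic_orf(300, bottleneck = c(150, 5), seed = 1, gene_id = "MID")
edge <- make_synthetic_orf(300, bottleneck = c(2, 5),  seed = 1, gene_id = "EDGE")
mid$profile
#> <rate_profile> MID: L = 300 codons, k in [1, 20] s^-1

# a synthetic "experimental" density measured at the (hidden) true
# initiation rate 0.12 s^-1
rho_obs <- simulate_steady_state(mid$profile, 0.12, sim_config(seed = 7))$rho
rho_obs
#> [1] 0.01156

# sweep alpha and invert the density response
cfg  <- sim_config(burn_in_time = 300, measure_time = 1500, seed = 42)
grid <- default_alpha_grid(n_log = 40, n_lin = 10)
cv_mid <- sweep_alpha(mid$profile, grid, cfg)
cv_mid
#> <response_curve> MID: 50 alpha points in [0.001, 5] s^-1, J up to 0.1873 s^-1

infer_alpha(cv_mid, rho_obs)
#> <initiation_estimate> MID: alpha_ph = 0.1006 s^-1 [OK]

saturation_values(cv_mid)
#> $J_max   0.1788      $rho_max 0.06362
translation_efficiency(cv_mid, 0.1006)   # Te, proteins/s
#> [1] 0.0888
gearing_factor(cv_mid, 0.1006)           # K, responsiveness at alpha_ph
#> [1] 0.7412
```

The bottleneck position, not the composition, decides the traffic
class:

```r
cfg$seed <- 43
cv_edge <- sweep_alpha(edge$profile, grid, cfg)
feats <- rbind(as.data.frame(curve_features(cv_mid)),
               as.data.frame(curve_features(cv_edge)))
feats
#>   gene_id kink_score sat_sharpness rho_jump
#> 1     MID      0.670         0.692   0.0818
#> 2    EDGE      0.215         0.918   0.0429
classify_curves(feats, band = 0)
#> [1] "ABRUPT" "SMOOTH"
```

And arrangement alone moves the current while usage indices are frozen:

```r
tab <- synthetic_rate_table()
ens <- shuffle_ensemble_currents(mid$codons, tab, n = 10, alpha = 1,
         config = sim_config(burn_in_time = 300, measure_time = 2000, seed = 9),
         gene_id = "MID")
ens
#> <shuffle_ensemble> MID: 11 variants at alpha = 1 s^-1, J in [0.1865, 0.4595] s^-1
w <- cai_weights(list(mid$codons), "pool")
length(unique(sapply(ens$variants, cai, weights = w)))
#> [1] 1        # identical CAI across the whole ensemble
```

A 2.5-fold spread in protein output at exactly constant CAI and mean
capture rate.

## Command line

```sh
exec/ribotraffic fixtures --out-dir panel --n 5 --length 300 --seed 1
exec/ribotraffic sweep --orfs panel/orfs.fasta --rates panel/rates.tsv \
    --out-dir curves --seed 1
exec/ribotraffic infer --curves curves --density panel/density.tsv \
    --out summary.tsv
```

Every stochastic subcommand takes `--seed` and writes a YAML manifest.

## Documentation

Function documentation is written as roxygen comments in `R/`;
`vignettes/ribosome-traffic-model.Rmd` describes the model, the
numerical choices (smoothing, saturation definitions, inversion
policy), the synthetic-data scope and the limitations.
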