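# routedmix

Bayesian mixing models for diet reconstruction from isotopic and elemental
proxy signals, for ecologists, archaeologists, forensic scientists and
dietary physiologists who need quantitative intake estimates — with honest
uncertainties — from consumer tissue chemistry.

Classical linear mixing models treat a consumer signal as a weighted
average of bulk food signals. Real proxies are rarely that obliging: bone
collagen δ¹³C draws ~74% of its carbon from dietary protein however little
protein the diet contains (*dietary routing*), each food fraction
contributes in proportion to its elemental concentration, and every input —
source signals, concentrations, routing weights, diet-to-tissue offsets —
is uncertain. `routedmix` models the consumer signal for proxy *k* as

```
P_k = Δ_k + Σ_j (w_jk / 100) · [ Σ_i α_i c_ij s_ijk / Σ_i α_i c_ij ] + ε_k
```

where `α_i` are the food-group intake proportions (the estimand, on the
simplex), `c_ij` fraction concentrations, `s_ijk` source signals, `w_jk`
routing weights and `Δ_k` the diet-to-tissue offset
(*consumer = mixture + offset*). All uncertain inputs are latent parameters
with normal priors at their stated mean ± sd; intakes get a Dirichlet
prior; expert knowledge enters as algebraic constraints
(`"Corn > Gluten"`, `"Protein > 5"`) encoded as normal or
Bernoulli–Heaviside pseudo-observations. Inference is a self-contained
blocked adaptive random-walk Metropolis sampler in stick-breaking
coordinates, with split-R̂/ESS diagnostics. See
`vignettes/routedmix-methods.Rmd` for the full model.

## Worked example

Three food groups (Plant/Animal/Fish) with protein δ¹⁵N of 2/6/10‰, a
diet-to-tissue offset of 3‰, and a consumer measured at 6.6 ± 0.2‰ — the
value implied by a true 70/20/10 diet:

```r
library(routedmix)

sc <- builtinScenario("table1")
predictConsumerSignal(sc, c(0.7, 0.2, 0.1))
#> d15N
#>  6.6

fit <- runMcmc(buildPosteriorLogDensity(sc), samplerConfig(seed = 1))
sm  <- summarizePosterior(fit, paste0("alpha_", foodGroups(sc)))
round(sm[, c("mean", "sd", "p2.5", "p97.5")] * 100, 1)
#>   mean   sd p2.5 p97.5
#> 1 69.4  6.9 55.5  81.3
#> 2 20.6 12.0  1.1  42.5
#> 3 10.0  6.0  0.5  21.2
```

Rows are Plant, Animal and Fish: the posterior mean intakes (69/21/10%)
recover the generating diet, and the 95% credible intervals (`p2.5`,
`p97.5`) quantify what one proxy can and cannot resolve — the Plant share
is pinned to ±7 points while Animal and Fish trade off against each other.

A routed, multi-proxy scenario with a prior constraint:

```r
hb  <- builtinScenario("hare_b")        # pig feeding experiment, Corn > Gluten prior
fit <- runMcmc(buildPosteriorLogDensity(hb), samplerConfig(seed = 1))
summarizePosterior(fit, c("alpha_Corn", "alpha_Gluten", "beta_Protein"))
```

Scenarios are plain text directories (`readScenario()`,
`writeScenario()`), and `inst/cli/routedmix` exposes `run` / `validate` /
`simulate` / `fixtures` subcommands for shell use.

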