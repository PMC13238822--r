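# rebuildsim

Age- and sex-structured simulation of a rebuilding prey stock coupled
one-way to a harvested, gape-limited predator. The package is built around
the U.S. West Coast groundfish case of yelloweye rockfish (*Sebastes
ruberrimus*), a long-lived prey recovering under a rebuilding plan, and
lingcod (*Ophiodon elongatus*), a productive predator whose fishery takes
yelloweye as bycatch. It is aimed at fisheries modelers asking when
harvesting a predator helps or hurts the recovery of its prey: harvest
releases the prey from predation, but the bycatch that rides along with it
adds mortality, and the balance depends on how specialized the predator is
on that prey.

## The model

Both species follow a semi-discrete age-structured model: continuous
mortality within each year, punctuated by an annual pulse of recruitment and
aging into a plus group. Lingcod (sexes tracked separately) decay as

    dL[j,s]/dt = -(M[s] + v[j,s] * F) * L[j,s]

and yelloweye face natural mortality, bycatch proportional to lingcod
fishing, and size-selective Holling type-II predation:

    dY[i]/dt = -(M + v[i] * b * F) * Y[i]
               - sum_{j,s} a[i,j,s] * Y[i] * L[j,s] /
                 (1 + delta * sum_i' a[i',j,s] * Y[i'] + delta * q)

The attack rates `a[i,j,s]` come from a gape-limitation window (prey between
5% and 29% of predator length), the predator's consumption allometry, and
the prey-specialization parameter `gamma` — the proportion of consumed
biomass that is yelloweye (0 none, 0.001 generalist, 0.014 intermediate,
0.05 specialist). Annual recruitment is Beverton–Holt in pre-pulse spawning
biomass, parameterized by steepness (`alpha = 4h/((1-h)phi)`,
`beta = (5h-1)/((1-h) phi R0)`), with mean-one lognormal AR(1) deviates
(`sigma = 0.5`, `rho = 0.23`).

Scenario analysis calibrates, per specialization level: the unfished
equilibria `S0`, the management target `F40` (the fishing rate leaving the
predator at 40% of `S0`), and historical fishing rates that deplete both
stocks to 22% of `S0` over a 100-year deterministic burn-in. Rebuilding is
then simulated for 350 stochastic years across a grid of predator harvest
rates; outcomes are mean spawning biomass, stability (inverse CV), the
plus-group share of numbers over the final 150 years, and rebuilding time —
years until the prey first reaches `0.4 * S0`. A Monte-Carlo global
sensitivity analysis with random-forest permutation importance (%IncMSE)
screens the poorly known predation and recruitment parameters.

## Worked example

```r
library(rebuildsim)

# specialist predator scenario (gamma = 0.05)
model  <- build_model(gamma = 0.05)
refpts <- calibrate_model(model)
F40    <- solve_F40(model)
c(S0_prey = refpts$S0_Y, S0_pred = refpts$S0_L, F40 = F40,
  F_hist_pred = refpts$F_hist_L, F_hist_prey = refpts$F_hist_Y)
#>      S0_prey      S0_pred          F40  F_hist_pred  F_hist_prey
#> 3.974571e+03 3.136755e+04 1.247325e-01 2.354902e-01 4.386957e-02

# 150 stochastic rebuilding replicates at the predator management target
run <- run_scenario(model, refpts, F = F40, b = 0.05, n_reps = 150,
                    master_seed = 1)
ss <- steady_state_metrics(run$ssb_Y, run$n_tot_Y, run$n_plus_Y)
rb <- rebuilding_time(run$ssb_Y, refpts$S0_Y)
c(mean_ssb = ss$mean_ssb, stability = ss$stability,
  plus_group = ss$plus_prop, rebuild_mean = rb$mean, rebuild_sd = rb$sd)
#>     mean_ssb    stability   plus_group rebuild_mean   rebuild_sd
#> 3.278743e+03 1.507815e+01 4.033858e-02 2.222667e+01 1.488870e+00
```

Reading the output: under specialist predation the prey's unfished spawning
biomass is 3,975 kg (predation depresses it below the no-predation value of
6,215 kg), and the predator's management target is F40 = 0.125 / yr. Fishing
the predator at F40 with 5% bycatch leaves the prey fluctuating around
3,279 kg of spawning biomass (about 82% of this scenario's unfished level),
with stability 15.1 (the annual CV of spawning biomass over the last 150
years is about 6.6%), 4.0% of individuals in the 65+ plus group, and a mean
rebuilding time of 22.2 years (SD 1.5 across replicates) to reach 40% of
unfished spawning biomass.

`run_scenario_grid()` sweeps (gamma, F, b) cells into a tidy metrics table,
`run_gsa()` runs the sensitivity screen, `load_config()` reads YAML
parameter files with dotted-path overrides, and `write_outputs()` writes
CSVs with a checksummed run manifest.

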