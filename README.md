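# betamyo

Deterministic simulation of the compartmentalized beta1-adrenergic
signaling system of the mouse ventricular myocyte, coupled to a whole-cell
action-potential and Ca2+-dynamics model.

## The problem

Sympathetic stimulation of beta1-adrenergic receptors (beta1-ARs) drives
cardiac inotropy and lusitropy through the cascade

    beta1-AR -> Gs -> adenylyl cyclase -> cAMP -> PKA -> targets,

but in a ventricular myocyte this cascade is spatially organized: receptor,
cyclase and phosphodiesterase isoforms, protein kinase A isoforms,
phosphatases and the PKA targets are segregated between **caveolae**
(caveolin-3-rich sarcolemma), the **extracaveolae** membrane (which hosts
the dyadic junctions), and the **cytosol**. `betamyo` implements a
three-compartment biochemical network (45 ODE states: ligand-receptor-G
protein algebra, Gs activation, AC5/6 and AC4/7 synthesis, PDE2/3/4
degradation with PKA feedback, the four-cAMP PKA activation chain with PKI
buffering, PP1/PP2A with inhibitor-1) coupled to an 84-state
electrophysiological layer: Markov models with paired
non-phosphorylated/phosphorylated sub-diagrams for the two L-type Ca2+
channel populations (20 % caveolae / 80 % extracaveolae, phosphorylated
conductance 2.09-fold), the fast Na+ channel (phosphorylation-trafficking)
and the ryanodine receptor, plus the modulated K+ currents, pumps,
exchangers, SR Ca2+ handling and phosphorylatable buffers.

The membrane equation is

    dV/dt = -(I_CaL + I_p(Ca) + I_NaCa + I_Cab + I_Na + I_Nab + I_NaK
              + I_Kto,f + I_K1 + I_Kur + I_Kss + I_Kr + I_Cl,Ca - I_stim)

with currents in pA/pF, an 80 pA/pF, 1-ms stimulus, and time in ms
throughout. Every numeric constant lives in a machine-readable parameter
ledger (`inst/extdata/ledger.json`) with per-entry units and provenance
tags; see the methods vignette (`vignettes/betamyo-methods.Rmd`) for the
model equations, assumptions, and the meaning of the `refit` tag.

## Worked example

```r
library(betamyo)
m <- build_model()                      # ledger-backed model object

# basal steady state of the unstimulated biochemical network, found from a
# perturbed start by the windowed convergence rule
basal <- find_steady_state(m, initial_state(m, "signaling") * 1.2)$state
signif(basal[c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")], 4)
#> cAMP_cav cAMP_ecav  cAMP_cyt
#>   0.2531    0.5062    0.4075

# 30-s pulse of 0.1 uM isoproterenol at t = 200 s with PDE4 inhibited 90 %
ex <- camp_pulse_experiment(m, basal, pde4_mult = 0.1)
signif(ex$amplitude_peak, 4)
#> [1] 0.9782
```

The three basal numbers are the steady-state cAMP concentrations (uM) of
the caveolae, extracaveolae and cytosolic compartments — the balance of
synthesis, degradation and inter-compartment diffusion at zero agonist.
The pulse amplitude is the peak whole-cell cAMP (uM) of the transient
elicited by the brief agonist pulse when PDE4, the dominant
cAMP-hydrolyzing isoform, is 90 % inhibited.

Other entry points: `pace_model()` (current-clamp pacing, 1-5 Hz),
`run_voltage_clamp()` (step protocols with the membrane equation
bypassed), `icail_decay_experiment()` (bi-exponential I_CaL inactivation),
`run_dose_response()`, `run_block_experiment()` (selective block of one
L-type population), `ap_metrics()` / `ca_metrics()` /
`accumulate_fluxes()` (AP durations, Ca2+ transient characteristics,
per-cycle flux budgets), and `trajectory_write_csv()` for tidy exports.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the basal
compartment cAMP triple (steady state from a seed-perturbed start); the
whole-cell cAMP transient amplitudes for the pulsed-isoproterenol protocol
under control, 90 % PDE3 and 90 % PDE4 inhibition; the basal
phosphorylated fraction of the L-type channel population; the fast time
constant of bi-exponential I_CaL inactivation at 0 mV without SR release;
and the peak-current fold increases of the two L-type populations after a
600-s exposure to 1 uM isoproterenol. Results are written as a JSON object
keyed by target id.
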