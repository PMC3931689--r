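---
title: "Model and methods: compartmentalized beta1-adrenergic signaling in a mouse ventricular myocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Stimulation of beta1-adrenergic receptors (beta1-ARs) by catecholamines is
the principal mechanism by which the sympathetic nervous system raises the
strength (inotropy) and relaxation rate (lusitropy) of the heartbeat. The
cascade — receptor, stimulatory G protein (Gs), adenylyl cyclases (AC),
cyclic AMP, protein kinase A (PKA) — does not operate in a well-stirred
cell. Its components are segregated between caveolae (caveolin-3-rich
sarcolemmal domains), extracaveolae membrane (cholesterol-rich rafts
without caveolin-3, which here contain the dyadic junctions), and the bulk
cytosol, and so are the PKA targets: one sub-population of L-type Ca2+
channels, the fast Na+ channel and phospholemman sit in caveolae; the
second, larger L-type population, the ryanodine receptors (RyR) and the
K+ currents I_Kur and I_Kto,f face the extracaveolae compartment;
phospholamban (PLB) and troponin I (TnI) are cytosolic.

`betamyo` implements a deterministic ODE model of this system for the
mouse ventricular myocyte: a three-compartment biochemical network (45
states) coupled to a whole-cell action-potential and Ca2+-dynamics model
(84 further states: membrane potential, ionic concentrations, SR Ca2+
pools, buffers, and Markov occupancy vectors for the two L-type channel
populations, the fast Na+ channel, the RyR and the rapid delayed
rectifier).

## Biochemical part

**Receptor module.** Ligand-receptor and receptor-G-protein binding are
fast (tens of milliseconds) relative to everything downstream and are
treated algebraically. With \[AB\] = \[A\]\[B\]/K for each complex, the two
conservation laws — non-phosphorylated receptor
$R_{tot}^{np} = R + LR + LRG + RG$ and G protein
$Gs_{tot} = Gs + LRG + RG$ — reduce to a quadratic in free receptor which
is solved in closed form at every right-hand-side evaluation
(`solve_receptor_equilibrium()`); the physical root is the unique
non-negative one. Slower processes are ODEs: G-protein activation through
the LRG (fast) and RG (slow) routes, GTP hydrolysis and holoenzyme
reassociation; and receptor desensitization, in which PKA phosphorylates
all non-phosphorylated receptor states while GRK2 phosphorylates only
ligand-bound states, so the GRK2 route shuts off exactly at zero agonist.
The PKA route saturates in catalytic subunit (Michaelis constant
`Km_bar_pka`), which is what bounds the equilibrium phosphorylation rise
at saturating isoproterenol near the observed ~108 %.

**AC and PDE.** AC5/6 activity (caveolae) and AC4/7 activity
(extracaveolae, cytosol) are saturating functions of Gs-alpha with a
multiplicative Gs-betagamma boost and a basal turnover fraction.
Degradation is the sum of Michaelis terms for PDE2 (low affinity), PDE3
(high affinity, caveolae and cytosol only) and PDE4 (intermediate);
PKA phosphorylation of PDE3/PDE4 scales their catalytic rate by
`1 + delta * f` with `delta = 4` — the "several-fold" activation is what
terminates the rising phase of the cAMP transient at ~35–70 s and makes
the transient biphasic. Selective inhibition (cilostamide/milrinone,
rolipram/Ro 20-1724) is a multiplier on one isoform's rate; IBMX
multiplies all three.

**cAMP and PKA.** Each compartment's cAMP balances synthesis, degradation,
binding to PKA and diffusive exchange; exchange fluxes are pairwise
antisymmetric in amount units, so with reactions disabled the
volume-weighted total is conserved (a property test). PKA holoenzyme binds
four cAMP in two cooperative two-molecule steps with equal site constants
(2.5 uM for PKAII in the membrane compartments, 2.9 uM for cytosolic
PKAI), then releases two catalytic subunits, which PKI buffers with
nanomolar affinity. Phosphatases are compartment-local (PP1+PP2A in
caveolae, PP1 only in extracaveolae, PP1+PP2A in cytosol); cytosolic PP1
is inhibited by phosphorylated inhibitor-1 through a closed-form
high-affinity complex (K = 1 nM), with I-1 phosphorylated by PKA and
dephosphorylated by PP2A.

## Electrophysiological part

The membrane equation sums I_CaL (two populations), I_p(Ca), I_NaCa,
I_Cab, I_Na, I_Nab, I_NaK, I_Kto,f, I_K1, I_Kur, I_Kss, I_Kr and I_Cl,Ca;
the stimulus is 80 pA/pF for 1 ms. The stimulus current is excluded from
the K+ bookkeeping (the alternative, assigning it to K+, is noted but not
used). Non-adrenergic formulations (I_Kss, I_Kr, I_K1, I_Cl,Ca,
backgrounds, buffers, SR geometry) follow the base mouse-myocyte model
lineage; their constants carry the `base-model` tag in the ledger.

**L-type Ca2+ channel.** Each population is an 18-state Markov chain: a
closed ladder C1–C4 with voltage-dependent rates, a pre-open closed state
C_P whose opening step (`kco`, phosphorylated: `kcop > kco`) is
rate-limiting at test potentials and keeps the non-phosphorylated maximum
open probability low; Ca2+-dependent inactivation O->I1 driven by
subspace Ca2+ through a Hill-2 saturating rate; voltage-dependent
inactivation O->I2 and I1->I3 with a voltage-insensitive recovery rate
`kvr`. Two numerically motivated departures from a literal reading of the
state diagram are documented here: the closing rate `koc` accelerates on
hyperpolarization (`koc * (1 + exp(-(V+50)/10))`; flat above ~-20 mV), so
channels recovering from inactivation do not dwell in the open state at
the resting potential — without this the model carries a ~6 uM/cycle
diastolic Ca2+ leak; and the recovery from the voltage-inactivated states
is the constant `kvr` rather than proportional to the activation rate,
which would otherwise trap channels in inactivation between beats and
collapse availability during 1-Hz pacing. The phosphorylated sub-diagram shares all rates except that its
activation ladder is evaluated at `V + dVact_p` (hyperpolarizing shift)
and its conductance is 2.09-fold larger. Both populations read the dyadic
subspace Ca2+ — the subspace sits in the extracaveolae domain, and no
separate Ca2+ sensor is defined for the caveolar channels, so a single
subspace signal is used for both (documented interpretation).
Phosphorylation/dephosphorylation transitions connect paired states with
a uniform rate (kinase activity times the compartment's catalytic PKA;
phosphatase activity times the compartment's PP pool), which makes the
phosphorylated-branch occupancy follow the same two-state balance as the
scalar substrates.

**Fast Na+ channel.** Nine states per sub-diagram (closed C3–C1, open,
fast/intermediate/slow inactivated, two closed-inactivated), identical
voltage-dependent rates in both sub-diagrams; PKA acts through a single
combined phosphorylation-trafficking rate into the second diagram, whose
only difference is a larger conductance. This reproduces an availability
increase without any shift of activation or steady-state inactivation.

**RyR.** Four states per sub-diagram (C1, C2, O1, O2) with
Ca4/Ca3-dependent opening; the phosphorylated branch speeds forward rates
slightly more than backward ones, so open probability versus cytosolic
Ca2+ is almost unchanged by PKA — deliberately, following the evidence
that RyR phosphorylation does not change Ca2+ sensitivity.

**Scalar substrates.** PLB, TnI, PLM, I_Kur and I_Kto,f carry a
phosphorylated fraction obeying `df/dt = kp*C*(1-f) - kd*PP*f`.
Functionally: PLB phosphorylation lowers the SERCA Ca2+ half-saturation
constant; TnI phosphorylation raises troponin Ca2+ unbinding by 50 % at
full phosphorylation (linear mixing); PLM phosphorylation lowers the
Na+/K+ pump's Km(Nai); I_Kur gains conductance; I_Kto,f loses roughly
half its conductance at full phosphorylation, with its phosphorylated
gating shifted +13 mV (activation) and +6 mV (inactivation). Currents mix
linearly between the non-phosphorylated and phosphorylated limiting
formulations — the mixing rule is a documented choice, tested at both
extremes.

## Parameters: the ledger and what "refit" means

Every numeric constant lives in `inst/extdata/ledger.json` with units,
compartment, source tag and citation; `load_ledger()` validates
completeness and attaches a checksum that simulations carry into their
outputs. Three source classes exist:

* `main-text` — whole-cell totals and statements fixed directly by the
  published description (beta1-AR 0.0103 uM; AC 0.02622 uM with 74 %
  AC5/6; I-1 0.08543 uM; K_PKAI = 2.9 uM, K_PKAII = 2.5 uM;
  K(I-1–PP1) = 1 nM; G_CaLp = 2.09 G_CaL; 20/80 L-type split; the
  I_Kto,f shifts; the stimulus).
* `base-model` — the mouse-myocyte electrophysiology lineage (geometry,
  buffers, SR fluxes, non-modulated currents).
* `refit` — everything whose primary numeric source is the model
  supplement, which is not machine-readable here. These constants were
  recalibrated against the *printed* quantitative anchors: the basal
  compartment cAMP triple (0.2534/0.5079/0.4078 uM), the pulsed-agonist
  cAMP transient series with PDE3/PDE4 inhibition, the steady-state
  inhibited cAMP rises (~35 %/~130 %), the receptor-phosphorylation rise
  (+108 %, ~30 % GRK2), the 10.3 % basal L-type phosphorylation, the
  bi-exponential I_CaL decay (7.77/22.0 ms), and the population fold
  increases (2.03/1.42). The basal state is constructed to be an exact
  fixed point: given the PDE pools and exchange conductances, the basal
  AC turnover of each compartment is solved from the basal balance, so
  the printed basal cAMP values are reproduced by construction and the
  calibration only shapes the *responses*.

A single-source-of-truth rule applies: ledger values never appear as
literals in model code (enforced by a lint test); voltage-dependence
shape constants of base-model rate formulas remain part of the formula
definitions and are tagged through their scale factors.

## Numerics

* Default integrator: embedded Cash–Karp 4(5) with mixed
  absolute/relative error control (rtol 1e-7 by default), step capped at
  protocol discontinuities (stimulus edges, segment boundaries). The
  integrator restarts at every drug event, so discontinuities are never
  stepped across.
* Reference integrator: classical fixed-step RK4 including the original
  step policy (2e-6 ms during 10 ms after each stimulus, 1e-4 ms during
  the remainder of paced runs, 0.1 ms unstimulated). It exists for
  cross-validation at short durations; the acceptance suite checks that
  the two engines agree on the paced membrane potential to <= 0.1 mV.
* Occupancy vectors are renormalized after an accepted step if their sum
  deviates from 1 by more than 1e-8; events are counted and reported in
  the trajectory (`n_renorm`).
* Steady-state detection integrates unstimulated windows of 10 s and
  requires every state variable to change by less than a relative 1e-4
  per window, mirroring the original "0.01 %" rule.
* The bi-exponential fitter sorts time constants (tau_fast < tau_slow)
  and reports R^2; APD_x is measured from maximal upstroke velocity to
  the linearly interpolated crossing of peak minus x % of amplitude.
* Degenerate inputs: negative concentrations are rejected at the API
  boundary; the receptor quadratic falls back to the linear solution when
  the coupling term underflows; the I-1 discriminant is clamped at zero
  (it is non-negative analytically).

## Drugs as parameter multipliers

Isoproterenol is the ligand concentration; selective PDE3/PDE4 inhibition
multiplies that isoform's catalytic rate by 0.1 ("inhibited by 90 %");
IBMX multiplies all isoforms; H-89 sets total PKA to zero; Calyculin A
multiplies PP1 and PP2A activity by 0.35 ("inhibits 65 %"). All are
segment-constant context fields, applied instantaneously at event times.

## What a green test establishes — and what it does not

There is no external data in this package: the "world" is the published
model description itself. The acceptance suite therefore checks that the
reconstructed system reproduces the printed simulation outputs (basal
compartment cAMP, pulsed-agonist transient amplitudes, clamp time
constants, fold increases, paced AP/Ca2+ changes), and the property suite
checks internal mathematics (conservation laws, Markov simplex and
stationary distributions, monotone dose responses, engine agreement).
Green tests establish faithful reconstruction and numerical soundness;
they do not validate the biology beyond what the original model already
claimed, and parameters tagged `refit` are this package's own calibration,
not transcribed constants.

Long paced experiments (300-s settling at 1–5 Hz) are the one place where
the test suite uses a labeled *scaled-down mode*: the biochemical
subsystem is pre-equilibrated separately (its 600-s agonist exposure costs
milliseconds of CPU), the resulting phosphorylation fractions are injected
into the full-cell state, and the cell is paced for a shortened settling
window. Scaled-down results are labeled as such and carry the wider (10 %)
tolerance; the full-length mode remains available through the same
functions by passing the full durations.

## Known limitations

* beta2-adrenergic/Gi competition, CaMKII signaling, receptor
  internalization beyond the two phosphorylated pools, spatial gradients
  within a compartment, and contractile mechanics are out of scope.
* I_K1 is not modulated by beta1-AR stimulation (as in the source
  description).
* The electrophysiological layer reproduces the base-model structure from
  its published lineage; individual rate constants that could not be
  verified against a machine-readable source carry the `refit`/
  `base-model` tags. Quantitative deviations in the paced experiments are
  expected and are reported openly by the acceptance suite: with the
  shipped ledger the paced layer reproduces the APD50 prolongation, the
  AP-amplitude increase, the diastolic-Ca2+ insensitivity, the staircase
  dichotomy and the isoproterenol SR load, but over-estimates the control
  Ca2+ influx per cycle and SR load (hence under-estimates the Ca2+
  transient fold) and does not reproduce the APD90 prolongation or the
  published Na+-influx partition. The corresponding test lists all paced
  quantities with their 10 % scaled-down band in a single comparison
  table.
* "Heavy buffer" clamp conditions are realized as J_rel = 0 with
  otherwise intact Ca2+ dynamics; the alternative (clamping cytosolic
  Ca2+) is noted but not used.
* The model is isothermal at 25 degrees C.
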