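---
title: "Causal mapping: model, translation and parameter search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal mapping: model, translation and parameter search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalmap)
```

## The model

A causal map describes a signaling pathway as a directed graph: nodes are
*species* (proteins, protein states, or abstract inputs) carrying a
dimensionless activity $C_j \in [0, C_j^{max}]$ with $C_j^{max} \le 1$,
and edges are signed *influences*. An influence may have several source
species; its *order* is the number of sources, whose values are
multiplied, so a second-order influence such as "receptor × ligand"
captures a binding event just as the corresponding mass-action term
would. The aggregate input on species $j$ is

$$x_j = \sum_i C_i W_{ij} + \sum_{i,k} C_i C_k W_{ikj} + \cdots$$

with weights $W \in (0, 1]$ playing the role of normalized rate
constants. Time is discrete and synchronous: every species is updated
from the frozen previous state (a Jacobi sweep), so the result is
independent of species ordering and each iteration represents the
smallest increment of signal propagation through the network ("virtual
time"). No conversion between iterations and physical time is defined or
attempted. The update is

$$C_j(t) = C_j(t-1) + \Lambda_j\!\left(C_j(t-1), f_j\right) f_j, \qquad
  f_j = \frac{1 - e^{-\alpha_j x_j}}{1 + e^{-\alpha_j x_j}},$$

where the causal function $f$ is an odd sigmoid (algebraically equal to
$\tanh(\alpha x / 2)$, which the test suite uses as an independent
cross-check) and the range-restriction factor
$\Lambda_j = C_j^{max} - C_j$ if $f_j > 0$, else $C_j$, scales the step
by the available headroom. Because $|f| < 1$, every trajectory provably
stays inside $[0, C_j^{max}]$; a property-style sweep over random
networks confirms this numerically.

Two kinds of species are special. *Clamped* species (external inputs
such as insulin, or a lumped disease parameter) have no update
expression and hold their value until reassigned between runs. *Clones*
are purely cosmetic display aliases used by drawing tools to avoid edge
crossings; here they are stored as labels on the canonical species and
have no dynamic meaning.

### Parameters that matter

* `alpha` (per species, default 1.2, validated range $[0.5, 5]$):
  steepness of the causal function; large values give switch-like
  responses.
* `weight` (per influence, $(0, 1]$): influence strength; constant
  during a simulation. Translated models leave weights as free
  parameters (see below).
* `c_max` (default 1): per-species ceiling. All packaged models use 1;
  the code supports smaller ceilings and the property tests exercise
  them.
* Steady-state detection: `tol` (default $10^{-6}$) on the max-norm of
  the one-step change, `max_iter` (default 10000). Non-convergence is
  reported by flag, never by exception.

The sigmoid is evaluated in an overflow-safe form (negative arguments go
through the odd symmetry), so arbitrarily large $|\alpha x|$ cannot
produce `Inf`/`NaN`.

## Translating mass-action ODE models

Each signed product term of a derivative maps to exactly one influence:
sign to sign, species factors to the (multi-order) source list, rate
constant to a provenance label on the edge. Two deliberate choices:

* **Weights are never numerically carried over from rate constants.**
  Rate constants have units and magnitudes incompatible with the
  normalized weight interval; translated weights are placeholders (0.5)
  labeled by their rate symbol, to be assigned by random search or by
  hand. The translation report lists the full symbol-to-weight map.
* **Saturation factors collapse to their substrate.** A Michaelis–Menten
  or Hill factor $S^n / (k_m^n + S^n)$ becomes the bare species $S$ in
  the source list; the dropped denominator is recorded in the
  translation report. The saturating shape is re-supplied by the causal
  function itself.

A derivative may contain two terms with the same species product but
different rate constants (e.g. two independent dephosphorylation routes
of a receptor). These translate to two parallel influences that differ
only in their label, and the network container treats edges with
distinct labels as distinct; *unlabeled* exact duplicates are rejected
by the validator as modeling errors.

A term with no species factor at all (a bare constant influx) has no
influence-graph counterpart and is rejected with an explanatory error.

## The insulin case study

The packaged model is a reduced insulin-signaling network: 27 dynamic
species (receptor states IR/IRp/IRins/IRip/IRi, the IRS1 pool with
tyrosine and serine-307 phosphoforms, a phosphatase-like X/Xp pair, PKB
with three phosphostates, mTORC1/2, AS160, GLUT4 at membrane and
cytosol, S6K and S6) plus two clamped inputs, insulin and a lumped
"diabetes" feedback strength. Its 72 ODE terms translate one-to-one into
72 influences, including two third-order edges
(IRS1p × mTORC1a × diabetes) and four Hill-saturated reactions
(AS160/AS160p via km6, S6K/S6Kp via km9). The type-2-diabetes condition
rescales initial IR to 0.55×, GLUT4 to 0.5× and the diabetes input to
0.15×.

The parameter search screens random assignments of all 72 weights and
27 sensitivities:

1. weights uniform on $[w_{max}/1000,\, w_{max}]$ with $w_{max} = 1$
   (so the largest admissible weight is 1000× the smallest), alphas
   uniform on $[0.5, 3]$ — "evenly distributed" is read as uniform on
   the linear scale, with a log-uniform option behind a flag;
2. for each set and each condition, the basal model (insulin = 0) is
   iterated to steady state;
3. the basal state is restarted with insulin clamped to 1 for 500
   iterations (the transients of interest complete well within this
   window; the length is exposed in the configuration);
4. the set must produce a `transient_up` response of
   `measuredIRp = IRp + IRip` and `measuredIRS1p = IRS1p + IRS1p307`
   in the normal condition,
5. and in the T2D condition,
6. and the normal curves must lie pointwise at or above the T2D curves
   within a slack of 0.01 (an area-under-curve alternative is available
   behind a flag; the pointwise reading is the stricter and the
   default).

### Rule thresholds

Verbal criteria ("transient", "oscillation") need operational
definitions to be decidable on finite trajectories. The defaults are:
minimum excursion $\delta = 0.05$ (anything smaller is treated as
noise-level on the unit activity scale); retained fraction
$\rho = 0.5$ (a transient must give back at least half of its peak
excursion); oscillations need at least $k_{osc} = 4$ direction
alternations of magnitude $\ge \delta/10$. All three are exposed in
`cmap_rule()`. The oscillation criterion is one defensible choice among
several; nothing in the packaged pipelines depends on it.

### Numerical choices in the pipeline

The basal phase uses its own convergence defaults
(`basal_tol = 1e-4`, `basal_max_iter = 5000`) rather than the engine's
general-purpose `1e-6`/10000. Near their fixed points these randomly
parameterized networks contract very slowly — one-step changes of order
$10^{-5}$ persist for tens of thousands of iterations — while the
downstream rules cannot resolve anything below $\delta = 0.05$. A basal
tolerance of $10^{-4}$ bounds the residual drift three orders of
magnitude below that threshold at a fraction of the cost; sets that
still fail to converge (e.g. sustained flip-flops at high $\alpha$) are
discarded with a logged reason, as the contract requires. The engine
operation `run_to_steady_state()` keeps the stricter defaults.

At 20,000 sampled sets (the scale used throughout the documentation and
checks; the method itself is indifferent to scale) a typical screen
retains a few tens of sets after the normal-condition rules, loses a few
at the T2D stage and a few more to dominance, leaving on the order of
10–25 survivors, so existence of survivors is robustly reproducible
across seeds. The stochastic acceptance check tries up to three
consecutive seeds before declaring failure.

## The reference integrator

To compare the causal map against its source ODE model, the package
integrates the mass-action system with a classical fixed-step
fourth-order Runge–Kutta scheme (default step 0.01 time units). A fixed
step keeps runs bit-reproducible and dependency-free; stiff solvers,
events and parameter estimation are out of scope. Small negative
undershoots are clipped at zero with a warning. Step-halving on a
closed-form two-state system confirms fourth-order convergence, and
linear moieties (e.g. the five receptor forms) are conserved to rounding
because RK4 preserves linear invariants exactly.

The packaged rate file `rates_synthetic_transient.json` is *synthetic*:
the source publication's rate values are not reprinted in the material
this model was transcribed from, so the file documents one illustrative
assignment — fast receptor activation and binding, slower recovery and
feedback — under which the ODE side shows the same qualitative
IRp + IRip transient as the causal-map pipeline. It is a demonstration
of qualitative concordance, not a reproduction of fitted constants.

## What the random-network generator does and does not emulate

`random_network()` draws structurally valid networks: orders 1–3 with
self-influences, weights across the admissible interval, alphas across
the full validated range, occasional clamped species and sub-unit
ceilings. It is designed to probe *invariants* (boundedness,
determinism, oracle agreement), not to resemble curated pathways: it has
no moiety structure, no conservation relations between states of one
protein, and no biologically plausible sparsity pattern. Passing those
sweeps therefore certifies the update rule's contract, not fidelity to
any real pathway; the insulin model plays the latter role.

## Motif initial values

The five elemental two-species motifs fix all weights at 0.5 (except the
deliberately weak 0.01 input of the positive self-influence motif, so
that the autocatalytic loop, not the input, dominates its rise). Their
initial values are a package choice: activator A = 1 and clamped, P = 0,
except P = 1 for the negative motif (so inhibition has something to
erase), P = 0.8 for the self-limited decay, and — for the combined
transient — an *un-clamped* activator with a negative self-influence, so
A decays while driving P and P's own decay then returns it toward zero.
That is the minimal two-species configuration whose response rises and
substantially returns with all weights at 0.5.

## Manual tuning guidelines

Random screening is not the only way to parameterize a causal map; for
hand-built networks (e.g. large receptor-kinase cascades with multiple
feedback phosphatases) the following heuristics, applied while watching
the simulated signal propagate, converge quickly and are shipped here as
documentation rather than code:

* a slow reaction (low weight) placed after a fast one accumulates the
  intermediate between them;
* a species whose inputs all share one sign can only change
  monotonically — a transient (non-monotone) response requires at least
  two inputs of opposite sign;
* tune each weight inside its most sensitive range: the region where the
  smallest adjustment produces the largest change in downstream
  activity;
* selectively raising `alpha` on switch-like nodes (e.g. doubly
  phosphorylated terminal kinases) sharpens their response without
  touching the topology.

## Known limitations

* Only synchronous updating is implemented; asynchronous or random-order
  schemes can change qualitative behavior and are out of scope.
* Iterations have no physical-time calibration, so trajectories are
  comparable between models only qualitatively.
* The search is pure random screening — no gradient or heuristic
  refinement; consequently hit rates fall quickly as rule sets grow
  stricter.
* SBML import is declared but not implemented; the native JSON formats
  are the only interchange.
* With $\alpha \le 5$ and weights $\le 1$, the range-restriction factor
  damps one side of every putative limit cycle; sustained oscillations
  were not observed in two-species configurations, and the oscillation
  rule is exercised on constructed series rather than on emergent
  dynamics.
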