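---
title: "Methods: an executable Boolean model of TNF/IL6/TGFB1 signalling in RA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an executable Boolean model of TNF/IL6/TGFB1 signalling in RA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ralogic)
```

## Scope and model

`ralogic` analyses rheumatoid-arthritis signalling with Boolean
(logical) models: every species is 0/1, and each has an update rule
over its regulators built from AND, OR and NOT. The formalism trades
kinetic detail for exhaustiveness — with 13 variables all 2^13 states
can be checked, so statements like "there are exactly five stable
states" are proofs within the model, not samples.

A *stable state* (fixed point) is an assignment `x` with `f(x) = x`
under clamps. A variable whose rule is itself is an *input*: both of
its values are self-consistent, which is how "leave the other inputs
free" is modelled; a *clamp* (knock-out = 0) overrides a rule. The
anti-TNF treatment is modelled throughout as the clamp `TNF = 0`.

### The packaged 13-variable fixture

The fixture covers the cascade from the three cytokine inputs (TNF,
IL6, TGFB1) through ILK, MAP2K1, MAPK1, MAPK14, DAXX and NFKB1 to the
four transcription factors JUN, FOS, JUND and NFKBIA. Its topology
(`ra_subnetwork()`) contains only activations, so the interaction graph
has only positive circuits; by the standard circuit-functionality
argument this rules out sustained asynchronous oscillation, and
`async_attractors()` indeed classifies every terminal SCC as a
singleton (a property the test suite checks, both for the fixture and
for randomly generated all-positive models).

Two modelling choices deserve explanation:

- **IL6 and TGFB1 are self-sustaining regulated species, not pure
  inputs.** The published stable-state tables contain five wild-type
  fixed points, not the eight that three free inputs would force: no
  fixed point exists with IL6 off while TNF is on, and none with TGFB1
  on while IL6 is off. The only monotone way to realise that is
  feedback: IL6 is maintained by itself, TNF or NF-kB signalling
  (`IL6 = IL6 | NFKB1 | TNF`), and TGFB1 persists only in an IL6-active
  context (`TGFB1 = IL6 & TGFB1`). The tables do not state this
  explicitly; it is the package's own resolution, and it is what makes
  all four tables exactly reproducible at once.
- **Rules are reconstructed, not transcribed.** The source material
  prints stable-state tables but no rule listing. The packaged model
  (`ra_model()`, stored as `inst/extdata/ra_model.bnet`) is the output
  of `solve_rules_from_constraints()` run on the topology plus the
  constraint tables; the solver stays runnable
  (`ra_solve_model()`) and a test asserts the re-derived model is
  constraint-equivalent to the stored one. Multiple rule sets satisfy
  the tables; the minimal-literal, lexicographic tie-break picks one
  canonical representative, so e.g. `NFKBIA = MAPK14 | NFKB1` is kept
  although wider equivalents exist.

### Constraint-based rule reconstruction

`solve_rules_from_constraints()` searches, per variable, monotone
disjunctive-normal-form rules over the variable's topology regulators
(activators positive, inhibitors negated), bounded at 4 conjuncts of at
most 3 literals — enough to cover the fixture while keeping the
per-variable candidate list enumerable as an antichain set. Fully
specified required states decompose into per-variable point constraints
`f_v(s) = s_v`, which prune candidates up front; the *exactness*
requirement (no spurious fixed points) does not decompose, and is
enforced by a counterexample-guided loop: whenever the current
candidate assignment admits an extra fixed point, the search branches
on which variable must reject that state and restricts its candidate
list to the rejecting rules. Because each branch strictly shrinks a
list, termination is guaranteed; candidate lists are explored in
(literal-count, lexicographic) order, so the result is deterministic.
Infeasibility (two required states with identical regulator values but
different outputs, or a non-monotone requirement) is reported with the
offending variable and table row.

Nine additional *qualitative* constraint tables encode the real-time
simulation outcomes over the TF read-out {JUN, FOS, JUND, NFKBIA}: for
each knock-out signature, each single input switched fully on must
yield the published TF pattern (all four on, except IL6-only under the
DAXX+ILK+MAP2K1 knock-out, where only NFKBIA activates). These tables
clamp exactly the variables that the corresponding stochastic
simulation doses, mirroring `run_stochastic()` semantics in which
undosed variables follow their rules. One asymmetry is deliberate: the
IL6-only case additionally clamps `TGFB1 = 0`, because `TGFB1`
(rule `IL6 & TGFB1`) cannot self-activate from the all-OFF initial
state, and without the clamp the exactness check would count a
TGFB1-on fixed point that no trajectory from the initial condition
reaches.

## Dynamics engines and numerical choices

- **Fixed points** are found by exhaustive vectorised enumeration over
  the free (unclamped) variables, chunked at 2^18 states so memory is
  bounded; the supported limit is 24 free variables (~17M states), and
  larger models must go through `reduce_model()` first. Rows are
  returned in lexicographic order for reproducible diffs. The engine is
  certified against a deliberately naive scalar oracle (a loop over all
  assignments) on hundreds of random models in the test suite.
- **Asynchronous attractors** build the full one-variable-flip
  transition graph (limit 16 free variables) and take terminal
  strongly-connected components, using `igraph` for the SCC step;
  singleton terminal SCCs are exactly the fixed points, and this
  cross-method agreement is property-tested.
- **Reduction** substitutes an eliminated variable's rule into every
  rule referencing it. Autoregulated or clamped variables are rejected
  — eliminating them does not preserve fixed points. The returned
  object carries back-substitution expressions so reduced fixed points
  can be extended and compared against the original model's
  (`extend_states()`), which is how the preservation property is
  tested.
- **Stochastic simulation** (`run_stochastic()`) starts from the
  all-OFF state, resamples each dosed variable ON with probability
  equal to its dose at every step, clamps perturbed variables, and
  updates everything else synchronously. The published platform's exact
  scheduler is not documented; synchronous update was chosen because it
  is reproducible and satisfies every qualitative claim used for
  acceptance. Defaults — 2000 steps, burn-in 500, 50 runs — put the
  Monte-Carlo standard error of a Bernoulli-like activity near
  0.01-0.02, comfortably inside the 0.95/0.05 acceptance margins;
  activity is averaged per run and the standard error taken across
  runs. Unit tests use shorter simulations (documented in the test
  file); the acceptance suite runs the defaults.
- **Seeds.** Every stochastic entry point takes an explicit seed and
  restores the caller's RNG state (`withr::with_seed`). Grid sweeps
  derive one seed per grid point (`seed + index`) — simpler than the
  originally considered per-run hash, still reproducible and
  parallelisable at the grid level, with all runs of one point sharing
  a single vectorised stream.

## Synthetic data: what it does and does not establish

The generators emulate the *shapes* of the processed inputs the
pipeline consumes, at their published sizes: a co-regulatory network of
19 TFs with 14 expected TF–TF co-regulation edges (density
14/171) and 373 targets each regulated by 1–3 TFs; a layered
signalling cascade of 6×40 proteins (≈ the 244-node upstream network)
ending in 6 shared TFs, with ~15 % complexes of 2–3 members; directed
edges split roughly half activation / half inhibition as in the global
network; DEG tables with a planted fraction of FDRs below 0.1; and
2387 variant rows with independent uniform VDA/EI scores. Uniform
nulls are used for all scores because the pipeline only thresholds
them; consequently the kept fraction at (0.7, 0.7) is 9 %, not the
enrichment a curated database shows — parameter *recovery*, not
realism, is what these tests certify. A green synthetic test
establishes that merging, extraction, thresholding and the engines
recover exactly what was planted; it says nothing about inference
quality on real expression data, which is out of scope (the upstream
machine-learning and differential-expression steps are consumed as
already-processed tables).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_threshold` | 0.1 (strict `<`) | DEG selection on corrected p-values |
| `vda_min`, `ei_min` | 0.7 (inclusive `>=`) | variant filter; "lower than 0.7" is removed |
| `steps`, `burn_in`, `runs` | 2000 / 500 / 50 | simulation length, transient discard, replicates |
| `max_conjuncts`, `max_literals` | 4 / 3 | solver DNF bounds |
| enumeration limits | 24 / 16 free vars | exhaustive / asynchronous engine caps |

## Known limitations

- The full published model (38 nodes, 59 interactions; 23 after
  reduction) is shown only as a figure and its exact topology is not
  recoverable; the fixture is the 13 tabulated species. The 614-node
  global network, 244-node upstream network and the DisGeNET variant
  counts likewise depend on external data and are documented but not
  reproduced or asserted.
- Dose–response *curves* are checked only for qualitative properties
  (monotonicity within two standard errors, IL6+TGFB1 synergy, flat
  zero under no input); published numeric curves are figure-only.
- Co-regulation edges are treated as non-directional evidence: ignored
  by directed traversals and removed before any dynamics.
- The SIF dialect carries no node-kind annotation, so kinds survive
  only through the in-memory containers and the JSON export, not
  through SIF round-trips.
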