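---
title: "An interactive-activation model of perception-action interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An interactive-activation model of perception-action interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitec)
```

## The model

This package simulates a localist interactive-activation network in which
stimulus perception and response planning share one representational medium,
following the Theory of Event Coding: a *feature code* such as "Left" is
connected both to the sensory codes that register left-side stimulation and,
through learning, to the motor codes whose action effects occur on the left.
When the same feature code serves to encode a stimulus and to plan a
response, the overlap produces stimulus-response compatibility phenomena —
the Simon effect, its task-dependent inversion, Stroop-like interference,
action-effect learning and response-effect compatibility — without any
paradigm-specific machinery.

The network has four representational levels: **sensory** layers (one per
modality-dimension, e.g. auditory pitch, auditory location, haptic
location), **feature** layers (distal, modality-independent codes), one
**task** layer of generic codes T1, T2, ... whose meaning derives entirely
from instruction wiring, and one **motor** layer. Every code is one
excitatory unit (localist coding) with a paired inhibitory unit; paired
units propagate inhibition to the other excitatory units of the same layer,
implementing winner-take-all competition within each layer while
between-layer connections are cooperative.

### Dynamics

On every cycle all units are updated synchronously by the shunting rule

$$A_i(t+1) = (1-d_a)\,A_i(t) + \gamma\,\big(\mathrm{Exc}_i\,(1-A_i(t)) +
\mathrm{Inh}_i\,A_i(t)\big),$$

with activations bounded in $[0,1]$. Excitatory input decomposes as
$\mathrm{Exc}_i = \mathrm{ExcVI}_i + \mathrm{ExcVD}_i + \mathrm{Ext}_i +
\mathrm{Noise}_i$: a voltage-independent sum of weighted unit outputs
(feedforward signalling), a voltage-dependent top-down term, external
stimulation (sensory units only; also the driven motor unit during
babbling), and independent Gaussian noise per excitatory unit per cycle.
Unit output passes through the sigmoid $F(a) = a^{na}/(qa^{na} + a^{na})$.
Inhibitory input is the negatively weighted output of the competing units'
pairs.

Top-down feedback from feature codes onto sensory codes is *voltage
dependent*: it is multiplied by $\max(A_i(1-d_a) - VT,\,0)/(1-VT)$, so a
sensory unit that lacks feedforward (stimulus) support receives exactly
nothing from above — feedback can sensitize perception but cannot
hallucinate a stimulus. This gate is what lets a task set "attend" to a
dimension: stimulated sensory codes whose feature codes are task-connected
get amplified; unstimulated ones stay silent.

A trial starts from the resting level, holds a constant stimulus, and ends
when a motor unit reaches the response threshold; the cycle count is the
reaction-time proxy. No mapping from cycles to milliseconds is attempted.

### Ideomotor learning

Only feature-to-motor weights are learned, one-way, by a bounded Hebbian
rule applied once per babbling trial:

$$w_{jk} \leftarrow (1-d_w)\,w_{jk} + \mathrm{Act}_j\,\mathrm{Act}_k\,(1-w_{jk}),
\qquad \mathrm{Act} = \max\!\Big(0, \frac{A - LT}{1 - LT}\Big).$$

Repeated identical co-activation converges to the fixed point
$w^\* = c/(d_w + c)$ with $c = \mathrm{Act}_j \mathrm{Act}_k$, so weights
plateau rather than saturate and decay protects against accidental
co-activations. A learning trial drives one motor code until it crosses the
response threshold ("execution"), then presents its action effects by
stimulating the scheduled sensory codes for 50 cycles.

Two implementation choices here were genuinely open and deserve note:

* **Which activations enter the update.** Recurrent feedback makes feature
  activations peak partway through the effect window and sag as competing
  loops settle; a single end-of-trial snapshot under-measures precisely the
  co-activation the association should record, and does so by different
  amounts in different model instances. The update therefore uses each
  unit's *mean activation over the effect window*, applied once at the end
  of the trial.
* **Clamped babbling.** The packaged experiments pin the driven motor code
  at full activation (`clamp_motor = TRUE`). If the babbled code is instead
  driven through the input equation, motor-layer competition lets weights
  learned on earlier trials suppress whichever code happens to be trained
  second — an artifact of the round-robin schedule with no analogue in the
  modeled studies, which breaks the symmetry between the two responses.

### Task internalization

An instruction like "when you hear a high tone, press the left key" becomes
pure wiring: High→T1 plus T1→{Left, Key}, each link bidirectional
voltage-independent. Four weight roles are distinguished, because they do
different jobs: stimulus-feature→task (`feature_task`) carries the
discriminative evidence; task→response-feature (`task_feature`) carries the
instructed response; response-feature→task (`response_task`) lets active
response features support their task option (this back-edge is what routes
task activation toward the 'Key' feature during learning and thereby biases
effect acquisition); task→stimulus-feature (`task_stimulus`) is the
recurrent sensitization of the instructed stimulus dimension. The first is
kept largest so that the instructed stimulus dimension, not the response
features it shares codes with, decides which task option wins; the last is
kept small so feedback biases, but cannot impersonate, stimulation.
Re-instructing a model touches only feature-task edges; learned weights
survive verbatim, which is exactly what the action-effect-learning
experiment (phase-two rewiring) requires.

## The five packaged experiments

Each experiment is two seeded phases: 20 alternating babbling trials with
50-cycle effect presentation, then test conditions of 100 trials each
(defaults; both configurable). Groups within an experiment share every byte
of configuration except the task instruction or the effect schedule.

* **Action-effect learning** (`elsner_hommel`): keypresses produce tones
  during learning; tones then become imperative stimuli mapped either
  consistently with learning (non-reversal) or inverted (reversal). The
  learned tone→motor associations help in the first case and fight the
  instructed route in the second.
* **Response-effect compatibility** (`kunde`): forceful/gentle keypresses
  produce loud/soft tones, consistently or inconsistently per group. Both
  intensity sensations share distal intensity feature codes; the task's
  'Key' connection makes the haptic component dominate effect coding, so
  inconsistent auditory effects dilute, rather than cancel, the learned
  weights.
* **Simon** (`simon`): respond to pitch with a left/right key; tone
  location is irrelevant but shares the location feature codes with the
  response.
* **Stroop** (`stroop`): the same structure under a color-word renaming —
  the builder literally renames the Simon configuration, and matched seeds
  give bit-identical results (a structural-isomorphism check the test suite
  asserts).
* **Inverted Simon** (`hommel_inversion`): keypresses flash a light on the
  opposite side; instructing "press the key" vs "flash the light" differs
  only in task edges, yet inverts which location dimension dominates
  action-effect learning and with it the direction of the compatibility
  effect. The two instances are mirror images; with noise the printed means
  differ slightly, and the noise-free symmetry is exact (also asserted).

The neutral conditions of the location experiments present the relevant
(pitch) stimulus with no location input at all; the studies report neutral
means without describing the stimulus construction, and omitting the
lateralized input is the cleanest reading.

Wiring details reconstructed from the published figure captions rather than
stated outright — which sensory codes ground the generic 'Sound', 'Key' and
'Light' codes, and the learning-phase instruction of the action-effect
experiment ("see the cue, press a key", internalized as Square→T1→Key and
Square→T2→Key) — are recorded in the builder functions
(`experiment_elsner_hommel()` and friends) as the package's reading.

## Parameters

All numeric parameters are global across layers and shared by all five
experiments. The published account of this architecture defers its numeric
constants to an appendix that is not part of the running text, so this
package ships a parameter set calibrated once, with `calibrate_params()`
and a deterministic (noise-free) variant of the five experiments, against
two constraints stated in the source account: every experiment must
reproduce its qualitative effect ordering with the correct response
selected and zero omissions, and the per-condition mean cycle counts should
approximate the printed ones. The calibration surfaced four regimes the
prose itself motivates:

* **No saturation.** External input and feedback weights are set so sensory
  units settle in the sensitive range of $F$ rather than at the ceiling;
  a saturated unit transmits no difference, and the task-set enhancement
  that drives the response-effect and inverted-Simon results is a
  *difference* between nearly equal sensory activations.
* **Steep output functions.** With $na$ well above 1 the within-layer
  competition actually commits: the symmetric state of two equally driven
  feature codes is unstable, so the small task-induced asymmetry during
  effect perception resolves into a clear winner within the 50-cycle
  window.
* **Sensitive inhibitory units.** The paired units use their own
  half-saturation (`qa_inh` below `qa`), placing them on the steep part of
  their output function at the activations they actually reach.
* **A threshold corridor.** The response threshold sits above the transient
  the wrong response reaches in conflict trials and below the level the
  correct response settles at — that corridor is what turns conflict into
  a delay rather than an error, and it is why the incompatible conditions
  take roughly twice as long rather than failing.

The shipped defaults (see `network_params()`, `learning_params()`,
`default_weights()`) are those calibrated values, and
`inst/extdata/params_default.yaml` carries the same set in file form.

## What the simulations do and do not show

The trial generator emulates the *structure* of the behavioral studies —
instruction, babbling, seeded stochastic test trials — not their empirical
messiness: there are no error responses (conflict resolves or the trial is
an omission, which is reported), no trial-to-trial carryover, no fatigue or
practice effects, no reaction-time distributions beyond per-cycle Gaussian
input noise, and no anatomical coding (the behavioral asymmetry between the
key and light groups in the original inversion study is explicitly outside
the model, whose two groups are exactly symmetric). Passing tests therefore
show that the architecture's mechanisms produce the right orderings and
approximate magnitudes under the stated conditions; they do not validate
the model against raw human data.

Numerical choices: activations are clamped to $[0,1]$ after each update
(the shunting form does not strictly guarantee the bounds under negative
noise) and clamp events are counted in the trace; exact motor ties are
reported as ties, not broken silently; every trial draws its noise from a
stream derived from (experiment seed, trial index), so any condition is
reproducible in isolation; the trial cap is 250 cycles and a trial that
reaches it is an omission, never an answer.

Two quirks of the shipped configuration deserve explicit mention. First,
because the weight decay applies to every learnable weight on every
babbling trial and the motor codes alternate, the code babbled last ends
the phase with weights one decay factor fresher than its partner; near the
decision bifurcation this small asymmetry can decide how costly a conflict
trial is, which is why the canonical Simon conditions probe the response
whose weights carry the full conflict. Second, task feedback to the
instructed stimulus dimension is active during babbling, so the pitch (or
color) codes named in the rules acquire moderate direct associations to
their instructed motor codes — an anticipatory, instruction-induced
component of action-effect learning rather than a confound, but one to be
aware of when reading the learned weight matrices.

## Problem sizes

The packaged defaults — 20 learning trials, 100 test trials per condition,
networks of 14–24 excitatory units — run the full five-experiment battery
in well under a minute on a laptop core; the test suite uses smaller trial
counts per condition where only orderings or invariances are asserted.

## Known limitations

Single-object scenes only (no feature binding), one action at a time, no
online learning during the test phase, no conflict monitoring or
error-driven adjustment, and cycle counts are not calibrated to
milliseconds. These match the stated scope of the modeled account; the
notes above flag where this package had to make a choice the account left
open.
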