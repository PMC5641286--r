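# hitec

An R simulator for a connectionist account of how perception and action
planning interact. The package is aimed at cognitive modelers who want to
reproduce, probe, or extend stimulus–response compatibility simulations —
the Simon effect and its instruction-driven inversion, Stroop-like
interference, action–effect (ideomotor) learning and response–effect
compatibility — inside one fixed architecture, rather than with one ad-hoc
model per paradigm.

## The model in brief

Localist coding units are organized in layers at four levels: sensory codes
(one layer per modality–dimension), distal feature codes shared by
perception and action, generic task codes (T1, T2, ...), and motor codes.
Within a layer, paired inhibitory units implement winner-take-all
competition; between layers, excitatory connections are cooperative. On
every cycle all units update synchronously by a shunting rule

    A(t+1) = (1 - d_a) A(t) + γ [ Exc (1 - A(t)) + Inh A(t) ],

where excitatory input sums voltage-independent feedforward input, a
voltage-dependent top-down term — feedback from feature to sensory codes is
gated by `max(A (1-d_a) - VT, 0) / (1-VT)`, so top-down input alone cannot
activate a sensory code — external stimulation, and Gaussian noise. Unit
output passes through `F(a) = a^na / (qa^na + a^na)`.

Feature→motor weights are not fixed: they are acquired by motor babbling
under a bounded Hebbian rule with learning threshold `LT` and decay `d_w`,
so a motor code comes to be addressed by the perceptual effects it
produces. A task instruction is internalized purely as bidirectional wiring
between feature codes and task codes. Reaction time is the number of cycles
from stimulus onset until a motor code crosses the response threshold.

## A worked example

Fit the Simon-task model — build the network, internalize "high tone →
left key; low tone → right key", run 20 babbling trials in which each
keypress is felt at its location — then test it:

```r
library(hitec)

es  <- hitec_experiment("simon")
fit <- hitec(es$groups$instructed$spec, seed = 1)

round(coef(fit), 2)          # learned feature -> motor weights
#>         M1   M2
#> High  0.53 0.00
#> Low   0.00 0.54
#> Left  0.90 0.00
#> Right 0.00 0.92
#> Key   0.91 0.92

predict(fit, c("Auditory high", "Auditory left"))   # compatible trial
#>   winner cycles   tie omission
#> 1     M1     19 FALSE    FALSE
predict(fit, c("Auditory high", "Auditory right"))  # incompatible trial
#>   winner cycles   tie omission
#> 1     M1     32 FALSE    FALSE
```

The left-key motor code M1 is selected in both cases — the instructed
(pitch) route prevails — but the task-irrelevant tone location moves
selection time by a factor of 1.7: the Simon effect. The felt key
locations (`Left`, `Right`) and the generic `Key` code acquire the
strongest weights; each pitch code also forms a weaker association with
the motor code its task rule points at, because the internalized
instruction is already active during babbling and feeds pitch features
back into the learning episode. A full seeded experiment aggregates such
trials:

```r
run_experiment(hitec_experiment("simon", n_trials = 100, seed = 1))
#> Experiment 'simon' (100 trials/condition):
#>   instructed   compatible         19.0 cycles (SD 0.0, omissions 0)
#>   instructed   neutral            24.0 cycles (SD 0.0, omissions 0)
#>   instructed   incompatible       31.6 cycles (SD 0.5, omissions 0)
```

Five experiments ship as seeded configurations:
`elsner_hommel` (action–effect learning with reversed vs non-reversed test
mapping), `kunde` (response–effect compatibility), `simon`, `stroop`
(structurally the Simon model under a color-word renaming), and
`hommel_inversion` (keypresses flash a contralateral light; instructing
"press the key" vs "flash the light" inverts the Simon effect). A thin CLI
wraps the same functions:

```sh
Rscript scripts/hitec_run.R run --experiment simon --trials 100 --seed 1 --out results/
Rscript scripts/hitec_run.R trace --experiment simon --condition incompatible --trial 1 --out results/
```

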