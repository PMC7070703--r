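# dyadsleep

Minute-by-minute analysis of paired human–dog actigraphy during shared
sleep periods.

People who share a bed with their dog report sleeping well, while
objective actigraphy suggests pets fragment sleep. Resolving that tension
requires looking *within* the night: does the dog's movement in one minute
change what the person does in the next? `dyadsleep` is built for exactly
that question. It takes per-minute activity summaries for each partner
(wrist-worn device for the human, collar-mounted for the dog), a morning
sleep diary, and produces the complete dyadic movement analysis:
thresholded binary movement states, simultaneous co-occurrence tables,
four-state transition dynamics, per-origin transition regressions,
movement-bout comparisons, and night-level mixed models linking objective
movement to subjective sleep ratings.

## The models at the core

Each partner's epoch-level activity is thresholded into a binary movement
state (human: ≥ 91 SVM_gs, the 1.1 MET level; dog: ≥ 400 cpm), giving the
dyadic state sequence over {Both, HumanOnly, DogOnly, Neither}. Within
each night, lag-one transitions are tabulated and the human's movement
dynamics are modeled as two logistic transition regressions — the
discrete-time equivalent of a two-state Markov model with covariates:

    logit P(h_t = 1 | h_{t-1} = 0) = β0 + β1·d_{t-1} + β2·w_t     (onset)
    logit P(h_t = 0 | h_{t-1} = 1) = γ0 + γ1·d_{t-1} + γ2·w_t     (settling)

with `d_{t-1}` the dog's lagged movement state and `w_t = t/(T−1)` the
proportion of the night elapsed. `exp(β1)` is the odds multiplier that
prior dog movement puts on human movement onset, reported with 99%
confidence intervals. Human movement bouts (maximal runs of the moving
state) are compared by a Wilcoxon rank-sum test according to whether dog
movement immediately preceded onset, and nightly summaries feed linear
mixed models — including a random-intercept model of the 1–5 diary rating
on the dog's nightly moving proportion, with a variance decomposition into
fixed / between-dyad / residual shares.

A calibrated generator (`simulate_study()`) produces synthetic studies of
coupled two-state chains — cross-excitation between partners, night-time
drift, dyad- and night-level heterogeneity, lognormal activity emissions,
and diary ratings tied to dog activity — so every estimator in the package
is validated closed-loop against known truth. See the methods vignette
(`vignettes/dyadsleep-methods.Rmd`) for model details and design choices.

## Worked example

Simulate a 12-dyad study, run the full analysis, and render the report:

```r
library(dyadsleep)

study <- simulate_study(sim_params(), seed = 20)
write_study(study, "demo")

cfg <- pipeline_config(epochs = "demo/epochs.csv",
                       diary  = "demo/diary.csv",
                       out_dir = "demo/out")
run_analyze(cfg)
run_report(cfg)
cat(readLines("demo/out/report.txt"), sep = "\n")
```

```
Nights analyzed: 120 (7.3 h mean monitoring)
Human onset probability: 0.061 after dog movement, 0.024 otherwise (raw odds 2.51)
Dog onset probability: 0.095 after human movement, 0.051 otherwise (raw odds 1.86)
Transition-model odds ratios:
  Dog Movement Present, No Move to Move: OR 2.60 [2.21, 3.06]
  Dog Movement Present, Move to No Move: OR 0.59 [0.46, 0.77]
  Proportion of Night Passed, No Move to Move: OR 1.29 [1.02, 1.64]
  Proportion of Night Passed, Move to No Move: OR 1.03 [0.71, 1.50]
Bout durations: 1.75 min (dog-preceded, n=346) vs 1.68 min (n=1076), W=194356.5, p=0.164
Movement correlation over nights: r=0.11, t(118)=1.16
Variance shares: fixed 4.5%, between-dyad 41.9%, residual 53.7%
Dog-disturbance reports: 20 of 120 nights
```

Reading the output: the human moved in 2.4% of minutes after a still dog
but 6.1% after a moving dog (raw ratio 2.5); the model's onset odds ratio
of 2.60 [2.21, 3.06] says prior dog movement multiplies the odds of the
person starting to move by about 2.6 on this particular simulated study
(generating value 2.98), while the settling OR of 0.59 means a moving dog
keeps the person moving. The influence is asymmetric — the human raises
the dog's onset odds less (raw ratio 1.86). Onset odds also rise slightly
across the night (OR 1.29 per full night). The output directory also
contains the co-occurrence and transition tables, per-bout records, night
summaries, a machine-readable `model.json`, and a one-character-per-epoch
text raster of each night's four dyadic states (`.` neither, `h` human
only, `d` dog only, `B` both).

A thin command-line wrapper with the same functionality ships in
`inst/cli/dyadsleep.R` (`simulate`, `analyze`, `report` subcommands).

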