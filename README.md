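# engagekit

Measuring the engagement of autistic children during robot-assisted
therapy sessions from face-visible video.

Therapy sessions with a social robot are recorded by the robot's camera;
therapists want an objective, frame-by-frame measure of whether the child
is engaged. `engagekit` implements such a measure end to end, for
researchers and clinical engineers working on robot-assisted autism
therapy (RAAT) who need a reproducible, testable reference pipeline:

1. **Per-frame engagement.** Engagement is defined on Russell's
   circumplex model of affect: a frame is *engaged* exactly when the
   child's affective state has positive valence **and** positive (high)
   arousal. Frames are classified by a small convolutional network over
   rasterized 68-point facial landmarks (iBUG-300W scheme):
   conv(32, 3×3) + ReLU + 2×2 max-pool, conv(32, 3×3) + ReLU + pool,
   conv(64, 3×3) + ReLU + pool, flatten, dense → 2 classes.
2. **Session-level percentages.** Per task,
   `EPM = 100 · (engaged frames) / (total frames)` from the model, and
   `EPT = 100 · (sum of points) / (maximum points)` from the therapist's
   8-item, 0–3-scale behaviour-assessment sheet (24 points max/task).
   Per child, the overall percentage is the unweighted mean of the task
   percentages, rounded half-up.
3. **Agreement.** Each child's EPM and EPT are binarized at the
   inclusive 50% threshold and compared with Cohen's kappa,
   `κ = (p_o − p_e) / (1 − p_e)`, interpreted on the standard bands
   (≤0 none, ≤0.20 slight, ≤0.40 fair, ≤0.60 moderate, ≤0.80
   substantial, ≤1.00 almost perfect).
4. **Synthetic sessions.** Clinical recordings of children cannot be
   redistributed, so the package ships a fully labelled synthetic
   generator: schematic faces whose mouth-corner height encodes valence
   and whose eye/mouth opening encode arousal, a two-state Markov chain
   for engagement dynamics, configurable landmark noise and face
   dropout, and correlated therapist sheets. Every pipeline stage is
   validated against this generator's ground truth.

## Worked example

```r
library(engagekit)

# a labelled three-task synthetic session (19 s / 8 s / 19 s at 10 fps)
cfg <- sessionConfig(taskDurationsS = c(19, 8, 19), landmarkNoisePx = 0,
                     noFaceProb = 0, seed = 21)
sess <- simulateSession(cfg, tempfile("session"))

# train the convolutional classifier on 2000 rendered frames
ds <- engagementTrainingSet(2000, noisePx = 0, seed = 11)
model <- trainClassifier(buildClassifier(classifierSpec(seed = 11)),
                         ds$x, ds$y, epochs = 5, seed = 11)
model@valAccuracy
#> [1] 0.98

# analyze the session: per-task EPM and the child's overall
res <- analyzeSession(sess$framesDir, model)
res$task_metrics[, c("task_id", "n_frames_total", "epm_percent")]
#>   task_id n_frames_total epm_percent
#> 1  task01            190    41.57895
#> 2  task02             80    37.50000
#> 3  task03            190    25.78947
res$overall_epm_percent
#> [1] 35

# model truth: the generator says 32.6% of frames were engaged, so the
# session-level estimate is within a few points of the ground truth
100 * mean(sess$manifest$engaged)
#> [1] 32.6087

# therapist sheets for the same tasks, and the agreement workflow
truth <- tapply(sess$manifest$engaged, sess$manifest$task_id, mean)
sheet <- simulateAssessment(as.numeric(truth), raterNoiseSd = 0.1, seed = 2)
epts <- sapply(1:3, function(i) computeEPT(sheet[i, ]))
epts
#> [1] 37.50000 37.50000 29.16667
aggregateChildEPT(epts)
#> [1] 35

# published five-child endpoint: reconstruct the printed overalls and
# the model-vs-therapist agreement
rep <- reproduceTable3()
rep$per_child$recomputed
#> [1] 84 13 41 15  9
rep$kappa; rep$band
#> [1] 1
#> [1] "almost_perfect"
```

The per-child reconstruction returns 84, 13, 41, 15 and 9; all except
the second child match the published overalls exactly (the second
differs by one point because the published overall was evidently
computed from unrounded task values). Binarizing both raters at 50%
labels the children identically (engaged, then four not engaged), giving
κ = 1 — almost-perfect agreement.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/engagekit-cli.R` with subcommands `simulate`, `train`,
`analyze`, `agree` and `reproduce-table3`.

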