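# loomdyn

Integrated analysis of looming-threat experiments: psychophysical modeling
of judged time-to-collision, pupillometry preprocessing and functional
analysis, and Markov-chain characterization of behavioral–pupillary state
dynamics.

## The problem

In a looming paradigm, a stimulus expands on screen at a constant velocity,
disappears, and the participant presses a key at the moment they judge it
would have collided with them. The judged time-to-collision (jTTC) measures
temporal threat processing; concurrent pupillometry measures the arousal
dynamics that accompany it. Pharmacological studies with this paradigm
(e.g., vasopressin or angiotensin-receptor blockade arms against placebo)
ask three linked questions, each of which is one stage of this package:

1. **Psychophysics.** How does subjective collision time map onto actual
   time-to-collision (aTTC)? The core model is Stevens' power law,
   `jTTC = α · aTTC^β`, where `α` captures overall over/underestimation
   and `β < 1` indicates temporal compression that accelerates with longer
   aTTCs. It is fitted per subject and condition by least squares and
   compared with a linear baseline `jTTC = α + β·aTTC` via AIC/BIC;
   treatment/sex/threat effects on the fitted parameters are tested with
   linear mixed-effects models.
2. **Pupillary trajectories.** Traces are cleaned, down-sampled into 10-ms
   bins, baseline-corrected against the 0–300 ms pre-stimulus window,
   mapped onto a unified time scale by a piecewise-linear warp (stimulus
   epoch → [0, 0.5], imagination epoch → [0.5, 1]), smoothed with penalized
   cubic B-splines, and decomposed by functional PCA into a mean function
   plus orthonormal eigenfunctions with per-trial scores
   (`diameter(t) ≈ mean(t) + Σⱼ scoreⱼ·φⱼ(t)`), retaining components by the
   >85% cumulative / >5% individual variance rule.
3. **State dynamics.** Trials are assigned to eight behavioral–pupillary
   profiles (E1–E4 / L1–L4) by two-level k-means (log jTTC, then FPCA
   scores within each behavioral subgroup), and each subject's profile
   sequence is analyzed as a first-order Markov chain: stationary
   distributions, occupancy contrasts with adjusted standardized residuals,
   transition contrasts with subject-level bootstrap CIs, attractor states,
   and trigram block entropy as a sequence-flexibility index.

No raw data ships with the package. A first-class synthetic-data generator
(`sim_config()`, `generate_*()`) emulates the full study — a 5 (aTTC) × 4
(category) × 2 (initial size) factorial of 160 trials per subject, three
arms with configurable effects on `α`/`β`, tonic pupil level, component
scores, and per-arm transition matrices — so every stage is testable and
every reported number is recomputable.

## Worked example

The `analysis/` directory is a numbered end-to-end run over a synthetic
cohort (3 arms × 12 subjects × 160 trials, seed 2026):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_behavior.R
Rscript analysis/04_trajectories_fpca.R
Rscript analysis/05_profiles.R
Rscript analysis/06_dynamics.R
```

Outputs land under `results/`. The run prints, among others:

```
fitted 72 subject x condition cells; power law preferred in 59.7%
armLT on beta: -0.200 [-0.254, -0.146], p = 3.92e-10
armAVP on alpha: +0.418 [0.298, 0.538], p = 2.62e-09
FPCA shares: 63.4% 19.8% 8.1% 1.7%; retained components: 1,2,3 (cumulative 91.4%)
level 2 (E): k = 4; bootstrap ARI 0.571 +/- 0.219; CV accuracy 0.830 +/- 0.159
occupancy contrast: chi2(14) = 1401.54, p = 7.58e-291
generator chains: entropy ordering LT > AVP > PLC
```

Reading those numbers: the mixed model recovers the injected Losartan
compression of `β` (configured −0.15) and the vasopressin inflation of `α`
(configured +0.30) with CIs covering the truth; FPCA retains three
components whose shares mirror the configured 62:18:7 variance ratio under
noise; level-2 clustering selects k = 4 per behavioral subgroup, giving the
eight profiles; and the per-arm generator chains reproduce the configured
entropy ordering (near-uniform LT most flexible, E1-anchored placebo most
rigid). Stage 6 also shows an instructive contrast: profile sequences
*fitted* from trial-level data carry arm differences in occupancy but not
in temporal dynamics, because the generator draws each trial's behavior and
pupil response independently — only the generator's own state sequences
carry the configured chain structure.

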