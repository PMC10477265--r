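# phaseresetr

Phase-resetting rate analysis of resting EEG, and its within-person
correlation with depressed mood.

## The problem

Most EEG biomarkers of depression separate patients from controls on
long-term cognitive signatures, and fail at the harder, more useful task:
tracking how depressed *mood* moves from day to day inside one person.
One candidate signal is **phase resetting** — abrupt realignments of an
ongoing oscillation's phase, visible in a wavelet decomposition as an
amplitude minimum coinciding with a jump in instantaneous angular speed.
How often resets occur (per oscillation cycle) turns out to co-vary with
the mood score measured at the same session, positively at some analysis
frequencies and negatively at others, with the crossover frequencies
specific to the individual.

phaseresetr implements that analysis end to end for anyone working with
short resting-state recordings from few-channel devices: readers for EDF
and per-channel CSV, session quality filtering, the time–frequency
decomposition and reset detector, correlation curves, and the
permutation test for the curve's alternating "swing". A synthetic
resting-EEG generator with planted reset/mood coupling makes the whole
pipeline testable without any real data.

## The statistics

For each channel and each of 40 grid frequencies
$f_k = 32\cdot 2^{-(k-1)/10}$ Hz (~2.1–32 Hz, 10 per octave), a session's
bandpassed signal (1–40 Hz) is decomposed with an analytic Morlet wavelet
($\omega_0 = 6$) into phase $\varphi_f(t)$ and amplitude $A_f(t)$, with
1.5 s trimmed from each end. The **relative angular speed**

$$RAS_f(t) = \frac{\varphi_f(t) - \varphi_f(t-\Delta t)}{2\pi f \Delta t} - 1$$

(wrap-corrected by $\pm 2\pi$) measures how much faster than $f$ the
phase advances. A **reset event** is a strict local minimum of $A_f$
with $|RAS_f(t) - \overline{RAS_f}| > 0.05$; the **phase resetting
rate** is events per cycle, $PRR_f = \#\text{events}/(T \cdot f)$.

Per participant, $PRR_f$ is correlated with the session-wise
Depression–Dejection scores (Pearson $r$, Spearman $r_s$ reported
alongside). The test statistic is the **swing magnitude**: over every
three consecutive alternating local extrema $(p_1, p_2, p_3)$ of the
$r$-versus-frequency curve, the maximum of
$|r(p_2) - \tfrac{1}{2}(r(p_1) + r(p_3))|$, maximised over channels. Its
null distribution comes from a **constrained permutation test**: score
shuffles are accepted only if $|r(\text{shuffle}, \text{original})| \le
0.5$, so the null genuinely breaks the feature–score association, and
10,000 accepted shuffles give $p = \#\{\text{null} > \text{observed}\}/10{,}000$.

## Worked example

Simulate a 14-session study with coupling −0.5 events/s per score SD at
8 Hz and +0.5 at 16 Hz, then run the pipeline:

```r
library(phaseresetr)
study <- generate_study(synth_config(seed = 42L))
qc <- filter_sessions(study$sessions)
features <- extract_features(qc$included)
scores <- setNames(vapply(qc$included, function(s) s$dd_score, 0L),
                   vapply(qc$included, session_id, ""))
test <- constrained_permutation_test(features, scores,
                                     analysis_config(n_permutations = 1000L))
print(test)
```

```
Constrained permutation test of the PRR CC swing
  participant SIM, n = 14 sessions
  max swing over channels: 1.652 (channel F8)
  null (1000 accepted permutations): 1.122 +/- 0.137
  p-value: < 0.001
  characteristic frequencies (Hz): + {4.29, 6.5, 17.1}  - {8, 13, 24.3}
```

The observed swing (1.652) is the largest alternation found in any
channel's PRR correlation curve; the null mean ± SD describes the swing
sizes that score shuffles produce by chance; "p < 0.001" says no
accepted shuffle among 1000 beat the observed value. The planted
couplings surface as a negative characteristic frequency at exactly 8 Hz
and a positive one at 17.1 Hz (one grid step from the planted 16 Hz);
the remaining entries are noise peaks that clear the n = 14 reference
bound (|r| ≥ 0.53), a reminder that characteristic-frequency lists at
small n need the permutation test behind them.
`plot(test$curves, channel = test$best_channel)` draws the correlation
curve with reference significance bounds, and `participant_summary()`
assembles the per-participant results table.

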