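---
title: "Jitter-based spike synchrony: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jitter-based spike synchrony: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jbsi)
```

## The model

Given two simultaneously recorded spike trains on a shared epoch $[0, T]$
(milliseconds throughout), the slower-firing train is the *reference*
($n_1$ spikes at $t^1_i$) and the other the *target* ($n_2$ spikes at
$t^2_k$). A reference spike is *coincident* when it lies within the
synchrony span $\tau_S$ of at least one target spike; the observed count
$N_C$ counts each reference spike at most once, so $N_C \le n_1$ and the
coincidence rate $R_C = N_C/n_1 \in [0, 1]$. No binning is involved, so
near-coincident spikes cannot be split across a bin edge.

The null model is *virtual uniform jitter*: each reference spike is
independently displaced by a uniform offset in $[-\tau_J, +\tau_J]$,
$\tau_J \ge \tau_S$. Jitter destroys coordination on time scales faster
than $2\tau_J$ while leaving the local firing rate — and hence every
coincidence driven by slow rate co-modulation — intact. The probability
that spike $i$ is synchronous after jitter is purely geometric:

$$p_i = \frac{1}{2\tau_J}\,\bigl|\,[t^1_i - \tau_J,\ t^1_i + \tau_J] \cap
U\,\bigr|, \qquad U = \bigcup_k\,[t^2_k - \tau_S,\ t^2_k + \tau_S],$$

computed here by merging the sorted target windows into disjoint segments
(a sweep-line pass) and accumulating the overlap of each jitter window via
a cumulative-coverage lookup, $O((n_1 + n_2)\log n_2)$ overall. The
jittered count is then a sum of independent non-identical Bernoulli trials:
a Poisson-binomial variable with mean $\sum_i p_i$, variance
$\sum_i p_i(1 - p_i)$, and an exact pmf computable by the one-row
recursion $P_m(N) = p_m P_{m-1}(N-1) + (1 - p_m)P_{m-1}(N)$
($O(n_1^2)$ time, $O(n_1)$ memory).

From these the package reports the Z-score
$Z = (N_C - \sum p_i)/\sqrt{\sum p_i(1-p_i)}$, a p-value, and the
normalized index

$$\mathrm{JBSI} = \beta\,\frac{N_C - \sum_i p_i}{n_1}, \qquad
\beta = \begin{cases} 2 & \alpha \le 2\\ \alpha/(\alpha-1) & \alpha > 2
\end{cases}, \quad \alpha = \tau_J/\tau_S .$$

At $\alpha \le 2$ the JBSI is bounded in $[-1, 1]$: for isolated,
perfectly coincident spikes each $p_i = 1/\alpha$, making the index equal
$R_C$ (hence 1 at full synchrony), and in the opposite extreme (every
reference spike just beyond $\tau_S$, $N_C = 0$, $p_i \to 1/2$) it reaches
$-1$. Negative values mean *less-than-expected* synchrony under the jitter
null, not anti-phase firing.

## Parameters

* `tauS` (ms, > 0) — synchrony span; half-width of the coincidence window.
  Choose it at the temporal precision of interest (default 1 ms).
* `tauJ` (ms, ≥ `tauS`) — jitter span. Values below `tauS` are rejected: so
  small a jitter would preserve both chance and real coincidences. The
  default is `2 * tauS` ($\alpha = 2$), the ratio that maximizes the
  dynamic range of the index (larger $\alpha$ compresses the attainable
  negative range to $-1/(\alpha - 1)$); at $\alpha = 2$ the scaling is
  simply $\beta = 2$.
* p-values are **two-tailed** by default. The method's significance
  convention ties $Z = 3.3$ to $p = 0.001$, which is the two-tailed normal
  tail; one-tailed variants are available via `alternative`. `pMode =
  "exact"` uses the Poisson-binomial tail (doubling the smaller tail,
  capped at 1) and refuses $n_1 > 10^4$, where the normal approximation is
  indistinguishable anyway.
* Reference/target roles follow the fewer-spikes rule (`assignRoles`),
  jittering the shorter train; ties keep the first train, and an override
  exists for deliberate asymmetric designs.

## Numerical conventions

* Coincidence uses closed intervals ($|\Delta t| \le \tau_S$). The boundary
  has measure zero under continuous jitter; a fixed convention keeps the
  integer counts reproducible.
* Synchrony windows that exactly abut (gap = 0) merge into one segment.
* Jitter windows are **not** truncated at the epoch boundaries: the
  geometric $p_i$ has no boundary correction, so jittered spikes may
  conceptually leave $[0, T]$.
* Probabilities are clamped to $[0, 1]$ against floating-point overshoot in
  densely covered regions.
* If every $p_i \in \{0, 1\}$ the null is degenerate: Z and the normal
  p-value are reported as `NA`, while the JBSI (which needs only the mean)
  is still returned.
* The recording epoch is $[0, T]$ with $T$ an explicit input (or the
  largest spike time rounded up to an integer ms when inferred from a
  file). The epoch convention matters only for the *classical* indices,
  whose expected chance count $2\tau_S n_1 n_2 / T$ scales with $T$; the
  jitter statistics never use $T$.

## Classical comparison indices

For benchmarking, the package computes the cross-correlogram (all pairwise
lags, central bin symmetric about 0) and the classical indices, with
$\langle N_C\rangle = 2\tau_S n_1 n_2/T$ by default or, optionally, the
off-center CCG flank average (bins with $|$lag$| \in [5\tau_S, 25\tau_S]$):

* ECI $= (N_C - \langle N_C\rangle)/n_1$ and ECIcor
  $= (N_C - \langle N_C\rangle)/(n_1 - \langle N_C\rangle)$;
* CCC, the $\sqrt{K-1}$-normalized hypergeometric Z-score with
  $K = \mathrm{round}(T/2\tau_S)$ bins (the derivation treats $K$ as an
  exact integer; real epochs rarely divide evenly, and at $K \gg n_2$ the
  rounding is immaterial), CCCmax $= \sqrt{(K/n_2-1)/(K/n_1-1)}$ and
  CCCcor $=$ CCC/CCCmax, which is algebraically identical to ECIcor;
* the JSSI, $Z/\sqrt{(\alpha-1) n_1}$, kept for continuity with earlier
  work but superseded by the JBSI (it retains a negative rate dependence).

These indices presuppose stationary Poisson firing; the test suite
reproduces their characteristic failures (ECI declines with rate, CCC with
the rate differential, both report spurious synchrony under rate
co-modulation) and the JBSI's robustness in the same conditions.

## The simulator

`simulatePair` emulates paired extracellular recordings: per 1 ms bin a
spike fires when a uniform draw falls below rate·bin; its time is uniform
within the bin; after a spike the bins covering the next 2 ms are blocked
(absolute refractory period). This renewal process emits
$p/(1 + 2p)$ spikes per ms at per-bin probability $p$, below the nominal
rate — `epochForSpikeCount` inverts that correction, and the default epoch
(24222 ms at 45 Hz) targets the canonical ~1000-spike trains. Coincidences
are injected by selecting reference spikes with probability $D$ and moving
each to within $\pm C$ of the *next* target spike at or after it (the
destination reading of "shifted forward"; the displacement is uniform in
$\pm C$, the minimal assumption, and consistent with the sweep cutoff
landing at $\tau_S = C$). Afterward the refractory period is re-enforced
on the shifted train by deleting the later spike of any violating pair —
deletion of the later spike preserves more of the just-injected
coincidences. Selected spikes with no later target spike stay put
(≤ 1 spike per train), and shifted spikes landing outside the epoch are
dropped. With $M > 0$ both rates are multiplied by a rectified sinusoid
$|\sin(2\pi t/1000)|^M$ (1 s underlying period, hence a 0.5 s modulation
period), normalized by quadrature so the time-averaged rate — and thus the
expected spike count — is unchanged. All draws come from one seeded
generator in a fixed order (train 1 bins then placements, train 2, then
selection mask, then displacements), so a seed fully reproduces a pair.

The simulator emulates stationarity violations only through this smooth
shared modulator. It does not produce bursting, serial interspike
correlations beyond refractoriness, spike-sorting noise, or common input
with synaptic delay — so passing tests demonstrate correctness of the
statistics under the stated generative model, not robustness to every
failure mode of real recordings.

## Temporal-precision estimation

`sweepPrecision` evaluates the pair(s) over a geometric $\tau_J$ grid
(default 1–16 ms in $\sqrt2$ steps, $\alpha = 2$ fixed), averaging Z and
JBSI across runs per grid point — averaging the derived statistics, not
the counts, matching the five-run averaging the curves are meant for.
Two read-outs:

* `zThresholdCrossing` — the smallest $\tau_J$ whose averaged Z reaches
  the threshold (default 3.3 ↔ two-tailed $p = 0.001$), refined by linear
  interpolation in $(\log\tau_J, Z)$ between the bracketing grid points
  (log, because the grid is geometric). A curve already above threshold at
  the first point returns it flagged `atFloor`; a curve never reaching it
  returns not-found. No multiple-comparison correction is applied across
  the grid — the sweep is an estimation, not a testing, procedure.
* `jbsiCutoff` — the JBSI-vs-$\tau_S$ curve falls steeply to the left of
  the system's precision and shallowly to the right. The "steep drop-off"
  is formalized as the smallest grid $\tau_S$ reaching 90% of the curve
  maximum; the fraction is tunable, and 0.9 reproduces the injected
  precision $C \in \{1, 2, 4\}$ ms on regenerated simulations (see the
  acceptance tests).

## Problem sizes and verification

The test suite verifies the exact distribution against full $2^n$
enumeration ($n \le 12$), the probability geometry against a $10^5$-draw
Monte-Carlo jitter and against the disjoint-window closed form, and the
analytic moments against $10^4$ explicit surrogates (including a
chi-square of the surrogate histogram against the exact pmf). Simulation
properties use ~1000-spike trains with 5 seeds per grid point (the
five-run averaging of the precision figures), 10 seeds for the
co-modulation contrast, and 200 runs for null calibration. These sizes
give stable verdicts for every property while keeping the full suite in
the tens of seconds.

## Limitations

* Strictly bivariate and zero-lag: no multi-train extension, no lagged
  ($L \ne 0$) synchrony windows, and no time-resolved sliding-window
  index.
* The jitter null assumes rate co-modulations are slow relative to
  $2\tau_J$; co-modulation approaching the jitter time scale will be
  partially destroyed by the jitter and counted as synchrony.
* Exact p-values are quadratic in $n_1$ and capped at $n_1 = 10^4$.
* File input is plain text (per-train columns or two-column CSV) only.
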