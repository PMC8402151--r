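---
title: "Single-shell DEP spectrum analysis: model, fitting and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shell DEP spectrum analysis: model, fitting and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcell)
```

## The physical model

A cell in a non-uniform AC field experiences the dielectrophoretic
force $F = 2\pi\varepsilon_m r^3\,\mathrm{Re}[K(\omega)]\,\nabla E^2$,
where the Clausius–Mossotti factor
$K = (\varepsilon_p^* - \varepsilon_m^*)/(\varepsilon_p^* + 2\varepsilon_m^*)$
compares the complex permittivities
$\varepsilon^* = \varepsilon - j\sigma/\omega$ of particle and medium.
For physical materials ($\varepsilon > 0$, $\sigma \ge 0$) the real
part of $K$ is bounded in $[-0.5, 1]$, a property the test suite
verifies over $10^4$ random parameter sets.

The cell is modelled as a **single-shell sphere**: cytoplasm of
conductivity $\sigma_{cyt}$ and relative permittivity
$\varepsilon_{cyt}$, wrapped in a membrane of thickness $d$. We use the
canonical smeared-shell reduction: with $\gamma = r/(r-d)$ and
$E = (\varepsilon_{cyt}^* - \varepsilon_{mem}^*)/(\varepsilon_{cyt}^* +
2\varepsilon_{mem}^*)$,

$$\varepsilon_{cell}^* \;=\; \varepsilon_{mem}^*\,
\frac{\gamma^3 + 2E}{\gamma^3 - E}.$$

The membrane is parameterised by its *specific* (per-area) quantities —
effective conductance $G_{eff}$ (S/m²) and capacitance $C_{eff}$
(F/m²) — because those are what whole-cell measurements report. The
nominal thickness $d$ enters only through
$\sigma_{mem} = G_{eff}\,d$ and $\varepsilon_{mem} = C_{eff}\,d$, so
results are invariant to $d$ inside the thin-shell regime
($d < r/100$); the default is the conventional lipid-bilayer value
$d = 5$ nm, and the suite checks that moving $d$ between 1 and 10 nm
shifts the spectrum by less than $2\times10^{-3}$ in Re[K]. An
independent thin-shell approximation
($\varepsilon_{cell}^* \approx r C_{mem}^* \varepsilon_{cyt}^* /
(r C_{mem}^* + \varepsilon_{cyt}^*)$ with
$C_{mem}^* = C_{eff} - jG_{eff}/\omega$) lives in the test helpers as
an oracle and agrees with the full formula to better than 1% at
$d/r \le 10^{-3}$.

Two permittivities are fixed rather than fitted: the aqueous
iso-osmotic buffer at $\varepsilon_{m,rel} = 78$ and the cytoplasm at
$\varepsilon_{cyt,rel} = 60$. Whole-cell DEP tables report three free
parameters per group ($G_{eff}$, $C_{eff}$, $\sigma_{cyt}$), which
implies permittivities were held constant; both constants are exposed
in `dep_fit_control()` and `dep_medium()` for other conventions. The
medium conductivity defaults to 0.15 S/m, the standard
sucrose/dextrose DEP buffer adjusted with PBS.

## Measurement model and fitting

Well-plate DEP readers energize 20 wells at 20 log-spaced frequencies
(default band 1 kHz – 45 MHz) and report a relative light-intensity
change per well. We model it linearly:
$I_i = s\,\mathrm{Re}[K(\omega_i)] + b + e_i$, $e_i \sim N(0,
\sigma_{noise})$, with the gain $s$ a free nuisance parameter.

**The baseline $b$ is fixed at zero by default.** This was a genuinely
open design choice, settled by computation: the reader's output is a
*relative* intensity change, zero-baselined by construction, and at
realistic noise a free baseline makes the inversion ill-posed — a
nearly flat high-$G_{eff}$/high-$C_{eff}$ spectrum stretched by a
large gain attains a *lower* residual than the true solution (we
measured runaway fits pinned at the $G_{eff}$ bound in the majority of
replicates, with group means off by several hundred percent). Set
`fit_offset = TRUE` when an instrument export carries a genuine
baseline; noise-free and low-noise spectra remain exactly identifiable
with it, which is how the round-trip tests exercise that path.

`dep_fit()` minimises the sum of squared residuals with bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), restarted
from a $3\times3\times3$ log-spaced grid over
$(G_{eff}, C_{eff}, \sigma_{cyt})$; at each start the gain (and
baseline, if freed) is pre-solved linearly. The lowest residual wins;
numerical ties break toward lower $G_{eff}$. Bounds bracket literature
chondrocyte values with wide margins: $G_{eff} \in [0, 10^5]$ S/m²,
$C_{eff} \in [10^{-3}, 10^{-1}]$ F/m², $\sigma_{cyt} \in [0.01, 2]$
S/m, gain $> 0$, baseline unbounded. Convergence tolerances are
$10^{-12}$ (relative) with up to 200 iterations per start — on a
20-point spectrum a full 27-start fit takes ~0.3 s.

A fit is **accepted** only if the optimiser converged and the Pearson
correlation between the best-fit curve and the data (computed on the
model values, not residuals) exceeds 0.9 — reading the exclusion rule
"R of 0.9 or less" strictly, so $R = 0.9$ exactly is excluded. Constant
intensity vectors, where the correlation is undefined, are rejected
with the explicit status `"degenerate-data"`.

The crossover finder scans Re[K] on a 200-point log grid and refines
each sign change by bisection to relative tolerance $10^{-9}$; the
returned roots satisfy $|\mathrm{Re}[K]| < 10^{-6}$. The textbook
low-frequency closed form
$f_{x1} = \sqrt{2}\sigma_m/(2\pi r C_{eff})$ is reproduced within 5%
*only in its validity regime* — negligible membrane conductance and
$\sigma_{cyt} \gg \sigma_m$. For the healthy-chondrocyte parameter set
($G_{eff} = 8571$ S/m², $\sigma_{cyt}/\sigma_m \approx 1.7$) the true
root sits ~14% above the closed form; the membrane-conduction term is
not small there, and tests respect that.

## The synthetic cohort generator

The generator emulates the experimental design: per group, 4
biological repeats (independent cell preparations) × 3 technical
repeats (re-measurements). For each biological repeat one
$(r, G_{eff}, C_{eff}, \sigma_{cyt})$ tuple is drawn from independent
normals truncated at zero, using the published group means ± SD as the
generating distribution; technical repeats share that tuple and differ
only through per-well Gaussian noise. The five presets
(`table_presets()`) carry the printed group values verbatim — equine
control/chronic/acute TEA and canine control/OA-induced.

Default noise is 5% of the noiseless spectrum's peak-to-peak
amplitude, which keeps fitted $R$ values almost always above the 0.9
acceptance threshold, as in accepted experiments. One master seed per
cohort drives both the parameter draws and deterministic per-sample
noise streams, so cohorts are byte-reproducible.

What the generator does **not** emulate: correlations between
parameters within a cell (no covariance information is published; the
printed OA whole-cell capacitance of 9.58 pF exceeds the
$4\pi r^2 C_{eff}$ of the OA group means, ≈ 6.3 pF, which only a
positive per-repeat radius–$C_{eff}$ covariance could explain — that
value is therefore not a recovery target); cell-to-cell variability
within a well (the reader averages ~20 000 cells); pearl-chaining,
electrode effects and multi-shell (nucleated) dielectric structure.
Passing recovery tests on this generator shows the *inverse problem*
is solved correctly under the published design, not that real 3DEP
data are this well behaved. The published radius tables also imply an
≈35% OA radius increase while the accompanying text says 20%; the
generator follows the tables.

## Statistics

Technical repeats are averaged (accepted fits only) into one estimate
per biological repeat; the biological repeat is the statistical unit
($n = 4$), the conservative choice given that group SDs are reported
at that level. Whole-cell capacitance is computed per repeat from its
own radius and $C_{eff}$, then summarised — not from the product of
group means. Group differences use the unpaired two-tailed t-test,
pooled-variance by default (the common default in commercial stats
software) with Welch as an option; no multiple-testing correction is
applied, matching the original analysis; p-values are reported exactly
alongside the conventional star code (* < 0.05 … **** < 0.0001).

## Known limitations

At the default 5% noise the membrane conductance is **weakly
identified per spectrum** when the gain is free: profiling the
noise-free residual along $G_{eff}$ (re-optimising the other
parameters) shows the residual rises by only ~$10^{-3}$ between
$G_{eff}=0$ and $8571$ S/m², an order of magnitude below the noise
floor $n\sigma^2 \approx 1.25\times10^{-2}$ — the gain can almost
exactly mimic a change in $G_{eff}$, which sets the depth of the
low-frequency plateau. Group means over 12 spectra remain usable
(median error < 10% across seeds), but per-repeat scatter spans much
of the allowed range, so Acute-vs-Control significance on $G_{eff}$
at $n = 4$ reproduces only rarely on synthetic cohorts, even though
$C_{eff}$ (significant) and $\sigma_{cyt}$ (not significant) reproduce
in ~9/10 replicate experiments. Recovering the published $G_{eff}$
contrast statistically would need lower well noise (~2%) or a
calibrated gain; we report this rather than quietly changing the
simulated conditions.

## Problem sizes used by the tests

The suite runs entirely on synthetic data built in code: 20-point
spectra; five noise-free round trips; 10-seed replicate studies of
4 × 3 cohorts for recovery and significance checks; $10^4$-draw
law-of-large-numbers checks of the generator; $10^4$ random parameter
sets for the Re[K] bound. The full suite completes in a few minutes on
one core.
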