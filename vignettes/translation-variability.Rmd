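---
title: "Translation variability of multirate wavelet decompositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation variability of multirate wavelet decompositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftwave)
```

## The model

A `J`-level decimated wavelet decomposition splits a length-`N` signal
`x(n)` into detail subspaces `w_1 … w_J` and one approximation subspace,
by iterating a two-channel filter bank: circular convolution with an
orthonormal lowpass/highpass pair followed by downsampling by 2. Level-`j`
detail carries `N / 2^j` coefficients; the `J+1` full-length subspace
reconstructions (each band zeroed except one) sum exactly to `x`. Detail
band `j` nominally occupies the theoretical spectral passing band
`TSPB{w_j} = [fs/2^(j+1), fs/2^j]`.

Because of the decimation, the analysis operator does not commute with
translation. Writing `S_s` for the circular right shift by `s` samples and
`P_j` for the projection onto subspace `j`, the decimated transform only
satisfies `P_j S_s = S_s P_j` when `s` is a multiple of the band's
decimation factor. That is the translation variability (TV) this package
measures. Its structure is dyadic:

* detail band `j` has TV period `2^j` — the smallest `s > 0` with
  `P_j S_s x = S_s P_j x` exactly;
* the approximation band has period `2^J` (forced by the coarsest
  decimation grid; see "Numerical and design choices" below);
* the redundant transform has period 1 in every band: removing the
  down/upsampling makes each band a plain circular convolution of the
  input, i.e. a linear time-invariant map.

The redundant transform is implemented by the à trous scheme: at level `j`
the filters are dilated by inserting `2^(j-1) - 1` zeros between taps and
applied without decimation. We keep the sqrt(2)-normalized filters at every
level and compensate with a factor 1/2 per level in the inverse. This
normalization is deliberate: it preserves the subsampling identity — the
decimated level-`j` coefficients are exactly the redundant level-`j`
coefficients at indices `0, 2^j, 2·2^j, …` — which is the strongest
cross-check linking the two transforms and is asserted in the tests.

## Filter construction

Daubechies filters of order `p` (2`p` taps, `p` vanishing moments) are
computed by spectral factorization of the maxflat half-band polynomial:
the roots of the degree-`(p-1)` binomial polynomial are mapped to
reciprocal root pairs in `z` and the in-circle root of each pair is kept,
giving the minimum-phase (extremal-phase) solution; the product with the
`(1 + z^{-1})^p` factor is normalized to sum sqrt(2). Nothing is
hard-coded, so any order up to 20 works; beyond that the factorization is
too ill-conditioned in double precision and the constructor refuses.
Published coefficient tables serve as test oracles, not as the source.

Which phase convention (minimum-phase vs its time reverse) underlies a
given published figure of subspace waveforms is generally not stated; we
fix minimum-phase everywhere. Magnitude spectra, energies, TV periods,
pattern counts and LTI/LTV verdicts are all unaffected by that choice.

Conventions fixed once and used by every module:

* filters stored causally, applied by circular convolution;
* decimation keeps the even-index samples (offset 0) — required for the
  subsampling identity to hold coefficient-for-coefficient;
* "shift by `s`" means circular right shift (`n -> n + s mod N`);
* equivariance comparisons shift the baseline output by `s` (equivalent,
  under circular shifts, to un-shifting the test output).

## Boundary handling

All convolutions are circular (periodic extension). This is what makes the
package's exactness claims true *as equalities*: perfect reconstruction,
subspace additivity, the redundant transform's shift invariance and the
subsampling identity all hold to ~1e-14 with no boundary caveats, because
the periodized orthonormal family remains an orthonormal basis for every
even length at each level. Signal lengths must be divisible by `2^J`;
padding is refused rather than applied, since padding would inject its own
shift artifacts into precisely the quantity this tool measures. For the
delta experiments (impulse at the center of `N = 1000`) the boundary is
inert anyway.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `order` | 8 | Daubechies order; db8 (16 taps) is the conventional choice in biomedical work and the basis of the reference experiments |
| `levels` | 3 (1000 Hz delta), 4 (200 Hz EEG) | decomposition depth `J`; at 200 Hz, `J = 4` puts `TSPB{w_3} = [12.5, 25]` and `TSPB{w_4} = [6.25, 12.5]` Hz around the alpha/beta rhythms |
| `tolerance` | 1e-10 | absolute equivariance threshold; machine-precision congruence sits ~6 orders below, genuine TV ~8 orders above |
| `rel_tolerance` | 1e-8 | relative L-infinity threshold for counting distinct magnitude-spectrum patterns |
| `max_period` | `2^(J+1)` | exhaustive TV-period search bound; brute force over `1..max_period` is its own oracle at these sizes |

## The synthetic generators

`delta_impulse()` and `shifted_family()` reproduce the impulse experiments
exactly (0-based impulse index; energy preserved per member). `synth_eeg()`
stands in for real ictal recordings: seeded white noise bandpassed (in the
frequency domain) into the four conventional rhythms delta/theta/alpha/beta
with amplitudes 1/0.6/0.45/0.25, a 1/f background at relative RMS 0.4, and
Mexican-hat transients (~40 ms, amplitude 3, Poisson rate 0.5/s) supplying
epileptiform-like sharp events. Those values were chosen once as a
plausible ictal-like mix whose energy is concentrated below 40 Hz (the
generator contract requires >= 80%; the realized fraction is ~0.99). The
surrogate reproduces the gross spectral shape and the transient content
that TV distorts; it does **not** model physiology (no neural mass
dynamics, no multichannel structure, no EMG/baseline-wander artifacts), so
tests passing on it demonstrate correctness of the transforms and
diagnostics, not clinical realism.

## Numerical and design choices

* **Convolution via FFT.** Circular filtering is done in the frequency
  domain; round-off stays ~1e-14 for `N <= 1000`, far below every
  tolerance used.
* **Approximation-band period.** The dyadic period statement for the
  approximation band is sometimes written ambiguously as `2^j` with
  `j = J+1`; the decimation structure forces `2^J`, and the package's
  exhaustive search confirms `8` for `J = 3`. We implement and document
  `2^J`.
* **Vanishing moments check.** The raw moment `sum(n^p g[n])` cancels to
  machine precision *relative to its terms*; at order 10 and `p = 9` the
  absolute residual is necessarily ~1e-5 in doubles. `validate_filterbank()`
  therefore reports the residual scaled by `sum |n^p g[n]|`, which is
  < 1e-10 for all supported orders.
* **Approximation-band TSPB** is defined as `[0, fs/2^(J+1)]`, the
  complement of the detail bands.
* **Ties in `empirical_spb()`** (equal-width minimal windows) resolve
  toward lower frequency, matching the low-frequency concentration of the
  signals this is used on.
* **Pattern counting** is greedy in input order against class
  representatives: deterministic, and its count (not its labels) is stable
  under permutation at the separations that occur here (~16 orders of
  magnitude between "same" and "different").
* **Sentinel for period search**: when no shift up to `max_period` restores
  equivariance, `max_period + 1` is returned rather than an error, so
  reports can render "no period found".

## Scope and limitations

Problem sizes follow the reference experiments (`N = 1000` deltas, 10–10.24
s surrogates at 200 Hz, orders 1–10, depths 1–3(4)); all suites run in
seconds. Library cross-checks (PyWavelets) bridge the convention gap
explicitly: our analysis lowpass equals the library's reconstruction
lowpass; its decimated coefficients correspond to ours on the time-reversed
input with an order-dependent circular shift; its undecimated bands match
ours after the same reversal bridge with shift `(Ltap/2 - 1)(2^j - 1)`.
Only the dyadic orthonormal Daubechies family is provided — biorthogonal,
symlet/coiflet, wavelet-packet, dual-tree complex and rational-dilation
transforms are out of scope, as are EDF/BDF readers and any
classification stage downstream of feature extraction. The cost of exact
shift invariance is the usual one: `(J+1)·N` coefficients instead of `N`.
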