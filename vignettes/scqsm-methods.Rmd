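---
title: "Spinal-cord QSM: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spinal-cord QSM: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quantitative susceptibility mapping (QSM) reconstructs the voxelwise magnetic
susceptibility of tissue from the phase of multi-echo gradient-echo (GRE)
data. In the cervical spinal cord this is substantially harder than in the
brain: the cord is a thin structure (under a centimetre across) surrounded by
strong susceptibility sources (vertebral bone, fatty marrow, air), tissue
contrasts are roughly an order of magnitude weaker than cortical iron
contrast, and fat in and around the vertebrae perturbs the phase evolution
that field fitting relies on. `scqsm` implements a complete reconstruction
chain for a dual-series acquisition designed for this problem, together with
a numerical phantom that stands in for acquired data at every stage.

# Signal model

Without fat, the complex GRE signal at echo time $TE_n$ is
$s(TE_n) = a(TE_n)\,e^{-i 2\pi \Delta B\, TE_n}$, where $\Delta B$ is the
total field shift in Hz. With a fat component the model becomes

$$s(TE_n) = e^{-R_2^* TE_n}\Bigl(\rho_W + \rho_F \sum_{k=1}^{K} \alpha_k
e^{-i 2\pi \Delta f_k TE_n}\Bigr) e^{-i 2\pi \Delta B\, TE_n},$$

with water and fat complex amplitudes $\rho_W, \rho_F$ at $TE = 0$, apparent
transverse relaxation rate $R_2^*$, and a $K$-peak fat spectrum with
chemical shifts $\Delta f_k$ and relative amplitudes $\alpha_k$ summing to
one. All internal code works with $\Delta B$ in Hz; conversions use
$\bar\gamma = 42.577\,\mathrm{MHz/T}$.

The fat spectrum is a tunable object (`fat_spectrum()`). The default is a
six-peak model at $(-3.80, -3.40, -2.60, -1.94, -0.39, +0.60)$ ppm with
amplitudes $(0.087, 0.693, 0.128, 0.004, 0.039, 0.048)$ (renormalised); a
single-peak option whose beat period is exactly the 2.46 ms in-phase spacing
is provided for closed-form verification. The acquisition context gives no
definitive $K/\Delta f_k/\alpha_k$, so the spectrum is deliberately a
configuration parameter rather than a constant.

# Acquisition protocol

Two bipolar 3D GRE series are acquired at 3 T (TR 33 ms, 12 echoes each,
$0.4 \times 0.4 \times 1\ \mathrm{mm}$ voxels, 12° flip, 1000 Hz/pixel):
one on the water-fat in-phase (IP) times and one on the out-of-phase (OOP)
times. Gradient limits forbid the nominal first in-phase time of 2.46 ms, so
the first IP echo sits at 2.64 ms and is only *partially* in phase (PIP);
the IP train then snaps back to the nominal grid (4.92, 7.38, ... ms). The
OOP train is regular from 3.69 ms. `build_schedule()` therefore generates
`[TE1, TE2, TE2 + dTE, ...]` with `TE2` an explicit protocol field — the
displaced first echo makes the naive `TE1 + n dTE` rule wrong for the IP
series. Merging both series (`merge_schedules()`) interleaves 24 echoes with
1.05/1.23 ms gaps and keeps per-echo provenance so image volumes can be
gathered in merged order. A PIP label is applied when the first IP echo
misses the in-phase grid by more than 0.01 ms, which is also the duplicate
tolerance for merges; sub-microsecond differences are below protocol
precision.

# The phantom

`build_phantom()` creates a 2.5D cervical geometry: a 4 mm-radius cord with
a parametric gray-matter "H" (two slender dorsal and two larger ventral
horns plus a central commissure, built from overlapping ellipses), WM as the
cord complement, a CSF ring to 6 mm, and a vertebral body (3.5 mm radius,
centred 8.5 mm anterior) carrying bone susceptibility and a 0.5 fat
fraction. Default relative susceptibilities are GM $+3.1$ ppb and WM $-0.7$
ppb — the measured cord values — with CSF at 0; the bone value ($-2000$
ppb) and all $R_2^*$/proton-density numbers are generator defaults chosen to
exercise the pipeline (realistic orders of magnitude, not measurements).
Only susceptibility *differences* are observable, so the absolute offset is
arbitrary and set to zero. The vertebral proton density is modulated along
$z$ ($\pm 30\%$, one period over the volume) to emulate the vertebral
body/disc alternation; without some axial structure the phantom would be
translation-degenerate along $z$ and registration would be untestable.
Default noise is complex Gaussian with per-component standard deviation 2%
of the peak magnitude (SNR 50 at the first echo). Lesions are painted as
spheres inside the cord at the measured category means (+1.5, $-0.4$,
$-3.6$ ppb), with a "rim" pattern adding a one-voxel $+3$ ppb shell around
a hypointense core.

What the phantom does *not* emulate: motion, flow, partial-volume mixing at
tissue borders, coil sensitivity structure, realistic vertebral anatomy, or
$B_0$ inhomogeneity beyond susceptibility sources. Passing tests therefore
demonstrate algorithmic correctness on the stated model, not clinical
robustness.

## Forward model

The field is generated in k-space: $\Delta B = \bar\gamma B_0\,
\mathcal{F}^{-1}\!\left[D(k)\,\mathcal{F}[\chi]\right]$ with
$D(k) = 1/3 - k_z^2/|k|^2$ and $D(0) = 0$, computed on a grid zero-padded by
a factor 2 per axis and cropped, which suppresses circular-convolution
wraparound. The same operator is used by the simulator, the background-field
solver and the inversion, so recovery tests exercise a self-consistent
chain. One caveat worth stating: the *discretely sampled* k-space kernel is
not pointwise identical to the continuum dipole $\,(3\cos^2\theta - 1)/
(4\pi r^3)$ at short range near the polar axis and the equatorial plane (the
multiplier is discontinuous at $k \to 0$, and the truncated oscillatory
spectrum converges only weakly). For smooth, extended sources the two agree:
the test suite checks the FFT field of a Gaussian blob against brute-force
direct summation of the continuum kernel (a few percent RMS, correlation
above 0.999), which is the regime the phantom occupies.

# Field estimation

Both estimators run on the merged 24-echo train after translation
registration of IP onto OOP and bipolar offset correction.

**Registration** estimates a 3D subvoxel shift by regularised phase
correlation between the first-echo magnitudes (integer peak with
nearest-to-zero tie-breaking, then a weighted least-squares fit to the
cross-spectrum phase slope restricted to low frequencies). Axes without
spectral content are frozen at the integer estimate — an estimator cannot
localise a shift along a direction in which the image is invariant. The
shift is applied by Fourier phase ramp to the real and imaginary channels
separately, avoiding interpolation of wrapped phase.

**Bipolar offsets.** Reversed-gradient echoes carry a common phase offset
$\psi$. For a phase linear in TE the triplet
$s_n s_{n+2} / s_{n+1}^2$ cancels the linear term and leaves $\mp 2\psi$
depending on which parity carries the offset; the estimator averages the
sign-folded triplet phasors, smooths them over a $3^3$ neighbourhood (the
offset is spatially smooth), and removes half the resulting angle from the
reversed-polarity echoes. Magnitudes are untouched by construction. On the
IP series the first gap (2.28 ms) differs from the rest, contributing a
curvature bias proportional to $\Delta B \cdot 0.18\,$ms $\cdot 2\pi$ — for
cord-scale fields this is below 0.02 rad and inside the stated 0.01 rad
residual after averaging.

**Laplacian unwrapping.** The wrap-insensitive estimate
$\nabla^{-2}\left[\cos\varphi\, \nabla^2 \sin\varphi - \sin\varphi\,
\nabla^2\cos\varphi\right]$ is computed spectrally on a mirror-padded grid
(the even extension avoids boundary jumps), the undetermined constant is
restored as the circular mean of (wrapped − estimate) over the mask, and the
result is *snapped to congruence*: the spectral estimate only decides the
integer $2\pi$ count per voxel, the fractional phase is kept exactly as
measured. Wherever the estimate is within $\pi$ of the truth the output
equals the true phase up to one global $2\pi$ multiple — in particular the
unwrapper is exact (not merely approximate) on unwrapped or mildly wrapped
smooth inputs, which is what makes the two field estimators agree to
sub-mHz on noiseless data. The method fails, as any sampled method must,
when the true phase gradient exceeds $\pi$ per voxel.

**Optimum weights (no FWS).** Successive-echo phase differences are
unwrapped and combined as an inverse-variance weighted average of per-pair
rates: $\Delta B = \sum_n w_n \frac{\Delta\varphi_n}{2\pi\,\Delta TE_n} /
\sum_n w_n$ with $w_n = A_n^2 A_{n+1}^2/(A_n^2 + A_{n+1}^2)$ from the echo
magnitudes. This weight is the high-SNR phase-noise limit
($\mathrm{Var}(\Delta\varphi) \propto A_n^{-2} + A_{n+1}^{-2}$); the exact
weighting of the original reference is not restated in the acquisition
context, so the weighted-average-of-rates reading is a declared design
choice. Zero-magnitude voxels are zeroed and dropped from the validity mask.

**R2\*-IDEAL (FWS).** The nonlinear model above is fit per voxel on the
merged grid by variable projection: for fixed $(\Delta B, R_2^*)$ the
amplitudes $(\rho_W, \rho_F)$ are linear and solved from a $2\times 2$
Hermitian system; the two nonlinear parameters are updated by a damped
Gauss-Newton (Levenberg-Marquardt) step with $R_2^* \ge 0$ enforced by
projection and per-voxel damping adaptation, all voxels iterated
simultaneously as flat vectors. Because variable projection recomputes the
amplitudes in closed form at every iterate, the Dixon water/fat initial
value is accepted for interface completeness but does not enter the
numerics; the field starts at the null map (the classical choice) and
$R_2^*$ at the ARLO estimate. Echo phases are pre-unwrapped with the same
Laplacian method (with congruence snapping this leaves the complex data
numerically unchanged — the model is periodic in phase — but mirrors the
sequential unwrap-then-fit pipeline order). Convergence is declared at
relative cost change below $10^{-8}$ or 50 iterations; stalled voxels
(damping exhausted) are flagged in an auxiliary mask. Within the merged
train the per-voxel cost as a function of $\Delta B$ has its first aliasing
lobe roughly $1/T_\mathrm{span} \approx 36$ Hz away, so null initialisation
converges for cord-scale fields; much larger fields would need an
initialisation from the optimum-weights map (available via `init$field0`).

**ARLO.** $R_2^*$ is initialised by auto-regression on linear operations
over a uniformly spaced magnitude train: with $\alpha_i = (\delta/3)(y_i +
4y_{i+1} + y_{i+2})$ (Simpson integral) and $\beta_i = y_i - y_{i+2}$,
$R_2^* = \sum \alpha_i\beta_i / \sum \alpha_i^2$, clipped at zero. The IP
series is non-uniform between its first two echoes, so the pipeline runs
ARLO on the OOP series (uniform 2.46 ms throughout); `skip_first` handles
the IP series when needed. The Simpson bias at $R_2^*\delta \approx 0.12$
is below $10^{-3}\,\mathrm{ms}^{-1}$.

**Two-point Dixon.** The textbook magnitude combination
$|\rho_F| = \bigl||s_\mathrm{IP}| - |s_\mathrm{OOP}|\bigr|/2$ cannot
represent fat fractions above one half (it always assigns the larger
amplitude to water). The implementation therefore uses the phase-corrected
variant: the water phase at the OOP time is predicted by linear
interpolation of the first two IP echo phases, and the *signed* real part of
the phase-corrected OOP signal distinguishes water- from fat-dominant
voxels. Magnitudes are compensated for $R_2^*$ decay between the two echo
times using the ARLO map. With a single-peak fat model at exact IP/OOP
times this recovers fat fractions of 0, 0.4 and 1 to $10^{-6}$.

**Echo weights.** Per-echo SNR is the mean in-mask magnitude over
$1.526 \times$ the raw median absolute deviation of the magnitude in a
noise-only region; weights are squared SNRs normalised to sum to one, with a
uniform fallback (and warning) for empty or degenerate noise regions.

# Background removal (PDF)

The total field inside the measured region is decomposed by projection onto
dipole fields: $\chi_\mathrm{ext} = \arg\min \lVert W(f_\mathrm{total} -
D * \chi_\mathrm{ext})\rVert_2$ with $\chi_\mathrm{ext}$ supported outside
the measured mask, solved by conjugate gradient on the normal equations;
the local field is the masked residual. Two choices matter and are easy to
get wrong at cord scale:

* *What is "outside".* The projection's source support is the complement of
  the **measured** region, not of the cord: in the brain the background
  sources (skull, air) are exactly the unmeasured voxels. Here the measured
  region is the spinal canal (cord + CSF). If external sources are instead
  allowed directly at the cord boundary, they can mimic a large share of the
  interior field (the harmonic component), and the internal-field
  preservation contract fails by a wide margin (16-30% observed). With the
  canal convention the phantom numbers are 0.5% leakage for purely external
  sources and under 5% distortion for purely internal ones.
* *Solver tolerance.* The CG residual tolerance defaults to $10^{-3}$
  (200 iterations maximum): at $10^{-2}$ the external-field solve is
  visibly under-converged (6.6% in-mask residual vs 0.5%). Both values are
  exposed as arguments.

No spherical-mean-value prefiltering is applied (SMV radius 0): the cord
cross-section is a few voxels across and the through-plane resolution is
anisotropic, so an SMV kernel would erode most of the region of interest.

# Dipole inversion (MEDI)

The local field is inverted with an anatomically edge-weighted L1 gradient
prior: $\chi = \arg\min\ \lambda\lVert M_G \nabla\chi\rVert_1 +
\lVert W(f_\mathrm{local} - D * \chi)\rVert_2^2$. The anatomical image is
the voxelwise $\ell_2$ norm of all 24 echo magnitudes; per gradient
direction, the binary mask $M_G$ regularises the voxels whose anatomical
gradient magnitude lies below the 0.7 quantile within the cord mask and
leaves the strong edges free. The solver is iteratively reweighted least
squares on the $\varepsilon$-smoothed absolute value
($\sqrt{t^2 + \varepsilon^2}$, $\varepsilon = 10^{-6}$ on the normalised
field scale) with inner conjugate-gradient solves (warm-started, 50
iterations or $10^{-3}$ relative residual), 10 outer iterations or a
$10^{-2}$ relative update. IRLS with a linear data term replaces the
original Gauss-Newton on a nonlinear exponential data term: for unwrapped
fields in Hz the two share fixed points at small residual and the linear
form is far simpler to verify. The field is normalised to its maximum
before inversion, so $\lambda = 10^{-3}$ (the default) is scale-free; the
output is converted to ppb and referenced by subtracting the global mean
over the mask (`reference_map()`), after which the in-mask mean is zero by
construction.

# Analysis

Per-tissue statistics, lesion records and the with/without-FWS comparison
mirror the quantitative outputs of the study: ordinary least squares of one
map on the other over concatenated in-mask voxels per tissue, Shapiro-Wilk
normality and a paired t-test on per-replicate means (per-subject means in
the in-vivo setting; a voxelwise option exists), significance at 0.05.
Whether the original paired tests ran over voxels or subject means is
ambiguous in the source; per-replicate means are the default here because
voxelwise paired tests on $10^4$ correlated voxels produce meaninglessly
small p-values. Lesions are classified against a WM reference of $-0.7$ ppb
with a $\pm 1$ ppb margin: hyperintense strictly above $0.3$ ppb,
hypointense strictly below $-1.7$ ppb, isointense in the closed interval
between (both printed boundaries are inclusive-isointense because the
source states strict inequalities for the outer categories). The reference
is a configuration field — any new dataset must re-derive it from its own
healthy-control WM.

# Problem sizes and determinism

All tests and the acceptance script run on the 64 x 64 x 16 desk-scale
phantom grid (the full 154 mm field of view is configurable), with smaller
grids for closed-form unit checks. The complete reconstruction of one
phantom takes on the order of two minutes on a single core, dominated by
the padded-FFT convolutions inside PDF and MEDI. Every stochastic input
(noise, test case generation) is seeded; the acceptance script derives all
randomness from its `--seed` argument.

# Known limitations

* The k-space dipole kernel's short-range discretisation error (see the
  forward-model section) means single-voxel point-source fields are not
  meaningful validation targets; extended-source agreement is.
* PDF at cord scale requires the canal convention described above; with a
  cord-only measured region the method's internal/external orthogonality
  degrades substantially.
* The bipolar offset estimator assumes a spatially smooth, echo-parity
  offset; eddy-current offsets with odd spatial structure would need the
  phase-difference polynomial models used on some scanners.
* Fat-water swaps: at very low SNR individual voxels can converge to the
  swapped solution; no graph-cut or region-growing swap resolution is
  implemented (out of scope).
* The phantom's lesions are uniform disks; real lesion heterogeneity (and
  paramagnetic rims) are only qualitatively represented.
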