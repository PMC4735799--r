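---
title: "Models and methods behind egfrswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind egfrswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrswitch)
```

# The biological question

MCF10A mammary epithelial cells adopt a scattered, mesenchymal-like
phenotype when grown on EGF and a clustered, epithelial-like phenotype
when grown on equimolar amphiregulin (AREG); switching the ligand
reversibly interconverts the two states. The proposed mechanism is
quantitative, not qualitative: both ligands activate the same receptor,
but AREG binds EGFR with roughly 10-fold lower affinity, so at the same
1.8 nM dose it produces a much weaker integrated EGFR–ERK signal. Chronic
AREG exposure also leaves more EGFR on the cell surface (weaker
ubiquitination and induced internalization), which partially compensates
for the weaker binding. `egfrswitch` implements the computational pieces
of that argument.

# The receptor trafficking model

## Structure and assumptions

The model is a deterministic mass-action system with five receptor
species: free surface receptor `Rs`, unphosphorylated surface complex
`Cs`, phosphorylated surface complex `Ps`, internalized phosphorylated
receptor `Pi`, and internalized non-phosphorylated receptor `Ri`.
Reactions: ligand binding/unbinding (`kon`, `koff`), phosphorylation /
dephosphorylation at the surface (`kp`, `kdp`), constitutive
internalization of free receptor (`ke0`), induced internalization of the
phospho complex (`ke1 >= ke0`), internal dephosphorylation (`kdpi`),
recycling (`kr`), degradation of non-phospho and phospho internal
receptor (`kdeg`, `kdegP`), and synthesis (`vs`).

This is the minimal trafficking scheme that can express the two
behaviors the analysis rests on: the ligand-dependent phospho-signal
difference, and ligand-dependent surface accumulation (low-occupancy
ligands route less receptor through induced internalization and
degradation). Deliberate simplifications:

* **Ligands differ only in affinity.** `kon` is shared; ligand identity
  enters through `koff = kon * Kd` alone, with `Kd(AREG)/Kd(EGF) = 10`
  (packaged defaults 20 and 200 nM). This encodes the hypothesis that the
  phenotype switch is driven by signal quantity, not quality.
* **Constant ligand.** At nM doses the bulk medium vastly exceeds the
  cellular binding capacity, so `L` is not depleted.
* **No ERK cascade inside the ODE.** The mechanistic model stops at
  phospho-EGFR; ERK curves are generated phenomenologically (below).
  Extending the mass-action system below the receptor would add many
  unidentifiable parameters without changing the receptor-level
  comparisons the package makes.
* **Dimensionless receptor units.** Blots are relative, so absolute
  receptor counts are unidentifiable; the unit convention is that the
  ligand-free steady-state surface pool of the E-cell scenario
  (`r_scale = 1`) equals 1. The A-cell surface scenario uses
  `r_scale = 10`, the measured ~10-fold surface-EGFR excess.

Readouts map species onto measurements: whole-lysate phospho-EGFR is
`Ps + Pi` (RIPA lysates capture all compartments), surface EGFR is
`Rs + Cs + Ps`, total EGFR sums all five pools.

## Initial condition

Stimulations start from the ligand-free steady state (cells deprived of
growth factor for 8 h): `Cs = Ps = Pi = 0` and `Rs`, `Ri` solving the
linear balance `vs = ke0*Rs - kr*Ri`, `ke0*Rs = (kr + kdeg)*Ri`. When the
surface pool is closed (no synthesis and no internalization, or no
degradation route) the balance fixes only ratios and the convention
`Rs = 1` applies; synthesis without any degradation route has no finite
steady state and is rejected.

## Default parameters and their calibration

No parameter values are identifiable from blots alone, so the packaged
defaults are an explicit calibration with two targets: (i) at 1.8 nM the
0–60 min integrated phospho-EGFR ratio EGF:AREG should be close to the
~10-fold difference measured on blots, and (ii) AREG with a 10-fold
surface pool should approximately match EGF at the baseline pool (the
compensation observed in A-cells).

The ratio target constrains the kinetic regime, not just magnitudes.
If phosphorylation outruns dissociation (`kp >> koff(EGF)`), every
binding event commits to the phospho pathway and the integrated signal
becomes nearly affinity-independent (ratios ~2–3). The defaults therefore
put binding in the pre-equilibrated, subsaturating regime:
`kon = 0.1 /nM/min` (so `koff` is 2 and 20 /min for EGF and AREG — fast
against `kp`), `kp = 0.05 /min`, `kdp = 0.3 /min`, `ke0 = 0.02 /min`,
`ke1 = 0.2 /min`, `kdpi = 0.1 /min`, `kr = 0.05 /min`, `kdeg = 0.02
/min`, `kdegP = 0.1 /min`, and `vs = ke0*kdeg/(kr + kdeg)` so the resting
surface pool is 1. In this regime the occupancy ratio
`(L + Kd_AREG)/(L + Kd_EGF) ≈ 9.3` propagates almost linearly to the
integrated phospho signal; receptor depletion and the finite 60-min
window bring the computed fold to 9.0, and the compensation ratio to
0.98. Both are computed, not asserted, by the test suite and
`scripts/acceptance.R`.

Integration uses `deSolve::lsoda` with relative tolerance 1e-8 and
absolute tolerance 1e-10; binding (sub-minute) and trafficking (tens of
minutes) time scales differ enough that a stiff-capable solver is the
safe default. Output states are clipped at zero below an absolute 1e-9
tolerance; larger negative excursions raise an integration error naming
the offending time.

# Parameter estimation

The objective is the plain sum of squared residuals between observed,
reference-normalized intensities and the model prediction normalized by
its own value at the dataset's declared reference point — the same
convention as the data, so the unidentifiable blot scale cancels. Failed
integrations return the documented penalty `1e12`, keeping the search
totally ordered without exceptions.

The global stage is classic self-adaptive ("meta") evolutionary
programming in log10 parameter space (default box `[-4, 2]` per rate):
each individual carries per-coordinate step sizes, offspring are
`x_i' = x_i + sigma_i*N(0,1)`,
`sigma_i' = sigma_i*exp(tau'*N(0,1) + tau*N_i(0,1))` with
`tau = 1/sqrt(2*sqrt(n))`, `tau' = 1/sqrt(2n)`, and survivor selection
over parents plus offspring is by q-tournament (default q = 10). Log
space is essential: rates span orders of magnitude and linear-space
mutation would effectively freeze the small ones.

The local stage is Nelder-Mead (classic coefficients: reflection 1,
expansion 2, contraction 0.5, shrink 0.5) run inside a bound-penalty
wrapper, with a single polish restart from the converged point; the
returned objective never exceeds the starting value. The full protocol
runs independent seeded restart chains (global + local) and keeps the
minimum-objective fit; the reference protocol uses 200 restarts, while
the test suite uses 20 with smaller populations (pop 12, 25 generations),
which is sufficient for the 2-parameter recovery problems it poses.

Identifiability is respected rather than fought: single-condition,
single-dose data constrain mostly downstream kinetics, so the recovery
tests fit `Kd(EGF)` against a two-dose design (1.8 and 18 nM) whose
relative amplitudes pin the affinity. Reproducibility is exact: restart
`i` is seeded `seed + i - 1`, and identical (data, settings, seed) give
bit-identical results.

# Signal quantification

Normalization divides every intensity by the reference band (a stated
condition, target and time — e.g. pERK in EGF-treated E-cells at
10 min), replicate-matched when the reference exists in the same
replicate and by the replicate-mean reference otherwise.

Integrated signal strength is the trapezoidal area under each
replicate's curve over a stated window, linearly interpolated to the
window edges when sampling extends beyond them, then summarized as mean
and SD across replicates (the experimental design is 3 independent
experiments). Trapezoid-on-observations was chosen because densitometry
sampling is sparse and irregular; it is exact for piecewise-linear
signals and its error against a fine-grid quadrature oracle on smooth
pulse shapes is below 0.5% at 1-min sampling.

Re-activation onset is an operationalization of what is read off a
plotted time course: on the replicate-mean signal, find the global early
peak, the subsequent trough, and report the earliest post-trough time at
which the signal exceeds `trough + rise_fraction*(peak - trough)`
(default `rise_fraction = 0.2`) and stays at or above that level at the
next sample. The one-sample persistence requirement rejects single-point
noise spikes; the 20% rise is exposed as a parameter. Monotone signals
return no onset with a reason code. On the packaged A-to-E switch
scenario (second pulse programmed at 160 min, 10-min sampling) the
detector reports 170 min — within one sampling interval, which is the
resolution limit of any threshold detector on sampled data.

# The nucleus–nucleus distance index

Segmentation is Otsu's global threshold (foreground above threshold),
hole filling, and one 3×3 opening — removing sub-element specks.
Counting is 8-connected. Dilation by `d` pixels means `d` iterations of
the 3×3 box element, i.e. Chebyshev radius `d` (the ImageJ binary-dilate
convention), default 5 px ≈ half a cell diameter. The index is
`N5/N0`; two nuclei merge after dilation exactly when their edge-to-edge
Chebyshev gap is at most `2d` pixels. Because dilation can only merge
objects, `N5 <= N0` and the index lies in (0, 1] whenever any nucleus is
found; an empty field is flagged undefined rather than divided.

Known degeneracy: when nuclei physically overlap they already fuse at
the segmentation stage, so `N0` undercounts and the index drifts back up
for extremely tight layouts. This is inherent to the published index
(no watershed splitting is applied, by design — merged nuclei *are* the
cluster signal); the package's Monte-Carlo monotonicity checks therefore
enforce a 1-px minimum gap in generated layouts so the index isolates
the dilation-merge effect.

The pipeline is validated against an independent brute-force oracle that
never touches the image code: per-nucleus rasters are opened by explicit
pixel-shift morphology, pairwise minimal Chebyshev distances are computed
between pixel sets, and components are merged by union-find at thresholds
1 (adjacency, N0) and `2d + 1` (dilation merge, N5). Pipeline and oracle
agree exactly on 50 seeded noise-free layouts.

# Synthetic data

The generators define the study conditions under which everything above
is tested.

**Nuclei images**: cluster centers uniform in the frame, nucleus centers
Gaussian (`cluster_sd`) around them, optionally rejection-sampled to
honor a minimum edge-to-edge gap (computed exactly on the rasterized
disks); nuclei are radius-5 solid disks (≈ half a cell diameter) at
intensity 200 on background 10, plus clipped Gaussian noise (default
SD 5, 8-bit range). Defaults: 512×512 frame, 20 nuclei. Not emulated:
point-spread blur, vignetting, intensity heterogeneity, 3-D structure —
so passing tests demonstrate correctness of the index pipeline, not
robustness to real microscopy artifacts.

**Time courses**: pEGFR comes from the mechanistic model; pERK is a
phenomenological sum of two log-normal pulses (immediate transient
peaking at 10 min; optional re-activation pulse starting at a programmed
onset, default 160 min in the switch scenario, peaking 20 min later at
0.8 relative amplitude) because ERK is outside the ODE model and an
analytic curve gives the quantification tests exact ground truth.
Replicate noise is multiplicative lognormal with CV 0.1 (typical
densitometry variation; mean ratio to the latent curve is exactly 1),
3 replicates by default, sampled every 10 min over 0–60 or 0–310 min.
The four packaged scenarios are `E-EGF`, `E-AREG` (baseline pool,
`r_scale = 1`), `A-AREG` and `A-EGF-switch` (10-fold surface pool),
all at 1.8 nM.

# Numerical and scale choices

* Steady states are solved linearly, never by burn-in integration.
* Equilibrium checks in the suite run 30 binding half-lives so the
  residual transient (2^-30) sits far below the 1e-6 comparison
  tolerance.
* Test problem sizes are deliberately modest — 256×256 oracle layouts,
  20 estimation restarts with populations of 12 — chosen so the entire
  suite exercises every code path in a few minutes while leaving the
  statistical conclusions unchanged; the defaults embedded in the
  functions (200 restarts, population 50) are the reference protocol.
* All stochastic components (generators, meta-EP, multistart) are
  seeded explicitly and reproduce bit-identically per seed on R's
  default Mersenne-Twister generator.

# Limitations

The receptor model is a minimal trafficking scheme: no receptor
dimerization, no ErbB heterodimers, no compartmental/spatial resolution,
and no downstream cascade — it supports claims about relative integrated
receptor-level signals, not about absolute fluxes or ERK dynamics. The
default parameter set is a documented calibration, not a fitted optimum;
any quantitative reuse should re-fit against the user's own data via
`multistart_fit()`. The clustering index inherits the merged-nuclei
degeneracy of the published method and is a relative, not absolute,
measure of clustering.
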