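# egfrswitch

Mammary epithelial cells (MCF10A) can be reversibly switched between an
epithelial-like and a mesenchymal-like phenotype simply by exchanging the
EGFR ligand in the medium: EGF drives strong, sustained EGFR–ERK signaling
and scattering, while its low-affinity cousin amphiregulin (AREG) — dosed
equimolar at 1.8 nM — drives weak signaling and tight epithelial clusters.
`egfrswitch` packages the computational core of that analysis for systems
biologists who want to model, quantify and reproduce it:

1. **Receptor trafficking model** — a mass-action ODE model of EGFR
   binding, phosphorylation, internalization, recycling, degradation and
   synthesis in which EGF and AREG differ *only* in their dissociation
   constant (Kd ratio fixed at 10). Five species:

   ```
   dRs/dt = vs − kon·L·Rs + koff·Cs − ke0·Rs + kr·Ri
   dCs/dt = kon·L·Rs − koff·Cs − kp·Cs + kdp·Ps
   dPs/dt = kp·Cs − kdp·Ps − ke1·Ps
   dPi/dt = ke1·Ps − kdpi·Pi − kdegP·Pi
   dRi/dt = ke0·Rs + kdpi·Pi − kr·Ri − kdeg·Ri
   ```

   with `koff = kon·Kd` and ligand `L` held constant. Readouts map onto
   blot measurements: whole-lysate phospho-EGFR (`Ps + Pi`), surface EGFR
   (`Rs + Cs + Ps`) and total EGFR.

2. **Hybrid parameter estimation** — sum-of-squared-residuals fitting of
   the model to normalized densitometry time courses by self-adaptive
   (meta) evolutionary programming followed by Nelder-Mead refinement,
   over independent seeded restarts (the reference protocol runs 200 and
   keeps the minimum-objective fit).

3. **Integrated signal strength** — normalization of band intensities to
   a reference band, trapezoidal area under the curve over stated windows
   (0–60 min, 0–310 min), fold changes, and detection of the delayed ERK
   re-activation onset (observed from ~160 min after an A-to-E ligand
   switch).

4. **Nucleus–nucleus distance index** — quantification of cell clustering
   in nuclei-stained images: Otsu threshold, fill-hole, opening, count
   nuclei (N0), dilate by 5 px, count merged objects (N5), and report
   `index = N5/N0` (≈1 for sparse fields, →0 for clustered cells).

5. **Synthetic data generators** — seeded nuclei images with controllable
   clustering and ground-truth centers, and noisy phospho-signal time
   courses (mechanistic pEGFR; phenomenological two-pulse pERK) for the
   four packaged stimulation scenarios.

## Worked example

```r
library(egfrswitch)

p <- receptor_params()                      # packaged E-cell defaults
traj <- simulate_receptor(p, ligand_spec("EGF", 1.8), times = seq(0, 60, 1))
r_egf  <- integrated_pEGFR(p, ligand_spec("EGF", 1.8))
r_areg <- integrated_pEGFR(p, ligand_spec("AREG", 1.8))
sprintf("EGF AUC = %.4f, AREG AUC = %.4f, fold = %.2f",
        r_egf, r_areg, r_egf / r_areg)
#> "EGF AUC = 0.8881, AREG AUC = 0.0986, fold = 9.00"
```

Equimolar AREG yields a ~9-fold weaker 1-h integrated phospho-EGFR signal
than EGF — the model's account of the ~10-fold difference measured on
blots, driven purely by the 10-fold affinity gap at a subsaturating dose.

```r
g <- gen_nuclei_image(image_spec(n_nuclei = 20, n_clusters = 4,
                                 cluster_sd = 12, min_gap = 1,
                                 noise_sd = 5, seed = 11))
nn_distance_index(g$image)
#> <cluster_index_result> N0 = 20, N5 = 4, index = 0.2
```

Twenty nuclei in four tight clusters merge into four objects after the
5-px dilation: index 0.2, a strongly clustered (epithelial-like) field.

```r
sc  <- scenario_presets()[["A-EGF-switch"]]
gen <- gen_timecourse(sc, p, seed = 8)
tc  <- normalize_timecourse(gen$timecourse,
                            list(condition = "A-EGF-switch",
                                 target = "pERK", time = 10))
integrated_signal(tc, c(0, 310), condition = "A-EGF-switch", target = "pERK")
#> <signal_summary> A-EGF-switch/pERK: AUC = 76.49 +/- 5.75 over [0, 310] min (n = 3)
reactivation_onset(tc, condition = "A-EGF-switch", target = "pERK")
#> [1] 170
```

The A-to-E switch scenario programs a second ERK pulse rising at 160 min;
with 10-min sampling the detector reports the first persistent crossing
at 170 min, one sampling interval later.

A command-line wrapper for all of the above lives in
`inst/scripts/egfrswitch-cli.R` (subcommands `simulate`, `fit`,
`quantify`, `cluster-index`, `synth-image`, `synth-timecourse`).

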