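# bspim — localizing atrial ectopic beats from body-surface P-wave integral maps

`bspim` is an R package for the non-invasive localization of atrial ectopic
beats (the triggers of focal atrial tachycardia) by forward modelling and
machine learning.  It targets computational electrophysiologists who want a
desk-scale, fully reproducible version of the classic simulate–project–learn
pipeline:

1. **Geometry** — a synthetic biatrial surface model: two ellipsoidal
   chambers with valve/vein orifices, 21 rule-based regions with fiber
   orientations, interatrial connections (Bachmann's bundle, fossa ovalis,
   six coronary-sinus bridges with a 7.5× proximal/distal conductivity
   ratio), a 58-site focus catalog (SAN + 30 RA + 27 LA) and a 252-lead
   front+back torso array.
2. **Propagation** — a monodomain reaction–diffusion solver
   (∇·(D∇V) = C_m ∂V/∂t + I_ion with zero-flux boundaries; surface FEM,
   operator splitting) with a Mitchell–Schaeffer-class membrane model whose
   regional variants are APD-calibrated (shortest: mitral region, 170 ms),
   plus a calibrated anisotropic eikonal solver as a fast surrogate
   (v = v_ref √(σ/σ_ref)).
3. **Forward projection** — per-triangle equivalent current dipoles
   p = −(D_i ∇V)·A in an infinite homogeneous volume conductor,
   Ve(r) = Σ p·(r−c) / (4π σ_t |r−c|³), assembled into body-surface
   potential maps (BSPM).
4. **Biomarker** — the body-surface P-wave integral map (BSPiM): per-lead
   signed ∫Ve dt between P-wave onset (stimulus) and offset (latest atrial
   depolarization), plus RMS/extrema/product maps, global-range
   normalization, and the min→max dipole-axis summary.
5. **Learning** — K-means (k-means++, 10 restarts) and EM clustering of the
   58 BSPiMs into ectopic clusters, a spatial-coherence audit, and a
   one-vs-one RBF SVM (built-in SMO solver) evaluated by stratified 4-fold
   cross-validation.

## Worked example

```r
library(bspim)

mesh  <- assign_fibers_and_regions(build_biatrial_mesh(geometry_params()))
cond  <- build_conductivity(mesh)          # bridge ratio 0.0060/0.0008 = 7.5
foci  <- place_foci(mesh)                  # 58 sites incl. SAN
leads <- build_torso_leads(torso_params(), mesh)   # 252 leads
model <- membrane_model()
single_cell_apd(model, "MV_RING")          # 170.4 ms  (target 170 +/- 2)

sim <- simulate_all_foci(mesh, cond, model, foci, leads, mode = "eikonal")
sw  <- sweep_k(sim$features, k_range = 2:5)
sw[, c("k", "cv_accuracy", "misclassified")]
#>   k cv_accuracy      misclassified
#> 1 2   0.9654762            R22,R28
#> 2 3   0.9821429                L12
#> 3 4   1.0000000
#> 4 5   0.9154762 R7,R18,R22,R27,R28
```

Read: with two ectopic clusters, 56 of the 58 simulated maps are assigned to
the correct atrial region by the cross-validated SVM (96.5 %; the two errors
are interface foci on the septum and Bachmann bundle), mirroring the ~97 %
reported for the full-scale anatomical pipeline.  The whole run takes
~2–3 minutes on one CPU in eikonal mode.

The end-to-end driver writes artifacts and a manifest:

```r
man <- run_full(run_config(), out_dir = "bspim_run")
```

A command-line interface with subcommands (`make-geometry`, `simulate`,
`forward`, `biomarker`, `cluster`, `classify`, `sweep`, `run-full`,
`make-fixture`, `import`) is installed at `inst/cli/bspim`.

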