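---
title: "Methods: muscle-strength sensitivity of knee cartilage stress across gait modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-strength sensitivity of knee cartilage stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsens)
```

## What the package computes

`gaitsens` asks a specific biomechanical question at desk scale: **when the
isometric strength of a lower-limb muscle group is reduced, how much does the
superficial stress on the tibial cartilage change, and does that change depend
on how the person walks?** The pipeline runs, per synthetic participant and
gait style (normal, toe-out, toe-in, wide stance):

1. a seeded **stance-phase gait generator** (kinematics, ground reaction
   force, centre of pressure),
2. **quasi-static inverse dynamics** of the stance limb,
3. **static-optimization muscle recruitment** under the cubic polynomial
   criterion
   $G=\sum_i (f_i/N_i)^3$ subject to $\mathbf{C}\,\bar f = \bar r$, $f_i \ge 0$,
4. assembly of the tibiofemoral/patellofemoral loads and a
   **connector-restrained elastic-foundation contact** solve on the two tibial
   plateaus,
5. the **upper-quartile mean** of superficial contact stress per compartment,
   and
6. the sensitivity statistics
   $\%\text{Change}=\left|\frac{\sigma_\text{reduced}-\sigma_\text{ref}}{\sigma_\text{ref}}\right|\cdot 100\%$
   and
   $\text{PP}_\text{Difference}=\%\text{Change}_\text{modified}-\%\text{Change}_\text{normal}$,
   with paired $t$ tests on peak stresses and a repeated-measures ANOVA with
   Bonferroni post hocs on walking speeds ($\alpha = 0.05$).

Four strength conditions are compared: a reference model and three models
with a **uniform 40% reduction** of the isometric strength of, respectively,
the knee extensors (rectus femoris + three vasti), the hip abductors (gluteus
medius, gluteus minimus, tensor fasciae latae), and the ankle extensors
(gastrocnemius, soleus). Only the strength parameter $N_i$ changes between
conditions; kinematics and ground reaction forces are deliberately held
fixed, so every stress difference is attributable to recruitment
redistribution.

## The synthetic gait generator

No measured motion data ship with the package; the generator creates the
statistical structure the analysis needs.

* **Cohort.** Body mass 76.3 ± 8.6 kg and stature 1.777 ± 0.037 m (adult
  male), drawn from normals truncated at ±3 SD. Body-fat fraction follows a
  linear adult BMI regression (`fat% = 1.20·BMI + 0.23·age − 16.2`, age 29),
  clamped to (0.03, 0.6); lean mass feeds the strength scaling.
* **Speeds.** Self-selected speed per style: normal 1.16 ± 0.14, toe-out
  1.05 ± 0.11, toe-in 1.04 ± 0.12, wide 1.09 ± 0.13 m/s (truncated normals).
* **Waveforms.** Joint angles are natural splines through five knots per
  degree of freedom; the vertical GRF is
  $A\,\sin(\pi t)\,(1+b\cos 2\pi t)$, which is zero at heel strike and
  toe-off, double-peaked with a mid-stance valley, and scaled so the mean
  vertical load over stance is ≈1.05 body weight. All waveforms live on a
  101-point 0–100% stance grid; swing is never simulated.
* **Style offsets.** Toe-out adds +10 ± 3° of foot progression, toe-in
  −10 ± 3°, wide +0.10 ± 0.03 m of step width; these magnitudes are
  configuration choices (typical instructed-gait magnitudes from the
  gait-retraining literature), drawn once per participant and truncated at
  ±2 SD so the style orderings hold for every trial. Styles also modulate
  the mediolateral centre-of-pressure lever, which is what makes the frontal
  knee moment style-dependent downstream.
* **Trial-to-trial variability** is smooth random-phase Fourier noise with a
  sine envelope (so boundary conditions survive), ~1° on angles and ~1.5% of
  body weight on forces.

Hierarchical seeding (master seed → participant seed → trial seed) makes any
subset independently reproducible; with master seed 0 the seven participants
use seeds 1–7.

What the generator does **not** emulate: marker trajectories and inverse
kinematics, force-plate noise spectra, pathological gait, inter-limb
asymmetry, or kinematic adaptation to weakness. Passing the end-to-end
checks therefore shows that the pipeline's mechanics and statistics are
wired correctly under realistic load magnitudes — not that the specific
stress magnitudes generalize to any measured cohort.

## The musculoskeletal model

The limb is three segments (standard mass fractions 0.100/0.0465/0.0145 of
body mass) with hip (3 DoF), knee (1 DoF hinge) and ankle (2 DoF) joints.
Seventeen Hill-type-strength muscle-tendon units cover eight functional
groups; moment arms are constants (optionally cosine-modulated with joint
angle) in a minimal planar-pair layout. Two couplings matter for the study's
mechanism and are deliberately anatomical:

* **Gastrocnemius is biarticular** (plantarflexion arm 0.045 m + knee
  flexion arm 0.020 m, knee-crossing). At push-off, ankle-extensor demand
  loads the knee through it; weakening gastrocnemius and soleus makes the
  optimizer shift knee-flexion work to the hamstrings, whose larger knee arm
  needs less force — net knee compression falls.
* **Tensor fasciae latae carries a hip-flexion arm** (0.030 m) while the
  glutei are nearly pure abductors. Weakening the abductor group makes TFL's
  hip-flexion contribution expensive; rectus femoris and iliopsoas pick it
  up, and the extra rectus femoris force both compresses the knee directly
  and raises antagonist flexor demand — net knee compression rises. This is
  the compensation route the recruitment criterion exposes.

Scaling: segment lengths from participant anthropometry, masses with body
mass, and isometric strengths with lean mass to the two-thirds power
(cross-sectional-area scaling), `lean = mass × (1 − fat_fraction)`.
Strength reductions multiply $N_i$ by $1-0.40$ for the selected group only;
no other model parameter changes.

## Inverse dynamics

Quasi-static bottom-up recursion (foot → shank → thigh) in two planes
sharing the vertical force; the transverse hip moment is a configurable
fraction (default 0.1) of the frontal one. The hip is anchored laterally at
0.09 m (the pelvis riding over the stance foot), which is what produces the
stance-phase hip-abduction demand in a single-limb model. An `inertial` mode
adds finite-differenced segment accelerations (central differences on the
phase grid scaled by stance time) and is used by the property suite; the
study runs quasi-static, because stance-phase inertial terms are
second-order for the *relative* statistics computed here.

## Recruitment solver

The cubic criterion is strictly convex on the feasible slice in activation
coordinates $a_i = f_i/N_i$, so the minimizer is unique. The solver is a
feasible-start elastic interior point: slack variables absorb the moment
residual so the equalities hold exactly from the first iterate, a big-M term
drives the slacks to zero when the demand is reachable, and the slack
diagonal keeps the reduced (Schur) system full-rank. An active-set polish
then solves the equality-constrained problem on the strictly positive
coordinates exactly, with both removal (a coordinate driven to its bound)
and reactivation (a bound coordinate with profitable reduced gradient).
Tolerance 1e-8; KKT residuals on study traces are at machine precision.
There are no reserve actuators and no $f_i \le N_i$ caps: an unreachable
moment is an explicit `insufficient-strength` error (strength is the
experimental variable; silent reserves would mask it), and activations above
1 are reported and flagged.

## Contact model and its key surrogate

Each tibial plateau is an 8×8 grid of foundation springs
($k_e = E(1-\nu)/[(1+\nu)(1-2\nu)\,t_e]$, $\nu = 0.42$, $t_e$ = 3 mm) under
a paraboloid condyle sitting in a concave tibial dish (dish radii exceed
condyle radii, flattening the gap and spreading contact realistically). The
femur pose — axial penetration, ab-ad rotation, AP and ML translation, with
flexion prescribed and internal-external rotation held by its 1.2 Nm/deg
connector — is found by damped Levenberg-Marquardt iteration on the 4-DoF
force/moment residual; equilibria near compartment lift-off sit on a
contact-set kink and retry through a softplus-smoothed continuation.
Tangential load paths: the dish slope tilts element normals (global
restoring force), a pressure-proportional layer shear term
($1/[2(1+\nu)t]$ per unit normal force) carries local AP/ML shear, and the
0.5 N/mm tibiofemoral connectors stand in for the capsule and skin exactly
as restraints.

The **maximum principal stress is surrogated by the superficial contact
pressure magnitude**. In compressive contact the superficial maximum
principal stress tracks pressure; the full fibril-reinforced stress tensor
of a 3-D FE model is out of scope. This is the package's largest deviation
from a full MS-FE pipeline and the main caveat on magnitudes.

The effective foundation modulus is not a free constant: it is calibrated by
the **biphasic column** — a 1-D linear poroelastic confined-compression
solver (implicit finite differences, drained surface, impermeable base)
verified against the classical consolidation series to <0.1% L2. A
displacement ramp to 10% strain over the gait loading timescale (0.5 s)
yields ≈65 MPa with the default cartilage parameters
($H_A$ = 0.5 MPa, $k$ = 2×10⁻¹⁵ m⁴/(N·s), 3 mm), i.e. the fluid-trapped
short-time stiffness, about two orders above the drained modulus — which is
exactly why gait-rate loading must not use $H_A$ directly.

Patellofemoral forces are computed (quadriceps resultant through a
flexion-dependent pulley ratio, 0.7 at 20° to 1.0 at 60°) and reported, but
no patellar contact is solved; the analyzed outcomes are tibial.

## Stress summary and statistics

Per compartment and sample, elements in contact are ranked and the top
`ceil(0.25 n)` averaged — the upper-quartile mean, which suppresses
single-element outliers. The quartile base is per-compartment (results are
reported per compartment) and excludes zero-pressure elements by
definition of contact area.

%Change uses the absolute value as written above (the subsequent PP
subtraction is then a plain difference); reference stresses below 0.01 MPa
mask the sample rather than divide. Peak comparisons use the per-participant
maximum of the upper-quartile series over all of stance. Cohort curves carry
t-based 95% CIs across participants. No sphericity correction is applied to
the RM-ANOVA, and the package reports this in its output metadata.

The direction-structure check evaluated by the test suite summarizes the
late-stance window (70–90% of stance, around the second GRF peak where the
ankle extensors dominate): reduced ankle-extensor strength should lower
medial stress and reduced hip-abductor strength raise it, for nearly all
participants. On the default synthetic cohort both hold for 7 of 7.

## Numerical choices and degenerate inputs

* Phase grid: 101 points, 0–100% stance; all trials share it, so averaging
  needs no resampling (trials of different duration are compared on the
  normalized grid).
* Recruitment: barrier path μ = 10⁻² → 10⁻¹¹ (shorter when warm-started from
  the neighbouring sample), elastic big-M escalated ×100 at most twice;
  zero demand short-circuits to zero force.
* Contact: residual tolerance 10⁻⁶ × axial load (the equilibrium invariant
  asserts 10⁻³); lift-off (non-compressive axial input) returns a zero
  field, not an error; a load whose moment no pressure distribution on the
  plates can balance (tip-over) is a convergence error.
* Consolidation: the time step honours `dt ≤ 0.4 dz²/(H_A k)`; the load
  step enters the pore pressure instantaneously (undrained response).
* Problem sizes in the shipped tests: the full study (7 participants × 4
  styles × 5 trials × 4 conditions, ≈57,000 recruitment solves and 112
  contact traces) runs in about five minutes on one core, and the oracle
  comparisons use 200–1000 random cases each.

## Known limitations

Single-limb, stance-only mechanics without trunk or contralateral loads;
constant moment arms; no menisci, ligament bundles, or fluid pressurization
in the contact solve; contact pressure as the principal-stress surrogate;
fixed kinematics across strength conditions (a person who lost 40% of a
muscle group would walk differently); and a synthetic cohort whose
between-participant variability is purely parametric. Magnitudes are
therefore indicative; the package's claims are about mechanism direction,
internal consistency, and the statistics pipeline.
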