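# DualPoseReg

Rigid 2D/3D registration of a CT volume to a pair of frontal and lateral
radiographs, for image-guided procedures where the patient's pose at
acquisition time must be related back to a pre-operative CT. Single-view
2D/3D registration leaves the depth translation (the axis pointing at the
X-ray source) badly constrained; registering both views of a biplanar
acquisition at once makes every translation axis in-plane for at least one
view and repairs exactly that weakness.

## Method

Given a 6-DOF pose **p** = (tX, tY, tZ, θX, θY, θZ), the package renders
digitally reconstructed radiographs (DRRs) of the posed volume by
perspective ray casting with trilinear interpolation, reduces DRRs and
reference radiographs to Canny contour-point sets, and scores each view with
a banded contour similarity: a reference contour point at distance d from
the nearest floating contour point earns

    s(d) = 1 (d = 0) | w1 (0 < d ≤ a) | w2 (a < d ≤ b) | 0 (d > b)

with defaults a = 1 px, b = 3 px, w1 = 0.8, w2 = 0.5, averaged over all
reference points. The frontal and lateral scores combine as

    Sim(p) = wf · Simf(p) + wl · Siml(p),  wf = 0.6 > wl = 0.4,

where the lateral DRR is rendered under `LateralMat = TransMat · FrontalMat`
(TransMat: a fixed quarter-turn about the patient's longitudinal axis). The
pose maximizing Sim is found with a phased differential-evolution optimizer:
DE/rand/2 mutation, binomial crossover, greedy selection, with the scale
factor switching 0.5 → 0.8 and the crossover rate 0.9 → 0.3 at the halfway
generation, and a damped mutation step on the depth dimension. A procedural
spine-like phantom generator renders seeded synthetic fixtures so the entire
loop is testable without clinical data.

## Worked example

Register a synthetic fixture whose ground-truth pose is known:

```r
library(DualPoseReg)

fix <- makeFixtureSet(n = 1, seed = 1)[[1]]   # phantom + noisy reference pair
truePose(fix)
#> Pose: t = (-3.1620313,  0.1642999,  2.1977342) mm, theta = (-1.07512576, -0.07474291,  2.74327262) deg

res <- registerPose(fixtureVolume(fix), frontalImage(fix), lateralImage(fix),
                    fixtureGeometry(fix), RegistrationConfig(seed = 101),
                    transMat = fix@transMat, truth = truePose(fix))
res
#> RegistrationResult (dual mode): composite similarity 0.9850
#>   Pose: t = (-3.32217108,  0.03043853,  2.10245857) mm, theta = (-1.3819024,  0.4636104,  2.8571073) deg
#>   PoseError: rotation (0.3068, 0.5384, 0.1138) deg, translation (0.16014, 0.13386, 0.09528) mm
#>   success: TRUE
```

The recovered pose is within 0.2 mm and 0.6° of the truth on every axis —
far inside the 3° / 3 mm success criterion
(`evaluateSuccess`). `compareSingleVsDual(makeFixtureSet(n = 10, seed = 1),
RegistrationConfig(seed = 1))` runs the same trials in both modes and
reports per-axis mean errors, success rates and the percent error reduction
achieved by the dual view; the depth axis (tZ) is where single-view
registration degrades.

The optimizer can be used on its own, e.g. on the bundled benchmark
functions:

```r
cfg <- DEConfig(NP = 30, D = 4, Gmax = 1000, lower = -5, upper = 5, seed = 2)
res <- optimizePDE(benchmarkFunction("F6")@fun, cfg)   # Kowalik least squares
bestFitness(res)
#> [1] 0.000307486
```

A command-line wrapper with `register`, `benchmark`, `phantom` and
`compare-poses` subcommands is installed at
`system.file("cli", "dualposereg.R", package = "DualPoseReg")`.

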