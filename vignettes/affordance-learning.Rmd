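---
title: "Integrated learning of grasp affordances and motor parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated learning of grasp affordances and motor parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affgrasp)
```

## What the simulator models

`affgrasp` simulates an infant-stage primate learning, by trial and error,
both *what* in a seen object affords grasping and *how* to grasp it.  The
model couples four stages into one closed loop:

1. **Parietal feature extraction.**  Object position, main-axis orientation,
   visible surface normals and size are encoded as noisy Gaussian population
   codes (model areas V6A/MIP for direction and distance, cIPS for
   orientation, normals and size).
2. **Affordance extraction (area AIP).**  The concatenated, unit-normalized
   parietal vector (distance excluded — distance parameterizes the reach,
   not the grasp) feeds a 40 x 40 *toroidal self-organizing map* whose
   learning rate and neighborhood radius decay over training but are expanded
   additively by the global reinforcement signal, so feature combinations
   that led to reward recruit more map territory.
3. **Premotor parameter selection.**  Dynamic neural fields (DNFs) — grids of
   leaky-integrator units with sigmoidal rates, local excitation and global
   inhibition — perform winner-take-all selection of every movement
   parameter: object center (F2, via fixed identity weights scaled by 3),
   object-centered reach offset (F7), virtual-finger combination and maximum
   aperture (four mutually inhibiting F5 fields), and wrist rotation (the
   F2/F5 network).  Each parameter has a preparation field and an execution
   field; execution fields sit under a tonic inhibition of 10 that drops to
   0 at the go signal.  All afferents of the preparation fields other than
   the F2 relay are learned with a reinforcement rule
   `dW = alpha * rs * pre x exec` — Hebbian for reward, anti-Hebbian for
   punishment — with the execution-related activity acting as the
   eligibility trace.
4. **Motor execution.**  Field activities are decoded by thresholded
   center-of-mass readout (threshold `xi = 0.01`).  A dynamic movement
   primitive (a phase-gated damped point attractor) generates the wrist
   trajectory; the Jacobian pseudo-inverse converts waypoints into joint
   targets; PD controllers drive the 22 degrees of freedom (3 shoulder,
   1 elbow, 3 wrist, 15 finger).  The grasp controller runs preshape and
   enclose timing signals; enclose starts when the wrist comes within
   `kappa` of the object or at palm contact, whichever is first.

A trial lasts 5 simulated seconds: object onset at 0.5 s, go signal at 1 s,
reward in the last five control steps.  Training is staged: ~1000 trials of
AIP pretraining (no movements, `rs = 0`), wrist-rotation pretraining in
which any palm contact earns `DA_success / 4` and only the F7-to-wrist
projection learns, then grasp training in which stable grasps earn
`DA_success`, failures `DA_fail`, and every learned projection plus the map
adapts.

## The grasp-stability surrogate

The original formulation evaluated grasps inside a rigid-body physics
engine; here the only physics outputs the learning loop ever consumes —
contact events and a stability verdict — are produced geometrically.  A
hand landmark (palm patch, finger pads, radial finger sides, inner-finger
joints, thumb pad and side) within 5 mm of the object surface is a contact.
A grasp is **stable** when two contacts from opposing body parts (thumb vs.
finger, palm vs. finger or thumb) span an *opposition axis* that passes
through the object interior, continuously for 2 s of simulation time.
Non-grasping collisions can knock the object away: when contacts without an
opposition axis occur while the hand moves faster than 0.3 m/s, the object
is displaced along the push direction in proportion to the penetration
depth (capped at 5 mm per step).  Gravity is off and objects are otherwise
pose-fixed, so a settled open-loop system decides a trial's outcome exactly;
the simulator uses that to stop trials early without changing any verdict.

## Object stimuli

Trials draw from five primitives — cube, rectangular prism, cylinder,
sphere, flat plate — at uniformly random positions inside the reachable
workspace, orientations within +/- 60 degrees per Euler angle, and sizes
uniform in per-shape ranges.  Each shape occupies a characteristic region
of size space (small blocks of 2-5.5 cm, elongated thin prisms, 5.5-8.5 cm
cylinders, 7-10 cm balls, broad 4-12 mm plates).  This mirrors the ordinary
experience that object categories have characteristic scales, and it is
what lets a map driven purely by metric features develop *shape*-selective
units: cubes and spheres that shared an identical size distribution would
differ only in which gated populations (RECT/SOS vs. none) they activate.
The novel-object probe introduced halfway through grasp training keeps the
same shapes but draws positions from a disjoint radial band beyond the
training distances (26-28.5 cm versus 16-26 cm) and sizes 10 % below the
training ranges, so probe objects are outside the training distribution by
construction.  Long reaches to smaller objects are genuinely harder in this
arm (the extended configuration loses maneuverability), which is what makes
the probe informative: performance dips when the probes appear and climbs
again as the reinforcement rule adapts the offset and wrist mappings.

The generator does not emulate: multi-part objects (a hammer's head plus
handle), visual occlusion or retinal processing, object mass, friction or
gravity.  Passing tests therefore demonstrate the learning architecture
under idealized geometry, not robustness to real-world contact dynamics.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `parietal$dir$sigma` | 0.10 | rad | direction tuning width; sharp enough for shape-selective map prototypes, wide enough that the F2 relay always ignites |
| `parietal$cips$sigma` | 0.08 | normalized | orientation/normal/size tuning width (sizes are normalized by `size_max` = 0.25 m so one width serves all cIPS populations) |
| `som$r0`, `som$lambda`, `som$alpha0` | 20, 350, 1.5 | grid cells, trials, — | neighborhood and rate schedule; `lambda` is set so the map converges within the 1000-trial pretraining (and shrinks with the run scale, like the stage lengths) |
| `dnf$beta`, `dnf$u0` | 6, 0.4 | —, — | sigmoid steepness and threshold; steep enough that a single-unit input of ~1.2 ignites a bump while baseline fields stay silent |
| `dnf$w_excite`, `dnf$w_inhibit`, `dnf$sigma` | 2, 1.5, 2 | —, —, cells | winner-take-all kernel; one bump survives per field in 1, 2 and 3 dimensions |
| `premotor$w_init_max` | 0.022 | — | learned-weight initialization; chosen so the summed AIP drive lands in the fields' operating window (about 2-3.5) |
| `premotor$alpha_*` | 2e-3 | — | reinforcement rates; strong enough that one reward noticeably biases the next selection for the same object (objects persist six trials), weak enough not to saturate the fields within a run |
| `premotor$w_cap` | 0.3 | — | saturation bound on learned weights; the reinforcement rule has no reward baseline, so net growth is positive whenever successes outweigh the (smaller) punishments, and an explicit synaptic bound keeps the total drive inside the fields' operating window |
| `motor$kappa` | 0.06 | m | wrist-object distance that triggers enclose |
| `motor$xi` | 0.01 | — | decode inclusion threshold |
| `reward$da_success`, `da_fail` | 1, -0.2 | — | asymmetric so occasional failures do not erase rare successes |

## Numerical choices

* **Integration.**  All field dynamics use explicit Euler with
  `dt <= tau / 2`; the control step is the base 1 ms times the run scale,
  capped at `tau / 2` (5 ms).  A global `scale` divides every stage length
  (and the SOM decay constant) for desk-scale runs; the vignette and tests
  use `scale = 10`, i.e. 100 AIP / 200 wrist / 1000 grasp trials with a
  5 ms control step, and the full-scale AIP pretraining (1000 trials) for
  the selectivity analyses.
* **Convolution.**  The WTA kernel spans twice the field per dimension, so
  the zero-padded full convolution equals a separable Gaussian convolution
  minus `w_inhibit * sum(f)`; the implementation uses that identity (a test
  verifies it against the explicit kernel).
* **Ties and degeneracies.**  Best-matching-unit ties break to the lowest
  flat index; exact F5 peak ties select in the order precision, tripod,
  power, side; a degenerate all-zero parietal vector is flagged and skips
  the map update; a field with no super-threshold unit is a no-decode
  signal and the arm simply does not move.
* **Safeguards.**  The per-update SOM step `Theta * alpha` is clamped at 1
  (a reward-expanded rate may exceed it; an uncapped step would overshoot
  the input).  Parietal activity noise is clipped at zero, matching the
  floor of a firing-rate code.  IK displacements are capped at 1 cm per
  step and singular Jacobians hold the previous joint targets.

## Design choices where the architecture was open

* The printed PD law with `+ d * thetadot` is anti-dissipative; damping is
  implemented opposing velocity.
* The arm's closed-form Jacobian is derived analytically from the forward
  kinematics (shoulder `Rz Ry Rx`, rest arm along -y, elbow hinge about the
  local x axis, forearm at a right angle at rest), so the analytic and
  finite-difference Jacobians agree by construction.
* Epochs advance once per trial (object repetitions within the 6-trial
  refresh window count individually).
* The reinforcement signal enters the map schedule only with its positive
  part: a negative `rs` would turn the radius and rate negative, which the
  printed schedule does not define.
* The offset frame for the object-centered reach offset is world-aligned at
  the object center; after the offset point is reached the controller
  retargets the object center with the approach speed capped, and palm or
  inner-thumb contact freezes the reach permanently.
* Visibility of a face means its outward normal points against the gaze
  direction (fixed at +y).

## Limitations

The surrogate has no friction, so grasp stability is purely geometric;
absolute success rates are not comparable to a dynamics engine, only their
learning trends are.  The reinforcement rule is pure Hebbian-with-reward:
with no baseline subtraction it drifts, and although the chosen rates keep
a desk-scale run inside the fields' operating range, very long runs would
eventually saturate selection toward early-rewarded parameters.  The map
analyses use training-trial activity with whatever noise was present, so
block statistics at small block sizes are noisy.  One virtual-finger
posture table serves all object sizes; apertures outside a shape's
graspable window fail regardless of planning, which caps attainable
success below 100 %.
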