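# affgrasp

A neural simulator of how a developing primate can learn — simultaneously and
by trial and error — *grasp affordances* (which combinations of visible
object features permit a stable grasp) and the *motor parameters* that
exploit them.

The scientific core couples four mechanisms into one closed sensorimotor
loop:

* **Parietal population codes** (model areas V6A/MIP and cIPS): noisy
  Gaussian tuning over shoulder-centered object direction and distance, the
  main-axis orientation of elongated shapes, the normals of visible
  surfaces, and component size.
* **A reward-modulated self-organizing affordance map** (area AIP): a
  40 x 40 toroidal SOM over the normalized parietal vector *I*, with unit
  activity `AIP(i,j) = W(i,j) . I + noise`, weight updates
  `W <- W + Theta(beta; r) alpha (I - W)`, and both the truncated-Gaussian
  neighborhood radius `r(t,T) = r0 exp(-T/lambda) + rs(t)` and the rate
  `alpha(t,T) = alpha0 exp(-T/lambda) + rs(t)` expanded by the global
  reinforcement signal `rs`.
* **Premotor dynamic neural fields**: winner-take-all selection of every
  movement parameter through leaky-integrator grids
  `tau du/dt = -u + h + IN + f * W_DNF + noise`, `f = sigmoid(u)`, with a
  Gaussian-minus-constant kernel spanning twice the field.  F2 relays the
  object center, F7 selects an object-centered reach offset, four mutually
  inhibiting F5 fields select the virtual-finger combination and maximum
  aperture, and a 3-D F2/F5 field selects the wrist rotation.  Execution
  fields are released from tonic inhibition by the go signal, and all
  learned projections follow the reinforcement rule
  `dW = alpha rs (pre x exec)` with execution activity as the eligibility
  trace.
* **A kinematic 22-DOF arm/hand**: analytic Jacobian and pseudo-inverse
  inverse kinematics (`theta_hat = theta + J+ [dx dy dz]`), PD joint
  controllers (`tau = p(theta_hat - theta) - d thetadot`), dynamic movement
  primitives for the reach trajectory and grasp-phase timing, and a
  geometric grasp-stability criterion: a grasp is stable when two contacts
  from opposing body parts hold an *opposition axis* through the object for
  2 s of simulation time.

Training is staged as in the developmental story: AIP pretraining (no
movements), wrist-rotation pretraining rewarded by palm contact, then
full grasp training with novel-object probes halfway through.  The package
also ships the accompanying analyses: the shape preference index
`PI = (n - sum(r_i)/r_pref) / (n - 1)`, selectivity classes and their
time course in 500-trial blocks, per-feature PI panels, linear feature
fits of map activity, and blocked success-rate curves.

See `vignettes/affordance-learning.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

A desk-scale run (`scale = 10` divides the stage lengths and uses a 5 ms
control step):

```r
library(affgrasp)

cfg <- ag_config(seed = 1, scale = 10)
model <- grasp_model(cfg)
model <- run_stage(model, "aip")       # affordance-map pretraining
summary(model)
#> <grasp_model>
#>   seed: 1  scale: 10
#>   affordance map: 40 x 40 units, epoch 100
#>   stages completed: aip
#>   logged trials: 100
#>   aip   stage: 100 trials

sel <- selectivity_timecourse(model$log$records, model$log$aip, block = 50)
sel$blocks[, c("block", "n_high", "n_moderate", "n_non", "pi_mean")]
#>   block n_high n_moderate n_non   pi_mean
#> 1     1    374       1226     0 0.6545331
#> 2     2   1043        556     1 0.7645981
```

Even this short pretraining drives most of the 1600 map units from
moderate to high shape selectivity (`PI > 0.75`): the map is organizing by
object shape although shape is never given to it explicitly.

A hand-specified grasp plan run through the motor pipeline:

```r
plan <- structure(list(object_center = c(theta = 1.57, phi = -1.57, rho = 0.20),
                       reach_offset = c(theta = 0, phi = -3.0, rho = 0.08),
                       wrist = c(0, 0, 0), vf = "precision", aperture = 0.8),
                  class = "grasp_plan")
cube <- object_primitive("cube", c(0.04, 0.04, 0.04),
                         sph_to_cart(1.57, -1.57, 0.20))
res <- run_motor_phase(plan, cube, cfg)
res$verdict; res$palm_contact
#> [1] "stable"
#> [1] TRUE
```

The arm approaches the 4 cm cube from below, stops its reach on palm
contact, encloses, and the thumb-finger opposition axis through the cube
persists — a stable grasp.

A command-line driver over the same functions lives in
`inst/cli/affgrasp.R` (`pretrain-aip`, `pretrain-wrist`, `train`,
`evaluate`, `analyze`).

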