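# shared fixtures: small, fast configurations built in code

quiet_cfg <- function(...) ag_config(...)

# a reachable test cube straight ahead at shoulder height
test_cube <- function(side = 0.04) {
  object_primitive("cube", rep(side, 3), sph_to_cart(1.57, -1.57, 0.20))
}

# a hand-specified plan known to produce a stable pinch on test_cube():
# approach from below with a neutral wrist
golden_plan <- function(vf = "precision", aperture = 0.8) {
  structure(list(object_center = c(theta = 1.57, phi = -1.57, rho = 0.20),
                 reach_offset = c(theta = 0, phi = -3.0, rho = 0.08),
                 wrist = c(0, 0, 0), vf = vf, aperture = aperture),
            class = "grasp_plan")
}

# contacts data.frame helper
contact_df <- function(parts, pts, time = 0) {
  data.frame(body_part = parts, x = pts[1, ], y = pts[2, ], z = pts[3, ],
             time = time, stringsAsFactors = FALSE)
}
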