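cfg <- quiet_cfg()

obj_at <- function(theta = 1.5, phi = -1.6, rho = 0.2, shape = "cube",
                   size = rep(0.04, 3), orientation = c(0, 0, 0)) {
  object_primitive(shape, size, sph_to_cart(theta, phi, rho), orientation)
}

test_that("distance encoding peaks at 1 on a preferred value and falls as a Gaussian", {
  spec <- population_spec(list(c(0, 1)), 15, sigma = 0.1)
  rho_star <- spec$pref[[1]][6]
  act <- encode_distance(obj_at(rho = rho_star), spec, add_noise = FALSE)
  expect_equal(max(act$values), 1.0, tolerance = 1e-9)
  expect_equal(which.max(act$values), 6)
  # one tuning width away: exp(-1/2)
  act2 <- encode_distance(obj_at(rho = rho_star + 0.1), spec, add_noise = FALSE)
  expect_equal(act2$values[6], exp(-1 / 2), tolerance = 1e-9)
  # two identical components sum
  two <- encode_distance(list(obj_at(rho = rho_star), obj_at(rho = rho_star)),
                         spec, add_noise = FALSE)
  expect_equal(max(two$values), 2.0, tolerance = 1e-9)
})

test_that("direction encoding is an exact 2-D Gaussian over azimuth and elevation", {
  spec <- population_spec(list(c(0, pi), c(-pi, 0)), c(15, 15), sigma = 0.3)
  th_star <- spec$pref[[1]][8]; ph_star <- spec$pref[[2]][7]
  act <- encode_direction(obj_at(theta = th_star, phi = ph_star), spec,
                          add_noise = FALSE)
  expect_equal(act$values[8, 7], 1.0, tolerance = 1e-9)
  act2 <- encode_direction(obj_at(theta = th_star + 0.3, phi = ph_star), spec,
                           add_noise = FALSE)
  expect_equal(act2$values[8, 7], exp(-1 / 2), tolerance = 1e-9)
  # a symmetric pair of objects yields a field symmetric about the midpoint
  pair <- encode_direction(list(obj_at(theta = spec$pref[[1]][6], phi = ph_star),
                                obj_at(theta = spec$pref[[1]][10], phi = ph_star)),
                           spec, add_noise = FALSE)
  expect_equal(pair$values[6, ], pair$values[10, ], tolerance = 1e-12)
})

test_that("axis-orientation populations are gated by shape", {
  sp <- parietal_specs(cfg)
  sphere <- obj_at(shape = "sphere", size = rep(0.08, 3))
  ao <- encode_axis_orientation(sphere, sp$cyl, sp$rect, add_noise = FALSE)
  expect_true(all(ao$cyl$values == 0) && all(ao$rect$values == 0))
  # cylinder along +z drives only CYL, peak exactly 1 on the preferred axis
  cyl <- obj_at(shape = "cylinder", size = c(0.06, 0.06, 0.12))
  ao2 <- encode_axis_orientation(cyl, sp$cyl, sp$rect, add_noise = FALSE)
  expect_equal(max(ao2$cyl$values), 1.0, tolerance = 1e-9)
  expect_true(all(ao2$rect$values == 0))
  cube <- obj_at(shape = "cube")
  ao3 <- encode_axis_orientation(cube, sp$cyl, sp$rect, add_noise = FALSE)
  expect_equal(max(ao3$rect$values), 1.0, tolerance = 1e-9)
  expect_true(all(ao3$cyl$values == 0))
})

test_that("surface-normal encoding marks exactly the visible faces", {
  sp <- parietal_specs(cfg)
  cube <- obj_at(shape = "cube")
  # diagonal view: three faces visible, normals on exact grid points
  v <- -c(1, 1, 1) / sqrt(3)
  act <- encode_surface_normals(cube, sp$sos, view_dir = v, add_noise = FALSE)
  # oracle: faces with normal . view < 0
  vis <- which(colSums(cube$face_normals * v) < 0)
  expect_equal(length(vis), 3)
  expect_equal(sum(act$values > 0.999), 3)
  expect_equal(max(act$values), 1.0, tolerance = 1e-9)
  # spheres yield silence
  expect_true(all(encode_surface_normals(obj_at(shape = "sphere"), sp$sos,
                                         add_noise = FALSE)$values == 0))
  # rotating the cube rotates the peak pattern identically
  rot <- obj_at(shape = "cube", orientation = c(0, 0, pi / 2))
  a1 <- encode_surface_normals(cube, sp$sos, view_dir = v, add_noise = FALSE)
  a2 <- encode_surface_normals(rot, sp$sos, view_dir = v, add_noise = FALSE)
  expect_equal(sort(a1$values[a1$values > 0.5]), sort(a2$values[a2$values > 0.5]),
               tolerance = 1e-9)
})

test_that("size encoding hits preferred triples and decodes stably across resolutions", {
  smax <- cfg$parietal$cips$size_max
  spec <- population_spec(rep(list(c(0, 1)), 3), c(11, 11, 11),
                          sigma = cfg$parietal$cips$sigma)
  s_star <- spec$pref[[1]][3] * smax
  act <- encode_size(obj_at(size = rep(s_star, 3)), spec, size_max = smax,
                     add_noise = FALSE)
  expect_equal(max(act$values), 1.0, tolerance = 1e-9)
  off <- encode_size(obj_at(size = c(s_star + cfg$parietal$cips$sigma * smax,
                                     s_star, s_star)),
                     spec, size_max = smax, add_noise = FALSE)
  expect_equal(off$values[3, 3, 3], exp(-1 / 2), tolerance = 1e-6)
  # doubling the grid leaves the center-of-mass decode within 2 %
  spec2 <- population_spec(rep(list(c(0, 1)), 3), c(22, 22, 22),
                           sigma = cfg$parietal$cips$sigma)
  sz <- c(0.037, 0.043, 0.051)
  d1 <- decode_center_of_mass(
    encode_size(obj_at(size = sz), spec, smax, add_noise = FALSE)$values,
    spec$pref, xi = 0.01)
  d2 <- decode_center_of_mass(
    encode_size(obj_at(size = sz), spec2, smax, add_noise = FALSE)$values,
    spec2$pref, xi = 0.01)
  expect_lt(max(abs(d1 - d2) / d2), 0.02)
})

test_that("noise-free encoders shift their peak with the stimulus", {
  spec <- population_spec(list(c(0, 1)), 15, sigma = 0.1)
  delta <- diff(spec$pref[[1]][1:2])
  a <- encode_distance(obj_at(rho = spec$pref[[1]][5]), spec, add_noise = FALSE)
  b <- encode_distance(obj_at(rho = spec$pref[[1]][5] + delta), spec,
                       add_noise = FALSE)
  expect_equal(which.max(b$values), which.max(a$values) + 1)
  # decode recovers a random stimulus within one grid spacing
  set.seed(5)
  for (k in 1:10) {
    rho <- stats::runif(1, 0.1, 0.9)
    act <- encode_distance(obj_at(rho = rho), spec, add_noise = FALSE)
    expect_lt(abs(decode_center_of_mass(act$values, spec$pref, 0.01) - rho),
              delta)
  }
})

test_that("the AIP input vector is the normalized concatenation without distance", {
  obj <- obj_at()
  enc <- encode_scene(obj, cfg, add_noise = FALSE)
  expect_equal(sqrt(sum(enc$aip_input^2)), 1, tolerance = 1e-12)
  expect_length(enc$aip_input, aip_input_dim(cfg))
  expect_false(attr(enc$aip_input, "degenerate"))
  # scaling all activities leaves the vector unchanged
  scaled <- lapply(enc[c("dir", "cyl", "rect", "sos", "s")], function(a) {
    a$values <- a$values * 10; a
  })
  I2 <- build_aip_input(scaled$dir, scaled$cyl, scaled$rect, scaled$sos,
                        scaled$s)
  expect_equal(as.numeric(I2), as.numeric(enc$aip_input), tolerance = 1e-12)
  # all-zero populations flag degeneracy
  zero <- lapply(enc[c("dir", "cyl", "rect", "sos", "s")], function(a) {
    a$values[] <- 0; a
  })
  I0 <- build_aip_input(zero$dir, zero$cyl, zero$rect, zero$sos, zero$s)
  expect_true(attr(I0, "degenerate"))
  expect_true(all(I0 == 0))
  # non-finite input is a data error
  bad <- enc$dir; bad$values[1] <- NaN
  expect_error(build_aip_input(bad, enc$cyl, enc$rect, enc$sos, enc$s),
               "non-finite")
})

test_that("encoders are deterministic at zero noise and noisy otherwise", {
  obj <- obj_at()
  e1 <- encode_scene(obj, cfg, add_noise = FALSE)
  e2 <- encode_scene(obj, cfg, add_noise = FALSE)
  expect_identical(e1$aip_input, e2$aip_input)
  set.seed(1); n1 <- encode_scene(obj, cfg)
  set.seed(2); n2 <- encode_scene(obj, cfg)
  expect_false(identical(n1$aip_input, n2$aip_input))
  # noise is clipped at the zero activity floor
  expect_true(all(n1$dir$values >= 0))
})
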