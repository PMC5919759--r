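# Phantom builders shared across tests. All geometry is generated in code;
# cylinders are kept steep (near-axial) wherever counts are compared to
# truth, because the projection-based 2D->3D conversion is only
# approximately unbiased for vessels crossing the imaging plane.

# n vertical cylinders of length L um on a staggered grid; truth count is
# n * pi * r^2 * L / 942.48.
vertical_phantom <- function(n, L = 80, radius = 2,
                             blur_sigma_um = 0, noise_sd = 0, seed = NULL) {
  stopifnot(n >= 1, n <= 9)
  pos <- cbind(x = c(15, 40, 60, 20, 55, 35, 65, 12, 48),
               y = c(15, 20, 45, 55, 65, 38, 14, 40, 60))[seq_len(n), ,
                                                          drop = FALSE]
  nz <- ceiling((L + 8) / 2)
  cfg <- synth_config(dims = c(120L, 120L, nz), blur_sigma_um = blur_sigma_um,
                      read_noise_sd = noise_sd, seed = seed)
  specs <- lapply(seq_len(n), function(i) {
    cylinder_spec(c(pos[i, 1], pos[i, 2], 3),
                  c(pos[i, 1], pos[i, 2], 3 + L), radius)
  })
  generate_vessel_stack(specs, cfg)
}

# 12 near-axial cylinders (tilt <= 3 degrees), r = 2 um, L = 75 um:
# truth volume 11,309.7 um^3, truth count 12.
tilted_phantom_12 <- function(blur_sigma_um = 0.2, noise_sd = 5,
                              stack_seed = 11) {
  cfg <- synth_config(dims = c(160L, 160L, 44L),
                      blur_sigma_um = blur_sigma_um,
                      read_noise_sd = noise_sd, seed = stack_seed)
  angles <- with_fixed_seed(5, list(
    ang = stats::runif(12, 0, 2 * pi),
    tilt = stats::runif(12, 0, 3) * pi / 180
  ))
  specs <- lapply(seq_len(12), function(i) {
    gx <- 14 + ((i - 1) %% 4) * 25
    gy <- 14 + ((i - 1) %/% 4) * 28
    dx <- 75 * sin(angles$tilt[i]) * cos(angles$ang[i])
    dy <- 75 * sin(angles$tilt[i]) * sin(angles$ang[i])
    cylinder_spec(c(gx, gy, 4), c(gx + dx, gy + dy, 4 + 75 * cos(angles$tilt[i])), 2)
  })
  generate_vessel_stack(specs, cfg)
}

# run code under a fixed seed without disturbing the test RNG stream
with_fixed_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# an in-plane (horizontal) cylinder phantom for bias-direction checks
inplane_phantom <- function(blur_sigma_um = 0.2) {
  cfg <- synth_config(dims = c(160L, 40L, 10L), blur_sigma_um = blur_sigma_um)
  sp <- cylinder_spec(c(12, 12.4, 10), c(87, 12.4, 10), 2)
  generate_vessel_stack(list(sp), cfg)
}
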