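# shared fixtures: everything is generated in code, sized for fast tests

# a small periodic-cell configuration (30 x 30 x 20 um, coarse mesh)
tiny_config <- function(model = "smeared", preset = "plga1") {
  cfg <- preset_config(preset, model = model)
  cfg$geometry$extents_um <- c(30, 30, 20)
  cfg$geometry$divisions <- c(8L, 8L, 6L)
  cfg$fibers$n_layers <- 8L
  cfg$fibers$coverage <- 0.3
  cfg$time$n_steps <- 4L
  cfg
}

tiny_network <- function(cfg = tiny_config()) config_network(cfg)

# analytic release fraction of a unit-loaded slab 0 <= z <= L with a
# perfect sink at z = L and zero flux at z = 0 (Fourier series)
slab_release_series <- function(t, L, D, n_terms = 60) {
  m <- 0:(n_terms - 1)
  lam <- (2 * m + 1)^2 * pi^2 / (4 * L^2)
  sapply(t, function(tt) 1 - sum(8 / (pi^2 * (2 * m + 1)^2) *
                                   exp(-D * lam * tt)))
}

# run a bare slab problem (1D in z) with the continuum machinery
run_slab <- function(nz, n_steps, t_end, L = 1, D = 1) {
  mesh <- hex_mesh(c(1, 1, L), c(1L, 1L, as.integer(nz)))
  asm <- assemble_continuum(mesh, diag(3) * D)
  sink <- boundary_nodes(mesh, "z1")
  free <- rep(TRUE, mesh$n_nodes); free[sink] <- FALSE
  sys <- transport_system(asm$M, asm$K, free = free,
                          dirichlet_values = numeric(mesh$n_nodes))
  C <- rep(1, mesh$n_nodes)
  m0 <- total_mass(sys, C)
  dt <- t_end / n_steps
  out <- data.frame(time = 0, released = 0)
  for (i in seq_len(n_steps)) {
    C <- step_implicit(sys, C, dt)$C
    out <- rbind(out, data.frame(time = i * dt,
                                 released = 1 - total_mass(sys, C) / m0))
  }
  list(curve = out, C = C, mesh = mesh, sys = sys)
}
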