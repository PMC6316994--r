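test_that("hexahedral element matrices have the exact closed-form values", {
  e <- element_matrices_3d(c(1, 1, 1), diag(3))
  expect_equal(sum(e$M), 1)                        # partition of unity
  expect_true(all(e$M > 0))
  expect_lt(max(abs(rowSums(e$K))), 1e-12)         # constant field flux-free
  expect_equal(diag(e$K), rep(1 / 3, 8))           # analytic trilinear value
  expect_equal(e$K, t(e$K))
  # anisotropic tensor enters linearly
  D <- matrix(c(2, 0.3, 0, 0.3, 1, 0.1, 0, 0.1, 0.5), 3, 3)
  e2 <- element_matrices_3d(c(2, 1, 0.5), D)
  e3 <- element_matrices_3d(c(2, 1, 0.5), 2 * D)
  expect_equal(e3$K, 2 * e2$K)
  expect_error(element_matrices_3d(c(1, 0, 1), diag(3)), "degenerate")
  expect_error(element_matrices_3d(c(1, 1, 1), matrix(1:9, 3)), "symmetric")
})

test_that("global assembly equals a per-element summation oracle", {
  mesh <- hex_mesh(c(3, 2, 2), c(3L, 2L, 2L))
  set.seed(1)
  d6 <- cbind(runif(mesh$n_elem, 0.5, 2), runif(mesh$n_elem, 0.5, 2),
              runif(mesh$n_elem, 0.5, 2), runif(mesh$n_elem, -0.1, 0.1),
              runif(mesh$n_elem, -0.1, 0.1), runif(mesh$n_elem, -0.1, 0.1))
  asm <- assemble_continuum(mesh, d6)
  conn <- mesh_connectivity(mesh)
  x <- rnorm(mesh$n_nodes)
  yK <- numeric(mesh$n_nodes); yM <- numeric(mesh$n_nodes)
  for (e in seq_len(mesh$n_elem)) {
    D <- matrix(c(d6[e, 1], d6[e, 4], d6[e, 5],
                  d6[e, 4], d6[e, 2], d6[e, 6],
                  d6[e, 5], d6[e, 6], d6[e, 3]), 3, 3)
    el <- element_matrices_3d(mesh$h, D)
    idx <- conn[e, ]
    yK[idx] <- yK[idx] + el$K %*% x[idx]
    yM[idx] <- yM[idx] + el$M %*% x[idx]
  }
  expect_equal(as.numeric(asm$K %*% x), yK, tolerance = 1e-12)
  expect_equal(as.numeric(asm$M %*% x), yM, tolerance = 1e-12)
  # single-element mesh: global equals element matrices
  m1 <- hex_mesh(c(1, 1, 1), c(1L, 1L, 1L))
  a1 <- assemble_continuum(m1, diag(3))
  e1 <- element_matrices_3d(c(1, 1, 1), diag(3))
  expect_equal(as.matrix(a1$K), e1$K, ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(as.matrix(a1$M), e1$M, ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("implicit stepping preserves uniform states and reaches the
           steady linear profile", {
  mesh <- hex_mesh(c(1, 1, 1), c(4L, 2L, 8L))
  asm <- assemble_continuum(mesh, diag(3))
  sys <- transport_system(asm$M, asm$K)
  st <- step_implicit(sys, rep(0.7, mesh$n_nodes), 5)
  expect_lt(max(abs(st$C - 0.7)), 1e-10)
  expect_equal(st$iterations, 1L)   # linear problem: single solve
  # 1D slab with fixed ends: steady solution is linear to 1e-8
  d0 <- boundary_nodes(mesh, "z0"); d1 <- boundary_nodes(mesh, "z1")
  free <- rep(TRUE, mesh$n_nodes); free[c(d0, d1)] <- FALSE
  dv <- numeric(mesh$n_nodes); dv[d0] <- 1
  sysd <- transport_system(asm$M, asm$K, free = free, dirichlet_values = dv)
  C <- dv
  for (i in 1:60) C <- step_implicit(sysd, C, 50)$C
  expect_lt(max(abs(C - (1 - node_coords(mesh)[, 3]))), 1e-8)
})

test_that("mass accounting closes: no sink means no release", {
  mesh <- hex_mesh(c(2, 2, 2), c(3L, 3L, 3L))
  asm <- assemble_continuum(mesh, diag(3) * 0.3)
  sys <- transport_system(asm$M, asm$K)
  set.seed(2)
  C <- runif(mesh$n_nodes)
  m0 <- total_mass(sys, C)
  for (i in 1:5) {
    C2 <- step_implicit(sys, C, 0.7)$C
    expect_lt(abs(boundary_flux_mass(sys, C, C2)) / m0, 1e-12)
    C <- C2
  }
  expect_lt(abs(total_mass(sys, C) - m0) / m0, 1e-12)
})

test_that("slab release matches the analytic Fourier series", {
  run <- run_slab(nz = 40, n_steps = 400, t_end = 0.2)
  exact <- slab_release_series(run$curve$time, 1, 1)
  err <- sqrt(mean((run$curve$released - exact)^2))
  expect_lt(err, 0.01)
  expect_true(all(diff(run$curve$released) >= 0))
})

test_that("slab solution converges at second order under mesh refinement", {
  # dt scaled with h^2 so the spatial error dominates the total error
  t_end <- 0.05
  prof_err <- function(nz, n_steps) {
    run <- run_slab(nz, n_steps, t_end)
    z <- node_coords(run$mesh)[, 3]
    m <- 0:80
    exact <- sapply(z, function(zz) {
      sum(4 / (pi * (2 * m + 1)) * sin((2 * m + 1) * pi * (1 - zz) / 2) *
            exp(-(2 * m + 1)^2 * pi^2 / 4 * t_end))
    })
    sqrt(mean((run$C - exact)^2))
  }
  e1 <- prof_err(10, 50)
  e2 <- prof_err(20, 200)
  expect_gt(e1 / e2, 3)
})

test_that("symmetric data give a reflection-symmetric field", {
  mesh <- hex_mesh(c(1, 1, 1), c(4L, 4L, 6L))
  asm <- assemble_continuum(mesh, diag(3))
  d0 <- boundary_nodes(mesh, "z0"); d1 <- boundary_nodes(mesh, "z1")
  free <- rep(TRUE, mesh$n_nodes); free[c(d0, d1)] <- FALSE
  sys <- transport_system(asm$M, asm$K, free = free,
                          dirichlet_values = numeric(mesh$n_nodes))
  C <- rep(1, mesh$n_nodes); C[c(d0, d1)] <- 0
  for (i in 1:4) C <- step_implicit(sys, C, 0.01)$C
  xyz <- node_coords(mesh)
  # mirror each node through x -> 1 - x
  mirror <- apply(xyz, 1, function(p) {
    which(abs(xyz[, 1] - (1 - p[1])) < 1e-12 & abs(xyz[, 2] - p[2]) < 1e-12 &
            abs(xyz[, 3] - p[3]) < 1e-12)
  })
  expect_lt(max(abs(C - C[mirror])), 1e-10)
})

test_that("the immersed-node closure excludes fibers without leaking mass", {
  cfg <- tiny_config("detailed")
  net <- tiny_network(cfg)
  mesh <- hex_mesh(cfg$geometry$extents_um, cfg$geometry$divisions)
  imm <- mark_immersed_nodes(net, mesh)
  expect_gt(length(imm), 0)
  asm <- assemble_continuum(mesh, diag(3) * 0.04, immersed = imm)
  free <- rep(TRUE, mesh$n_nodes); free[imm] <- FALSE
  sys <- transport_system(asm$M, asm$K, free = free)
  C <- rep(0.8, mesh$n_nodes); C[imm] <- 0
  st <- step_implicit(sys, C, 1e4)
  expect_lt(max(abs(st$C[free] - 0.8)), 1e-10)   # constant field preserved
  expect_true(all(Matrix::rowSums(asm$K)[imm] == 0))
  expect_error(assemble_continuum(mesh, diag(3),
                                  immersed = seq_len(mesh$n_nodes)),
               "covers all elements")
})
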