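test_that("the homogenized fiber tensor equals brute-force summation", {
  set.seed(42)
  for (rep in 1:20) {
    nf <- sample(1:20, 1)
    D <- runif(nf, 0.01, 1); A <- runif(nf, 0.1, 2)
    dirs <- matrix(rnorm(3 * nf), nf, 3)
    got <- smeared_diffusion_tensor(D, A, dirs)
    u <- dirs / sqrt(rowSums(dirs^2))
    want <- matrix(0, 3, 3)
    for (k in seq_len(nf)) want <- want + D[k] * A[k] * tcrossprod(u[k, ])
    want <- want / sum(A)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_equal(sum(diag(got)), sum(D * A) / sum(A), tolerance = 1e-12)
    expect_gte(min(eigen(got, symmetric = TRUE)$values), -1e-14)
  }
  # one fiber along x
  expect_equal(smeared_diffusion_tensor(0.3, 1, matrix(c(1, 0, 0), 1)),
               diag(c(0.3, 0, 0)), tolerance = 1e-14)
  # two equal-area fibers at +-45 degrees in the xy-plane
  t45 <- smeared_diffusion_tensor(c(0.2, 0.2), c(1, 1),
                                  rbind(c(1, 1, 0), c(1, -1, 0)))
  expect_equal(t45, diag(c(0.1, 0.1, 0)), tolerance = 1e-14)
  expect_error(smeared_diffusion_tensor(numeric(0), numeric(0),
                                        matrix(0, 0, 3)), "at least one")
})

test_that("nodal volumes partition the mesh volume", {
  mesh <- hex_mesh(c(4, 6, 10), c(2L, 3L, 5L))
  v <- nodal_volume(mesh)
  cell <- prod(mesh$h)
  xyz <- node_coords(mesh)
  interior <- which(xyz[, 1] == 2 & xyz[, 2] == 2 & xyz[, 3] == 2)
  expect_equal(v[interior], cell)        # 8 adjacent elements x 1/8
  expect_equal(v[1], cell / 8)           # corner node
  expect_equal(sum(v), 4 * 6 * 10)
})

test_that("connectivity element matrices follow the documented forms", {
  cm <- connectivity_matrices(100, 1.25, 0.04, P = 2, mode = "mass_conserving")
  expect_equal(cm$K, matrix(c(3.2, -3.2, -6.4, 6.4), 2, 2))
  expect_equal(cm$M, matrix(0, 2, 2))
  # P = 1: both modes give the same symmetric conductance
  k1 <- connectivity_matrices(50, 1, 0.1, P = 1, mode = "mass_conserving")$K
  k2 <- connectivity_matrices(50, 1, 0.1, P = 1, mode = "paper_literal")$K
  expect_equal(k1, k2)
  expect_equal(k1, 5 * matrix(c(1, -1, -1, 1), 2, 2))
  # no fibers: zero matrices
  z <- connectivity_matrices(0, 1, 0.1, P = 3)
  expect_equal(z$K, matrix(0, 2, 2))
  # paper-literal mass matrix as printed (with the radius factor)
  pl <- connectivity_matrices(12, 2, 0.1, P = 3, mode = "paper_literal")
  expect_equal(pl$M, 12 * 2 * matrix(c(1 / 3, 3 / 6, 3 / 6, 3 / 3), 2, 2))
  expect_equal(pl$K, 12 * 0.1 / 2 * matrix(c(1, -3, -3, 3), 2, 2))
  # mass-conserving fluxes: surrounding gains what the fiber loses
  expect_equal(colSums(cm$K), c(0, 0))
  expect_error(connectivity_matrices(10, 0, 0.1), "radius")
})

test_that("the assembled CSFE system starts with the fiber load only", {
  mesh <- hex_mesh(c(10, 10, 10), c(3L, 3L, 3L))
  pr <- csfe_nodal_params(mesh, rV = 0.4223, diameter = 2.5, P = 10)
  sys <- assemble_csfe(mesh, pr, D_liquid = 0.1)
  n <- mesh$n_nodes
  C0 <- c(rep(1, n), rep(0, n))
  expect_equal(total_mass(sys, C0), 0.4223 * 1000, tolerance = 1e-12)
  lay <- attr(sys, "layout")
  expect_equal(sum(sys$cap[lay$fiber_dofs]), 0.4223 * 1000, tolerance = 1e-12)
  # surrounding capacity in physical concentration units
  expect_equal(sum(sys$cap[lay$sur_dofs] * lay$varscale[lay$sur_dofs]),
               (1 - 0.4223) * 1000, tolerance = 1e-12)
})

test_that("a closed two-compartment system equilibrates at C_fib/C_sur = P", {
  mesh <- hex_mesh(c(10, 10, 10), c(2L, 2L, 2L))
  P <- 7
  pr <- csfe_nodal_params(mesh, rV = 0.4, diameter = 2.5, P = P)
  sys <- assemble_csfe(mesh, pr, D_liquid = 0.1)
  lay <- attr(sys, "layout")
  n <- mesh$n_nodes
  C <- c(rep(1, n), rep(0, n))
  m0 <- total_mass(sys, C)
  for (i in 1:300) C <- step_implicit(sys, C, 5000, kscale = 0.04)$C
  Cs <- C[lay$sur_dofs] / lay$varscale[lay$sur_dofs]
  expect_equal(max(abs(C[lay$fiber_dofs] / Cs - P)) / P, 0, tolerance = 1e-3)
  expect_lt(abs(total_mass(sys, C) - m0) / m0, 1e-10)
  # equilibrium mass split matches the partition capacities
  expect_equal(mean(C[lay$fiber_dofs]),
               m0 / (0.4 * 1000 + 0.6 * 1000 / P), tolerance = 1e-3)
})

test_that("strong coupling equilibrates the two fields when P = 1", {
  mesh <- hex_mesh(c(10, 10, 10), c(2L, 2L, 2L))
  pr <- csfe_nodal_params(mesh, rV = 0.4, diameter = 2.5, P = 1)
  sys <- assemble_csfe(mesh, pr, D_liquid = 0.04)
  lay <- attr(sys, "layout")
  n <- mesh$n_nodes
  C <- c(rep(1, n), rep(0, n))
  for (i in 1:50) C <- step_implicit(sys, C, 1e5, kscale = 0.04)$C
  expect_lt(max(abs(C[lay$fiber_dofs] - C[lay$sur_dofs])), 1e-6)
})

test_that("distributed source terms reproduce the connectivity fluxes", {
  mesh <- hex_mesh(c(5, 5, 5), c(1L, 1L, 1L))
  Cf <- rep(0.8, 8); Cs <- rep(0.3, 8)
  st <- distributed_source_terms(mesh, 1, Cf, Cs, dt = 5, rV = 0.4,
                                 rAV = 1.6, R = 1.25, P = 2, Dfib = 0.04)
  kI <- 1.6 * 0.4 * nodal_volume(mesh)[st$nodes] * 0.04 / 1.25
  expect_lt(max(abs(st$Q_fib - kI * (0.8 - 2 * 0.3))), 1e-10)
  expect_equal(st$Q_sur, st$Q_fib)
  # equilibrium (C_fib = P C_sur) and steady fields: zero flux
  st0 <- distributed_source_terms(mesh, 1, rep(0.6, 8), rep(0.3, 8), dt = 5,
                                  rV = 0.4, rAV = 1.6, R = 1.25, P = 2,
                                  Dfib = 0.04)
  expect_equal(max(abs(st0$Q_fib)), 0)
  # transient corrections vanish for steady fields, act when C != Ct
  st1 <- distributed_source_terms(mesh, 1, Cf, Cs, Cfib_t = Cf - 0.1,
                                  Csur_t = Cs, dt = 10, rV = 0.4, rAV = 1.6,
                                  R = 1.25, P = 2, Dfib = 0.04)
  shift <- -1.25 / (6 * 10) * 0.1 * 1.6 * 0.4 * nodal_volume(mesh)[1]
  expect_equal(st1$Q_fib[1] - st$Q_fib[1], shift, tolerance = 1e-12)
})

test_that("network binning recovers volume fractions and directions", {
  # uniform parallel fiber array: constant rV equal to the packing fraction
  mesh <- hex_mesh(c(8, 8, 8), c(2L, 2L, 2L))
  rows <- expand.grid(y = seq(1, 7, 2), z = seq(1, 7, 2))
  seg <- data.frame(x0 = 0, y0 = rows$y, z0 = rows$z, x1 = 8, y1 = rows$y,
                    z1 = rows$z, radius = 0.5)
  net <- fiber_network(seg, c(8, 8, 8))
  got <- map_network_to_csfe(net, mesh)
  packing <- pi * 0.5^2 / 4          # one fiber per 2 x 2 um cell
  expect_lt(max(abs(got$rV_elem - packing)) / packing, 0.02)
  # directions: all along x
  expect_lt(max(abs(got$tensor_elem[, 2:6])), 1e-12)
  expect_equal(got$tensor_elem[, 1], rep(1, mesh$n_elem))
  # total volume bookkeeping on a random network
  cfg <- tiny_config()
  net2 <- tiny_network(cfg)
  mesh2 <- hex_mesh(cfg$geometry$extents_um, cfg$geometry$divisions)
  got2 <- map_network_to_csfe(net2, mesh2)
  expect_lt(abs(sum(got2$rV_elem * prod(mesh2$h)) - fiber_volume(net2)) /
              fiber_volume(net2), 0.02)
  # empty elements give zero tensor and zero rV
  empty <- got2$rV_elem == 0
  if (any(empty)) expect_true(all(got2$tensor_elem[empty, ] == 0))
})

test_that("numerical homogenization reduces the pore diffusivity", {
  cfg <- tiny_config()
  net <- tiny_network(cfg)
  mesh <- hex_mesh(cfg$geometry$extents_um, cfg$geometry$divisions)
  imm <- mark_immersed_nodes(net, mesh)
  Deff <- homogenize_liquid_diffusivity(mesh, imm, 0.04)
  expect_lt(Deff, 0.04)
  expect_gt(Deff, 0)
  # no fibers: the box conducts at the full diffusivity
  D0 <- homogenize_liquid_diffusivity(mesh, integer(0), 0.04)
  expect_equal(D0, 0.04, tolerance = 1e-10)
})
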