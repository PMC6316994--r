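test_that("layer generation is deterministic and hits the target coverage", {
  lay1 <- generate_layer(c(90, 90), 2.5, 0.42, seed = 42)
  lay2 <- generate_layer(c(90, 90), 2.5, 0.42, seed = 42)
  expect_identical(lay1$segments, lay2$segments)
  expect_true(all(lay1$segments$z0 == lay1$segments$z1))

  # independent Monte-Carlo point-in-fiber oracle (different seed, 1e5 pts)
  set.seed(9099)
  n <- 1e5
  px <- runif(n, 0, 90); py <- runif(n, 0, 90)
  cov <- rep(FALSE, n)
  seg <- lay1$segments
  for (s in seq_len(nrow(seg))) {
    dx <- seg$x1[s] - seg$x0[s]; dy <- seg$y1[s] - seg$y0[s]
    L2 <- dx^2 + dy^2
    tt <- pmin(pmax(((px - seg$x0[s]) * dx + (py - seg$y0[s]) * dy) / L2, 0), 1)
    d2 <- (px - seg$x0[s] - tt * dx)^2 + (py - seg$y0[s] - tt * dy)^2
    cov <- cov | d2 <= seg$radius[s]^2
  }
  expect_gte(mean(cov), 0.42 * 0.98)
  expect_lte(mean(cov), 0.42 * 1.02)
})

test_that("infeasible layer targets fail loudly", {
  expect_error(generate_layer(c(90, 90), 80, 0.9999, seed = 1),
               "unreachable coverage")
  expect_error(generate_layer(c(90, 90), 2.5, 0.999, seed = 1),
               "unreachable coverage")
})

test_that("stacking preserves per-layer fiber volume and volume fraction", {
  lay <- generate_layer(c(40, 40), 2.5, 0.35, seed = 7)
  # single layer, explicit zero shift: unchanged apart from the z offset
  st1 <- stack_layers(lay, 1L, 2.5, shifts = matrix(0, 1, 2))
  expect_equal(st1$segments$x0, lay$segments$x0)
  expect_equal(st1$segments$z0, rep(1.25, nrow(lay$segments)))

  st <- stack_layers(lay, 16L, 2.5, seed = 11)
  expect_equal(fiber_volume(st), 16 * fiber_volume(lay), tolerance = 1e-12)
  expect_equal(st$domain[3], 40)
  expect_error(stack_layers(lay, 16L, 2.5, seed = 1, domain_z = 30),
               "exceeds domain")

  # Monte-Carlo volume-fraction oracle: the stacked mat keeps the
  # single-layer volume fraction (layers are tangent, no z-overlap)
  s_lay <- compute_summary(lay, 5e4, seed = 3)
  s_stk <- compute_summary(st, 5e4, seed = 4)
  expect_lt(abs(s_stk$volume_fraction - s_lay$volume_fraction) /
              s_lay$volume_fraction, 0.03)
})

test_that("network summary matches closed-form single-cylinder values", {
  seg <- data.frame(x0 = 0, y0 = 5, z0 = 5, x1 = 10, y1 = 5, z1 = 5,
                    radius = 1)
  net <- fiber_network(seg, domain = c(10, 10, 10))
  sm <- compute_summary(net, 5e4, seed = 1)
  # rAV = 4 / diameter = 2 / R; exact cylinder area/volume ratio
  expect_equal(sm$surface_ratio, 2)
  expect_equal(sm$mean_diameter, 2)
  # MC volume fraction converges to pi R^2 L / V within 3 binomial sigmas
  p_true <- pi * 1^2 * 10 / 1000
  sig <- sqrt(p_true * (1 - p_true) / 5e4)
  expect_lt(abs(sm$volume_fraction - p_true), 3 * sig)
  # rAV * rV equals the exact surface density 2 pi R L / V
  expect_equal(sm$surface_ratio * p_true, 2 * pi * 1 * 10 / 1000)
  # all fibers parallel to x
  expect_equal(sm$orientation_moment, diag(c(1, 0, 0)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(diag(sm$orientation_moment)), 1)
  # preset fiber diameter: rAV = 4 / 2.5 = 1.6 1/um
  net2 <- fiber_network(data.frame(x0 = 0, y0 = 5, z0 = 5, x1 = 10, y1 = 5,
                                   z1 = 5, radius = 1.25), c(10, 10, 10))
  expect_equal(compute_summary(net2, 1e4, seed = 1)$surface_ratio, 1.6)
})

test_that("fiber discretization follows the half-sum belonging rule", {
  seg <- data.frame(x0 = 0, y0 = 0, z0 = 0, x1 = 10, y1 = 0, z1 = 0,
                    radius = 1.25)
  net <- fiber_network(seg, domain = c(10, 1, 1))
  pts <- discretize_fibers(net, 2.5)
  expect_equal(nrow(pts), 5)
  expect_equal(pts$Lbar, c(1.25, 2.5, 2.5, 2.5, 1.25))
  expect_equal(sum(pts$Lbar), 10)
  # segment lengths 3 and 4 sharing a point: Lbar = 3.5 at the junction
  pts2 <- discretize_fibers(fiber_network(
    data.frame(x0 = 0, y0 = 0, z0 = 0, x1 = 7, y1 = 0, z1 = 0, radius = 1),
    c(7, 1, 1)), 4)
  expect_equal(pts2$Lbar, c(1.75, 3.5, 1.75))

  # volume telescoping on a random network
  net3 <- tiny_network()
  pts3 <- discretize_fibers(net3, 3)
  expect_equal(sum(pi * pts3$radius^2 * pts3$Lbar), fiber_volume(net3),
               tolerance = 1e-10)
})

test_that("immersed nodes match an exhaustive distance oracle", {
  mesh <- hex_mesh(c(10, 10, 10), c(5L, 5L, 5L))
  # axis-aligned fiber along a grid line: exactly the on-axis nodes
  net <- fiber_network(data.frame(x0 = 0, y0 = 4, z0 = 4, x1 = 10, y1 = 4,
                                  z1 = 4, radius = 0.5), c(10, 10, 10))
  imm <- mark_immersed_nodes(net, mesh)
  xyz <- node_coords(mesh)
  oracle <- which(xyz[, 2] == 4 & xyz[, 3] == 4)
  expect_setequal(imm, oracle)

  # thin fiber between grid lines: empty set
  net2 <- fiber_network(data.frame(x0 = 0, y0 = 3, z0 = 3, x1 = 10, y1 = 3,
                                   z1 = 3, radius = 0.4), c(10, 10, 10))
  expect_length(mark_immersed_nodes(net2, mesh), 0)

  # random network vs brute-force point-in-cylinder test over all nodes
  net3 <- tiny_network()
  mesh3 <- hex_mesh(c(30, 30, 20), c(8L, 8L, 6L))
  imm3 <- mark_immersed_nodes(net3, mesh3)
  xyz3 <- node_coords(mesh3)
  seg <- net3$segments
  inside <- rep(FALSE, nrow(xyz3))
  for (s in seq_len(nrow(seg))) {
    p0 <- c(seg$x0[s], seg$y0[s], seg$z0[s])
    u <- c(seg$x1[s], seg$y1[s], seg$z1[s]) - p0
    L <- sqrt(sum(u^2)); u <- u / L
    w <- sweep(xyz3, 2, p0)
    tt <- as.vector(w %*% u)
    per2 <- rowSums(w^2) - tt^2
    inside <- inside | (tt >= 0 & tt <= L & per2 < seg$radius[s]^2 * (1 - 1e-12))
  }
  expect_setequal(imm3, which(inside))
})

test_that("common points map to the nearest admissible node", {
  mesh <- hex_mesh(c(10, 10, 10), c(5L, 5L, 5L))
  # point exactly at a node maps there
  pts <- data.frame(x = 4, y = 6, z = 2)
  id <- map_to_continuum(pts, mesh)
  xyz <- node_coords(mesh)
  expect_equal(unname(xyz[id, ]), c(4, 6, 2))
  # cell-center tie broken by lowest node id among the 8 corners
  ptc <- data.frame(x = 1, y = 1, z = 1)
  idc <- map_to_continuum(ptc, mesh)
  corners <- which(apply(xyz, 1, function(p) all(abs(p - 1) <= 1 + 1e-9)) &
                     xyz[, 1] %in% c(0, 2) & xyz[, 2] %in% c(0, 2) &
                     xyz[, 3] %in% c(0, 2))
  expect_equal(idc, min(corners))
  # randomized points vs brute-force nearest-node search
  set.seed(5)
  rp <- data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10),
                   z = runif(40, 0, 10))
  ids <- map_to_continuum(rp, mesh)
  for (i in seq_len(nrow(rp))) {
    d <- sqrt(colSums((t(xyz) - as.numeric(rp[i, ]))^2))
    expect_equal(d[ids[i]], min(d), tolerance = 1e-12)
    expect_lte(d[ids[i]], sqrt(sum(mesh$h^2)))
  }
  # excluded nodes are avoided
  excl <- map_to_continuum(pts, mesh, excluded = id)
  expect_false(excl == id)
})

test_that("network files round-trip bit-exactly", {
  net <- tiny_network()
  path <- tempfile(fileext = ".csv")
  write_fiber_network(net, path)
  back <- read_fiber_network(path)
  expect_identical(back$segments, net$segments)
  expect_equal(back$domain, net$domain)
  path2 <- tempfile(fileext = ".csv")
  write_fiber_network(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})
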