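#' Homogenized fiber diffusion tensor
#'
#' Continuum-equivalent tensor of axial diffusion along a bundle of fibers:
#' `D_ij = (1 / A_tot) * sum_K D_K A_K l_Ki l_Kj` over the fibers near a
#' point, with `A_tot = sum_K A_K`.
#'
#' @param D Per-fiber diffusion coefficients (um^2/s).
#' @param A Per-fiber cross-sectional areas (um^2), > 0.
#' @param dirs `n x 3` matrix of fiber direction cosines (rows need not be
#'   normalized; they are normalized internally).
#' @return Symmetric positive semi-definite 3x3 tensor with
#'   `trace = sum(D * A) / sum(A)`.
#' @export
smeared_diffusion_tensor <- function(D, A, dirs) {
  if (length(D) == 0L) stop("at least one fiber is required")
  dirs <- as.matrix(dirs)
  if (is.null(dim(dirs)) || ncol(dirs) != 3L) dirs <- matrix(dirs, ncol = 3)
  stopifnot(length(A) == length(D), nrow(dirs) == length(D), all(A > 0))
  u <- dirs / sqrt(rowSums(dirs^2))
  crossprod(u * (D * A), u) / sum(A)
}

#' Nodal parameters of the composite smeared finite element
#'
#' Per-node smeared quantities driving the connectivity elements: fiber
#' volume fraction `rV`, surface ratio `rAV = 4 / diameter`, mean fiber
#' radius `R`, partitioning `P`, nodal volume `V_I` and the smeared fiber
#' surface area at the node `A_fib = rAV * rV * V_I`.
#'
#' @param mesh A [hex_mesh()].
#' @param rV Fiber volume fraction, scalar or per-node, in (0, 1).
#' @param diameter Fiber diameter (um), scalar or per-node.
#' @param P Partitioning coefficient, scalar or per-node, >= 0.
#' @return Object of class `csfe_nodal_params` (list of per-node vectors).
#' @export
csfe_nodal_params <- function(mesh, rV, diameter, P = 1) {
  stopifnot(inherits(mesh, "hex_mesh"))
  n <- mesh$n_nodes
  rV <- rep_len(rV, n); diameter <- rep_len(diameter, n); P <- rep_len(P, n)
  stopifnot(all(rV >= 0), all(rV < 1), all(diameter > 0), all(P >= 0))
  V_I <- nodal_volume(mesh)
  rAV <- 4 / diameter
  structure(
    list(rV = rV, rAV = rAV, R = diameter / 2, P = P, V_I = V_I,
         A_fib = rAV * rV * V_I, n = n),
    class = "csfe_nodal_params"
  )
}

#' Connectivity-element matrices at one node
#'
#' The 2-DOF element coupling the fiber concentration (DOF 1) and the
#' surrounding concentration (DOF 2) at a node, encoding the smeared fiber
#' surface area `A_fib`, the radial conductance `A_fib * Dfib / R`, and the
#' partitioning `P`. In the default `mass_conserving` mode the stiffness is
#' `K = k * [[1, -P], [-1, P]]` with `k = scale * A_fib * Dfib / R` (the
#' surrounding gains exactly what the fiber loses, for any `P`) and the
#' transient interface corrections are omitted (at practical time steps they
#' are O(R^2 / (D dt)) ~ 1e-5 of the conductance). `paper_literal` mode
#' keeps the textbook form: `K = k * [[1, -P], [-P, P]]` plus the mass
#' matrix `M = A_fib * R * [[1/3, P/6], [P/6, P/3]]`.
#'
#' @param A_fib Fiber surface area at the node (um^2), >= 0.
#' @param R Mean fiber radius (um), > 0 whenever `A_fib > 0`.
#' @param Dfib Fiber transport coefficient (um^2/s).
#' @param P Partitioning coefficient, >= 0.
#' @param mode `"mass_conserving"` (default) or `"paper_literal"`.
#' @param conductance_scale Dimensionless multiplier on the interface
#'   conductance (default 1).
#' @return List with 2x2 `M` (um^3) and `K` (um^3/s) on DOFs
#'   `(C_fib, C_sur)`.
#' @export
connectivity_matrices <- function(A_fib, R, Dfib, P = 1,
                                  mode = c("mass_conserving", "paper_literal"),
                                  conductance_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(A_fib >= 0, Dfib >= 0, P >= 0, conductance_scale > 0)
  if (A_fib == 0) {
    return(list(M = matrix(0, 2, 2), K = matrix(0, 2, 2)))
  }
  if (R <= 0) stop("fiber radius must be > 0 where A_fib > 0")
  k <- conductance_scale * A_fib * Dfib / R
  if (mode == "mass_conserving") {
    list(M = matrix(0, 2, 2),
         K = matrix(c(k, -k, -P * k, P * k), 2, 2))
  } else {
    list(M = A_fib * R * matrix(c(1 / 3, P / 6, P / 6, P / 3), 2, 2),
         K = matrix(c(k, -P * k, -P * k, P * k), 2, 2))
  }
}

#' Assemble the composite smeared finite element system
#'
#' Builds the dual-field transport system on `2 N` DOFs (fiber field first,
#' surrounding field second, co-located at every mesh node): fiber-domain
#' continuum matrices use the homogenized fiber tensor weighted by
#' `rV * V`, surrounding-domain matrices use isotropic `D_liquid` weighted
#' by `(1 - rV) * V`, and one connectivity element per node couples the two
#' fields. Fiber-block and connectivity stiffness are per unit fiber
#' diffusivity and live in `K1` (degradation rescales them); the
#' surrounding block is `K0`. In `mass_conserving` mode the surrounding
#' field is carried internally as `u = P * C_sur`, which keeps the system
#' symmetric for any partitioning while banishing the (possibly enormous)
#' `P` factors from the matrix entries; the capacity vector and the DOF
#' scaling recorded in the layout map back to physical concentrations.
#'
#' @param mesh A [hex_mesh()].
#' @param params A [csfe_nodal_params()].
#' @param D_liquid Surrounding-domain diffusivity (um^2/s).
#' @param fiber_tensor_unit Per-element fiber tensor at unit fiber
#'   diffusivity: an `n_elem` x 6 matrix of components, a 3x3 matrix, or
#'   `NULL` for the preset in-plane isotropic tensor
#'   `diag(1/2, 1/2, 0)` of a random planar mat.
#' @param rV_elem Per-element fiber volume fraction (default: mean of the
#'   element's nodal `rV`).
#' @param mode Connectivity mode, see [connectivity_matrices()].
#' @param conductance_scale Interface conductance multiplier.
#' @param sink_nodes Mesh node ids where both fields are held at zero (the
#'   outer implant boundary).
#' @return A [transport_system()] with attribute `layout` (`n_nodes`,
#'   `fiber_dofs`, `sur_dofs`).
#' @export
assemble_csfe <- function(mesh, params, D_liquid, fiber_tensor_unit = NULL,
                          rV_elem = NULL,
                          mode = c("mass_conserving", "paper_literal"),
                          conductance_scale = 1, sink_nodes = integer(0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "hex_mesh"), inherits(params, "csfe_nodal_params"),
            params$n == mesh$n_nodes, D_liquid >= 0)
  n <- mesh$n_nodes
  if (is.null(rV_elem)) {
    conn <- mesh_connectivity(mesh)
    rV_elem <- rowMeans(matrix(params$rV[conn], nrow(conn), 8))
  }
  if (is.null(fiber_tensor_unit)) {
    fiber_tensor_unit <- diag(c(0.5, 0.5, 0))
  }
  fib <- assemble_continuum(mesh, fiber_tensor_unit, weight = rV_elem)
  sur <- assemble_continuum(mesh, diag(3) * D_liquid, weight = 1 - rV_elem)

  # connectivity elements: diagonal coupling between co-located DOFs
  idx <- seq_len(n)
  k <- conductance_scale * params$A_fib / ifelse(params$A_fib > 0,
                                                 params$R, 1)
  P <- params$P
  scaled <- mode == "mass_conserving"
  if (scaled && any(P <= 0)) {
    stop("partitioning P must be > 0 in mass_conserving mode")
  }
  two <- function(A, B) methods::as(Matrix::bdiag(A, B), "CsparseMatrix")
  zero_n <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  if (scaled) {
    if (diff(range(P)) > 1e-12 * max(P)) {
      stop("mass_conserving mode requires a spatially uniform partitioning P")
    }
    P1 <- P[1]
    # u = P C_sur: the connectivity in (C_fib, u) is the plain conductance
    # k [[1, -1], [-1, 1]] and the surrounding operators carry 1/P -- the
    # system stays symmetric and free of large partitioning factors
    Kconn <- sparseMatrix(
      i = c(idx, idx, n + idx, n + idx),
      j = c(idx, n + idx, idx, n + idx),
      x = c(k, -k, -k, k), dims = c(2 * n, 2 * n))
    M_eq <- two(fib$M, sur$M / P1)
    K0 <- two(zero_n, sur$K / P1)
    K1 <- two(fib$K, zero_n) + Kconn
    cap <- c(as.numeric(colSums(fib$M)), as.numeric(colSums(sur$M)) / P1)
    varscale <- c(rep(1, n), P)
  } else {
    # paper-literal connectivity (symmetric as printed), physical variables
    Kconn <- sparseMatrix(
      i = c(idx, idx, n + idx, n + idx),
      j = c(idx, n + idx, idx, n + idx),
      x = c(k, -P * k, -P * k, P * k), dims = c(2 * n, 2 * n))
    M_eq <- two(fib$M, sur$M)
    K0 <- two(zero_n, sur$K)
    K1 <- two(fib$K, zero_n) + Kconn
    AR <- params$A_fib * params$R
    M_eq <- M_eq + sparseMatrix(
      i = c(idx, idx, n + idx, n + idx),
      j = c(idx, n + idx, idx, n + idx),
      x = c(AR / 3, P * AR / 6, P * AR / 6, P * AR / 3),
      dims = c(2 * n, 2 * n))
    cap <- as.numeric(colSums(two(fib$M, sur$M)))
    varscale <- rep(1, 2 * n)
  }

  free <- rep(TRUE, 2 * n)
  free[c(sink_nodes, n + sink_nodes)] <- FALSE
  # fiber DOFs carry no equation where the binned network leaves a node
  # without any fiber capacity, conduction or surface exchange
  fib_dead <- Matrix::diag(fib$M) == 0 & Matrix::diag(fib$K) == 0 & k == 0
  free[which(fib_dead)] <- FALSE
  sys <- transport_system(M = M_eq, K0 = K0, K1 = K1, free = free,
                          dirichlet_values = numeric(2 * n), cap = cap,
                          perm = nd_dof_order(mesh, n_fields = 2L))
  attr(sys, "layout") <- list(n_nodes = n, fiber_dofs = idx,
                              sur_dofs = n + idx,
                              eqscale = rep(1, 2 * n), varscale = varscale,
                              mesh_nn = mesh$nn,
                              # direct sparse factors are robust for the
                              # substituted system; CG with the rotated
                              # block preconditioner takes over where a
                              # monolithic dual-field factor would not fit
                              # in memory
                              schur_pcg = scaled && n > 30000L)
  sys
}

#' Distributed interface source terms (reference cross-check)
#'
#' Gauss-point evaluation of the smeared fiber-surface flux on one element,
#' distributed to nodes through the shape functions: the flux density is
#' `dq = [D/R (Cfib - P Csur) - R/(6 dt) (C - Ct)_fib - R/(3 dt) P (C - Ct)_sur]
#' * rAV * rV` per unit volume, integrated as `Q_I = int N_I dq dV`. The
#' fiber field loses `Q_I`, the surrounding field gains it (multiplied by
#' `1 - rV` when `tissue_reduction = TRUE`, the literal textbook variant).
#' This path is an alternative to the connectivity elements and is provided
#' as a numerical cross-check: for uniform fields it reproduces the
#' connectivity-element fluxes with the nodal areas `A_fib = rAV rV V_I`.
#'
#' @param mesh A [hex_mesh()]; the element geometry source.
#' @param element Element id.
#' @param Cfib,Csur,Cfib_t,Csur_t Per-node field vectors (full mesh).
#' @param dt Time step (s).
#' @param rV,rAV,R,P,Dfib Scalar smeared parameters on the element.
#' @param tissue_reduction Apply the `(1 - rV)` factor to the surrounding
#'   distribution (default `FALSE`, matching the connectivity elements).
#' @return List with per-local-node fluxes `Q_fib` (mass/s leaving the
#'   fiber field) and `Q_sur` (mass/s entering the surrounding field),
#'   each length 8, plus the element node ids.
#' @export
distributed_source_terms <- function(mesh, element, Cfib, Csur,
                                     Cfib_t = Cfib, Csur_t = Csur, dt = 1,
                                     rV, rAV, R, P = 1, Dfib,
                                     tissue_reduction = FALSE) {
  stopifnot(inherits(mesh, "hex_mesh"), element >= 1,
            element <= mesh$n_elem, dt > 0)
  conn <- mesh_connectivity(mesh)[element, ]
  g <- 1 / sqrt(3)
  detJ <- prod(mesh$h) / 8
  Qf <- numeric(8)
  for (gx in c(-g, g)) for (gy in c(-g, g)) for (gz in c(-g, g)) {
    N <- hex_shape(c(gx, gy, gz))$N
    cf <- sum(N * Cfib[conn]); cs <- sum(N * Csur[conn])
    cft <- sum(N * Cfib_t[conn]); cst <- sum(N * Csur_t[conn])
    dq <- (Dfib / R * (cf - P * cs) -
             R / (6 * dt) * (cf - cft) -
             R / (3 * dt) * P * (cs - cst)) * rAV * rV
    Qf <- Qf + N * dq * detJ
  }
  list(Q_fib = Qf,
       Q_sur = if (tissue_reduction) (1 - rV) * Qf else Qf,
       nodes = conn)
}

#' Bin a fiber network onto the smeared-model mesh
#'
#' Computes per-element fiber volume fractions and homogenized unit-
#' diffusivity tensors (length-weighted directional moments of the fibers
#' crossing each element), and per-node smeared parameters by averaging
#' over adjacent elements. Fiber lengths are binned by sampling each
#' segment at sub-cell resolution.
#'
#' @param net A [fiber_network()].
#' @param mesh A [hex_mesh()].
#' @param P Partitioning coefficient passed through to the nodal params.
#' @param step_frac Sampling step as a fraction of the smallest cell edge.
#' @return List with `rV_elem` (length `n_elem`), `tensor_elem`
#'   (`n_elem` x 6 unit-diffusivity components), and `params`
#'   (a [csfe_nodal_params()]).
#' @export
map_network_to_csfe <- function(net, mesh, P = 1, step_frac = 0.25) {
  stopifnot(inherits(net, "fiber_network"), inherits(mesh, "hex_mesh"))
  seg <- net$segments
  len <- segment_lengths(net)
  step <- min(mesh$h) * step_frac
  ne <- mesh$n_elem
  vol <- numeric(ne)
  tens <- matrix(0, ne, 6)
  wsum <- numeric(ne)
  for (s in seq_len(nrow(seg))) {
    nsmp <- max(1L, ceiling(len[s] / step))
    dl <- len[s] / nsmp
    tt <- (seq_len(nsmp) - 0.5) / nsmp
    px <- seg$x0[s] + tt * (seg$x1[s] - seg$x0[s])
    py <- seg$y0[s] + tt * (seg$y1[s] - seg$y0[s])
    pz <- seg$z0[s] + tt * (seg$z1[s] - seg$z0[s])
    ex <- pmin(pmax(floor(px / mesh$h[1]), 0), mesh$div[1] - 1)
    ey <- pmin(pmax(floor(py / mesh$h[2]), 0), mesh$div[2] - 1)
    ez <- pmin(pmax(floor(pz / mesh$h[3]), 0), mesh$div[3] - 1)
    eid <- 1 + ex + mesh$div[1] * (ey + mesh$div[2] * ez)
    w <- pi * seg$radius[s]^2 * dl
    cnt <- tabulate(eid, nbins = ne)
    add <- cnt * w
    vol <- vol + add
    u <- c(seg$x1[s] - seg$x0[s], seg$y1[s] - seg$y0[s],
           seg$z1[s] - seg$z0[s]) / len[s]
    uu <- c(u[1]^2, u[2]^2, u[3]^2, u[1] * u[2], u[1] * u[3], u[2] * u[3])
    tens <- tens + outer(add, uu)
    wsum <- wsum + add
  }
  Vel <- prod(mesh$h)
  rV_elem <- pmin(vol / Vel, 0.99)
  nzw <- wsum > 0
  tens[nzw, ] <- tens[nzw, ] / wsum[nzw]

  # nodal rV: average of adjacent elements (equal 1/8-volume weights)
  conn <- mesh_connectivity(mesh)
  num <- numeric(mesh$n_nodes); den <- numeric(mesh$n_nodes)
  for (l in 1:8) {
    num_add <- tapply(rV_elem, conn[, l], sum)
    ids <- as.integer(names(num_add))
    num[ids] <- num[ids] + as.numeric(num_add)
    cnt <- tapply(rep(1, ne), conn[, l], sum)
    den[ids] <- den[ids] + as.numeric(cnt)
  }
  rV_nodal <- ifelse(den > 0, num / pmax(den, 1), 0)
  d_mean <- sum(2 * seg$radius * len) / sum(len)
  params <- csfe_nodal_params(mesh, rV = pmin(rV_nodal, 0.99),
                              diameter = d_mean, P = P)
  list(rV_elem = rV_elem, tensor_elem = tens, params = params)
}

#' Numerical homogenization of the surrounding diffusivity
#'
#' Effective through-thickness diffusivity of the pore space obstructed by
#' the fiber network: a steady diffusion problem with unit concentration
#' drop across the z-extent is solved on the continuum with immersed nodes
#' removed, and the effective coefficient is recovered from the dissipated
#' energy. Used to hand the detailed model's pore space to the smeared
#' model on a consistent footing.
#'
#' @param mesh A [hex_mesh()].
#' @param immersed Immersed node ids ([mark_immersed_nodes()]).
#' @param D_liquid Pore diffusivity (um^2/s).
#' @return Effective diffusivity (um^2/s), `<= D_liquid`.
#' @export
homogenize_liquid_diffusivity <- function(mesh, immersed, D_liquid) {
  asm <- assemble_continuum(mesh, diag(3) * D_liquid, immersed = immersed)
  z0 <- setdiff(boundary_nodes(mesh, "z0"), immersed)
  z1 <- setdiff(boundary_nodes(mesh, "z1"), immersed)
  n <- mesh$n_nodes
  free <- rep(TRUE, n); free[immersed] <- FALSE
  free[c(z0, z1)] <- FALSE
  free[Matrix::diag(asm$K) == 0] <- FALSE   # enclosed pocket nodes
  dval <- numeric(n); dval[z0] <- 1
  sys <- transport_system(asm$M, asm$K, free = free, dirichlet_values = dval,
                          perm = nd_dof_order(mesh))
  C <- steady_state(sys)
  E <- as.numeric(C %*% (asm$K %*% C))     # total dissipation = flux * dC
  A <- mesh$extents[1] * mesh$extents[2]
  E * mesh$extents[3] / A
}
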