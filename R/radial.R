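#' Mass and stiffness of one radial 1D subelement
#'
#' Closed-form matrices of a 2-node axisymmetric radial element spanning
#' `[Ri, Ri + L]` inside a fiber, for the cross-section of axial extent
#' `Lbar` (the belonging length of the common point):
#' `M11 = 2 pi Lbar L (Ri/3 + L/12)`, `M12 = 2 pi Lbar L (Ri/6 + L/12)`,
#' `M22 = 2 pi Lbar L (Ri/3 + L/4)`, and
#' `K = (2 pi Lbar D / L) (Ri + L/2) * [[1, -1], [-1, 1]]`.
#' Node 1 is the inner node (closer to the fiber axis), node 2 the outer.
#' The matrix entries sum to the subelement volume
#' `pi ((Ri+L)^2 - Ri^2) Lbar`.
#'
#' @param Ri Inner radius of the subelement (um), >= 0.
#' @param L Subelement radial length (um), > 0.
#' @param Lbar Belonging length of the common point (um), > 0.
#' @param Dfiber Fiber diffusivity (um^2/s).
#' @return List with `M` (um^3) and `K` (um^3/s), both 2x2.
#' @export
radial_subelement_matrices <- function(Ri, L, Lbar, Dfiber) {
  stopifnot(Ri >= 0, L > 0, Lbar > 0, Dfiber >= 0)
  c0 <- 2 * pi * Lbar * L
  M <- matrix(c(c0 * (Ri / 3 + L / 12), c0 * (Ri / 6 + L / 12),
                c0 * (Ri / 6 + L / 12), c0 * (Ri / 3 + L / 4)), 2, 2)
  k <- 2 * pi * Lbar * Dfiber * (Ri + L / 2) / L
  K <- matrix(c(k, -k, -k, k), 2, 2)
  list(M = M, K = K)
}

#' Build a radial chain for one common point
#'
#' Assembles `n_sub` equal-length radial subelements from the fiber axis
#' (node 1) to the fiber surface (node `n_sub + 1`). The assembled mass
#' matrix totals the fiber volume `pi R^2 Lbar` belonging to the point.
#' The stiffness is stored per unit diffusivity (`K = Dfiber * K_unit`).
#'
#' @param R Fiber radius (um), > 0.
#' @param Lbar Belonging length (um), > 0.
#' @param n_sub Number of subelements, >= 1.
#' @param Dfiber Fiber diffusivity (um^2/s), default 1.
#' @return Object of class `radial_chain` with `M`, `K_unit`, `Dfiber`,
#'   `radii` (node radii), `R`, `Lbar`, `n_sub`, `surface_area`
#'   (`2 pi R Lbar`).
#' @export
build_chain <- function(R, Lbar, n_sub, Dfiber = 1) {
  stopifnot(R > 0, Lbar > 0, n_sub >= 1L)
  n <- n_sub + 1L
  L <- R / n_sub
  M <- matrix(0, n, n)
  K <- matrix(0, n, n)
  for (j in seq_len(n_sub)) {
    el <- radial_subelement_matrices((j - 1) * L, L, Lbar, 1)
    idx <- c(j, j + 1L)
    M[idx, idx] <- M[idx, idx] + el$M
    K[idx, idx] <- K[idx, idx] + el$K
  }
  structure(
    list(M = M, K_unit = K, Dfiber = Dfiber, radii = (0:n_sub) * L,
         R = R, Lbar = Lbar, n_sub = n_sub, surface_area = 2 * pi * R * Lbar),
    class = "radial_chain"
  )
}

#' Update the chain diffusivity from the degradation model
#'
#' Rebuilds the chain stiffness with
#' `Dfiber = effective_diffusivity(params, t)`; the mass matrix is
#' unchanged (the fiber radius does not swell).
#'
#' @param chain A [build_chain()] object.
#' @param t Time in seconds.
#' @param params A [degradation_params()] object.
#' @return The updated chain.
#' @export
update_chain_diffusivity <- function(chain, t, params) {
  stopifnot(inherits(chain, "radial_chain"))
  chain$Dfiber <- effective_diffusivity(params, t)
  chain
}

#' Chain stiffness at the current diffusivity
#' @param chain A [build_chain()] object.
#' @return Dense `(n_sub+1)` square stiffness matrix (um^3/s).
#' @export
chain_stiffness <- function(chain) chain$Dfiber * chain$K_unit

#' Simulate release from a single radial chain with a surface sink
#'
#' Fixes the surface node at zero concentration (instantaneous sink) and
#' integrates the chain with backward Euler on the supplied time grid;
#' the release fraction is compared in tests against the analytic
#' infinite-cylinder Bessel series.
#'
#' @param chain A [build_chain()] object.
#' @param times Increasing vector of output times (s), starting after 0.
#' @param C0 Initial concentration in the chain (default 1, uniform).
#' @return Data frame with `time` and `released` (fraction of initial mass).
#' @export
chain_release_curve <- function(chain, times, C0 = 1) {
  stopifnot(inherits(chain, "radial_chain"), all(diff(times) > 0),
            times[1] > 0)
  n <- chain$n_sub + 1L
  free <- rep(TRUE, n); free[n] <- FALSE
  sys <- transport_system(
    M = methods::as(Matrix::Matrix(chain$M, sparse = TRUE), "CsparseMatrix"),
    K0 = methods::as(Matrix::Matrix(chain_stiffness(chain), sparse = TRUE),
                     "CsparseMatrix"),
    free = free, dirichlet_values = numeric(n))
  C <- rep(C0, n)
  m0 <- total_mass(sys, C)
  out <- numeric(length(times))
  t_prev <- 0
  for (i in seq_along(times)) {
    st <- step_implicit(sys, C, times[i] - t_prev)
    C <- st$C
    out[i] <- 1 - total_mass(sys, C) / m0
    t_prev <- times[i]
  }
  data.frame(time = times, released = out)
}

#' Analytic release fraction from an infinite cylinder with a surface sink
#'
#' Fourier-Bessel series for uniform initial concentration and zero surface
#' concentration: `released(t) = 1 - sum_n (4 / a_n^2) exp(-D a_n^2 t / R^2)`
#' over the positive roots `a_n` of `J0`.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param R Cylinder radius (um).
#' @param D Diffusivity (um^2/s).
#' @param n_roots Number of Bessel roots (>= 20 recommended).
#' @return Released fraction(s).
#' @export
cylinder_release_series <- function(t, R, D, n_roots = 50) {
  roots <- bessel_j0_roots(n_roots)
  tau <- outer(D * t / R^2, roots^2)           # n_t x n_roots
  rem <- colSums(t(exp(-tau)) * (4 / roots^2))
  1 - rem
}

# first n positive roots of J0, by bisection around the asymptotic spacing
bessel_j0_roots <- function(n) {
  vapply(seq_len(n), function(k) {
    lo <- (k - 0.75) * pi; hi <- (k + 0.25) * pi
    stats::uniroot(function(x) besselJ(x, 0), c(lo, hi),
                   tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Assemble the detailed model: continuum plus radial chains
#'
#' Builds the coupled transport system of the detailed model: trilinear
#' continuum elements for the surrounding (with immersed nodes removed from
#' the unknowns), one radial chain per fiber common point, and the
#' fiber-surface coupling. With partitioning `P = 1` the chain surface node
#' shares the DOF of the nearest admissible continuum node; with `P != 1`
#' the surface node is an independent unknown tied to the continuum node by
#' an interface element with flux `g A (C_surf - P C_cont)`,
#' `g = Dfiber / L_sub` (conductance of the outermost subelement) and
#' `A = 2 pi R Lbar`. Chain and interface stiffness are proportional to the
#' fiber diffusivity and live in `K1`, so degradation updates amount to
#' rescaling. For `P != 1` the continuum field is carried internally as
#' `u = P * C_cont` (and its equations divided by `P`), which keeps the
#' system symmetric and removes the huge partitioning factors from the
#' matrix; the capacity vector and the DOF scaling in the layout map back
#' to physical concentrations.
#'
#' @param mesh A [hex_mesh()].
#' @param points Common points from [discretize_fibers()].
#' @param mapping Continuum node ids from [map_to_continuum()].
#' @param immersed Immersed node ids from [mark_immersed_nodes()].
#' @param D_liquid Surrounding diffusivity (um^2/s).
#' @param n_sub Radial subelements per chain.
#' @param P Fiber-surface partitioning coefficient (>= 0).
#' @param conductance_scale Multiplier on the interface conductance
#'   (default 1; only used when `P != 1`).
#' @param sink_nodes Continuum node ids held at zero concentration.
#' @return A [transport_system()] with attribute `layout` describing the
#'   DOF blocks (`n_cont`, per-chain index ranges, `fiber_dofs`).
#' @export
assemble_detailed <- function(mesh, points, mapping, immersed, D_liquid,
                              n_sub = 8L, P = 1, conductance_scale = 1,
                              sink_nodes = integer(0)) {
  stopifnot(inherits(mesh, "hex_mesh"), nrow(points) == length(mapping),
            n_sub >= 1L, P >= 0)
  if (length(intersect(mapping, immersed)) ||
      length(intersect(mapping, sink_nodes))) {
    stop("chain surface nodes must be free continuum DOFs (not immersed or Dirichlet-fixed)")
  }
  nc <- mesh$n_nodes
  npt <- nrow(points)
  shared <- (P == 1)
  dof_per_chain <- if (shared) n_sub else n_sub + 1L
  n <- nc + npt * dof_per_chain

  cont <- assemble_continuum(mesh, diag(3) * D_liquid, immersed = immersed)

  # chain DOFs: axis first; for shared coupling the outermost chain node IS
  # the mapped continuum node
  chain0 <- nc + (seq_len(npt) - 1L) * dof_per_chain   # offset per chain
  R <- points$radius
  Lb <- points$Lbar
  Ls <- R / n_sub

  ti <- list(); tj <- list(); tm <- list(); tk <- list()
  push <- function(i, j, m, k) {
    idx <- length(ti) + 1L
    ti[[idx]] <<- i; tj[[idx]] <<- j; tm[[idx]] <<- m; tk[[idx]] <<- k
  }
  dof_of <- function(j) {
    # global dof of chain node j (1 = axis .. n_sub+1 = surface), vectorized
    if (shared && j == n_sub + 1L) mapping else chain0 + j
  }
  for (j in seq_len(n_sub)) {
    Ri <- (j - 1) * Ls
    c0 <- 2 * pi * Lb * Ls
    m11 <- c0 * (Ri / 3 + Ls / 12); m12 <- c0 * (Ri / 6 + Ls / 12)
    m22 <- c0 * (Ri / 3 + Ls / 4)
    kk <- 2 * pi * Lb * (Ri + Ls / 2) / Ls
    d1 <- dof_of(j); d2 <- dof_of(j + 1L)
    push(c(d1, d1, d2, d2), c(d1, d2, d1, d2),
         c(m11, m12, m12, m22), c(kk, -kk, -kk, kk))
  }
  if (!shared) {
    # interface element in (C_surf, u = P C_cont): flux g (C_surf - u);
    # conductance per unit Dfiber
    g <- conductance_scale * (2 * pi * R * Lb) / Ls
    ds <- chain0 + n_sub + 1L
    dc <- mapping
    push(c(ds, ds, dc, dc), c(ds, dc, ds, dc),
         rep(0, 4L * npt), c(g, -g, -g, g))
  }
  ti <- unlist(ti); tj <- unlist(tj); tm <- unlist(tm); tk <- unlist(tk)

  Mch <- sparseMatrix(i = ti, j = tj, x = tm, dims = c(n, n))
  K1 <- sparseMatrix(i = ti, j = tj, x = tk, dims = c(n, n))

  # in u the continuum equations keep their physical scale while the huge
  # partitioning factors disappear from the matrix entirely
  eqscale <- rep(1, n)                       # equation rows stay physical
  varscale <- rep(1, n)                      # DOF = varscale * physical value
  if (!shared) varscale[seq_len(nc)] <- P
  pad <- function(A) {
    z <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(n - nc, n - nc))
    methods::as(Matrix::bdiag(A, z), "CsparseMatrix")
  }
  cscale <- if (shared) 1 else 1 / P
  Mc <- pad(cont$M); Kc <- pad(cont$K)
  M_eq <- cscale * Mc + Mch
  K0 <- cscale * Kc

  cap <- as.numeric(cscale * colSums(Mc) + colSums(Mch))
  free <- rep(TRUE, n)
  free[immersed] <- FALSE
  free[sink_nodes] <- FALSE
  # continuum nodes fully enclosed by immersed neighbors end up with empty
  # equations (every adjacent element reduces to its free-node average);
  # they carry no unknown either
  dA <- Matrix::diag(M_eq) + Matrix::diag(K0) + Matrix::diag(K1)
  free[dA == 0] <- FALSE
  dval <- numeric(n)

  sys <- transport_system(M = M_eq, K0 = K0, K1 = K1, free = free,
                          dirichlet_values = dval, cap = cap,
                          perm = nd_dof_order(mesh, n_fields = 1L,
                                              extra_first = (nc + 1L):n))
  fiber_dofs <- logical(n)
  for (j in seq_len(n_sub + if (shared) 0L else 1L)) fiber_dofs[chain0 + j] <- TRUE
  attr(sys, "layout") <- list(n_cont = nc, n_chains = npt,
                              dof_per_chain = dof_per_chain,
                              chain_offset = chain0, shared = shared,
                              fiber_dofs = which(fiber_dofs),
                              eqscale = eqscale, varscale = varscale)
  sys
}
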