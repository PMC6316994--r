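#' @importFrom Matrix sparseMatrix Cholesky solve crossprod t Diagonal colSums
NULL

# trilinear shape functions and gradients on [-1,1]^3, corners ordered with
# x fastest (local l = 1 + dx + 2 dy + 4 dz)
hex_shape <- function(xi) {
  s <- expand.grid(dx = c(-1, 1), dy = c(-1, 1), dz = c(-1, 1))
  N <- (1 + s$dx * xi[1]) * (1 + s$dy * xi[2]) * (1 + s$dz * xi[3]) / 8
  dN <- rbind(
    s$dx * (1 + s$dy * xi[2]) * (1 + s$dz * xi[3]) / 8,
    s$dy * (1 + s$dx * xi[1]) * (1 + s$dz * xi[3]) / 8,
    s$dz * (1 + s$dx * xi[1]) * (1 + s$dy * xi[2]) / 8
  )
  list(N = N, dN = dN)
}

# reference mass matrix and the six stiffness component matrices
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) for a box element with edge lengths h,
# integrated with 2x2x2 Gauss quadrature (exact for trilinear functions)
hex_reference_matrices <- function(h) {
  stopifnot(length(h) == 3L, all(h > 0))
  g <- 1 / sqrt(3)
  detJ <- prod(h) / 8
  M <- matrix(0, 8, 8)
  Kc <- replicate(6, matrix(0, 8, 8), simplify = FALSE)
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (gx in c(-g, g)) for (gy in c(-g, g)) for (gz in c(-g, g)) {
    sh <- hex_shape(c(gx, gy, gz))
    B <- sh$dN * (2 / h)              # physical gradients, 3 x 8
    M <- M + detJ * tcrossprod(sh$N)
    for (p in seq_along(pairs)) {
      a <- pairs[[p]][1]; b <- pairs[[p]][2]
      contrib <- detJ * tcrossprod(B[a, ], B[b, ])
      Kc[[p]] <- Kc[[p]] + if (a == b) contrib else contrib + t(contrib)
    }
  }
  list(M = M, Kc = Kc)
}

#' Element mass and stiffness matrices of a trilinear hexahedron
#'
#' Consistent matrices `M_IJ = int N_I N_J dV` and
#' `K_IJ = int D_ij N_I,i N_J,j dV` on an axis-aligned box element,
#' evaluated with 2x2x2 Gauss quadrature.
#'
#' @param h Numeric length-3 element edge lengths (um), all > 0.
#' @param D A symmetric positive semi-definite 3x3 diffusion tensor
#'   (um^2/s), or a scalar for isotropic diffusion.
#' @return List with `M` (um^3) and `K` (um^3/s), both 8x8; local node `l`
#'   sits at corner offsets `(dx, dy, dz)` with `l = 1 + dx + 2 dy + 4 dz`.
#' @export
element_matrices_3d <- function(h, D) {
  h <- as.numeric(h)
  if (length(h) != 3L || any(!is.finite(h)) || any(h <= 0)) {
    stop("degenerate element: edge lengths must be finite and > 0")
  }
  if (length(D) == 1L) D <- diag(3) * as.numeric(D)
  stopifnot(is.matrix(D), all(dim(D) == c(3L, 3L)))
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D)))) {
    stop("diffusion tensor must be symmetric")
  }
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("diffusion tensor must be positive semi-definite")
  }
  ref <- hex_reference_matrices(h)
  d6 <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  K <- matrix(0, 8, 8)
  for (p in 1:6) K <- K + d6[p] * ref$Kc[[p]]
  list(M = ref$M, K = K)
}

#' Assemble global continuum mass and stiffness matrices
#'
#' Sums element contributions over a structured mesh into sparse global
#' matrices. Per-element diffusion tensors and per-element volume-fraction
#' weights (used by the smeared model) are supported. Nodes listed in
#' `immersed` carry no continuum unknown: within each element an immersed
#' nodal value is slaved to the mean of the element's free nodes (a
#' zero-flux closure of the fiber surface: the congruence transform keeps
#' the matrices symmetric positive semi-definite, preserves constant
#' fields, and leaks no mass into the excluded nodes), and elements whose
#' eight nodes are all immersed contribute nothing.
#'
#' @param mesh A [hex_mesh()].
#' @param D Uniform 3x3 tensor (or scalar), or an `n_elem` x 6 matrix of
#'   per-element tensor components `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @param weight Scalar or `n_elem` vector multiplying both element matrices
#'   (e.g. a fiber volume fraction). Default 1.
#' @param immersed Integer vector of node ids geometrically inside fibers.
#' @return List with sparse `M` and `K` (`n_nodes` x `n_nodes`).
#' @export
assemble_continuum <- function(mesh, D, weight = 1, immersed = integer(0)) {
  stopifnot(inherits(mesh, "hex_mesh"))
  ne <- mesh$n_elem
  if (length(D) == 1L) D <- diag(3) * as.numeric(D)
  if (is.matrix(D) && all(dim(D) == c(3L, 3L))) {
    d6 <- matrix(rep(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                     each = ne), ne, 6)
  } else {
    stopifnot(is.matrix(D), nrow(D) == ne, ncol(D) == 6L)
    d6 <- D
  }
  if (length(weight) == 1L) weight <- rep(as.numeric(weight), ne)
  stopifnot(length(weight) == ne)

  ref <- hex_reference_matrices(mesh$h)
  Kref <- vapply(ref$Kc, as.vector, numeric(64))   # 64 x 6
  conn <- mesh_connectivity(mesh)

  if (length(immersed)) {
    imm <- logical(mesh$n_nodes); imm[immersed] <- TRUE
    pat <- matrix(imm[conn], ne, 8)
    n_imm <- rowSums(pat)
    if (all(n_imm == 8L)) stop("immersed set covers all elements")
    pat_id <- as.integer(pat %*% 2^(0:7))   # immersion pattern per element
  } else {
    pat_id <- integer(ne)
    n_imm <- integer(ne)
  }
  keep_el <- n_imm < 8L
  conn <- conn[keep_el, , drop = FALSE]
  d6 <- d6[keep_el, , drop = FALSE]
  weight <- weight[keep_el]
  pat_id <- pat_id[keep_el]
  ner <- nrow(conn)

  li <- rep(1:8, times = 8)
  lj <- rep(1:8, each = 8)
  ii <- as.vector(conn[, li]); jj <- as.vector(conn[, lj])   # ner*64
  xm <- numeric(ner * 64)
  xk <- numeric(ner * 64)
  Mvec <- as.vector(ref$M)
  for (pid in unique(pat_id)) {
    rows <- which(pat_id == pid)
    if (pid == 0L) {
      Mref_p <- Mvec
      Kref_p <- Kref
    } else {
      loc_imm <- bitwAnd(pid, 2^(0:7)) > 0L
      Z <- diag(8)
      Z[loc_imm, ] <- 0
      Z[loc_imm, !loc_imm] <- 1 / sum(!loc_imm)
      Mref_p <- as.vector(crossprod(Z, ref$M %*% Z))
      Kref_p <- vapply(ref$Kc, function(Kc) as.vector(crossprod(Z, Kc %*% Z)),
                       numeric(64))
    }
    idx <- as.vector(outer(rows, (0:63) * ner, "+"))
    xm[idx] <- weight[rows] * rep(Mref_p, each = length(rows))
    xk[idx] <- as.vector((d6[rows, , drop = FALSE] %*% t(Kref_p)) *
                           weight[rows])
  }
  n <- mesh$n_nodes
  keep <- xm != 0 | xk != 0
  list(
    M = sparseMatrix(i = ii[keep], j = jj[keep], x = xm[keep], dims = c(n, n)),
    K = sparseMatrix(i = ii[keep], j = jj[keep], x = xk[keep], dims = c(n, n))
  )
}

#' Transport system: matrices, constraints and mass accounting
#'
#' Container for a first-order transport problem
#' `M dC/dt + K(s) C = 0`, `K(s) = K0 + s * K1`, with Dirichlet-constrained
#' DOFs. `K1` collects every stiffness contribution proportional to the
#' (degradation-updated) fiber diffusivity so that time-dependent
#' diffusivity amounts to rescaling `s`. The capacity vector `cap` (one
#' entry per DOF, `cap = 1' M_physical`) defines the mass inventory
#' `mass = sum(cap * C)`; it is kept separately from the equation matrices
#' because for partitioning `P != 1` the surrounding-field equations are
#' row-scaled by `P` to keep the system symmetric.
#'
#' @param M Equation mass matrix (sparse).
#' @param K0 Stiffness independent of fiber diffusivity.
#' @param K1 Stiffness per unit fiber diffusivity (or `NULL`).
#' @param free Logical vector, `TRUE` for unconstrained DOFs.
#' @param dirichlet_values Numeric vector of prescribed values (used at
#'   `!free` entries; typically 0 at the release boundary).
#' @param cap Capacity vector for mass accounting; default `1' M`.
#' @return An object of class `transport_system`.
#' @export
transport_system <- function(M, K0, K1 = NULL, free = NULL,
                             dirichlet_values = NULL, cap = NULL,
                             perm = NULL) {
  n <- nrow(M)
  if (is.null(free)) free <- rep(TRUE, n)
  if (is.null(dirichlet_values)) dirichlet_values <- numeric(n)
  if (is.null(cap)) cap <- as.numeric(colSums(M))
  stopifnot(nrow(K0) == n, length(free) == n,
            length(dirichlet_values) == n, length(cap) == n)
  if (!any(free)) stop("no free degrees of freedom")
  if (!is.null(perm)) stopifnot(length(perm) == n)
  structure(
    list(M = M, K0 = K0, K1 = K1, free = free,
         dirichlet_values = dirichlet_values, cap = cap, n = n,
         perm = perm, cache = new.env(parent = emptyenv())),
    class = "transport_system"
  )
}

sys_K <- function(sys, kscale) {
  if (is.null(sys$K1) || kscale == 0) return(sys$K0)
  key <- sprintf("%.17g", kscale)
  if (!identical(sys$cache$K_key, key)) {
    sys$cache$Kfull <- sys$K0 + kscale * sys$K1
    sys$cache$K_key <- key
  }
  sys$cache$Kfull
}

# ordering of the free DOFs used for the factorization: the system's
# geometric nested-dissection permutation restricted to the free set
# (CHOLMOD's own ordering is kept for systems without a mesh permutation)
sys_free_perm <- function(sys) {
  if (is.null(sys$cache$pf)) {
    if (is.null(sys$perm)) {
      sys$cache$pf <- NA
    } else {
      wf <- which(sys$free)
      sys$cache$pf <- match(sys$perm[sys$perm %in% wf], wf)
    }
  }
  sys$cache$pf
}

sys_factor <- function(sys, dt, kscale) {
  key <- sprintf("%.17g_%.17g", dt, kscale)
  if (!is.null(sys$cache$key) && identical(sys$cache$key, key)) {
    return(sys$cache$fac)
  }
  K <- sys_K(sys, kscale)
  sys$cache$K <- K
  A <- (sys$M / dt + K)[sys$free, sys$free]
  pf <- sys_free_perm(sys)
  use_perm <- !identical(pf, NA)
  if (use_perm) A <- A[pf, pf]
  A <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
  fac <- tryCatch({
    if (!is.null(sys$cache$fac)) {
      Matrix::update(sys$cache$fac, A)
    } else if (use_perm) {
      Cholesky(A, LDL = FALSE, perm = FALSE, super = NA)
    } else {
      Cholesky(A, LDL = FALSE)
    }
  }, error = function(e) stop("singular or indefinite system: ",
                              conditionMessage(e), call. = FALSE))
  sys$cache$key <- key
  sys$cache$fac <- fac
  sys$cache$K <- K
  fac
}

# solve the factored free-DOF system, honoring the permutation
sys_solve <- function(sys, fac, b_free) {
  pf <- sys_free_perm(sys)
  if (identical(pf, NA)) return(as.numeric(solve(fac, b_free)))
  x <- numeric(length(b_free))
  x[pf] <- as.numeric(solve(fac, b_free[pf]))
  x
}

#' One implicit (backward Euler) time step with equilibrium iterations
#'
#' Solves `(M/dt + K) dC = -M/dt (C - C_t) - K C` iteratively until the
#' equation residual falls below `tol` relative to its initial norm (a
#' single solve suffices when `K` is constant within the step, as it is
#' here; the loop is retained for generality). Dirichlet values are
#' enforced exactly. Factorizations are cached and reused across steps.
#'
#' @param sys A [transport_system()].
#' @param C_t Full DOF vector at the start of the step.
#' @param dt Time step in seconds, > 0.
#' @param kscale Fiber diffusivity multiplying `K1` during this step
#'   (um^2/s); 0 if `K1` is `NULL`.
#' @param max_iter Maximum equilibrium iterations.
#' @param tol Relative increment tolerance.
#' @return List with `C` (end-of-step vector), `iterations`, and `resid`
#'   (final relative increment norm).
#' @export
step_implicit <- function(sys, C_t, dt, kscale = 0, max_iter = 25,
                          tol = 1e-10) {
  stopifnot(inherits(sys, "transport_system"), dt > 0,
            length(C_t) == sys$n)
  K <- sys_K(sys, kscale)
  C <- C_t
  C[!sys$free] <- sys$dirichlet_values[!sys$free]
  resid <- Inf
  for (i in seq_len(max_iter)) {
    r <- as.numeric((-(sys$M %*% (C - C_t)) / dt - K %*% C)[sys$free])
    dC <- solve_free(sys, dt, kscale, r)
    C[sys$free] <- C[sys$free] + dC
    resid <- sqrt(sum(dC^2)) / max(sqrt(sum(C^2)), .Machine$double.eps)
    if (resid < tol) break
  }
  if (resid >= tol && max_iter > 1L) {
    stop(sprintf("equilibrium iterations did not converge: increment %.3e",
                 resid))
  }
  list(C = C, iterations = i, resid = resid)
}

#' Total mass carried by a concentration state
#'
#' `mass = sum(cap * C)` with the physical capacity vector of the system
#' (concentration times um^3).
#'
#' @param sys A [transport_system()].
#' @param C Full DOF vector.
#' @return Scalar mass (concentration * um^3).
#' @export
total_mass <- function(sys, C) {
  stopifnot(inherits(sys, "transport_system"), length(C) == sys$n)
  sum(sys$cap * C)
}

#' Mass released through constrained boundaries during a step
#'
#' Global balance: released = mass(start) - mass(end) - source input. With
#' no source and no Dirichlet sink this is zero to solver precision.
#'
#' @param sys A [transport_system()].
#' @param C_t,C DOF vectors at start and end of the step.
#' @param source_mass Mass injected by sources during the step (default 0).
#' @return Released mass increment (concentration * um^3).
#' @export
boundary_flux_mass <- function(sys, C_t, C, source_mass = 0) {
  total_mass(sys, C_t) - total_mass(sys, C) + source_mass
}

#' Steady state of a transport system
#'
#' Solves `K C = 0` on the free DOFs subject to the Dirichlet values
#' (used for steady diffusion checks and numerical homogenization).
#'
#' @param sys A [transport_system()].
#' @param kscale Fiber diffusivity applied to `K1`.
#' @return Full DOF vector.
#' @export
steady_state <- function(sys, kscale = 0) {
  K <- sys_K(sys, kscale)
  C <- sys$dirichlet_values
  C[sys$free] <- 0
  rhs <- as.numeric(-(K %*% C)[sys$free])
  A <- K[sys$free, sys$free]
  pf <- sys_free_perm(sys)
  if (!identical(pf, NA)) {
    A <- A[pf, pf]
    A <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
    fac <- Cholesky(A, LDL = FALSE, perm = FALSE, super = NA)
    x <- numeric(length(rhs)); x[pf] <- as.numeric(solve(fac, rhs[pf]))
    C[sys$free] <- x
  } else {
    A <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
    C[sys$free] <- as.numeric(solve(Cholesky(A, LDL = FALSE), rhs))
  }
  C
}
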