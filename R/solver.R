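# Linear solvers for the implicit step.
#
# Small and medium systems are solved by sparse Cholesky with the geometric
# nested-dissection ordering (ordering.R). For the dual-field CSFE systems
# a monolithic factor is memory- and flop-expensive (two co-located fields
# double every separator plane), so those are solved by conjugate gradients
# with one of two block preconditioners.
#
# The smeared assembly carries the surrounding field as u = P C_sur, so the
# nodal exchange pencil is the plain conductance s k [[1, -1], [-1, 1]].
# In the exchange-dominated regime (the strongly partition-retarded preset
# releases) that pencil dwarfs the spatial operators of both fields, and
# rotating every coupled node pair onto (1, 1)/sqrt(2) (slow) and
# (1, -1)/sqrt(2) (stiff) maps the exchange exactly onto the stiff channel:
# the rotated system Q' A Q has a diagonal-dominated stiff block handled by
# its diagonal, while the slow block is the retarded-diffusion operator --
# a single-field SPD matrix, formed explicitly (no numerical cancellation)
# and factored with the nested-dissection ordering; nodes without fibers
# keep their surrounding DOF as a slow channel unrotated, and CG runs in
# the rotated, Jacobi-equilibrated coordinates.
#
# In the weak-coupling regime (P ~ 1, exchange small against surrounding
# diffusion) a block-diagonal preconditioner with the two single-field
# factors is used instead. Factors are reused while the fiber diffusivity
# stays within a moderate ratio of the factorization point.

solve_free <- function(sys, dt, kscale, b_free, tol = 1e-12) {
  if (isTRUE(attr(sys, "layout")$schur_pcg)) {
    schur_pcg_solve(sys, dt, kscale, b_free, tol)
  } else {
    fac <- sys_factor(sys, dt, kscale)
    sys_solve(sys, fac, b_free)
  }
}

schur_pcg_setup <- function(sys, dt, kscale) {
  cache <- sys$cache
  lay <- attr(sys, "layout")
  if (is.null(cache$blocks) || cache$blocks_dt != dt) {
    n <- lay$n_nodes
    wf <- which(sys$free)
    nf <- length(wf)
    pos <- integer(2L * n); pos[wf] <- seq_len(nf)   # dof -> free position
    fib_free <- sys$free[seq_len(n)]
    sur_free <- sys$free[n + seq_len(n)]
    paired <- which(fib_free & sur_free)
    # slow DOFs ordered by grid nested dissection (they carry the factored
    # operator); stiff DOFs (one per coupled pair) follow
    nd <- nd_node_order(lay$mesh_nn)
    slow_nodes <- nd[fib_free[nd] | sur_free[nd]]
    is_paired <- logical(n); is_paired[paired] <- TRUE
    n_slow <- length(slow_nodes)
    n_stiff <- length(paired)
    h <- 1 / sqrt(2)
    slow_slot <- integer(n); slow_slot[slow_nodes] <- seq_len(n_slow)
    stiff_slot <- integer(n); stiff_slot[paired] <- n_slow + seq_len(n_stiff)
    qi <- integer(0); qj <- integer(0); qx <- numeric(0)
    pn <- is_paired[slow_nodes]
    sn <- slow_nodes
    # paired nodes: slow = (fib + sur)/sqrt2, stiff = (fib - sur)/sqrt2
    pp <- sn[pn]
    qi <- c(pos[pp], pos[n + pp], pos[pp], pos[n + pp])
    qj <- c(slow_slot[pp], slow_slot[pp], stiff_slot[pp], stiff_slot[pp])
    qx <- c(rep(h, 2L * length(pp)), rep(h, length(pp)), rep(-h, length(pp)))
    # unpaired nodes keep their single free DOF as a slow channel
    up <- sn[!pn]
    if (length(up)) {
      d_up <- ifelse(fib_free[up], up, n + up)
      qi <- c(qi, pos[d_up]); qj <- c(qj, slow_slot[up])
      qx <- c(qx, rep(1, length(up)))
    }
    Q <- sparseMatrix(i = qi, j = qj, x = qx, dims = c(nf, n_slow + n_stiff))
    A0 <- (sys$M / dt + sys$K0)[wf, wf]
    K1f <- sys$K1[wf, wf]
    R0 <- methods::as(Matrix::forceSymmetric(crossprod(Q, A0 %*% Q)),
                      "CsparseMatrix")
    R1 <- methods::as(Matrix::forceSymmetric(crossprod(Q, K1f %*% Q)),
                      "CsparseMatrix")
    blocks <- list(
      Q = Q, R0 = R0, R1 = R1,
      d0 = Matrix::diag(R0), d1 = Matrix::diag(R1),
      n_slow = n_slow, n_stiff = n_stiff,
      islow = seq_len(n_slow), istiff = n_slow + seq_len(n_stiff),
      # regime indicator data: surrounding spatial diagonal vs exchange,
      # over the coupled pairs
      theta_num = Matrix::diag((sys$M / dt + sys$K0)[n + paired, n + paired]),
      theta_den = Matrix::diag(sys$K1[paired, n + paired]) * -1,
      # single-field blocks for the weak-coupling preconditioner
      i1 = pos[which(fib_free)], i2 = pos[n + which(sur_free)],
      p1 = slow_slot[nd[fib_free[nd]]] * 0L, # placeholders set below
      f1 = which(fib_free), f2 = which(sur_free)
    )
    blocks$p1 <- match(nd[fib_free[nd]], blocks$f1)
    blocks$p2 <- match(nd[sur_free[nd]], blocks$f2)
    cache$blocks <- blocks
    cache$blocks_dt <- dt
    cache$pc <- NULL
  }
  b <- cache$blocks
  s <- kscale
  theta <- if (b$n_stiff) {
    max(b$theta_num / pmax(s * b$theta_den, .Machine$double.xmin))
  } else {
    Inf
  }
  mode <- if (theta <= 0.05) "rotated" else "block_diag"
  if (!is.null(cache$pc) && cache$pc$mode == mode &&
      max(s / cache$pc$s, cache$pc$s / s) <= 1.6) {
    return(invisible(NULL))
  }
  cache$pc <- NULL                           # free the previous factors
  gc(FALSE)
  if (mode == "rotated") {
    Rs <- (b$R0 + s * b$R1)[b$islow, b$islow]
    Rs <- methods::as(Matrix::forceSymmetric(Rs), "CsparseMatrix")
    pc <- list(s = s, mode = "rotated",
               facS = Cholesky(Rs, LDL = FALSE, perm = FALSE, super = NA))
  } else {
    wf_all <- which(sys$free)
    Af <- (sys$M / dt + sys$K0 + s * sys$K1)[b$f1, b$f1]
    As <- (sys$M / dt + sys$K0 + s * sys$K1)[attr(sys, "layout")$n_nodes + b$f2,
                                             attr(sys, "layout")$n_nodes + b$f2]
    pc <- list(
      s = s, mode = "block_diag",
      facF = Cholesky(methods::as(Matrix::forceSymmetric(Af[b$p1, b$p1]),
                                  "CsparseMatrix"),
                      LDL = FALSE, perm = FALSE, super = NA),
      facS2 = Cholesky(methods::as(Matrix::forceSymmetric(As[b$p2, b$p2]),
                                   "CsparseMatrix"),
                       LDL = FALSE, perm = FALSE, super = NA))
  }
  cache$pc <- pc
  invisible(NULL)
}

schur_pcg_solve <- function(sys, dt, kscale, b_free, tol = 1e-12,
                            max_iter = 400L) {
  schur_pcg_setup(sys, dt, kscale)
  cache <- sys$cache
  bl <- cache$blocks
  pc <- cache$pc
  s <- kscale
  # CG runs in the rotated, Jacobi-equilibrated coordinates
  dR <- bl$d0 + s * bl$d1
  sc <- 1 / sqrt(dR)
  matvec <- function(y) {
    y <- sc * y
    sc * (as.numeric(bl$R0 %*% y) + s * as.numeric(bl$R1 %*% y))
  }
  if (pc$mode == "rotated") {
    dstiff <- dR[bl$istiff]
    prec <- function(r) {
      r <- r / sc
      z <- numeric(length(r))
      zs <- numeric(bl$n_slow)
      zs[] <- as.numeric(solve(pc$facS, r[bl$islow]))
      z[bl$islow] <- zs
      if (bl$n_stiff) z[bl$istiff] <- r[bl$istiff] / dstiff
      z / sc
    }
  } else {
    prec <- function(r) {
      r <- r / sc
      # back to field coordinates, solve each field, rotate forward again
      x <- as.numeric(bl$Q %*% r)
      z <- numeric(length(x))
      z1 <- numeric(length(bl$i1)); z2 <- numeric(length(bl$i2))
      z1[bl$p1] <- as.numeric(solve(pc$facF, x[bl$i1][bl$p1]))
      z2[bl$p2] <- as.numeric(solve(pc$facS2, x[bl$i2][bl$p2]))
      z[bl$i1] <- z1; z[bl$i2] <- z2
      as.numeric(crossprod(bl$Q, z)) / sc
    }
  }
  y <- numeric(ncol(bl$Q))
  r <- sc * as.numeric(crossprod(bl$Q, b_free))
  nb <- sqrt(sum(r^2))
  if (nb == 0) return(numeric(length(b_free)))
  z <- prec(r)
  p <- z
  rz <- sum(r * z)
  best <- Inf
  best_it <- 0L
  for (it in seq_len(max_iter)) {
    Ap <- matvec(p)
    alpha <- rz / sum(p * Ap)
    y <- y + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / nb
    if (rel <= tol) break
    if (rel < best / 2) { best <- rel; best_it <- it }
    # rounding floor of the equilibrated system: accept a stagnated but
    # converged solve rather than iterate against roundoff
    if (it - best_it >= 15L) {
      if (rel <= 1e-8) break
      stop(sprintf(
        "PCG stagnated after %d iterations (relative residual %.2e)",
        it, rel))
    }
    if (it == max_iter) {
      stop(sprintf(
        "PCG did not converge in %d iterations (relative residual %.2e)",
        max_iter, rel))
    }
    z <- prec(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  as.numeric(bl$Q %*% (sc * y))
}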