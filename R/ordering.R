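# Fill-reducing orderings for structured-grid systems.
#
# CHOLMOD's default minimum-degree ordering produces excessive fill on 3D
# grid graphs; a geometric nested-dissection permutation (recursive
# coordinate bisection with plane separators) keeps the factor size and
# flop count near the theoretical optimum for box meshes, so the direct
# solves stay within laptop-scale memory at the full preset resolution.

# elimination order of the grid nodes of a hex_mesh (1-based node ids):
# recursive bisection along the longest axis, separator plane ordered last
nd_node_order <- function(nn, leaf = 32L) {
  ids_of_box <- function(lo, hi) {
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    as.vector(outer(outer(ix, iy * nn[1], "+"), iz * nn[1] * nn[2], "+")) + 1L
  }
  rec <- function(lo, hi) {
    sz <- hi - lo + 1L
    if (prod(sz) <= leaf) return(ids_of_box(lo, hi))
    d <- which.max(sz)
    mid <- lo[d] + (sz[d] - 1L) %/% 2L
    lo_l <- lo; hi_l <- hi; hi_l[d] <- mid - 1L
    lo_r <- lo; hi_r <- hi; lo_r[d] <- mid + 1L
    lo_s <- lo; hi_s <- hi; lo_s[d] <- mid; hi_s[d] <- mid
    left <- if (hi_l[d] >= lo_l[d]) rec(lo_l, hi_l) else integer(0)
    right <- if (hi_r[d] >= lo_r[d]) rec(lo_r, hi_r) else integer(0)
    c(left, right, ids_of_box(lo_s, hi_s))
  }
  rec(c(0L, 0L, 0L), nn - 1L)
}

# DOF elimination order for a mesh-based system: `n_fields` co-located
# fields (field-major DOF layout) are interleaved per node so nodal
# couplings stay local; `extra_first` DOFs (e.g. radial-chain unknowns,
# which form paths hanging off the grid) are eliminated before the grid
nd_dof_order <- function(mesh, n_fields = 1L, extra_first = integer(0)) {
  p <- nd_node_order(mesh$nn)
  n <- mesh$n_nodes
  if (n_fields > 1L) {
    p <- as.vector(t(outer(p, (0:(n_fields - 1L)) * n, "+")))
  }
  c(extra_first, p)
}
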