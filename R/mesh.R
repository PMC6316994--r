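#' Structured hexahedral mesh on an axis-aligned box
#'
#' Builds a uniform trilinear 8-node hexahedral mesh. Node and element ids
#' are 1-based, x-index fastest: node id = 1 + ix + (nx+1)*(iy + (ny+1)*iz).
#' All lengths in micrometres; z is the implant thickness direction by
#' convention.
#'
#' @param extents Numeric length-3, box edge lengths `(Lx, Ly, Lz)` in um.
#' @param divisions Integer length-3, element counts `(nx, ny, nz)`, each >= 1.
#' @return An object of class `hex_mesh` with fields `extents`, `div`,
#'   `h` (cell sizes), `nn` (nodes per dimension), `n_nodes`, `n_elem`.
#' @export
hex_mesh <- function(extents, divisions) {
  extents <- as.numeric(extents)
  divisions <- as.integer(divisions)
  stopifnot(length(extents) == 3L, all(is.finite(extents)), all(extents > 0),
            length(divisions) == 3L, all(divisions >= 1L))
  nn <- divisions + 1L
  structure(
    list(extents = extents, div = divisions, h = extents / divisions,
         nn = nn, n_nodes = prod(nn), n_elem = prod(divisions)),
    class = "hex_mesh"
  )
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %g x %g x %g um, %d x %d x %d divisions (%d nodes, %d elements)\n",
              x$extents[1], x$extents[2], x$extents[3],
              x$div[1], x$div[2], x$div[3], x$n_nodes, x$n_elem))
  invisible(x)
}

#' Node coordinates of a structured mesh
#'
#' @param mesh A [hex_mesh()].
#' @return An `n_nodes` x 3 matrix of coordinates (um), in node-id order.
#' @export
node_coords <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nn <- mesh$nn
  ix <- rep.int(0:(nn[1] - 1L), nn[2] * nn[3])
  iy <- rep.int(rep(0:(nn[2] - 1L), each = nn[1]), nn[3])
  iz <- rep(0:(nn[3] - 1L), each = nn[1] * nn[2])
  cbind(x = ix * mesh$h[1], y = iy * mesh$h[2], z = iz * mesh$h[3])
}

#' Node id from integer grid indices (0-based)
#' @noRd
node_id <- function(mesh, ix, iy, iz) {
  1L + ix + mesh$nn[1] * (iy + mesh$nn[2] * iz)
}

#' Element connectivity
#'
#' @param mesh A [hex_mesh()].
#' @return An `n_elem` x 8 integer matrix of node ids; local node `l`
#'   corresponds to corner offsets `(dx, dy, dz)` with
#'   `l = 1 + dx + 2 dy + 4 dz`.
#' @export
mesh_connectivity <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nd <- mesh$div
  ex <- rep.int(0:(nd[1] - 1L), nd[2] * nd[3])
  ey <- rep.int(rep(0:(nd[2] - 1L), each = nd[1]), nd[3])
  ez <- rep(0:(nd[3] - 1L), each = nd[1] * nd[2])
  base <- node_id(mesh, ex, ey, ez)
  off <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  conn <- matrix(0L, mesh$n_elem, 8L)
  for (l in 1:8) {
    conn[, l] <- base + off$dx[l] + mesh$nn[1] * (off$dy[l] + mesh$nn[2] * off$dz[l])
  }
  conn
}

#' Nodal volumes (lumped shape-function integrals)
#'
#' `V_I = sum over adjacent elements of the integral of N_I`, which for a
#' uniform trilinear mesh gives 1/8 of each adjacent element volume. The
#' nodal volumes partition the mesh volume exactly.
#'
#' @param mesh A [hex_mesh()].
#' @param nodes Optional node id vector; default all nodes.
#' @return Numeric vector of nodal volumes (um^3).
#' @export
nodal_volume <- function(mesh, nodes = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  w <- function(n) c(0.5, rep(1, max(n - 1L, 0L)), 0.5)[1:(n + 1L)]
  wx <- w(mesh$div[1]) * mesh$h[1]
  wy <- w(mesh$div[2]) * mesh$h[2]
  wz <- w(mesh$div[3]) * mesh$h[3]
  v <- as.vector(outer(as.vector(outer(wx, wy)), wz))
  if (is.null(nodes)) v else v[nodes]
}

#' Node ids on a mesh boundary face
#'
#' @param mesh A [hex_mesh()].
#' @param face One of `"x0"`, `"x1"`, `"y0"`, `"y1"`, `"z0"`, `"z1"`
#'   (`"z1"` is the outer implant surface by the package convention).
#' @return Integer vector of node ids.
#' @export
boundary_nodes <- function(mesh, face = "z1") {
  stopifnot(inherits(mesh, "hex_mesh"))
  face <- match.arg(face, c("x0", "x1", "y0", "y1", "z0", "z1"))
  dim <- match(substr(face, 1, 1), c("x", "y", "z"))
  idx <- if (substr(face, 2, 2) == "0") 0L else mesh$div[dim]
  rng <- lapply(1:3, function(d) if (d == dim) idx else 0:(mesh$div[d]))
  g <- expand.grid(ix = rng[[1]], iy = rng[[2]], iz = rng[[3]])
  sort(node_id(mesh, g$ix, g$iy, g$iz))
}

#' Integer grid indices (0-based) of nearest grid node to points
#' @noRd
nearest_grid_index <- function(mesh, pts) {
  idx <- sapply(1:3, function(d) {
    pmin(pmax(as.integer(round(pts[, d] / mesh$h[d])), 0L), mesh$div[d])
  })
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  idx
}
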