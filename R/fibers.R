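#' Fiber network container
#'
#' A set of straight cylindrical fiber segments clipped to an axis-aligned
#' box domain. Segments are rows of a data frame with endpoint coordinates
#' and radius (all in um).
#'
#' @param segments Data frame with columns `x0,y0,z0,x1,y1,z1,radius`.
#' @param domain Numeric length-3 box extents `(Lx, Ly, Lz)` in um.
#' @param seed Integer seed the network was generated from (`NA` for
#'   imported networks).
#' @param params List of generation parameters (kept for provenance).
#' @return An object of class `fiber_network`.
#' @export
fiber_network <- function(segments, domain, seed = NA_integer_,
                          params = list()) {
  req <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius")
  stopifnot(is.data.frame(segments), all(req %in% names(segments)))
  segments <- segments[, req]
  if (nrow(segments) == 0L) stop("fiber network must be non-empty")
  if (any(segments$radius <= 0)) stop("fiber radius must be > 0")
  len <- segment_lengths_df(segments)
  if (any(len == 0)) stop("degenerate fiber segment (p0 == p1)")
  domain <- as.numeric(domain)
  stopifnot(length(domain) == 3L, all(domain > 0))
  lo <- as.matrix(segments[, c("x0", "y0", "z0")])
  hi <- as.matrix(segments[, c("x1", "y1", "z1")])
  eps <- 1e-9 * max(domain)
  if (any(lo < -eps) || any(hi < -eps) ||
      any(sweep(lo, 2, domain) > eps) || any(sweep(hi, 2, domain) > eps)) {
    stop("segment endpoints must lie within the closed domain box")
  }
  structure(list(segments = segments, domain = domain,
                 seed = as.integer(seed), params = params),
            class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf(
    "fiber_network: %d segments, domain %g x %g x %g um, total length %.1f um\n",
    nrow(x$segments), x$domain[1], x$domain[2], x$domain[3],
    sum(segment_lengths(x))))
  invisible(x)
}

segment_lengths_df <- function(seg) {
  sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
}

#' Segment lengths of a fiber network
#' @param net A [fiber_network()].
#' @return Numeric vector of lengths (um).
#' @export
segment_lengths <- function(net) segment_lengths_df(net$segments)

#' Total fiber volume (sum of segment cylinders, overlaps double-counted)
#' @param net A [fiber_network()].
#' @return Volume in um^3.
#' @export
fiber_volume <- function(net) {
  sum(pi * net$segments$radius^2 * segment_lengths(net))
}

# distance from 2D points to a 2D segment (stadium test helper)
dist2d_point_segment <- function(px, py, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  L2 <- dx * dx + dy * dy
  t <- pmin(pmax(((px - a[1]) * dx + (py - a[2]) * dy) / L2, 0), 1)
  sqrt((px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2)
}

# clip the infinite line through p with direction u to the rectangle
# [0,Lx]x[0,Ly]; returns NULL if the intersection is empty/degenerate
clip_line_rect <- function(p, u, L) {
  tmin <- -Inf; tmax <- Inf
  for (d in 1:2) {
    if (abs(u[d]) < 1e-14) {
      if (p[d] < 0 || p[d] > L[d]) return(NULL)
    } else {
      t1 <- (0 - p[d]) / u[d]; t2 <- (L[d] - p[d]) / u[d]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!is.finite(tmin) || !is.finite(tmax) || tmax <= tmin) return(NULL)
  list(a = p + tmin * u, b = p + tmax * u)
}

#' Generate one planar layer of a random fiber mat
#'
#' Emulates a single electrospun fiber layer as seen in a SEM window:
#' straight chords at uniformly random positions and orientations are added
#' to the plane until the areal coverage (union of fiber footprints,
#' overlaps counted once) reaches `target_coverage`; the final chord is
#' trimmed so the measured coverage lands within 2% relative of the target.
#' Coverage is measured on a deterministic grid of cell-center sample
#' points, so the result is reproducible bit-for-bit from the seed.
#'
#' @param domain_xy Numeric length-2 planar extents `(Lx, Ly)` in um.
#' @param diameter Fiber diameter in um; must be below `min(domain_xy)/3`
#'   so that no single fiber dominates the window.
#' @param target_coverage Areal coverage fraction in (0, 0.99].
#' @param seed Integer RNG seed.
#' @param z z-coordinate assigned to the layer (default `diameter / 2`, so
#'   the layer's cylinders sit centered inside their slab).
#' @param n_grid Coverage-estimation grid resolution per axis (default 256).
#' @return A [fiber_network()] with all segments at one z-level and domain
#'   `(Lx, Ly, diameter)`.
#' @export
generate_layer <- function(domain_xy, diameter, target_coverage, seed,
                           z = diameter / 2, n_grid = 256L) {
  domain_xy <- as.numeric(domain_xy)
  stopifnot(length(domain_xy) == 2L, all(domain_xy > 0),
            diameter > 0, target_coverage > 0, target_coverage < 1)
  if (diameter >= min(domain_xy) / 3) {
    stop("unreachable coverage: fiber diameter too large for the window")
  }
  if (target_coverage > 0.99) {
    stop("unreachable coverage: target above the 0.99 areal limit of a fiber mat")
  }
  R <- diameter / 2
  gx <- (seq_len(n_grid) - 0.5) * domain_xy[1] / n_grid
  gy <- (seq_len(n_grid) - 0.5) * domain_xy[2] / n_grid
  px <- rep(gx, times = n_grid)
  py <- rep(gy, each = n_grid)
  covered <- logical(length(px))

  rng <- local({ set.seed(seed); function(n) runif(n) })
  segs <- list()
  max_chords <- 10000L
  repeat {
    if (length(segs) >= max_chords) {
      stop("unreachable coverage: chord budget exhausted")
    }
    r3 <- rng(3)
    p <- c(r3[1] * domain_xy[1], r3[2] * domain_xy[2])
    th <- r3[3] * pi
    ch <- clip_line_rect(p, c(cos(th), sin(th)), domain_xy)
    if (is.null(ch)) next
    if (sqrt(sum((ch$b - ch$a)^2)) < 0.1 * diameter) next
    newly <- !covered & dist2d_point_segment(px, py, ch$a, ch$b) <= R
    cov_next <- mean(covered | newly)
    if (cov_next < target_coverage) {
      covered <- covered | newly
      segs[[length(segs) + 1L]] <- c(ch$a, ch$b)
      next
    }
    # crossing the target: trim the final chord by bisection on its length
    chord_len <- sqrt(sum((ch$b - ch$a)^2))
    f_lo <- max(0.1 * diameter / chord_len, 1e-6)
    cov_at <- function(f) {
      bb <- ch$a + f * (ch$b - ch$a)
      mean(covered | (!covered & dist2d_point_segment(px, py, ch$a, bb) <= R))
    }
    lo <- f_lo; hi <- 1
    if (cov_at(lo) >= target_coverage) {
      f <- lo
    } else {
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (cov_at(mid) >= target_coverage) hi <- mid else lo <- mid
      }
      f <- hi
    }
    cov_f <- cov_at(f)
    if (abs(cov_f - target_coverage) / target_coverage > 0.02) {
      stop("unreachable coverage: cannot land within 2% of target")
    }
    segs[[length(segs) + 1L]] <- c(ch$a, ch$a + f * (ch$b - ch$a))
    break
  }
  m <- do.call(rbind, segs)
  segments <- data.frame(x0 = m[, 1], y0 = m[, 2], z0 = z,
                         x1 = m[, 3], y1 = m[, 4], z1 = z,
                         radius = R)
  fiber_network(segments, domain = c(domain_xy, max(diameter, z * 2)),
                seed = seed,
                params = list(generator = "layer", diameter = diameter,
                              target_coverage = target_coverage,
                              n_grid = n_grid))
}

# split a 2D segment into pieces on the torus [0,Lx)x[0,Ly) after a shift,
# preserving total length exactly
wrap_segment_2d <- function(a, b, L) {
  d <- b - a
  ts <- c(0, 1)
  for (dim in 1:2) {
    if (abs(d[dim]) > 1e-14) {
      ks <- seq(ceiling(min(a[dim], b[dim]) / L[dim]),
                floor(max(a[dim], b[dim]) / L[dim]))
      ts <- c(ts, (ks * L[dim] - a[dim]) / d[dim])
    }
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  pieces <- list()
  for (i in seq_len(length(ts) - 1L)) {
    t0 <- ts[i]; t1 <- ts[i + 1L]
    if (t1 - t0 < 1e-12) next
    mid <- a + (t0 + t1) / 2 * d
    off <- floor(mid / L) * L
    pieces[[length(pieces) + 1L]] <-
      c(a + t0 * d - off, a + t1 * d - off)
  }
  pieces
}

#' Stack copies of a planar layer into a 3D fiber mat
#'
#' Replicates a planar layer at z-levels `(i - 1/2) * z_spacing`,
#' `i = 1..n_layers`, each copy displaced in-plane by a seeded random shift
#' with toroidal wrap so that the fiber volume per layer is preserved
#' exactly.
#'
#' @param layer A planar [fiber_network()] from [generate_layer()].
#' @param n_layers Number of copies, >= 1.
#' @param z_spacing Layer spacing in um, > 0.
#' @param seed Integer RNG seed for the shifts.
#' @param shifts Optional `n_layers` x 2 matrix of explicit in-plane shifts
#'   (um), overriding the seeded ones.
#' @param domain_z Optional domain height; errors if
#'   `n_layers * z_spacing` exceeds it. Default exactly
#'   `n_layers * z_spacing`.
#' @return A 3D [fiber_network()].
#' @export
stack_layers <- function(layer, n_layers, z_spacing, seed = 1L,
                         shifts = NULL, domain_z = NULL) {
  stopifnot(inherits(layer, "fiber_network"), n_layers >= 1L, z_spacing > 0)
  Lxy <- layer$domain[1:2]
  if (is.null(domain_z)) domain_z <- n_layers * z_spacing
  if (n_layers * z_spacing > domain_z * (1 + 1e-12)) {
    stop("stack height exceeds domain")
  }
  if (is.null(shifts)) {
    shifts <- local({
      set.seed(seed)
      matrix(stats::runif(2L * n_layers), ncol = 2) %*% diag(Lxy)
    })
  }
  stopifnot(nrow(shifts) == n_layers, ncol(shifts) == 2L)
  seg <- layer$segments
  out <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    zi <- (i - 0.5) * z_spacing
    rows <- list()
    for (s in seq_len(nrow(seg))) {
      a <- c(seg$x0[s], seg$y0[s]) + shifts[i, ]
      b <- c(seg$x1[s], seg$y1[s]) + shifts[i, ]
      for (pc in wrap_segment_2d(a, b, Lxy)) {
        rows[[length(rows) + 1L]] <-
          c(pc[1], pc[2], zi, pc[3], pc[4], zi, seg$radius[s])
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  m <- do.call(rbind, out)
  segments <- data.frame(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3],
                         x1 = m[, 4], y1 = m[, 5], z1 = m[, 6],
                         radius = m[, 7])
  fiber_network(segments, domain = c(Lxy, domain_z), seed = seed,
                params = c(layer$params,
                           list(n_layers = n_layers, z_spacing = z_spacing)))
}

# logical: are points (n x 3 matrix) inside the finite cylinder of segment?
points_in_cylinder <- function(pts, p0, p1, radius, strict = FALSE) {
  u <- p1 - p0
  L <- sqrt(sum(u^2))
  u <- u / L
  w <- sweep(pts, 2, p0)
  t <- as.vector(w %*% u)
  per2 <- rowSums(w^2) - t^2
  if (strict) {
    t >= 0 & t <= L & per2 < radius^2 * (1 - 1e-12)
  } else {
    t >= 0 & t <= L & per2 <= radius^2
  }
}

#' Geometric summary of a fiber network
#'
#' Monte-Carlo volume fraction (points inside at least one fiber cylinder,
#' overlaps counted once), the ideal surface ratio `rAV = 4 / diameter` of
#' straight cylinders, length-weighted mean diameter, and the
#' length-weighted orientation moment (trace 1).
#'
#' @param net A [fiber_network()].
#' @param n_samples Monte-Carlo sample count, >= 1e4.
#' @param seed Integer RNG seed for the sample points.
#' @return An object of class `network_summary` with fields
#'   `volume_fraction`, `surface_ratio` (1/um), `mean_diameter` (um),
#'   `orientation_moment` (3x3), `n_samples`.
#' @export
compute_summary <- function(net, n_samples = 1e5, seed = 1L) {
  stopifnot(inherits(net, "fiber_network"))
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  seg <- net$segments
  len <- segment_lengths(net)
  set.seed(seed)
  pts <- cbind(stats::runif(n_samples, 0, net$domain[1]),
               stats::runif(n_samples, 0, net$domain[2]),
               stats::runif(n_samples, 0, net$domain[3]))
  inside <- logical(n_samples)
  for (s in seq_len(nrow(seg))) {
    p0 <- c(seg$x0[s], seg$y0[s], seg$z0[s])
    p1 <- c(seg$x1[s], seg$y1[s], seg$z1[s])
    cand <- which(!inside)
    if (!length(cand)) break
    # cheap bounding-box precull
    lo <- pmin(p0, p1) - seg$radius[s]; hi <- pmax(p0, p1) + seg$radius[s]
    bb <- cand[pts[cand, 1] >= lo[1] & pts[cand, 1] <= hi[1] &
               pts[cand, 2] >= lo[2] & pts[cand, 2] <= hi[2] &
               pts[cand, 3] >= lo[3] & pts[cand, 3] <= hi[3]]
    if (!length(bb)) next
    inside[bb] <- points_in_cylinder(pts[bb, , drop = FALSE], p0, p1,
                                     seg$radius[s])
  }
  mean_d <- sum(2 * seg$radius * len) / sum(len)
  u <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0) / len
  om <- crossprod(u * sqrt(len)) / sum(len)
  structure(
    list(volume_fraction = mean(inside), surface_ratio = 4 / mean_d,
         mean_diameter = mean_d, orientation_moment = om,
         n_samples = n_samples),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network_summary: rV = %.4f, rAV = %.4g 1/um, mean diameter = %.3g um\n",
              x$volume_fraction, x$surface_ratio, x$mean_diameter))
  invisible(x)
}

#' Discretize fibers into common points
#'
#' Splits each fiber segment into sub-segments no longer than
#' `max_seg_length` and returns one common point per division node with its
#' belonging length `Lbar` (half-sum of adjoining sub-segment lengths;
#' half a sub-segment at fiber ends), so that `sum(Lbar)` over a fiber
#' equals its length and `sum(pi R^2 Lbar)` its volume.
#'
#' @param net A [fiber_network()].
#' @param max_seg_length Maximum sub-segment length in um, > 0.
#' @return Data frame with columns `x,y,z,Lbar,radius,segment_id`.
#' @export
discretize_fibers <- function(net, max_seg_length) {
  stopifnot(inherits(net, "fiber_network"), max_seg_length > 0)
  seg <- net$segments
  len <- segment_lengths(net)
  out <- vector("list", nrow(seg))
  for (s in seq_len(nrow(seg))) {
    n <- max(1L, ceiling(len[s] / max_seg_length))
    l <- len[s] / n
    tt <- (0:n) / n
    Lbar <- rep(l, n + 1L); Lbar[c(1L, n + 1L)] <- l / 2
    out[[s]] <- data.frame(
      x = seg$x0[s] + tt * (seg$x1[s] - seg$x0[s]),
      y = seg$y0[s] + tt * (seg$y1[s] - seg$y0[s]),
      z = seg$z0[s] + tt * (seg$z1[s] - seg$z0[s]),
      Lbar = Lbar, radius = seg$radius[s], segment_id = s)
  }
  do.call(rbind, out)
}

#' Mark continuum nodes immersed in fibers
#'
#' Returns the ids of mesh nodes lying strictly inside any fiber cylinder.
#' In the detailed model these nodes carry no continuum unknown.
#'
#' @param net A [fiber_network()].
#' @param mesh A [hex_mesh()].
#' @return Sorted integer vector of node ids (possibly empty).
#' @export
mark_immersed_nodes <- function(net, mesh) {
  stopifnot(inherits(net, "fiber_network"), inherits(mesh, "hex_mesh"))
  seg <- net$segments
  hit <- logical(mesh$n_nodes)
  for (s in seq_len(nrow(seg))) {
    p0 <- c(seg$x0[s], seg$y0[s], seg$z0[s])
    p1 <- c(seg$x1[s], seg$y1[s], seg$z1[s])
    R <- seg$radius[s]
    lo <- pmax(ceiling((pmin(p0, p1) - R) / mesh$h), 0)
    hi <- pmin(floor((pmax(p0, p1) + R) / mesh$h), mesh$div)
    if (any(lo > hi)) next
    g <- expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
    ids <- node_id(mesh, g$ix, g$iy, g$iz)
    pts <- cbind(g$ix * mesh$h[1], g$iy * mesh$h[2], g$iz * mesh$h[3])
    hit[ids[points_in_cylinder(pts, p0, p1, R, strict = TRUE)]] <- TRUE
  }
  which(hit)
}

#' Map common points to nearest admissible continuum nodes
#'
#' Each common point is tied to the nearest mesh node that is not excluded
#' (immersed or Dirichlet-fixed); ties are broken by the lowest node id.
#' Errors if a point has no admissible node within `max_reach` cell
#' diagonals (1 by default; the simulation pipeline allows 2, since on
#' coarse meshes a point deep inside a fiber cluster near the release face
#' can have its entire one-diagonal neighborhood immersed or constrained).
#'
#' @param points Data frame from [discretize_fibers()] (columns `x,y,z`).
#' @param mesh A [hex_mesh()].
#' @param excluded Integer node ids not admissible as coupling targets.
#' @param max_reach Admissibility radius in cell diagonals (>= 1).
#' @return Integer vector of node ids, one per point.
#' @export
map_to_continuum <- function(points, mesh, excluded = integer(0),
                             max_reach = 1) {
  stopifnot(inherits(mesh, "hex_mesh"))
  pts <- as.matrix(points[, c("x", "y", "z")])
  eps <- 1e-9 * max(mesh$extents)
  if (any(pts < -eps) || any(sweep(pts, 2, mesh$extents) > eps)) {
    stop("all common points must lie inside the mesh domain")
  }
  np <- nrow(pts)
  excl <- logical(mesh$n_nodes); excl[excluded] <- TRUE
  cell <- sapply(1:3, function(d) {
    pmin(pmax(as.integer(floor(pts[, d] / mesh$h[d])), 0L), mesh$div[d] - 1L)
  })
  if (np == 1L) cell <- matrix(cell, nrow = 1L)
  stopifnot(max_reach >= 1)
  diag_len <- sqrt(sum(mesh$h^2)) * max_reach
  best_d <- rep(Inf, np)
  best_id <- rep(NA_integer_, np)
  w <- as.integer(ceiling(max_reach))
  offs <- expand.grid(ox = (-w):(w + 1L), oy = (-w):(w + 1L),
                      oz = (-w):(w + 1L))
  for (o in seq_len(nrow(offs))) {
    ix <- cell[, 1] + offs$ox[o]; iy <- cell[, 2] + offs$oy[o]
    iz <- cell[, 3] + offs$oz[o]
    ok <- ix >= 0L & ix <= mesh$div[1] & iy >= 0L & iy <= mesh$div[2] &
      iz >= 0L & iz <= mesh$div[3]
    if (!any(ok)) next
    ids <- node_id(mesh, pmax(ix, 0L), pmax(iy, 0L), pmax(iz, 0L))
    d <- sqrt((pts[, 1] - ix * mesh$h[1])^2 +
              (pts[, 2] - iy * mesh$h[2])^2 +
              (pts[, 3] - iz * mesh$h[3])^2)
    adm <- ok & !excl[ids] & d <= diag_len * (1 + 1e-12)
    upd <- adm & (d < best_d * (1 - 1e-12) |
                  (abs(d - best_d) <= 1e-12 * diag_len & ids < best_id))
    upd[is.na(upd)] <- FALSE
    best_d[upd] <- d[upd]
    best_id[upd] <- ids[upd]
  }
  if (anyNA(best_id)) {
    stop(sprintf("%d common point(s) have no admissible continuum node within %g cell diagonal(s)",
                 sum(is.na(best_id)), max_reach))
  }
  best_id
}

#' Write a fiber network to CSV (with a JSON sidecar)
#'
#' CSV columns `x0,y0,z0,x1,y1,z1,radius_um`, one segment per row; numeric
#' values at full double precision so read/write round-trips bit-exactly.
#' The sidecar `<path>.json` records the domain, seed and generator
#' parameters.
#'
#' @param net A [fiber_network()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_network <- function(net, path) {
  stopifnot(inherits(net, "fiber_network"))
  seg <- net$segments
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# fiber network: one straight cylindrical segment per row (um)",
               "x0,y0,z0,x1,y1,z1,radius_um"), con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                     seg$x0, seg$y0, seg$z0, seg$x1, seg$y1, seg$z1,
                     seg$radius), con)
  jsonlite::write_json(
    list(domain = net$domain, seed = net$seed, generator_params = net$params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fiber network written by [write_fiber_network()]
#'
#' @param path CSV path; the JSON sidecar `<path>.json` is read when present.
#' @param domain Domain extents, required if there is no sidecar.
#' @return A [fiber_network()].
#' @export
read_fiber_network <- function(path, domain = NULL) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = rep("numeric", 7))
  names(df) <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius")
  side <- paste0(path, ".json")
  seed <- NA_integer_; params <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    domain <- meta$domain
    if (!is.null(meta$seed)) seed <- meta$seed
    if (!is.null(meta$generator_params)) params <- as.list(meta$generator_params)
  }
  if (is.null(domain)) stop("domain required when no JSON sidecar is present")
  fiber_network(df, domain = domain, seed = seed, params = params)
}
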