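# Structured mapped triangulations of the intima domain.
#
# Both fixture geometries are star-shaped graphs over a reference coordinate
# (channel: y over x; annulus: r over theta), so meshes are built by mapping a
# structured grid. Remeshing after boundary motion is re-gridding along the
# mapped direction, which keeps topology, node counts and periodic pairing
# fixed and bounds element quality by the boundary slope.

#' Build the longitudinal channel domain
#'
#' A rectangular strip of intima (media at `y = 0`, lumen above) whose
#' lumen-facing free boundary carries a smooth Gaussian bump, the initial
#' "small formed plaque". The lateral boundaries are periodically paired.
#'
#' @param length domain length (cm).
#' @param thickness intima thickness away from the bump (cm).
#' @param bump_amp bump amplitude (cm); 0 gives a flat strip.
#' @param bump_width Gaussian standard deviation of the bump (cm).
#' @param h target edge length (cm).
#' @return A `plaque_mesh` object.
#' @examples
#' m <- build_channel_domain(0.1, 0.01, bump_amp = 0.005, h = 0.002)
#' mesh_area(m)
#' @export
build_channel_domain <- function(length = 0.1, thickness = 0.01,
                                 bump_amp = 0.005, bump_width = 0.015,
                                 h = 0.002) {
  stopifnot(length > 0, thickness > 0, h > 0, bump_amp >= 0)
  if (bump_amp > 0 && bump_width <= 0) stop("bump_width must be positive")
  nx <- max(8L, as.integer(round(length / h)))
  ny <- max(3L, as.integer(round(thickness / h)))
  xs <- seq(0, length, length.out = nx + 1)
  gvals <- thickness + bump_profile(xs, length / 2, bump_amp, bump_width)
  .channel_mesh(xs, gvals, ny, length, thickness, h,
                bump = list(amp = bump_amp, width = bump_width))
}

# Gaussian bump, zeroed smoothly at the ends so the profile is periodic
bump_profile <- function(x, x0, amp, width) {
  if (amp == 0) return(rep(0, length(x)))
  amp * exp(-((x - x0)^2) / (2 * width^2))
}

.channel_mesh <- function(xs, gvals, ny, length, thickness, h, bump = NULL) {
  nx <- length(xs) - 1L
  if (any(gvals <= 0)) stop("degenerate geometry: boundary pinches the media")
  node_id <- function(i, j) (i - 1L) * (ny + 1L) + j + 1L  # i in 1..nx+1, j in 0..ny
  ii <- rep(seq_len(nx + 1L), each = ny + 1L)
  jj <- rep(0:ny, times = nx + 1L)
  nodes <- cbind(x = xs[ii], y = gvals[ii] * jj / ny)
  tri <- matrix(0L, nrow = 2L * nx * ny, ncol = 3)
  k <- 0L
  for (i in seq_len(nx)) {
    j <- 0:(ny - 1L)
    a <- node_id(i, j); b <- node_id(i + 1L, j)
    c_ <- node_id(i + 1L, j + 1L); d <- node_id(i, j + 1L)
    tri[k + seq_len(ny), ] <- cbind(a, b, c_)
    tri[k + ny + seq_len(ny), ] <- cbind(a, c_, d)
    k <- k + 2L * ny
  }
  gamma_I <- node_id(seq_len(nx + 1L), ny)       # ordered along x
  gamma_M <- node_id(seq_len(nx + 1L), 0L)
  gamma_L <- node_id(1L, 0:ny)
  gamma_R <- node_id(nx + 1L, 0:ny)
  mesh <- structure(list(
    nodes = nodes, tri = tri,
    geom = list(kind = "channel", nx = nx, ny = ny, length = length,
                thickness = thickness, xs = xs, gvals = gvals, h = h,
                bump = bump),
    gamma_I = gamma_I, gamma_M = gamma_M,
    gamma_L = gamma_L, gamma_R = gamma_R,
    periodic = cbind(master = gamma_L, slave = gamma_R)
  ), class = "plaque_mesh")
  .finalize_mesh(mesh)
}

#' Build the annulus cross-section domain
#'
#' Intima between the lumen-facing inner boundary and the media at the outer
#' circle. The inner boundary radius may vary with angle (an annular plaque
#' bump); the default is circular.
#'
#' @param inner inner (lumen) radius (cm) or a function of angle `f(theta)`.
#' @param outer outer (media) radius (cm).
#' @param h target edge length (cm).
#' @return A `plaque_mesh` object.
#' @examples
#' m <- build_annulus_domain(0.9, 1, h = 0.05)
#' mesh_area(m)  # ~ pi * (1 - 0.81)
#' @export
build_annulus_domain <- function(inner, outer, h = 0.02) {
  stopifnot(outer > 0, h > 0)
  thetas0 <- NULL
  if (is.function(inner)) {
    ntheta <- max(16L, as.integer(round(2 * pi * outer / h)))
    thetas0 <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
    fvals <- inner(thetas0)
  } else {
    stopifnot(inner > 0)
    if (inner >= outer) stop("inner radius must be smaller than outer radius")
    ntheta <- max(16L, as.integer(round(2 * pi * inner / h)))
    thetas0 <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
    fvals <- rep(inner, ntheta)
  }
  if (any(fvals <= 0) || any(fvals >= outer)) {
    stop("degenerate geometry: inner boundary outside (0, outer)")
  }
  nr <- max(3L, as.integer(round((outer - mean(fvals)) / h)))
  .annulus_mesh(thetas0, fvals, nr, outer, h)
}

.annulus_mesh <- function(thetas, fvals, nr, outer, h) {
  ntheta <- length(thetas)
  node_id <- function(i, j) (i - 1L) * (nr + 1L) + j + 1L  # j = 0 inner .. nr outer
  ii <- rep(seq_len(ntheta), each = nr + 1L)
  jj <- rep(0:nr, times = ntheta)
  rr <- fvals[ii] + (outer - fvals[ii]) * jj / nr
  nodes <- cbind(x = rr * cos(thetas[ii]), y = rr * sin(thetas[ii]))
  tri <- matrix(0L, nrow = 2L * ntheta * nr, ncol = 3)
  k <- 0L
  for (i in seq_len(ntheta)) {
    ip <- if (i == ntheta) 1L else i + 1L
    j <- 0:(nr - 1L)
    a <- node_id(i, j); b <- node_id(ip, j)
    c_ <- node_id(ip, j + 1L); d <- node_id(i, j + 1L)
    # (theta, r) parameterization is left-handed in (x, y)
    tri[k + seq_len(nr), ] <- cbind(a, c_, b)
    tri[k + nr + seq_len(nr), ] <- cbind(a, d, c_)
    k <- k + 2L * nr
  }
  mesh <- structure(list(
    nodes = nodes, tri = tri,
    geom = list(kind = "annulus", ntheta = ntheta, nr = nr, outer = outer,
                thetas = thetas, fvals = fvals, h = h),
    gamma_I = node_id(seq_len(ntheta), 0L),
    gamma_M = node_id(seq_len(ntheta), nr),
    gamma_L = integer(0), gamma_R = integer(0),
    periodic = cbind(master = integer(0), slave = integer(0))
  ), class = "plaque_mesh")
  .finalize_mesh(mesh)
}

# precompute element geometry: areas and P1 basis gradients
.finalize_mesh <- function(mesh) {
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  x1 <- x[t1]; x2 <- x[t2]; x3 <- x[t3]
  y1 <- y[t1]; y2 <- y[t2]; y3 <- y[t3]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(det <= 0)) stop("mesh contains non-positively-oriented triangles")
  area <- det / 2
  # gradient of basis function at node k: (b_k, c_k)
  mesh$elem <- list(
    area = area,
    b = cbind(y2 - y3, y3 - y1, y1 - y2) / det,
    c = cbind(x3 - x2, x1 - x3, x2 - x1) / det
  )
  mesh$n_nodes <- nrow(mesh$nodes)
  mesh$n_tri <- nrow(mesh$tri)
  mesh
}

#' Total mesh area
#' @param mesh a `plaque_mesh`.
#' @return Area (cm^2).
#' @export
mesh_area <- function(mesh) sum(mesh$elem$area)

#' Element quality (2 * inradius / circumradius)
#' @param mesh a `plaque_mesh`.
#' @return Numeric vector, one value in (0, 1] per triangle.
#' @export
mesh_quality <- function(mesh) {
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  a <- sqrt((x[mesh$tri[, 2]] - x[mesh$tri[, 3]])^2 +
            (y[mesh$tri[, 2]] - y[mesh$tri[, 3]])^2)
  b <- sqrt((x[mesh$tri[, 1]] - x[mesh$tri[, 3]])^2 +
            (y[mesh$tri[, 1]] - y[mesh$tri[, 3]])^2)
  c_ <- sqrt((x[mesh$tri[, 1]] - x[mesh$tri[, 2]])^2 +
             (y[mesh$tri[, 1]] - y[mesh$tri[, 2]])^2)
  s <- (a + b + c_) / 2
  (8 * (s - a) * (s - b) * (s - c_)) / (a * b * c_)
}

#' Polygonal (shoelace) area of a boundary loop
#' @param xy two-column coordinate matrix of an ordered loop (not closed).
#' @return Signed area.
#' @export
shoelace_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]) / 2
}

#' Free-boundary polyline of a mesh
#' @param mesh a `plaque_mesh`.
#' @param tag boundary tag, `"gamma_I"` or `"gamma_M"`.
#' @return Two-column matrix of ordered node coordinates.
#' @export
boundary_polyline <- function(mesh, tag = "gamma_I") {
  idx <- mesh[[tag]]
  if (length(idx) == 0) stop("no boundary with tag ", tag)
  mesh$nodes[idx, , drop = FALSE]
}

#' Signed curvature along a boundary
#'
#' Curvature at each node of a tagged boundary, positive where the boundary is
#' convex toward the lumen (so a circular lumen-facing boundary of radius R has
#' curvature 1/R everywhere, and a straight segment 0). Computed by a local
#' least-squares quadratic fit over a 5-node stencil in the node's tangent
#' frame, which is second-order accurate and robust to uneven node spacing.
#'
#' @param mesh a `plaque_mesh`.
#' @param tag boundary tag (default the free boundary `"gamma_I"`).
#' @return Numeric vector of curvature values (1/cm), one per boundary node.
#' @examples
#' m <- build_annulus_domain(0.9, 1, h = 0.05)
#' summary(boundary_curvature(m))  # ~ 1/0.9
#' @export
boundary_curvature <- function(mesh, tag = "gamma_I") {
  xy <- boundary_polyline(mesh, tag)
  if (mesh$geom$kind == "channel") {
    # lumen above; periodic continuation across the lateral boundaries
    -curvature_polyline(xy, closed = FALSE, period = mesh$geom$length)
  } else {
    # counter-clockwise loop with the lumen inside
    curvature_polyline(xy, closed = TRUE)
  }
}

#' Signed curvature of a polyline
#'
#' @param xy two-column coordinate matrix, ordered.
#' @param closed treat the polyline as a closed loop.
#' @param period if non-`NULL`, continue the open polyline periodically with
#'   this x-translation (channel geometry).
#' @param outward optional function `(xy) -> n x 2` outward normals; by default
#'   normals are taken to the left of the traversal direction reversed so that
#'   a counter-clockwise loop has positive curvature for a convex boundary.
#' @return Curvature per node (1/cm).
#' @export
curvature_polyline <- function(xy, closed = TRUE, period = NULL) {
  n <- nrow(xy)
  stopifnot(n >= 5)
  idx_of <- function(i) ((i - 1) %% n) + 1
  kap <- numeric(n)
  for (i in seq_len(n)) {
    off <- -2:2
    if (closed) {
      js <- idx_of(i + off)
      pts <- xy[js, , drop = FALSE]
    } else if (!is.null(period)) {
      js <- i + off
      pts <- matrix(0, 5, 2)
      for (q in 1:5) {
        j <- js[q]
        if (j < 1) {
          # skip the duplicated seam node at the far end
          pts[q, ] <- xy[n - 1 + j, ] - c(period, 0)
        } else if (j > n) {
          pts[q, ] <- xy[j - n + 1, ] + c(period, 0)
        } else pts[q, ] <- xy[j, ]
      }
    } else {
      js <- pmin(pmax(i + off, 1), n)
      pts <- xy[unique(js), , drop = FALSE]
      if (nrow(pts) < 5) pts <- xy[pmin(pmax(i + (-2:2), 1), n), , drop = FALSE]
    }
    # local tangent frame from endpoints of the stencil
    tvec <- pts[nrow(pts), ] - pts[1, ]
    tlen <- sqrt(sum(tvec^2))
    if (tlen == 0) { kap[i] <- 0; next }
    tvec <- tvec / tlen
    nvec <- c(-tvec[2], tvec[1])
    rel <- sweep(pts, 2, pts[3, ])
    s <- rel %*% tvec
    d <- rel %*% nvec
    X <- cbind(1, s, s^2)
    cf <- tryCatch(qr.coef(qr(X), d), error = function(e) c(0, 0, 0))
    dp <- cf[2]; dpp <- 2 * cf[3]
    kap[i] <- dpp / (1 + dp^2)^1.5
  }
  # deviation is measured along the left normal of the traversal direction:
  # for a counter-clockwise loop the left normal points to the enclosed
  # (lumen) side, so a convex-toward-lumen boundary yields positive values
  kap
}

#' Remesh after free-boundary displacement
#'
#' Re-grids the structured mapped mesh so it conforms to a displaced
#' lumen-facing boundary, and transfers nodal fields by linear interpolation
#' along the mapped direction (values beyond the old boundary are extended
#' with the old boundary value).
#'
#' @param mesh a `plaque_mesh`.
#' @param displaced for a channel, the new boundary heights `g(x)` at the mesh
#'   x-grid; for an annulus, the new inner radii `f(theta)` at the mesh angles.
#' @param fields optional named list of nodal vectors to transfer.
#' @return A list with elements `mesh` (the new `plaque_mesh`) and `fields`.
#' @export
remesh <- function(mesh, displaced, fields = NULL) {
  g <- mesh$geom
  if (g$kind == "channel") {
    if (length(displaced) != length(g$xs)) stop("displaced profile size mismatch")
    if (any(displaced <= 0)) stop("boundary collapse: free boundary reached the media")
    new <- .channel_mesh(g$xs, displaced, g$ny, g$length, g$thickness, g$h,
                         bump = g$bump)
    new_fields <- .transfer_fields(fields, g$ny, g$nx + 1L,
                                   old_top = g$gvals, new_top = displaced)
    return(list(mesh = new, fields = new_fields))
  }
  if (length(displaced) != length(g$thetas)) stop("displaced profile size mismatch")
  if (any(displaced <= 0) || any(displaced >= g$outer)) {
    stop("boundary collapse: inner boundary left the annulus")
  }
  new <- .annulus_mesh(g$thetas, displaced, g$nr, g$outer, g$h)
  # radial coordinate measured from the fixed outer (media) wall
  new_fields <- .transfer_fields(fields, g$nr, length(g$thetas),
                                 old_top = g$outer - g$fvals,
                                 new_top = g$outer - displaced,
                                 from_top = TRUE)
  list(mesh = new, fields = new_fields)
}

# Spatial (per-column linear) interpolation of nodal fields under re-gridding.
# Columns run over the structured direction; within a column the distance from
# the fixed (media) wall is old_top*frac resp. new_top*frac, where frac is the
# layer fraction; from_top reverses the layer order (annulus: layer 0 is the
# moving inner boundary). Points that the domain grew past are extended with
# the old boundary value.
.transfer_fields <- function(fields, nlay, ncol_, old_top, new_top,
                             from_top = FALSE) {
  if (is.null(fields)) return(NULL)
  # within a column the old sample heights are j/nlay * old_top; a new node at
  # fraction j/nlay sits at old fractional index j * new_top/old_top, linearly
  # interpolated and clamped (constant extension past the old boundary)
  ratio <- new_top / old_top
  m <- 0:nlay                                # layer index from the fixed wall
  posq <- outer(m, ratio)                    # [layer, col] fractional index
  posq <- pmin(pmax(posq, 0), nlay)
  k0 <- pmin(floor(posq), nlay - 1)
  w <- as.numeric(posq - k0)
  coloff <- rep((seq_len(ncol_) - 1L) * (nlay + 1L), each = nlay + 1L)
  if (from_top) {
    # storage runs from the moving side: storage index j = nlay - m
    i_lo <- coloff + as.integer(nlay - k0) + 1L
    i_hi <- coloff + as.integer(nlay - (k0 + 1L)) + 1L
  } else {
    i_lo <- coloff + as.integer(k0) + 1L
    i_hi <- coloff + as.integer(k0) + 2L
  }
  out <- lapply(fields, function(v) {
    res <- matrix((1 - w) * v[i_lo] + w * v[i_hi], nlay + 1L, ncol_)
    if (from_top) res <- res[(nlay + 1L):1, , drop = FALSE]
    as.numeric(res)
  })
  names(out) <- names(fields)
  out
}

#' @export
print.plaque_mesh <- function(x, ...) {
  cat("<plaque_mesh> ", x$geom$kind, ": ", x$n_nodes, " nodes, ",
      x$n_tri, " triangles, area ", signif(mesh_area(x), 4), " cm^2\n", sep = "")
  invisible(x)
}
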