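# Free-boundary kinematics: the lumen-facing boundary moves with normal
# velocity V_n = -dsigma/dn (continuity with the Darcy velocity), under the
# adhesion condition sigma = gamma_adh * kappa imposed in the pressure solve.

#' Normal velocity of the free boundary
#'
#' Evaluates `V_n = -dsigma/dn` at every free-boundary node from the one-sided
#' P1 pressure gradients of boundary-adjacent elements, averaged per node.
#' Positive values grow the plaque into the lumen.
#'
#' @param state a closed `plaque_state` (sigma solved).
#' @param p parameters (used for the displacement cap fraction).
#' @return A `boundary_motion` list: node ids, outward normals, `V_n` (cm/day).
#' @export
normal_velocity <- function(state, p = default_parameters()) {
  mesh <- state$mesh
  if (all(state$sigma == 0) && is.null(state$sigma)) stop("sigma missing")
  gI <- mesh$gamma_I
  nrml <- .outward_normals(mesh)
  grad <- -state$u_elem  # grad(sigma) per element
  # average gradient over elements touching each free-boundary node
  acc <- matrix(0, length(gI), 2)
  cnt <- numeric(length(gI))
  pos <- match(seq_len(mesh$n_nodes), gI)   # node -> position in gI
  for (k in 1:3) {
    nd <- mesh$tri[, k]
    sel <- !is.na(pos[nd])
    if (any(sel)) {
      rows <- pos[nd[sel]]
      acc[, 1] <- acc[, 1] + .accum(rows, grad[sel, 1], length(gI))
      acc[, 2] <- acc[, 2] + .accum(rows, grad[sel, 2], length(gI))
      cnt <- cnt + .accum(rows, rep(1, sum(sel)), length(gI))
    }
  }
  gbar <- acc / pmax(cnt, 1)
  Vn <- -(gbar[, 1] * nrml[, 1] + gbar[, 2] * nrml[, 2])
  structure(list(nodes = gI, normal = nrml, V_n = Vn), class = "boundary_motion")
}

# unit outward normals at free-boundary nodes (outward = toward the lumen)
.outward_normals <- function(mesh) {
  g <- mesh$geom
  if (g$kind == "channel") {
    gp <- .periodic_deriv(g$xs, g$gvals)
    nn <- cbind(-gp, 1) / sqrt(1 + gp^2)
    nn
  } else {
    fp <- .circular_deriv(g$thetas, g$fvals)
    # inner boundary r = f(theta); outward-from-domain points toward the axis
    th <- g$thetas
    nr <- cbind(cos(th), sin(th))     # radial unit vector
    nt <- cbind(-sin(th), cos(th))    # angular unit vector
    v <- -(nr * g$fvals - nt * fp)    # normal of r = f(theta), toward the axis
    v / sqrt(rowSums(v^2))
  }
}

.periodic_deriv <- function(xs, ys) {
  n <- length(xs)
  # xs include both ends of the period; ys[1] == ys[n]
  dx <- xs[2] - xs[1]
  ym <- c(ys[n - 1], ys[-n]); yp <- c(ys[-1], ys[2])
  (yp - ym) / (2 * dx)
}

.circular_deriv <- function(th, f) {
  n <- length(th)
  dt <- th[2] - th[1]
  (f[c(2:n, 1)] - f[c(n, 1:(n - 1))]) / (2 * dt)
}

# one [1/4, 1/2, 1/4] pass along the boundary: damps node-scale noise of the
# explicit interface update without affecting resolved profile scales
.smooth_profile <- function(v, periodic = TRUE, seam = FALSE) {
  n <- length(v)
  if (seam) {          # v[1] and v[n] are the same physical node
    w <- v[-n]; m <- length(w)
    sm <- (w[c(m, 1:(m - 1))] + 2 * w + w[c(2:m, 1)]) / 4
    return(c(sm, sm[1]))
  }
  (v[c(n, 1:(n - 1))] + 2 * v + v[c(2:n, 1)]) / 4
}

#' Advance the free boundary
#'
#' Moves the free boundary along its normal by `V_n * dt` (explicit update of
#' the graph representation), enforces the displacement cap, and remeshes with
#' field transfer.
#'
#' @param state a closed `plaque_state`.
#' @param motion a `boundary_motion` from [normal_velocity()].
#' @param dt time step (day).
#' @param cap maximum displacement as a fraction of the local layer spacing;
#'   exceeding it signals the caller to halve `dt`.
#' @return The state on the displaced, remeshed domain, or a condition of
#'   class `plaque_dt_reject` when the cap is exceeded.
#' @export
advance_boundary <- function(state, motion, dt, cap = 0.2) {
  mesh <- state$mesh
  g <- mesh$geom
  if (g$kind == "channel") {
    gp <- .periodic_deriv(g$xs, g$gvals)
    disp <- .smooth_profile(motion$V_n * dt * sqrt(1 + gp^2), periodic = TRUE,
                            seam = TRUE)
    layer <- g$gvals / g$ny
    if (max(abs(disp)) > cap * max(layer)) {
      cond <- structure(class = c("plaque_dt_reject", "error", "condition"),
                        list(message = "displacement cap exceeded",
                             call = NULL))
      stop(cond)
    }
    newg <- g$gvals + disp
    newg[length(newg)] <- newg[1]  # keep the periodic seam exact
    out <- remesh(mesh, newg, fields = state$fields)
  } else {
    fp <- .circular_deriv(g$thetas, g$fvals)
    disp <- .smooth_profile(motion$V_n * dt * sqrt(1 + (fp / g$fvals)^2),
                            periodic = TRUE, seam = FALSE)
    layer <- (g$outer - g$fvals) / g$nr
    if (max(abs(disp)) > cap * max(layer)) {
      cond <- structure(class = c("plaque_dt_reject", "error", "condition"),
                        list(message = "displacement cap exceeded",
                             call = NULL))
      stop(cond)
    }
    newf <- g$fvals - disp   # growth into the lumen shrinks the inner radius
    out <- remesh(mesh, newf, fields = state$fields)
  }
  state$mesh <- out$mesh
  state$fields <- out$fields
  state$rho <- rep_len(1, out$mesh$n_nodes)
  state
}
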