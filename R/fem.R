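# P1 Galerkin spatial discretization with backward-Euler time stepping.
#
# Assembly is fully vectorized over elements and collects a single triplet
# set per solve; the periodic identification of the lateral boundaries is
# folded into the triplet indices (master/slave dof elimination), so no
# sparse-matrix arithmetic happens in the step loop. The time term uses the
# lumped mass matrix, which makes the pure-diffusion no-flux step exactly
# conservative and keeps the system an M-matrix on non-obtuse meshes.

# lumped mass vector: area/3 to each vertex
.lumped_mass <- function(mesh) {
  ml <- numeric(mesh$n_nodes)
  a3 <- mesh$elem$area / 3
  for (k in 1:3) ml <- ml + .accum(mesh$tri[, k], a3, mesh$n_nodes)
  ml
}

.accum <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# stiffness triplets  K_ij = int grad(phi_i).grad(phi_j)
.stiffness_triplets <- function(mesh) {
  tri <- mesh$tri; area <- mesh$elem$area
  b <- mesh$elem$b; cc <- mesh$elem$c
  nt <- mesh$n_tri
  ii <- jj <- integer(9 * nt); vv <- numeric(9 * nt)
  pos <- 0L
  for (i in 1:3) for (j in 1:3) {
    rng <- pos + seq_len(nt)
    ii[rng] <- tri[, i]; jj[rng] <- tri[, j]
    vv[rng] <- area * (b[, i] * b[, j] + cc[, i] * cc[, j])
    pos <- pos + nt
  }
  list(i = ii, j = jj, v = vv)
}

# advection triplets for conservative transport div(uX) with element-wise
# constant u. Weak form after integration by parts: -int X u.grad(v);
# boundary terms vanish (u.n = 0 on the media wall, and the free boundary
# moves with the material speed).
.advection_triplets <- function(mesh, u_elem) {
  tri <- mesh$tri; area <- mesh$elem$area
  b <- mesh$elem$b; cc <- mesh$elem$c
  nt <- mesh$n_tri
  ii <- jj <- integer(9 * nt); vv <- numeric(9 * nt)
  pos <- 0L
  for (i in 1:3) {
    ug <- -(area / 3) * (u_elem[, 1] * b[, i] + u_elem[, 2] * cc[, i])
    for (j in 1:3) {
      rng <- pos + seq_len(nt)
      ii[rng] <- tri[, i]; jj[rng] <- tri[, j]
      vv[rng] <- ug
      pos <- pos + nt
    }
  }
  list(i = ii, j = jj, v = vv)
}

# boundary edge list (consecutive node pairs) for a tag, with edge lengths
.boundary_edges <- function(mesh, tag) {
  idx <- mesh[[tag]]
  n <- length(idx)
  if (mesh$geom$kind == "annulus") {
    e1 <- idx; e2 <- idx[c(2:n, 1)]
  } else {
    e1 <- idx[-n]; e2 <- idx[-1]
  }
  len <- sqrt(rowSums((mesh$nodes[e1, , drop = FALSE] -
                       mesh$nodes[e2, , drop = FALSE])^2))
  list(n1 = e1, n2 = e2, len = len)
}

# Robin terms for flux condition dX/dn + b (X - X0) = 0: adds D*int_G b X v
# to the matrix and D*int_G b X0 v to the RHS (consistent edge quadrature)
.robin_triplets <- function(mesh, tag, D, b_node, X0_node) {
  ed <- .boundary_edges(mesh, tag)
  idx <- mesh[[tag]]
  pos <- match(ed$n1, idx); pos2 <- match(ed$n2, idx)
  be <- (b_node[pos] + b_node[pos2]) / 2
  x0e <- (X0_node[pos] + X0_node[pos2]) / 2
  w <- D * be * ed$len
  list(
    i = c(ed$n1, ed$n2, ed$n1, ed$n2),
    j = c(ed$n1, ed$n2, ed$n2, ed$n1),
    v = c(w / 3, w / 3, w / 6, w / 6),
    rhs_i = c(ed$n1, ed$n2),
    rhs_v = c(w * x0e / 2, w * x0e / 2)
  )
}

# periodic master/slave map: full node -> reduced dof index
.periodic_map <- function(mesh) {
  n <- mesh$n_nodes
  slave <- mesh$periodic[, "slave"]
  master <- mesh$periodic[, "master"]
  target <- seq_len(n)
  target[slave] <- master
  keep <- setdiff(seq_len(n), slave)
  red_of <- integer(n)
  red_of[keep] <- seq_along(keep)
  red <- red_of[target]          # full index -> reduced index
  list(red = red, keep = keep, n_red = length(keep))
}

#' Precompute mesh-level FEM operators
#'
#' Lumped mass vector, stiffness triplets/matrix and the periodic reduction
#' map; valid until the mesh changes.
#' @param mesh a `plaque_mesh`.
#' @return A cache list.
#' @export
fem_cache <- function(mesh) {
  kt <- .stiffness_triplets(mesh)
  pmap <- .periodic_map(mesh)
  Ksp <- Matrix::sparseMatrix(i = pmap$red[kt$i], j = pmap$red[kt$j],
                              x = kt$v, dims = c(pmap$n_red, pmap$n_red))
  list(ml = .lumped_mass(mesh), kt = kt, pmap = pmap, Ksp = Ksp,
       mesh = mesh)
}

#' Assemble a backward-Euler transport step
#'
#' Builds the (periodically reduced) linear system for one implicit step of
#' `dX/dt + div(uX) - D lap(X) + decay*X = source` with the flux condition
#' `dX/dn + b (X - X0) = 0` on tagged boundary segments, natural (no-flux)
#' conditions elsewhere, and periodic identification of the lateral
#' boundaries.
#'
#' @param mesh a `plaque_mesh`.
#' @param D diffusivity (cm^2/day).
#' @param dt time step (day); must be positive.
#' @param prev nodal values at the previous time level.
#' @param source nodal source rate (or scalar).
#' @param decay nodal (or scalar) implicit linear rate (1/day).
#' @param u_elem optional per-element velocity (n_tri x 2), cell species only.
#' @param robin optional list of Robin specifications, each
#'   `list(tag=, b=, X0=)` with `b`, `X0` scalars or per-boundary-node vectors
#'   (ordered as the tag's node list).
#' @param cache optional assembly cache from [fem_cache()].
#' @return A linear-system list consumed by [solve_transport()].
#' @export
assemble_transport <- function(mesh, D, dt, prev, source = 0, decay = 0,
                               u_elem = NULL, robin = NULL, cache = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(cache)) cache <- fem_cache(mesh)
  n <- mesh$n_nodes
  ml <- cache$ml
  red <- cache$pmap$red
  dvals <- ml / dt + ml * rep_len(decay, n)
  ti <- c(red[seq_len(n)], red[cache$kt$i])
  tj <- c(red[seq_len(n)], red[cache$kt$j])
  tv <- c(dvals, D * cache$kt$v)
  rhs_full <- ml * prev / dt + ml * rep_len(source, n)
  if (!is.null(u_elem)) {
    at <- .advection_triplets(mesh, u_elem)
    ti <- c(ti, red[at$i]); tj <- c(tj, red[at$j]); tv <- c(tv, at$v)
  }
  if (!is.null(robin)) {
    for (rb in robin) {
      idx <- mesh[[rb$tag]]
      rt <- .robin_triplets(mesh, rb$tag, D,
                            rep_len(rb$b, length(idx)),
                            rep_len(rb$X0, length(idx)))
      ti <- c(ti, red[rt$i]); tj <- c(tj, red[rt$j]); tv <- c(tv, rt$v)
      rhs_full <- rhs_full + .accum(rt$rhs_i, rt$rhs_v, n)
    }
  }
  nr <- cache$pmap$n_red
  rhs <- .accum(red, rhs_full, nr)
  if (nr <= 600) {
    # dense fast path: small systems solve quicker through LAPACK than
    # through S4 sparse dispatch
    A <- matrix(0, nr, nr)
    lin <- (tj - 1L) * nr + ti
    acc <- rowsum(tv, lin)
    A[as.integer(rownames(acc))] <- acc[, 1]
    return(list(A = A, rhs = rhs, pmap = cache$pmap, mesh = mesh,
                dense = TRUE))
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nr, nr))
  list(A = A, rhs = rhs, pmap = cache$pmap, mesh = mesh, dense = FALSE)
}

#' Solve an assembled transport system
#'
#' Direct sparse LU with one step of iterative refinement and a normwise
#' backward-error check.
#'
#' @param sys system from [assemble_transport()].
#' @return Nodal solution vector (slave nodes filled from their masters).
#' @export
solve_transport <- function(sys) {
  Ar <- sys$A
  br <- sys$rhs
  if (isTRUE(sys$dense)) {
    xr <- tryCatch(solve(Ar, br),
                   error = function(e) stop("linear solve failed: ",
                                            conditionMessage(e),
                                            call. = FALSE))
    res <- sqrt(sum((Ar %*% xr - br)^2))
    scale <- max(abs(Ar)) * sqrt(sum(xr^2)) + sqrt(sum(br^2))
    if (scale > 0 && res / scale > 1e-8) {
      stop(sprintf("linear solve backward error too large (%.2e)",
                   res / scale))
    }
    return(as.numeric(xr)[sys$pmap$red])
  }
  fac <- tryCatch(Matrix::lu(Ar),
                  error = function(e) stop("linear solve failed: ",
                                           conditionMessage(e), call. = FALSE))
  xr <- as.numeric(Matrix::solve(fac, br))
  r1 <- br - as.numeric(Ar %*% xr)
  xr <- xr + as.numeric(Matrix::solve(fac, r1))
  res <- sqrt(sum((as.numeric(Ar %*% xr) - br)^2))
  scale <- max(abs(Ar)) * sqrt(sum(xr^2)) + sqrt(sum(br^2))
  if (scale > 0 && res / scale > 1e-8) {
    stop(sprintf("linear solve backward error too large (%.2e)", res / scale))
  }
  xr[sys$pmap$red]
}

#' Assemble and solve the pressure (Darcy) problem
#'
#' Solves `-lap(sigma) = f` with `sigma` fixed to the adhesion value on the
#' free boundary, natural conditions on the media wall and periodic lateral
#' boundaries. `grad_correction` adds the weak term
#' `-coef * int grad(c).grad(v)` accounting for the common cell diffusivity
#' in the summed mass balance.
#'
#' @param mesh a `plaque_mesh`.
#' @param f nodal source (1/day).
#' @param dirichlet sigma values on the free-boundary nodes (ordered as
#'   `mesh$gamma_I`), or a scalar.
#' @param grad_correction optional `list(field=, coef=)`.
#' @param cache optional [fem_cache()].
#' @return Nodal sigma vector.
#' @export
solve_pressure <- function(mesh, f, dirichlet, grad_correction = NULL,
                           cache = NULL) {
  if (is.null(cache)) cache <- fem_cache(mesh)
  n <- mesh$n_nodes
  red <- cache$pmap$red
  nr <- cache$pmap$n_red
  Ar <- cache$Ksp
  rhs <- .accum(red, cache$ml * rep_len(f, n), nr)
  if (!is.null(grad_correction)) {
    cred <- grad_correction$field[cache$pmap$keep]
    rhs <- rhs - grad_correction$coef * as.numeric(Ar %*% cred)
  }
  gI <- mesh$gamma_I
  dval <- rep_len(dirichlet, length(gI))
  bc_i <- red[gI]
  first <- !duplicated(bc_i)
  bc_i <- bc_i[first]; bc_v <- dval[first]
  known <- numeric(nr); known[bc_i] <- bc_v
  rhs <- rhs - as.numeric(Ar %*% known)
  free <- setdiff(seq_len(nr), bc_i)
  x_red <- known
  x_red[free] <- as.numeric(Matrix::solve(Ar[free, free, drop = FALSE],
                                          rhs[free]))
  x_red[red]
}

#' Per-element gradient of a P1 field
#' @param mesh a `plaque_mesh`.
#' @param field nodal values.
#' @return n_tri x 2 matrix of (d/dx, d/dy).
#' @export
p1_gradient <- function(mesh, field) {
  tri <- mesh$tri
  gx <- mesh$elem$b[, 1] * field[tri[, 1]] +
        mesh$elem$b[, 2] * field[tri[, 2]] +
        mesh$elem$b[, 3] * field[tri[, 3]]
  gy <- mesh$elem$c[, 1] * field[tri[, 1]] +
        mesh$elem$c[, 2] * field[tri[, 2]] +
        mesh$elem$c[, 3] * field[tri[, 3]]
  cbind(gx, gy)
}

#' Integrate a nodal field over the mesh
#'
#' Exact quadrature for P1 (nodal-linear) integrands via the lumped mass.
#' @param mesh a `plaque_mesh`.
#' @param field nodal values.
#' @return The integral.
#' @export
integrate_field <- function(mesh, field) sum(.lumped_mass(mesh) * field)
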