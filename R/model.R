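# Right-hand sides, boundary influx coefficients and the pressure closure of
# the intima plaque model.
#
# Fourteen transported species plus ECM density rho, pressure sigma and the
# Darcy velocity u. The total density closure M + T + S + F + rho = C_tot is
# exact by construction: rho is eliminated, not integrated, and the ECM
# kinetics enter only through the pressure source.

# species metadata: diffusivity parameter, advected by u (cells only)
.species_table <- function() {
  tibble::tibble(
    name = c("L", "H", "Lox", "r", "M", "P", "T", "Ig", "S", "I12",
             "G", "Q", "Qr", "F"),
    D = c("D_L", "D_H", "D_Lox", "D_r", "D_M", "D_P", "D_T", "D_Ig",
          "D_S", "D_I12", "D_G", "D_Q", "D_Qr", "D_F"),
    cell = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
             FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Species names of the plaque model
#' @return Character vector of the 14 transported species.
#' @export
plaque_species <- function() .species_table()$name

# HDL anti-inflammatory damping (Hill), on IL-12 production, monocyte influx
# and T-cell activation
.E_H <- function(H, p) 1 / (1 + (pmax(H, 0) / p$H_ref)^p$n_H)

# macrophage activation state set by local ox-LDL exposure
.g_act <- function(Lox, p) pmax(Lox, 0) / (p$K_actLox + pmax(Lox, 0))

#' Construct a model state
#'
#' Bundles a mesh with nodal fields. Missing species are initialized to zero;
#' `rho` and `sigma` are derived fields maintained by [close_state()].
#'
#' @param mesh a `plaque_mesh`.
#' @param fields named list of nodal vectors (species subset).
#' @param time simulation time (day).
#' @return A `plaque_state` object.
#' @export
new_state <- function(mesh, fields = list(), time = 0) {
  n <- mesh$n_nodes
  all_fields <- stats::setNames(
    lapply(plaque_species(), function(s) {
      v <- fields[[s]]
      if (is.null(v)) rep(0, n) else rep_len(v, n)
    }), plaque_species())
  st <- structure(list(mesh = mesh, fields = all_fields, time = time,
                       rho = rep(1, n), sigma = rep(0, n),
                       u_elem = matrix(0, mesh$n_tri, 2),
                       clipped_mass = 0),
                  class = "plaque_state")
  st
}

#' Reaction right-hand sides, split for semi-implicit stepping
#'
#' Returns, for every species, the explicit nodal source and the non-negative
#' (or stabilizing) linear-in-own-species rate treated implicitly by the
#' backward-Euler step. The sum `source - decay * X` is the full reaction term
#' F_X of the model:
#' bilinear oxidation losses of LDL and HDL; ox-LDL gain and its
#' macrophage-ingestion loss; the free-radical source, oxidation consumption
#' and quench; IFN-gamma-driven macrophage activation; MCP-1 production
#' saturating in ox-LDL; IL-12-driven T-cell activation (macrophage MHC-II
#' saturation, implicit IL-10 attenuation, HDL damping); IFN-gamma production
#' by T cells; IL-12 production by activated macrophages (IFN-gamma enhanced,
#' HDL resisted) and foam cells; PDGF production by M, F, S; MMP/TIMP
#' production, mutual binding and degradation; foam-cell conversion and death.
#' SMC chemotaxis/haptotaxis is transported weakly (see [chemotaxis_drift()]).
#'
#' @param state a `plaque_state`.
#' @param p parameters.
#' @return List with matrices `source` and `decay` (nodes x species).
#' @export
reaction_rhs <- function(state, p) {
  f <- state$fields
  if (any(vapply(f, function(v) any(!is.finite(v)), logical(1)))) {
    stop("non-finite field values in state")
  }
  n <- state$mesh$n_nodes
  sp <- plaque_species()
  src <- matrix(0, n, length(sp), dimnames = list(NULL, sp))
  dec <- matrix(0, n, length(sp), dimnames = list(NULL, sp))

  EH <- .E_H(f$H, p)
  gact <- .g_act(f$Lox, p)
  satLox <- f$Lox / (p$K_Lox + f$Lox)
  satM <- f$M / (p$K_M + f$M)
  satF <- f$F / (p$K_F + f$F)
  gIg <- 1 + f$Ig / (p$K_Ig_I12 + f$Ig)
  conv <- p$lam_F * satLox                       # macrophage -> foam cell
  actMg <- p$lam_MIg * f$Ig / (p$K_Ig_act + f$Ig)

  dec[, "L"] <- p$k_L * f$r
  dec[, "H"] <- p$k_H * f$r
  src[, "Lox"] <- p$k_L * f$L * f$r
  dec[, "Lox"] <- p$lam_ox * (f$M / p$C_tot) / (p$K_Lox + f$Lox)
  src[, "r"] <- p$r0
  dec[, "r"] <- p$d_r + p$k_L * f$L + p$k_H * f$H
  # activation is a negative implicit rate: still linear in M
  dec[, "M"] <- p$d_M + conv - actMg
  src[, "P"] <- p$lam_P * satLox
  dec[, "P"] <- p$d_P
  src[, "T"] <- p$delta_T * EH * p$lam_TI12 * f$I12 * satM
  dec[, "T"] <- p$d_T
  src[, "Ig"] <- p$lam_IgT * f$T
  dec[, "Ig"] <- p$d_Ig
  dec[, "S"] <- p$d_S
  src[, "I12"] <- (p$lam_I12M * satM * gIg + p$lam_I12F * satF) * gact * EH
  dec[, "I12"] <- p$d_I12
  src[, "G"] <- p$lam_GM * f$M + p$lam_GF * f$F + p$lam_GS * f$S
  dec[, "G"] <- p$d_G
  src[, "Q"] <- p$lam_QS * f$S
  dec[, "Q"] <- p$d_Q + p$k_QQr * f$Qr
  src[, "Qr"] <- p$lam_QrS * f$S + p$lam_QrM * f$M
  dec[, "Qr"] <- p$d_Qr + p$k_QrQ * f$Q
  src[, "F"] <- conv * f$M
  dec[, "F"] <- p$d_F

  list(source = src, decay = dec)
}

#' State-dependent boundary influx coefficients
#'
#' Robin data for the lumen-facing boundary (LDL, HDL, monocytes, T cells) and
#' the media wall (SMCs). The monocyte influx rate increases with local ox-LDL
#' (chemoattraction of monocytes by oxidized lipid) and decreases with local
#' HDL (its anti-inflammatory damping); the SMC influx rate increases with
#' local MCP-1 and PDGF. All other species are no-flux. Coefficients are
#' physical permeabilities (cm/day); the FEM layer receives beta/D.
#'
#' @param state a `plaque_state`.
#' @param p parameters.
#' @return Named list: per-species list of `list(tag, perm, X0)` with `perm`
#'   per-boundary-node permeability.
#' @export
boundary_coefficients <- function(state, p) {
  f <- state$fields
  if (is.null(f$Lox) || is.null(f$H)) stop("state lacks Lox/H fields")
  mesh <- state$mesh
  gI <- mesh$gamma_I; gM <- mesh$gamma_M
  enh_M <- (1 + p$a_M * pmax(f$Lox[gI], 0) / p$K_MLox) * .E_H(f$H[gI], p)
  enh_S <- 1 + f$P[gM] / (p$P0 + pmax(f$P[gM], 0)) +
    f$G[gM] / (p$G0 + pmax(f$G[gM], 0))
  list(
    L = list(tag = "gamma_I", perm = rep(p$s_lip * p$beta_L, length(gI)),
             X0 = p$L0),
    H = list(tag = "gamma_I", perm = rep(p$s_lip * p$beta_H, length(gI)),
             X0 = p$H0),
    M = list(tag = "gamma_I", perm = p$s_cell * p$beta_M * enh_M, X0 = p$M0),
    T = list(tag = "gamma_I", perm = rep(p$s_cell * p$beta_T, length(gI)),
             X0 = p$T0),
    S = list(tag = "gamma_M", perm = p$s_cell * p$beta_S * enh_S, X0 = p$S0)
  )
}

#' Chemotaxis/haptotaxis drift velocity for SMCs
#'
#' Element-wise drift `chi_P grad(P) + chi_G grad(G) + chi_rho grad(rho)`
#' multiplying the SMC density in its conservative transport term.
#'
#' @param state a `plaque_state`.
#' @param p parameters.
#' @return n_tri x 2 matrix (cm/day).
#' @export
chemotaxis_drift <- function(state, p) {
  m <- state$mesh
  p$chi_P * p1_gradient(m, state$fields$P) +
    p$chi_G * p1_gradient(m, state$fields$G) +
    p$chi_rho * p1_gradient(m, state$rho)
}

#' Pressure-equation source
#'
#' The volumetric source of the Darcy pressure problem: the summed cell
#' reaction terms f (net production of M, T, S, F) plus the weighted ECM
#' turnover term g = w_ecm * (lam_rho (1 - rho/rho0) - d_rhoQ Q rho).
#'
#' @param state a `plaque_state`.
#' @param p parameters.
#' @return List with nodal vectors `f_cells`, `g_ecm` and `total` (1/day).
#' @export
pressure_rhs <- function(state, p) {
  f <- state$fields
  rr <- reaction_rhs(state, p)
  cells <- c("M", "T", "S", "F")
  f_cells <- rowSums(rr$source[, cells, drop = FALSE] -
                     rr$decay[, cells, drop = FALSE] *
                       do.call(cbind, f[cells]))
  g_ecm <- p$w_ecm * (p$lam_rho * (1 - state$rho / p$rho0) -
                      p$d_rhoQ * f$Q * state$rho)
  list(f_cells = f_cells, g_ecm = g_ecm,
       total = (f_cells + g_ecm) / p$C_tot)
}

#' Close a state: density closure, pressure and Darcy velocity
#'
#' Sets `rho := C_tot - (M+T+S+F)` nodewise (the exact closure), solves the
#' pressure problem with the adhesion condition `sigma = gamma_adh * kappa` on
#' the free boundary, and sets the velocity `u = -grad(sigma)` per element.
#'
#' @param state a `plaque_state`.
#' @param p parameters.
#' @param cache optional [fem_cache()] for the current mesh.
#' @return The closed `plaque_state`.
#' @export
close_state <- function(state, p, cache = NULL) {
  f <- state$fields
  cc <- f$M + f$T + f$S + f$F
  if (any(cc > p$C_tot)) {
    stop("overcrowding: total cell density exceeds C_tot (step rejected)")
  }
  state$rho <- p$C_tot - cc
  pr <- pressure_rhs(state, p)
  kap <- boundary_curvature(state$mesh, "gamma_I")
  state$sigma <- solve_pressure(
    state$mesh, f = pr$total, dirichlet = p$gamma_adh * kap,
    grad_correction = list(field = cc, coef = p$D_M / p$C_tot),
    cache = cache)
  state$u_elem <- -p1_gradient(state$mesh, state$sigma)
  state
}

#' Plaque weight of a state
#'
#' The headline observable: the integral of the total cell density
#' (macrophages + T cells + SMCs + foam cells) over the evolving domain,
#' per unit vessel depth (2D model), by P1-exact quadrature.
#'
#' @param state a `plaque_state`.
#' @return Weight (g/cm).
#' @export
plaque_weight <- function(state) {
  f <- state$fields
  integrate_field(state$mesh, f$M + f$T + f$S + f$F)
}

#' @export
print.plaque_state <- function(x, ...) {
  cat("<plaque_state> t = ", x$time, " d, ", x$mesh$n_nodes, " nodes, W = ",
      signif(plaque_weight(x), 4), " g/cm\n", sep = "")
  invisible(x)
}

#' Tidy a model state into a long tibble
#'
#' @param x a `plaque_state`.
#' @param ... unused.
#' @return Tibble with columns `node`, `x`, `y`, `species`, `value`.
#' @export
tidy.plaque_state <- function(x, ...) {
  flds <- c(x$fields, list(rho = x$rho, sigma = x$sigma))
  tibble::tibble(
    node = rep(seq_len(x$mesh$n_nodes), times = length(flds)),
    x = rep(x$mesh$nodes[, 1], times = length(flds)),
    y = rep(x$mesh$nodes[, 2], times = length(flds)),
    species = rep(names(flds), each = x$mesh$n_nodes),
    value = unlist(flds, use.names = FALSE)
  )
}
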