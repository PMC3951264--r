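# Independent reference implementations used only by the tests.
# These are deliberately written in a different style from the package code
# (scalar algebra on named values, dense linear algebra, closed forms) and
# are never called by the simulator.

# Well-mixed (0-D) reaction terms of the 14-species network, coded directly
# from the model description. Returns dX/dt contributions from reactions only
# (no transport, no boundary exchange).
oracle_wellmixed_rhs <- function(y, p) {
  hill_H <- 1 / (1 + (y[["H"]] / p$H_ref)^p$n_H)
  act <- y[["Lox"]] / (p$K_actLox + y[["Lox"]])
  oxL <- p$k_L * y[["L"]] * y[["r"]]
  oxH <- p$k_H * y[["H"]] * y[["r"]]
  ingest <- p$lam_ox * (y[["M"]] / p$C_tot) *
    y[["Lox"]] / (p$K_Lox + y[["Lox"]])
  mhc <- y[["M"]] / (p$K_M + y[["M"]])
  foam_sat <- y[["F"]] / (p$K_F + y[["F"]])
  ifn_boost <- 1 + y[["Ig"]] / (p$K_Ig_I12 + y[["Ig"]])
  to_foam <- p$lam_F * y[["Lox"]] / (p$K_Lox + y[["Lox"]]) * y[["M"]]
  c(
    L = -oxL,
    H = -oxH,
    Lox = oxL - ingest,
    r = p$r0 - (p$k_L * y[["L"]] + p$k_H * y[["H"]]) * y[["r"]] -
      p$d_r * y[["r"]],
    M = p$lam_MIg * y[["Ig"]] / (p$K_Ig_act + y[["Ig"]]) * y[["M"]] -
      to_foam - p$d_M * y[["M"]],
    P = p$lam_P * y[["Lox"]] / (p$K_Lox + y[["Lox"]]) - p$d_P * y[["P"]],
    T = p$delta_T * hill_H * p$lam_TI12 * y[["I12"]] * mhc -
      p$d_T * y[["T"]],
    Ig = p$lam_IgT * y[["T"]] - p$d_Ig * y[["Ig"]],
    S = -p$d_S * y[["S"]],
    I12 = (p$lam_I12M * mhc * ifn_boost + p$lam_I12F * foam_sat) *
      act * hill_H - p$d_I12 * y[["I12"]],
    G = p$lam_GM * y[["M"]] + p$lam_GF * y[["F"]] + p$lam_GS * y[["S"]] -
      p$d_G * y[["G"]],
    Q = p$lam_QS * y[["S"]] - p$k_QQr * y[["Q"]] * y[["Qr"]] -
      p$d_Q * y[["Q"]],
    Qr = p$lam_QrS * y[["S"]] + p$lam_QrM * y[["M"]] -
      p$k_QrQ * y[["Q"]] * y[["Qr"]] - p$d_Qr * y[["Qr"]],
    F = to_foam - p$d_F * y[["F"]]
  )
}

# plausible random state for oracle comparisons (named scalar vector)
oracle_random_state <- function() {
  sc <- c(L = 2e-3, H = 6e-4, Lox = 1e-3, r = 15, M = 1e-4, P = 1e-9,
          T = 1e-2, Ig = 1e-3, S = 1e-3, I12 = 5e-7, G = 1e-4, Q = 1e-7,
          Qr = 1e-8, F = 5e-3)
  stats::setNames(stats::runif(length(sc)) * sc, names(sc))
}

# closed-form radial pressure on an annulus r_i < r < r_o:
#   -(1/r)(r sigma')' = f (constant), sigma(r_i) = kappa_val,
#   natural condition sigma'(r_o) = 0.
# Integrating: sigma'(r) = -f r / 2 + C1 / r, C1 = f r_o^2 / 2.
oracle_radial_pressure <- function(r, r_i, r_o, f, kappa_val) {
  C1 <- f * r_o^2 / 2
  kappa_val - f * (r^2 - r_i^2) / 4 + C1 * (log(r) - log(r_i))
}

oracle_radial_dpressure <- function(r, r_o, f) {
  -f * r / 2 + f * r_o^2 / (2 * r)
}

# circumcircle curvature of three consecutive polyline points
oracle_circumcircle_curvature <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
    (p2[2] - p1[2]) * (p3[1] - p1[1])
  if (cross == 0) return(0)
  4 * abs(cross) / 2 / (a * b * cc) * sign(cross)
}

# brute-force PRCC: explicit rank transform, dense least squares via solve(),
# residual correlation
oracle_prcc <- function(X, y) {
  X <- as.matrix(X)
  Rx <- apply(X, 2, rank)
  ry <- rank(y)
  k <- ncol(X)
  out <- numeric(k)
  for (j in seq_len(k)) {
    Z <- cbind(1, Rx[, -j, drop = FALSE])
    bx <- solve(t(Z) %*% Z, t(Z) %*% Rx[, j])
    by <- solve(t(Z) %*% Z, t(Z) %*% ry)
    ex <- Rx[, j] - Z %*% bx
    ey <- ry - Z %*% by
    out[j] <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  }
  out
}

# small helpers shared across test files
default_p <- atherosim::default_parameters()

tiny_channel <- function(h = 0.002, bump = 0.005) {
  atherosim::build_channel_domain(0.1, 0.01, bump_amp = bump,
                                  bump_width = 0.015, h = h)
}
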