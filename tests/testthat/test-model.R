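test_that("reaction terms match the independent well-mixed oracle", {
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.005)
  p <- default_parameters()
  set.seed(11)
  for (rep in 1:100) {
    y <- oracle_random_state()
    st <- new_state(m, fields = as.list(y))
    rr <- reaction_rhs(st, p)
    got <- rr$source[1, ] - rr$decay[1, ] * y[colnames(rr$source)]
    want <- oracle_wellmixed_rhs(y, p)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
  }
})

test_that("reaction limiting cases", {
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.005)
  p <- default_parameters()
  # no radicals: no oxidation of either lipoprotein, no ox-LDL gain
  st <- new_state(m, fields = list(L = 1e-3, H = 5e-4))
  rr <- reaction_rhs(st, p)
  expect_equal(max(abs(rr$decay[, "L"])), 0)
  expect_equal(max(abs(rr$decay[, "H"])), 0)
  expect_equal(max(abs(rr$source[, "Lox"])), 0)
  # direct bilinear product: oxidation loss k_L * L * r
  st2 <- new_state(m, fields = list(L = 1e-3, r = 1e-2))
  rr2 <- reaction_rhs(st2, p)
  expect_equal(unname(rr2$decay[1, "L"]) * 1e-3, 2.35e-9)
  # all-zero state: only the radical source is active
  st0 <- new_state(m)
  rr0 <- reaction_rhs(st0, p)
  net0 <- rr0$source - rr0$decay * 0
  expect_equal(unname(net0[1, "r"]), p$r0)
  expect_equal(max(abs(net0[, setdiff(colnames(net0), "r")])), 0)
  expect_error(reaction_rhs(new_state(m, fields = list(L = NaN)), p),
               "non-finite")
})

test_that("MMP-TIMP binding is mass-consistent with the tabulated rate pair", {
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.005)
  p <- default_parameters()
  st <- new_state(m, fields = list(Q = 3e-8, Qr = 4e-8))
  rr <- reaction_rhs(st, p)
  lossQ <- rr$decay[1, "Q"] * 3e-8 - p$d_Q * 3e-8
  lossQr <- rr$decay[1, "Qr"] * 4e-8 - p$d_Qr * 4e-8
  # both losses use the same product Q*Qr, at rates in the MW ratio 52/25
  expect_equal(unname(lossQ) / (p$k_QQr * 3e-8 * 4e-8), 1, tolerance = 1e-12)
  expect_equal(unname(lossQr / lossQ), p$k_QrQ / p$k_QQr, tolerance = 1e-12)
  expect_equal(p$k_QrQ / p$k_QQr, 52 / 25, tolerance = 5e-3)
})

test_that("monocyte influx responds to ox-LDL and HDL as chemoattraction dictates", {
  m <- tiny_channel()
  p <- default_parameters()
  base <- new_state(m, fields = list(Lox = 0, H = 5e-4, M = 1e-5))
  b0 <- boundary_coefficients(base, p)$M$perm
  # zero ox-LDL reduces to the HDL-damped baseline (no enhancement)
  baseline <- p$s_cell * p$beta_M / (1 + (5e-4 / p$H_ref)^p$n_H)
  expect_equal(unname(b0), rep(baseline, length(b0)))
  hi <- new_state(m, fields = list(Lox = 2e-4, H = 5e-4))
  hi2 <- new_state(m, fields = list(Lox = 4e-4, H = 5e-4))
  b1 <- boundary_coefficients(hi, p)$M$perm
  b2 <- boundary_coefficients(hi2, p)$M$perm
  expect_true(all(b1 > b0) && all(b2 > b1))  # increasing in ox-LDL
  hdl2 <- new_state(m, fields = list(Lox = 2e-4, H = 1e-3))
  b3 <- boundary_coefficients(hdl2, p)$M$perm
  expect_true(all(b3 < b1))                  # decreasing in HDL
  # SMC influx on the media wall increases with MCP-1 and PDGF
  sA <- boundary_coefficients(new_state(m, fields = list(H = 5e-4)), p)$S$perm
  sB <- boundary_coefficients(new_state(m, fields = list(H = 5e-4, P = 1e-9,
                                                         G = 1e-7)), p)$S$perm
  expect_true(all(sB > sA))
  # lipids/T cells carry constant influx coefficients
  expect_equal(diff(range(boundary_coefficients(hi, p)$L$perm)), 0)
})

test_that("density closure and Darcy velocity are exact by construction", {
  m <- tiny_channel()
  p <- default_parameters()
  st <- new_state(m, fields = list(M = 0.1, T = 0.05, S = 0.1, F = 0.05))
  st <- close_state(st, p)
  expect_equal(st$rho, rep(0.7, m$n_nodes))
  expect_equal(max(abs(st$fields$M + st$fields$T + st$fields$S +
                       st$fields$F + st$rho - p$C_tot)), 0)
  # all-empty state: rho = C_tot
  st0 <- close_state(new_state(m), p)
  expect_equal(st0$rho, rep(1, m$n_nodes))
  # overcrowding is rejected
  expect_error(close_state(new_state(m, fields = list(M = 1.2)), p),
               "overcrowding")
  # linear sigma gives the constant negative-slope velocity on every element
  st$sigma <- 2 * m$nodes[, 1]
  u <- -p1_gradient(m, st$sigma)
  expect_equal(unname(u[, 1]), rep(-2, m$n_tri), tolerance = 1e-12)
})

test_that("pressure source assembles the summed cell budget plus ECM turnover", {
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.005)
  p <- default_parameters()
  set.seed(3)
  for (rep in 1:100) {
    y <- oracle_random_state()
    st <- new_state(m, fields = as.list(y))
    st$rho <- rep(1 - sum(y[c("M", "T", "S", "F")]), m$n_nodes)
    pr <- pressure_rhs(st, p)
    want <- oracle_wellmixed_rhs(y, p)
    f_want <- sum(want[c("M", "T", "S", "F")])
    expect_equal(pr$f_cells[1], f_want, tolerance = 1e-12 * max(1, abs(f_want)))
    g_want <- p$w_ecm * (p$lam_rho * (1 - st$rho[1] / p$rho0) -
                         p$d_rhoQ * y[["Q"]] * st$rho[1])
    expect_equal(pr$g_ecm[1], g_want, tolerance = 1e-12)
  }
  # no sources: sigma is the harmonic extension of the adhesion values and
  # the velocity is (numerically) tiny
  st0 <- close_state(new_state(m), p)
  pr0 <- pressure_rhs(st0, p)
  expect_equal(max(abs(pr0$f_cells)), 0)
  # remodeling-only source is positive when below the packing density
  stq <- new_state(m, fields = list(M = 0.1))
  stq$rho <- rep(0.9, m$n_nodes)
  expect_true(all(pressure_rhs(stq, p)$g_ecm > 0))
})

test_that("plaque weight is exact P1 quadrature", {
  m <- tiny_channel()
  st <- new_state(m)
  expect_equal(plaque_weight(st), 0)
  st2 <- new_state(m, fields = list(M = 0.05, T = 0.05, S = 0.05, F = 0.05))
  expect_equal(plaque_weight(st2), 0.2 * mesh_area(m), tolerance = 1e-12)
  # random nodal field: lumped quadrature equals exact nodal-linear integral
  set.seed(5)
  v <- runif(m$n_nodes)
  st3 <- new_state(m, fields = list(M = v))
  tri <- m$tri
  exact <- sum(m$elem$area / 3 * (v[tri[, 1]] + v[tri[, 2]] + v[tri[, 3]]))
  expect_equal(plaque_weight(st3), exact, tolerance = 1e-12)
})

test_that("lipid-free conditions starve the cascade", {
  # with no radical source and no initial radicals, no ox-LDL forms
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.005)
  p <- default_parameters()
  p$r0 <- 1e-30
  st <- new_state(m, fields = list(L = 1.9e-3, H = 4e-4))
  rr <- reaction_rhs(st, p)
  expect_equal(max(abs(rr$source[, "Lox"])), 0)
  expect_equal(max(abs(rr$source[, "I12"])), 0)  # activation gate closed
})

test_that("well-mixed lipid decay matches the closed-form exponential", {
  skip_if_not_installed("deSolve")
  p <- default_parameters()
  r_fix <- 12  # held fixed: L then decays as L0 * exp(-k_L * r * t)
  rhs <- function(t, y, parms) list(-p$k_L * r_fix * y)
  out <- deSolve::ode(c(L = 1.9e-3), seq(0, 50, by = 1), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  expect_equal(out[, "L"], 1.9e-3 * exp(-p$k_L * r_fix * out[, "time"]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # and the oracle network reduces to exactly this term when only L and r
  # are present
  y <- c(L = 1.9e-3, H = 0, Lox = 0, r = r_fix, M = 0, P = 0, T = 0,
         Ig = 0, S = 0, I12 = 0, G = 0, Q = 0, Qr = 0, F = 0)
  expect_equal(unname(oracle_wellmixed_rhs(y, p)[["L"]]),
               -p$k_L * 1.9e-3 * r_fix)
})
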