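test_that("constant states are preserved exactly under diffusion + Robin", {
  m <- tiny_channel()
  x <- rep(2.5, m$n_nodes)
  sys <- assemble_transport(m, D = 1, dt = 0.5, prev = x,
                            robin = list(list(tag = "gamma_I", b = 3,
                                              X0 = 2.5)))
  expect_equal(solve_transport(sys), x, tolerance = 1e-12)
})

test_that("steady Robin flux balance drives the field to the exterior value", {
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.002)
  x <- rep(0, m$n_nodes)
  cache <- fem_cache(m)
  for (k in 1:400) {
    sys <- assemble_transport(m, D = 0.5, dt = 1, prev = x,
                              robin = list(list(tag = "gamma_I", b = 10,
                                                X0 = 4)),
                              cache = cache)
    x <- solve_transport(sys)
  }
  expect_equal(x, rep(4, m$n_nodes), tolerance = 1e-6)
})

test_that("no-flux diffusion conserves mass and respects the maximum principle", {
  m <- tiny_channel()
  set.seed(42)
  x <- runif(m$n_nodes)
  sys <- assemble_transport(m, D = 0.3, dt = 0.25, prev = x)
  xn <- solve_transport(sys)
  # conserved to the 1e-10 per-step bound (direct-solve rounding only)
  expect_equal(integrate_field(m, xn), integrate_field(m, x),
               tolerance = 1e-10)
  expect_true(max(xn) <= max(x) + 1e-12)
  expect_true(min(xn) >= min(x) - 1e-12)
})

test_that("manufactured solutions converge at order ~2 (transport and pressure)", {
  L <- 0.1; th <- 0.01
  errT <- errP <- numeric(0)
  for (h in c(0.002, 0.001, 0.0005)) {
    m <- build_channel_domain(L, th, bump_amp = 0, h = h)
    x <- m$nodes[, 1]; y <- m$nodes[, 2]
    ml <- integrate_field(m, rep(1, m$n_nodes))  # warm nothing; area
    Xe <- cos(2 * pi * x / L) * cos(pi * y / th)
    D <- 1e-3
    src <- D * ((2 * pi / L)^2 + (pi / th)^2) * Xe
    s <- assemble_transport(m, D = D, dt = 1, prev = Xe, source = src)
    Xn <- solve_transport(s)
    errT <- c(errT, sqrt(integrate_field(m, (Xn - Xe)^2)))
    Se <- cos(2 * pi * x / L) * cos(pi * y / (2 * th))
    fp <- ((2 * pi / L)^2 + (pi / (2 * th))^2) * Se
    Sn <- solve_pressure(m, f = fp, dirichlet = 0)
    errP <- c(errP, sqrt(integrate_field(m, (Sn - Se)^2)))
  }
  expect_true(all(log2(errT[-3] / errT[-1]) >= 1.8))
  expect_true(all(log2(errP[-3] / errP[-1]) >= 1.8))
})

test_that("sparse solve matches a dense direct solve", {
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.005)
  set.seed(7)
  prev <- runif(m$n_nodes)
  src <- rnorm(m$n_nodes)
  sys <- assemble_transport(m, D = 0.05, dt = 0.5, prev = prev, source = src,
                            decay = 0.3)
  xs <- solve_transport(sys)
  Ad <- as.matrix(sys$A)
  xd <- solve(Ad, sys$rhs)
  expect_equal(xs, xd[sys$pmap$red], tolerance = 1e-9)
})

test_that("advection of a linear field by constant velocity is consistent", {
  # div(uX) with u constant and X linear is u.grad(X), a constant source
  m <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.002)
  u <- cbind(rep(3, m$n_tri), rep(0, m$n_tri))
  X <- 2 + 5 * m$nodes[, 1]
  dt <- 1e-3
  sys <- assemble_transport(m, D = 0, dt = dt, prev = X, u_elem = u)
  xn <- solve_transport(sys)
  interior <- which(m$nodes[, 1] > 0.02 & m$nodes[, 1] < 0.08)
  expect_equal((xn[interior] - X[interior]) / dt,
               rep(-15, length(interior)), tolerance = 0.05)
})

test_that("pressure solve: harmonic extension, interior positivity, gradient", {
  a <- build_annulus_domain(0.9, 1, h = 0.02)
  sg <- solve_pressure(a, f = 0, dirichlet = 7)
  expect_equal(sg, rep(7, a$n_nodes), tolerance = 1e-10)
  sp <- solve_pressure(a, f = 1, dirichlet = 0)
  inner <- setdiff(seq_len(a$n_nodes), a$gamma_I)
  expect_true(all(sp[inner] > 0))
  # P1 gradients: exact for linear fields, zero for constants
  m <- tiny_channel()
  g <- p1_gradient(m, 3 * m$nodes[, 1] - 2 * m$nodes[, 2])
  expect_equal(unname(g[, 1]), rep(3, m$n_tri), tolerance = 1e-12)
  expect_equal(unname(g[, 2]), rep(-2, m$n_tri), tolerance = 1e-12)
  expect_equal(max(abs(p1_gradient(m, rep(4, m$n_nodes)))), 0)
  # quadratic field: elementwise gradient within O(h) of the analytic one
  q <- m$nodes[, 1]^2
  gq <- p1_gradient(m, q)
  cx <- (m$nodes[m$tri[, 1], 1] + m$nodes[m$tri[, 2], 1] +
         m$nodes[m$tri[, 3], 1]) / 3
  expect_equal(unname(gq[, 1]), 2 * cx, tolerance = 0.05)
})

test_that("invalid systems are rejected", {
  m <- tiny_channel()
  expect_error(assemble_transport(m, D = 1, dt = -1, prev = rep(0, m$n_nodes)),
               "dt")
})
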