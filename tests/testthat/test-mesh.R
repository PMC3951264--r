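test_that("channel domain area matches geometry", {
  flat <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.002)
  expect_equal(mesh_area(flat), 0.1 * 0.01, tolerance = 0.01)
  m <- tiny_channel()
  bump_int <- stats::integrate(function(x)
    bump_profile(x, 0.05, 0.005, 0.015), 0, 0.1)$value
  expect_equal(mesh_area(m) - 0.001, bump_int, tolerance = 0.02)
  # resolution scaling: halving h roughly doubles free-boundary node count
  m2 <- build_channel_domain(0.1, 0.01, bump_amp = 0.005, h = 0.001)
  expect_equal(length(m2$gamma_I) / length(m$gamma_I), 2, tolerance = 0.1)
  expect_error(build_channel_domain(0.1, 0.01, bump_amp = -0.02),
               "amp")
})

test_that("annulus area, tags and boundary-node spacing", {
  m <- build_annulus_domain(0.9, 1, h = 0.02)
  expect_equal(mesh_area(m), pi * (1 - 0.81), tolerance = 0.01)
  expect_length(m$gamma_L, 0)
  # inner boundary node count times h ~ inner circumference
  expect_equal(length(m$gamma_I) * 0.02, 2 * pi * 0.9, tolerance = 0.05)
  expect_error(build_annulus_domain(1, 0.9), "inner radius")
  # refinement reduces the polygonal area deficit monotonically
  errs <- vapply(c(0.08, 0.04, 0.02), function(h)
    abs(mesh_area(build_annulus_domain(0.9, 1, h = h)) - pi * 0.19),
    numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mesh area equals shoelace area of its boundary loops", {
  m <- tiny_channel()
  # channel boundary loop: media wall left-to-right, then the free boundary
  # right-to-left (the lateral edges are vertical segments joining the ends)
  loop <- rbind(m$nodes[m$gamma_M, ],
                m$nodes[rev(m$gamma_I), ])
  expect_equal(abs(shoelace_area(loop)), mesh_area(m), tolerance = 1e-10)
  a <- build_annulus_domain(0.9, 1, h = 0.02)
  outer_l <- abs(shoelace_area(a$nodes[a$gamma_M, ]))
  inner_l <- abs(shoelace_area(a$nodes[a$gamma_I, ]))
  expect_equal(outer_l - inner_l, mesh_area(a), tolerance = 1e-10)
})

test_that("triangles are positively oriented with bounded quality", {
  for (m in list(tiny_channel(), build_annulus_domain(0.9, 1, h = 0.03))) {
    expect_true(all(m$elem$area > 0))
    q <- mesh_quality(m)
    expect_true(all(q > 0.3) && all(q <= 1 + 1e-12))
  }
})

test_that("periodic partners share coordinates up to the translation", {
  m <- tiny_channel()
  d <- m$nodes[m$periodic[, "slave"], ] - m$nodes[m$periodic[, "master"], ]
  expect_equal(unname(d[, 1]), rep(0.1, nrow(d)))
  expect_equal(unname(d[, 2]), rep(0, nrow(d)), tolerance = 1e-14)
})

test_that("curvature: circle, straight segment, ellipse, turning number", {
  a <- build_annulus_domain(0.9, 1, h = 0.01)
  kap <- boundary_curvature(a, "gamma_I")
  expect_equal(kap, rep(1 / 0.9, length(kap)), tolerance = 1e-3)
  flat <- build_channel_domain(0.1, 0.01, bump_amp = 0, h = 0.002)
  expect_equal(max(abs(boundary_curvature(flat, "gamma_I"))), 0,
               tolerance = 1e-10)
  # analytic ellipse curvature
  aa <- 2; bb <- 1
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  xy <- cbind(aa * cos(th), bb * sin(th))
  kap_num <- curvature_polyline(xy, closed = TRUE)
  kap_an <- aa * bb / (aa^2 * sin(th)^2 + bb^2 * cos(th)^2)^1.5
  expect_equal(kap_num, kap_an, tolerance = 1e-3)
  # curvature of the inner circle agrees with the circumcircle oracle
  xyI <- a$nodes[a$gamma_I, ]
  i <- 10
  oc <- oracle_circumcircle_curvature(xyI[i - 1, ], xyI[i, ], xyI[i + 1, ])
  expect_equal(boundary_curvature(a, "gamma_I")[i], unname(abs(oc)),
               tolerance = 1e-3)
  # turning number: integral of curvature over a closed loop is 2*pi
  ed <- sqrt(rowSums((xy - xy[c(2:400, 1), ])^2))
  ds <- (ed + ed[c(400, 1:399)]) / 2
  expect_equal(sum(kap_num * ds), 2 * pi, tolerance = 1e-3)
})

test_that("curvature error decreases at second order on circles", {
  errs <- vapply(c(0.04, 0.02, 0.01), function(h) {
    a <- build_annulus_domain(0.9, 1, h = h)
    max(abs(boundary_curvature(a, "gamma_I") - 1 / 0.9))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders > 1.6))
})

test_that("remesh: identity, uniform displacement, field clamping", {
  m <- tiny_channel()
  f <- list(v = 1 + m$nodes[, 2])
  out <- remesh(m, m$geom$gvals, fields = f)
  expect_equal(out$mesh$nodes, m$nodes, tolerance = 1e-15)
  expect_equal(mesh_area(out$mesh), mesh_area(m), tolerance = 1e-12)
  expect_identical(out$fields$v, f$v)
  # uniform inward displacement of the annulus free boundary grows the area
  # by ~ 2 pi r d
  a <- build_annulus_domain(0.9, 1, h = 0.02)
  d <- 0.005
  out2 <- remesh(a, a$geom$fvals - d)
  expect_equal(mesh_area(out2$mesh) - mesh_area(a), 2 * pi * 0.9 * d,
               tolerance = 0.02)
  # collapse detection
  expect_error(remesh(m, m$geom$gvals * 0 - 1), "collapse")
  # quality is restored by construction after remesh
  expect_true(min(mesh_quality(out2$mesh)) > 0.3)
})
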