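test_that("optical properties derive the diffusion quantities exactly", {
  op <- optical_properties(mu_a = 0.01, mu_s = 10, g = 0.9)
  expect_equal(op$mu_s_prime, 1, tolerance = 1e-12)
  expect_equal(op$D, 1 / (3 * 1.01), tolerance = 1e-12)
  expect_equal(op$mu_eff, sqrt(3 * 0.01 * 1.01), tolerance = 1e-12)
  expect_error(optical_properties(-0.1, 1, 0.9), "non-negative")
  expect_error(optical_properties(0.1, 1, 1.5), "anisotropy")
  for (r in dplyr::group_split(default_optical_properties(),
    dplyr::row_number())) {
    # quoted effective attenuation depth range for scattering tissues
    if (r$region == "csf") next
    expect_gt(1 / r$mu_eff, 2)
    expect_lt(1 / r$mu_eff, 5)
  }
})

test_that("point kernel matches the closed form and decays monotonically", {
  op <- optical_properties(mu_a = 0.01, mu_s = 10, g = 0.9) # mu_s' = 1.0
  # frozen from an independent evaluation of exp(-mu_eff r) / (4 pi D r)
  expect_equal(point_kernel(10, op), 4.229226179298e-03, tolerance = 1e-10)
  r <- seq(1, 60, by = 0.5)
  expect_true(all(diff(point_kernel(r, op)) < 0))
  expect_lt(point_kernel(300, op), 1e-25)
  expect_error(point_kernel(0, op), "singular")
  expect_error(point_kernel(c(1, -2), op), "singular")
})

test_that("Gauss-Legendre rules integrate polynomials of degree 2n-1 exactly", {
  for (n in c(2, 5, 8)) {
    gl <- gauss_legendre(n)
    for (p in seq(0, 2 * n - 1)) {
      expect_equal(
        sum(gl$weights * gl$nodes^p),
        (1 + (-1)^p) / (p + 1),
        tolerance = 1e-12
      )
    }
  }
})

test_that("line fluence matches dense brute-force integration and its symmetries", {
  op <- optical_properties(mu_a = 0.02, mu_s = 20, g = 0.9)
  a <- c(0, 0, -10)
  b <- c(0, 0, 10)
  pts <- rbind(c(5, 0, 4), c(5, 0, -4), c(0, 8, 2), c(0, 8, -2), c(12, 3, 7))
  phi <- line_fluence(pts, a, b, op)
  # mirror symmetry about the midplane
  expect_equal(phi[1], phi[2], tolerance = 1e-9)
  expect_equal(phi[3], phi[4], tolerance = 1e-9)
  # brute-force trapezoid oracle at 1e4 subdivisions
  tt <- seq(0, 1, length.out = 10001)
  for (i in seq_len(nrow(pts))) {
    s <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]), a[3] + tt * (b[3] - a[3]))
    rr <- sqrt((s[, 1] - pts[i, 1])^2 + (s[, 2] - pts[i, 2])^2 + (s[, 3] - pts[i, 3])^2)
    ref <- sum(diff(tt) * (point_kernel(rr[-1], op) + point_kernel(rr[-length(rr)], op)) / 2)
    expect_equal(phi[i], ref, tolerance = 1e-3)
  }
  # short segment converges to the point kernel at equal total energy
  short <- line_fluence(c(10, 0, 0), c(0, 0, -0.05), c(0, 0, 0.05), op)
  expect_equal(short, point_kernel(10, op), tolerance = 1e-4)
  expect_error(line_fluence(c(0, 0, 0), a, b, op), "on the source segment")
})

test_that("dose matrix columns reproduce single-source fields and superpose linearly", {
  model <- tiny_model()
  plan <- as_plan(tibble::tibble(
    source = 1:2, kind = c("line", "point"),
    px = c(20, 24), py = c(20, 24), pz = c(26, 20),
    dx = c(20, 24), dy = c(20, 24), dz = c(16, 20),
    length = c(10, 0), power = 0
  ))
  dose <- build_dose_matrix(model, plan)
  expect_true(all(dose$G >= 0))
  one <- build_dose_matrix(model, plan[1, ])
  expect_equal(dose$G[, 1], one$G[, 1], tolerance = 1e-12)
  # superposition equals the hand-scaled column sum, and is linear
  x <- c(0.3, 0.5)
  expect_equal(
    superpose(dose, x),
    0.3 * dose$G[, 1] + 0.5 * dose$G[, 2],
    tolerance = 1e-12
  )
  expect_equal(superpose(dose, 2 * x), 2 * superpose(dose, x), tolerance = 1e-12)
  expect_equal(superpose(dose, c(0, 0)), rep(0, nrow(model$elements)))
  expect_error(superpose(dose, c(-0.1, 0.2)), "non-negative")
  expect_error(superpose(dose, 1), "length")
  # duration converts power to energy linearly
  dose10 <- build_dose_matrix(model, plan, duration = 10)
  expect_equal(dose10$G, 10 * dose$G, tolerance = 1e-12)
})

test_that("analytic fluence decreases with distance in a homogeneous medium", {
  model <- tiny_model()
  src <- as_plan(tibble::tibble(
    source = 1L, kind = "point", px = 20, py = 20, pz = 20,
    dx = 20, dy = 20, dz = 20, length = 0, power = 0
  ))
  dose <- build_dose_matrix(model, src)
  el <- model$elements
  r <- sqrt((el$x - 20)^2 + (el$y - 20)^2 + (el$z - 20)^2)
  ord <- order(r)
  keep <- r[ord] > 1 # beyond the clamp radius
  phi_sorted <- dose$G[ord, 1][keep]
  expect_true(all(diff(phi_sorted) <= 1e-12))
})
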