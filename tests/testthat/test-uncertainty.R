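# small library fixture: two sources on the tiny phantom
tiny_library <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    model <- tiny_model()
    plan <- as_plan(tibble::tibble(
      source = 1:2, kind = c("line", "point"),
      px = c(18, 23), py = c(20, 20), pz = c(25, 20),
      dx = c(18, 23), dy = c(20, 20), dz = c(15, 20),
      length = c(10, 0), power = 0
    ))
    con <- make_injection_constraint(model, plan)
    dose <- build_dose_matrix(model, plan)
    th <- apply_guardband(dose_thresholds())
    cfg <- uncertainty_config(seed = 17)
    lib <- build_library(model, plan, con, cfg, dose = dose)
    cache <<- list(
      model = model, plan = plan, con = con, dose = dose,
      th = th, cfg = cfg, lib = lib
    )
    cache
  }
})

test_that("the worst-case deflection angle comes from the isosceles chord", {
  expect_equal(deflection_angle_max(50, 0), 0)
  th <- deflection_angle_max(50, 3)
  expect_equal(th, 2 * asin(3 / (2 * 50)), tolerance = 1e-12)
  expect_equal(th, 0.060009003647, tolerance = 1e-9)
  # chord inversion returns d to machine precision
  for (L in c(10, 25, 50, 80)) {
    expect_equal(2 * L * sin(deflection_angle_max(L, 3) / 2), 3,
      tolerance = 1e-12
    )
  }
  expect_error(deflection_angle_max(1.4, 3), "insertion length")
})

test_that("principal directions are orthogonal, 45 degrees apart and seeded", {
  axis <- c(0.2, -0.3, -0.9)
  d <- principal_directions(axis, seed = 5)
  expect_equal(dim(d), c(8, 3))
  expect_true(all(abs(d %*% axis) < 1e-12))
  expect_equal(rowSums(d^2), rep(1, 8), tolerance = 1e-12)
  for (i in 1:8) {
    ang <- acos(pmin(1, pmax(-1, sum(d[i, ] * d[i %% 8 + 1, ]))))
    expect_equal(ang, pi / 4, tolerance = 1e-9)
  }
  # opposite directions are antipodal (Dir k vs Dir k+4)
  expect_equal(d[1, ], -d[5, ], tolerance = 1e-12)
  expect_identical(principal_directions(axis, seed = 5), d)
  expect_false(isTRUE(all.equal(principal_directions(axis, seed = 6)[1, ], d[1, ])))
})

test_that("deflection preserves insertion and emission lengths and hits the 3 mm chord", {
  src <- tibble::tibble(
    source = 1L, kind = "line", px = 20, py = 20, pz = 30,
    dx = 20, dy = 20, dz = 10, length = 20, power = 0
  )
  inj <- c(20, 20, 60) # insertion length 50 to the distal tip
  dirs <- principal_directions(c(0, 0, -1), seed = 2)
  th_max <- deflection_angle_max(50, 3)
  expect_identical(deflect_source(src, inj, dirs[1, ], 0), tibble::as_tibble(src))
  worst <- deflect_source(src, inj, dirs[3, ], th_max)
  tip_shift <- sqrt((worst$dx - src$dx)^2 + (worst$dy - src$dy)^2 +
    (worst$dz - src$dz)^2)
  expect_equal(tip_shift, 3, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    ang <- runif(1, 0, th_max)
    d <- deflect_source(src, inj, dirs[sample.int(8, 1), ], ang)
    ins <- sqrt((d$dx - inj[1])^2 + (d$dy - inj[2])^2 + (d$dz - inj[3])^2)
    em <- sqrt((d$dx - d$px)^2 + (d$dy - d$py)^2 + (d$dz - d$pz)^2)
    expect_equal(ins, 50, tolerance = 1e-9)
    expect_equal(em, 20, tolerance = 1e-9)
    # chord formula for the tip displacement
    shift <- sqrt((d$dx - src$dx)^2 + (d$dy - src$dy)^2 + (d$dz - src$dz)^2)
    expect_equal(shift, 2 * 50 * sin(ang / 2), tolerance = 1e-9)
  }
  expect_error(deflect_source(src, inj, dirs[1, ], th_max * 1.01), "exceeds")
})

test_that("the deflection library holds 89 configurations per source", {
  fx <- tiny_library()
  expect_equal(nrow(fx$lib$configs), 89) # 1 + 8 + 8 x 10
  expect_equal(sum(fx$lib$configs$kind == "worst"), 8)
  expect_equal(sum(fx$lib$configs$kind == "quantile"), 80)
  expect_equal(
    sort(unique(fx$lib$configs$magnitude[fx$lib$configs$kind == "quantile"])),
    seq(0.05, 0.95, by = 0.1)
  )
  for (j in 1:2) {
    expect_equal(ncol(fx$lib$columns[[j]]), 89)
    # nominal entry reproduces the undeflected dose-matrix column
    nom <- ipdtplan:::library_entry(fx$lib, "nominal")
    expect_equal(fx$lib$columns[[j]][, nom], fx$dose$G[, j], tolerance = 1e-12)
  }
})

test_that("quantile magnitudes displace the tip strictly less than the tolerance", {
  fx <- tiny_library()
  inj <- injection_points(fx$plan, fx$con)
  j <- 1
  L <- sqrt(sum((c(fx$plan$dx[j], fx$plan$dy[j], fx$plan$dz[j]) -
    c(inj$ix[j], inj$iy[j], inj$iz[j]))^2))
  th_max <- fx$lib$angles[j]
  chord <- function(q) 2 * L * sin(q * th_max / 2)
  expect_lt(chord(0.95), 3)
  expect_equal(chord(1), 3, tolerance = 1e-9)
})

test_that("worst-case sampling deflects every source by the full tolerance", {
  fx <- tiny_library()
  x <- c(0.3, 0.2)
  wc <- sample_worst_case(fx$lib, x, fx$model, fx$th, n_samples = 12, seed = 3)
  expect_equal(wc$n_samples, 12)
  expect_true(all(fx$lib$configs$kind[wc$entries] == "worst"))
  # single-sample field equals the picked columns scaled by the powers
  one <- sample_worst_case(fx$lib, x, fx$model, fx$th, n_samples = 1, seed = 5)
  phi <- fx$lib$columns[[1]][, one$entries[1, 1]] * x[1] +
    fx$lib$columns[[2]][, one$entries[1, 2]] * x[2]
  direct <- v100(phi, fx$model, fx$th)
  expect_equal(
    one$samples$v100[one$samples$tissue == "tumour"],
    direct$v100[direct$tissue == "tumour"],
    tolerance = 1e-9
  )
  # seeded reproducibility, sample for sample
  wc2 <- sample_worst_case(fx$lib, x, fx$model, fx$th, n_samples = 12, seed = 3)
  expect_identical(wc$samples, wc2$samples)
})

test_that("truncated-Gaussian magnitudes respect the bound and the quantile bins", {
  set.seed(2)
  tg <- draw_truncated_magnitudes(1e5)
  expect_true(all(abs(tg$z) <= 3))
  expect_lt(abs(tg$acceptance - 0.95), 0.005) # 2 Phi(1.96) - 1
  fx <- tiny_library()
  x <- c(0.3, 0.2)
  ga <- sample_gaussian(fx$lib, x, fx$model, fx$th, n_samples = 40, seed = 4)
  expect_true(all(ga$magnitudes <= 3))
  expect_true(all(fx$lib$configs$kind[ga$entries] == "quantile"))
  # positive magnitudes on Dir 1-4, negative on Dir 5-8, per the histogram
  # construction convention: directions recorded in 1..8
  expect_true(all(ga$directions %in% 1:8))
  # sigma -> 0: every draw lands in the smallest quantile bin
  tiny_sigma <- uncertainty_config(sigma = 1e-6, seed = 17)
  lib2 <- fx$lib
  lib2$cfg <- tiny_sigma
  ga0 <- sample_gaussian(lib2, x, fx$model, fx$th, n_samples = 10, seed = 4)
  expect_true(all(fx$lib$configs$magnitude[ga0$entries] == 0.05))
})

test_that("power re-optimization is optimal on the realized geometry", {
  fx <- tiny_library()
  nom_entry <- ipdtplan:::library_entry(fx$lib, "nominal")
  nominal_sol <- optimize_power(fx$dose, fx$model, fx$th, coverage_target = NULL)
  same <- reoptimize_power(fx$lib, rep(nom_entry, 2), fx$model, fx$th,
    coverage_target = NULL
  )
  expect_equal(same$solution$cost, nominal_sol$cost, tolerance = 1e-8)
  # on a deflected geometry, re-optimized powers never cost more than the
  # nominal powers evaluated on that geometry
  set.seed(7)
  ga <- sample_gaussian(fx$lib, nominal_sol$x, fx$model, fx$th,
    n_samples = 3, seed = 21
  )
  for (s in 1:3) {
    ro <- reoptimize_power(fx$lib, ga$entries[s, ], fx$model, fx$th,
      coverage_target = NULL
    )
    cb <- cost(nominal_sol$x, ro$dose, fx$model, fx$th)
    expect_lte(ro$solution$cost, cb$f + 1e-8)
  }
})

test_that("the worst-case power report collapses to the nominal outcome at eta 0", {
  model <- tiny_model()
  plan <- heuristic_placement(model, add_points = FALSE)
  dose <- build_dose_matrix(model, plan)
  th <- apply_guardband(dose_thresholds())
  rep0 <- power_uncertainty_report(list(model), list(dose), th,
    eta_levels = c(0), coverage_target = NULL
  )
  s <- rep0$summary
  expect_equal(s$v100_max, s$v100)
  expect_equal(s$v100_min, s$v100)
  expect_true(all(s$dv100[!is.na(s$dv100)] == 0))
  expect_true(all(c(
    "mode", "eta", "tissue", "v100", "v100_max", "v100_min",
    "dv100", "dv100_pct", "V100_max", "V100_min"
  ) %in% names(s)))
})
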