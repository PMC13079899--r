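# brute-force / closed-form oracles for the LP machinery live in this file;
# the toy problems are small enough to enumerate

toy_problem <- function(seed = 1, m = 20, k = 2) {
  set.seed(seed)
  region <- c(rep("tumour", ceiling(m * 0.6)), rep("white", floor(m * 0.4)))
  model <- fake_model(region, volume = runif(m, 0.5, 2))
  G <- matrix(runif(m * k, 0, 2e-4), m, k)
  th <- toy_thresholds(d_min = 5e-5, d_max = 6e-5)
  list(model = model, dose = fake_dose(G), th = th, G = G, k = k)
}

toy_cost_fn <- function(tp) {
  ed <- ipdtplan:::element_dosimetry(tp$model, tp$th)
  function(x) {
    phi <- as.vector(tp$G %*% x)
    tum <- ed$role == "tumour"
    oar <- ed$role == "oar"
    sum(ed$weight[tum] * ed$volume[tum] * pmax(0, ed$threshold[tum] - phi[tum])) +
      sum(ed$weight[oar] * ed$volume[oar] * pmax(0, phi[oar] - ed$threshold[oar]))
  }
}

test_that("cost reproduces the single-element hand evaluations and additivity", {
  model <- fake_model("tumour", volume = 2)
  th <- toy_thresholds(d_min = 1)
  dose <- fake_dose(matrix(0.4, 1, 1))
  cb <- cost(1, dose, model, th)
  expect_equal(cb$f, 2 * (1 - 0.4), tolerance = 1e-12) # w t (d_min - g.x)
  # within bounds -> zero
  expect_equal(cost(3, dose, model, th)$f, 0)
  # OAR over-dose branch
  oarm <- fake_model("white", volume = 3)
  oth <- toy_thresholds(d_max = 1)
  expect_equal(cost(5, fake_dose(matrix(0.4, 1, 1)), oarm, oth)$f,
    3 * (2 - 1),
    tolerance = 1e-12
  )
  # two-element additivity
  m2 <- fake_model(c("tumour", "white"), volume = c(2, 3))
  d2 <- fake_dose(matrix(c(0.4, 2), 2, 1))
  expect_equal(
    cost(1, d2, m2, toy_thresholds(d_min = 1, d_max = 1))$f,
    2 * 0.6 + 3 * 1,
    tolerance = 1e-12
  )
})

test_that("uncertainty-aware cost modes evaluate at the scaled powers", {
  model <- fake_model("tumour", volume = 1)
  th <- toy_thresholds(d_min = 1)
  dose <- fake_dose(matrix(1, 1, 1))
  x <- 0.5
  eta <- 0.2
  f <- function(s) max(0, 1 - s * x)
  expect_equal(cost(x, dose, model, th, mode = "min_only", eta = eta)$f,
    f(1 - eta),
    tolerance = 1e-12
  )
  expect_equal(cost(x, dose, model, th, mode = "max_min", eta = eta)$f,
    f(1 + eta) + f(1 - eta),
    tolerance = 1e-12
  )
  expect_equal(cost(x, dose, model, th, mode = "min_only", eta = 0)$f,
    cost(x, dose, model, th)$f,
    tolerance = 1e-12
  )
})

test_that("the LP optimum matches a brute-force power grid on a 2-source toy", {
  tp <- toy_problem(seed = 42)
  fcost <- toy_cost_fn(tp)
  sol <- optimize_power(tp$dose, tp$model, tp$th,
    coverage_target = NULL,
    tol = 1e-10
  )
  expect_equal(sol$status, "optimal")
  # exhaustive grid over the feasible simplex (the finer 0.001 W oracle
  # runs in the acceptance suite)
  xs <- seq(0, 1, by = 0.005)
  best <- Inf
  for (x1 in xs) {
    x2max <- 1 - x1
    f2 <- vapply(xs[xs <= x2max], function(x2) fcost(c(x1, x2)), numeric(1))
    best <- min(best, min(f2))
  }
  expect_lte(sol$cost, best + 1e-9)
  expect_lt(best - sol$cost, 0.05 * max(best, 1e-12) + 1e-6)
})

test_that("the level-bundle solution agrees with a direct epigraph simplex LP", {
  tp <- toy_problem(seed = 7, m = 12)
  sol <- optimize_power(tp$dose, tp$model, tp$th,
    coverage_target = NULL, tol = 1e-10
  )
  # independent oracle: the full epigraph LP (one slack per element) handed
  # to the simplex solver directly
  ed <- ipdtplan:::element_dosimetry(tp$model, tp$th)
  m <- nrow(ed)
  k <- tp$k
  tum <- ed$role == "tumour"
  sgn <- ifelse(tum, -1, 1) # s_i >= +-(g_i.x - d_i)
  A1 <- cbind(sweep(tp$G, 1, sgn, `*`), -diag(m)) # sgn*g.x - s <= sgn*d
  b1 <- sgn * ed$threshold
  A1 <- rbind(A1, c(rep(1, k), rep(0, m))) # total power cap
  b1 <- c(b1, 1)
  r <- ipdtplan:::solve_lp(
    a = c(rep(0, k), ed$weight * ed$volume),
    A1 = A1, b1 = b1
  )
  expect_equal(r$solved, 1)
  expect_equal(sol$cost, unname(r$value), tolerance = 1e-6)
})

test_that("solutions respect the power polytope and the 1 W default cap", {
  tp <- toy_problem(seed = 9)
  sol <- optimize_power(tp$dose, tp$model, tp$th, coverage_target = NULL)
  expect_true(all(sol$x >= -1e-12))
  expect_lte(sum(sol$x), 1 + 1e-8)
  # custom constraint rows are honoured too
  cons <- power_constraints(2,
    A = rbind(c(1, 1), c(1, 0)),
    p_max = c(0.8, 0.25)
  )
  sol2 <- optimize_power(tp$dose, tp$model, tp$th,
    constraints = cons,
    coverage_target = NULL
  )
  expect_lte(sum(sol2$x), 0.8 + 1e-8)
  expect_lte(sol2$x[1], 0.25 + 1e-8)
})

test_that("LP optimality and convexity hold against random feasible powers", {
  tp <- toy_problem(seed = 5, m = 30, k = 3)
  fcost <- toy_cost_fn(tp)
  sol <- optimize_power(tp$dose, tp$model, tp$th, coverage_target = NULL,
    tol = 1e-10)
  set.seed(99)
  for (i in 1:100) {
    x <- runif(3)
    x <- x / sum(x) * runif(1) # random feasible point under the 1 W cap
    expect_gte(fcost(x) - sol$cost, -1e-8)
  }
  # piecewise-linear convexity: midpoint cost <= mean of endpoint costs
  for (i in 1:50) {
    x1 <- runif(3, 0, 1 / 3)
    x2 <- runif(3, 0, 1 / 3)
    expect_lte(
      fcost((x1 + x2) / 2),
      (fcost(x1) + fcost(x2)) / 2 + 1e-12
    )
  }
})

test_that("min-only optimization dominates nominal at the derated powers", {
  tp <- toy_problem(seed = 31)
  eta <- 0.2
  nom <- optimize_power(tp$dose, tp$model, tp$th, coverage_target = NULL)
  mo <- optimize_power(tp$dose, tp$model, tp$th,
    mode = "min_only", eta = eta,
    coverage_target = NULL
  )
  fcost <- toy_cost_fn(tp)
  expect_lte(
    fcost(mo$x * (1 - eta)),
    fcost(nom$x * (1 - eta)) + 1e-8
  )
  # min_only at eta = 0 is the nominal LP
  mo0 <- optimize_power(tp$dose, tp$model, tp$th,
    mode = "min_only", eta = 0,
    coverage_target = NULL
  )
  expect_equal(mo0$cost, nom$cost, tolerance = 1e-9)
})

test_that("worst-case power bounds scale element-wise", {
  b <- worst_case_bounds(c(0.5, 0.2), 0.2)
  expect_equal(b$x_max, c(0.6, 0.24), tolerance = 1e-12)
  expect_equal(b$x_min, c(0.4, 0.16), tolerance = 1e-12)
  b0 <- worst_case_bounds(c(0.5, 0.2), 0)
  expect_equal(b0$x_max, b0$x_min)
  expect_error(worst_case_bounds(c(0.5), 1), "eta")
  expect_true(all(worst_case_bounds(c(1, 0), 0.99)$x_min >= 0))
})

test_that("the coverage escalation loop reaches the tumour target when feasible", {
  model <- small_model()
  plan <- heuristic_placement(model)
  dose <- build_dose_matrix(model, plan)
  th <- apply_guardband(dose_thresholds())
  sol <- optimize_power(dose, model, th)
  expect_gte(sol$coverage, 0.98)
  expect_lte(sum(sol$x), 1 + 1e-8)
  g <- glance(sol)
  expect_equal(g$total_power, sum(sol$x))
  expect_equal(nrow(tidy(sol)), nrow(plan))
})
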