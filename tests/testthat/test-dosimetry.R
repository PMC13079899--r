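test_that("guardbanding scales OAR thresholds only", {
  th <- dose_thresholds(
    d_min = 2, d_max = c(grey = 1, white = 1.5),
    guardband = c(grey = 0.1, white = 0.1)
  )
  g <- apply_guardband(th)
  expect_equal(g$threshold[g$region == "grey"], 0.1)
  expect_equal(g$threshold[g$region == "white"], 0.15)
  expect_equal(g$threshold[g$region == "tumour"], 2) # tumour untouched
  # factor 1 leaves thresholds unchanged
  th1 <- apply_guardband(dose_thresholds(
    d_min = 2, d_max = c(grey = 1),
    guardband = c(grey = 1)
  ))
  expect_equal(th1$threshold, th1$nominal)
  expect_error(
    dose_thresholds(guardband = c(grey = 0, white = 0.1)),
    "guardband"
  )
  expect_error(
    dose_thresholds(guardband = c(grey = 1.2, white = 0.1)),
    "guardband"
  )
})

test_that("v100 reproduces the printed toy element set and boundary rule", {
  model <- fake_model(
    region = c("tumour", "tumour", "tumour"),
    volume = c(1, 2, 3)
  )
  th <- toy_thresholds(d_min = 1)
  out <- v100(c(2.0, 0.5, 1.5), model, th)
  expect_equal(out$v100[out$tissue == "tumour"], 100 * 4 / 6, tolerance = 1e-9)
  # zero field: nothing treated
  z <- v100(c(0, 0, 0), model, th)
  expect_equal(z$v100[z$tissue == "tumour"], 0)
  # exactly at threshold counts (>= comparator)
  b <- v100(c(1, 1, 1), model, th)
  expect_equal(b$v100[b$tissue == "tumour"], 100)
})

test_that("OAR v100 is an absolute volume and empty tumours are rejected", {
  model <- fake_model(
    region = c("tumour", "grey", "grey", "white"),
    volume = c(2, 3, 4, 5)
  )
  th <- toy_thresholds(d_min = 1, d_max = 1)
  out <- v100(c(1, 1.2, 0.8, 2), model, th)
  expect_equal(out$v100[out$tissue == "grey"], 3)
  expect_equal(out$v100[out$tissue == "white"], 5)
  expect_equal(out$unit[out$tissue == "white"], "mm^3")
  oar_free <- fake_model(region = c("grey"), volume = 1)
  expect_error(v100(1, oar_free, th), "tumour")
})

test_that("spread metrics follow the max-minus-min definition", {
  mk <- function(v) {
    structure(
      tibble::tibble(tissue = "tumour", role = "tumour", v100 = v, unit = "%"),
      class = c("outcome_summary", class(tibble::tibble()))
    )
  }
  sp <- spread_metrics(mk(68.3), mk(62.4), mk(65.6))
  expect_equal(sp$dv100, 5.9, tolerance = 1e-9)
  expect_equal(sp$dv100_pct, 100 * 5.9 / 65.6, tolerance = 1e-9)
  same <- spread_metrics(mk(50), mk(50), mk(50))
  expect_equal(same$dv100, 0)
  expect_equal(same$dv100_pct, 0)
  zero <- spread_metrics(mk(1), mk(0.5), mk(0))
  expect_true(is.na(zero$dv100_pct))
})

test_that("geometric mean is exact on closed forms and bounded by the arithmetic mean", {
  expect_equal(geometric_mean(7), 7)
  expect_equal(geometric_mean(c(2, 8)), 4, tolerance = 1e-12)
  expect_error(geometric_mean(c(1, 0)), "positive")
  set.seed(11)
  for (i in 1:50) {
    v <- rexp(sample(2:10, 1)) + 0.01
    expect_lte(geometric_mean(v), mean(v) + 1e-12)
  }
})

test_that("paired t-test matches the closed-form statistic and handles ties", {
  a <- c(98.0, 97.5, 96.8, 98.4)
  b <- c(97.2, 97.9, 96.1, 97.6)
  res <- paired_ttest(a, b)
  # frozen from the closed form t = mean(d) / (sd(d) / sqrt(n)), df = 3
  expect_equal(res$statistic, 1.6232795497, tolerance = 1e-8)
  expect_equal(res$p_value, 0.2029887952, tolerance = 1e-8)
  expect_false(res$significant)
  eq <- paired_ttest(a, a)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(paired_ttest(a, a + 1), "degenerate")
  nine <- paired_ttest(rnorm(9) + 1:9, rnorm(9) + 1:9) # nine tumour models
  expect_true(is.finite(nine$p_value))
})

test_that("v100 never decreases when all powers scale up, and is order-invariant", {
  set.seed(21)
  model <- fake_model(
    region = sample(c("tumour", "grey", "white"), 40, replace = TRUE,
      prob = c(0.5, 0.25, 0.25)
    ),
    volume = runif(40, 0.5, 2)
  )
  th <- toy_thresholds(d_min = 1, d_max = 0.8)
  for (i in 1:20) {
    phi <- rexp(40)
    up <- v100(phi * 1.3, model, th)
    base <- v100(phi, model, th)
    expect_true(all(up$v100 >= base$v100 - 1e-12))
    # permutation invariance
    p <- sample(40)
    pm <- fake_model(model$elements$region[p], model$elements$volume[p])
    expect_equal(
      dplyr::arrange(as.data.frame(v100(phi[p], pm, th)), tissue)$v100,
      dplyr::arrange(as.data.frame(base), tissue)$v100,
      tolerance = 1e-12
    )
  }
  # splitting an element into equal-volume halves at equal fluence
  m2 <- fake_model(
    region = rep(model$elements$region, each = 2),
    volume = rep(model$elements$volume, each = 2) / 2
  )
  phi <- rexp(40)
  expect_equal(
    v100(rep(phi, each = 2), m2, th)$v100,
    v100(phi, model, th)$v100,
    tolerance = 1e-12
  )
})
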