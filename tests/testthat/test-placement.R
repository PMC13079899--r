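test_that("Metropolis acceptance follows exp(-dcost/T)", {
  expect_true(accept_move(-1, 1e-9)) # improvements always accepted
  expect_true(accept_move(0, 0.5))
  expect_false(accept_move(1, 1e-12, u = 1e-6)) # T -> 0: frozen
  # deterministic check against the closed form via the supplied deviate
  expect_true(accept_move(1, 1, u = exp(-1) - 1e-6))
  expect_false(accept_move(1, 1, u = exp(-1) + 1e-6))
  # empirical frequency over 1e5 draws matches exp(-1)
  set.seed(33)
  acc <- mean(vapply(1:1e5, function(i) accept_move(1, 1), logical(1)))
  expect_lt(abs(acc - exp(-1)), 0.01)
})

test_that("proposals modify one source and keep lengths in the allowed set", {
  model <- small_model()
  plan <- heuristic_placement(model)
  moves <- move_set()
  set.seed(14)
  for (i in 1:50) {
    prop <- propose_move(plan, moves)
    changed <- vapply(seq_len(nrow(plan)), function(j) {
      !isTRUE(all.equal(as.data.frame(plan[j, ]), as.data.frame(prop[j, ])))
    }, logical(1))
    expect_lte(sum(changed), 1)
    lines <- prop$kind == "line"
    expect_true(all(prop$length[lines] %in% moves$lengths))
    expect_true(all(prop$length[!lines] == 0))
  }
  # zero step sizes with only translation moves leave the plan unchanged
  frozen <- move_set(lateral_step = 0, depth_step = 0, length_move = FALSE)
  set.seed(1)
  expect_equal(
    as.data.frame(propose_move(plan, frozen)),
    as.data.frame(plan)
  )
  # seeded proposal streams are reproducible
  set.seed(99)
  p1 <- propose_move(plan, moves)
  set.seed(99)
  p2 <- propose_move(plan, moves)
  expect_identical(p1, p2)
})

test_that("placement validation rejects overlaps, protrusions and constraint misses", {
  model <- small_model()
  plan <- heuristic_placement(model)
  con <- make_injection_constraint(model, plan)
  expect_true(validate_placement(plan, model, con))
  # coincident duplicate source
  dup <- dplyr::bind_rows(plan, plan[1, ])
  dup$source <- seq_len(nrow(dup))
  expect_false(validate_placement(dup, model, con))
  # segment protruding outside the tumour
  out <- plan
  out$pz[1] <- out$pz[1] + 25
  out$dz[1] <- out$dz[1] + 25
  expect_false(validate_placement(out, model, con))
  # axis missing the injection disc
  tight <- con
  tight$radius <- 0.5
  tight$centre <- con$centre + c(25, 25, 0)
  expect_false(validate_placement(plan, model, tight))
})

test_that("segment-to-segment distance agrees with brute-force sampling", {
  set.seed(8)
  for (i in 1:25) {
    p1 <- runif(3, 0, 10); p2 <- runif(3, 0, 10)
    q1 <- runif(3, 0, 10); q2 <- runif(3, 0, 10)
    d <- ipdtplan:::segment_segment_distance(p1, p2, q1, q2)
    tt <- seq(0, 1, length.out = 60)
    a <- t(sapply(tt, function(s) p1 + s * (p2 - p1)))
    b <- t(sapply(tt, function(s) q1 + s * (q2 - q1)))
    brute <- min(as.matrix(stats::dist(rbind(a, b)))[1:60, 61:120])
    expect_lte(d, brute + 1e-9)
    expect_gt(d, brute - 0.05) # sampling resolution slack
  }
})

test_that("zero-move annealing returns the initial plan with LP-optimal powers", {
  model <- tiny_model()
  plan <- heuristic_placement(model, add_points = FALSE)
  con <- make_injection_constraint(model, plan)
  th <- apply_guardband(dose_thresholds())
  res <- sa_optimize(model, plan, con, th,
    seed = 3, max_moves = 0,
    coverage_target = NULL
  )
  expect_equal(
    as.data.frame(res$plan[, c("px", "py", "pz", "dx", "dy", "dz")]),
    as.data.frame(plan[, c("px", "py", "pz", "dx", "dy", "dz")])
  )
  expect_equal(res$plan$power, res$solution$x)
  expect_equal(res$best_cost, res$initial_cost)
})

test_that("short annealing runs keep best-so-far monotone and plans valid", {
  model <- tiny_model()
  plan <- heuristic_placement(model, add_points = FALSE)
  con <- make_injection_constraint(model, plan)
  th <- apply_guardband(dose_thresholds())
  res <- sa_optimize(model, plan, con, th,
    seed = 11, max_moves = 25,
    schedule = sa_schedule(moves_per_stage_per_source = 5, max_stages = 3),
    coverage_target = NULL
  )
  expect_lte(res$best_cost, res$initial_cost + 1e-12)
  expect_true(all(diff(res$trace$best_cost) <= 1e-12))
  expect_true(validate_placement(res$plan, model, con))
  expect_equal(nrow(res$plan), nrow(plan)) # source count preserved
  expect_true(all(res$trace$temperature > 0))
})
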