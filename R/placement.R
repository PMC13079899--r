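#' Simulated-annealing move set
#'
#' Perturbation moves for source placement optimization. Each proposal
#' modifies exactly one source by one enabled move type: a lateral
#' translation of the whole source perpendicular to its axis, a change of
#' insertion depth along the axis, a change of emission length within the
#' allowed 5 mm-increment set, or a point/line toggle (off by default so
#' the source-type mix is preserved).
#'
#' @param lateral_step,depth_step Maximum displacement per move, mm.
#' @param length_move Enable emission-length moves?
#' @param toggle_move Enable point/line toggles?
#' @param lengths Allowed diffuser lengths, mm.
#' @return A `move_set` list.
#' @export
move_set <- function(lateral_step = 2, depth_step = 2, length_move = TRUE,
                     toggle_move = FALSE, lengths = seq(5, 40, by = 5)) {
  stopifnot(lateral_step >= 0, depth_step >= 0)
  enabled <- c(
    lateral = TRUE, depth = TRUE,
    length = isTRUE(length_move), toggle = isTRUE(toggle_move)
  )
  if (!any(enabled)) abort("at least one move type must be enabled")
  structure(
    list(
      lateral_step = lateral_step, depth_step = depth_step,
      enabled = enabled, lengths = sort(lengths)
    ),
    class = "move_set"
  )
}

#' Annealing schedule
#'
#' Geometric cooling: the initial temperature is `t0_frac` times the
#' absolute initial cost (floored at `t0_floor`), multiplied by `cool`
#' after every `moves_per_stage_per_source x n_sources` proposals, and the
#' search terminates when T drops below `term_frac x T0` or after
#' `patience` consecutive stages without best-cost improvement.
#'
#' @param t0_frac Initial temperature as a fraction of |initial cost|.
#' @param t0_floor Temperature floor for zero-cost starts.
#' @param cool Geometric cooling factor in (0, 1).
#' @param moves_per_stage_per_source Proposals per stage per source.
#' @param term_frac Terminal temperature as a fraction of T0.
#' @param patience Stages without improvement before stopping.
#' @param max_stages Hard cap on stages.
#' @return An `sa_schedule` list.
#' @export
sa_schedule <- function(t0_frac = 0.2, t0_floor = 1e-9, cool = 0.95,
                        moves_per_stage_per_source = 20, term_frac = 1e-3,
                        patience = 10, max_stages = 200) {
  stopifnot(t0_frac > 0, cool > 0, cool < 1, term_frac > 0, patience >= 1)
  structure(
    list(
      t0_frac = t0_frac, t0_floor = t0_floor, cool = cool,
      moves_per_stage_per_source = moves_per_stage_per_source,
      term_frac = term_frac, patience = patience, max_stages = max_stages
    ),
    class = "sa_schedule"
  )
}

#' Validate a source placement
#'
#' A placement is valid when (1) every pair of sources keeps at least the
#' minimum clearance (segment-to-segment distance), (2) every emitting
#' segment lies inside the tumour region (checked at points sampled along
#' the segment), and (3) every line-source axis extension passes through
#' the injection constraint disc.
#'
#' @param plan A `pdt_plan`.
#' @param model A `tissue_model`.
#' @param constraint An [make_injection_constraint()] result.
#' @param min_clearance Minimum pairwise source clearance, mm.
#' @param sample_step Spacing of the inside-tumour probe points, mm.
#' @return `TRUE` or `FALSE`.
#' @export
validate_placement <- function(plan, model, constraint, min_clearance = 2,
                               sample_step = 1) {
  plan <- as_plan(plan)
  n <- nrow(plan)
  seg <- lapply(seq_len(n), function(i) {
    list(
      a = c(plan$px[i], plan$py[i], plan$pz[i]),
      b = c(plan$dx[i], plan$dy[i], plan$dz[i])
    )
  })
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (segment_segment_distance(seg[[i]]$a, seg[[i]]$b, seg[[j]]$a, seg[[j]]$b) <
          min_clearance) {
          return(FALSE)
        }
      }
    }
  }
  for (i in seq_len(n)) {
    pts <- segment_samples(seg[[i]]$a, seg[[i]]$b, sample_step)
    if (any(region_at(model, pts) != "tumour")) {
      return(FALSE)
    }
  }
  inj <- tryCatch(injection_points(plan, constraint), error = function(e) NULL)
  if (is.null(inj) || !all(inj$inside)) {
    return(FALSE)
  }
  TRUE
}

segment_samples <- function(a, b, step = 1) {
  len <- sqrt(sum((b - a)^2))
  if (len < 1e-12) {
    return(matrix(a, 1, 3))
  }
  tt <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
  cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]), a[3] + tt * (b[3] - a[3]))
}

# minimum distance between segments [p1,p2] and [q1,q2]
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-18 && e < 1e-18) {
    return(sqrt(sum(r^2)))
  }
  if (a < 1e-18) {
    s <- 0
    t <- min(1, max(0, f / e))
  } else {
    c0 <- sum(d1 * r)
    if (e < 1e-18) {
      t <- 0
      s <- min(1, max(0, -c0 / a))
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-18) min(1, max(0, (b * f - c0 * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0
        s <- min(1, max(0, -c0 / a))
      } else if (t > 1) {
        t <- 1
        s <- min(1, max(0, (b - c0) / a))
      }
    }
  }
  sqrt(sum((p1 + s * d1 - (q1 + t * d2))^2))
}

#' Metropolis acceptance rule
#'
#' Improving moves (`dcost <= 0`) are always accepted; worsening moves are
#' accepted with probability `exp(-dcost / temperature)`.
#'
#' @param dcost Cost difference (proposed minus current).
#' @param temperature Current annealing temperature (> 0).
#' @param u Optional uniform deviate (drawn from the session RNG when
#'   omitted).
#' @return `TRUE` to accept.
#' @export
accept_move <- function(dcost, temperature, u = runif(1)) {
  stopifnot(temperature > 0)
  if (dcost <= 0) {
    return(TRUE)
  }
  u < exp(-dcost / temperature)
}

#' Propose a placement perturbation
#'
#' Modifies exactly one source (chosen uniformly) by one enabled move type
#' (chosen uniformly). Lateral and depth displacements are uniform in
#' `[-step, step]` per component; length moves step one 5 mm increment up
#' or down within the allowed set, resizing about the segment centre.
#' Invalid proposals are handled downstream by [validate_placement()].
#'
#' @param plan A `pdt_plan`.
#' @param moves A [move_set()].
#' @return The perturbed `pdt_plan`.
#' @export
propose_move <- function(plan, moves) {
  plan <- as_plan(plan)
  i <- sample.int(nrow(plan), 1)
  types <- names(moves$enabled)[moves$enabled]
  type <- types[sample.int(length(types), 1)]
  src <- plan[i, ]
  axis <- c(src$dx - src$px, src$dy - src$py, src$dz - src$pz)
  if (sqrt(sum(axis^2)) < 1e-12) axis <- c(0, 0, -1)
  u <- axis / sqrt(sum(axis^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(u, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  if (type == "lateral") {
    d <- runif(2, -moves$lateral_step, moves$lateral_step)
    shift <- d[1] * e1 + d[2] * e2
  } else if (type == "depth") {
    shift <- runif(1, -moves$depth_step, moves$depth_step) * u
  } else {
    shift <- c(0, 0, 0)
  }
  if (type %in% c("lateral", "depth")) {
    src$px <- src$px + shift[1]; src$py <- src$py + shift[2]; src$pz <- src$pz + shift[3]
    src$dx <- src$dx + shift[1]; src$dy <- src$dy + shift[2]; src$dz <- src$dz + shift[3]
  } else if (type == "length" && src$kind == "line") {
    pos <- match(src$length, moves$lengths)
    if (!is.na(pos)) {
      cand <- c(pos - 1, pos + 1)
      cand <- cand[cand >= 1 & cand <= length(moves$lengths)]
      if (length(cand)) {
        newlen <- moves$lengths[cand[sample.int(length(cand), 1)]]
        mid <- c(src$px + src$dx, src$py + src$dy, src$pz + src$dz) / 2
        src$px <- mid[1] + newlen / 2 * (-u[1]); src$dx <- mid[1] + newlen / 2 * u[1]
        src$py <- mid[2] + newlen / 2 * (-u[2]); src$dy <- mid[2] + newlen / 2 * u[2]
        src$pz <- mid[3] + newlen / 2 * (-u[3]); src$dz <- mid[3] + newlen / 2 * u[3]
        src$length <- newlen
      }
    }
  } else if (type == "toggle") {
    if (src$kind == "line") {
      mid <- c(src$px + src$dx, src$py + src$dy, src$pz + src$dz) / 2
      src$kind <- "point"; src$length <- 0
      src$px <- mid[1]; src$py <- mid[2]; src$pz <- mid[3]
      src$dx <- mid[1]; src$dy <- mid[2]; src$dz <- mid[3]
    } else {
      len <- moves$lengths[1]
      ctr <- c(src$dx, src$dy, src$dz)
      src$kind <- "line"; src$length <- len
      src$px <- ctr[1]; src$py <- ctr[2]; src$pz <- ctr[3] + len / 2
      src$dx <- ctr[1]; src$dy <- ctr[2]; src$dz <- ctr[3] - len / 2
    }
  }
  plan[i, ] <- src
  plan
}

#' Simulated-annealing source placement optimization
#'
#' Optimizes source locations with the LP power optimizer as the inner
#' cost evaluator, repeating: validate the placement (overlap, tumour
#' containment, injection constraint); LP-optimize the powers and evaluate
#' the cost; Metropolis-accept or reject; perturb with a random move.
#' The temperature follows the [sa_schedule()] geometric cooling. The
#' source count and injection constraint are identical between input and
#' output; the returned plan is the best valid placement seen, with its
#' LP-optimal powers filled in.
#'
#' @param model A `tissue_model`.
#' @param init_plan A valid initial `pdt_plan`.
#' @param constraint An [make_injection_constraint()] result.
#' @param thresholds A guardbanded [dose_thresholds()] tibble.
#' @param constraints A [power_constraints()] object.
#' @param schedule An [sa_schedule()].
#' @param moves A [move_set()].
#' @param seed RNG seed.
#' @param min_clearance Minimum inter-source clearance, mm.
#' @param engine,medium,duration Dose-matrix settings for the inner
#'   evaluations (analytic engine strongly recommended).
#' @param max_moves Optional hard cap on total proposals (testing aid).
#' @param ... Forwarded to [optimize_power()].
#' @return An `sa_result`: list with `plan` (best, powers filled),
#'   `solution` (its `power_solution`), `initial_cost`, `best_cost`,
#'   `trace` (tibble: iteration, stage, temperature, proposed cost,
#'   accepted, best cost).
#' @export
sa_optimize <- function(model, init_plan, constraint, thresholds,
                        constraints = NULL, schedule = sa_schedule(),
                        moves = move_set(), seed = 1L, min_clearance = 2,
                        engine = "analytic", medium = "tumour", duration = 1,
                        max_moves = Inf, ...) {
  plan <- as_plan(init_plan)
  if (!validate_placement(plan, model, constraint, min_clearance)) {
    abort("initial placement is invalid")
  }
  evaluate <- function(p) {
    dose <- build_dose_matrix(model, p,
      engine = engine, medium = medium,
      duration = duration
    )
    sol <- optimize_power(dose, model, thresholds, constraints = constraints, ...)
    list(cost = sol$cost, solution = sol)
  }
  set.seed(seed)
  cur <- evaluate(plan)
  init_cost <- cur$cost
  best_plan <- plan
  best <- cur
  if (max_moves < 1) {
    out_plan <- best_plan
    out_plan$power <- best$solution$x
    return(structure(
      list(
        plan = out_plan, solution = best$solution,
        initial_cost = init_cost, best_cost = best$cost,
        trace = tibble::tibble(
          iteration = integer(), stage = integer(), temperature = numeric(),
          valid = logical(), cost = numeric(), accepted = logical(),
          best_cost = numeric()
        )
      ),
      class = "sa_result"
    ))
  }
  t0 <- max(schedule$t0_frac * abs(cur$cost), schedule$t0_floor)
  temp <- t0
  k <- nrow(plan)
  per_stage <- schedule$moves_per_stage_per_source * k
  trace <- list()
  it <- 0L
  stagnant <- 0L
  for (stage in seq_len(schedule$max_stages)) {
    improved <- FALSE
    for (m in seq_len(per_stage)) {
      it <- it + 1L
      if (it > max_moves) break
      prop <- propose_move(plan, moves)
      ok <- validate_placement(prop, model, constraint, min_clearance)
      acc <- FALSE
      pcost <- NA_real_
      if (ok) {
        ev <- tryCatch(evaluate(prop), error = function(e) NULL)
        if (!is.null(ev)) {
          pcost <- ev$cost
          if (accept_move(pcost - cur$cost, temp)) {
            plan <- prop
            cur <- ev
            acc <- TRUE
            if (cur$cost < best$cost) {
              best <- cur
              best_plan <- plan
              improved <- TRUE
            }
          }
        }
      }
      trace[[it]] <- tibble::tibble(
        iteration = it, stage = stage, temperature = temp,
        valid = ok, cost = pcost, accepted = acc, best_cost = best$cost
      )
    }
    stagnant <- if (improved) 0L else stagnant + 1L
    temp <- temp * schedule$cool
    if (temp < schedule$term_frac * t0 || stagnant >= schedule$patience ||
      it > max_moves) {
      break
    }
  }
  out_plan <- best_plan
  out_plan$power <- best$solution$x
  structure(
    list(
      plan = out_plan, solution = best$solution,
      initial_cost = init_cost, best_cost = best$cost,
      trace = dplyr::bind_rows(trace)
    ),
    class = "sa_result"
  )
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf(
    "<sa_result> %d proposals, cost %.6g -> %.6g (%.1f%% reduction)\n",
    nrow(x$trace), x$initial_cost, x$best_cost,
    100 * (1 - x$best_cost / max(x$initial_cost, .Machine$double.eps))
  ))
  invisible(x)
}
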