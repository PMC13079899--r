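#' Clinician power constraints
#'
#' Linear constraints `A x <= p_max` on the source power vector. The
#' default is the single aggregate-power row enforcing a total of at most
#' 1 W across all sources, the standard cap against tissue overheating.
#' The constraint set (with `x >= 0`) must bound every power from above.
#'
#' @param n_sources Number of sources.
#' @param A Optional constraint matrix (rows = constraints).
#' @param p_max Right-hand side, W; all entries must be positive.
#' @param total_power Total-power cap used by the default row, W.
#' @return A `power_constraints` object.
#' @export
power_constraints <- function(n_sources, A = NULL, p_max = NULL, total_power = 1) {
  if (is.null(A)) {
    A <- matrix(1, 1, n_sources)
    p_max <- total_power
  }
  A <- as.matrix(A)
  stopifnot(ncol(A) == n_sources, length(p_max) == nrow(A))
  if (any(p_max <= 0)) abort("all p_max entries must be positive")
  structure(list(A = A, p_max = as.numeric(p_max), n_sources = n_sources),
    class = "power_constraints"
  )
}

# minimize a'z subject to A1 z <= b1, A2 z >= b2, z >= 0.
# boot::simplex silently returns wrong answers for negative right-hand
# sides, so rows are sign-normalized first.
solve_lp <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL, eps = 1e-10) {
  M <- rbind(A1, A2)
  rhs <- c(b1, b2)
  dir <- c(rep(1, length(b1)), rep(-1, length(b2))) # 1: <=, -1: >=
  flip <- rhs < 0
  if (any(flip)) {
    M[flip, ] <- -M[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- -dir[flip]
  }
  le <- dir > 0
  res <- tryCatch(
    boot::simplex(
      a = a,
      A1 = if (any(le)) M[le, , drop = FALSE] else NULL,
      b1 = if (any(le)) rhs[le] else NULL,
      A2 = if (any(!le)) M[!le, , drop = FALSE] else NULL,
      b2 = if (any(!le)) rhs[!le] else NULL,
      maxi = FALSE, eps = eps, n.iter = max(200, 20 * (length(a) + length(rhs)))
    ),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(solution = NULL, value = NA_real_, solved = -2L))
  }
  list(solution = unname(res$soln), value = res$value, solved = res$solved)
}

# precompute the LP data: tumour/OAR rows of G, weights*volumes,
# thresholds; OAR elements that can never be over-dosed under the power
# constraints are dropped exactly (their cost term is identically zero)
lp_data <- function(dose, model, thresholds, constraints, max_scale = 1) {
  G <- dose$G
  ed <- element_dosimetry(model, thresholds)
  ti <- which(ed$role == "tumour")
  oi <- which(ed$role == "oar")
  # valid upper bound on any achievable g.x: row max times total-power bound
  A <- constraints$A
  p <- constraints$p_max
  ub_j <- rep(Inf, ncol(G))
  for (j in seq_len(ncol(G))) {
    rows <- which(A[, j] > 0)
    if (length(rows)) ub_j[j] <- min(p[rows] / A[rows, j])
  }
  tot_rows <- which(apply(A, 1, function(r) all(r > 0)))
  p_total <- if (length(tot_rows)) {
    min(p[tot_rows] / apply(A[tot_rows, , drop = FALSE], 1, min))
  } else {
    sum(ub_j)
  }
  if (length(oi)) {
    bound <- apply(G[oi, , drop = FALSE], 1, max) * p_total * max_scale
    oi <- oi[bound >= ed$threshold[oi]]
  }
  list(
    Gt = G[ti, , drop = FALSE], ct = ed$weight[ti] * ed$volume[ti],
    dmin = ed$threshold[ti],
    Go = G[oi, , drop = FALSE], co = ed$weight[oi] * ed$volume[oi],
    dmax = ed$threshold[oi],
    tumour_volume = sum(ed$volume[ti]), tumour_vol_i = ed$volume[ti],
    idx_tumour = ti, idx_oar = oi
  )
}

lp_cost_value <- function(ld, x, scales) {
  f <- 0
  for (s in scales) {
    dt <- as.vector(ld$Gt %*% (s * x))
    f <- f + sum(ld$ct * pmax(0, ld$dmin - dt))
    if (length(ld$dmax)) {
      do <- as.vector(ld$Go %*% (s * x))
      f <- f + sum(ld$co * pmax(0, do - ld$dmax))
    }
  }
  f
}

lp_cost_subgrad <- function(ld, x, scales) {
  g <- numeric(length(x))
  for (s in scales) {
    dt <- as.vector(ld$Gt %*% (s * x))
    under <- dt < ld$dmin
    if (any(under)) {
      g <- g - s * colSums(ld$Gt[under, , drop = FALSE] * ld$ct[under])
    }
    if (length(ld$dmax)) {
      do <- as.vector(ld$Go %*% (s * x))
      over <- do > ld$dmax
      if (any(over)) {
        g <- g + s * colSums(ld$Go[over, , drop = FALSE] * ld$co[over])
      }
    }
  }
  g
}

mode_scales <- function(mode, eta) {
  switch(mode,
    nominal = 1,
    max_min = c(1 + eta, 1 - eta),
    min_only = 1 - eta
  )
}

#' Piecewise-linear dose cost
#'
#' The planning objective: each under-dosed tumour element i contributes
#' `w_i t_i (d_min_i - g_i . x)`, each over-dosed OAR element contributes
#' `w_i t_i (g_i . x - d_max_i)`, all other elements contribute zero; the
#' total cost is the sum over elements. Uncertainty-aware variants evaluate
#' the same cost at scaled powers: `max_min` sums the costs at
#' `x (1 + eta)` and `x (1 - eta)`; `min_only` evaluates at `x (1 - eta)`
#' alone.
#'
#' @param x Source power vector, W.
#' @param dose A [build_dose_matrix()] result.
#' @param model A `tissue_model`.
#' @param thresholds A (guardbanded) [dose_thresholds()] tibble.
#' @param mode `"nominal"`, `"max_min"` or `"min_only"`.
#' @param eta Relative power uncertainty in `[0, 1)`; ignored for
#'   `"nominal"`.
#' @return A `cost_breakdown`: list with total `f`, per-element `f_i`
#'   (summed over power extremes, aligned with `model$elements`), `mode`,
#'   `eta`.
#' @export
cost <- function(x, dose, model, thresholds, mode = c("nominal", "max_min", "min_only"),
                 eta = 0) {
  mode <- match.arg(mode)
  ed <- element_dosimetry(model, thresholds)
  scales <- mode_scales(mode, eta)
  f_i <- numeric(nrow(ed))
  G <- dose$G
  tum <- ed$role == "tumour"
  oar <- ed$role == "oar"
  for (s in scales) {
    phi <- as.vector(G %*% (s * x))
    f_i[tum] <- f_i[tum] + ed$weight[tum] * ed$volume[tum] *
      pmax(0, ed$threshold[tum] - phi[tum])
    f_i[oar] <- f_i[oar] + ed$weight[oar] * ed$volume[oar] *
      pmax(0, phi[oar] - ed$threshold[oar])
  }
  structure(list(f = sum(f_i), f_i = f_i, mode = mode, eta = eta),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> f = %.6g (%s%s), %d contributing elements\n",
    x$f, x$mode, if (x$mode == "nominal") "" else sprintf(", eta=%g", x$eta),
    sum(x$f_i > 0)
  ))
  invisible(x)
}

#' Optimize source powers by linear programming
#'
#' Minimizes the piecewise-linear convex dose cost (see [cost()]) over the
#' power polytope `A x <= p_max, x >= 0`. The epigraph linear program (one
#' slack per element and power extreme) is solved by Kelley cutting planes:
#' master LPs in the source powers plus one epigraph variable are solved
#' with the simplex method, each cut being a subgradient plane of the exact
#' cost; for a piecewise-linear objective this terminates at the LP optimum
#' (gap below `tol`).
#'
#' An optional outer loop escalates the tumour element weights
#' geometrically (factor `coverage_factor`, at most `coverage_max_iter`
#' rounds) until nominal tumour coverage reaches `coverage_target`,
#' mirroring planning practice of constraining tumour v100 at 98%. Set
#' `coverage_target = NULL` to disable.
#'
#' @inheritParams cost
#' @param constraints A [power_constraints()] object (default: total power
#'   at most 1 W).
#' @param coverage_target Tumour v100 target as a fraction (default 0.98).
#' @param coverage_factor,coverage_max_iter Weight-escalation controls.
#' @param tol Relative optimality gap for termination.
#' @param max_iter Maximum cutting-plane iterations per solve.
#' @return A `power_solution`: list with `x` (W), `status`, `cost`,
#'   `mode`, `eta`, `iterations`, `lower_bound`, `coverage` (tumour v100
#'   fraction at nominal powers), `weight_scale`.
#' @export
optimize_power <- function(dose, model, thresholds,
                           constraints = NULL,
                           mode = c("nominal", "max_min", "min_only"), eta = 0,
                           coverage_target = 0.98, coverage_factor = 2,
                           coverage_max_iter = 20,
                           tol = 1e-9, max_iter = 400) {
  mode <- match.arg(mode)
  if (eta < 0 || eta >= 1) abort("eta must lie in [0, 1)")
  k <- ncol(dose$G)
  constraints <- constraints %||% power_constraints(k)
  scales <- mode_scales(mode, eta)
  ld <- lp_data(dose, model, thresholds, constraints, max_scale = max(scales))

  wscale <- 1
  rounds <- 0
  repeat {
    sol <- cutting_plane_solve(ld, scales, constraints, tol, max_iter)
    cov <- sum(ld$tumour_vol_i[as.vector(ld$Gt %*% sol$x) >= ld$dmin]) /
      ld$tumour_volume
    rounds <- rounds + 1
    if (is.null(coverage_target) || cov >= coverage_target ||
      rounds >= coverage_max_iter) {
      break
    }
    wscale <- wscale * coverage_factor
    ld$ct <- ld$ct * coverage_factor
  }

  structure(
    list(
      x = sol$x, status = sol$status, cost = sol$f, mode = mode, eta = eta,
      iterations = sol$iterations, lower_bound = sol$lb,
      coverage = cov, weight_scale = wscale, constraints = constraints
    ),
    class = "power_solution"
  )
}

# Level-bundle solver for the epigraph LP: cutting planes give a simplex
# lower bound; the next iterate is the projection of the incumbent onto the
# level set {cutting-plane model <= lb + level_frac (ub - lb)}, a small
# strictly convex QP. The level stabilization removes Kelley zigzagging
# while keeping exact LP bounds on both sides of the gap.
cutting_plane_solve <- function(ld, scales, constraints, tol, max_iter,
                                max_cuts = 150, level_frac = 0.3) {
  k <- ncol(ld$Gt)
  A <- constraints$A
  p <- constraints$p_max
  x <- rep(0, k)
  cut_g <- matrix(0, 0, k)
  cut_c <- numeric(0) # model: fhat(x) = max_t cut_g[t, ] . x + cut_c[t]
  ub <- Inf
  lb <- 0 # the cost is non-negative by construction
  xbest <- x
  status <- "max_iterations"
  it <- 0
  for (it in seq_len(max_iter)) {
    f <- lp_cost_value(ld, x, scales)
    g <- lp_cost_subgrad(ld, x, scales)
    if (f < ub) {
      ub <- f
      xbest <- x
    }
    cut_g <- rbind(cut_g, g)
    cut_c <- c(cut_c, f - sum(g * x))
    if (nrow(cut_g) > max_cuts) {
      keep <- seq.int(nrow(cut_g) - max_cuts + 1, nrow(cut_g))
      cut_g <- cut_g[keep, , drop = FALSE]
      cut_c <- cut_c[keep]
    }
    # lower bound: minimize tau st A x <= p, cut_g x - tau <= -cut_c, x >= 0.
    # Cut rows are normalized for tableau conditioning (row scaling leaves
    # the LP unchanged); on a simplex failure the oldest cuts are dropped
    # and the master retried once.
    master <- function(gm, cm) {
      s <- pmax(apply(abs(gm), 1, max), abs(cm), 1)
      solve_lp(
        a = c(rep(0, k), 1),
        A1 = rbind(cbind(A, 0), cbind(gm / s, -1 / s)),
        b1 = c(p, -cm / s)
      )
    }
    r <- master(cut_g, cut_c)
    if (r$solved != 1 && nrow(cut_g) > 4) {
      keep <- seq.int(max(1, nrow(cut_g) - 20), nrow(cut_g))
      cut_g <- cut_g[keep, , drop = FALSE]
      cut_c <- cut_c[keep]
      r <- master(cut_g, cut_c)
    }
    if (r$solved != 1) {
      status <- "master_lp_failed"
      break
    }
    lb <- max(lb, r$solution[k + 1])
    if (ub - lb <= tol * max(1, abs(ub))) {
      status <- "optimal"
      break
    }
    level <- lb + level_frac * (ub - lb)
    # project the incumbent onto the level set (strictly convex QP);
    # constraint rows normalized as above
    sc <- pmax(apply(abs(cut_g), 1, max), abs(cut_c), 1)
    Amat <- t(rbind(diag(k), -A, -cut_g / sc))
    bvec <- c(rep(0, k), -p, (cut_c - level) / sc)
    qp <- tryCatch(
      quadprog::solve.QP(diag(k), xbest, Amat, bvec),
      error = function(e) NULL
    )
    x <- if (is.null(qp)) r$solution[seq_len(k)] else qp$solution
    x <- pmax(0, x)
  }
  list(
    x = pmax(0, xbest), f = ub, lb = lb, iterations = it, status = status
  )
}

#' @export
print.power_solution <- function(x, ...) {
  cat(sprintf(
    "<power_solution> %d sources, total %.4f W, cost %.6g (%s), %s after %d cuts\n",
    length(x$x), sum(x$x), x$cost, x$mode, x$status, x$iterations
  ))
  cat(sprintf(
    "  tumour coverage at nominal powers: %.2f%% (weight scale %g)\n",
    100 * x$coverage, x$weight_scale
  ))
  invisible(x)
}

#' @export
tidy.power_solution <- function(x, ...) {
  tibble::tibble(source = seq_along(x$x), power = x$x)
}

#' @export
glance.power_solution <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, total_power = sum(x$x), mode = x$mode, eta = x$eta,
    status = x$status, iterations = x$iterations,
    coverage = x$coverage, weight_scale = x$weight_scale
  )
}

#' Worst-case power bounds
#'
#' Element-wise bounds on delivered power under a relative uncertainty
#' `eta`: `x_max = x (1 + eta)`, `x_min = x (1 - eta)`. The study levels
#' are eta = 5%, 10% and 20%.
#'
#' @param x Nominal power vector, W.
#' @param eta Relative uncertainty in `[0, 1)`.
#' @return List with `x_max` and `x_min` vectors, W.
#' @export
worst_case_bounds <- function(x, eta) {
  if (eta < 0 || eta >= 1) abort("eta must lie in [0, 1)")
  if (any(x < 0)) abort("powers must be non-negative")
  list(x_max = x * (1 + eta), x_min = x * (1 - eta))
}
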