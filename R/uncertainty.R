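#' Uncertainty analysis configuration
#'
#' Settings for power and position uncertainty analysis. Defaults follow
#' clinical practice: power uncertainty levels of 5/10/20%, a maximum
#' distal-tip displacement of 3 mm (the conservative end of needle/catheter
#' placement tolerance), 8 principal deflection directions at 45 degrees,
#' 10 magnitude quantiles (0.05 to 0.95), a truncated-Gaussian magnitude
#' with `sigma = 3 / 1.96` mm so ~95% of draws fall within 3 mm before
#' truncation, and 10,000 outcome samples (1,000 when each sample requires
#' a power re-optimization).
#'
#' @param eta_levels Relative power uncertainty levels.
#' @param max_displacement Maximum distal-tip displacement d, mm.
#' @param n_directions Number of principal deflection directions (even).
#' @param quantiles Deflection-angle quantile fractions, strictly
#'   increasing in (0, 1).
#' @param sigma Gaussian magnitude standard deviation, mm.
#' @param n_samples Outcome samples for fixed-power analysis.
#' @param n_samples_reopt Outcome samples when re-optimizing power.
#' @param seed RNG seed for sampling.
#' @return An `uncertainty_config` list.
#' @export
uncertainty_config <- function(eta_levels = c(0.05, 0.10, 0.20),
                               max_displacement = 3,
                               n_directions = 8,
                               quantiles = seq(0.05, 0.95, by = 0.1),
                               sigma = 3 / 1.96,
                               n_samples = 10000, n_samples_reopt = 1000,
                               seed = 1L) {
  stopifnot(
    max_displacement > 0, n_directions %% 2 == 0, n_directions >= 2,
    all(diff(quantiles) > 0), all(quantiles > 0 & quantiles < 1),
    sigma > 0, n_samples >= 1, n_samples_reopt >= 1
  )
  structure(
    list(
      eta_levels = eta_levels, max_displacement = max_displacement,
      n_directions = n_directions, quantiles = quantiles, sigma = sigma,
      n_samples = n_samples, n_samples_reopt = n_samples_reopt, seed = seed
    ),
    class = "uncertainty_config"
  )
}

#' Worst-case deflection angle
#'
#' The maximum angular deviation of a source about its injection point is
#' set by the isosceles triangle whose two equal sides are the insertion
#' length L and whose base is the maximum tip displacement d:
#' `theta_max = 2 asin(d / (2 L))`, so that the chord
#' `2 L sin(theta_max / 2)` equals d exactly.
#'
#' @param insertion_length Injection point to distal tip distance L, mm.
#' @param d Maximum tip displacement, mm (default 3).
#' @return Angle in radians.
#' @export
deflection_angle_max <- function(insertion_length, d = 3) {
  if (d < 0) abort("displacement d must be non-negative")
  if (d == 0) return(0)
  if (any(insertion_length <= d / 2)) {
    abort("insertion length must exceed d / 2 for the deflection geometry")
  }
  2 * asin(d / (2 * insertion_length))
}

# Rodrigues rotation of vector v about unit axis k by angle a
rotate_about <- function(v, k, a) {
  v * cos(a) + cross3(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Principal deflection directions
#'
#' `n` equally spaced unit vectors (default 8, at 45-degree increments) in
#' the plane normal to the source axis, discretizing the possible angular
#' insertion errors. Dir1 is obtained from a seeded random vector
#' (projected into the plane and normalized); the rest follow by rotation
#' about the axis.
#'
#' @param axis Source axis (any non-zero length-3 vector).
#' @param seed RNG seed fixing Dir1.
#' @param n Number of directions.
#' @return An n-by-3 matrix of unit row vectors.
#' @export
principal_directions <- function(axis, seed = 1L, n = 8) {
  la <- sqrt(sum(axis^2))
  if (la <= 0) abort("source axis must be non-zero")
  u <- axis / la
  set.seed(seed)
  repeat {
    r <- rnorm(3)
    r <- r - sum(r * u) * u
    if (sqrt(sum(r^2)) > 1e-8) break
  }
  d1 <- r / sqrt(sum(r^2))
  t(vapply(
    seq_len(n) - 1,
    function(k) rotate_about(d1, u, 2 * pi * k / n),
    numeric(3)
  ))
}

#' Deflect a source about its injection point
#'
#' Rigid rotation of the source toward a principal direction by a given
#' angle, pivoting at the injection point. The insertion length (injection
#' point to distal tip) and the emission length are preserved exactly;
#' the distal tip moves by the chord `2 L sin(angle / 2)`.
#'
#' @param source One-row plan tibble.
#' @param injection Injection point, mm (length 3).
#' @param direction Unit deflection direction (perpendicular to the source
#'   axis, from [principal_directions()]).
#' @param angle Rotation angle, radians; must not exceed the worst-case
#'   angle for the source's insertion length (checked against
#'   `max_displacement`).
#' @param max_displacement Tip-displacement tolerance used for the angle
#'   check, mm; `NULL` skips the check.
#' @return The deflected one-row plan tibble.
#' @export
deflect_source <- function(source, injection, direction, angle,
                           max_displacement = 3) {
  source <- tibble::as_tibble(source)
  stopifnot(nrow(source) == 1)
  tip <- c(source$dx, source$dy, source$dz)
  L <- sqrt(sum((tip - injection)^2))
  if (L <= 0) abort("source tip coincides with the injection point")
  if (!is.null(max_displacement) && angle < 0) abort("angle must be non-negative")
  if (!is.null(max_displacement)) {
    tmax <- deflection_angle_max(L, max_displacement)
    if (angle > tmax + 1e-12) {
      abort("deflection angle exceeds the worst-case angle for this insertion length")
    }
  }
  if (angle == 0) return(source)
  u <- (tip - injection) / L # unit axis, injection -> tip
  d <- direction - sum(direction * u) * u
  dn <- sqrt(sum(d^2))
  if (dn < 1e-12) abort("deflection direction is parallel to the source axis")
  d <- d / dn
  rotaxis <- cross3(u, d) # rotating u toward d by `angle`
  rotaxis <- rotaxis / sqrt(sum(rotaxis^2))
  u2 <- rotate_about(u, rotaxis, angle)
  tip2 <- injection + L * u2
  out <- source
  out$dx <- tip2[1]; out$dy <- tip2[2]; out$dz <- tip2[3]
  if (source$kind == "line") {
    Lp <- sqrt(sum((c(source$px, source$py, source$pz) - injection)^2))
    p2 <- injection + Lp * u2
    out$px <- p2[1]; out$py <- p2[2]; out$pz <- p2[3]
  } else {
    out$px <- tip2[1]; out$py <- tip2[2]; out$pz <- tip2[3]
  }
  out
}

#' Discrete deflection configurations per source
#'
#' The configuration table sampled by the position-uncertainty protocol:
#' one nominal (undeflected) entry, one worst-case entry per principal
#' direction, and one entry per direction and angle quantile - with the
#' defaults, `1 + 8 + 8 x 10 = 89` forward simulations per source.
#'
#' @param cfg An [uncertainty_config()].
#' @return Tibble with `entry`, `magnitude` (fraction of the worst-case
#'   angle; `NA` for nominal, 1 for worst case), `direction` (1-based
#'   principal direction index), `kind`.
#' @export
deflection_configs <- function(cfg = uncertainty_config()) {
  nd <- cfg$n_directions
  q <- cfg$quantiles
  dplyr::bind_rows(
    tibble::tibble(
      entry = 1L, magnitude = NA_real_, direction = NA_integer_,
      kind = "nominal"
    ),
    tibble::tibble(
      entry = 1L + seq_len(nd), magnitude = 1, direction = seq_len(nd),
      kind = "worst"
    ),
    tidyr::expand_grid(direction = seq_len(nd), magnitude = q) |>
      dplyr::mutate(entry = 1L + nd + dplyr::row_number(), kind = "quantile") |>
      dplyr::select("entry", "magnitude", "direction", "kind")
  )
}

#' Per-source deflection fluence library
#'
#' For every source, precomputes the unit-power fluence column of each
#' discrete deflection configuration: the nominal (undeflected) geometry,
#' the worst-case angle in each of the 8 principal directions, and the 10
#' quantile angles (fractions 0.05 to 0.95 of the worst-case angle) in each
#' direction - `1 + 8 + 8 x 10 = 89` forward simulations per source.
#' Point sources pivot about the injection-disc centre (their injection
#' point is unobserved).
#'
#' @param model A `tissue_model`.
#' @param plan A `pdt_plan`.
#' @param constraint An [make_injection_constraint()] result.
#' @param cfg An [uncertainty_config()].
#' @param dose Optional `dose_matrix` for the same plan/engine; its columns
#'   are reused as the nominal entries.
#' @param engine,medium,duration,n_packets Forwarded to
#'   [build_dose_matrix()].
#' @return A `deflection_library`: list with `columns` (list of
#'   element-by-89 matrices per source), `configs` (tibble: `entry`,
#'   `magnitude` in \{"nominal","worst",quantile fraction\}, `direction`),
#'   `directions` (per-source 8-by-3 matrices), `injection`
#'   (per-source points), `angles` (per-source worst-case angles),
#'   `duration`.
#' @export
build_library <- function(model, plan, constraint, cfg = uncertainty_config(),
                          dose = NULL, engine = "analytic", medium = "tumour",
                          duration = 1, n_packets = 1e5) {
  plan <- as_plan(plan)
  inj <- injection_points(plan, constraint)
  nd <- cfg$n_directions
  configs <- deflection_configs(cfg)
  columns <- vector("list", nrow(plan))
  directions <- vector("list", nrow(plan))
  angles <- numeric(nrow(plan))
  for (j in seq_len(nrow(plan))) {
    src <- plan[j, ]
    pj <- c(inj$ix[j], inj$iy[j], inj$iz[j])
    axis <- c(src$dx, src$dy, src$dz) - pj
    L <- sqrt(sum(axis^2))
    th_max <- deflection_angle_max(L, cfg$max_displacement)
    dirs <- principal_directions(axis, seed = cfg$seed + j, n = nd)
    directions[[j]] <- dirs
    angles[j] <- th_max
    cols <- matrix(0, nrow(model$elements), nrow(configs))
    for (e in seq_len(nrow(configs))) {
      src_e <- if (configs$kind[e] == "nominal") {
        src
      } else {
        deflect_source(src, pj, dirs[configs$direction[e], ],
          configs$magnitude[e] * th_max,
          max_displacement = cfg$max_displacement
        )
      }
      if (configs$kind[e] == "nominal" && !is.null(dose)) {
        cols[, e] <- dose$G[, j]
      } else {
        d1 <- build_dose_matrix(model, new_plan(src_e),
          engine = engine,
          medium = medium, duration = duration, n_packets = n_packets,
          seed = cfg$seed + 100L * j + e
        )
        cols[, e] <- d1$G[, 1]
      }
    }
    columns[[j]] <- cols
  }
  structure(
    list(
      columns = columns, configs = configs, directions = directions,
      injection = inj, angles = angles, duration = duration,
      cfg = cfg, plan = plan
    ),
    class = "deflection_library"
  )
}

#' @export
print.deflection_library <- function(x, ...) {
  cat(sprintf(
    "<deflection_library> %d sources x %d configurations (%d elements)\n",
    length(x$columns), nrow(x$configs), nrow(x$columns[[1]])
  ))
  invisible(x)
}

library_entry <- function(library, kind, direction = NA, magnitude = NA) {
  cf <- library$configs
  i <- switch(kind,
    nominal = which(cf$kind == "nominal"),
    worst = which(cf$kind == "worst" & cf$direction == direction),
    quantile = which(cf$kind == "quantile" & cf$direction == direction &
      abs(cf$magnitude - magnitude) < 1e-9)
  )
  if (length(i) != 1) abort("no library entry for the requested configuration")
  i
}

sampled_outcomes <- function(library, x, model, thresholds, entry_idx) {
  # entry_idx: n_samples x n_sources matrix of library entries
  n_samples <- nrow(entry_idx)
  k <- length(library$columns)
  ed <- element_dosimetry(model, thresholds)
  # OAR elements that cannot reach threshold under any configuration at
  # these powers never count towards v100; drop them exactly
  phi_bound <- numeric(nrow(ed))
  for (j in seq_len(k)) {
    m <- library$columns[[j]]
    phi_bound <- phi_bound +
      do.call(pmax, lapply(seq_len(ncol(m)), function(e) m[, e])) * x[j]
  }
  keep <- which(ed$role == "tumour" |
    (ed$role == "oar" & phi_bound >= ed$threshold))
  cols <- lapply(library$columns, function(m) m[keep, , drop = FALSE])
  edk <- ed[keep, ]
  tum <- edk$role == "tumour"
  tumour_vol <- sum(edk$volume[tum])
  oars <- unique(edk$region[edk$role == "oar"])
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    phi <- numeric(length(keep))
    for (j in seq_len(k)) {
      phi <- phi + cols[[j]][, entry_idx[s, j]] * x[j]
    }
    hit <- phi >= edk$threshold
    row <- c(
      tumour = 100 * sum(edk$volume[tum & hit]) / tumour_vol,
      vapply(oars, function(r) {
        sum(edk$volume[edk$region == r & hit])
      }, numeric(1))
    )
    out[[s]] <- row
  }
  mat <- do.call(rbind, out)
  tibble::as_tibble(mat) |>
    dplyr::mutate(sample = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "tissue", values_to = "v100")
}

new_outcome_distribution <- function(samples, nominal, mode, library, extra = list()) {
  structure(
    c(
      list(
        samples = samples, nominal = nominal, mode = mode,
        n_samples = max(samples$sample)
      ),
      extra
    ),
    class = "outcome_distribution"
  )
}

#' Worst-case position-uncertainty sampling
#'
#' Each source is independently deflected by the maximum tip displacement
#' (3 mm by default) in a uniformly random principal direction; the total
#' fluence is the superposition of the per-source library columns scaled by
#' the (fixed) powers, and the v100 outcomes are recorded per sample.
#'
#' @param library A [build_library()] result.
#' @param x Source powers, W.
#' @param model,thresholds As for [v100()].
#' @param n_samples Number of samples (default from the library's config).
#' @param seed RNG seed.
#' @return An `outcome_distribution`: `samples` (tibble `sample`, `tissue`,
#'   `v100`), `nominal` outcome, `configs` (per-sample directions).
#' @export
sample_worst_case <- function(library, x, model, thresholds,
                              n_samples = NULL, seed = 1L) {
  cfg <- library$cfg
  n_samples <- n_samples %||% cfg$n_samples
  k <- length(library$columns)
  nd <- cfg$n_directions
  set.seed(seed)
  dirs <- matrix(sample.int(nd, n_samples * k, replace = TRUE), n_samples, k)
  worst_entries <- vapply(
    seq_len(nd),
    function(d) library_entry(library, "worst", direction = d), integer(1)
  )
  entry_idx <- matrix(worst_entries[dirs], n_samples, k)
  samples <- sampled_outcomes(library, x, model, thresholds, entry_idx)
  nom_idx <- matrix(library_entry(library, "nominal"), 1, k)
  nominal <- sampled_outcomes(library, x, model, thresholds, nom_idx) |>
    dplyr::select(-"sample")
  new_outcome_distribution(samples, nominal, "worst_case", library,
    extra = list(configs = dirs, entries = entry_idx, seed = seed)
  )
}

#' Truncated-Gaussian deflection magnitudes
#'
#' Draws signed magnitudes from `Normal(0, sigma)`, redrawing any sample
#' whose absolute value exceeds the bound `d` (rejection, as in the
#' clinical deflection model); with the default `sigma = d / 1.96` about
#' 95% of raw draws fall within the bound before truncation.
#'
#' @param n Number of accepted draws required.
#' @param sigma Gaussian standard deviation, mm.
#' @param d Truncation bound, mm.
#' @return List with `z` (n signed magnitudes, mm) and `acceptance` (the
#'   empirical pre-truncation within-bound fraction).
#' @export
draw_truncated_magnitudes <- function(n, sigma = 3 / 1.96, d = 3) {
  zs <- numeric(0)
  n_raw <- 0L
  n_ok <- 0L
  while (length(zs) < n) {
    draw <- rnorm(2 * (n - length(zs)) + 16, 0, sigma)
    keep <- abs(draw) <= d
    n_raw <- n_raw + length(draw)
    n_ok <- n_ok + sum(keep)
    zs <- c(zs, draw[keep])
  }
  list(z = zs[seq_len(n)], acceptance = n_ok / n_raw)
}

#' Truncated-Gaussian position-uncertainty sampling
#'
#' For each source and sample: an axis is drawn uniformly from the first
#' `n_directions / 2` principal directions, a magnitude `z` is drawn from
#' `Normal(0, sigma)` and redrawn until `|z|` is within the 3 mm bound
#' (with `sigma = 3 / 1.96`, ~95% of raw draws already are); positive
#' magnitudes map to the drawn direction and negative ones to the opposite
#' direction (Dir 5-8), and `|z| / 3` is snapped to the nearest quantile
#' fraction to select the precomputed library column.
#'
#' @inheritParams sample_worst_case
#' @return An `outcome_distribution`; `acceptance` holds the empirical
#'   pre-truncation within-bound fraction, `magnitudes` the realized
#'   per-source displacements (mm).
#' @export
sample_gaussian <- function(library, x, model, thresholds,
                            n_samples = NULL, seed = 1L) {
  cfg <- library$cfg
  n_samples <- n_samples %||% cfg$n_samples
  k <- length(library$columns)
  nd <- cfg$n_directions
  half <- nd / 2
  d <- cfg$max_displacement
  set.seed(seed)
  need <- n_samples * k
  tg <- draw_truncated_magnitudes(need, cfg$sigma, d)
  zs <- tg$z
  axis <- sample.int(half, need, replace = TRUE)
  direction <- ifelse(zs >= 0, axis, axis + half)
  qbin <- cfg$quantiles[
    vapply(abs(zs) / d, function(f) which.min(abs(cfg$quantiles - f)), integer(1))
  ]
  entries <- vapply(seq_len(need), function(i) {
    library_entry(library, "quantile", direction = direction[i], magnitude = qbin[i])
  }, integer(1))
  entry_idx <- matrix(entries, n_samples, k)
  samples <- sampled_outcomes(library, x, model, thresholds, entry_idx)
  nom_idx <- matrix(library_entry(library, "nominal"), 1, k)
  nominal <- sampled_outcomes(library, x, model, thresholds, nom_idx) |>
    dplyr::select(-"sample")
  new_outcome_distribution(samples, nominal, "gaussian", library,
    extra = list(
      entries = entry_idx, seed = seed, acceptance = tg$acceptance,
      magnitudes = matrix(abs(zs), n_samples, k),
      directions = matrix(direction, n_samples, k)
    )
  )
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat(sprintf(
    "<outcome_distribution> %s sampling, %d samples\n", x$mode, x$n_samples
  ))
  s <- dplyr::summarise(
    dplyr::group_by(x$samples, .data$tissue),
    mean = mean(.data$v100), min = min(.data$v100), max = max(.data$v100),
    .groups = "drop"
  )
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.outcome_distribution <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$samples, .data$tissue),
    mean = mean(.data$v100),
    sd = stats::sd(.data$v100),
    q25 = stats::quantile(.data$v100, 0.25),
    median = stats::median(.data$v100),
    q75 = stats::quantile(.data$v100, 0.75),
    min = min(.data$v100), max = max(.data$v100),
    spread = max(.data$v100) - min(.data$v100),
    .groups = "drop"
  ) |>
    dplyr::left_join(
      dplyr::select(x$nominal, "tissue", nominal = "v100"),
      by = "tissue"
    )
}

#' Re-optimize powers for measured source positions
#'
#' Once the realized (deviated) source positions are known, a new dose
#' matrix is assembled from the corresponding library columns and the LP
#' power optimization is re-run on it, independent of the nominal plan;
#' the re-optimized powers restore the prescribed tumour coverage on the
#' realized geometry.
#'
#' @param library A [build_library()] result.
#' @param realized Integer vector of library entry indices (one per
#'   source), e.g. a row of the `entries` matrix of a sampled
#'   `outcome_distribution`.
#' @param model,thresholds,constraints,... Forwarded to
#'   [optimize_power()].
#' @return List with the `power_solution` (`solution`), the realized
#'   `dose` matrix, and the realized-geometry `outcome` at the new powers.
#' @export
reoptimize_power <- function(library, realized, model, thresholds,
                             constraints = NULL, ...) {
  k <- length(library$columns)
  stopifnot(length(realized) == k)
  G <- vapply(
    seq_len(k),
    function(j) library$columns[[j]][, realized[j]],
    numeric(nrow(library$columns[[1]]))
  )
  dose <- structure(
    list(
      G = G, duration = library$duration, engine = "library",
      medium = NA_character_
    ),
    class = "dose_matrix"
  )
  sol <- optimize_power(dose, model, thresholds, constraints = constraints, ...)
  out <- v100(superpose(dose, sol$x), model, thresholds)
  list(solution = sol, dose = dose, outcome = out)
}

#' Worst-case power-uncertainty report
#'
#' For each tumour model and each uncertainty level: solves the LP in each
#' requested mode, evaluates v100 at the nominal powers and at the
#' worst-case bounds `x (1 +/- eta)`, and reports per-tissue spread
#' metrics, their geometric averages across models, and the absolute
#' tumour-coverage extrema across all simulations.
#'
#' @param models List of `tissue_model`s.
#' @param doses List of matching `dose_matrix` objects.
#' @param thresholds A guardbanded [dose_thresholds()] tibble (shared).
#' @param modes Character vector of optimization modes.
#' @param eta_levels Relative power uncertainty levels.
#' @param ... Forwarded to [optimize_power()].
#' @return List with `per_model` (tibble: model, mode, eta, tissue,
#'   v100/v100_max/v100_min/dv100/dv100_pct), `summary` (geometric
#'   averages across models plus per-mode/eta tumour `V100_max`,
#'   `V100_min` extrema).
#' @export
power_uncertainty_report <- function(models, doses, thresholds,
                                     modes = "nominal",
                                     eta_levels = c(0.05, 0.10, 0.20), ...) {
  stopifnot(length(models) == length(doses))
  rows <- list()
  for (im in seq_along(models)) {
    for (mode in modes) {
      for (eta in eta_levels) {
        sol <- optimize_power(doses[[im]], models[[im]], thresholds,
          mode = mode, eta = if (mode == "nominal") 0 else eta, ...
        )
        b <- worst_case_bounds(sol$x, eta)
        vn <- v100(superpose(doses[[im]], sol$x), models[[im]], thresholds)
        vmax <- v100(superpose(doses[[im]], b$x_max), models[[im]], thresholds)
        vmin <- v100(superpose(doses[[im]], b$x_min), models[[im]], thresholds)
        sp <- spread_metrics(vmax, vmin, vn)
        rows[[length(rows) + 1]] <- dplyr::mutate(sp,
          model = im, mode = mode, eta = eta, .before = 1
        )
      }
    }
  }
  per_model <- dplyr::bind_rows(rows)
  gm <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v) || any(v <= 0)) NA_real_ else geometric_mean(v)
  }
  summary <- dplyr::summarise(
    dplyr::group_by(per_model, .data$mode, .data$eta, .data$tissue),
    v100 = gm(.data$v100),
    v100_max = gm(.data$v100_max),
    v100_min = gm(.data$v100_min),
    dv100 = gm(.data$dv100),
    dv100_pct = gm(.data$dv100_pct),
    V100_max = max(.data$v100_max),
    V100_min = min(.data$v100_min),
    .groups = "drop"
  )
  list(per_model = per_model, summary = summary)
}
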