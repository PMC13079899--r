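#' Write / read a tissue model as legacy VTK
#'
#' Serializes the tetrahedral model as a legacy ASCII VTK unstructured grid
#' (cell type 10) with an integer cell-data field `region` coding the five
#' tissues in the order skull, CSF, grey, white, tumour (codes 1-5).
#' Reading recomputes element volumes and centroids from the geometry;
#' models read from file carry no structured grid, so they support the
#' analytic engine and all dosimetry but not the voxel Monte Carlo.
#'
#' @param model A `tissue_model`.
#' @param path File path.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns a
#'   `tissue_model`.
#' @export
write_mesh <- function(model, path) {
  stopifnot(inherits(model, "tissue_model"))
  n <- nrow(model$nodes)
  m <- nrow(model$cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "ipdtplan labelled tissue model",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d float", n)
  ), con)
  writeLines(apply(model$nodes, 1, function(r) {
    paste(sprintf("%.9g", r), collapse = " ")
  }), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(model$cells - 1L, 1, function(r) {
    paste(c(4L, r), collapse = " ")
  }), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(model$elements$region, REGIONS)), con)
  invisible(path)
}

#' @rdname write_mesh
#' @param properties Per-region optical properties to attach on read.
#' @export
read_mesh <- function(path, properties = default_optical_properties()) {
  lines <- readLines(path)
  hdr <- grep("^DATASET", lines, value = TRUE)
  if (!length(hdr) || !grepl("UNSTRUCTURED_GRID", hdr[1])) {
    abort("not a legacy VTK unstructured grid file")
  }
  tok <- function(pattern) {
    i <- grep(pattern, lines)
    if (!length(i)) abort(paste0("VTK file missing '", pattern, "' section"))
    i[1]
  }
  ip <- tok("^POINTS ")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- tok("^CELLS ")
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cellv <- scan(text = lines[(ic + 1):length(lines)], n = 5 * m, quiet = TRUE)
  cellm <- matrix(as.integer(cellv), ncol = 5, byrow = TRUE)
  if (any(cellm[, 1] != 4L)) abort("non-tetrahedral cells found; only simplex (tet) cells are supported")
  it <- tok("^CELL_TYPES")
  types <- scan(text = lines[(it + 1):length(lines)], n = m, quiet = TRUE)
  if (any(types != 10)) abort("non-tetrahedral cells found; only VTK cell type 10 is supported")
  ir <- grep("^SCALARS region ", lines)
  if (!length(ir)) abort("VTK file has no cell-data field named 'region'")
  codes <- as.integer(scan(text = lines[(ir[1] + 2):length(lines)], n = m, quiet = TRUE))
  if (any(is.na(codes)) || any(codes < 1 | codes > length(REGIONS))) {
    abort("region codes must be integers in 1..5 (skull, csf, grey, white, tumour)")
  }
  cells <- cellm[, 2:5, drop = FALSE] + 1L
  a <- nodes[cells[, 1], , drop = FALSE]
  b <- nodes[cells[, 2], , drop = FALSE]
  cc <- nodes[cells[, 3], , drop = FALSE]
  d <- nodes[cells[, 4], , drop = FALSE]
  u <- b - a; v <- cc - a; w <- d - a
  vol <- abs(
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  ) / 6
  cent <- (a + b + cc + d) / 4
  elements <- tibble::tibble(
    element = seq_len(m),
    region = REGIONS[codes],
    volume = vol,
    x = cent[, 1], y = cent[, 2], z = cent[, 3]
  )
  dom <- apply(nodes, 2, max) - apply(nodes, 2, min)
  structure(
    list(
      nodes = nodes, cells = cells, elements = elements,
      properties = properties,
      grid = list(n = NULL, h = NULL, domain = dom),
      config = NULL
    ),
    class = "tissue_model"
  )
}

#' Write / read a treatment plan as JSON
#'
#' Endpoint coordinates are stored in mm, emission lengths in cm (the unit
#' diffusers are catalogued in) and powers in W.
#'
#' @param plan A `pdt_plan`.
#' @param path File path.
#' @export
write_plan <- function(plan, path) {
  plan <- as_plan(plan)
  doc <- list(sources = lapply(seq_len(nrow(plan)), function(i) {
    list(
      source = plan$source[i],
      kind = plan$kind[i],
      proximal_mm = c(plan$px[i], plan$py[i], plan$pz[i]),
      distal_mm = c(plan$dx[i], plan$dy[i], plan$dz[i]),
      length_cm = plan$length[i] / 10,
      power_W = plan$power[i]
    )
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(doc$sources, function(s) {
    tibble::tibble(
      source = as.integer(s$source), kind = s$kind,
      px = s$proximal_mm[[1]], py = s$proximal_mm[[2]], pz = s$proximal_mm[[3]],
      dx = s$distal_mm[[1]], dy = s$distal_mm[[2]], dz = s$distal_mm[[3]],
      length = as.numeric(s$length_cm) * 10,
      power = as.numeric(s$power_W)
    )
  })
  as_plan(rows)
}

# ---- run configuration -----------------------------------------------------

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(paste0(
      "unknown ", where, " key(s): ", paste(extra, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Run configuration for the planning pipeline
#'
#' A fully serializable description of one planning/analysis run; every
#' random procedure derives its stream from the single `seed`. Unknown
#' keys are rejected.
#'
#' @param phantom Named list of [phantom_config()] arguments.
#' @param engine `"analytic"` or `"mc"`.
#' @param n_packets Monte Carlo packets per source.
#' @param duration Treatment duration, s.
#' @param thresholds Named list of [dose_thresholds()] arguments.
#' @param total_power Total power cap, W.
#' @param mode Power optimization mode.
#' @param eta Relative power uncertainty for uncertainty-aware modes.
#' @param uncertainty Named list of [uncertainty_config()] arguments.
#' @param placement Named list of [heuristic_placement()] arguments.
#' @param sa Named list of [sa_schedule()] arguments.
#' @param seed Base RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = list(), engine = "analytic", n_packets = 1e6,
                       duration = 1, thresholds = list(), total_power = 1,
                       mode = "nominal", eta = 0, uncertainty = list(),
                       placement = list(), sa = list(), seed = 1L) {
  check_keys(phantom, names(formals(phantom_config)), "phantom")
  check_keys(thresholds, names(formals(dose_thresholds)), "thresholds")
  check_keys(uncertainty, names(formals(uncertainty_config)), "uncertainty")
  check_keys(
    placement,
    setdiff(names(formals(heuristic_placement)), "model"), "placement"
  )
  check_keys(sa, names(formals(sa_schedule)), "sa")
  if (!engine %in% c("analytic", "mc")) abort("engine must be 'analytic' or 'mc'")
  if (!mode %in% c("nominal", "max_min", "min_only")) {
    abort("mode must be one of nominal, max_min, min_only")
  }
  structure(
    list(
      phantom = phantom, engine = engine, n_packets = n_packets,
      duration = duration, thresholds = thresholds, total_power = total_power,
      mode = mode, eta = eta, uncertainty = uncertainty,
      placement = placement, sa = sa, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(doc, names(formals(run_config)), "run_config")
  do.call(run_config, doc)
}

pipeline_state <- function(config) {
  seed <- config$seed
  model <- make_layered_phantom(do.call(phantom_config, config$phantom))
  plan <- do.call(heuristic_placement, c(list(model = model), config$placement))
  constraint <- make_injection_constraint(model, plan)
  th <- apply_guardband(do.call(dose_thresholds, config$thresholds))
  cons <- power_constraints(nrow(plan), total_power = config$total_power)
  dose <- build_dose_matrix(model, plan,
    engine = config$engine,
    duration = config$duration, n_packets = config$n_packets, seed = seed
  )
  list(
    model = model, plan = plan, constraint = constraint, thresholds = th,
    constraints = cons, dose = dose, seed = seed
  )
}

write_manifest <- function(config, command, out_dir, outputs) {
  manifest <- list(
    command = command,
    config_hash = rlang::hash(config),
    seed = config$seed,
    package = "ipdtplan",
    version = as.character(utils::packageVersion("ipdtplan")),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
}

#' Run one pipeline command
#'
#' Thin orchestration over the package functions: builds the phantom, the
#' heuristic plan and the dose matrix as needed, executes the requested
#' command and writes its artifacts (plus a manifest with the config hash
#' and seed) into `out_dir`.
#'
#' Commands: `phantom` (VTK mesh), `plan-heuristic` (plan JSON),
#' `optimize-power` (optimized plan JSON + cost CSV), `optimize-placement`
#' (SA plan JSON + anneal trace CSV), `analyze-power` (worst-case power
#' report CSV), `analyze-position` (worst-case and Gaussian outcome
#' samples CSV + summary JSON), `reoptimize` (per-sample re-optimized
#' outcomes CSV), `report` (power report CSV over all modes).
#'
#' @param config A [run_config()].
#' @param command One of the commands above.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, command, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  commands <- c(
    "phantom", "plan-heuristic", "optimize-power", "optimize-placement",
    "analyze-power", "analyze-position", "reoptimize", "report"
  )
  if (!command %in% commands) {
    abort(paste0(
      "unknown command '", command, "'; expected one of: ",
      paste(commands, collapse = ", ")
    ))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  if (command == "phantom") {
    model <- make_layered_phantom(do.call(phantom_config, config$phantom))
    outputs$mesh <- file.path(out_dir, "phantom.vtk")
    write_mesh(model, outputs$mesh)
  } else if (command == "plan-heuristic") {
    st <- pipeline_state(config)
    outputs$plan <- file.path(out_dir, "plan.json")
    write_plan(st$plan, outputs$plan)
  } else if (command == "optimize-power") {
    st <- pipeline_state(config)
    sol <- optimize_power(st$dose, st$model, st$thresholds,
      constraints = st$constraints,
      mode = config$mode, eta = config$eta
    )
    st$plan$power <- sol$x
    outputs$plan <- file.path(out_dir, "plan_optimized.json")
    write_plan(st$plan, outputs$plan)
    cb <- cost(sol$x, st$dose, st$model, st$thresholds,
      mode = config$mode, eta = config$eta
    )
    outputs$cost <- file.path(out_dir, "cost_breakdown.csv")
    readr::write_csv(
      dplyr::mutate(st$model$elements, cost = cb$f_i),
      outputs$cost
    )
    outputs$summary <- file.path(out_dir, "power_solution.csv")
    readr::write_csv(glance(sol), outputs$summary)
  } else if (command == "optimize-placement") {
    st <- pipeline_state(config)
    sa <- sa_optimize(st$model, st$plan, st$constraint, st$thresholds,
      constraints = st$constraints,
      schedule = do.call(sa_schedule, config$sa),
      seed = st$seed, duration = config$duration
    )
    outputs$plan <- file.path(out_dir, "plan_sa.json")
    write_plan(sa$plan, outputs$plan)
    outputs$trace <- file.path(out_dir, "anneal_trace.csv")
    readr::write_csv(sa$trace, outputs$trace)
  } else if (command %in% c("analyze-power", "report")) {
    st <- pipeline_state(config)
    modes <- if (command == "report") {
      c("nominal", "max_min", "min_only")
    } else {
      config$mode
    }
    ucfg <- do.call(uncertainty_config, config$uncertainty)
    rep <- power_uncertainty_report(
      list(st$model), list(st$dose), st$thresholds,
      modes = modes, eta_levels = ucfg$eta_levels,
      constraints = st$constraints
    )
    outputs$report <- file.path(out_dir, "power_uncertainty.csv")
    write_power_report_csv(rep, outputs$report)
  } else if (command == "analyze-position") {
    st <- pipeline_state(config)
    ucfg <- do.call(uncertainty_config, config$uncertainty)
    sol <- optimize_power(st$dose, st$model, st$thresholds,
      constraints = st$constraints
    )
    lib <- build_library(st$model, st$plan, st$constraint, ucfg,
      dose = st$dose, engine = config$engine, duration = config$duration
    )
    wc <- sample_worst_case(lib, sol$x, st$model, st$thresholds,
      seed = st$seed
    )
    ga <- sample_gaussian(lib, sol$x, st$model, st$thresholds,
      seed = st$seed + 1L
    )
    outputs$samples <- file.path(out_dir, "position_samples.csv")
    readr::write_csv(
      dplyr::bind_rows(
        dplyr::mutate(wc$samples, mode = "worst_case"),
        dplyr::mutate(ga$samples, mode = "gaussian")
      ),
      outputs$samples
    )
    outputs$summary <- file.path(out_dir, "position_summary.json")
    jsonlite::write_json(
      list(
        worst_case = tidy(wc), gaussian = tidy(ga),
        gaussian_acceptance = ga$acceptance
      ),
      outputs$summary,
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  } else if (command == "reoptimize") {
    st <- pipeline_state(config)
    ucfg <- do.call(uncertainty_config, config$uncertainty)
    sol <- optimize_power(st$dose, st$model, st$thresholds,
      constraints = st$constraints
    )
    lib <- build_library(st$model, st$plan, st$constraint, ucfg,
      dose = st$dose, engine = config$engine, duration = config$duration
    )
    ga <- sample_gaussian(lib, sol$x, st$model, st$thresholds,
      n_samples = ucfg$n_samples_reopt, seed = st$seed + 1L
    )
    rows <- purrr::map_dfr(seq_len(ucfg$n_samples_reopt), function(s) {
      ro <- reoptimize_power(lib, ga$entries[s, ], st$model, st$thresholds,
        constraints = st$constraints
      )
      dplyr::mutate(tibble::as_tibble(ro$outcome), sample = s)
    })
    outputs$reopt <- file.path(out_dir, "reoptimized_outcomes.csv")
    readr::write_csv(rows, outputs$reopt)
  }
  write_manifest(config, command, out_dir, outputs)
  invisible(outputs)
}

#' Write the worst-case power report as CSV
#'
#' One row per statistic (`v100`, `v100_max`, `v100_min`, `dv100`,
#' `dv100_pct`, `V100_max`, `V100_min`), one column per tissue x
#' uncertainty level x mode combination.
#'
#' @param report A [power_uncertainty_report()] result.
#' @param path Output CSV path.
#' @export
write_power_report_csv <- function(report, path) {
  long <- tidyr::pivot_longer(
    report$summary,
    cols = c(
      "v100", "v100_max", "v100_min", "dv100", "dv100_pct",
      "V100_max", "V100_min"
    ),
    names_to = "statistic", values_to = "value"
  )
  wide <- tidyr::pivot_wider(
    dplyr::mutate(long,
      column = sprintf("%s|eta=%g|%s", .data$tissue, .data$eta, .data$mode)
    ),
    id_cols = "statistic", names_from = "column", values_from = "value"
  )
  readr::write_csv(wide, path)
  invisible(path)
}
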