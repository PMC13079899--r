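#' Configuration for a synthetic layered tissue phantom
#'
#' Describes a box-shaped, five-region brain-like phantom: an outer skull
#' shell, a CSF layer, a grey-matter layer, a white-matter core, and a
#' tumour (ellipsoid or union of spheres) embedded in the core. The box is
#' discretized into a structured voxel grid and every voxel is split into
#' six tetrahedra (Kuhn subdivision), matching the tetrahedral data model of
#' patient meshes while remaining generable without an atlas.
#'
#' @param domain Box edge lengths, mm (length 3 or scalar). Default 80 mm
#'   cube.
#' @param h Target voxel pitch, mm (the grid uses the nearest integer cell
#'   count per axis). Default 4 mm, a desk-scale resolution; 2 mm gives
#'   384K tetrahedra, close to clinical-mesh density.
#' @param skull,csf,grey Layer thicknesses from the outer surface, mm.
#'   The remaining interior is white matter. A zero thickness removes the
#'   layer.
#' @param tumour_centre Tumour centre, mm. Default domain centre.
#' @param tumour_radii Ellipsoid semi-axes, mm (length 3). The default
#'   (19, 19, 22) mm gives a ~33 cm^3 tumour, mid-range for glioblastoma
#'   planning studies, with its long axis vertical.
#' @param tumour_spheres Optional n-by-4 matrix `(x, y, z, r)` describing a
#'   union of spheres instead of the ellipsoid.
#' @param properties Per-region optical properties tibble
#'   (default [default_optical_properties()]).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(domain = c(80, 80, 80), h = 4,
                           skull = 4, csf = 2, grey = 6,
                           tumour_centre = NULL, tumour_radii = c(19, 19, 22),
                           tumour_spheres = NULL,
                           properties = default_optical_properties()) {
  if (length(domain) == 1) domain <- rep(domain, 3)
  stopifnot(length(domain) == 3, all(domain > 0), h > 0,
            skull >= 0, csf >= 0, grey >= 0)
  tumour_centre <- tumour_centre %||% (domain / 2)
  cfg <- structure(
    list(
      domain = as.numeric(domain), h = h,
      skull = skull, csf = csf, grey = grey,
      tumour_centre = as.numeric(tumour_centre),
      tumour_radii = as.numeric(tumour_radii),
      tumour_spheres = tumour_spheres,
      properties = properties
    ),
    class = "phantom_config"
  )
  check_tumour_interior(cfg)
  cfg
}

# the tumour must sit strictly inside the grey/white interior: its depth
# from every outer face must exceed the skull + CSF thickness
check_tumour_interior <- function(cfg) {
  inner <- cfg$skull + cfg$csf
  if (is.null(cfg$tumour_spheres)) {
    lo <- cfg$tumour_centre - cfg$tumour_radii
    hi <- cfg$tumour_centre + cfg$tumour_radii
  } else {
    s <- cfg$tumour_spheres
    lo <- apply(s[, 1:3, drop = FALSE] - s[, 4], 2, min)
    hi <- apply(s[, 1:3, drop = FALSE] + s[, 4], 2, max)
  }
  if (any(lo <= inner) || any(hi >= cfg$domain - inner)) {
    abort(paste0(
      "tumour exceeds the grey/white interior: it must lie more than ",
      inner, " mm (skull + CSF) inside every face of the ",
      paste(cfg$domain, collapse = "x"), " mm domain"
    ))
  }
  invisible(cfg)
}

# 6 Kuhn tetrahedra per voxel, one per permutation of the axes; tet k of a
# unit cube is {f : f[perm[1]] >= f[perm[2]] >= f[perm[3]]}
kuhn_perms <- rbind(
  c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
)

kuhn_vertex_bits <- function(perm) {
  e <- diag(3)
  rbind(c(0, 0, 0), e[perm[1], ], e[perm[1], ] + e[perm[2], ], c(1, 1, 1))
}

inside_tumour <- function(pts, cfg) {
  if (is.null(cfg$tumour_spheres)) {
    c0 <- cfg$tumour_centre
    r <- cfg$tumour_radii
    ((pts[, 1] - c0[1]) / r[1])^2 + ((pts[, 2] - c0[2]) / r[2])^2 +
      ((pts[, 3] - c0[3]) / r[3])^2 <= 1
  } else {
    hit <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(cfg$tumour_spheres))) {
      s <- cfg$tumour_spheres[i, ]
      hit <- hit | ((pts[, 1] - s[1])^2 + (pts[, 2] - s[2])^2 +
        (pts[, 3] - s[3])^2 <= s[4]^2)
    }
    hit
  }
}

label_points <- function(pts, cfg) {
  depth <- pmin(
    pts[, 1], cfg$domain[1] - pts[, 1],
    pts[, 2], cfg$domain[2] - pts[, 2],
    pts[, 3], cfg$domain[3] - pts[, 3]
  )
  lab <- rep("white", nrow(pts))
  lab[depth < cfg$skull + cfg$csf + cfg$grey] <- "grey"
  lab[depth < cfg$skull + cfg$csf] <- "csf"
  lab[depth < cfg$skull] <- "skull"
  lab[inside_tumour(pts, cfg) & depth >= cfg$skull + cfg$csf] <- "tumour"
  lab
}

#' Generate a labelled synthetic tissue phantom
#'
#' Builds the tetrahedral tissue model described by a [phantom_config()]:
#' a structured box grid, six tetrahedra per voxel, each labelled by the
#' region at its centroid. Element volumes partition the domain volume
#' exactly.
#'
#' @param config A [phantom_config()].
#' @return An object of class `tissue_model`: list with `nodes` (n-by-3
#'   matrix, mm), `cells` (m-by-4 integer matrix of tetra vertex indices),
#'   `elements` (tibble: `element`, `region`, `volume` mm^3, centroid
#'   `x`, `y`, `z`), `properties`, `grid`, `config`.
#' @examples
#' model <- make_layered_phantom(phantom_config(domain = 60, h = 6,
#'   tumour_radii = c(10, 10, 10)))
#' dplyr::count(model$elements, region, wt = volume)
#' @export
make_layered_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- pmax(1L, as.integer(round(config$domain / config$h)))
  hv <- config$domain / n # per-axis pitch actually realized
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  # node grid
  gx <- (0:nx) * hv[1]; gy <- (0:ny) * hv[2]; gz <- (0:nz) * hv[3]
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  nid <- function(i, j, k) i + j * (nx + 1L) + k * (nx + 1L) * (ny + 1L) + 1L
  cell <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  ncell <- nrow(cell)
  corner <- cbind(cell$i * hv[1], cell$j * hv[2], cell$k * hv[3])
  cells <- matrix(0L, ncell * 6L, 4L)
  cent <- matrix(0, ncell * 6L, 3L)
  for (p in 1:6) {
    bits <- kuhn_vertex_bits(kuhn_perms[p, ])
    rows <- seq.int(p, by = 6L, length.out = ncell)
    for (v in 1:4) {
      cells[rows, v] <- nid(cell$i + bits[v, 1], cell$j + bits[v, 2], cell$k + bits[v, 3])
    }
    off <- colMeans(bits) * hv
    cent[rows, ] <- cbind(corner[, 1] + off[1], corner[, 2] + off[2], corner[, 3] + off[3])
  }
  vol <- prod(hv) / 6
  elements <- tibble::tibble(
    element = seq_len(ncell * 6L),
    region = label_points(cent, config),
    volume = vol,
    x = cent[, 1], y = cent[, 2], z = cent[, 3]
  )
  structure(
    list(
      nodes = nodes, cells = cells, elements = elements,
      properties = config$properties,
      grid = list(n = n, h = hv, domain = config$domain),
      config = config
    ),
    class = "tissue_model"
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  counts <- dplyr::count(x$elements, .data$region, wt = .data$volume, name = "volume_mm3")
  cat(sprintf(
    "<tissue_model> %d tetrahedra on a %s mm domain\n",
    nrow(x$elements), paste(signif(x$grid$domain, 4), collapse = " x ")
  ))
  print(as.data.frame(counts), row.names = FALSE)
  invisible(x)
}

#' Region label at arbitrary points
#'
#' For procedurally generated phantoms the generating geometry is evaluated
#' directly (exact); for models read from file the label of the nearest
#' element centroid is used.
#'
#' @param model A `tissue_model`.
#' @param pts Length-3 vector or n-by-3 matrix of points, mm.
#' @return Character vector of region labels.
#' @export
region_at <- function(model, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  if (!is.null(model$config)) {
    return(label_points(pts, model$config))
  }
  cent <- as.matrix(model$elements[, c("x", "y", "z")])
  lab <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (cent[, 1] - pts[i, 1])^2 + (cent[, 2] - pts[i, 2])^2 +
      (cent[, 3] - pts[i, 3])^2
    lab[i] <- model$elements$region[which.min(d2)]
  }
  lab
}

new_plan <- function(sources) {
  stopifnot(all(c(
    "source", "kind", "px", "py", "pz", "dx", "dy", "dz",
    "length", "power"
  ) %in% names(sources)))
  structure(tibble::as_tibble(sources), class = c("pdt_plan", class(tibble::tibble())))
}

#' Coerce to a treatment plan
#'
#' A plan is a tibble with one row per light source: `source` (id), `kind`
#' (`"line"` or `"point"`), proximal endpoint `px, py, pz` and distal
#' endpoint `dx, dy, dz` (mm), emission `length` (mm, 0 for point sources)
#' and `power` (W). Line sources must satisfy
#' `length == |distal - proximal| > 0`; point sources have coincident
#' endpoints.
#'
#' @param x A data frame with the plan columns.
#' @return A validated `pdt_plan` tibble.
#' @export
as_plan <- function(x) {
  if (inherits(x, "pdt_plan")) return(x)
  p <- new_plan(x)
  validate_plan_geometry(p)
  p
}

validate_plan_geometry <- function(p) {
  len <- sqrt((p$dx - p$px)^2 + (p$dy - p$py)^2 + (p$dz - p$pz)^2)
  line <- p$kind == "line"
  if (any(line & (p$length <= 0 | abs(len - p$length) > 1e-6))) {
    abort("line sources must have length == |distal - proximal| > 0")
  }
  if (any(!line & (len > 1e-9 | p$length != 0))) {
    abort("point sources must have coincident endpoints and zero length")
  }
  if (any(p$power < 0)) abort("source powers must be non-negative")
  invisible(p)
}

#' Clinically heuristic initial source placement
#'
#' Places parallel cylindrical-diffuser line sources on a regular grid
#' aligned with the tumour's longest principal axis: centre-to-centre
#' spacing `spacing` (default 10 mm), outermost source axes kept at least
#' `margin[1]` mm (default 8, target band 8-10 mm) inside the lateral
#' tumour boundary. Diffuser lengths are drawn from the allowed set
#' (default 5 mm increments, 5-40 mm). Optionally, isotropic point sources
#' are added in tumour pockets farther than `gap_distance` from every line
#' axis. A tumour too small for any diffuser gets a single central point
#' source (with a warning).
#'
#' @param model A `tissue_model` with a non-empty tumour region.
#' @param spacing Grid spacing between adjacent parallel sources, mm.
#' @param margin Allowed distance band of the outermost source axes from
#'   the tumour boundary, mm (length 2).
#' @param lengths Allowed diffuser emission lengths, mm (5 mm increments).
#' @param axial_margin Clearance kept between diffuser tips and the axial
#'   tumour boundary, mm.
#' @param add_points Add gap-filling point sources?
#' @param gap_distance Tumour elements farther than this from every line
#'   axis seed a candidate point source, mm.
#' @param max_points Cap on gap-filling point sources.
#' @return A `pdt_plan` tibble (powers initialized to 0).
#' @export
heuristic_placement <- function(model, spacing = 10, margin = c(8, 10),
                                lengths = seq(5, 40, by = 5),
                                axial_margin = 3, add_points = TRUE,
                                gap_distance = 7, max_points = 4) {
  stopifnot(inherits(model, "tissue_model"), spacing > 0, all(lengths > 0))
  if (any(round(lengths / 5) * 5 != lengths)) {
    abort("diffuser lengths must be multiples of 5 mm")
  }
  tum <- dplyr::filter(model$elements, .data$region == "tumour")
  if (nrow(tum) == 0) abort("model has no tumour elements")
  C <- as.matrix(tum[, c("x", "y", "z")])
  ctr <- colMeans(C)
  pca <- prcomp(C, center = TRUE, scale. = FALSE)
  a1 <- pca$rotation[, 1] # insertion axis: longest tumour axis
  if (a1[which.max(abs(a1))] < 0) a1 <- -a1
  a2 <- pca$rotation[, 2]
  a3 <- pca$rotation[, 3]
  Cc <- sweep(C, 2, ctr)
  w <- Cc %*% a1
  u <- Cc %*% a2
  v <- Cc %*% a3
  pitch <- max(model$grid$h)

  grid_axis <- function(e) {
    # most lines that keep the outer ones >= margin[1] inside the boundary
    nmax <- max(1L, floor((e - 2 * margin[1]) / spacing) + 1L)
    (seq_len(nmax) - (nmax + 1) / 2) * spacing
  }
  off_u <- grid_axis(max(u) - min(u)) + (max(u) + min(u)) / 2
  off_v <- grid_axis(max(v) - min(v)) + (max(v) + min(v)) / 2
  grid <- expand.grid(gu = off_u, gv = off_v)

  inside_lateral <- function(qu, qv) {
    min((u - qu)^2 + (v - qv)^2) < (1.5 * pitch)^2
  }
  probe_ok <- function(gu, gv) {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    all(vapply(
      ang,
      function(a) inside_lateral(gu + margin[1] * cos(a), gv + margin[1] * sin(a)),
      logical(1)
    ))
  }

  rows <- list()
  sid <- 0L
  for (gi in seq_len(nrow(grid))) {
    gu <- grid$gu[gi]; gv <- grid$gv[gi]
    if (!probe_ok(gu, gv)) next
    near <- (u - gu)^2 + (v - gv)^2 <= (spacing / 2)^2
    if (!any(near)) next
    wspan <- range(w[near])
    avail <- lengths[lengths <= diff(wspan) - 2 * axial_margin]
    if (length(avail) == 0) next
    len <- max(avail)
    mid <- mean(wspan)
    c3 <- ctr + as.vector(mid * a1 + gu * a2 + gv * a3)
    sid <- sid + 1L
    rows[[sid]] <- tibble::tibble(
      source = sid, kind = "line",
      px = c3[1] + len / 2 * a1[1], py = c3[2] + len / 2 * a1[2],
      pz = c3[3] + len / 2 * a1[3],
      dx = c3[1] - len / 2 * a1[1], dy = c3[2] - len / 2 * a1[2],
      dz = c3[3] - len / 2 * a1[3],
      length = len, power = 0
    )
  }

  if (length(rows) == 0) {
    warn("tumour too small for a line diffuser; placing one central point source")
    plan <- tibble::tibble(
      source = 1L, kind = "point",
      px = ctr[1], py = ctr[2], pz = ctr[3],
      dx = ctr[1], dy = ctr[2], dz = ctr[3],
      length = 0, power = 0
    )
    return(new_plan(plan))
  }

  plan <- dplyr::bind_rows(rows)

  if (add_points) {
    dmin <- rep(Inf, nrow(C))
    for (i in seq_len(nrow(plan))) {
      dmin <- pmin(dmin, point_segment_distance(
        C,
        c(plan$px[i], plan$py[i], plan$pz[i]),
        c(plan$dx[i], plan$dy[i], plan$dz[i])
      ))
    }
    added <- 0L
    while (added < max_points && any(dmin > gap_distance)) {
      k <- which.max(dmin)
      p0 <- C[k, ]
      sid <- sid + 1L
      added <- added + 1L
      plan <- dplyr::bind_rows(plan, tibble::tibble(
        source = sid, kind = "point",
        px = p0[1], py = p0[2], pz = p0[3],
        dx = p0[1], dy = p0[2], dz = p0[3],
        length = 0, power = 0
      ))
      dmin <- pmin(dmin, sqrt((C[, 1] - p0[1])^2 + (C[, 2] - p0[2])^2 +
        (C[, 3] - p0[3])^2))
    }
  }
  new_plan(plan)
}

# distance from each row of pts to segment [a, b]
point_segment_distance <- function(pts, a, b) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  seg <- b - a
  len2 <- sum(seg^2)
  if (len2 < 1e-18) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2 + (pts[, 3] - a[3])^2))
  }
  tp <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * seg[1] + (pts[, 2] - a[2]) * seg[2] +
    (pts[, 3] - a[3]) * seg[3]) / len2))
  sqrt((pts[, 1] - a[1] - tp * seg[1])^2 + (pts[, 2] - a[2] - tp * seg[2])^2 +
    (pts[, 3] - a[3] - tp * seg[3])^2)
}

#' Injection constraint circle on the outer surface
#'
#' Defines the circle on the phantom's outer surface through which all
#' source trajectories must pass: the plane is the outer box face that the
#' mean source axis points toward, the centre is the centroid of the
#' axis/plane intersection points, and the radius encircles all of them
#' (with a pad). Point sources have no axis of their own and are assigned
#' the disc centre as their injection point.
#'
#' @param model A `tissue_model`.
#' @param plan A `pdt_plan`.
#' @param min_radius Minimum disc radius, mm.
#' @param pad Extra radius beyond the outermost intersection, mm.
#' @return An `injection_constraint`: list with `centre`, `normal`,
#'   `radius` (mm).
#' @export
make_injection_constraint <- function(model, plan, min_radius = 5, pad = 2) {
  plan <- as_plan(plan)
  line <- plan$kind == "line"
  dirs <- cbind(plan$px - plan$dx, plan$py - plan$dy, plan$pz - plan$dz)
  if (any(line)) {
    dm <- colMeans(dirs[line, , drop = FALSE])
  } else {
    dm <- c(0, 0, 1)
  }
  ax <- which.max(abs(dm))
  pos <- dm[ax] >= 0
  level <- if (pos) model$grid$domain[ax] else 0
  normal <- c(0, 0, 0); normal[ax] <- if (pos) 1 else -1

  pts <- matrix(NA_real_, nrow(plan), 3)
  for (i in which(line)) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    if (abs(d[ax]) < 1e-6) {
      abort("source axis nearly parallel to the outer surface; cannot form injection constraint")
    }
    t0 <- (level - plan[[c("dx", "dy", "dz")[ax]]][i]) / d[ax]
    pts[i, ] <- c(plan$dx[i], plan$dy[i], plan$dz[i]) + t0 * d
  }
  hit <- pts[line, , drop = FALSE]
  if (nrow(hit) == 0) {
    centre <- c(model$grid$domain[1] / 2, model$grid$domain[2] / 2, model$grid$domain[3] / 2)
    centre[ax] <- level
  } else {
    centre <- colMeans(hit)
  }
  radius <- min_radius
  if (nrow(hit) > 0) {
    r <- sqrt(rowSums(sweep(hit, 2, centre)^2))
    radius <- max(min_radius, max(r) + pad)
  }
  structure(list(centre = centre, normal = normal, radius = radius),
    class = "injection_constraint"
  )
}

#' @export
print.injection_constraint <- function(x, ...) {
  cat(sprintf(
    "<injection_constraint> centre (%s) mm, normal (%s), radius %.2f mm\n",
    paste(signif(x$centre, 4), collapse = ", "),
    paste(x$normal, collapse = ", "), x$radius
  ))
  invisible(x)
}

#' Injection point of every source
#'
#' Line sources: intersection of the extended source axis with the
#' constraint plane. Point sources: the disc centre (their trajectory is
#' unobserved).
#'
#' @param plan A `pdt_plan`.
#' @param constraint An [make_injection_constraint()] result.
#' @return Tibble with `source`, `ix`, `iy`, `iz` (mm) and `inside`
#'   (logical: within the constraint disc).
#' @export
injection_points <- function(plan, constraint) {
  plan <- as_plan(plan)
  n <- constraint$normal
  c0 <- constraint$centre
  out <- matrix(NA_real_, nrow(plan), 3)
  for (i in seq_len(nrow(plan))) {
    if (plan$kind[i] == "point") {
      out[i, ] <- c0
    } else {
      d <- c(plan$px[i] - plan$dx[i], plan$py[i] - plan$dy[i], plan$pz[i] - plan$dz[i])
      d <- d / sqrt(sum(d^2))
      dn <- sum(d * n)
      if (abs(dn) < 1e-9) abort("source axis parallel to the injection plane")
      t0 <- sum((c0 - c(plan$dx[i], plan$dy[i], plan$dz[i])) * n) / dn
      out[i, ] <- c(plan$dx[i], plan$dy[i], plan$dz[i]) + t0 * d
    }
  }
  dist <- sqrt(rowSums(sweep(out, 2, c0)^2))
  tibble::tibble(
    source = plan$source, ix = out[, 1], iy = out[, 2], iz = out[, 3],
    inside = dist <= constraint$radius + 1e-9
  )
}
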