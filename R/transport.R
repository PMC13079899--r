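#' Optical properties of a turbid tissue
#'
#' Bundles the absorption coefficient, scattering coefficient and scattering
#' anisotropy of a tissue, together with the derived diffusion-theory
#' quantities: the reduced scattering coefficient
#' \eqn{\mu_s' = \mu_s (1 - g)}, the diffusion coefficient
#' \eqn{D = 1 / (3 (\mu_a + \mu_s'))} and the effective attenuation
#' coefficient \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}.
#'
#' @param mu_a Absorption coefficient, 1/mm. Non-negative.
#' @param mu_s Scattering coefficient, 1/mm. Non-negative.
#' @param g Scattering anisotropy (mean cosine of the scattering angle),
#'   in \eqn{[-1, 1]}.
#' @return An object of class `optical_properties`: a list with elements
#'   `mu_a`, `mu_s`, `g`, `mu_s_prime`, `D`, `mu_eff`.
#' @examples
#' op <- optical_properties(mu_a = 0.02, mu_s = 20, g = 0.9)
#' 1 / op$mu_eff # effective attenuation depth, mm
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g))
  if (mu_a < 0 || mu_s < 0) abort("mu_a and mu_s must be non-negative")
  if (g < -1 || g > 1) abort("anisotropy g must lie in [-1, 1]")
  mu_s_prime <- mu_s * (1 - g)
  structure(
    list(
      mu_a = mu_a, mu_s = mu_s, g = g,
      mu_s_prime = mu_s_prime,
      D = 1 / (3 * (mu_a + mu_s_prime)),
      mu_eff = sqrt(3 * mu_a * (mu_a + mu_s_prime))
    ),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a=%g mu_s=%g g=%g  (mu_s'=%g, D=%g mm, mu_eff=%g /mm)\n",
    x$mu_a, x$mu_s, x$g, x$mu_s_prime, x$D, x$mu_eff
  ))
  invisible(x)
}

#' Default per-region optical properties
#'
#' Absorption/scattering values representative of brain tissue at typical
#' PDT wavelengths (~630-665 nm), chosen so that every scattering-dominated
#' region has an effective attenuation depth \eqn{1/\mu_{eff}} in the 2-5 mm
#' range quoted for PDT in tissue. CSF is modelled as a low-scattering,
#' low-absorption clear layer.
#'
#' @return A tibble with one row per region (`skull`, `csf`, `grey`, `white`,
#'   `tumour`) and columns `region`, `mu_a`, `mu_s`, `g` plus the derived
#'   `mu_s_prime`, `D`, `mu_eff`.
#' @export
default_optical_properties <- function() {
  base <- tibble::tribble(
    ~region,  ~mu_a,  ~mu_s, ~g,
    "skull",  0.010,  30,    0.90,
    "csf",    0.002,  1,     0.90,
    "grey",   0.020,  25,    0.90,
    "white",  0.015,  40,    0.90,
    "tumour", 0.020,  20,    0.90
  )
  dplyr::mutate(base,
    mu_s_prime = .data$mu_s * (1 - .data$g),
    D = 1 / (3 * (.data$mu_a + .data$mu_s_prime)),
    mu_eff = sqrt(3 * .data$mu_a * (.data$mu_a + .data$mu_s_prime))
  )
}

region_properties <- function(model, region) {
  row <- dplyr::filter(model$properties, .data$region == !!region)
  if (nrow(row) != 1) abort(paste0("no optical properties for region '", region, "'"))
  optical_properties(row$mu_a, row$mu_s, row$g)
}

#' Infinite-medium diffusion point-source kernel
#'
#' Fluence per unit emitted energy at distance `r` from an isotropic point
#' source in an unbounded homogeneous medium under the diffusion
#' approximation: \eqn{\phi(r) = \exp(-\mu_{eff} r) / (4 \pi D r)}.
#'
#' @param r Distance(s) from the source, mm. Must be strictly positive
#'   (the kernel is singular at the origin).
#' @param op An [optical_properties()] object with `mu_a > 0`.
#' @return Fluence per unit energy, 1/mm^2 (i.e. J/mm^2 per J emitted).
#' @export
point_kernel <- function(r, op) {
  stopifnot(inherits(op, "optical_properties"))
  if (op$mu_a <= 0) abort("point_kernel requires mu_a > 0")
  if (any(r <= 0)) abort("point_kernel is singular at r = 0; r must be > 0")
  exp(-op$mu_eff * r) / (4 * pi * op$D * r)
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (no quadrature package in the dependency set provides this).
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * (e$vectors[1, idx])^2)
}

#' Fluence of a finite line (cylindrical diffuser) source
#'
#' Fluence per unit emitted energy at field point(s) `p` from a uniformly
#' emitting line source, computed by Gauss-Legendre quadrature of the
#' diffusion point kernel along the segment. The emission profile is flat:
#' linear source density \eqn{1/L} per mm.
#'
#' @param p Field point (length-3 vector) or an n-by-3 matrix of points, mm.
#' @param proximal,distal Segment endpoints, mm.
#' @param op An [optical_properties()] object.
#' @param nodes_per_cm Gauss-Legendre nodes per 10 mm of diffuser length
#'   (default 32); the actual order is scaled to the segment length with a
#'   floor of 8 nodes.
#' @return Fluence per unit energy at each field point, 1/mm^2.
#' @export
line_fluence <- function(p, proximal, distal, op, nodes_per_cm = 32) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  seg <- distal - proximal
  len <- sqrt(sum(seg^2))
  if (len <= 0) abort("line source must have positive length")
  n <- max(8L, ceiling(nodes_per_cm * len / 10))
  gl <- gauss_legendre(n)
  tpar <- (gl$nodes + 1) / 2 # [0, 1] along the segment
  w <- gl$weights / 2        # integrates a density over [0, 1]
  # distance from every field point to the segment axis: reject on-axis points
  tproj <- pmin(1, pmax(0, ((p[, 1] - proximal[1]) * seg[1] +
    (p[, 2] - proximal[2]) * seg[2] +
    (p[, 3] - proximal[3]) * seg[3]) / len^2))
  dmin2 <- (p[, 1] - (proximal[1] + tproj * seg[1]))^2 +
    (p[, 2] - (proximal[2] + tproj * seg[2]))^2 +
    (p[, 3] - (proximal[3] + tproj * seg[3]))^2
  if (any(dmin2 < 1e-12)) abort("field point lies on the source segment")
  phi <- numeric(nrow(p))
  for (k in seq_len(n)) {
    s <- proximal + tpar[k] * seg
    r <- sqrt((p[, 1] - s[1])^2 + (p[, 2] - s[2])^2 + (p[, 3] - s[3])^2)
    phi <- phi + w[k] * point_kernel(r, op)
  }
  phi
}

# Unit-power, per-duration fluence column for one source row at the given
# field points. Distances are clamped at r_clamp (the physical fibre radius
# scale) to keep the infinite-medium kernel finite next to the source.
source_fluence <- function(points, src, op, r_clamp = 0.5, nodes_per_cm = 32) {
  prox <- c(src$px, src$py, src$pz)
  dist <- c(src$dx, src$dy, src$dz)
  if (src$kind == "point") {
    r <- sqrt((points[, 1] - dist[1])^2 + (points[, 2] - dist[2])^2 +
      (points[, 3] - dist[3])^2)
    point_kernel(pmax(r, r_clamp), op)
  } else {
    # clamp by nudging points that sit on/next to the axis outward
    seg <- dist - prox
    len2 <- sum(seg^2)
    tp <- pmin(1, pmax(0, ((points[, 1] - prox[1]) * seg[1] +
      (points[, 2] - prox[2]) * seg[2] +
      (points[, 3] - prox[3]) * seg[3]) / len2))
    foot <- cbind(prox[1] + tp * seg[1], prox[2] + tp * seg[2], prox[3] + tp * seg[3])
    dv <- points - foot
    dn <- sqrt(rowSums(dv^2))
    near <- dn < r_clamp
    if (any(near)) {
      # push near-axis points to the clamp radius along a perpendicular
      perp <- dv[near, , drop = FALSE]
      degen <- dn[near] < 1e-9
      if (any(degen)) {
        ax <- seg / sqrt(len2)
        ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        pv <- c(
          ax[2] * ref[3] - ax[3] * ref[2],
          ax[3] * ref[1] - ax[1] * ref[3],
          ax[1] * ref[2] - ax[2] * ref[1]
        )
        pv <- pv / sqrt(sum(pv^2))
        perp[degen, ] <- matrix(pv, sum(degen), 3, byrow = TRUE)
        dn_n <- dn[near]
        dn_n[degen] <- 1
        perp <- perp / dn_n
      } else {
        perp <- perp / dn[near]
      }
      points[near, ] <- foot[near, , drop = FALSE] + r_clamp * perp
    }
    line_fluence(points, prox, dist, op, nodes_per_cm = nodes_per_cm)
  }
}

#' Assemble the dose matrix G
#'
#' Builds the elements-by-sources matrix whose column j holds the fluence at
#' every tissue element when source j alone emits at 1 W for the treatment
#' duration. Total dose for a power vector x is then the superposition
#' `G %*% x` (see [superpose()]).
#'
#' The `analytic` engine evaluates the infinite-medium diffusion kernel
#' (point sources) or its line-quadrature (cylindrical diffusers) at element
#' centroids, using a single homogeneous effective medium (`medium`,
#' default the tumour's optical properties). The `mc` engine runs the voxel
#' Monte Carlo transport of [mc_fluence()] per source and honours per-region
#' optical properties.
#'
#' @param model A [make_layered_phantom()] tissue model.
#' @param plan A plan tibble (see [heuristic_placement()]).
#' @param engine `"analytic"` (diffusion kernel, default) or `"mc"`.
#' @param medium Region whose optical properties define the homogeneous
#'   medium for the analytic engine (default `"tumour"`).
#' @param duration Treatment duration in seconds, converting source power
#'   (W) into emitted energy (J). Default 1 s; thresholds must be expressed
#'   on the matching fluence scale.
#' @param n_packets Photon packets per source for the `mc` engine.
#' @param seed Base seed for the `mc` engine (source j uses `seed + j`).
#' @param r_clamp Minimum source-element distance, mm, for the analytic
#'   kernel (default 0.5, the physical fibre radius scale).
#' @param nodes_per_cm Quadrature order per 10 mm of diffuser length.
#' @return An object of class `dose_matrix`: list with `G` (matrix, J/mm^2
#'   per W of source power), `duration` (s), `engine`, `medium`.
#' @export
build_dose_matrix <- function(model, plan, engine = c("analytic", "mc"),
                              medium = "tumour", duration = 1,
                              n_packets = 1e5, seed = 1L,
                              r_clamp = 0.5, nodes_per_cm = 32) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "tissue_model"))
  plan <- as_plan(plan)
  pts <- as.matrix(model$elements[, c("x", "y", "z")])
  m <- nrow(pts)
  G <- matrix(0, m, nrow(plan))
  if (engine == "analytic") {
    op <- region_properties(model, medium)
    for (j in seq_len(nrow(plan))) {
      G[, j] <- source_fluence(pts, plan[j, ], op,
        r_clamp = r_clamp, nodes_per_cm = nodes_per_cm
      )
    }
  } else {
    for (j in seq_len(nrow(plan))) {
      fl <- mc_fluence(model, plan[j, ],
        n_packets = n_packets,
        seed = seed + j
      )
      G[, j] <- fl$phi
    }
  }
  structure(
    list(G = G * duration, duration = duration, engine = engine, medium = medium),
    class = "dose_matrix"
  )
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf(
    "<dose_matrix> %d elements x %d sources, engine=%s, duration=%gs\n",
    nrow(x$G), ncol(x$G), x$engine, x$duration
  ))
  invisible(x)
}

#' Superpose per-source fluence fields
#'
#' Total fluence is linear in the source powers: `phi = G %*% x` where
#' column j of G is the unit-power single-source field.
#'
#' @param dose A `dose_matrix` from [build_dose_matrix()], or a bare matrix.
#' @param x Power vector, W; non-negative, one entry per source.
#' @return Numeric vector of per-element fluence, J/mm^2.
#' @export
superpose <- function(dose, x) {
  G <- if (inherits(dose, "dose_matrix")) dose$G else dose
  if (length(x) != ncol(G)) abort("power vector length must equal the number of sources")
  if (any(x < 0)) abort("source powers must be non-negative")
  as.vector(G %*% x)
}
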