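# Shared fixtures, built in code at test time. Phantoms are kept coarse
# (few thousand tetrahedra) so the suite stays fast; resolution-sensitive
# checks build their own finer grids locally.

tiny_config <- function(...) {
  args <- list(
    domain = 40, h = 5, skull = 2, csf = 1, grey = 3,
    tumour_radii = c(8, 8, 10)
  )
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_layered_phantom(tiny_config())
    cache
  }
})

# mid-size phantom used where the heuristic grid needs room to breathe
small_config <- function(...) {
  phantom_config(
    domain = 60, h = 4, skull = 3, csf = 2, grey = 5,
    tumour_radii = c(12, 12, 15), ...
  )
}

small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_layered_phantom(small_config())
    cache
  }
})

# hand-built element table wrapped as a tissue model: lets dosimetry and
# cost oracles run on printed toy element sets
fake_model <- function(region, volume, x = NULL) {
  n <- length(region)
  structure(
    list(
      nodes = matrix(0, 0, 3), cells = matrix(0L, 0, 4),
      elements = tibble::tibble(
        element = seq_len(n), region = region, volume = volume,
        x = x %||% seq_len(n), y = 0, z = 0
      ),
      properties = default_optical_properties(),
      grid = list(n = NULL, h = NULL, domain = c(1, 1, 1)),
      config = NULL
    ),
    class = "tissue_model"
  )
}

fake_dose <- function(G, duration = 1) {
  structure(
    list(G = G * duration, duration = duration, engine = "manual", medium = "tumour"),
    class = "dose_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# threshold table for toy problems on explicit fluence scales
toy_thresholds <- function(d_min = 1, d_max = 1, guardband = 1, oar_weight = 1) {
  apply_guardband(dose_thresholds(
    d_min = d_min, d_max = c(grey = d_max, white = d_max),
    guardband = c(grey = guardband, white = guardband),
    oar_weight = oar_weight
  ))
}

# uniform-power feasibility helper
uniform_powers <- function(k, total = 1) rep(total / k, k)
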