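# Synthetic condyle-like template and its OA deformation. The template is a
# smooth closed bilobed ellipsoid standing in for the femoral condyle
# surface; a per-vertex "rim weight" marks the equatorial band playing the
# role of the cartilage-plate edge, where osteoarthritic shape change
# (osteophyte growth) concentrates.

# Internal RNG scoping: run `code` under `seed`, restoring the caller's RNG
# state afterwards so generation is a pure function of (config, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  force(code)
}

#' Build the synthetic condyle template
#'
#' A deterministic latitude/longitude triangulation of a bilobed ellipsoid
#' (two fused condyle-like lobes, radii of the order of a femoral condyle in
#' mm), with per-vertex rim weights in \[0, 1\] peaking along the equatorial
#' band that emulates the cartilage-plate edge. The realized vertex count is
#' the largest grid realization not exceeding `n_vertices`.
#'
#' @param n_vertices Requested resolution (at least 50).
#' @param seed Accepted for interface uniformity; the construction is fully
#'   deterministic.
#' @return List with `shape` (a [corresponded_shape()]), `rim_weights`
#'   (numeric, max exactly 1, min >= 0), and grid dimensions.
#' @export
make_template <- function(n_vertices = 500L, seed = 1L) {
  if (n_vertices < 50L)
    stop("template needs at least 50 vertices")
  n_theta <- max(4L, floor(sqrt((n_vertices - 2L) / 2)))
  n_phi <- max(8L, floor((n_vertices - 2L) / n_theta))
  theta <- pi * seq_len(n_theta) / (n_theta + 1L)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  grid <- expand.grid(phi = phi, theta = theta)  # phi fastest: id(j,i) below
  # bilobed ellipsoid: posterior condylar lobes via a cos^2 longitude bump
  lobe <- 1 + 0.15 * exp(-((grid$theta - 1.9) / 0.5)^2) * cos(grid$phi)^2
  a <- 32; b <- 26; cc <- 22  # semi-axes, mm
  verts <- cbind(a * lobe * sin(grid$theta) * cos(grid$phi),
                 b * lobe * sin(grid$theta) * sin(grid$phi),
                 cc * lobe * cos(grid$theta))
  verts <- rbind(verts, c(0, 0, cc), c(0, 0, -cc))  # poles
  top <- n_theta * n_phi + 1L
  bottom <- n_theta * n_phi + 2L
  id <- function(j, i) (j - 1L) * n_phi + ((i - 1L) %% n_phi) + 1L
  tris <- list()
  for (j in seq_len(n_theta - 1L)) {
    i <- seq_len(n_phi)
    tris[[length(tris) + 1L]] <- cbind(id(j, i), id(j, i + 1L), id(j + 1L, i))
    tris[[length(tris) + 1L]] <- cbind(id(j, i + 1L), id(j + 1L, i + 1L), id(j + 1L, i))
  }
  i <- seq_len(n_phi)
  tris[[length(tris) + 1L]] <- cbind(rep(top, n_phi), id(1L, i + 1L), id(1L, i))
  tris[[length(tris) + 1L]] <- cbind(rep(bottom, n_phi), id(n_theta, i), id(n_theta, i + 1L))
  triangles <- do.call(rbind, tris) - 1L
  topo <- tri_topology(nrow(verts), triangles)
  rim <- exp(-((c(grid$theta, 0, pi) - pi / 2) / 0.25)^2)
  rim <- rim / max(rim)
  list(shape = corresponded_shape(verts, topo, "template"),
       rim_weights = rim, n_theta = n_theta, n_phi = n_phi)
}

#' Deform the template to a latent B-score
#'
#' Displaces vertices outward along their normals by
#' `latent_b * amplitude * profile`, where the profile is the rim weight
#' raised to `rim_concentration` (osteophyte-like growth at the plate edge)
#' plus a small uniform term (the central flattening/broadening component),
#' then adds i.i.d. Gaussian vertex noise of SD `measurement_noise_sd`.
#' Surface area is monotone increasing in `latent_b` in expectation.
#'
#' Noise is drawn from the current RNG state; generators that must be pure
#' functions of a seed wrap their calls accordingly.
#'
#' @param template Result of [make_template()] (or a [corresponded_shape()]
#'   if `rim_weights` and `normals` are given).
#' @param rim_weights Per-vertex rim weights; defaults to the template's.
#' @param latent_b Latent B-score driving the deformation (finite scalar).
#' @param config A [generator_config()] supplying `oa_deformation_amplitude`
#'   (mm per B-score unit), `rim_concentration`, `flatten_fraction` and
#'   `measurement_noise_sd` (mm).
#' @param normals Optional precomputed unit vertex normals (n x 3); passing
#'   them avoids recomputation inside cohort loops.
#' @param shape_id Identifier for the deformed shape.
#' @return A [corresponded_shape()].
#' @export
deform_to_bscore <- function(template, rim_weights = NULL, latent_b, config,
                             normals = NULL, shape_id = "deformed") {
  if (!is.finite(latent_b)) stop("latent_b must be finite")
  shape <- if (inherits(template, "corresponded_shape")) template else template$shape
  if (is.null(rim_weights)) rim_weights <- template$rim_weights
  if (is.null(rim_weights)) stop("rim_weights are required")
  if (is.null(normals)) normals <- vertex_normals(shape)
  f <- config$flatten_fraction
  profile <- (1 - f) * rim_weights^config$rim_concentration + f
  disp <- latent_b * config$oa_deformation_amplitude * profile * normals
  v <- shape$vertices + disp
  if (config$measurement_noise_sd > 0)
    v <- v + matrix(stats::rnorm(length(v), 0, config$measurement_noise_sd),
                    ncol = 3L)
  corresponded_shape(v, shape$topology, shape_id)
}
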