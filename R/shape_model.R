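# Principal-component shape space over aligned corresponded shapes.
# Flattened coordinate order is (x1, y1, z1, x2, ...) throughout.

#' Fit a PCA shape model to aligned corresponded shapes
#'
#' Eigendecomposition (via SVD of the centred data matrix) of the
#' vertex-coordinate covariance of an aligned training set. The smallest
#' number of leading modes whose cumulative variance reaches
#' `variance_retained` is kept. Mode signs are fixed deterministically: the
#' first component of each mode exceeding 1e-9 in magnitude is made positive,
#' so repeated fits of the same data produce identical models.
#'
#' @param shapes List of aligned [corresponded_shape()] objects (e.g. the
#'   `aligned` element of [generalized_procrustes()]), or that result itself.
#' @param variance_retained Fraction of total variance to retain, in (0, 1].
#' @return Object of class `shape_model` with elements `topology`,
#'   `mean_shape` (length 3n flattened vector, mm), `modes` (3n x k
#'   orthonormal matrix), `mode_variances` (length k, mm^2, non-increasing),
#'   `n_training`, and `variance_retained` (the achieved fraction).
#' @export
fit_shape_model <- function(shapes, variance_retained = 0.98) {
  if (is.list(shapes) && !is.null(shapes$aligned)) shapes <- shapes$aligned
  if (length(variance_retained) != 1L || !is.finite(variance_retained) ||
      variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must be in (0, 1]")
  n <- length(shapes)
  if (n < 3L) stop("need at least 3 shapes to fit a shape model")
  topo <- shapes[[1]]$topology
  for (s in shapes)
    if (!same_topology(s$topology, topo))
      stop("all shapes must share one topology")
  X <- t(vapply(shapes, function(s) flatten_vertices(s$vertices),
                numeric(3L * topo$n_vertices)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  vars <- sv$d^2 / (n - 1)
  # discard numerically-null directions (identical shapes give total ~ 0)
  keep <- vars > max(vars[1], 0) * 1e-12 & seq_along(vars) <= n - 1L
  vars <- vars[keep]
  if (length(vars) == 0L) {
    modes <- matrix(0, length(mu), 0L)
    achieved <- 1
  } else {
    cum <- cumsum(vars) / sum(vars)
    k <- which(cum >= variance_retained)[1]
    modes <- sv$v[, seq_len(k), drop = FALSE]
    vars <- vars[seq_len(k)]
    achieved <- cum[k]
    for (j in seq_len(k)) {
      lead <- which(abs(modes[, j]) > 1e-9)[1]
      if (!is.na(lead) && modes[lead, j] < 0) modes[, j] <- -modes[, j]
    }
  }
  structure(list(topology = topo, mean_shape = mu, modes = modes,
                 mode_variances = vars, n_training = n,
                 variance_retained = achieved),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d vertices, %d training shapes, %d modes (%.1f%% variance)\n",
              x$topology$n_vertices, x$n_training, ncol(x$modes),
              100 * x$variance_retained))
  invisible(x)
}

#' Mean shape of a model as a corresponded shape
#' @param model A [fit_shape_model()] result.
#' @return A [corresponded_shape()].
#' @export
mean_shape_of <- function(model) {
  corresponded_shape(unflatten_vertices(model$mean_shape), model$topology,
                     "model_mean")
}

#' Project a shape into a model's shape space
#'
#' Shape-space coordinates are the retained-mode loadings of the deviation
#' from the model mean: `t(modes) %*% (flatten(shape) - mean_shape)`. By
#' default the shape is first rigidly aligned to the model mean so that
#' coordinates are invariant to rigid motion of the input.
#'
#' @param shape A [corresponded_shape()] with the model's topology.
#' @param model A `shape_model`.
#' @param align Rigidly pre-align `shape` to the model mean (default `TRUE`);
#'   set `FALSE` if the shape is already in model pose.
#' @return Numeric coordinate vector, one entry per retained mode.
#' @export
project_to_space <- function(shape, model, align = TRUE) {
  if (!same_topology(shape$topology, model$topology))
    stop("shape topology does not match the model")
  if (align) shape <- procrustes_align(shape, mean_shape_of(model))$shape
  drop(crossprod(model$modes, flatten_vertices(shape$vertices) - model$mean_shape))
}

#' Reconstruct a shape from shape-space coordinates
#'
#' @param coords Numeric vector, length at most the number of retained modes;
#'   shorter vectors are zero-padded (unused trailing modes at the mean).
#' @param model A `shape_model`.
#' @param shape_id Identifier for the reconstruction.
#' @return A [corresponded_shape()] equal to
#'   `mean_shape + modes %*% coords` reshaped to vertices.
#' @export
reconstruct <- function(coords, model, shape_id = "reconstruction") {
  k <- ncol(model$modes)
  if (length(coords) > k)
    stop(sprintf("coords length %d exceeds the %d retained modes",
                 length(coords), k))
  full <- c(as.numeric(coords), rep(0, k - length(coords)))
  flat <- model$mean_shape + as.numeric(model$modes %*% full)
  corresponded_shape(unflatten_vertices(flat), model$topology, shape_id)
}

topology_hash <- function(topology) {
  sprintf("v%d_t%d_s%.0f", topology$n_vertices, nrow(topology$triangles),
          sum(as.numeric(topology$triangles)))
}

#' Serialize a shape model to a directory
#'
#' Writes `model.json` (counts, variances, topology hash), `mean.csv`
#' (x, y, z per vertex), `modes.csv` (one column per mode, flattened
#' coordinate order) and `faces.csv` (0-based triangle indices).
#'
#' @param model A `shape_model`.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n_vertices = model$topology$n_vertices,
               n_triangles = nrow(model$topology$triangles),
               topology_hash = topology_hash(model$topology),
               n_training = model$n_training,
               n_modes = ncol(model$modes),
               mode_variances = as.numeric(model$mode_variances),
               variance_retained = model$variance_retained)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  mu <- unflatten_vertices(model$mean_shape)
  utils::write.csv(data.frame(x = mu[, 1], y = mu[, 2], z = mu[, 3]),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  modes <- as.data.frame(model$modes)
  names(modes) <- if (ncol(modes)) paste0("mode_", seq_len(ncol(modes))) else character()
  utils::write.csv(modes, file.path(dir, "modes.csv"), row.names = FALSE)
  tr <- model$topology$triangles
  utils::write.csv(data.frame(v1 = tr[, 1], v2 = tr[, 2], v3 = tr[, 3]),
                   file.path(dir, "faces.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a shape model serialized by [write_shape_model()]
#'
#' @param dir Model directory.
#' @return A `shape_model`.
#' @export
read_shape_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  faces <- utils::read.csv(file.path(dir, "faces.csv"))
  topo <- tri_topology(meta$n_vertices, as.matrix(faces))
  if (topology_hash(topo) != meta$topology_hash)
    stop("shape model directory is inconsistent: topology hash mismatch")
  mu <- as.matrix(utils::read.csv(file.path(dir, "mean.csv")))
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv")))
  if (nrow(modes) == 0L) modes <- matrix(0, 3L * topo$n_vertices, 0L)
  structure(list(topology = topo, mean_shape = flatten_vertices(mu),
                 modes = unname(modes),
                 mode_variances = as.numeric(meta$mode_variances),
                 n_training = meta$n_training,
                 variance_retained = meta$variance_retained),
            class = "shape_model")
}
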