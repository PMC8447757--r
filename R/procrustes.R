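# Rigid Procrustes alignment of corresponded shapes. OA-related bone shape
# change includes genuine growth (osteophytes enlarge the condylar rim), so
# the default alignment removes rotation and translation but preserves scale;
# similarity alignment is available behind a flag.

#' Rigidly align one corresponded shape onto another
#'
#' Least-squares (Kabsch) superimposition of `moving` onto `fixed`:
#' the rotation (determinant +1) and translation minimizing the sum of
#' squared vertex distances. Scaling is off by default so that size
#' differences, which carry osteoarthritic signal, are preserved.
#'
#' @param moving,fixed [corresponded_shape()] objects with identical topology.
#' @param scale If `TRUE`, also estimate a single positive scale factor
#'   (similarity alignment).
#' @return List with `shape` (the aligned moving shape), `rotation` (3 x 3),
#'   `translation` (length 3), `scale`, and `rms` (root-mean-square residual
#'   in mm).
#' @export
procrustes_align <- function(moving, fixed, scale = FALSE) {
  if (!inherits(moving, "corresponded_shape") || !inherits(fixed, "corresponded_shape"))
    stop("moving and fixed must be corresponded_shape objects")
  if (!same_topology(moving$topology, fixed$topology))
    stop("cannot align shapes with different topologies")
  X <- moving$vertices
  Y <- fixed$vertices
  cm <- colMeans(X)
  cf <- colMeans(Y)
  Xc <- sweep(X, 2, cm)
  Yc <- sweep(Y, 2, cf)
  ssx <- sum(Xc^2)
  if (ssx < 1e-24)
    stop("degenerate shape: all vertices coincident")
  A <- crossprod(Xc, Yc)
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  C <- diag(c(1, 1, d))
  R <- sv$u %*% C %*% t(sv$v)
  s <- if (scale) sum(sv$d * c(1, 1, d)) / ssx else 1
  aligned <- s * Xc %*% R
  aligned <- sweep(aligned, 2, cf, `+`)
  rms <- sqrt(mean(rowSums((aligned - Y)^2)))
  list(shape = corresponded_shape(aligned, fixed$topology, moving$shape_id),
       rotation = R,
       translation = as.numeric(cf - s * cm %*% R),
       scale = s,
       rms = rms)
}

#' Generalized Procrustes analysis of a shape set
#'
#' Iterative rigid alignment to an evolving consensus: every shape is
#' centred, aligned to the current mean, and the mean recomputed (and
#' re-centred at the origin) until its RMS change falls below `tol` mm.
#'
#' @param shapes List of [corresponded_shape()] objects sharing one topology.
#' @param scale Passed to [procrustes_align()] (default rigid, no scaling).
#' @param tol Convergence tolerance on the consensus RMS change (mm).
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   final change for diagnosis.
#' @return List with `aligned` (list of aligned shapes), `mean_shape`
#'   (consensus [corresponded_shape()], centroid at the origin),
#'   `iterations`, and `converged`.
#' @export
generalized_procrustes <- function(shapes, scale = FALSE, tol = 1e-7,
                                   max_iter = 100L) {
  if (length(shapes) < 2L)
    stop("generalized Procrustes needs at least 2 shapes")
  topo <- shapes[[1]]$topology
  for (s in shapes)
    if (!same_topology(s$topology, topo))
      stop("all shapes must share one topology")
  centred <- lapply(shapes, function(s) {
    corresponded_shape(sweep(s$vertices, 2, colMeans(s$vertices)),
                       topo, s$shape_id)
  })
  mean_v <- centred[[1]]$vertices
  aligned <- centred
  for (it in seq_len(max_iter)) {
    mean_shape <- corresponded_shape(mean_v, topo, "consensus")
    aligned <- lapply(centred, function(s) procrustes_align(s, mean_shape, scale)$shape)
    new_mean <- Reduce(`+`, lapply(aligned, `[[`, "vertices")) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    delta <- sqrt(mean(rowSums((new_mean - mean_v)^2)))
    mean_v <- new_mean
    if (delta < tol) {
      return(list(aligned = aligned,
                  mean_shape = corresponded_shape(mean_v, topo, "consensus"),
                  iterations = it, converged = TRUE))
    }
  }
  stop(sprintf(paste0("generalized Procrustes did not converge in %d iterations ",
                      "(last consensus RMS change %.3e mm, tol %.1e)"),
               max_iter, delta, tol))
}
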