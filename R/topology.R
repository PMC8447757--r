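#' Triangle-mesh topology shared by a set of corresponded shapes
#'
#' A `tri_topology` records the vertex count and the triangle list that every
#' shape in a corresponded set shares. Triangle indices are 0-based, matching
#' common mesh file conventions; they are validated to lie in
#' `[0, n_vertices)` and to reference three distinct vertices.
#'
#' @param n_vertices Number of vertices (positive integer).
#' @param triangles Integer matrix with 3 columns (or coercible), one row per
#'   triangle, 0-based vertex indices.
#' @return An object of class `tri_topology` with elements `n_vertices` and
#'   `triangles` (integer matrix, M x 3).
#' @examples
#' tri_topology(4, rbind(c(0, 1, 2), c(0, 1, 3), c(0, 2, 3), c(1, 2, 3)))
#' @export
tri_topology <- function(n_vertices, triangles) {
  n_vertices <- as.integer(n_vertices)
  if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 1L)
    stop("n_vertices must be a single positive integer")
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L)
    stop("triangles must have exactly 3 columns")
  storage.mode(triangles) <- "integer"
  if (anyNA(triangles))
    stop("triangle indices must not be missing")
  if (any(triangles < 0L) || any(triangles >= n_vertices))
    stop(sprintf("triangle index out of range [0, %d)", n_vertices))
  degen <- triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
    triangles[, 2] == triangles[, 3]
  if (any(degen))
    stop(sprintf("degenerate triangle(s) with repeated vertex indices: %s",
                 paste(which(degen), collapse = ", ")))
  dimnames(triangles) <- NULL
  structure(list(n_vertices = n_vertices, triangles = triangles),
            class = "tri_topology")
}

#' @export
print.tri_topology <- function(x, ...) {
  cat(sprintf("tri_topology: %d vertices, %d triangles\n",
              x$n_vertices, nrow(x$triangles)))
  invisible(x)
}

#' Test whether two topologies are identical
#'
#' @param a,b `tri_topology` objects.
#' @return Logical scalar.
#' @export
same_topology <- function(a, b) {
  identical(a$n_vertices, b$n_vertices) && identical(a$triangles, b$triangles)
}

#' A corresponded bone surface
#'
#' One shape of a corresponded set: an ordered vertex list (millimetres)
#' sharing its triangulation with every other shape in the set. Vertex order
#' carries the anatomical correspondence, so it is never permuted.
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param topology A [tri_topology()] with `n_vertices == nrow(vertices)`.
#' @param shape_id Character identifier.
#' @return Object of class `corresponded_shape`.
#' @export
corresponded_shape <- function(vertices, topology, shape_id = "shape") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix")
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices)))
    stop("all vertex coordinates must be finite")
  if (!inherits(topology, "tri_topology"))
    stop("topology must be a tri_topology object")
  if (nrow(vertices) != topology$n_vertices)
    stop(sprintf("vertex count (%d) does not match topology (%d)",
                 nrow(vertices), topology$n_vertices))
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, topology = topology,
                 shape_id = as.character(shape_id)),
            class = "corresponded_shape")
}

#' @export
print.corresponded_shape <- function(x, ...) {
  cat(sprintf("corresponded_shape '%s': %d vertices, %d triangles\n",
              x$shape_id, nrow(x$vertices), nrow(x$topology$triangles)))
  invisible(x)
}

# Flatten vertex matrix to (x1,y1,z1,x2,...) vector; the fixed coordinate
# order used by shape models throughout the package.
flatten_vertices <- function(vertices) as.vector(t(vertices))

unflatten_vertices <- function(flat) matrix(flat, ncol = 3L, byrow = TRUE)

#' Per-triangle areas of a corresponded shape
#'
#' Areas by the cross-product formula, in mm^2, one value per triangle in
#' topology order.
#'
#' @param shape A [corresponded_shape()] (or a vertex matrix if `topology`
#'   is supplied).
#' @param topology Optional [tri_topology()] when `shape` is a bare matrix.
#' @return Numeric vector of triangle areas.
#' @export
triangle_areas <- function(shape, topology = NULL) {
  if (inherits(shape, "corresponded_shape")) {
    v <- shape$vertices
    topology <- shape$topology
  } else {
    v <- as.matrix(shape)
  }
  tr <- topology$triangles
  a <- v[tr[, 1] + 1L, , drop = FALSE]
  e1 <- v[tr[, 2] + 1L, , drop = FALSE] - a
  e2 <- v[tr[, 3] + 1L, , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Outward per-vertex normals
#'
#' Area-weighted average of incident face normals, normalized to unit length,
#' then oriented outward (positive dot product with the vector from the mesh
#' centroid); intended for closed, roughly star-shaped surfaces such as the
#' synthetic condyle template.
#'
#' @param shape A [corresponded_shape()].
#' @return Numeric matrix, n x 3, unit normals.
#' @export
vertex_normals <- function(shape) {
  v <- shape$vertices
  tr <- shape$topology$triangles
  a <- v[tr[, 1] + 1L, , drop = FALSE]
  e1 <- v[tr[, 2] + 1L, , drop = FALSE] - a
  e2 <- v[tr[, 3] + 1L, , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    acc <- rowsum(fn, group = tr[, k] + 1L)
    rows <- as.integer(rownames(acc))
    n[rows, ] <- n[rows, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  ctr <- colMeans(v)
  outward <- rowSums(n * sweep(v, 2, ctr)) < 0
  n[outward, ] <- -n[outward, , drop = FALSE]
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
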