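# The OA vector: the line in shape space through the mean non-OA and mean OA
# shapes. B-score standardizes the orthogonal projection onto this line by
# the non-OA group's per-sex mean (origin, B = 0) and standard deviation
# (1 B-score unit).

#' Fit the OA vector from shape-space coordinates and group labels
#'
#' The direction is the normalized difference between the OA and non-OA
#' coordinate means, pooled across sex; the origin and unit are per-sex,
#' taken from the non-OA projections of each sex (mean and n-1 standard
#' deviation respectively).
#'
#' @param coords Numeric matrix, one row per shape, columns = shape-space
#'   coordinates (retained modes).
#' @param meta Data frame aligned with `coords` rows, with columns `sex`
#'   (`"female"`/`"male"`) and `group` (`"non_OA"`, `"OA"`, or
#'   `"unlabeled"`; unlabeled shapes are ignored during fitting).
#' @return Object of class `oa_vector`: `direction` (unit vector),
#'   `origin_by_sex`, `scale_by_sex` (named by sex), and per-group counts.
#' @export
fit_oa_vector <- function(coords, meta) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(meta))
    stop("coords and meta must have the same number of rows")
  non <- meta$group == "non_OA"
  oa <- meta$group == "OA"
  if (sum(non) < 2L || sum(oa) < 2L)
    stop("need at least 2 non-OA and 2 OA shapes to fit the OA vector")
  dirv <- colMeans(coords[oa, , drop = FALSE]) -
    colMeans(coords[non, , drop = FALSE])
  nrm <- sqrt(sum(dirv^2))
  if (nrm < 1e-12)
    stop("OA and non-OA mean shapes coincide: OA vector undefined")
  dirv <- dirv / nrm
  sexes <- sort(unique(meta$sex[non]))
  origin <- scale_sd <- stats::setNames(numeric(length(sexes)), sexes)
  for (s in sexes) {
    idx <- non & meta$sex == s
    if (sum(idx) < 2L)
      stop(sprintf("sex '%s' has fewer than 2 non-OA shapes", s))
    proj <- as.numeric(coords[idx, , drop = FALSE] %*% dirv)
    origin[s] <- mean(proj)
    scale_sd[s] <- stats::sd(proj)
    if (!is.finite(scale_sd[s]) || scale_sd[s] < 1e-12)
      stop(sprintf("degenerate scale: non-OA projections of sex '%s' have zero spread", s))
  }
  structure(list(direction = dirv, origin_by_sex = origin,
                 scale_by_sex = scale_sd,
                 n_non_oa = sum(non), n_oa = sum(oa)),
            class = "oa_vector")
}

#' @export
print.oa_vector <- function(x, ...) {
  cat(sprintf("oa_vector in %d-mode space (fit on %d non-OA / %d OA shapes)\n",
              length(x$direction), x$n_non_oa, x$n_oa))
  for (s in names(x$origin_by_sex))
    cat(sprintf("  %s: origin %.4f, 1 unit = %.4f\n",
                s, x$origin_by_sex[s], x$scale_by_sex[s]))
  invisible(x)
}

#' B-score of shape-space coordinates
#'
#' Orthogonal projection onto the OA vector, standardized per sex:
#' `(coords %*% direction - origin[sex]) / scale[sex]`. B = 0 is the mean
#' non-OA shape of that sex; 1 unit is 1 non-OA SD along the vector.
#'
#' @param coords Numeric vector (one shape) or matrix (one row per shape).
#' @param sex Character scalar or vector (recycled) of `"female"`/`"male"`;
#'   must match a sex the vector was fitted with.
#' @param oa_vector A [fit_oa_vector()] result.
#' @return Numeric B-score(s), dimensionless SD units.
#' @export
bscore_of <- function(coords, sex, oa_vector) {
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != length(oa_vector$direction))
    stop("coords are not in the OA vector's shape space")
  sex <- rep_len(as.character(sex), nrow(coords))
  unknown <- setdiff(unique(sex), names(oa_vector$origin_by_sex))
  if (length(unknown))
    stop(sprintf("unknown sex key(s): %s", paste(unknown, collapse = ", ")))
  proj <- as.numeric(coords %*% oa_vector$direction)
  unname((proj - oa_vector$origin_by_sex[sex]) / oa_vector$scale_by_sex[sex])
}

#' B-scores for a set of corresponded shapes
#'
#' Composition of rigid alignment to the model mean, projection into the
#' retained-mode shape space and [bscore_of()]; deterministic.
#'
#' @param shapes List of [corresponded_shape()] objects.
#' @param meta Data frame with one row per shape, columns `shape_id` and
#'   `sex` (and optionally others, carried through).
#' @param model A `shape_model`.
#' @param oa_vector An `oa_vector` fitted in the model's shape space.
#' @param align Passed to [project_to_space()].
#' @return `meta` with a `bscore` column appended.
#' @export
bscore_cohort <- function(shapes, meta, model, oa_vector, align = TRUE) {
  if (length(shapes) != nrow(meta))
    stop("shapes and meta must have the same length")
  out <- meta
  out$bscore <- if (length(shapes) == 0L) numeric(0) else
    vapply(seq_along(shapes), function(i) {
      coords <- project_to_space(shapes[[i]], model, align = align)
      as.numeric(bscore_of(coords, meta$sex[i], oa_vector))
    }, numeric(1))
  out
}

#' Serialize an OA vector to JSON
#' @param oa_vector An `oa_vector`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_oa_vector <- function(oa_vector, path) {
  jsonlite::write_json(list(direction = as.numeric(oa_vector$direction),
                            origin_by_sex = as.list(oa_vector$origin_by_sex),
                            scale_by_sex = as.list(oa_vector$scale_by_sex),
                            n_non_oa = oa_vector$n_non_oa,
                            n_oa = oa_vector$n_oa),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an OA vector serialized by [write_oa_vector()]
#' @param path JSON path.
#' @return An `oa_vector`.
#' @export
read_oa_vector <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(direction = as.numeric(x$direction),
                 origin_by_sex = unlist(x$origin_by_sex),
                 scale_by_sex = unlist(x$scale_by_sex),
                 n_non_oa = x$n_non_oa, n_oa = x$n_oa),
            class = "oa_vector")
}

#' Per-triangle area change between two points on the OA vector
#'
#' Reconstructs the model shapes at B-scores `b_from` and `b_to` along the
#' OA vector (using the chosen sex's origin and unit) and returns the percent
#' change of each corresponded triangle's area, the quantity shown in
#' local area-change maps of OA bone shape progression.
#'
#' @param oa_vector An `oa_vector` fitted in `model`'s shape space.
#' @param model A `shape_model`.
#' @param b_from,b_to B-scores delimiting the change.
#' @param sex Which sex's origin/unit to use (default `"female"`).
#' @return Numeric vector, `100 * (area_to - area_from) / area_from` per
#'   triangle, class `area_change_map`.
#' @export
local_area_change <- function(oa_vector, model, b_from, b_to, sex = "female") {
  if (length(oa_vector$direction) != ncol(model$modes))
    stop("oa_vector and model do not share a shape space")
  if (!sex %in% names(oa_vector$origin_by_sex))
    stop(sprintf("unknown sex key: %s", sex))
  at_b <- function(b) {
    coords <- oa_vector$direction *
      (oa_vector$origin_by_sex[[sex]] + b * oa_vector$scale_by_sex[[sex]])
    reconstruct(coords, model, sprintf("b=%g", b))
  }
  a_from <- triangle_areas(at_b(b_from))
  a_to <- triangle_areas(at_b(b_to))
  bad <- which(a_from < 1e-12)
  if (length(bad))
    stop(sprintf("zero-area triangle %d at b_from = %g", bad[1], b_from))
  structure(100 * (a_to - a_from) / a_from, class = "area_change_map")
}

#' Write an area-change map as CSV
#' @param map An `area_change_map` (from [local_area_change()]).
#' @param path Destination CSV with columns `triangle_index` (0-based) and
#'   `pct_change`.
#' @return `path`, invisibly.
#' @export
write_area_change <- function(map, path) {
  utils::write.csv(data.frame(triangle_index = seq_along(map) - 1L,
                              pct_change = as.numeric(map)),
                   path, row.names = FALSE)
  invisible(path)
}
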