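# Mesh readers/writers for corresponded surfaces.
# Supported: ascii PLY (read/write), binary_little_endian PLY (read),
# Wavefront OBJ (read/write). Triangles only; vertex order is preserved
# exactly because it carries the anatomical correspondence.

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_type_signed <- c(char = TRUE, int8 = TRUE, uchar = FALSE, uint8 = FALSE,
                     short = TRUE, int16 = TRUE, ushort = FALSE, uint16 = FALSE,
                     int = TRUE, int32 = TRUE, uint = FALSE, uint32 = FALSE,
                     float = TRUE, float32 = TRUE, double = TRUE, float64 = TRUE)

ply_type_float <- c(float = TRUE, float32 = TRUE, double = TRUE, float64 = TRUE)

parse_ply_header <- function(lines) {
  if (length(lines) < 2L || trimws(lines[1]) != "ply")
    stop("malformed PLY file: missing 'ply' magic line")
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (length(fmt_line) == 0L) stop("malformed PLY file: no format line")
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s'", fmt))
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "format") next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), properties = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header: property before element")
      if (tok[2] == "list") {
        cur$properties[[length(cur$properties) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$properties[[length(cur$properties) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      return(list(format = fmt, elements = elements))
    }
  }
  stop("malformed PLY file: no end_header")
}

read_ply <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  # locate end_header in the byte stream so binary payloads are untouched
  hdr_end <- grepRaw("end_header\r?\n", raw)
  if (length(hdr_end) == 0L) stop("malformed PLY file: no end_header")
  hdr_end <- hdr_end[1]
  match_len <- length(grepRaw("end_header\r?\n", raw, value = TRUE))
  body_off <- hdr_end + match_len
  header_txt <- rawToChar(raw[seq_len(hdr_end - 1L)])
  hdr <- parse_ply_header(c(strsplit(header_txt, "\r?\n")[[1]], "end_header"))
  ve <- hdr$elements[["vertex"]]
  fe <- hdr$elements[["face"]]
  if (is.null(ve) || is.null(fe))
    stop("malformed PLY file: need 'vertex' and 'face' elements")
  pnames <- vapply(ve$properties, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stop("malformed PLY file: vertex element lacks x/y/z properties")
  if (any(vapply(ve$properties, `[[`, FALSE, "list")))
    stop("unsupported PLY: list-typed vertex property")

  if (hdr$format == "ascii") {
    body <- strsplit(rawToChar(raw[body_off:length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    if (length(body) < ve$count + fe$count)
      stop("malformed PLY file: truncated body")
    vparts <- strsplit(trimws(body[seq_len(ve$count)]), "\\s+")
    nprop <- length(ve$properties)
    vmat <- t(vapply(vparts, function(p) {
      if (length(p) < nprop) stop("malformed PLY file: short vertex line")
      as.numeric(p[seq_len(nprop)])
    }, numeric(nprop)))
    vertices <- vmat[, match(c("x", "y", "z"), pnames), drop = FALSE]
    fparts <- strsplit(trimws(body[ve$count + seq_len(fe$count)]), "\\s+")
    triangles <- t(vapply(fparts, function(p) {
      cnt <- as.integer(p[1])
      if (cnt != 3L) stop("unsupported PLY: non-triangular face")
      as.integer(p[2:4])
    }, integer(3)))
  } else {
    off <- body_off  # 1-based offset of next unread byte
    read_scalar <- function(type, n = 1L) {
      sz <- ply_type_size[[type]]
      bytes <- raw[off:(off + n * sz - 1L)]
      off <<- off + n * sz
      if (isTRUE(ply_type_float[type])) {
        readBin(bytes, "double", n = n, size = sz, endian = "little")
      } else {
        readBin(bytes, "integer", n = n, size = sz,
                signed = ply_type_signed[[type]] || sz >= 4L, endian = "little")
      }
    }
    types <- vapply(ve$properties, `[[`, "", "type")
    if (length(unique(types)) == 1L) {
      vmat <- matrix(read_scalar(types[1], ve$count * length(types)),
                     ncol = length(types), byrow = TRUE)
    } else {
      vmat <- matrix(0, ve$count, length(types))
      for (i in seq_len(ve$count))
        for (j in seq_along(types)) vmat[i, j] <- read_scalar(types[j])
    }
    vertices <- vmat[, match(c("x", "y", "z"), pnames), drop = FALSE]
    fprop <- fe$properties[[1]]
    if (!fprop$list) stop("malformed PLY file: face element lacks index list")
    triangles <- matrix(0L, fe$count, 3L)
    for (i in seq_len(fe$count)) {
      cnt <- read_scalar(fprop$count_type)
      if (cnt != 3L) stop("unsupported PLY: non-triangular face")
      triangles[i, ] <- read_scalar(fprop$type, 3L)
    }
  }
  list(vertices = vertices, triangles = triangles)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("malformed OBJ file: no vertices or no faces")
  vertices <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(p) {
    xyz <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(xyz)) stop("malformed OBJ file: bad vertex line")
    xyz
  }, numeric(3)))
  triangles <- t(vapply(strsplit(trimws(flines), "\\s+"), function(p) {
    if (length(p) != 4L) stop("unsupported OBJ: non-triangular face")
    idx <- suppressWarnings(as.integer(sub("/.*$", "", p[2:4])))
    if (anyNA(idx)) stop("malformed OBJ file: bad face line")
    if (any(idx < 1L)) stop("unsupported OBJ: non-positive face index")
    idx
  }, integer(3))) - 1L
  list(vertices = vertices, triangles = triangles)
}

#' Read a corresponded surface from PLY or OBJ
#'
#' @param path Path to a `.ply` (ascii or binary little-endian) or `.obj`
#'   triangle mesh.
#' @param topology Optional [tri_topology()]; when supplied, the file's
#'   triangle list and vertex count must match it exactly, otherwise a
#'   correspondence error is raised.
#' @param shape_id Identifier for the returned shape; defaults to the file
#'   name without extension.
#' @return A [corresponded_shape()] with vertices in file order.
#' @export
read_shape <- function(path, topology = NULL, shape_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 ply = read_ply(path),
                 obj = read_obj(path),
                 stop(sprintf("unsupported mesh format '.%s' (use PLY or OBJ)", ext)))
  file_topo <- tri_topology(nrow(mesh$vertices), mesh$triangles)
  if (!is.null(topology)) {
    if (topology$n_vertices != file_topo$n_vertices)
      stop(sprintf("correspondence error: file has %d vertices, topology expects %d",
                   file_topo$n_vertices, topology$n_vertices))
    if (!same_topology(topology, file_topo))
      stop("correspondence error: triangle list does not match supplied topology")
    file_topo <- topology
  }
  if (is.null(shape_id))
    shape_id <- tools::file_path_sans_ext(basename(path))
  corresponded_shape(mesh$vertices, file_topo, shape_id)
}

#' Write a corresponded surface to PLY (ascii) or OBJ
#'
#' Coordinates are written with enough digits that a read/write round trip
#' reproduces vertices to better than 1e-6 mm and the triangle list exactly.
#'
#' @param shape A [corresponded_shape()].
#' @param path Destination path ending in `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_shape <- function(shape, path) {
  if (!inherits(shape, "corresponded_shape"))
    stop("shape must be a corresponded_shape")
  ext <- tolower(tools::file_ext(path))
  v <- shape$vertices
  tr <- shape$topology$triangles
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(tr)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else if (ext == "obj") {
    writeLines(sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", tr[, 1] + 1L, tr[, 2] + 1L, tr[, 3] + 1L), con)
  } else {
    stop(sprintf("unsupported mesh format '.%s' (use PLY or OBJ)", ext))
  }
  invisible(path)
}
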