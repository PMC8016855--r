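#' Read a triangulated surface mesh from a PLY file
#'
#' Supports ascii 1.0 and binary_little_endian 1.0 dialects with triangular
#' faces. Vertex normals stored in the file are ignored (normals are always
#' recomputed from face winding). Per-vertex scalar properties beyond the
#' coordinates are returned in the `scalars` attribute.
#'
#' @param path Path to a `.ply` file.
#' @param bone,side,subject_id Metadata attached to the mesh; `bone`
#'   defaults to `"synthetic"`.
#' @param triangulate If `TRUE`, quad faces are split into two triangles;
#'   if `FALSE` (default) non-triangular faces are an error.
#' @return A [surface_mesh()]; any extra per-vertex properties are attached
#'   as a named list in `attr(mesh, "scalars")`.
#' @export
load_mesh <- function(path, bone = "synthetic", side = "n/a",
                      subject_id = NA_character_, triangulate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)

  fmt <- NULL
  elements <- list()   # name -> list(count, props = list(name, type, list))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY header (no end_header)")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      if (length(tok) < 3L) stop("malformed PLY format line")
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format: ", fmt)
    } else if (tok[1] == "element") {
      if (length(tok) < 3L) stop("malformed PLY element line")
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element")
      if (tok[2] == "list") {
        p <- list(name = tok[5], type = tok[4], count_type = tok[3],
                  list = TRUE)
      } else {
        p <- list(name = tok[3], type = tok[2], list = FALSE)
      }
      elements[[cur]]$props <- c(elements[[cur]]$props, list(p))
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop("malformed PLY header line: ", line)
    }
  }
  if (is.null(fmt)) stop("malformed PLY header: no format line")
  if (is.null(elements$vertex)) stop("PLY has no vertex element")
  if (is.null(elements$face)) stop("PLY has no face element")

  if (fmt == "ascii") {
    parsed <- ply_read_ascii(con, elements)
  } else {
    parsed <- ply_read_binary(con, elements)
  }
  vdat <- parsed$vertex
  req <- c("x", "y", "z")
  if (!all(req %in% names(vdat))) stop("PLY vertex element lacks x/y/z")
  v <- cbind(vdat$x, vdat$y, vdat$z)

  flist <- parsed$face
  lens <- lengths(flist)
  if (any(lens > 3L)) {
    if (!triangulate)
      stop("non-triangular faces present and triangulation disabled")
    flist <- unlist(lapply(flist, function(ix) {
      lapply(seq_len(length(ix) - 2L), function(k) ix[c(1L, k + 1L, k + 2L)])
    }), recursive = FALSE)
  }
  if (any(lengths(flist) < 3L)) stop("face with fewer than 3 vertices")
  f <- do.call(rbind, flist) + 1L   # PLY indices are 0-based

  used <- unique(as.vector(f))
  if (length(used) < nrow(v))
    warning(sprintf("%d vertex/vertices not referenced by any face; retained",
                    nrow(v) - length(used)))

  mesh <- surface_mesh(v, f, bone = bone, side = side,
                       subject_id = subject_id)
  extra <- setdiff(names(vdat), c("x", "y", "z", "nx", "ny", "nz"))
  if (length(extra))
    attr(mesh, "scalars") <- vdat[extra]
  mesh
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
    float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported PLY property type: ", type)
  )
}

ply_read_ascii <- function(con, elements) {
  out <- list()
  for (en in names(elements)) {
    el <- elements[[en]]
    n <- el$count
    lines <- readLines(con, n = n)
    if (length(lines) < n) stop("truncated PLY body")
    toks <- strsplit(trimws(lines), "\\s+")
    if (en == "face" || any(vapply(el$props, `[[`, TRUE, "list"))) {
      # assume single list property per element row (PLY convention)
      out[[en]] <- lapply(toks, function(tk) {
        cnt <- as.integer(tk[1])
        as.integer(tk[seq_len(cnt) + 1L])
      })
    } else {
      mat <- vapply(toks, function(tk) as.numeric(tk),
                    numeric(length(el$props)))
      mat <- if (is.null(dim(mat))) matrix(mat, nrow = 1) else t(mat)
      cols <- lapply(seq_along(el$props), function(j) mat[, j])
      names(cols) <- vapply(el$props, `[[`, "", "name")
      out[[en]] <- cols
    }
  }
  out
}

ply_read_binary <- function(con, elements) {
  out <- list()
  for (en in names(elements)) {
    el <- elements[[en]]
    n <- el$count
    has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
    if (!has_list) {
      infos <- lapply(el$props, function(p) ply_type_info(p$type))
      sizes <- vapply(infos, `[[`, 0L, "size")
      stride <- sum(sizes)
      raw <- readBin(con, "raw", n = n * stride)
      if (length(raw) < n * stride) stop("truncated PLY body")
      offs <- cumsum(c(0L, sizes))
      cols <- vector("list", length(el$props))
      for (j in seq_along(el$props)) {
        idx <- as.vector(outer(seq_len(sizes[j]) + offs[j],
                               (seq_len(n) - 1L) * stride, `+`))
        cols[[j]] <- readBin(raw[idx], infos[[j]]$what, n = n,
                             size = sizes[j], signed = infos[[j]]$signed,
                             endian = "little")
      }
      names(cols) <- vapply(el$props, `[[`, "", "name")
      out[[en]] <- cols
    } else {
      p <- el$props[[1]]
      cinfo <- ply_type_info(p$count_type)
      iinfo <- ply_type_info(p$type)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        cnt <- readBin(con, cinfo$what, n = 1L, size = cinfo$size,
                       signed = cinfo$signed, endian = "little")
        rows[[i]] <- readBin(con, iinfo$what, n = cnt, size = iinfo$size,
                             signed = iinfo$signed, endian = "little")
      }
      out[[en]] <- rows
    }
  }
  out
}

#' Write a surface mesh to a PLY file
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param dialect `"binary_le"` (default; binary little-endian, coordinates
#'   and scalars stored as doubles, bit-exact round trip) or `"ascii"`
#'   (written with 17 significant digits).
#' @param scalars Optional named list of per-vertex numeric vectors stored
#'   as extra vertex properties (e.g. a distance map for visualization).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, dialect = c("binary_le", "ascii"),
                      scalars = NULL) {
  dialect <- match.arg(dialect)
  validate_mesh(mesh)
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  v <- mesh$vertices
  n <- nrow(v)
  if (!is.null(scalars)) {
    stopifnot(is.list(scalars), !is.null(names(scalars)))
    for (s in scalars)
      if (length(s) != n) stop("scalar length != vertex count")
  }
  fmt <- if (dialect == "ascii") "ascii" else "binary_little_endian"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", n),
           "property double x", "property double y", "property double z")
  for (nm in names(scalars)) hdr <- c(hdr, paste("property double", nm))
  hdr <- c(hdr, paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")

  vdat <- cbind(v, do.call(cbind, lapply(scalars, as.numeric)))
  f0 <- mesh$faces - 1L
  if (dialect == "ascii") {
    con <- file(path, "wb")  # binary mode: fixed \n line endings
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(vdat, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(paste(3L, f0[, 1], f0[, 2], f0[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(t(vdat)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f0))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Export a per-vertex scalar field as CSV
#'
#' @param values Numeric vector, one value per vertex.
#' @param path Output CSV path (columns `vertex_id`, `value`).
#' @return `path`, invisibly.
#' @export
save_vertex_scalars_csv <- function(values, path) {
  utils::write.csv(data.frame(vertex_id = seq_along(values),
                              value = values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a mesh with per-vertex scalars as legacy VTK PolyData
#'
#' Ascii legacy `.vtk` PolyData, readable by ParaView-class viewers.
#'
#' @inheritParams save_mesh
#' @return `path`, invisibly.
#' @export
save_mesh_vtk <- function(mesh, path, scalars = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices
  f0 <- mesh$faces - 1L
  writeLines(c("# vtk DataFile Version 3.0", "jointshape surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f0), 4L * nrow(f0)), con)
  writeLines(paste(3L, f0[, 1], f0[, 2], f0[, 3]), con)
  if (!is.null(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", as.numeric(scalars[[nm]])), con)
    }
  }
  invisible(path)
}
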