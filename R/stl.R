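#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (dialect auto-detected) into a triangle-soup
#' [triangle_mesh()]: three private vertices per facet, no shared
#' connectivity. Facet normals stored in the file are discarded; they are
#' recomputed from vertex order when needed. Use [weld_vertices()] to
#' recover shared-vertex topology.
#'
#' A file is treated as ASCII when it begins with `solid` and contains a
#' `facet` token within its first 1024 bytes; otherwise as binary
#' (little-endian, 80-byte header, 50-byte facet records).
#'
#' @param path Path to an STL file.
#' @return A triangle-soup [triangle_mesh()] with `3 * facet_count`
#'   vertices and `facet_count` faces.
#' @export
#' @seealso [write_stl()], [weld_vertices()]
read_stl <- function(path) {
  if (!file.exists(path)) {
    stop_dentalign("dentalign_error_io", sprintf("file not found: %s", path))
  }
  head_raw <- readBin(path, "raw", n = 1024)
  is_ascii <- length(head_raw) >= 5 &&
    identical(head_raw[1:5], charToRaw("solid")) &&
    (length(grepRaw("facet", head_raw)) > 0 ||
       length(grepRaw("endsolid", head_raw)) > 0)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  size <- file.size(path)
  if (size < 84) {
    stop_dentalign(
      "dentalign_error_format",
      sprintf("malformed binary STL '%s': only %d bytes, header needs 84",
              path, size)
    )
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_facets <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(n_facets) || n_facets < 0) {
    stop_dentalign("dentalign_error_format",
                   sprintf("invalid facet count at byte 80 of '%s'", path))
  }
  expected <- 84 + 50 * n_facets
  if (size != expected) {
    stop_dentalign(
      "dentalign_error_format",
      sprintf(paste0("binary STL '%s' declares %d facets (%d bytes expected)",
                     " but has %d bytes; truncation detected at byte %d"),
              path, n_facets, expected, size, min(size, expected))
    )
  }
  if (n_facets == 0) {
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3)))
  }
  rec <- readBin(con, "raw", n = 50 * n_facets)
  dim(rec) <- c(50, n_facets)
  vals <- readBin(as.vector(rec[1:48, ]), "double",
                  n = 12 * n_facets, size = 4, endian = "little")
  vals <- matrix(vals, nrow = 12)          # cols = facets; rows 4:12 vertices
  verts <- matrix(as.vector(vals[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * n_facets), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^[[:space:]]*vertex[[:space:]]", lines)
  if (length(vl) %% 3 != 0) {
    stop_dentalign(
      "dentalign_error_format",
      sprintf("ASCII STL '%s': %d vertex lines (not a multiple of 3); last at line %d",
              path, length(vl), if (length(vl)) max(vl) else 0L)
    )
  }
  n_facets <- length(grep("^[[:space:]]*facet[[:space:]]", lines))
  if (n_facets != length(vl) / 3) {
    stop_dentalign(
      "dentalign_error_format",
      sprintf("ASCII STL '%s': %d facet records but %d vertex triples",
              path, n_facets, length(vl) / 3)
    )
  }
  if (length(vl) == 0) {
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3)))
  }
  toks <- strsplit(trimws(lines[vl]), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad) > 0) {
    stop_dentalign("dentalign_error_format",
                   sprintf("ASCII STL '%s': malformed vertex at line %d",
                           path, vl[bad[1]]))
  }
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3, byrow = TRUE)
  )
  if (anyNA(coords)) {
    bad_row <- which(apply(is.na(coords), 1, any))[1]
    stop_dentalign("dentalign_error_format",
                   sprintf("ASCII STL '%s': non-numeric coordinate at line %d",
                           path, vl[bad_row]))
  }
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  triangle_mesh(coords, faces)
}

#' Write a mesh to STL
#'
#' Facet normals are recomputed from counter-clockwise vertex order; input
#' normals are never reused. Binary output uses little-endian 32-bit float
#' coordinates and 50-byte facet records with a zero attribute byte count,
#' so `read_stl(write_stl(m))` reproduces coordinates bit-exactly once
#' they are in single precision. ASCII output emits 17 significant digits.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  nrm <- face_normals(mesh)
  f <- mesh$faces
  v <- mesh$vertices
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "dentalign binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    if (nrow(f) > 0) {
      vals <- cbind(nrm,
                    v[f[, 1], , drop = FALSE],
                    v[f[, 2], , drop = FALSE],
                    v[f[, 3], , drop = FALSE])   # facets x 12
      fr <- writeBin(as.vector(t(vals)), raw(), size = 4, endian = "little")
      dim(fr) <- c(48, nrow(f))
      rec <- rbind(fr, matrix(as.raw(0), 2, nrow(f)))
      writeBin(as.vector(rec), con)
    }
  } else {
    fmt <- function(x) sprintf("%.17g", x)
    lines <- c("solid dentalign")
    if (nrow(f) > 0) {
      facet_txt <- vapply(seq_len(nrow(f)), function(i) {
        p <- v[f[i, ], , drop = FALSE]
        paste0(
          "  facet normal ", paste(fmt(nrm[i, ]), collapse = " "), "\n",
          "    outer loop\n",
          paste(sprintf("      vertex %s %s %s",
                        fmt(p[, 1]), fmt(p[, 2]), fmt(p[, 3])),
                collapse = "\n"), "\n",
          "    endloop\n",
          "  endfacet"
        )
      }, character(1))
      lines <- c(lines, facet_txt)
    }
    lines <- c(lines, "endsolid dentalign")
    writeLines(lines, path)
  }
  invisible(path)
}
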