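#' Read a triangle mesh
#'
#' Supports PLY (ascii and binary little-endian), OFF, and VTK legacy
#' PolyData (ascii). The format is inferred from the file extension unless
#' given. Faces must be triangles; quad or polygon faces raise an error
#' rather than being implicitly triangulated. Per-vertex scalar attributes
#' present in PLY or VTK files are returned in the `fields` attribute as a
#' named list of length-V numeric vectors.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"off"`, `"vtk"`; default inferred from
#'   the extension.
#' @return A `triangle_mesh`; vertex fields, if any, in `attr(, "fields")`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "off", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", off = "off", vtk = "vtk",
                     stop("cannot infer mesh format from extension of ", path))
  }
  switch(format,
         ply = read_ply(path),
         off = read_off(path),
         vtk = read_vtk_polydata(path))
}

#' Write a triangle mesh
#'
#' Writes PLY (ascii), OFF, or VTK legacy PolyData (ascii). Optional
#' per-vertex scalar fields are written as extra vertex properties (PLY) or
#' `POINT_DATA` arrays (VTK) so that statistic maps open in standard 3D
#' viewers. Coordinates are written with 17 significant digits so that
#' write/read round-trips are exact for doubles.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path; extension selects the format unless given.
#' @param fields named list of length-V numeric vectors, or `NULL`.
#' @param format one of `"ply"`, `"off"`, `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fields = NULL,
                       format = c("auto", "ply", "off", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", off = "off", vtk = "vtk",
                     stop("cannot infer mesh format from extension of ", path))
  }
  validate_mesh(mesh)
  if (!is.null(fields)) {
    stopifnot(is.list(fields), !is.null(names(fields)))
    for (f in fields) stopifnot(length(f) == nrow(mesh$vertices))
  }
  switch(format,
         ply = write_ply(mesh, path, fields),
         off = write_off(mesh, path),
         vtk = write_vtk_polydata(mesh, path, fields))
  invisible(path)
}

num17 <- function(x) formatC(x, format = "g", digits = 17)

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()  # list of list(name, count, props = data.frame(type, name, list_count_type, list_item_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header truncated in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(kind = "list", count_type = tok[3L], item_type = tok[4L],
               name = tok[5L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(kind = "scalar", type = tok[2L], name = tok[3L])
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY file missing format line: ", path)
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format '", fmt, "' in ", path)
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("PLY file lacks vertex or face element: ", path)
  }
  parsed <- if (fmt == "ascii") {
    read_ply_ascii(con, elements)
  } else {
    read_ply_binary(con, elements)
  }
  vp <- elements$vertex$props
  vnames <- vapply(vp, `[[`, "", "name")
  need <- match(c("x", "y", "z"), vnames)
  if (anyNA(need)) stop("PLY vertex element lacks x/y/z in ", path)
  verts <- parsed$vertex[, need, drop = FALSE]
  extra <- setdiff(seq_along(vnames), need)
  fields <- NULL
  if (length(extra)) {
    fields <- lapply(extra, function(i) parsed$vertex[, i])
    names(fields) <- vnames[extra]
  }
  mesh <- triangle_mesh(verts, parsed$faces + 1L)
  if (!is.null(fields)) attr(mesh, "fields") <- fields
  mesh
}

ply_type_size <- function(type) {
  switch(type,
         char = , uchar = , int8 = , uint8 = 1L,
         short = , ushort = , int16 = , uint16 = 2L,
         int = , uint = , int32 = , uint32 = , float = , float32 = 4L,
         double = , float64 = 8L,
         stop("unknown PLY type: ", type))
}

ply_read_what <- function(type) {
  # returns list(what, size, signed)
  switch(type,
         char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
         float = , float32 = list(what = "double", size = 4L, signed = TRUE),
         double = , float64 = list(what = "double", size = 8L, signed = TRUE),
         stop("unknown PLY type: ", type))
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      rows <- txt[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      m <- matrix(scan(text = rows, quiet = TRUE), nrow = el$count,
                  byrow = TRUE)
      if (ncol(m) != length(el$props)) {
        stop("PLY vertex row has wrong number of values")
      }
      out$vertex <- m
    } else if (el$name == "face") {
      rows <- txt[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      fl <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
      counts <- vapply(fl, `[[`, 0, 1L)
      if (any(counts != 3)) {
        stop(sprintf("face %d has %d vertices; only triangles supported",
                     which(counts != 3)[1L], counts[counts != 3][1L]))
      }
      out$faces <- matrix(unlist(lapply(fl, `[`, 2:4)), ncol = 3L,
                          byrow = TRUE)
    } else {
      pos <- pos + el$count  # skip unknown elements (one line each)
    }
  }
  out$faces <- matrix(as.integer(out$faces), ncol = 3L)
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      kinds <- vapply(el$props, `[[`, "", "kind")
      if (any(kinds != "scalar")) stop("list property in PLY vertex element")
      rws <- lapply(el$props, function(p) ply_read_what(p$type))
      m <- matrix(0, el$count, length(rws))
      # row-wise layout: read the full block then slice per property
      sizes <- vapply(rws, `[[`, 0L, "size")
      rowsize <- sum(sizes)
      raw <- readBin(con, "raw", n = rowsize * el$count)
      off <- c(0L, cumsum(sizes))
      for (j in seq_along(rws)) {
        idx <- as.vector(outer(seq_len(sizes[j]) + off[j],
                               (seq_len(el$count) - 1L) * rowsize, `+`))
        m[, j] <- readBin(raw[idx], rws[[j]]$what, n = el$count,
                          size = rws[[j]]$size, signed = rws[[j]]$signed,
                          endian = "little")
      }
      out$vertex <- m
    } else if (el$name == "face") {
      p <- el$props[[1L]]
      if (p$kind != "list") stop("PLY face element lacks list property")
      cw <- ply_read_what(p$count_type)
      iw <- ply_read_what(p$item_type)
      faces <- matrix(0L, el$count, 3L)
      for (i in seq_len(el$count)) {
        cnt <- readBin(con, cw$what, n = 1L, size = cw$size,
                       signed = cw$signed, endian = "little")
        if (cnt != 3L) {
          stop(sprintf("face %d has %d vertices; only triangles supported",
                       i, cnt))
        }
        faces[i, ] <- as.integer(readBin(con, iw$what, n = 3L, size = iw$size,
                                         signed = iw$signed,
                                         endian = "little"))
      }
      out$faces <- faces
    }
  }
  out
}

write_ply <- function(mesh, path, fields = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z")
  if (!is.null(fields)) {
    hdr <- c(hdr, sprintf("property double %s", names(fields)))
  }
  hdr <- c(hdr,
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  vm <- v
  if (!is.null(fields)) vm <- cbind(vm, do.call(cbind, fields))
  vrows <- apply(vm, 1L, function(r) paste(num17(r), collapse = " "))
  writeLines(vrows, con)
  frows <- paste("3", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(frows, con)
  invisible(path)
}

## ---- OFF ----

read_off <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
  if (!identical(trimws(txt[1L]), "OFF")) stop("not an OFF file: ", path)
  counts <- scan(text = txt[2L], quiet = TRUE)
  nv <- counts[1L]
  nf <- counts[2L]
  verts <- matrix(scan(text = txt[3:(2 + nv)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  frows <- lapply(strsplit(trimws(txt[(3 + nv):(2 + nv + nf)]), "\\s+"),
                  as.numeric)
  fc <- vapply(frows, `[[`, 0, 1L)
  if (any(fc != 3)) {
    stop(sprintf("face %d has %d vertices; only triangles supported",
                 which(fc != 3)[1L], fc[fc != 3][1L]))
  }
  faces <- matrix(as.integer(unlist(lapply(frows, `[`, 2:4))), ncol = 3L,
                  byrow = TRUE)
  triangle_mesh(verts, faces + 1L)
}

write_off <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c("OFF",
             sprintf("%d %d 0", nrow(v), nrow(f)),
             apply(v, 1L, function(r) paste(num17(r), collapse = " ")),
             paste("3", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L))
  writeLines(lines, path)
  invisible(path)
}

## ---- VTK legacy PolyData (ascii) ----

read_vtk_polydata <- function(path) {
  txt <- readLines(path)
  if (!grepl("^# vtk DataFile", txt[1L])) stop("not a VTK legacy file: ", path)
  if (!any(grepl("^DATASET\\s+POLYDATA", txt, ignore.case = TRUE))) {
    stop("VTK file is not POLYDATA: ", path)
  }
  toks <- strsplit(trimws(txt), "\\s+")
  i_pts <- which(vapply(toks, function(t) length(t) > 0 && t[1L] == "POINTS",
                        TRUE))
  if (!length(i_pts)) stop("VTK file lacks POINTS: ", path)
  np <- as.integer(toks[[i_pts]][2L])
  vals <- numeric(0)
  i <- i_pts + 1L
  while (length(vals) < 3L * np) {
    vals <- c(vals, as.numeric(toks[[i]]))
    i <- i + 1L
  }
  verts <- matrix(vals[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  i_poly <- which(vapply(toks, function(t) length(t) > 0 &&
                           t[1L] == "POLYGONS", TRUE))
  if (!length(i_poly)) stop("VTK file lacks POLYGONS: ", path)
  nf <- as.integer(toks[[i_poly]][2L])
  faces <- matrix(0L, nf, 3L)
  i <- i_poly + 1L
  for (k in seq_len(nf)) {
    row <- as.integer(toks[[i]])
    if (row[1L] != 3L) {
      stop(sprintf("polygon %d has %d vertices; only triangles supported",
                   k, row[1L]))
    }
    faces[k, ] <- row[2:4]
    i <- i + 1L
  }
  fields <- list()
  i_pd <- which(vapply(toks, function(t) length(t) > 0 &&
                         t[1L] == "POINT_DATA", TRUE))
  if (length(i_pd)) {
    i <- i_pd + 1L
    while (i <= length(toks)) {
      t <- toks[[i]]
      if (length(t) == 0L) { i <- i + 1L; next }
      if (t[1L] == "SCALARS") {
        nm <- t[2L]
        i <- i + 1L  # LOOKUP_TABLE line
        vals <- numeric(0)
        i <- i + 1L
        while (length(vals) < np && i <= length(toks)) {
          vals <- c(vals, as.numeric(toks[[i]]))
          i <- i + 1L
        }
        fields[[nm]] <- vals
      } else if (t[1L] == "FIELD") {
        narr <- as.integer(t[3L])
        i <- i + 1L
        for (a in seq_len(narr)) {
          nm <- toks[[i]][1L]
          ntot <- as.integer(toks[[i]][2L]) * as.integer(toks[[i]][3L])
          i <- i + 1L
          vals <- numeric(0)
          while (length(vals) < ntot && i <= length(toks)) {
            vals <- c(vals, as.numeric(toks[[i]]))
            i <- i + 1L
          }
          fields[[nm]] <- vals
        }
      } else i <- i + 1L
    }
  }
  mesh <- triangle_mesh(verts, faces + 1L)
  if (length(fields)) attr(mesh, "fields") <- fields
  mesh
}

write_vtk_polydata <- function(mesh, path, fields = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "surface mesh with per-vertex statistics",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1L, function(r) paste(num17(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste("3", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  if (!is.null(fields) && length(fields)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    writeLines(sprintf("FIELD per_vertex %d", length(fields)), con)
    for (nm in names(fields)) {
      writeLines(sprintf("%s 1 %d double", nm, nrow(v)), con)
      writeLines(paste(num17(fields[[nm]]), collapse = " "), con)
    }
  }
  invisible(path)
}
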