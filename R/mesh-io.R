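#' Read a triangle mesh from PLY, STL or OFF
#'
#' Accepts ASCII and binary little-endian PLY, ASCII and binary STL, and
#' ASCII OFF. Faces with more than three vertices are fan-triangulated.
#' Vertex order is preserved as stored in the file.
#'
#' @param path path to the mesh file.
#' @param format one of `"auto"` (default, from the file extension and
#'   magic bytes), `"ply"`, `"stl"`, `"off"`.
#' @return a [trimesh]. PLY per-vertex/per-face `quality`-style scalar
#'   properties are attached as attributes `vertex_scalars` / `face_scalars`
#'   (named lists of numeric vectors).
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl", "off")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", stl = "stl", off = "off", {
      head <- readBin(path, "raw", 4L)
      if (identical(rawToChar(head[1:3]), "ply")) "ply"
      else if (identical(rawToChar(head[1:3]), "OFF")) "off"
      else "stl"
    })
  }
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         off = read_off(path))
}

#' Write a triangle mesh to PLY, STL or OFF
#'
#' PLY output (ASCII) can embed named per-vertex and per-face scalar fields
#' as float properties, plus an 8-bit grey colour ramp derived from the first
#' vertex field, so metric maps (DNE, OPC bins, PCV) can be inspected in any
#' mesh viewer. STL and OFF carry geometry only; requesting scalars there
#' drops them with a warning.
#'
#' @param mesh a [trimesh].
#' @param path output path.
#' @param format `"ply"` (default), `"stl"` or `"off"`.
#' @param vertex_scalars named list of numeric vectors, one value per vertex.
#' @param face_scalars named list of numeric vectors, one value per face.
#' @param binary write binary PLY/STL instead of ASCII.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "stl", "off"),
                       vertex_scalars = NULL, face_scalars = NULL,
                       binary = FALSE) {
  stopifnot_trimesh(mesh)
  format <- match.arg(format)
  chk <- function(fields, n, what) {
    if (is.null(fields)) return(invisible())
    if (is.null(names(fields)) || any(!nzchar(names(fields))))
      stop(what, " scalar fields must have non-empty names")
    for (nm in names(fields))
      if (length(fields[[nm]]) != n)
        stop(what, " scalar '", nm, "' has length ", length(fields[[nm]]),
             ", expected ", n)
  }
  chk(vertex_scalars, nrow(mesh$vertices), "vertex")
  chk(face_scalars, nrow(mesh$faces), "face")
  if (format != "ply" && (!is.null(vertex_scalars) || !is.null(face_scalars))) {
    warning(toupper(format), " carries no scalar fields; writing geometry only")
    vertex_scalars <- face_scalars <- NULL
  }
  switch(format,
         ply = write_ply(mesh, path, vertex_scalars, face_scalars, binary),
         stl = write_stl(mesh, path, binary),
         off = write_off(mesh, path))
  invisible(path)
}

## ---- PLY -------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  line1 <- read_hdr_line(con)
  if (!identical(line1, "ply")) stop("not a PLY file (missing 'ply' magic): ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props=list(name,type,islist,count_type,item_type))
  cur <- NULL
  repeat {
    ln <- read_hdr_line(con)
    if (is.null(ln)) stop("PLY header ended prematurely (no end_header)")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format: ", fmt)
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before any element")
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], islist = TRUE, count_type = tok[3], item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], islist = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else stop("unrecognised PLY header line: ", ln)
  }
  if (is.null(fmt)) stop("PLY header missing format line")
  if (is.null(elements$vertex) || elements$vertex$count == 0L)
    stop("empty mesh: PLY has no vertices")
  dat <- if (fmt == "ascii") read_ply_ascii(con, elements)
         else read_ply_binary(con, elements)
  v <- dat$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% names(v))) stop("PLY vertex element lacks x/y/z properties")
  verts <- cbind(v$x, v$y, v$z)
  if (is.null(dat$face)) stop("empty mesh: PLY has no faces")
  fl <- dat$face$vertex_indices
  if (is.null(fl)) fl <- dat$face$vertex_index
  if (is.null(fl)) stop("PLY face element lacks a vertex index list")
  faces <- triangulate_fans(fl)
  mesh <- trimesh(verts, faces + 1L)
  vs <- v[setdiff(names(v), c("x", "y", "z", "nx", "ny", "nz",
                              "red", "green", "blue", "alpha"))]
  if (length(vs)) attr(mesh, "vertex_scalars") <- vs
  if (!is.null(dat$face)) {
    fs <- dat$face[setdiff(names(dat$face),
                           c("vertex_indices", "vertex_index",
                             "red", "green", "blue", "alpha"))]
    if (length(fs)) attr(mesh, "face_scalars") <- fs
  }
  if (all(c("nx", "ny", "nz") %in% names(v)))
    mesh$normals <- cbind(v$nx, v$ny, v$nz)
  mesh
}

read_hdr_line <- function(con) {
  chars <- character(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) return(NULL)
    if (b == as.raw(10L)) break
    if (b != as.raw(13L)) chars <- c(chars, rawToChar(b))
  }
  paste(chars, collapse = "")
}

ply_rtype <- function(t) {
  switch(t,
         char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
         float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
         double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
         stop("unknown PLY type: ", t))
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    rows <- txt[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    toks <- strsplit(trimws(rows), "\\s+")
    if (any(vapply(toks, length, 1L) <
            length(el$props) - sum(vapply(el$props, `[[`, TRUE, "islist"))))
      stop("PLY ", el$name, " element row too short")
    cols <- list()
    if (any(vapply(el$props, `[[`, TRUE, "islist"))) {
      # generic row-wise parse (lists have per-row lengths)
      lists <- list(); scal <- list()
      for (p in el$props) if (p$islist) lists[[p$name]] <- vector("list", el$count)
        else scal[[p$name]] <- numeric(el$count)
      for (i in seq_len(el$count)) {
        x <- as.numeric(toks[[i]])
        j <- 1L
        for (p in el$props) {
          if (p$islist) {
            k <- as.integer(x[j])
            lists[[p$name]][[i]] <- as.integer(x[(j + 1L):(j + k)])
            j <- j + 1L + k
          } else { scal[[p$name]][i] <- x[j]; j <- j + 1L }
        }
      }
      cols <- c(lists, scal)
    } else {
      x <- matrix(as.numeric(unlist(toks)), nrow = el$count, byrow = TRUE)
      for (j in seq_along(el$props)) cols[[el$props[[j]]$name]] <- x[, j]
    }
    out[[el$name]] <- cols
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    haslist <- any(vapply(el$props, `[[`, TRUE, "islist"))
    cols <- list()
    if (!haslist) {
      sizes <- vapply(el$props, function(p) ply_rtype(p$type)$size, 1L)
      # read row-wise to honour mixed types
      for (p in el$props) cols[[p$name]] <- numeric(el$count)
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          rt <- ply_rtype(p$type)
          cols[[p$name]][i] <- readBin(con, rt$what, 1L, size = rt$size,
                                       signed = rt$signed, endian = "little")
        }
      }
    } else {
      for (p in el$props) cols[[p$name]] <- if (p$islist) vector("list", el$count)
                                            else numeric(el$count)
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (p$islist) {
            ct <- ply_rtype(p$count_type); it <- ply_rtype(p$item_type)
            k <- readBin(con, ct$what, 1L, size = ct$size,
                         signed = ct$signed, endian = "little")
            cols[[p$name]][[i]] <- as.integer(
              readBin(con, it$what, k, size = it$size,
                      signed = it$signed, endian = "little"))
          } else {
            rt <- ply_rtype(p$type)
            cols[[p$name]][i] <- readBin(con, rt$what, 1L, size = rt$size,
                                         signed = rt$signed, endian = "little")
          }
        }
      }
    }
    out[[el$name]] <- cols
  }
  out
}

# list of 0-based index vectors -> m x 3 0-based matrix (fan triangulation)
triangulate_fans <- function(fl) {
  ns <- vapply(fl, length, 1L)
  if (any(ns < 3L)) stop("PLY face with fewer than 3 vertices")
  tri <- vapply(fl[ns == 3L], identity, integer(3L))
  tri <- if (length(tri)) t(tri) else matrix(integer(0), 0, 3)
  if (any(ns > 3L)) {
    extra <- do.call(rbind, lapply(fl[ns > 3L], function(ix) {
      cbind(ix[1L], ix[-c(1L, length(ix))], ix[-(1:2)])
    }))
    tri <- rbind(tri, extra)
  }
  tri
}

write_ply <- function(mesh, path, vertex_scalars, face_scalars, binary) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v); nf <- nrow(f)
  grey <- NULL
  if (!is.null(vertex_scalars) && length(vertex_scalars)) {
    s <- vertex_scalars[[1L]]
    rng <- range(s, finite = TRUE)
    grey <- if (diff(rng) > 0) as.integer(round(255 * (s - rng[1]) / diff(rng)))
            else rep(128L, nv)
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment molartopo mesh",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(vertex_scalars))
    hdr <- c(hdr, sprintf("property float %s", names(vertex_scalars)))
  if (!is.null(grey))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  if (!is.null(face_scalars))
    hdr <- c(hdr, sprintf("property float %s", names(face_scalars)))
  hdr <- c(hdr, "end_header")
  if (!binary) {
    vrows <- apply(v, 1L, function(r) paste(sprintf("%.9g", r), collapse = " "))
    if (!is.null(vertex_scalars))
      for (nm in names(vertex_scalars))
        vrows <- paste(vrows, sprintf("%.9g", vertex_scalars[[nm]]))
    if (!is.null(grey)) vrows <- paste(vrows, grey, grey, grey)
    frows <- sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
    if (!is.null(face_scalars))
      for (nm in names(face_scalars))
        frows <- paste(frows, sprintf("%.9g", face_scalars[[nm]]))
    writeLines(c(hdr, vrows, frows), path)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    for (i in seq_len(nv)) {
      writeBin(as.numeric(v[i, ]), con, size = 4L, endian = "little")
      if (!is.null(vertex_scalars))
        for (nm in names(vertex_scalars))
          writeBin(as.numeric(vertex_scalars[[nm]][i]), con, size = 4L,
                   endian = "little")
      if (!is.null(grey))
        writeBin(as.raw(rep(grey[i], 3L)), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      if (!is.null(face_scalars))
        for (nm in names(face_scalars))
          writeBin(as.numeric(face_scalars[[nm]][i]), con, size = 4L,
                   endian = "little")
    }
  }
  invisible(path)
}

## ---- STL -------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", min(80L, sz))
  is_ascii <- identical(tolower(rawToChar(head[1:5])), "solid")
  if (is_ascii && sz >= 84L) {
    # a binary STL may still start with "solid": check the triangle count
    nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (84L + 50 * as.numeric(nt) == sz) is_ascii <- FALSE
  }
  close(con); on.exit(NULL)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L) stop("empty mesh: ASCII STL has no vertices")
  if (length(vl) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3")
  xyz <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(tok) as.numeric(tok[2:4]), numeric(3L)))
  stl_weld(xyz)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(nt) || nt < 1L) stop("empty mesh: binary STL has no triangles")
  # records interleave 12 floats with a 2-byte attribute; read per-triangle
  xyz <- matrix(0, nt * 3L, 3L)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    xyz[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  stl_weld(xyz)
}

# weld duplicated soup vertices back into an indexed mesh
stl_weld <- function(xyz) {
  key <- apply(xyz, 1L, function(r) paste(sprintf("%.9g", r), collapse = ","))
  uid <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  bad <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
         faces[, 1L] == faces[, 3L]
  faces <- faces[!bad, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: STL contains only degenerate triangles")
  trimesh(verts, faces)
}

write_stl <- function(mesh, path, binary) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)
  if (!binary) {
    con <- file(path, "w"); on.exit(close(con))
    cat("solid molartopo\n", file = con)
    for (i in seq_len(nrow(f))) {
      cat(sprintf("facet normal %.9g %.9g %.9g\n  outer loop\n", fn[i, 1],
                  fn[i, 2], fn[i, 3]), file = con)
      for (k in 1:3)
        cat(sprintf("    vertex %.9g %.9g %.9g\n", v[f[i, k], 1],
                    v[f[i, k], 2], v[f[i, k], 3]), file = con)
      cat("  endloop\nendfacet\n", file = con)
    }
    cat("endsolid molartopo\n", file = con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  }
  invisible(path)
}

## ---- OFF -------------------------------------------------------------

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
  if (!grepl("^OFF", txt[1])) stop("not an OFF file: ", path)
  txt <- txt[-1L]
  hdr <- as.integer(strsplit(trimws(txt[1]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  if (is.na(nv) || nv < 1L) stop("empty mesh: OFF has no vertices")
  verts <- matrix(as.numeric(unlist(strsplit(trimws(txt[2:(1 + nv)]), "\\s+"))),
                  nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- lapply(strsplit(trimws(txt[(2 + nv):(1 + nv + nf)]), "\\s+"),
               function(tok) as.integer(tok[2:(1 + as.integer(tok[1]))]))
  trimesh(verts, triangulate_fans(fl) + 1L)
}

write_off <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  lines <- c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
             apply(v, 1L, function(r) paste(sprintf("%.9g", r), collapse = " ")),
             sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L))
  writeLines(lines, path)
  invisible(path)
}
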