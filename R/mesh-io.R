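#' Read and write triangle meshes (OBJ, STL, PLY)
#'
#' Minimal readers/writers for the three interchange formats used by the
#' conch pipeline. OBJ and PLY are ASCII; STL is written in ASCII by default
#' and read in either ASCII or binary form (autodetected). Vertex indices are
#' 1-based on disk (OBJ convention) and in memory. STL files carry no
#' connectivity, so reading STL re-welds coincident vertices exactly.
#'
#' @param path file path; format inferred from the extension
#'   (`.obj`, `.stl`, `.ply`).
#' @param mesh a [tri_mesh()].
#' @param binary for STL output, write the 80-byte-header binary form.
#' @return `read_mesh()` returns a [tri_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(mesh, path),
         stl = if (binary) write_stl_binary(mesh, path) else
           write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  tri_mesh(v, f, name = sub("\\.obj$", "", basename(path), ignore.case = TRUE))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

weld_vertices <- function(v, f) {
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- !duplicated(key)
  id <- match(key, key[first])
  tri_mesh(v[first, , drop = FALSE],
           matrix(id[f], ncol = 3))
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 5L)
  if (identical(rawToChar(hdr), "solid") && is_ascii_stl(path))
    read_stl_ascii(path) else read_stl_binary(path)
}

is_ascii_stl <- function(path) {
  # binary STL can also start with "solid"; check for "facet" in the head
  txt <- tryCatch(suppressWarnings(readLines(path, n = 10L, warn = FALSE)),
                  error = function(e) character(0))
  any(grepl("facet", txt, fixed = TRUE))
}

read_stl_ascii <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  vl <- ln[startsWith(ln, "vertex")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  weld_vertices(v, matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n = nf * 50L)
  m <- matrix(rec, nrow = 50L)
  vals <- readBin(as.vector(m[1:48, ]), "numeric", n = 12L * nf, size = 4L,
                  endian = "little")
  vals <- matrix(vals, ncol = 12L, byrow = TRUE) # normal, v1, v2, v3
  v <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
             vals[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * nf), ncol = 3L))) # interleave
  v <- v[ord, , drop = FALSE]
  weld_vertices(v, matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE))
}

stl_facets <- function(mesh) {
  fc <- face_corners(mesh)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(n^2))
  n <- n / pmax(len, 1e-300)
  list(n = n, fc = fc)
}

write_stl_ascii <- function(mesh, path) {
  s <- stl_facets(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  nm <- if (is.null(mesh$name)) "mesh" else mesh$name
  writeLines(paste("solid", nm), con)
  body <- paste0(
    sprintf("facet normal %.9g %.9g %.9g\n", s$n[, 1], s$n[, 2], s$n[, 3]),
    "outer loop\n",
    sprintf("vertex %.9g %.9g %.9g\n", s$fc$a[, 1], s$fc$a[, 2], s$fc$a[, 3]),
    sprintf("vertex %.9g %.9g %.9g\n", s$fc$b[, 1], s$fc$b[, 2], s$fc$b[, 3]),
    sprintf("vertex %.9g %.9g %.9g\n", s$fc$c[, 1], s$fc$c[, 2], s$fc$c[, 3]),
    "endloop\nendfacet")
  writeLines(body, con)
  writeLines(paste("endsolid", nm), con)
}

write_stl_binary <- function(mesh, path) {
  s <- stl_facets(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(nrow(mesh$faces), con, size = 4L, endian = "little")
  dat <- cbind(s$n, s$fc$a, s$fc$b, s$fc$c)
  for (i in seq_len(nrow(dat))) {
    writeBin(as.numeric(dat[i, ]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!identical(trimws(ln[1]), "ply")) stop("not a PLY file")
  endh <- which(trimws(ln) == "end_header")[1]
  hdr <- ln[seq_len(endh)]
  if (!any(grepl("format ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  vl <- ln[(endh + 1L):(endh + nv)]
  fl <- ln[(endh + nv + 1L):(endh + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    if (as.integer(x[1]) != 3L) stop("non-triangular PLY face")
    as.integer(x[2:4]) + 1L
  }))
  tri_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}
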