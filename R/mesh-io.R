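#' Read a triangular surface mesh from STL, PLY or OBJ
#'
#' Formats: STL (binary or ASCII, autodetected), PLY (ASCII) and OBJ
#' (vertices and triangular faces). Coordinates are taken as millimetres in
#' the patient frame; none of these formats carries unit metadata. The mesh
#' is validated on read: duplicate vertices merged (1e-6 mm), closedness
#' checked, winding repaired to consistent outward normals.
#'
#' @param path file path; format inferred from the extension
#'   (`.stl`, `.ply`, `.obj`).
#' @param label organ label to attach (e.g. `"cervix"`).
#' @param max_vertices optional warning threshold passed to [validate_mesh()].
#' @return A validated [tri_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, label = NULL, max_vertices = NULL) {
  if (!file.exists(path))
    stop(sprintf("mesh file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  raw_mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop(sprintf("unsupported mesh format '.%s' (need .stl, .ply or .obj)", ext),
         call. = FALSE)
  )
  m <- tri_mesh(raw_mesh$vertices, raw_mesh$faces, label = label, validate = FALSE)
  validate_mesh(m, max_vertices = max_vertices)
}

#' Write a mesh to STL, PLY or OBJ
#'
#' STL is written as ASCII. Round-tripping through [read_mesh()] reproduces
#' vertex positions within 1e-5 mm and the same face topology (STL stores a
#' facet soup, so vertex order after re-reading follows first occurrence).
#'
#' @param mesh a validated [tri_mesh()].
#' @param path output file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; default inferred from
#'   the extension of `path`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(is_tri_mesh(mesh))
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("refusing to write an empty mesh", call. = FALSE)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply", "obj"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  switch(format,
    stl = write_stl_ascii(mesh, con),
    ply = write_ply_ascii(mesh, con),
    obj = write_obj(mesh, con)
  )
  invisible(path)
}

# ---- STL ------------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count + 50 bytes per facet
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 84)
  close(con)
  is_binary <- FALSE
  if (length(head) == 84) {
    n_tri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(n_tri) && n_tri > 0 && sz == 84 + 50 * n_tri) is_binary <- TRUE
  }
  if (is_binary) return(read_stl_binary(path))
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop(sprintf("'%s' is not a readable STL file (no facet vertices found)", path),
         call. = FALSE)
  nums <- strsplit(trimws(vl), "\\s+")
  V <- t(vapply(nums, function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(V))
    stop(sprintf("'%s': malformed vertex coordinates in ASCII STL", path),
         call. = FALSE)
  k <- nrow(V) / 3
  F <- matrix(seq_len(3 * k), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  k <- readBin(con, "integer", size = 4, endian = "little")
  body <- readBin(con, "raw", n = 50 * k)
  if (length(body) < 50 * k)
    stop(sprintf("'%s': truncated binary STL", path), call. = FALSE)
  m <- matrix(body, nrow = 50)
  tri <- apply(m, 2, function(rec)
    readBin(rec[13:48], "numeric", size = 4, n = 9, endian = "little"))
  V <- matrix(as.numeric(tri), ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(3 * k), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

write_stl_ascii <- function(mesh, con) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  fmt <- function(M) sprintf("%.9g %.9g %.9g", M[, 1], M[, 2], M[, 3])
  lines <- c(
    sprintf("solid %s", mesh$label),
    as.vector(rbind(
      sprintf("  facet normal %s", fmt(n)),
      "    outer loop",
      sprintf("      vertex %s", fmt(a)),
      sprintf("      vertex %s", fmt(b)),
      sprintf("      vertex %s", fmt(c)),
      "    endloop",
      "  endfacet")),
    sprintf("endsolid %s", mesh$label)
  )
  writeLines(lines, con)
}

# ---- PLY (ASCII) ----------------------------------------------------------

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || trimws(txt[1]) != "ply")
    stop(sprintf("'%s' is not a PLY file", path), call. = FALSE)
  hend <- match("end_header", trimws(txt))
  if (is.na(hend))
    stop(sprintf("'%s': PLY header has no end_header", path), call. = FALSE)
  header <- trimws(txt[seq_len(hend)])
  if (any(grepl("^format\\s+binary", header)))
    stop(sprintf("'%s': binary PLY is not supported (write ASCII PLY)", path),
         call. = FALSE)
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex\\s", header, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face\\s", header, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1 || is.na(nv) || is.na(nf))
    stop(sprintf("'%s': PLY header must declare vertex and face elements", path),
         call. = FALSE)
  body <- trimws(txt[(hend + 1):length(txt)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf)
    stop(sprintf("'%s': truncated PLY body", path), call. = FALSE)
  vparts <- strsplit(body[seq_len(nv)], "\\s+")
  V <- t(vapply(vparts, function(x) as.numeric(x[1:3]), numeric(3)))
  fparts <- strsplit(body[nv + seq_len(nf)], "\\s+")
  F <- t(vapply(fparts, function(x) {
    cnt <- as.integer(x[1])
    if (is.na(cnt) || cnt != 3)
      stop(sprintf("'%s': only triangular PLY faces are supported", path),
           call. = FALSE)
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  list(vertices = V, faces = F)
}

write_ply_ascii <- function(mesh, con) {
  V <- mesh$vertices
  F <- mesh$faces - 1L
  writeLines(c(
    "ply",
    "format ascii 1.0",
    sprintf("comment organmatch mesh '%s' (mm, LPS)", mesh$label),
    sprintf("element vertex %d", nrow(V)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(F)),
    "property list uchar int vertex_indices",
    "end_header",
    sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
    sprintf("3 %d %d %d", F[, 1], F[, 2], F[, 3])
  ), con)
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop(sprintf("'%s' is not a readable OBJ file (no v/f records)", path),
         call. = FALSE)
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  F <- t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- x[-1]
    if (length(idx) != 3)
      stop(sprintf("'%s': only triangular OBJ faces are supported", path),
           call. = FALSE)
    as.integer(sub("/.*$", "", idx))
  }, integer(3)))
  list(vertices = V, faces = F)
}

write_obj <- function(mesh, con) {
  V <- mesh$vertices
  F <- mesh$faces
  writeLines(c(
    sprintf("# organmatch mesh '%s' (mm, LPS)", mesh$label),
    sprintf("o %s", mesh$label),
    sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
    sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])
  ), con)
}
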