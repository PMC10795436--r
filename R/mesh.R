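#' Triangular surface mesh in patient coordinates
#'
#' The package's canonical mesh container: an S3 list with an `n x 3` numeric
#' vertex matrix (mm, LPS frame: +x left, +y posterior, +z superior), a
#' `k x 3` integer face matrix of 1-based vertex indices, and an organ label.
#' A validated `tri_mesh` is deduplicated (no two vertices closer than
#' 1e-6 mm), closed (every edge shared by exactly two faces) and consistently
#' wound with outward normals (positive signed volume).
#'
#' @param vertices numeric matrix (n x 3), vertex positions in mm.
#' @param faces integer matrix (k x 3), 1-based vertex indices.
#' @param label organ name, e.g. `"cervix"` or `"uterus"`.
#' @param validate validate (deduplicate, check closedness, repair winding)?
#' @return An object of class `tri_mesh`.
#' @examples
#' cube <- cube_mesh(10)
#' cube
#' mesh_volume(cube)
#' @export
tri_mesh <- function(vertices, faces, label = "organ", validate = TRUE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 3 || nrow(vertices) < 1)
    stop("`vertices` must be a non-empty numeric matrix with 3 columns", call. = FALSE)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  if (ncol(faces) != 3 || nrow(faces) < 1)
    stop("`faces` must be a non-empty matrix with 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (anyNA(vertices) || anyNA(faces))
    stop("mesh contains missing values", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range: every face index must name a vertex", call. = FALSE)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(
    list(vertices = vertices, faces = faces, label = as.character(label)[1]),
    class = "tri_mesh"
  )
  if (validate) m <- validate_mesh(m) else m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %s: %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' @rdname tri_mesh
#' @param x object to test.
#' @export
is_tri_mesh <- function(x) inherits(x, "tri_mesh")

DEDUP_TOL <- 1e-6 # mm

# integer grid keys at the dedup tolerance
vertex_keys <- function(V, tol = DEDUP_TOL) {
  g <- round(V / tol)
  paste(g[, 1], g[, 2], g[, 3], sep = "|")
}

#' Validate a mesh into canonical form
#'
#' Deduplicates vertices (tolerance 1e-6 mm), drops degenerate faces, checks
#' that the surface is closed (every undirected edge shared by exactly two
#' faces), repairs face winding by propagation from a seed face, and orients
#' the surface outward (positive signed volume). Validation is idempotent.
#'
#' @param mesh a [tri_mesh()] (possibly unvalidated).
#' @param max_vertices optional warning threshold on the vertex count;
#'   meshes above it are accepted with a warning (runtime grows with
#'   vertex count).
#' @return The validated `tri_mesh`.
#' @export
validate_mesh <- function(mesh, max_vertices = NULL) {
  V <- mesh$vertices
  F <- mesh$faces

  # -- deduplicate vertices on a 1e-6 mm grid
  keys <- vertex_keys(V)
  first <- !duplicated(keys)
  remap <- match(keys, keys[first])
  V <- V[first, , drop = FALSE]
  F[] <- remap[F]

  # -- drop faces degenerate after merging
  degen <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 3] == F[, 1]
  F <- F[!degen, , drop = FALSE]
  if (nrow(F) < 4)
    stop("mesh has fewer than 4 non-degenerate faces; not a closed surface", call. = FALSE)

  # -- closedness: every undirected edge in exactly two faces
  k <- nrow(F)
  ei <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  und <- cbind(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2]))
  ekey <- paste(und[, 1], und[, 2], sep = "-")
  cnt <- table(ekey)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L][1]
    n_bad <- sum(cnt != 2L)
    kind <- if (cnt[bad] == 1L) "boundary" else "non-manifold"
    stop(sprintf(
      "mesh '%s' is not closed: %s edge between vertices %s (%d defective edge%s)",
      mesh$label, kind, gsub("-", " and ", bad), n_bad, if (n_bad > 1) "s" else ""
    ), call. = FALSE)
  }

  # -- consistent winding: propagate orientation across shared edges
  face_of_edge <- rep(seq_len(k), 3L)
  by_edge <- split(seq_len(3L * k), ekey)
  flip <- rep(NA, k)
  flip[1] <- FALSE
  queue <- 1L
  # directed-edge endpoints per face under current (possibly flipped) winding
  while (length(queue)) {
    f <- queue[[1]]; queue <- queue[-1]
    fe <- c(f, f + k, f + 2L * k) # rows of ei belonging to face f
    for (row in fe) {
      mates <- by_edge[[ekey[row]]]
      other_row <- mates[mates != row]
      g <- face_of_edge[other_row]
      # orientations consistent iff the shared edge runs in opposite
      # directions in the two faces (accounting for flips already applied)
      same_dir <- ei[row, 1] == ei[other_row, 1]
      consistent <- xor(same_dir, TRUE) # opposite direction => consistent
      need_flip <- xor(flip[f], !consistent)
      if (is.na(flip[g])) {
        flip[g] <- need_flip
        queue <- c(queue, g)
      } else if (flip[g] != need_flip) {
        stop(sprintf("mesh '%s' is non-orientable; cannot repair winding",
                     mesh$label), call. = FALSE)
      }
    }
  }
  if (anyNA(flip))
    stop(sprintf("mesh '%s' has %d disconnected face component(s) beyond the first; expected a single closed surface",
                 mesh$label, sum(is.na(flip))), call. = FALSE)
  if (any(flip)) F[flip, ] <- F[flip, c(1, 3, 2), drop = FALSE]

  out <- structure(list(vertices = V, faces = F, label = mesh$label),
                   class = "tri_mesh")

  # -- outward orientation: signed volume must be positive
  if (mesh_volume(out, signed = TRUE) < 0) {
    out$faces <- out$faces[, c(1, 3, 2), drop = FALSE]
  }

  if (!is.null(max_vertices) && nrow(out$vertices) > max_vertices)
    warning(sprintf("mesh '%s' has %d vertices (> %d); expect slower cost evaluations",
                    out$label, nrow(out$vertices), max_vertices), call. = FALSE)
  out
}

#' Mesh volume by the divergence theorem
#'
#' @param mesh a validated [tri_mesh()].
#' @param signed return the signed volume (negative for inward winding)?
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  vol <- sum(
    a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  ) / 6
  if (signed) vol else abs(vol)
}

#' Area-weighted vertex normals
#'
#' Each vertex normal is the normalized sum of incident face normals weighted
#' by face area (the cross-product magnitude carries the area weight).
#'
#' @param mesh a validated [tri_mesh()].
#' @return An `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # 2*area-weighted
  N <- matrix(0, nrow(V), 3)
  for (j in 1:3) {
    N[, 1] <- N[, 1] + unname(tapply_add(fn[, 1], F[, j], nrow(V)))
    N[, 2] <- N[, 2] + unname(tapply_add(fn[, 2], F[, j], nrow(V)))
    N[, 3] <- N[, 3] + unname(tapply_add(fn[, 3], F[, j], nrow(V)))
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

# sum `x` into bins `idx` of length n (faster than tapply for this shape)
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Pooled vertex centroid of one or more meshes
#'
#' Arithmetic mean of all vertices pooled across the given meshes (vertices
#' already deduplicated by validation). This is the centroid the positioning
#' optimizer uses for its initial translational move and rotation center.
#'
#' @param ... one or more [tri_mesh()] objects (or a single list of them).
#' @return A length-3 numeric vector (mm).
#' @export
mesh_centroid <- function(...) {
  meshes <- list(...)
  if (length(meshes) == 1 && !is_tri_mesh(meshes[[1]])) meshes <- meshes[[1]]
  if (length(meshes) == 0) stop("at least one mesh required", call. = FALSE)
  stopifnot(all(vapply(meshes, is_tri_mesh, logical(1))))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  if (nrow(V) == 0) stop("empty mesh", call. = FALSE)
  colMeans(V)
}

#' Canonical axis-aligned cube mesh
#'
#' A closed, outward-wound cube `[0, side]^3` (8 vertices, 12 faces), offset
#' by `origin`. Used throughout the tests and examples as the simplest closed
#' surface with known geometry.
#'
#' @param side edge length in mm.
#' @param origin length-3 offset of the minimum corner.
#' @param label organ label.
#' @return A validated [tri_mesh()].
#' @export
cube_mesh <- function(side = 10, origin = c(0, 0, 0), label = "cube") {
  g <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  V <- sweep(g, 2, as.numeric(origin), `+`)
  # 12 triangles, outward wound for the expand.grid vertex order
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = side
  )
  tri_mesh(V, F, label = label)
}
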