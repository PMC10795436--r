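#' Icosphere mesh
#'
#' Unit sphere obtained by recursive 4-way subdivision of an icosahedron
#' with vertices projected to the sphere. Subdivision levels 0..4 give 12,
#' 42, 162, 642, 2562 vertices.
#'
#' @param subdivision non-negative integer subdivision level.
#' @param radius sphere radius (mm).
#' @param center length-3 center.
#' @param label organ label.
#' @return A validated [tri_mesh()].
#' @export
icosphere <- function(subdivision = 3, radius = 1, center = c(0, 0, 0),
                      label = "sphere") {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(subdivision)) {
    nv <- nrow(V)
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    Vlist <- lapply(seq_len(nv), function(i) V[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (Vlist[[i]] + Vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      Vlist[[length(Vlist) + 1]] <<- m
      idx <- length(Vlist)
      midcache[[key]] <- idx
      idx
    }
    Fnew <- matrix(0L, nrow(F) * 4, 3)
    for (t in seq_len(nrow(F))) {
      a <- F[t, 1]; b <- F[t, 2]; c <- F[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      Fnew[4 * t - 3, ] <- c(a, ab, ca)
      Fnew[4 * t - 2, ] <- c(b, bc, ab)
      Fnew[4 * t - 1, ] <- c(c, ca, bc)
      Fnew[4 * t, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, Vlist)
    F <- Fnew
  }
  V <- sweep(V * radius, 2, as.numeric(center), `+`)
  tri_mesh(V, F, label = label)
}

#' Superellipsoid organ surface
#'
#' A superellipsoid with semi-axes `(a, b, c)` and squareness `eps`
#' (satisfying `|x/a|^(2/eps) + |y/b|^(2/eps) + |z/c|^(2/eps) = 1`),
#' triangulated by radially mapping an icosphere. Squareness below 1 gives
#' a boxier-than-ellipsoid shape, so rotations about the center are
#' observable in the positioning cost (a sphere would make them no-ops).
#'
#' @param semi_axes length-3 positive semi-axes (mm).
#' @param squareness shape exponent `eps` in (0, 2]; 1 is an ellipsoid.
#' @param subdivision icosphere subdivision level.
#' @param center length-3 center (mm).
#' @param label organ label.
#' @return A validated [tri_mesh()].
#' @export
superellipsoid_mesh <- function(semi_axes, squareness = 0.8, subdivision = 3,
                                center = c(0, 0, 0), label = "organ") {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            squareness > 0, squareness <= 2)
  s <- icosphere(subdivision)
  U <- s$vertices # unit directions
  p <- 2 / squareness
  r <- (abs(U[, 1] / semi_axes[1])^p +
        abs(U[, 2] / semi_axes[2])^p +
        abs(U[, 3] / semi_axes[3])^p)^(-1 / p)
  V <- sweep(U * r, 2, as.numeric(center), `+`)
  tri_mesh(V, s$faces, label = label)
}

#' Phantom specification
#'
#' Parameters of the synthetic pelvic phantom: a superellipsoid cervix
#' (default semi-axes 15 x 15 x 20 mm at the origin) with a larger
#' anteverted uterus (default 25 x 20 x 40 mm, long axis tilted 30 degrees
#' anterior from the S-I axis, stacked superior-anterior to the cervix),
#' displaced as one rigid body by a known translation and rotation about
#' the pooled reference centroid, with optional smooth radial shape
#' deformation.
#'
#' When `translation` (or `rotation`) is `NULL` the truth is sampled
#' uniformly per axis: translations within `trans_widths` (default R-L
#' half-width 7.5 mm, A-P and S-I 15 mm, i.e. twice the R-L width,
#' emulating the anisotropy of inter-fraction cervix-uterus motion), and
#' rotations within `rot_ranges` (default pitch in [-6, 14] degrees and
#' yaw, roll in [-1, 1]: pitch-dominant motion biased toward posterior
#' tilt, so the computed corrections -- its inverse -- are dominated by
#' negative pitch, as observed clinically).
#'
#' @param seed integer random seed; fixes the sampled truth and the
#'   deformation field bit-reproducibly.
#' @param translation length-3 LPS truth vector (mm), or `NULL` to sample.
#' @param rotation length-3 truth (pitch, yaw, roll in degrees), or `NULL`
#'   to sample.
#' @param trans_widths per-axis half-widths (mm) for sampled translations.
#' @param rot_ranges list with `pitch`, `yaw`, `roll` ranges (degrees) for
#'   sampled rotations.
#' @param deformation_mm amplitude of the smooth radial deformation applied
#'   to the daily organs (0 = exactly rigid).
#' @param cervix_axes,uterus_axes superellipsoid semi-axes (mm).
#' @param squareness superellipsoid shape exponent.
#' @param subdivision mesh resolution (level 3 gives 642 vertices/organ).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         translation = NULL,
                         rotation = c(0, 0, 0),
                         trans_widths = c(7.5, 15, 15),
                         rot_ranges = list(pitch = c(-6, 14),
                                           yaw = c(-1, 1),
                                           roll = c(-1, 1)),
                         deformation_mm = 0,
                         cervix_axes = c(15, 15, 20),
                         uterus_axes = c(25, 20, 40),
                         squareness = 0.8,
                         subdivision = 3) {
  stopifnot(deformation_mm >= 0, length(trans_widths) == 3)
  if (deformation_mm > 0.2 * min(cervix_axes, uterus_axes))
    stop("deformation amplitude above 20% of the smallest semi-axis risks self-intersection",
         call. = FALSE)
  structure(
    list(seed = as.integer(seed), translation = translation,
         rotation = rotation, trans_widths = trans_widths,
         rot_ranges = rot_ranges, deformation_mm = deformation_mm,
         cervix_axes = cervix_axes, uterus_axes = uterus_axes,
         squareness = squareness, subdivision = as.integer(subdivision)),
    class = "phantom_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth band-limited radial field on directions U (low-order polynomial
# harmonics with random coefficients), scaled to max |f| = amplitude
radial_field <- function(U, amplitude) {
  basis <- cbind(U[, 1], U[, 2], U[, 3],
                 U[, 1] * U[, 2], U[, 2] * U[, 3], U[, 3] * U[, 1],
                 U[, 1]^2 - U[, 2]^2, 3 * U[, 3]^2 - 1)
  coef <- stats::rnorm(ncol(basis))
  f <- as.numeric(basis %*% coef)
  if (max(abs(f)) > 0) f <- f / max(abs(f)) * amplitude
  f
}

deform_mesh <- function(mesh, amplitude, center) {
  D <- sweep(mesh$vertices, 2, center)
  r <- sqrt(rowSums(D^2))
  r[r == 0] <- 1
  U <- D / r
  f <- radial_field(U, amplitude)
  out <- mesh
  out$vertices <- sweep(U * (sqrt(rowSums(D^2)) + f), 2, center, `+`)
  # deformation must not break the closed surface
  if (mesh_volume(out, signed = TRUE) <= 0)
    stop("deformation produced an inverted or self-intersecting surface",
         call. = FALSE)
  out
}

#' Generate a synthetic phantom case
#'
#' Builds the reference cervix/uterus pair, applies the (given or sampled)
#' ground-truth rigid transform to both organs about their pooled centroid,
#' then the optional smooth deformation. Bit-reproducible for a given seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `ref_cervix`, `ref_uterus`, `daily_cervix`,
#'   `daily_uterus` ([tri_mesh()]), and `truth` (the applied
#'   [rigid_transform()]).
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7, translation = c(6, -8, 4),
#'                                 subdivision = 1))
#' ph$truth
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    ref_cervix <- superellipsoid_mesh(
      spec$cervix_axes, spec$squareness, spec$subdivision,
      center = c(0, 0, 0), label = "cervix")
    # anteverted uterus: long axis tilted 30 degrees anterior from S-I
    ut0 <- superellipsoid_mesh(
      spec$uterus_axes, spec$squareness, spec$subdivision,
      center = c(0, 0, 0), label = "uterus")
    tilt <- rigid_transform(pitch = 30, center = c(0, 0, 0))
    ut0 <- apply_transform(ut0, tilt)
    ut_center <- c(0, -17.5, 50)
    ref_uterus <- ut0
    ref_uterus$vertices <- sweep(ut0$vertices, 2, ut_center, `+`)

    trans <- spec$translation %||%
      stats::runif(3, -spec$trans_widths, spec$trans_widths)
    rot <- spec$rotation %||% c(
      stats::runif(1, spec$rot_ranges$pitch[1], spec$rot_ranges$pitch[2]),
      stats::runif(1, spec$rot_ranges$yaw[1], spec$rot_ranges$yaw[2]),
      stats::runif(1, spec$rot_ranges$roll[1], spec$rot_ranges$roll[2])
    )
    center <- mesh_centroid(ref_cervix, ref_uterus)
    truth <- rigid_transform(trans, pitch = rot[1], yaw = rot[2],
                             roll = rot[3], center = center)

    daily_cervix <- apply_transform(ref_cervix, truth)
    daily_uterus <- apply_transform(ref_uterus, truth)
    if (spec$deformation_mm > 0) {
      daily_cervix <- deform_mesh(daily_cervix, spec$deformation_mm,
                                  colMeans(daily_cervix$vertices))
      daily_uterus <- deform_mesh(daily_uterus, spec$deformation_mm,
                                  colMeans(daily_uterus$vertices))
    }
    list(ref_cervix = ref_cervix, ref_uterus = ref_uterus,
         daily_cervix = daily_cervix, daily_uterus = daily_uterus,
         truth = truth)
  })
}

#' Generate a cohort of phantom cases
#'
#' `n_fractions` independent phantom cases with truths sampled under the
#' template spec; per-case seeds are derived deterministically from
#' `seed`, so the cohort is reproducible as a whole.
#'
#' @param n_fractions number of cases (>= 1).
#' @param template a [phantom_spec()]; its `seed` is ignored.
#' @param seed master seed for the cohort.
#' @return A list of `n_fractions` phantom cases (see [make_phantom()]),
#'   each with an added `case_id`.
#' @export
make_cohort <- function(n_fractions, template = phantom_spec(), seed = 1L) {
  stopifnot(n_fractions >= 1)
  case_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_fractions))
  lapply(seq_len(n_fractions), function(i) {
    sp <- template
    sp$seed <- case_seeds[i]
    ph <- make_phantom(sp)
    ph$case_id <- i
    ph
  })
}

#' Write a phantom case to mesh files plus a truth JSON
#'
#' @param phantom a case from [make_phantom()].
#' @param dir output directory (created if needed).
#' @param format mesh format (`"stl"` or `"ply"`).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("stl", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("ref_cervix", "ref_uterus", "daily_cervix", "daily_uterus"))
    write_mesh(phantom[[nm]], file.path(dir, paste0(nm, ".", format)),
               format = format)
  tr <- phantom$truth
  jsonlite::write_json(
    list(translation_mm = tr$translation,
         rotation_deg = list(pitch = tr$pitch, yaw = tr$yaw, roll = tr$roll),
         center_mm = tr$center),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
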