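#' PTV margin specification
#'
#' Six directional margins (R, L, A, P, S, I) in mm per organ. The default
#' anisotropic preset uses (5, 5, 15, 15, 10, 10) mm for the cervix and
#' (10, 10, 20, 20, 15, 15) mm for the uterus (cervix margins 5 mm smaller
#' than the uterine ones); the isotropic preset uses 5 mm everywhere.
#'
#' @param cervix,uterus named or positional length-6 numeric vectors of
#'   non-negative margins in the order R, L, A, P, S, I (mm).
#' @return An object of class `margin_spec`.
#' @examples
#' margin_preset("aniso")
#' @export
margin_spec <- function(cervix, uterus) {
  fix <- function(m, organ) {
    m <- as.numeric(m)
    if (length(m) == 1) m <- rep(m, 6)
    if (length(m) != 6 || anyNA(m) || any(m < 0))
      stop(sprintf("%s margins must be 6 non-negative numbers (R, L, A, P, S, I)",
                   organ), call. = FALSE)
    stats::setNames(m, c("R", "L", "A", "P", "S", "I"))
  }
  structure(list(cervix = fix(cervix, "cervix"), uterus = fix(uterus, "uterus")),
            class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  cat("<margin_spec> (R, L, A, P, S, I) mm\n")
  cat(sprintf("  cervix: (%s)\n", paste(x$cervix, collapse = ", ")))
  cat(sprintf("  uterus: (%s)\n", paste(x$uterus, collapse = ", ")))
  invisible(x)
}

#' @rdname margin_spec
#' @param name `"iso"` (isotropic 5 mm, alias `"ptv_iso_5mm"`) or
#'   `"aniso"` (the direction-dependent default, alias `"ptv_aniso"`).
#' @export
margin_preset <- function(name) {
  name <- as.character(name)[1]
  switch(name,
    iso = , ptv_iso_5mm = margin_spec(cervix = rep(5, 6), uterus = rep(5, 6)),
    aniso = , ptv_aniso = margin_spec(cervix = c(5, 5, 15, 15, 10, 10),
                                      uterus = c(10, 10, 20, 20, 15, 15)),
    stop(sprintf("unknown margin preset '%s'; valid: iso, aniso", name),
         call. = FALSE)
  )
}

#' Read a margin spec from a YAML or JSON config file
#'
#' The file either names a preset (`preset: aniso`) or gives `cervix:` and
#' `uterus:` as six numbers each in R, L, A, P, S, I order.
#'
#' @param path config file path.
#' @return A [margin_spec()].
#' @export
read_margins <- function(path) {
  cfg <- read_config(path)
  if (!is.null(cfg$preset)) return(margin_preset(cfg$preset))
  if (is.null(cfg$cervix) || is.null(cfg$uterus))
    stop(sprintf("'%s' must give `preset` or both `cervix` and `uterus`", path),
         call. = FALSE)
  margin_spec(unlist(cfg$cervix), unlist(cfg$uterus))
}

#' Expand a reference organ mesh by directional margins
#'
#' Each vertex is displaced outward along its area-weighted unit normal
#' `n` by `||(m_x n_x, m_y n_y, m_z n_z)||`, where `m_x` is the R margin
#' if `n_x < 0` else the L margin, `m_y` the A margin if `n_y < 0` else P,
#' and `m_z` the I margin if `n_z < 0` else S (LPS frame). For an
#' isotropic spec this is a uniform normal offset by the margin. The
#' result is re-validated as a closed surface.
#'
#' @param reference a validated, closed [tri_mesh()].
#' @param margins length-6 named margins for this organ (R, L, A, P, S, I)
#'   or a single number for isotropic expansion.
#' @return The expanded [tri_mesh()].
#' @export
expand_mesh <- function(reference, margins) {
  check_reference(reference)
  m <- as.numeric(margins)
  if (length(m) == 1) m <- rep(m, 6)
  stopifnot(length(m) == 6, all(m >= 0))
  names(m) <- c("R", "L", "A", "P", "S", "I")
  N <- vertex_normals(reference)
  mx <- ifelse(N[, 1] < 0, m[["R"]], m[["L"]])
  my <- ifelse(N[, 2] < 0, m[["A"]], m[["P"]])
  mz <- ifelse(N[, 3] < 0, m[["I"]], m[["S"]])
  mag <- sqrt((mx * N[, 1])^2 + (my * N[, 2])^2 + (mz * N[, 3])^2)
  out <- reference
  out$vertices <- reference$vertices + N * mag
  out$label <- paste0("ptv_", reference$label)
  # vertex displacement preserves topology; re-check the closed-surface
  # invariant (a self-intersecting expansion of a highly concave organ
  # could invert volume)
  if (!is_closed_mesh(out) || mesh_volume(out, signed = TRUE) <= 0)
    stop("margin expansion broke the closed-surface invariant", call. = FALSE)
  out
}

#' Build a planning target volume from the two reference organs
#'
#' Expands each reference organ by its margins and returns the PTV as a
#' containment predicate: a point is inside the PTV iff it is inside
#' either expanded organ surface. An advisory export mesh containing both
#' expanded components is included (the overlay of the two closed
#' components, not a boolean union; coverage never uses it).
#'
#' @param ref_cervix,ref_uterus reference organ meshes (closed).
#' @param spec a [margin_spec()].
#' @return An object of class `ptv`: `expanded_cervix`, `expanded_uterus`,
#'   `contains(points)` predicate, and `union_mesh` for export.
#' @export
build_ptv <- function(ref_cervix, ref_uterus, spec) {
  stopifnot(inherits(spec, "margin_spec"))
  ec <- expand_mesh(ref_cervix, spec$cervix)
  eu <- expand_mesh(ref_uterus, spec$uterus)
  contains <- function(points) {
    if (is_tri_mesh(points)) points <- points$vertices
    points <- as.matrix(points)
    inc <- cpp_classify_points(points, ec$vertices, ec$faces - 1L)$inside
    inu <- cpp_classify_points(points, eu$vertices, eu$faces - 1L)$inside
    inc | inu
  }
  union_mesh <- tri_mesh(
    rbind(ec$vertices, eu$vertices),
    rbind(ec$faces, eu$faces + nrow(ec$vertices)),
    label = "ptv_union", validate = FALSE
  )
  structure(list(expanded_cervix = ec, expanded_uterus = eu,
                 contains = contains, union_mesh = union_mesh,
                 spec = spec),
            class = "ptv")
}

#' @export
print.ptv <- function(x, ...) {
  cat("<ptv> expanded cervix + uterus\n")
  print(x$spec)
  invisible(x)
}

#' Vertex-based PTV coverage
#'
#' Fraction of daily organ-model vertices lying inside the PTV (inside
#' count over total vertex count), per organ and combined.
#'
#' @param daily_cervix,daily_uterus daily organ meshes (after positioning).
#' @param ptv a [build_ptv()] result (or any function mapping an `n x 3`
#'   matrix to a logical vector).
#' @return An object of class `coverage_result` with per-organ and
#'   combined fractions in `[0, 1]` and the vertex counts.
#' @export
coverage <- function(daily_cervix, daily_uterus, ptv) {
  pred <- if (inherits(ptv, "ptv")) ptv$contains else match.fun(ptv)
  inc <- pred(daily_cervix$vertices)
  inu <- pred(daily_uterus$vertices)
  nc <- length(inc); nu <- length(inu)
  structure(
    list(cervix = sum(inc) / nc,
         uterus = sum(inu) / nu,
         combined = (sum(inc) + sum(inu)) / (nc + nu),
         n_cervix = nc, n_uterus = nu,
         n_inside_cervix = sum(inc), n_inside_uterus = sum(inu)),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> cervix %.1f%%, uterus %.1f%%, combined %.1f%%\n",
              100 * x$cervix, 100 * x$uterus, 100 * x$combined))
  invisible(x)
}

#' Position a daily fraction and score its PTV coverage
#'
#' Runs the positioning optimizer in the requested mode (translation only,
#' or translation then clamped rotation), applies the computed displacement
#' to the daily organs, builds the PTV from the reference organs, and
#' returns the coverage together with the match result.
#'
#' @inheritParams auto_match
#' @param spec a [margin_spec()].
#' @param mode `"trans_only"` or `"trans_and_rot"`.
#' @param clamp_deg rotation limit in degrees for the rotational phase
#'   (default 3, the couch tolerance).
#' @return A list with `coverage` (a `coverage_result`) and `match`
#'   (a `match_result`).
#' @export
evaluate_fraction <- function(daily_cervix, daily_uterus, ref_cervix,
                              ref_uterus, weights, spec,
                              mode = c("trans_and_rot", "trans_only"),
                              clamp_deg = 3) {
  mode <- match.arg(mode)
  fit <- auto_match(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                    weights, clamp_deg = clamp_deg, mode = mode)
  ptv <- build_ptv(ref_cervix, ref_uterus, spec)
  cov <- coverage(fit$matched_cervix, fit$matched_uterus, ptv)
  list(coverage = cov, match = fit)
}

#' @rdname coverage
#' @param x a `coverage_result`.
#' @param ... unused.
#' @export
tidy.coverage_result <- function(x, ...) {
  tibble::tibble(
    organ = c("cervix", "uterus", "combined"),
    fraction = c(x$cervix, x$uterus, x$combined),
    n_vertices = c(x$n_cervix, x$n_uterus, x$n_cervix + x$n_uterus),
    n_inside = c(x$n_inside_cervix, x$n_inside_uterus,
                 x$n_inside_cervix + x$n_inside_uterus)
  )
}
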