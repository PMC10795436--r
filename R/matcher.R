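#' Auto-matching by step-halving ("dichotomy") positioning
#'
#' Rigidly positions the daily cervix and uterus (moved together as one
#' rigid body) onto their reference models by minimizing the weighted
#' vertex-to-surface cost, in two phases run once each: translational
#' positioning, then rotational positioning.
#'
#' Translational phase: the first move shifts both organs by the full
#' centroid difference (pooled reference centroid minus pooled daily
#' centroid), accepted only if the cost strictly decreases. Subsequent
#' iterations test signed axis-aligned moves (x+, x-, y+, y-, z+, z-) of a
#' magnitude that halves each iteration, floored at 1 mm (the translational
#' accuracy of the treatment couch); each magnitude is swept repeatedly
#' until a full sweep accepts nothing. The phase ends when a full 1 mm
#' sweep accepts nothing.
#'
#' Rotational phase: the same scheme about the pooled daily centroid at the
#' start of the phase, starting at 45 degrees, halving, floored at
#' 0.5 degrees (the rotational couch accuracy), sweeping pitch+, pitch-,
#' yaw+, yaw-, roll+, roll-. The reported total rotation is the Euler-angle
#' decomposition (pitch, yaw, roll) of the net accumulated rotation -- the
#' correction a treatment couch would execute. With `clamp_deg` set, any
#' candidate whose net rotation would exceed the clamp on any axis is
#' skipped (the limit constrains the search; it does not truncate the
#' result).
#'
#' Every move is accepted only on strict cost decrease (relative tolerance
#' 1e-9) and reverted otherwise, so the accepted-cost sequence is strictly
#' decreasing and the final cost never exceeds the original cost.
#'
#' @param daily_cervix,daily_uterus daily-organ meshes ([tri_mesh()]).
#' @param ref_cervix,ref_uterus reference-organ meshes (closed).
#' @param weights a [weight_set()], e.g. [scenario()]`("A")`.
#' @param clamp_deg per-axis rotation limit in degrees (e.g. 3 for the
#'   couch tolerance), or `NULL` for unconstrained rotation.
#' @param mode `"trans_and_rot"` (default) or `"trans_only"`.
#' @param max_evals cost-evaluation cap per phase; if reached, the
#'   best-so-far result is returned with `capped = TRUE` in the trace.
#' @return An object of class `match_result`: accumulated `translation`
#'   (mm, LPS signed), `rotation` (pitch, yaw, roll in degrees),
#'   `rotation_center`, `original_cost`, `final_cost` (a `cost_breakdown`),
#'   the per-move `trace` tibble, the moved daily meshes
#'   (`matched_cervix`, `matched_uterus`), and the settings in force.
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 1, translation = c(6, -8, 4),
#'                                 subdivision = 1))
#' fit <- auto_match(ph$daily_cervix, ph$daily_uterus,
#'                   ph$ref_cervix, ph$ref_uterus, scenario("A"))
#' fit$translation # approximately (-6, 8, -4)
#' @export
auto_match <- function(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                       weights, clamp_deg = NULL,
                       mode = c("trans_and_rot", "trans_only"),
                       max_evals = 500L) {
  mode <- match.arg(mode)
  st <- match_state(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                    weights, max_evals)
  st <- run_translation_phase(st)
  if (mode == "trans_and_rot") st <- run_rotation_phase(st, clamp_deg)
  finish_match(st, clamp_deg, mode)
}

#' Translational positioning phase
#'
#' Runs only the translational phase of [auto_match()] and returns the
#' partial result (rotation identically zero) together with the moved
#' meshes; see [auto_match()] for the scheme.
#'
#' @inheritParams auto_match
#' @return A `match_result` with zero rotation.
#' @export
translational_positioning <- function(daily_cervix, daily_uterus,
                                      ref_cervix, ref_uterus, weights,
                                      max_evals = 500L) {
  st <- match_state(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                    weights, max_evals)
  st <- run_translation_phase(st)
  finish_match(st, clamp_deg = NULL, mode = "trans_only")
}

#' Rotational positioning phase
#'
#' Runs only the rotational phase (assumes translational positioning has
#' already been applied to the supplied daily meshes); see [auto_match()].
#'
#' @inheritParams auto_match
#' @return A `match_result` with zero translation.
#' @export
rotational_positioning <- function(daily_cervix, daily_uterus,
                                   ref_cervix, ref_uterus, weights,
                                   clamp_deg = NULL, max_evals = 500L) {
  st <- match_state(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                    weights, max_evals)
  st <- run_rotation_phase(st, clamp_deg)
  finish_match(st, clamp_deg, mode = "rot_only")
}

# ---- internal optimizer engine --------------------------------------------

TRANS_FLOOR_MM <- 1
ROT_INIT_DEG <- 45
ROT_FLOOR_DEG <- 0.5
ACCEPT_RTOL <- 1e-9

match_state <- function(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                        weights, max_evals) {
  stopifnot(is_tri_mesh(daily_cervix), is_tri_mesh(daily_uterus),
            inherits(weights, "weight_set"))
  check_reference(ref_cervix)
  check_reference(ref_uterus)
  st <- list(
    Vc = daily_cervix$vertices, Vu = daily_uterus$vertices,
    mesh_c = daily_cervix, mesh_u = daily_uterus,
    ref_c = ref_cervix, ref_u = ref_uterus,
    w = weights, max_evals = as.integer(max_evals),
    translation = c(0, 0, 0), rotation = c(pitch = 0, yaw = 0, roll = 0),
    rotation_center = NULL,
    trace = list(), evals = 0L, capped = FALSE
  )
  st$current <- eval_cost(st)
  st$evals <- 1L
  st$original_cost <- st$current$total
  st
}

eval_cost <- function(st, Vc = st$Vc, Vu = st$Vu) {
  cc <- cpp_organ_cost(Vc, st$ref_c$vertices, st$ref_c$faces - 1L,
                       st$w$w_out_cervix, st$w$w_in_cervix)
  cu <- cpp_organ_cost(Vu, st$ref_u$vertices, st$ref_u$faces - 1L,
                       st$w$w_out_uterus, st$w$w_in_uterus)
  list(total = cc$cost + cu$cost, cost_cervix = cc$cost,
       cost_uterus = cu$cost, cervix = cc, uterus = cu)
}

strictly_less <- function(new, old) {
  (old - new) > ACCEPT_RTOL * max(abs(old), 1e-12)
}

record_move <- function(st, phase, iteration, step, axis, sign,
                        cost_after, accepted) {
  st$trace[[length(st$trace) + 1L]] <- list(
    phase = phase, iteration = iteration, step = step, axis = axis,
    sign = sign, cost_before = st$current$total,
    cost_after = cost_after$total, accepted = accepted
  )
  if (accepted) st$current <- cost_after
  st
}

# try one candidate state; accept on strict decrease, else leave unchanged
try_move <- function(st, Vc_new, Vu_new, phase, iteration, step, axis, sign,
                     on_accept) {
  if (st$evals >= st$max_evals) {
    st$capped <- TRUE
    return(st)
  }
  cand <- eval_cost(st, Vc_new, Vu_new)
  st$evals <- st$evals + 1L
  ok <- strictly_less(cand$total, st$current$total)
  st <- record_move(st, phase, iteration, step, axis, sign, cand, ok)
  if (ok) {
    st$Vc <- Vc_new
    st$Vu <- Vu_new
    st <- on_accept(st)
  }
  st
}

run_translation_phase <- function(st) {
  ref_cen <- colMeans(rbind(st$ref_c$vertices, st$ref_u$vertices))
  daily_cen <- colMeans(rbind(st$Vc, st$Vu))
  delta <- ref_cen - daily_cen
  len <- sqrt(sum(delta^2))

  # M = 1: the full centroid-difference move, itself subject to accept/revert
  if (len > 0) {
    st <- try_move(
      st, sweep(st$Vc, 2, delta, `+`), sweep(st$Vu, 2, delta, `+`),
      "translation", 1L, len, "centroid", 1L,
      on_accept = function(s) { s$translation <- s$translation + delta; s }
    )
  }

  # M >= 2: axis-aligned sweeps; magnitude halves with M (commanded
  # magnitude, independent of acceptance), floored at 1 mm
  M <- 2L
  mag <- max(len / 2, TRANS_FLOOR_MM)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  axis_names <- c("x", "y", "z")
  repeat {
    repeat { # sweep this magnitude until a full sweep accepts nothing
      accepted_any <- FALSE
      for (ax in 1:3) for (sgn in c(1L, -1L)) {
        step_vec <- sgn * mag * axes[[ax]]
        before <- st$evals
        st <- try_move(
          st, sweep(st$Vc, 2, step_vec, `+`), sweep(st$Vu, 2, step_vec, `+`),
          "translation", M, mag, axis_names[ax], sgn,
          on_accept = function(s) { s$translation <- s$translation + step_vec; s }
        )
        if (st$capped) return(st)
        if (length(st$trace) && st$trace[[length(st$trace)]]$accepted &&
            st$evals > before) accepted_any <- TRUE
      }
      if (!accepted_any) break
    }
    if (mag <= TRANS_FLOOR_MM) break # full floor-magnitude sweep rejected
    M <- M + 1L
    mag <- max(mag / 2, TRANS_FLOOR_MM)
  }
  st
}

rotate_about <- function(V, axis, angle_deg, center) {
  tf <- switch(axis,
    pitch = rigid_transform(pitch = angle_deg, center = center),
    yaw = rigid_transform(yaw = angle_deg, center = center),
    roll = rigid_transform(roll = angle_deg, center = center)
  )
  transform_points(V, tf)
}

run_rotation_phase <- function(st, clamp_deg) {
  if (!is.null(clamp_deg) && clamp_deg < 0)
    stop("`clamp_deg` must be >= 0 or NULL", call. = FALSE)
  # rotation center: pooled daily centroid at the start of this phase
  center <- colMeans(rbind(st$Vc, st$Vu))
  st$rotation_center <- center
  # net accumulated rotation; the reported (pitch, yaw, roll) are its Euler
  # angles -- the correction a couch would actually execute (per-axis sums
  # of non-commuting exploratory increments would not be)
  Rnet <- diag(3)

  M <- 1L
  mag <- ROT_INIT_DEG
  axes <- c("pitch", "yaw", "roll")
  repeat {
    repeat {
      accepted_any <- FALSE
      for (ax in axes) for (sgn in c(1L, -1L)) {
        ang <- sgn * mag
        Rcand <- switch(ax,
          pitch = rotation_matrix(pitch = ang),
          yaw = rotation_matrix(yaw = ang),
          roll = rotation_matrix(roll = ang)
        ) %*% Rnet
        cand_angles <- rotation_angles(Rcand)
        if (!is.null(clamp_deg) &&
            any(abs(cand_angles) > clamp_deg + 1e-12)) next
        before_len <- length(st$trace)
        st <- try_move(
          st, rotate_about(st$Vc, ax, ang, center),
          rotate_about(st$Vu, ax, ang, center),
          "rotation", M, mag, ax, sgn,
          on_accept = function(s) {
            Rnet <<- Rcand
            s$rotation <- c(pitch = cand_angles[["pitch"]],
                            yaw = cand_angles[["yaw"]],
                            roll = cand_angles[["roll"]])
            s
          }
        )
        if (st$capped) return(st)
        if (length(st$trace) > before_len &&
            st$trace[[length(st$trace)]]$accepted) accepted_any <- TRUE
      }
      if (!accepted_any) break
    }
    if (mag <= ROT_FLOOR_DEG) break
    M <- M + 1L
    mag <- max(mag / 2, ROT_FLOOR_DEG)
  }
  st
}

finish_match <- function(st, clamp_deg, mode) {
  trace <- if (length(st$trace)) {
    dplyr::bind_rows(lapply(st$trace, tibble::as_tibble))
  } else {
    tibble::tibble(phase = character(), iteration = integer(),
                   step = double(), axis = character(), sign = integer(),
                   cost_before = double(), cost_after = double(),
                   accepted = logical())
  }
  mc <- st$mesh_c; mc$vertices <- st$Vc
  mu <- st$mesh_u; mu$vertices <- st$Vu
  structure(
    list(
      translation = st$translation,
      rotation = st$rotation,
      rotation_center = st$rotation_center,
      original_cost = st$original_cost,
      final_cost = structure(
        st$current[c("total", "cost_cervix", "cost_uterus", "cervix", "uterus")],
        class = "cost_breakdown"),
      trace = trace,
      matched_cervix = mc,
      matched_uterus = mu,
      weights = st$w,
      clamp_deg = clamp_deg,
      mode = mode,
      n_evals = st$evals,
      capped = st$capped
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> mode %s, scenario %s\n", x$mode,
              attr(x$weights, "name") %||% "custom"))
  cat(sprintf("  translation (LPS mm): (%.2f, %.2f, %.2f)\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  rotation (deg): pitch %.2f, yaw %.2f, roll %.2f%s\n",
              x$rotation[["pitch"]], x$rotation[["yaw"]], x$rotation[["roll"]],
              if (!is.null(x$clamp_deg)) sprintf(" (clamp %g)", x$clamp_deg) else ""))
  cat(sprintf("  cost: %.4f -> %.4f in %d evaluations%s\n",
              x$original_cost, x$final_cost$total, x$n_evals,
              if (x$capped) " [evaluation cap hit]" else ""))
  invisible(x)
}

#' @describeIn auto_match tidy() returns the per-move optimization trace as
#'   a tibble (one row per attempted move).
#' @param x a `match_result`.
#' @param ... unused.
#' @export
tidy.match_result <- function(x, ...) x$trace

#' @describeIn auto_match glance() returns a one-row tibble summary.
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    scenario = attr(x$weights, "name") %||% NA_character_,
    mode = x$mode,
    tx = x$translation[1], ty = x$translation[2], tz = x$translation[3],
    pitch = x$rotation[["pitch"]], yaw = x$rotation[["yaw"]],
    roll = x$rotation[["roll"]],
    original_cost = x$original_cost, final_cost = x$final_cost$total,
    n_evals = x$n_evals, n_accepted = sum(x$trace$accepted),
    capped = x$capped
  )
}

#' @describeIn auto_match autoplot() draws cost against evaluation index,
#'   colored by phase, with accepted moves marked.
#' @param object a `match_result`.
#' @export
autoplot.match_result <- function(object, ...) {
  tr <- dplyr::mutate(object$trace, eval = dplyr::row_number())
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$eval, y = .data$cost_after,
                                   color = .data$phase)) +
    ggplot2::geom_step(ggplot2::aes(y = cummin(.data$cost_after)),
                       color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "cost evaluation", y = "total cost (weighted mm²)",
                  title = "Dichotomy positioning trace") +
    ggplot2::theme_minimal()
}

#' Anatomical-direction report of a translation
#'
#' Splits a signed LPS translation vector into the six anatomical direction
#' magnitudes (R, L, A, P, S, I): +x is Left, -x Right, +y Posterior,
#' -y Anterior, +z Superior, -z Inferior.
#'
#' @param translation length-3 signed LPS vector (mm).
#' @return Named numeric vector of six non-negative magnitudes.
#' @export
anatomical_directions <- function(translation) {
  t <- as.numeric(translation)
  c(R = max(-t[1], 0), L = max(t[1], 0),
    A = max(-t[2], 0), P = max(t[2], 0),
    S = max(t[3], 0), I = max(-t[3], 0))
}

#' Export a match result
#'
#' `write_trace_csv()` writes the per-move trace (one row per attempted
#' move); `write_match_json()` writes the result summary with the LPS
#' translation, the six-direction anatomical report, rotations, costs and
#' settings.
#'
#' @param result a `match_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_trace_json <- function(result, path) {
  jsonlite::write_json(result$trace, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_match_json <- function(result, path) {
  out <- list(
    translation_mm_lps = result$translation,
    translation_directions_mm = as.list(anatomical_directions(result$translation)),
    rotation_deg = as.list(result$rotation),
    rotation_center_mm = result$rotation_center,
    original_cost = result$original_cost,
    final_cost = result$final_cost$total,
    final_cost_cervix = result$final_cost$cost_cervix,
    final_cost_uterus = result$final_cost$cost_uterus,
    scenario = attr(result$weights, "name"),
    weights = unclass(result$weights)[c("w_out_cervix", "w_in_cervix",
                                        "w_out_uterus", "w_in_uterus")],
    clamp_deg = result$clamp_deg,
    mode = result$mode,
    n_evals = result$n_evals,
    capped = result$capped
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
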