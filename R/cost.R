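#' Cost-function weight set
#'
#' The four non-negative weights of the two-organ positioning cost:
#' `w_out` and `w_in` for the cervix and for the uterus. `w_out` pulls
#' vertices lying outside the reference surface toward it; `w_in` does the
#' same for vertices strictly inside.
#'
#' @param w_out_cervix,w_in_cervix,w_out_uterus,w_in_uterus non-negative
#'   weights (at least one positive).
#' @param name optional scenario label.
#' @return An object of class `weight_set`.
#' @seealso [scenario()] for the three named presets.
#' @export
weight_set <- function(w_out_cervix, w_in_cervix, w_out_uterus, w_in_uterus,
                       name = NULL) {
  w <- c(w_out_cervix = as.numeric(w_out_cervix),
         w_in_cervix = as.numeric(w_in_cervix),
         w_out_uterus = as.numeric(w_out_uterus),
         w_in_uterus = as.numeric(w_in_uterus))
  if (anyNA(w) || any(w < 0))
    stop("all four weights must be non-negative numbers", call. = FALSE)
  if (all(w == 0))
    stop("at least one weight must be positive", call. = FALSE)
  structure(as.list(c(w)), name = name, class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("<weight_set>%s (w_out_cervix, w_in_cervix, w_out_uterus, w_in_uterus) = (%g, %g, %g, %g)\n",
              if (is.null(nm)) "" else paste0(" scenario ", nm),
              x$w_out_cervix, x$w_in_cervix, x$w_out_uterus, x$w_in_uterus))
  invisible(x)
}

#' Named weight scenarios
#'
#' The three weight presets: scenario A is unweighted (1, 1, 1, 1) and
#' serves as the reference condition; scenario B up-weights outside
#' vertices of both organs (10, 5, 10, 5); scenario C additionally
#' prioritizes the cervix over the uterus (10, 5, 2, 0.5), ordered
#' (w_out_cervix, w_in_cervix, w_out_uterus, w_in_uterus).
#'
#' @param name `"A"`, `"B"` or `"C"`.
#' @return A [weight_set()].
#' @examples
#' scenario("C")
#' @export
scenario <- function(name) {
  presets <- list(
    A = c(1, 1, 1, 1),
    B = c(10, 5, 10, 5),
    C = c(10, 5, 2, 0.5)
  )
  name <- as.character(name)[1]
  if (!name %in% names(presets))
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                 name, paste(names(presets), collapse = ", ")), call. = FALSE)
  w <- presets[[name]]
  weight_set(w[1], w[2], w[3], w[4], name = name)
}

#' Per-organ weighted vertex-to-surface cost
#'
#' Classifies the daily mesh's vertices against the (closed) reference
#' surface of the same organ and returns
#' `w_out * sum(d_i^2) / i  +  w_in * sum(D_t^2) / t`,
#' where `d` are distances of the `i` outside vertices to the reference
#' surface and `D` those of the `t` inside vertices; a group with no
#' members contributes 0. Units: mm^2 scaled by the dimensionless weights.
#'
#' @param daily the daily-organ [tri_mesh()] (or an `n x 3` vertex matrix).
#' @param reference the reference-organ [tri_mesh()] (closed).
#' @param w_out,w_in non-negative weights for the outside and inside terms.
#' @return A list: `cost`, `outside_term`, `inside_term`, `n_outside`,
#'   `n_inside`, and the unweighted squared-distance sums
#'   `sum_sq_outside`, `sum_sq_inside`.
#' @examples
#' ref <- cube_mesh(10)
#' shifted <- cube_mesh(10, origin = c(20, 0, 0))
#' organ_cost(shifted, ref, 1, 1)$cost # 250
#' @export
organ_cost <- function(daily, reference, w_out = 1, w_in = 1) {
  P <- if (is_tri_mesh(daily)) daily$vertices else as.matrix(daily)
  if (!is.numeric(P) || nrow(P) < 1)
    stop("daily mesh is empty", call. = FALSE)
  check_reference(reference)
  stopifnot(w_out >= 0, w_in >= 0)
  cpp_organ_cost(P, reference$vertices, reference$faces - 1L, w_out, w_in)
}

#' Total two-organ positioning cost
#'
#' Sum of the per-organ costs, each organ scored against its own reference
#' only: cervix vs reference cervix plus uterus vs reference uterus.
#'
#' @param daily_cervix,daily_uterus daily-organ meshes.
#' @param ref_cervix,ref_uterus reference-organ meshes (closed).
#' @param weights a [weight_set()].
#' @return A list of class `cost_breakdown`: `total`, `cost_cervix`,
#'   `cost_uterus` and the per-organ term lists.
#' @export
total_cost <- function(daily_cervix, daily_uterus, ref_cervix, ref_uterus,
                       weights) {
  stopifnot(inherits(weights, "weight_set"))
  cc <- organ_cost(daily_cervix, ref_cervix,
                   weights$w_out_cervix, weights$w_in_cervix)
  cu <- organ_cost(daily_uterus, ref_uterus,
                   weights$w_out_uterus, weights$w_in_uterus)
  structure(
    list(total = cc$cost + cu$cost,
         cost_cervix = cc$cost, cost_uterus = cu$cost,
         cervix = cc, uterus = cu),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> total %.4f = cervix %.4f + uterus %.4f (mm^2, weighted)\n",
              x$total, x$cost_cervix, x$cost_uterus))
  invisible(x)
}

#' Read a weight set from a YAML or JSON config file
#'
#' The file either names a preset (`scenario: B`) or gives the four weights
#' (`w_out_cervix:` etc.); explicit weights override the preset.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return A [weight_set()].
#' @export
read_weights <- function(path) {
  cfg <- read_config(path)
  keys <- c("w_out_cervix", "w_in_cervix", "w_out_uterus", "w_in_uterus")
  if (all(keys %in% names(cfg))) {
    do.call(weight_set, c(cfg[keys], list(name = cfg$scenario %||% cfg$name)))
  } else if (!is.null(cfg$scenario)) {
    scenario(cfg$scenario)
  } else {
    stop(sprintf("'%s' must give either `scenario` or all of %s",
                 path, paste(keys, collapse = ", ")), call. = FALSE)
  }
}

read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop(sprintf("unsupported config format '.%s' (need YAML or JSON)", ext),
            call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
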