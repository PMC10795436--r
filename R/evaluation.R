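#' Run the full positioning pipeline over a phantom cohort
#'
#' For every case and weight scenario: translational positioning, then
#' clamped rotational positioning, with PTV coverage (isotropic and
#' anisotropic presets) scored after translation alone and after
#' translation plus rotation. One row per case x scenario.
#'
#' @param cohort a list of phantom cases from [make_cohort()] (each with
#'   `ref_cervix`, `ref_uterus`, `daily_cervix`, `daily_uterus`,
#'   `case_id`, and optionally `truth`).
#' @param scenarios character vector of scenario names (see [scenario()]).
#' @param clamp_deg rotation limit (degrees) applied when scoring coverage
#'   after rotation; the reported rotation angles always come from the
#'   unconstrained rotational phase (the computed correction).
#' @param margins_iso,margins_aniso the two [margin_spec()]s scored.
#' @return A `cohort_table` tibble: `case_id`, `scenario`, signed LPS
#'   translations `tx`, `ty`, `tz` (mm), `pitch`, `yaw`, `roll` (deg),
#'   coverages `cov_iso_trans`, `cov_iso_rot`, `cov_aniso_trans`,
#'   `cov_aniso_rot` (fractions), final costs, and the ground truth
#'   when available.
#' @examples
#' \donttest{
#' coh <- make_cohort(2, phantom_spec(subdivision = 2), seed = 1)
#' tab <- run_cohort(coh, scenarios = "A")
#' summarize_cohort(tab)
#' }
#' @export
run_cohort <- function(cohort, scenarios = c("A", "B", "C"), clamp_deg = 3,
                       margins_iso = margin_preset("iso"),
                       margins_aniso = margin_preset("aniso")) {
  stopifnot(length(cohort) >= 1)
  rows <- purrr::map_dfr(cohort, function(case) {
    ptv_iso <- build_ptv(case$ref_cervix, case$ref_uterus, margins_iso)
    ptv_aniso <- build_ptv(case$ref_cervix, case$ref_uterus, margins_aniso)
    purrr::map_dfr(scenarios, function(sc) {
      w <- scenario(sc)
      tp <- translational_positioning(case$daily_cervix, case$daily_uterus,
                                      case$ref_cervix, case$ref_uterus, w)
      # reported angles come from the unconstrained rotational phase (the
      # computed correction); coverage after rotation uses the clamped run
      # (the correction a couch is allowed to execute)
      rp <- rotational_positioning(tp$matched_cervix, tp$matched_uterus,
                                   case$ref_cervix, case$ref_uterus, w,
                                   clamp_deg = NULL)
      rp_cov <- if (is.null(clamp_deg)) rp else
        rotational_positioning(tp$matched_cervix, tp$matched_uterus,
                               case$ref_cervix, case$ref_uterus, w,
                               clamp_deg = clamp_deg)
      cov_t_iso <- coverage(tp$matched_cervix, tp$matched_uterus, ptv_iso)
      cov_t_aniso <- coverage(tp$matched_cervix, tp$matched_uterus, ptv_aniso)
      cov_r_iso <- coverage(rp_cov$matched_cervix, rp_cov$matched_uterus, ptv_iso)
      cov_r_aniso <- coverage(rp_cov$matched_cervix, rp_cov$matched_uterus, ptv_aniso)
      tibble::tibble(
        case_id = case$case_id %||% NA_integer_,
        scenario = sc,
        tx = tp$translation[1], ty = tp$translation[2], tz = tp$translation[3],
        pitch = rp$rotation[["pitch"]], yaw = rp$rotation[["yaw"]],
        roll = rp$rotation[["roll"]],
        cov_iso_trans = cov_t_iso$combined,
        cov_iso_rot = cov_r_iso$combined,
        cov_aniso_trans = cov_t_aniso$combined,
        cov_aniso_rot = cov_r_aniso$combined,
        final_cost_trans = tp$final_cost$total,
        final_cost_rot = rp$final_cost$total,
        truth_tx = if (!is.null(case$truth)) case$truth$translation[1] else NA_real_,
        truth_ty = if (!is.null(case$truth)) case$truth$translation[2] else NA_real_,
        truth_tz = if (!is.null(case$truth)) case$truth$translation[3] else NA_real_,
        truth_pitch = if (!is.null(case$truth)) case$truth$pitch else NA_real_
      )
    })
  })
  class(rows) <- c("cohort_table", class(rows))
  rows
}

#' Summarize a cohort table
#'
#' Per-direction translation summaries (median, interquartile range,
#' percentage of fractions exceeding `exceed_mm` in that direction),
#' per-axis rotation summaries, and the percentage of fractions reaching
#' each coverage threshold per PTV and positioning mode. Exceedance is
#' counted on per-direction magnitudes under the LPS sign map (a +12 mm
#' `ty` counts as posterior exceedance only).
#'
#' @param table a `cohort_table` from [run_cohort()] (or any data frame
#'   with its columns).
#' @param exceed_mm translation exceedance threshold (mm).
#' @param coverage_thresholds coverage fractions reported as "at least".
#' @return A list of three tibbles: `translations`, `rotations`,
#'   `coverage`.
#' @export
summarize_cohort <- function(table, exceed_mm = 10,
                             coverage_thresholds = c(0.8, 0.95)) {
  if (nrow(table) == 0) stop("empty cohort table", call. = FALSE)
  dir_map <- list(
    R = ~ pmax(-.x$tx, 0), L = ~ pmax(.x$tx, 0),
    A = ~ pmax(-.x$ty, 0), P = ~ pmax(.x$ty, 0),
    S = ~ pmax(.x$tz, 0), I = ~ pmax(-.x$tz, 0)
  )
  translations <- purrr::map_dfr(names(dir_map), function(d) {
    table |>
      dplyr::group_by(.data$scenario) |>
      dplyr::group_modify(function(g, key) {
        mags <- rlang::as_function(dir_map[[d]])(g)
        tibble::tibble(
          direction = d,
          median = stats::median(mags),
          q25 = stats::quantile(mags, 0.25, names = FALSE),
          q75 = stats::quantile(mags, 0.75, names = FALSE),
          pct_exceed = 100 * mean(mags > exceed_mm)
        )
      }) |>
      dplyr::ungroup()
  })
  rotations <- table |>
    tidyr::pivot_longer(cols = c("pitch", "yaw", "roll"),
                        names_to = "axis", values_to = "deg") |>
    dplyr::group_by(.data$scenario, .data$axis) |>
    dplyr::summarise(
      median = stats::median(.data$deg),
      q25 = stats::quantile(.data$deg, 0.25, names = FALSE),
      q75 = stats::quantile(.data$deg, 0.75, names = FALSE),
      .groups = "drop"
    )
  cov_cols <- c(iso_trans = "cov_iso_trans", iso_rot = "cov_iso_rot",
                aniso_trans = "cov_aniso_trans", aniso_rot = "cov_aniso_rot")
  coverage <- purrr::map_dfr(names(cov_cols), function(nm) {
    purrr::map_dfr(coverage_thresholds, function(th) {
      table |>
        dplyr::group_by(.data$scenario) |>
        dplyr::summarise(
          ptv_mode = nm, threshold = th,
          pct_at_or_above = 100 * mean(.data[[cov_cols[[nm]]]] >= th),
          median_coverage = stats::median(.data[[cov_cols[[nm]]]]),
          .groups = "drop"
        )
    })
  })
  list(translations = translations, rotations = rotations,
       coverage = coverage)
}

#' Paired scenario comparisons
#'
#' Paired t-tests between weight scenarios on each displacement variable,
#' with Bonferroni adjustment (raw p multiplied by the family size, capped
#' at 1). Rows are paired by `case_id`. Degenerate cases (zero-variance
#' differences) follow the paired-t limit: all-zero differences give
#' t = 0, p = 1; a constant nonzero difference gives p = 0.
#'
#' @param table a `cohort_table` from [run_cohort()].
#' @param pairs list of length-2 character vectors of scenario names;
#'   default all pairs present in the table.
#' @param variables displacement columns to test.
#' @param n_comparisons Bonferroni family size; default the number of
#'   tests actually performed (pairs x variables).
#' @param alpha significance level.
#' @return A tibble: `pair`, `variable`, `n`, `t`, `df`, `p`, `p_adj`,
#'   `n_comparisons`, `significant`.
#' @export
compare_scenarios <- function(table, pairs = NULL,
                              variables = c("tx", "ty", "tz",
                                            "pitch", "yaw", "roll"),
                              n_comparisons = NULL, alpha = 0.05) {
  scens <- unique(table$scenario)
  if (is.null(pairs)) {
    if (length(scens) < 2) stop("need at least two scenarios to compare", call. = FALSE)
    pairs <- utils::combn(sort(scens), 2, simplify = FALSE)
  }
  m <- n_comparisons %||% (length(pairs) * length(variables))
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::filter(table, .data$scenario == pr[1]) |> dplyr::arrange(.data$case_id)
    b <- dplyr::filter(table, .data$scenario == pr[2]) |> dplyr::arrange(.data$case_id)
    if (nrow(a) == 0 || nrow(b) == 0 || !identical(a$case_id, b$case_id))
      stop(sprintf("scenarios %s and %s are not paired on case_id", pr[1], pr[2]),
           call. = FALSE)
    purrr::map_dfr(variables, function(v) {
      d <- a[[v]] - b[[v]]
      n <- length(d)
      if (stats::sd(d) == 0) {
        tt <- if (mean(d) == 0) list(statistic = 0, p.value = 1)
              else list(statistic = sign(mean(d)) * Inf, p.value = 0)
        df <- n - 1
      } else {
        ht <- stats::t.test(a[[v]], b[[v]], paired = TRUE)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
        df <- unname(ht$parameter)
      }
      tibble::tibble(
        pair = paste(pr, collapse = "-"), variable = v, n = n,
        t = tt$statistic, df = df, p = tt$p.value,
        p_adj = min(1, tt$p.value * m), n_comparisons = m,
        significant = min(1, tt$p.value * m) < alpha
      )
    })
  })
  out
}

#' Plot a cohort table
#'
#' Box plots of the computed displacements or coverages per scenario:
#' `type = "translations"` shows the six anatomical directions with a
#' dashed 10 mm line, `"rotations"` the three axes with dashed lines at
#' the clamp, `"coverage"` the four PTV x mode coverages.
#'
#' @param object a `cohort_table`.
#' @param type which panel to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_table <- function(object,
                                  type = c("translations", "rotations",
                                           "coverage"), ...) {
  type <- match.arg(type)
  if (type == "translations") {
    long <- object |>
      dplyr::transmute(
        .data$scenario,
        R = pmax(-.data$tx, 0), L = pmax(.data$tx, 0),
        A = pmax(-.data$ty, 0), P = pmax(.data$ty, 0),
        S = pmax(.data$tz, 0), I = pmax(-.data$tz, 0)
      ) |>
      tidyr::pivot_longer(-"scenario", names_to = "direction",
                          values_to = "mm") |>
      dplyr::mutate(direction = factor(.data$direction,
                                       levels = c("R", "L", "A", "P", "S", "I")))
    ggplot2::ggplot(long, ggplot2::aes(.data$direction, .data$mm)) +
      ggplot2::geom_boxplot() +
      ggplot2::geom_hline(yintercept = 10, linetype = "dashed", color = "red") +
      ggplot2::facet_wrap(~scenario) +
      ggplot2::labs(y = "translation (mm)", x = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "rotations") {
    long <- object |>
      tidyr::pivot_longer(cols = c("pitch", "yaw", "roll"),
                          names_to = "axis", values_to = "deg")
    ggplot2::ggplot(long, ggplot2::aes(.data$axis, .data$deg)) +
      ggplot2::geom_boxplot() +
      ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed",
                          color = "red") +
      ggplot2::facet_wrap(~scenario) +
      ggplot2::labs(y = "rotation (degrees)", x = NULL) +
      ggplot2::theme_minimal()
  } else {
    long <- object |>
      tidyr::pivot_longer(cols = dplyr::starts_with("cov_"),
                          names_to = "ptv_mode", values_to = "coverage")
    ggplot2::ggplot(long, ggplot2::aes(.data$ptv_mode, 100 * .data$coverage)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~scenario) +
      ggplot2::labs(y = "PTV coverage (%)", x = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  }
}

#' Write a cohort table or its summaries
#'
#' @param table a `cohort_table` (or one of the [summarize_cohort()]
#'   tibbles).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
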