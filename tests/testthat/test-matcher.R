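# phantoms at subdivision 2 (162 vertices/organ) keep these unit tests quick;
# the acceptance suite exercises the default resolution

test_that("already-matched organs yield the identity result", {
  ph <- make_phantom(phantom_spec(seed = 1, translation = c(0, 0, 0),
                                  subdivision = 2))
  fit <- auto_match(ph$ref_cervix, ph$ref_uterus, ph$ref_cervix,
                    ph$ref_uterus, scenario("A"))
  expect_equal(fit$translation, c(0, 0, 0))
  expect_equal(unname(fit$rotation), c(0, 0, 0))
  expect_equal(fit$final_cost$total, 0)
  expect_false(any(fit$trace$accepted))
})

test_that("a pure translation is recovered within the 1 mm floor", {
  ph <- make_phantom(phantom_spec(seed = 2, translation = c(6, -8, 4),
                                  subdivision = 2))
  for (sc in c("A", "B", "C")) {
    fit <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                      ph$ref_uterus, scenario(sc))
    expect_true(all(abs(fit$translation - c(-6, 8, -4)) <= 1), info = sc)
    expect_true(all(abs(fit$rotation) <= 0.5), info = sc)
  }
})

test_that("a sub-floor displacement leaves at most a 0.6 mm residual", {
  ph <- make_phantom(phantom_spec(seed = 3, translation = c(0.4, 0, 0),
                                  subdivision = 2))
  fit <- translational_positioning(ph$daily_cervix, ph$daily_uterus,
                                   ph$ref_cervix, ph$ref_uterus, scenario("A"))
  expect_lte(abs(fit$translation[1] + 0.4), 0.6)
})

test_that("a single-axis rotation is recovered within the 0.5 degree floor", {
  ph <- make_phantom(phantom_spec(seed = 4, translation = c(0, 0, 0),
                                  rotation = c(10, 0, 0), subdivision = 2))
  rp <- rotational_positioning(ph$daily_cervix, ph$daily_uterus,
                               ph$ref_cervix, ph$ref_uterus, scenario("A"))
  expect_lte(abs(rp$rotation[["pitch"]] + 10), 0.5)
  expect_lte(abs(rp$rotation[["yaw"]]), 0.5)
  expect_lte(abs(rp$rotation[["roll"]]), 0.5)
})

test_that("yaw is recovered and roll reaches near-alignment despite weak identifiability", {
  ph <- make_phantom(phantom_spec(seed = 13, translation = c(0, 0, 0),
                                  rotation = c(0, 12, 0), subdivision = 2))
  rp <- rotational_positioning(ph$daily_cervix, ph$daily_uterus,
                               ph$ref_cervix, ph$ref_uterus, scenario("A"))
  expect_lte(abs(rp$rotation[["yaw"]] + 12), 0.5)

  # roll couples with yaw through the near-axisymmetric cervix and the
  # lever arm about the pooled centroid: the greedy dichotomy reaches a
  # well-aligned state (cost collapses) even when the roll angle itself
  # retains a residual around the floor
  ph2 <- make_phantom(phantom_spec(seed = 14, translation = c(0, 0, 0),
                                   rotation = c(0, 0, 12), subdivision = 2))
  rp2 <- rotational_positioning(ph2$daily_cervix, ph2$daily_uterus,
                                ph2$ref_cervix, ph2$ref_uterus, scenario("A"))
  expect_lt(rp2$final_cost$total, 0.02 * rp2$original_cost)
  expect_lte(abs(rp2$rotation[["roll"]] + 12), 2)
})

test_that("the rotation clamp bounds every cumulative axis angle", {
  ph <- make_phantom(phantom_spec(seed = 5, translation = c(0, 0, 0),
                                  rotation = c(10, 0, 0), subdivision = 2))
  fit <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                    ph$ref_uterus, scenario("A"), clamp_deg = 3)
  expect_true(all(abs(fit$rotation) <= 3))
  rot_rows <- dplyr::filter(fit$trace, phase == "rotation",
                            accepted)
  expect_true(all(rot_rows$step <= 3 + 1e-12))
})

test_that("clamp 0 reduces trans_and_rot to trans_only exactly", {
  ph <- make_phantom(phantom_spec(seed = 6, subdivision = 2))
  both <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                     ph$ref_uterus, scenario("B"), clamp_deg = 0)
  trans <- translational_positioning(ph$daily_cervix, ph$daily_uterus,
                                     ph$ref_cervix, ph$ref_uterus,
                                     scenario("B"))
  expect_identical(both$translation, trans$translation)
  expect_identical(unname(both$rotation), c(0, 0, 0))
  expect_identical(both$matched_cervix$vertices, trans$matched_cervix$vertices)
  expect_identical(both$final_cost$total, trans$final_cost$total)
})

test_that("traces are monotone and respect the step schedule", {
  for (seed in c(7, 8)) {
    ph <- make_phantom(phantom_spec(seed = seed, rotation = NULL,
                                    subdivision = 2))
    fit <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                      ph$ref_uterus, scenario("A"))
    tr <- fit$trace
    acc <- dplyr::filter(tr, accepted)
    expect_true(all(acc$cost_after < acc$cost_before))
    expect_true(all(diff(acc$cost_after) < 0) || nrow(acc) < 2)
    expect_lte(fit$final_cost$total, fit$original_cost)
    for (ph_name in c("translation", "rotation")) {
      rows <- dplyr::filter(tr, phase == ph_name, axis != "centroid")
      if (nrow(rows) < 2) next
      expect_true(all(diff(rows$step) <= 1e-12), info = ph_name)
      floor_val <- if (ph_name == "translation") 1 else 0.5
      expect_true(all(rows$step >= floor_val - 1e-12), info = ph_name)
      # the phase ends with a rejected floor-magnitude sweep
      tail_rows <- utils::tail(rows, 6)
      expect_true(all(!tail_rows$accepted), info = ph_name)
      expect_equal(max(tail_rows$step), floor_val, info = ph_name)
    }
  }
})

test_that("matching is deterministic: identical inputs, identical traces", {
  ph <- make_phantom(phantom_spec(seed = 9, rotation = NULL,
                                  deformation_mm = 1, subdivision = 2))
  f1 <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                   ph$ref_uterus, scenario("C"), clamp_deg = 3)
  f2 <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                   ph$ref_uterus, scenario("C"), clamp_deg = 3)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$translation, f2$translation)
  expect_identical(f1$rotation, f2$rotation)
  expect_identical(f1$matched_uterus$vertices, f2$matched_uterus$vertices)
})

test_that("the evaluation cap returns the best-so-far with a flag", {
  ph <- make_phantom(phantom_spec(seed = 10, translation = c(20, -25, 18),
                                  subdivision = 2))
  fit <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                    ph$ref_uterus, scenario("A"), max_evals = 5L)
  expect_true(fit$capped)
  expect_lte(fit$final_cost$total, fit$original_cost)
  expect_lte(fit$n_evals, 5L)
})

test_that("tidy, glance and the anatomical report expose the result", {
  ph <- make_phantom(phantom_spec(seed = 11, translation = c(6, -8, 4),
                                  subdivision = 2))
  fit <- auto_match(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                    ph$ref_uterus, scenario("A"))
  tr <- tidy(fit)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("phase", "iteration", "step", "axis", "sign",
                     "cost_before", "cost_after", "accepted"))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$tx, fit$translation[1])

  dirs <- anatomical_directions(c(-6, 8, -4))
  expect_equal(dirs[["R"]], 6)
  expect_equal(dirs[["P"]], 8)
  expect_equal(dirs[["I"]], 4)
  expect_equal(dirs[["L"]], 0)

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_match_json(fit, json)
  write_trace_csv(fit, csv)
  parsed <- jsonlite::read_json(json)
  expect_equal(unlist(parsed$translation_mm_lps), fit$translation)
  expect_equal(nrow(utils::read.csv(csv)), nrow(fit$trace))

  tjson <- withr::local_tempfile(fileext = ".json")
  write_trace_json(fit, tjson)
  expect_length(jsonlite::read_json(tjson), nrow(fit$trace))
})
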