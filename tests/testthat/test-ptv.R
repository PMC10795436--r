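test_that("margin presets match the published margins exactly", {
  iso <- margin_preset("iso")
  expect_identical(unname(iso$cervix), rep(5, 6))
  expect_identical(unname(iso$uterus), rep(5, 6))
  aniso <- margin_preset("aniso")
  expect_identical(unname(aniso$cervix), c(5, 5, 15, 15, 10, 10))
  expect_identical(unname(aniso$uterus), c(10, 10, 20, 20, 15, 15))
  expect_error(margin_preset("huge"), "unknown margin preset")
  expect_error(margin_spec(cervix = rep(-1, 6), uterus = rep(5, 6)),
               "non-negative")
})

test_that("margin specs load from config files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("preset: aniso", yml)
  expect_identical(unname(read_margins(yml)$uterus), c(10, 10, 20, 20, 15, 15))
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"cervix": [1,2,3,4,5,6], "uterus": [2,3,4,5,6,7]}', js)
  expect_identical(unname(read_margins(js)$cervix), c(1, 2, 3, 4, 5, 6))
})

test_that("zero margins leave the mesh unchanged; isotropic expansion offsets a sphere", {
  ico <- icosphere(3, radius = 10)
  same <- expand_mesh(ico, rep(0, 6))
  expect_equal(same$vertices, ico$vertices, tolerance = 1e-12)

  grown <- expand_mesh(ico, rep(5, 6))
  r <- sqrt(rowSums(grown$vertices^2))
  expect_lt(max(abs(r - 15)) / 15, 0.02)
})

test_that("directional margins displace axis-aligned normals by the right amount", {
  ico <- icosphere(3, radius = 10)
  m <- c(R = 5, L = 5, A = 15, P = 15, S = 10, I = 10)
  grown <- expand_mesh(ico, m)
  N <- vertex_normals(ico)
  probe <- function(dir_vec, expected) {
    i <- which.max(N %*% dir_vec)
    disp <- sqrt(sum((grown$vertices[i, ] - ico$vertices[i, ])^2))
    expect_equal(disp, expected, tolerance = 0.05)
  }
  probe(c(-1, 0, 0), 5)   # right-facing normal: R margin
  probe(c(0, 1, 0), 15)   # posterior-facing: P margin
  probe(c(0, 0, 1), 10)   # superior-facing: S margin
})

test_that("coverage monotone in margins and invariant under common rigid motion", {
  ph <- make_phantom(phantom_spec(seed = 21, subdivision = 2))
  small <- build_ptv(ph$ref_cervix, ph$ref_uterus,
                     margin_spec(cervix = rep(2, 6), uterus = rep(2, 6)))
  big <- build_ptv(ph$ref_cervix, ph$ref_uterus,
                   margin_spec(cervix = rep(8, 6), uterus = rep(8, 6)))
  cov_s <- coverage(ph$daily_cervix, ph$daily_uterus, small)
  cov_b <- coverage(ph$daily_cervix, ph$daily_uterus, big)
  expect_gte(cov_b$combined, cov_s$combined)
  expect_gte(cov_b$cervix, cov_s$cervix)

  tf <- rigid_transform(c(10, -5, 3), pitch = 15, center = c(0, 0, 0))
  moved <- build_ptv(apply_transform(ph$ref_cervix, tf),
                     apply_transform(ph$ref_uterus, tf),
                     margin_spec(cervix = rep(8, 6), uterus = rep(8, 6)))
  cov_m <- coverage(apply_transform(ph$daily_cervix, tf),
                    apply_transform(ph$daily_uterus, tf), moved)
  expect_equal(cov_m$combined, cov_b$combined, tolerance = 1e-12)
})

test_that("coverage endpoints: identical organs 100%, exterior organs 0%", {
  ph <- make_phantom(phantom_spec(seed = 22, translation = c(0, 0, 0),
                                  subdivision = 2))
  ptv <- build_ptv(ph$ref_cervix, ph$ref_uterus, margin_preset("iso"))
  full <- coverage(ph$ref_cervix, ph$ref_uterus, ptv)
  expect_equal(full$cervix, 1)
  expect_equal(full$uterus, 1)
  expect_equal(full$combined, 1)

  far <- rigid_transform(c(300, 0, 0))
  none <- coverage(apply_transform(ph$ref_cervix, far),
                   apply_transform(ph$ref_uterus, far), ptv)
  expect_equal(none$combined, 0)
  expect_equal(none$combined,
               (none$n_inside_cervix + none$n_inside_uterus) /
                 (none$n_cervix + none$n_uterus))
})

test_that("a shifted icosphere's coverage equals the brute-force count", {
  daily <- icosphere(2, radius = 10)
  shifted <- apply_transform(daily, rigid_transform(c(7, 0, 0)))
  ptv_sphere <- icosphere(4, radius = 15)
  # oracle: exact analytic containment in the radius-15 ball
  exact <- sqrt(rowSums(shifted$vertices^2)) < 15
  cov <- coverage(shifted, shifted,
                  function(P) sqrt(rowSums(as.matrix(P)^2)) < 15)
  expect_equal(cov$cervix, mean(exact))
  # the mesh-based predicate agrees with the analytic ball up to faceting
  cov_mesh <- coverage(shifted, shifted,
                       function(P) classify_vertices(P, ptv_sphere)$inside)
  expect_lt(abs(cov_mesh$cervix - mean(exact)), 0.05)
})

test_that("union containment covers both components and their overlap", {
  s1 <- icosphere(2, radius = 15, center = c(0, 0, 0), label = "cervix")
  s2 <- icosphere(2, radius = 15, center = c(20, 0, 0), label = "uterus")
  ptv <- build_ptv(s1, s2, margin_spec(cervix = rep(0.001, 6),
                                       uterus = rep(0.001, 6)))
  pts <- rbind(c(0, 0, 0), c(20, 0, 0), c(10, 0, 0), c(60, 0, 0))
  expect_identical(ptv$contains(pts), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(ptv$union_mesh$vertices),
               nrow(s1$vertices) + nrow(s2$vertices))
})

test_that("evaluate_fraction restores full PTV_iso coverage on a reachable translation", {
  ph <- make_phantom(phantom_spec(seed = 23, translation = c(6, -8, 4),
                                  subdivision = 2))
  for (mode in c("trans_only", "trans_and_rot")) {
    res <- evaluate_fraction(ph$daily_cervix, ph$daily_uterus, ph$ref_cervix,
                             ph$ref_uterus, scenario("A"),
                             margin_preset("iso"), mode = mode)
    expect_equal(res$coverage$combined, 1, info = mode)
  }
  idres <- evaluate_fraction(ph$ref_cervix, ph$ref_uterus, ph$ref_cervix,
                             ph$ref_uterus, scenario("A"),
                             margin_preset("aniso"))
  expect_equal(idres$coverage$combined, 1)
  expect_equal(idres$match$translation, c(0, 0, 0))
})
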