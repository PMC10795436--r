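test_that("cube corner classification matches the hand geometry", {
  cube <- cube_mesh(10)

  # corners of the cube itself lie on the surface: inside, distance 0
  on_surf <- classify_vertices(cube$vertices, cube)
  expect_true(all(on_surf$inside))
  expect_equal(on_surf$dist, rep(0, 8))
  expect_equal(on_surf$n_outside, 0)
  expect_equal(on_surf$n_inside, 8)

  # corners shifted +20 in x: all outside; near corners at 10 mm, far at 20
  shifted <- sweep(cube$vertices, 2, c(20, 0, 0), `+`)
  cl <- classify_vertices(shifted, cube)
  expect_false(any(cl$inside))
  expect_equal(sort(cl$dist), rep(c(10, 20), each = 4), tolerance = 1e-12)

  # center of the cube: inside at distance 5
  cen <- classify_vertices(rbind(c(5, 5, 5)), cube)
  expect_true(cen$inside)
  expect_equal(cen$dist, 5, tolerance = 1e-12)
})

test_that("counts partition the vertex set and distances are non-negative", {
  for (seed in 1:5) {
    ph <- random_pose_phantom(seed)
    cl <- classify_vertices(ph$daily_cervix, ph$ref_cervix)
    expect_equal(cl$n_outside + cl$n_inside, nrow(ph$daily_cervix$vertices))
    expect_true(all(cl$dist >= 0))
  }
})

test_that("classification agrees with the brute-force oracle", {
  for (seed in 1:12) {
    ph <- random_pose_phantom(seed, subdivision = 1)
    ref <- ph$ref_uterus
    P <- ph$daily_uterus$vertices[seq(1, 42, by = 2), , drop = FALSE]
    cl <- classify_vertices(P, ref)
    for (i in seq_len(nrow(P))) {
      expect_equal(cl$dist[i], oracle_min_dist(P[i, ], ref),
                   tolerance = 1e-9)
      if (cl$dist[i] > 1e-6)
        expect_identical(cl$inside[i], oracle_inside(P[i, ], ref))
    }
  }
})

test_that("winding number, ray parity and classification agree off-surface", {
  for (seed in c(2, 9)) {
    ph <- random_pose_phantom(seed, subdivision = 2)
    ref <- ph$ref_cervix
    set.seed(seed)
    P <- matrix(runif(3 * 120, -40, 40), ncol = 3)
    d <- classify_vertices(P, ref)
    off <- d$dist > 1e-6
    w <- winding_number(P, ref)
    rp <- ray_parity_inside(P, ref)
    expect_identical(d$inside[off], (w > 0.5)[off])
    expect_identical(d$inside[off], rp[off])
  }
})

test_that("an open reference is rejected", {
  cube <- cube_mesh(10)
  open_mesh <- structure(
    list(vertices = cube$vertices, faces = cube$faces[-1, ], label = "open"),
    class = "tri_mesh")
  expect_error(classify_vertices(rbind(c(5, 5, 5)), open_mesh), "not closed")
})

test_that("rigid transforms act as rotation about center then translation", {
  cube <- cube_mesh(10)

  expect_identical(apply_transform(cube, rigid_transform())$vertices,
                   cube$vertices)

  tr <- apply_transform(cube, rigid_transform(c(1, 2, 3)))
  expect_equal(tr$vertices, sweep(cube$vertices, 2, c(1, 2, 3), `+`))

  # two 90-degree pitches compose to one 180-degree pitch
  p90 <- rigid_transform(pitch = 90)
  twice <- apply_transform(apply_transform(cube, p90), p90)
  once <- apply_transform(cube, rigid_transform(pitch = 180))
  expect_lt(max(abs(twice$vertices - once$vertices)), 1e-9)
})

test_that("transforms are rigid: pairwise distances and volume preserved", {
  ph <- make_phantom(phantom_spec(seed = 4, translation = c(0, 0, 0),
                                  subdivision = 1))
  m <- ph$ref_uterus
  tf <- rigid_transform(c(5, -3, 8), pitch = 23, yaw = -11, roll = 7,
                        center = c(10, 0, -5))
  mt <- apply_transform(m, tf)
  expect_identical(mt$faces, m$faces)
  idx <- seq(1, nrow(m$vertices), by = 5)
  d0 <- dist(m$vertices[idx, ])
  d1 <- dist(mt$vertices[idx, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  expect_equal(mesh_volume(mt), mesh_volume(m), tolerance = 1e-9)
})

test_that("composition and inversion behave like the matrix product", {
  id <- rigid_transform()
  expect_equal(compose_transforms(id, id)$translation, c(0, 0, 0))

  t1 <- rigid_transform(c(1, 0, 0))
  t2 <- rigid_transform(c(0, 1, 0))
  expect_equal(compose_transforms(t1, t2)$translation, c(1, 1, 0))

  a <- rigid_transform(pitch = 10)
  b <- rigid_transform(pitch = -10)
  ab <- compose_transforms(a, b)
  expect_equal(abs(ab$pitch), 0, tolerance = 1e-9)
  expect_equal(ab$translation, c(0, 0, 0), tolerance = 1e-9)

  # compose(a, invert(a)) is the identity map pointwise
  tf <- rigid_transform(c(4, -7, 2), pitch = 31, yaw = -12, roll = 5,
                        center = c(3, 3, 3))
  P <- matrix(rnorm(30), ncol = 3)
  back <- transform_points(transform_points(P, tf), invert_transform(tf))
  expect_lt(max(abs(back - P)), 1e-9)

  # compose equals sequential application pointwise
  g <- rigid_transform(c(-2, 5, 1), pitch = -8, yaw = 14, roll = -3,
                       center = c(3, 3, 3))
  seq_app <- transform_points(transform_points(P, tf), g)
  one_app <- transform_points(P, compose_transforms(tf, g))
  expect_lt(max(abs(seq_app - one_app)), 1e-9)
})

test_that("centroids are pooled vertex means", {
  expect_equal(mesh_centroid(cube_mesh(10)), c(5, 5, 5))
  c1 <- cube_mesh(1, origin = c(-0.5, -0.5, -0.5))
  c2 <- cube_mesh(1, origin = c(9.5, -0.5, -0.5))
  expect_equal(mesh_centroid(c1, c2), c(5, 0, 0))
  ico <- icosphere(2, radius = 7, center = c(3, -2, 7))
  expect_equal(mesh_centroid(ico), c(3, -2, 7), tolerance = 1e-6)
  expect_error(mesh_centroid(), "at least one mesh")
})
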