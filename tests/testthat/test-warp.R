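## Small face scene shared by the warp tests.
make_test_faces <- function(n, size = 96, seed = 10, noise = 1.5) {
  cfg <- face_sim_config(image_size = size, landmark_noise_sd = noise,
                         rotation_range = 0.08, scale_range = 0.05,
                         translation_range = 0.03 * size, seed = seed)
  generate_faces(cfg, c(negative = n))
}

test_that("warping with source equal to the mesh vertices is the identity", {
  face <- make_test_faces(1)[[1]]
  mesh <- delaunay_mesh(face$landmarks)
  w <- piecewise_affine_warp(face$image, face$landmarks, mesh)
  inside <- w$coverage
  expect_gt(sum(inside), 500)
  expect_lt(max(abs(w$raster[inside] - face$image[inside])), 1e-6)
})

test_that("a pure translation of the source shifts the sampled appearance", {
  face <- make_test_faces(1)[[1]]
  mesh <- delaunay_mesh(face$landmarks)
  shift <- cbind(rep(10, 36), rep(0, 36))
  w <- piecewise_affine_warp(face$image, face$landmarks + shift, mesh)
  idx <- which(w$coverage, arr.ind = TRUE)
  ok <- idx[, 2] + 10 <= ncol(face$image)
  expected <- face$image[cbind(idx[ok, 1], idx[ok, 2] + 10)]
  expect_lt(max(abs(w$raster[idx[ok, , drop = FALSE]] - expected)), 1e-6)
})

test_that("a single-triangle warp equals the closed-form affine resampling", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  img <- cdlsmosaic:::gauss_blur(img, 2)
  target <- rbind(c(8, 8), c(56, 12), c(30, 56))
  source <- rbind(c(12, 10), c(50, 8), c(36, 52))
  mesh <- delaunay_mesh(target)
  w <- piecewise_affine_warp(img, source, mesh, 64, 64)
  ## direct 2x3 affine solve: [sx; sy] = M [px; py; 1]
  M <- t(source) %*% solve(rbind(t(target), c(1, 1, 1)))
  idx <- which(w$coverage, arr.ind = TRUE)
  src <- cbind(idx[, 2], idx[, 1], 1) %*% t(M)
  expected <- bilinear_sample(img, src[, 1], src[, 2])
  expect_lt(max(abs(w$raster[idx] - expected)), 1e-9)
})

test_that("degenerate source triangles are reported by index", {
  target <- rbind(c(8, 8), c(56, 12), c(30, 56))
  mesh <- delaunay_mesh(target)
  collinear_src <- rbind(c(0, 0), c(10, 10), c(20, 20))
  expect_error(
    piecewise_affine_warp(matrix(0.5, 64, 64), collinear_src, mesh),
    "degenerate source triangle 1")
})

test_that("warping preserves the intensity range (bilinear convexity)", {
  faces <- make_test_faces(3, seed = 44)
  mesh <- delaunay_mesh(faces[[1]]$landmarks)
  for (f in faces) {
    w <- piecewise_affine_warp(f$image, f$landmarks, mesh)
    expect_gte(min(w$raster, na.rm = TRUE), min(f$image) - 1e-12)
    expect_lte(max(w$raster, na.rm = TRUE), max(f$image) + 1e-12)
  }
})

test_that("averaging identical and constant rasters behaves exactly", {
  face <- make_test_faces(1)[[1]]
  mesh <- delaunay_mesh(face$landmarks)
  w <- piecewise_affine_warp(face$image, face$landmarks, mesh)
  avg <- average_appearance(list(w, w, w))
  expect_equal(avg$appearance[w$coverage], w$raster[w$coverage])
  expect_true(all(avg$coverage[w$coverage] == 3))

  c0 <- w; c0$raster[w$coverage] <- 0
  c100 <- w; c100$raster[w$coverage] <- 100
  half <- average_appearance(list(c0, c100))
  expect_true(all(half$appearance[w$coverage] == 50))
})

test_that("the average of two identical faces reproduces the face", {
  face <- make_test_faces(1, seed = 77)[[1]]
  avg <- build_average_face(list(face, face))
  expect_equal(avg$n, 2)
  ## the reference frame re-places the shape, so compare via a direct warp
  w <- piecewise_affine_warp(face$image, face$landmarks, avg$mesh)
  inside <- avg$coverage > 0
  expect_lt(max(abs(avg$appearance[inside] - w$raster[inside])), 1e-9)
  expect_error(build_average_face(list(face)), "at least 2")
})

test_that("group averages are bounded by the pointwise range of the warps", {
  faces <- make_test_faces(4, seed = 91)
  avg <- build_average_face(faces)
  warps <- lapply(faces, function(f)
    piecewise_affine_warp(f$image, f$landmarks, avg$mesh))
  stack <- simplify2array(lapply(warps, `[[`, "raster"))
  inside <- avg$coverage == length(faces)
  lo <- apply(stack, c(1, 2), min)
  hi <- apply(stack, c(1, 2), max)
  expect_true(all(avg$appearance[inside] >= lo[inside] - 1e-12))
  expect_true(all(avg$appearance[inside] <= hi[inside] + 1e-12))
})

test_that("groups with distinct landmark offsets give distinct mean shapes", {
  size <- 96
  offs <- default_group_offsets(size)
  offs$NIPBL <- offs$NIPBL * 2      # clearly separated group geometry
  offs$negative <- matrix(0, 36, 2)
  cfg <- face_sim_config(image_size = size, group_offsets = offs,
                         landmark_noise_sd = 1.5, seed = 13)
  faces <- generate_faces(cfg, c(NIPBL = 8, negative = 8))
  grp <- vapply(faces, `[[`, character(1), "group")
  avg_a <- build_average_face(faces[grp == "NIPBL"], group = "NIPBL")
  avg_b <- build_average_face(faces[grp == "negative"], group = "negative")
  between <- procrustes_distance(avg_a$shape, avg_b$shape)
  ## within-group perturbation: mean shapes of two disjoint halves
  half1 <- build_average_face(faces[grp == "negative"][1:4])
  half2 <- build_average_face(faces[grp == "negative"][5:8])
  within <- procrustes_distance(half1$shape, half2$shape)
  expect_gt(between, within)
})

test_that("average faces write valid PNGs with black uncovered pixels", {
  faces <- make_test_faces(2, seed = 3)
  avg <- build_average_face(faces)
  path <- withr::local_tempfile(fileext = ".png")
  write_average_face(avg, path)
  img <- read_face_image(path)
  expect_equal(dim(img), dim(avg$appearance))
  expect_true(all(img[avg$coverage == 0] == 0))
})
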