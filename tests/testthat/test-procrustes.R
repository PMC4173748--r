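test_that("aligning a constellation to itself is the identity", {
  tpl <- face_template(128)
  fit <- procrustes_align(tpl, tpl)
  expect_equal(fit$rotation, diag(2), tolerance = 1e-12)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0), tolerance = 1e-10)
  expect_equal(fit$distance, 0, tolerance = 1e-12)
})

test_that("a known similarity transform is recovered exactly", {
  tpl <- face_template(128)
  tf <- make_similarity(scale = 1.7, angle = 30 * pi / 180,
                        translation = c(5, -3))
  target <- apply_similarity(tpl, tf)
  fit <- procrustes_align(tpl, target)
  expect_lt(fit$distance, 1e-8)
  expect_equal(fit$scale, 1.7, tolerance = 1e-8)
  expect_equal(max(abs(fit$aligned - target)), 0, tolerance = 1e-8)
})

test_that("reflections are never used and collinear input errors", {
  tpl <- face_template(128)
  mirrored <- cbind(-tpl[, 1], tpl[, 2])
  fit <- procrustes_align(tpl, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$distance, 1)    # cannot match a mirror image
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(procrustes_align(line, line), "collinear")
})

test_that("alignment residual matches brute-force numeric minimisation", {
  set.seed(21)
  tpl <- face_template(128)
  noisy <- tpl + matrix(rnorm(72, sd = 1), 36, 2)
  tf <- make_similarity(scale = 1.2, angle = 0.4, translation = c(10, -6))
  src <- apply_similarity(tpl, tf)
  fit <- procrustes_align(src, noisy)
  expect_equal(fit$distance, oracle_procrustes_distance(src, noisy),
               tolerance = 1e-6)
})

test_that("alignment agrees with an established Procrustes implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  tpl <- face_template(128)
  noisy <- tpl + matrix(rnorm(72, sd = 2), 36, 2)
  fit <- procrustes_align(noisy, tpl)
  vfit <- vegan::procrustes(tpl, noisy, scale = TRUE, symmetric = FALSE)
  expect_equal(fit$distance, sqrt(vfit$ss / 36), tolerance = 1e-8)
})

test_that("GPA of copies returns that shape with zero residuals", {
  tpl <- face_template(128)
  gpa <- generalized_procrustes(list(tpl, tpl, tpl, tpl))
  expect_true(gpa$converged)
  expect_equal(max(gpa$residuals), 0, tolerance = 1e-10)
  expect_lt(procrustes_distance(gpa$mean, tpl), 1e-10)
})

test_that("the GPA mean of two shapes is equidistant from both", {
  set.seed(4)
  tpl <- face_template(128)
  other <- tpl + matrix(rnorm(72, sd = 3), 36, 2)
  gpa <- generalized_procrustes(list(tpl, other))
  d1 <- procrustes_distance(tpl, gpa$mean)
  d2 <- procrustes_distance(other, gpa$mean)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("GPA recovers the template from transformed noisy constellations", {
  set.seed(57)
  tpl <- face_template(128)
  shapes <- lapply(seq_len(50), function(i) {
    tf <- make_similarity(scale = runif(1, 0.8, 1.25),
                          angle = runif(1, -0.5, 0.5),
                          translation = runif(2, -20, 20))
    apply_similarity(tpl + matrix(rnorm(72, sd = 2), 36, 2), tf)
  })
  gpa <- generalized_procrustes(shapes)
  expect_true(gpa$converged)
  ## residual measured back in template pixel units
  fit <- procrustes_align(gpa$mean, tpl)
  expect_lt(fit$distance, 0.5)
})

test_that("the GPA mean is a fixed point of re-analysis", {
  set.seed(6)
  tpl <- face_template(128)
  shapes <- lapply(1:10, function(i) tpl + matrix(rnorm(72, sd = 2), 36, 2))
  gpa <- generalized_procrustes(shapes)
  gpa2 <- generalized_procrustes(gpa$aligned)
  expect_lt(sqrt(mean(rowSums((gpa2$mean - gpa$mean)^2))), 1e-6)
})

test_that("Delaunay meshes satisfy the empty-circumcircle property", {
  tri <- delaunay_mesh(rbind(c(0, 0), c(4, 0), c(1, 3)))
  expect_equal(nrow(tri$triangles), 1)

  square <- delaunay_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(square$triangles), 2)
  shared <- intersect(square$triangles[1, ], square$triangles[2, ])
  expect_equal(length(shared), 2)      # two triangles sharing a diagonal

  mesh <- delaunay_mesh(face_template(128))
  expect_true(all(seq_len(36) %in% mesh$triangles))
  expect_true(oracle_delaunay_ok(mesh))
  expect_error(delaunay_mesh(cbind(1:5, 1:5)), "collinear")
})

test_that("landmark files round-trip through the documented text format", {
  tpl <- face_template(96)
  path <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(tpl, path)
  lines <- readLines(path)
  expect_length(lines, 36)
  expect_match(lines[1], "\t")
  back <- read_landmarks(path)
  expect_equal(unname(back), unname(tpl), tolerance = 1e-12)
})
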