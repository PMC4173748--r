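## Landmark constellations are n x 2 numeric matrices of (x, y) image
## coordinates: origin top-left, x rightward, y downward. The face pipeline
## uses 36 ordered points per face.

as_constellation <- function(x, n_points = NULL) {
  m <- as.matrix(x)
  if (ncol(m) != 2) stop("a constellation is an n x 2 matrix of (x, y)")
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("constellation coordinates must be finite")
  if (!is.null(n_points) && nrow(m) != n_points)
    stop("expected ", n_points, " landmarks, got ", nrow(m))
  if (anyDuplicated(m)) stop("constellation has coincident points")
  m
}

centroid_size <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  sqrt(sum(c0^2))
}

## Unit centroid size, centred at the origin.
normalize_shape <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  s <- sqrt(sum(c0^2))
  if (s == 0) stop("degenerate constellation: all points coincide")
  c0 / s
}

#' Similarity (Procrustes) alignment of one constellation onto another
#'
#' Finds the translation, isotropic scale and rotation (reflections
#' disallowed) minimising the sum of squared distances between corresponding
#' landmarks, via the closed-form solution (SVD of the centred
#' cross-covariance, smallest singular direction sign-constrained to keep the
#' determinant positive). Points are row vectors, so the fitted map is
#' `aligned = scale * source %*% rotation + translation`.
#'
#' @param source,target constellations (n x 2 matrices, same landmark order).
#' @param allow_scale fit the isotropic scale (default `TRUE`); otherwise a
#'   rigid transform.
#' @return list of class `procrustes_fit`: `aligned` (transformed source),
#'   `rotation` (2 x 2), `scale`, `translation` (length 2), `distance`
#'   (root-mean-square residual per landmark).
#' @export
procrustes_align <- function(source, target, allow_scale = TRUE) {
  X <- as_constellation(source)
  Y <- as_constellation(target)
  if (nrow(X) != nrow(Y)) stop("constellations differ in landmark count")
  if (nrow(X) < 3) stop("need at least 3 landmarks")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-10 * sv$d[1])
    stop("degenerate constellation: landmarks are collinear")
  M <- crossprod(Xc, Yc)          # 2 x 2 cross-covariance
  dec <- svd(M)
  d <- sign(det(dec$u %*% t(dec$v)))
  D <- diag(c(1, d))
  R <- dec$u %*% D %*% t(dec$v)   # rotation, det(R) = +1
  s <- if (allow_scale) sum(dec$d * c(1, d)) / sum(Xc^2) else 1
  t_vec <- my - s * mx %*% R
  aligned <- s * X %*% R + matrix(t_vec, nrow(X), 2, byrow = TRUE)
  structure(list(aligned = aligned, rotation = R, scale = s,
                 translation = as.numeric(t_vec),
                 distance = sqrt(mean(rowSums((aligned - Y)^2)))),
            class = "procrustes_fit")
}

#' Generalized Procrustes analysis of a set of constellations
#'
#' Iterative alignment to a common mean shape: the mean is initialised as the
#' first constellation (centred, unit centroid size), every constellation is
#' similarity-aligned to it, the mean is recomputed from the aligned set and
#' renormalised, and the cycle repeats until the mean moves less than `tol`
#' (root-mean-square per landmark) or `max_iter` is reached (with a warning;
#' the best iterate is returned). The mean shape is defined up to rotation;
#' its returned orientation follows the first constellation.
#'
#' @param constellations list of at least two n x 2 landmark matrices with
#'   identical landmark order.
#' @param tol convergence tolerance on the mean-shape change (default 1e-7).
#' @param max_iter iteration cap (default 100).
#' @return list of class `gpa_fit`: `mean` (unit-centroid-size mean shape),
#'   `aligned` (list of aligned constellations), `iterations`, `converged`,
#'   `residuals` (per-shape Procrustes RMS distance to the mean).
#' @export
generalized_procrustes <- function(constellations, tol = 1e-7,
                                   max_iter = 100L) {
  if (length(constellations) < 2)
    stop("generalized Procrustes needs at least 2 constellations")
  shapes <- lapply(constellations, as_constellation)
  np <- unique(vapply(shapes, nrow, integer(1)))
  if (length(np) != 1) stop("constellations differ in landmark count")
  mean_shape <- normalize_shape(shapes[[1]])
  converged <- FALSE
  iter <- 0L
  aligned <- shapes
  while (iter < max_iter) {
    iter <- iter + 1L
    aligned <- lapply(shapes, function(s) procrustes_align(s, mean_shape)$aligned)
    new_mean <- normalize_shape(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean(rowSums((new_mean - mean_shape)^2)))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes did not converge in ", max_iter,
            " iterations; returning last iterate")
  res <- vapply(shapes, function(s) procrustes_align(s, mean_shape)$distance,
                numeric(1))
  structure(list(mean = mean_shape, aligned = aligned, iterations = iter,
                 converged = converged, residuals = res),
            class = "gpa_fit")
}

#' Procrustes distance between two constellations
#'
#' Root-mean-square residual after optimal similarity alignment of `a`
#' onto `b`.
#'
#' @param a,b constellations.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) procrustes_align(a, b)$distance

#' Read / write landmark constellation files
#'
#' Plain-text format: one landmark per line, `x<TAB>y`, in the documented
#' template order (see [face_template()]).
#'
#' @param path file path.
#' @param n_points expected landmark count (default 36; `NULL` to skip the
#'   check).
#' @return `read_landmarks`: an n x 2 matrix.
#' @export
read_landmarks <- function(path, n_points = 36L) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   col.names = c("x", "y")))
  as_constellation(m, n_points)
}

#' @rdname read_landmarks
#' @param landmarks an n x 2 matrix to write.
#' @export
write_landmarks <- function(landmarks, path) {
  m <- as_constellation(landmarks)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
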