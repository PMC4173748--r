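## Image convention: a grayscale image is a numeric matrix in [0, 1] with
## img[row, col]; landmark coordinates are (x, y) with x = column and
## y = row (floating point, pixel centre of img[i, j] at x = j, y = i).
## Multi-channel images are 3-D arrays (rows, cols, channels) treated
## identically per channel.

#' Bilinear sampling of an image at fractional coordinates
#'
#' Out-of-bounds locations are clamped to the nearest edge pixel.
#'
#' @param image numeric matrix.
#' @param x,y coordinate vectors (x = column, y = row).
#' @return vector of interpolated intensities.
#' @export
bilinear_sample <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    image[cbind(y0 + 1, x0 + 1)] * fx * fy
}

each_channel <- function(image, f) {
  if (length(dim(image)) == 2) return(f(as.matrix(image)))
  out <- image
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- f(image[, , ch])
  out
}

#' Piecewise affine warp of a face image onto a reference mesh
#'
#' Maps the appearance of one face onto the reference frame: every pixel
#' centre inside the mesh hull is located in its triangle (first containing
#' triangle in mesh order on shared edges), its barycentric coordinates are
#' transferred to the corresponding source triangle (the three vertex
#' correspondences define the per-triangle affine map), and the source image
#' is sampled bilinearly at the resulting location. Pixels outside the hull
#' are uncovered (`NA` intensity, `FALSE` coverage).
#'
#' @param image source face image (matrix, or rows x cols x channels array).
#' @param source landmark constellation of `image`, in one-to-one index
#'   correspondence with the mesh vertices.
#' @param mesh reference [delaunay_mesh()] whose vertices live in the output
#'   frame.
#' @param width,height output raster size (defaults to the input size).
#' @return list of class `warped_face`: `raster` (same layout as `image`,
#'   `NA` outside the hull) and `coverage` (logical matrix).
#' @export
piecewise_affine_warp <- function(image, source, mesh,
                                  width = NULL, height = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  src <- as_constellation(source)
  if (nrow(src) != nrow(mesh$vertices))
    stop("source constellation and mesh vertex counts differ")
  dims <- dim(image)
  if (is.null(width)) width <- dims[2]
  if (is.null(height)) height <- dims[1]
  V <- mesh$vertices
  tri <- mesh$triangles

  ## source-triangle degeneracy check (target triangles are already valid)
  for (k in seq_len(nrow(tri))) {
    a <- triangle_area(src[tri[k, 1], ], src[tri[k, 2], ], src[tri[k, 3], ])
    if (a < 1e-9)
      stop("degenerate source triangle ", k, " (vertices ",
           paste(tri[k, ], collapse = ","), ")")
  }

  assigned <- matrix(FALSE, height, width)
  sx <- matrix(NA_real_, height, width)
  sy <- matrix(NA_real_, height, width)
  tol <- -1e-9
  for (k in seq_len(nrow(tri))) {
    t1 <- V[tri[k, 1], ]; t2 <- V[tri[k, 2], ]; t3 <- V[tri[k, 3], ]
    cols <- max(1L, floor(min(t1[1], t2[1], t3[1]))):
      min(width, ceiling(max(t1[1], t2[1], t3[1])))
    rows <- max(1L, floor(min(t1[2], t2[2], t3[2]))):
      min(height, ceiling(max(t1[2], t2[2], t3[2])))
    if (!length(cols) || !length(rows)) next
    px <- rep(cols, each = length(rows))
    py <- rep(rows, times = length(cols))
    det_t <- (t2[2] - t3[2]) * (t1[1] - t3[1]) +
      (t3[1] - t2[1]) * (t1[2] - t3[2])
    l1 <- ((t2[2] - t3[2]) * (px - t3[1]) + (t3[1] - t2[1]) * (py - t3[2])) / det_t
    l2 <- ((t3[2] - t1[2]) * (px - t3[1]) + (t1[1] - t3[1]) * (py - t3[2])) / det_t
    l3 <- 1 - l1 - l2
    idx <- cbind(py, px)
    inside <- l1 >= tol & l2 >= tol & l3 >= tol & !assigned[idx]
    if (!any(inside)) next
    s1 <- src[tri[k, 1], ]; s2 <- src[tri[k, 2], ]; s3 <- src[tri[k, 3], ]
    sel <- idx[inside, , drop = FALSE]
    sx[sel] <- l1[inside] * s1[1] + l2[inside] * s2[1] + l3[inside] * s3[1]
    sy[sel] <- l1[inside] * s1[2] + l2[inside] * s2[2] + l3[inside] * s3[2]
    assigned[sel] <- TRUE
  }

  ok <- which(assigned)
  sample_one <- function(ch) {
    out <- matrix(NA_real_, height, width)
    out[ok] <- bilinear_sample(ch, sx[ok], sy[ok])
    out
  }
  raster <- each_channel(image, sample_one)
  structure(list(raster = raster, coverage = assigned),
            class = "warped_face")
}

#' Pixel-wise average of warped faces
#'
#' Arithmetic mean over the faces covering each pixel, with the per-pixel
#' contribution count recorded. Pixels covered by no face stay `NA`.
#'
#' @param warped list of `warped_face` objects on the same reference frame.
#' @return list with `appearance` (mean raster) and `coverage` (integer
#'   contribution counts).
#' @export
average_appearance <- function(warped) {
  if (!length(warped)) stop("no warped faces to average")
  stopifnot(all(vapply(warped, inherits, logical(1), "warped_face")))
  cov <- Reduce(`+`, lapply(warped, function(w) w$coverage + 0L))
  mean_ch <- function(rasters) {
    tot <- Reduce(`+`, lapply(rasters, function(r) ifelse(is.na(r), 0, r)))
    out <- tot / cov
    out[cov == 0] <- NA_real_
    out
  }
  first <- warped[[1]]$raster
  if (length(dim(first)) == 2) {
    appearance <- mean_ch(lapply(warped, `[[`, "raster"))
  } else {
    appearance <- first
    for (ch in seq_len(dim(first)[3]))
      appearance[, , ch] <- mean_ch(lapply(warped, function(w) w$raster[, , ch]))
  }
  list(appearance = appearance, coverage = cov)
}

## Map the unit-size GPA mean shape into raster coordinates: scaled so its
## bounding box fills `box` of the frame's shorter side, centred.
mean_shape_to_frame <- function(mean_shape, width, height, box = 0.8) {
  rng <- apply(mean_shape, 2, range)
  extent <- rng[2, ] - rng[1, ]
  s <- box * min(width / extent[1], height / extent[2])
  centre_in <- colMeans(rng)
  centre_out <- c((width + 1) / 2, (height + 1) / 2)
  sweep(mean_shape, 2, centre_in) * s +
    matrix(centre_out, nrow(mean_shape), 2, byrow = TRUE)
}

#' Build the average face of a patient group
#'
#' The full average-face construction: all landmark constellations are
#' brought into register by generalized Procrustes analysis and averaged to
#' give the mean shape constellation; the mean shape (placed centrally in
#' the reference raster) is Delaunay-triangulated into the reference face
#' mesh; each individual appearance is mapped onto that mesh by piecewise
#' affine warping; and the mapped appearances are averaged pixel-wise. For
#' 36-point constellations the mean shape is rotated onto the canonical
#' upright template ([face_template()]) before meshing, so the reference
#' frame — and hence the average — does not depend on a tilt, scale or
#' shift shared by every input photograph.
#'
#' @param faces list of faces, each a list with elements `image` and
#'   `landmarks` (n x 2, consistent landmark order across faces). At least 2.
#' @param group optional group label stored in the result.
#' @param width,height reference frame size (defaults to the first image).
#' @param box fraction of the frame the mean shape's bounding box occupies
#'   (default 0.8).
#' @return list of class `average_face`: `shape` (mean constellation in
#'   frame coordinates), `appearance`, `coverage`, `mesh`, `n`, `group`,
#'   and `gpa` convergence diagnostics.
#' @export
build_average_face <- function(faces, group = NULL, width = NULL,
                               height = NULL, box = 0.8) {
  if (length(faces) < 2) stop("need at least 2 faces to build an average")
  dims <- dim(faces[[1]]$image)
  if (is.null(width)) width <- dims[2]
  if (is.null(height)) height <- dims[1]
  gpa <- generalized_procrustes(lapply(faces, `[[`, "landmarks"))
  mean_shape <- gpa$mean
  ## canonical orientation: the GPA mean inherits the inputs' common
  ## orientation, so a cohort of uniformly tilted photographs would give a
  ## tilted average. For the standard 36-point scheme the mean is rotated
  ## onto the upright canonical template, making the whole pipeline
  ## invariant to a global similarity transform of the inputs.
  if (nrow(mean_shape) == 36)
    mean_shape <- normalize_shape(
      procrustes_align(mean_shape, normalize_shape(face_template()))$aligned)
  ref <- mean_shape_to_frame(mean_shape, width, height, box)
  mesh <- delaunay_mesh(ref)
  warped <- lapply(faces, function(f)
    piecewise_affine_warp(f$image, f$landmarks, mesh, width, height))
  avg <- average_appearance(warped)
  structure(list(shape = ref, appearance = avg$appearance,
                 coverage = avg$coverage, mesh = mesh, n = length(faces),
                 group = group,
                 gpa = list(iterations = gpa$iterations,
                            converged = gpa$converged,
                            residuals = gpa$residuals)),
            class = "average_face")
}

#' @export
print.average_face <- function(x, ...) {
  cat("Average face", if (!is.null(x$group)) paste0("for group '", x$group, "'"),
      "from n =", x$n, "faces;",
      sum(x$coverage > 0), "covered pixels; GPA",
      if (x$gpa$converged) "converged" else "did not converge",
      "in", x$gpa$iterations, "iteration(s)\n")
  invisible(x)
}

#' Write an average face to PNG (uncovered pixels rendered black)
#'
#' @param avg an `average_face`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_average_face <- function(avg, path) {
  img <- avg$appearance
  img[is.na(img)] <- 0
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Read a face image as a numeric raster in \[0, 1\]
#'
#' Grayscale PNGs load as a matrix; colour PNGs as a rows x cols x channels
#' array (alpha dropped).
#'
#' @param path PNG path.
#' @return matrix or 3-D array.
#' @export
read_face_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]
  img
}

#' @rdname read_face_image
#' @param image numeric raster in \[0, 1\].
#' @export
write_face_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
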