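#' The canonical 36-point facial landmark template
#'
#' The landmark annotation scheme is fixed by this package (row order is the
#' file order of landmark files). Coordinates are fractions of the image
#' frame (origin top-left, x rightward, y downward); multiply by the image
#' size to get pixels. Layout, by row index:
#' 1-9 face outline (chin, left/right jaw, left/right cheek, left/right
#' temple, left/right forehead), 10-12 left brow, 13-15 right brow,
#' 16-19 left eye (outer, top, inner, bottom), 20-23 right eye (inner, top,
#' outer, bottom), 24-28 nose (bridge, tip, left/right ala, columella),
#' 29-30 philtrum ridges, 31-36 mouth (left corner, upper-lip left, mid,
#' right, right corner, lower-lip mid).
#'
#' @param image_size optional scalar or `c(width, height)`; when given, the
#'   template is returned in pixel coordinates.
#' @return 36 x 2 matrix of (x, y) with descriptive rownames.
#' @export
face_template <- function(image_size = NULL) {
  pts <- rbind(
    chin         = c(0.50, 0.92),
    jaw_l        = c(0.30, 0.82), jaw_r       = c(0.70, 0.82),
    cheek_l      = c(0.22, 0.62), cheek_r     = c(0.78, 0.62),
    temple_l     = c(0.24, 0.38), temple_r    = c(0.76, 0.38),
    forehead_l   = c(0.35, 0.16), forehead_r  = c(0.65, 0.16),
    brow_l_out   = c(0.29, 0.385), brow_l_mid = c(0.37, 0.355),
    brow_l_in    = c(0.44, 0.375),
    brow_r_in    = c(0.56, 0.375), brow_r_mid = c(0.63, 0.355),
    brow_r_out   = c(0.71, 0.385),
    eye_l_out    = c(0.31, 0.445), eye_l_top  = c(0.37, 0.425),
    eye_l_in     = c(0.43, 0.445), eye_l_bot  = c(0.37, 0.462),
    eye_r_in     = c(0.57, 0.445), eye_r_top  = c(0.63, 0.425),
    eye_r_out    = c(0.69, 0.445), eye_r_bot  = c(0.63, 0.462),
    nose_bridge  = c(0.50, 0.47), nose_tip    = c(0.50, 0.60),
    ala_l        = c(0.44, 0.615), ala_r      = c(0.56, 0.615),
    columella    = c(0.50, 0.645),
    philtrum_l   = c(0.47, 0.685), philtrum_r = c(0.53, 0.685),
    mouth_l      = c(0.40, 0.735), lip_up_l   = c(0.45, 0.722),
    lip_up_mid   = c(0.50, 0.717), lip_up_r   = c(0.55, 0.722),
    mouth_r      = c(0.60, 0.735), lip_low_mid = c(0.50, 0.768)
  )
  colnames(pts) <- c("x", "y")
  if (!is.null(image_size)) {
    image_size <- rep_len(image_size, 2)
    pts <- pts * matrix(image_size, nrow(pts), 2, byrow = TRUE)
  }
  pts
}

## ---- similarity transforms ------------------------------------------------

#' Build and apply 2-D similarity transforms
#'
#' A similarity transform `x' = s R (x - c) + c + t` with rotation angle
#' `angle` (radians, positive = clockwise in image coordinates since y runs
#' downward), isotropic scale `s`, translation `t`, about centre `c`.
#'
#' @param scale isotropic scale factor.
#' @param angle rotation angle in radians.
#' @param translation length-2 translation (x, y).
#' @param centre length-2 centre of rotation/scaling.
#' @return list of class `similarity_transform` with the 2 x 2 matrix `A`
#'   and offset `b` such that points map as `p %*% t(A) + b`.
#' @export
make_similarity <- function(scale = 1, angle = 0, translation = c(0, 0),
                            centre = c(0, 0)) {
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2,
              byrow = TRUE)
  A <- scale * R
  b <- centre + translation - as.numeric(A %*% centre)
  structure(list(A = A, b = b, scale = scale, angle = angle,
                 translation = translation, centre = centre),
            class = "similarity_transform")
}

#' @rdname make_similarity
#' @param points n x 2 matrix of (x, y) points.
#' @param transform a `similarity_transform`.
#' @export
apply_similarity <- function(points, transform) {
  points %*% t(transform$A) +
    matrix(transform$b, nrow(points), 2, byrow = TRUE)
}

#' @rdname make_similarity
#' @export
invert_similarity <- function(transform) {
  Ainv <- solve(transform$A)
  structure(list(A = Ainv, b = as.numeric(-Ainv %*% transform$b),
                 scale = 1 / transform$scale, angle = -transform$angle,
                 translation = NULL, centre = NULL),
            class = "similarity_transform")
}

#' Resample an image under a similarity transform
#'
#' Each output pixel centre is mapped through the inverse transform and the
#' input image sampled bilinearly (edge-clamped), so the image moves the
#' same way as points mapped with [apply_similarity()].
#'
#' @param image numeric matrix or rows x cols x channels array.
#' @param transform a `similarity_transform`.
#' @param width,height output size (defaults: input size).
#' @return transformed image.
#' @export
warp_similarity <- function(image, transform, width = NULL, height = NULL) {
  dims <- dim(image)
  if (is.null(width)) width <- dims[2]
  if (is.null(height)) height <- dims[1]
  inv <- invert_similarity(transform)
  px <- rep(seq_len(width), each = height)
  py <- rep(seq_len(height), times = width)
  s <- cbind(px, py) %*% t(inv$A) +
    matrix(inv$b, width * height, 2, byrow = TRUE)
  each_channel(image, function(ch)
    matrix(bilinear_sample(ch, s[, 1], s[, 2]), height, width))
}

## ---- rasterisation helpers ------------------------------------------------

## Even-odd point-in-polygon fill over the polygon's bounding box.
fill_polygon <- function(canvas, poly, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  cols <- max(1L, floor(min(poly[, 1]))):min(w, ceiling(max(poly[, 1])))
  rows <- max(1L, floor(min(poly[, 2]))):min(h, ceiling(max(poly[, 2])))
  px <- rep(cols, each = length(rows))
  py <- rep(rows, times = length(cols))
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  canvas[cbind(py, px)[inside, , drop = FALSE]] <- value
  canvas
}

## Thick line segment: pixels within `halfwidth` of the segment.
draw_stroke <- function(canvas, p1, p2, halfwidth, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  cols <- max(1L, floor(min(p1[1], p2[1]) - halfwidth)):
    min(w, ceiling(max(p1[1], p2[1]) + halfwidth))
  rows <- max(1L, floor(min(p1[2], p2[2]) - halfwidth)):
    min(h, ceiling(max(p1[2], p2[2]) + halfwidth))
  px <- rep(cols, each = length(rows))
  py <- rep(rows, times = length(cols))
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - p1[1]) * d[1] + (py - p1[2]) * d[2]) / len2))
  dist2 <- (px - (p1[1] + t * d[1]))^2 + (py - (p1[2] + t * d[2]))^2
  sel <- dist2 <= halfwidth^2
  canvas[cbind(py, px)[sel, , drop = FALSE]] <- value
  canvas
}

## Separable Gaussian blur via banded convolution matrices, edge-renormalised.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  band <- function(n) {
    r <- ceiling(3 * sigma)
    k <- stats::dnorm(-r:r, sd = sigma)
    M <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      M[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    M / rowSums(M)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

## ---- face rendering -------------------------------------------------------

default_texture <- function() {
  list(background = 0.12, skin = 0.75, brow = 0.30, eye = 0.22,
       nose = 0.62, philtrum = 0.68, lip = 0.35, blur_sigma = NULL,
       illumination_jitter = 0.05)
}

#' Render a synthetic face from a landmark constellation
#'
#' Draws smooth shaded regions anchored on the 36 landmarks (skin polygon
#' through the outline points, brow and nose strokes, eye and mouth
#' polygons, philtrum ridges) and softens them with a Gaussian blur, giving
#' a schematic grayscale face whose geometry is exactly the supplied
#' constellation.
#'
#' @param landmarks 36 x 2 constellation in pixel coordinates (template row
#'   order).
#' @param width,height image size in pixels.
#' @param texture named list of feature intensities (see
#'   `cdlsmosaic:::default_texture`); `blur_sigma` defaults to 1% of the
#'   image width (at least 1 px).
#' @param illumination global intensity scale factor (1 = nominal).
#' @return grayscale matrix in \[0, 1\].
#' @export
render_face <- function(landmarks, width, height, texture = default_texture(),
                        illumination = 1) {
  lm <- as_constellation(landmarks, 36L)
  tx <- utils::modifyList(default_texture(), texture)
  sigma <- tx$blur_sigma %||% max(1, 0.01 * width)
  canvas <- matrix(tx$background, height, width)
  ## gentle top-lit illumination gradient
  canvas <- canvas + 0.03 * (1 - (row(canvas) / height))

  outline <- lm[c(8, 6, 4, 2, 1, 3, 5, 7, 9), ]
  canvas <- fill_polygon(canvas, outline, tx$skin)
  hw <- max(1, 0.012 * width)
  for (side in list(10:12, 13:15))
    for (k in 1:2)
      canvas <- draw_stroke(canvas, lm[side[k], ], lm[side[k + 1], ],
                            1.4 * hw, tx$brow)
  canvas <- fill_polygon(canvas, lm[c(16, 17, 18, 19), ], tx$eye)
  canvas <- fill_polygon(canvas, lm[c(20, 21, 22, 23), ], tx$eye)
  canvas <- draw_stroke(canvas, lm[24, ], lm[25, ], 0.7 * hw, tx$nose)
  canvas <- draw_stroke(canvas, lm[25, ], lm[26, ], 0.7 * hw, tx$nose)
  canvas <- draw_stroke(canvas, lm[25, ], lm[27, ], 0.7 * hw, tx$nose)
  canvas <- draw_stroke(canvas, lm[26, ], lm[28, ], 0.6 * hw, tx$nose)
  canvas <- draw_stroke(canvas, lm[27, ], lm[28, ], 0.6 * hw, tx$nose)
  canvas <- draw_stroke(canvas, lm[29, ], lm[31, ], 0.6 * hw, tx$philtrum)
  canvas <- draw_stroke(canvas, lm[30, ], lm[34, ], 0.6 * hw, tx$philtrum)
  canvas <- fill_polygon(canvas, lm[c(31, 32, 33, 34, 35, 36), ], tx$lip)

  pmin(pmax(illumination * gauss_blur(canvas, sigma), 0), 1)
}

## ---- face simulation config and generator --------------------------------

#' Configuration for the synthetic face generator
#'
#' @param image_size image width and height in pixels (square frame,
#'   default 128).
#' @param group_offsets named list of per-group mean landmark offsets: each
#'   a 36 x 2 matrix (pixels) added to the template for every member of
#'   that group. Groups absent from the list get zero offset. The default
#'   gives the `"NIPBL"` group the characteristic long philtrum and thin
#'   upper lip (mouth block shifted down, upper-lip points raised towards
#'   the lip line).
#' @param landmark_noise_sd per-individual isotropic Gaussian landmark
#'   jitter in pixels (default 2).
#' @param texture feature intensity list, see [render_face()].
#' @param illumination_jitter half-range of the uniform global illumination
#'   factor (default 0.05, i.e. factors in \[0.95, 1.05\]).
#' @param rotation_range,scale_range,translation_range half-ranges of the
#'   uniform random similarity transform applied to each face (radians,
#'   relative scale, pixels).
#' @param margin minimum distance (pixels) every transformed landmark must
#'   keep from the image border.
#' @param on_out_of_bounds `"resample"` (redraw the transform, up to 25
#'   times) or `"error"` when a landmark leaves the frame.
#' @param seed random seed.
#' @return list of class `face_sim_config`.
#' @export
face_sim_config <- function(image_size = 128L,
                            group_offsets = default_group_offsets(image_size),
                            landmark_noise_sd = 2,
                            texture = default_texture(),
                            illumination_jitter = 0.05,
                            rotation_range = 0.1,
                            scale_range = 0.08,
                            translation_range = 0.04 * image_size,
                            margin = 2,
                            on_out_of_bounds = c("resample", "error"),
                            seed = 1L) {
  template <- face_template(image_size)
  if (nrow(template) != 36) stop("template must have exactly 36 points")
  if (any(template < 0) || any(template[, 1] > image_size) ||
      any(template[, 2] > image_size))
    stop("template points must lie inside the image bounds")
  structure(list(image_size = as.integer(image_size), template = template,
                 group_offsets = group_offsets,
                 landmark_noise_sd = landmark_noise_sd, texture = texture,
                 illumination_jitter = illumination_jitter,
                 rotation_range = rotation_range, scale_range = scale_range,
                 translation_range = translation_range, margin = margin,
                 on_out_of_bounds = match.arg(on_out_of_bounds),
                 seed = as.integer(seed)),
            class = "face_sim_config")
}

#' Default per-group landmark offsets
#'
#' @param image_size image size in pixels.
#' @return named list of 36 x 2 offset matrices.
#' @export
default_group_offsets <- function(image_size = 128L) {
  u <- image_size / 128            # offsets specified at 128 px and scaled
  nipbl <- matrix(0, 36, 2)
  nipbl[29:36, 2] <- 4 * u         # philtrum + mouth shifted down: long philtrum
  nipbl[32:34, 2] <- nipbl[32:34, 2] + 1.5 * u  # upper lip thinned
  nipbl[c(10, 15), 2] <- 2 * u     # arched brows: outer ends lower
  nipbl[c(12, 13), 2] <- -1 * u
  list(NIPBL = nipbl)
}

#' Generate landmark-annotated synthetic face images
#'
#' Each face's constellation is the template plus its group's mean offset
#' plus per-individual Gaussian landmark noise; a random similarity
#' transform (rotation, scale, translation about the image centre) is then
#' applied and the face rendered at the transformed landmarks, so image and
#' constellation stay exactly consistent. Illumination is jittered per
#' face. Reproducible under the config seed.
#'
#' @param config a [face_sim_config()].
#' @param n_per_group named integer vector, e.g. `c(NIPBL = 10, negative = 10)`.
#' @return list of faces, each a list with `image` (grayscale matrix),
#'   `landmarks` (36 x 2), `group`, and the applied `transform`.
#' @export
generate_faces <- function(config = face_sim_config(), n_per_group) {
  stopifnot(inherits(config, "face_sim_config"))
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector of group sizes")
  set.seed(config$seed)
  size <- config$image_size
  centre <- c((size + 1) / 2, (size + 1) / 2)
  faces <- list()
  for (grp in names(n_per_group)) {
    offset <- config$group_offsets[[grp]]
    if (is.null(offset)) offset <- matrix(0, 36, 2)
    for (i in seq_len(n_per_group[[grp]])) {
      lm0 <- config$template + offset +
        matrix(stats::rnorm(72, 0, config$landmark_noise_sd), 36, 2)
      for (try in seq_len(25L)) {
        tf <- make_similarity(
          scale = 1 + stats::runif(1, -config$scale_range, config$scale_range),
          angle = stats::runif(1, -config$rotation_range, config$rotation_range),
          translation = stats::runif(2, -config$translation_range,
                                     config$translation_range),
          centre = centre)
        lm <- apply_similarity(lm0, tf)
        ok <- all(lm >= 1 + config$margin) &&
          all(lm <= size - config$margin)
        if (ok) break
        if (config$on_out_of_bounds == "error" || try == 25L)
          stop("landmarks left the image frame for group '", grp, "'")
      }
      illum <- 1 + stats::runif(1, -config$illumination_jitter,
                                config$illumination_jitter)
      faces[[length(faces) + 1L]] <-
        list(image = render_face(lm, size, size, config$texture, illum),
             landmarks = lm, group = grp, transform = tf)
    }
  }
  faces
}
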