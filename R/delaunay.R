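## Bowyer-Watson Delaunay triangulation in 2-D. Written in-package because
## the face pipeline needs a reference mesh over 36 landmarks; at that scale
## the incremental algorithm is exact enough with a relative tolerance on the
## circumcircle test. Triangles are canonicalised (ascending vertex indices,
## lexicographic order) so the mesh is deterministic for a given point order.

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (d == 0) return(NULL)                      # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)          # centre + squared radius
}

triangle_area <- function(p1, p2, p3) {
  abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
        (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
}

#' Delaunay triangulation of a constellation
#'
#' Builds the reference face mesh: a triangulation of the landmark points in
#' which no point lies strictly inside any triangle's circumcircle, covering
#' the convex hull of the points. Incremental Bowyer-Watson construction
#' with a super-triangle; co-circular point groups (where the Delaunay
#' diagonal is not unique) are resolved deterministically by insertion
#' order.
#'
#' @param points n x 2 matrix of vertex coordinates (n >= 3, not all
#'   collinear).
#' @return list of class `triangle_mesh` with `vertices` (the input points)
#'   and `triangles` (m x 3 integer matrix of vertex indices, each row
#'   ascending, rows in lexicographic order).
#' @export
delaunay_mesh <- function(points) {
  pts <- as_constellation(points)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  if (sv$d[2] < 1e-10 * sv$d[1]) stop("points are collinear")

  ## super-triangle comfortably containing every point
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1)
  mid <- colMeans(rng)
  super <- rbind(c(mid[1] - 20 * span, mid[2] - 10 * span),
                 c(mid[1] + 20 * span, mid[2] - 10 * span),
                 c(mid[1], mid[2] + 20 * span))
  all_pts <- rbind(pts, super)
  eps <- 1e-10 * span^2

  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circ <- list(circumcircle(super[1, ], super[2, ], super[3, ]))

  for (i in seq_len(n)) {
    p <- pts[i, ]
    bad <- vapply(circ, function(cc)
      (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3] - eps, logical(1))
    if (!any(bad)) stop("internal error: point outside all circumcircles")
    ## boundary of the cavity = edges of bad triangles that appear only once
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (k in seq_len(nrow(boundary))) {
      tri <- c(boundary[k, 1], boundary[k, 2], i)
      cc <- circumcircle(all_pts[tri[1], ], all_pts[tri[2], ],
                         all_pts[tri[3], ])
      if (is.null(cc)) next                     # degenerate sliver, skip
      tris <- c(tris, list(tri))
      circ <- c(circ, list(cc))
    }
  }

  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  tri_mat <- do.call(rbind, lapply(tris[keep], sort))
  tri_mat <- tri_mat[order(tri_mat[, 1], tri_mat[, 2], tri_mat[, 3]), ,
                     drop = FALSE]
  areas <- apply(tri_mat, 1, function(t)
    triangle_area(pts[t[1], ], pts[t[2], ], pts[t[3], ]))
  tri_mat <- tri_mat[areas > 1e-12 * span^2, , drop = FALSE]
  if (!all(seq_len(n) %in% tri_mat))
    warning("triangulation does not use every vertex")
  structure(list(vertices = pts, triangles = tri_mat),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("Triangle mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}
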