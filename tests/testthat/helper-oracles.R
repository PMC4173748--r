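## Independent oracles used by the test suite. Each deliberately takes a
## different computational route from the implementation it checks.

## Truncated percentage by long division, digit by digit, in integer
## arithmetic only (no floating-point division at all).
oracle_percent_truncated <- function(num, den, decimals) {
  rem <- 100 * num
  q <- rem %/% den
  rem <- rem - q * den
  frac <- 0
  for (d in seq_len(decimals)) {
    rem <- rem * 10
    digit <- rem %/% den
    rem <- rem - digit * den
    frac <- frac + digit / 10^d
  }
  q + frac
}

## Exhaustive depth-1 CART split: try every (feature, midpoint) pair and
## return the best by Gini decrease, with the implementation's tie rule
## (lowest feature index, then smallest threshold).
oracle_best_stump <- function(data, features, label) {
  y <- factor(data[[label]])
  gini <- function(v) {
    p <- table(v) / length(v)
    1 - sum(p^2)
  }
  best <- NULL
  for (j in seq_along(features)) {
    v <- data[[features[j]]]
    obs <- is.finite(v)
    uv <- sort(unique(v[obs]))
    if (length(uv) < 2) next
    for (t in (uv[-length(uv)] + uv[-1]) / 2) {
      left <- obs & v < t
      right <- obs & v >= t
      if (!any(left) || !any(right)) next
      n <- sum(obs)
      gain <- (n / nrow(data)) *
        (gini(y[obs]) - (sum(left) * gini(y[left]) +
                           sum(right) * gini(y[right])) / n)
      if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12))
        best <- list(feature = features[j], threshold = t, gain = gain)
    }
  }
  best
}

## Brute-force check of the Delaunay empty-circumcircle property over all
## (triangle, vertex) pairs, via a direct circumcentre solve.
oracle_delaunay_ok <- function(mesh, tol = 1e-7) {
  pts <- mesh$vertices
  for (k in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[k, ]
    p1 <- pts[tri[1], ]; p2 <- pts[tri[2], ]; p3 <- pts[tri[3], ]
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                p3[1] * (p1[2] - p2[2]))
    ux <- ((sum(p1^2)) * (p2[2] - p3[2]) + (sum(p2^2)) * (p3[2] - p1[2]) +
             (sum(p3^2)) * (p1[2] - p2[2])) / d
    uy <- ((sum(p1^2)) * (p3[1] - p2[1]) + (sum(p2^2)) * (p1[1] - p3[1]) +
             (sum(p3^2)) * (p2[1] - p1[1])) / d
    r <- sqrt((p1[1] - ux)^2 + (p1[2] - uy)^2)
    others <- setdiff(seq_len(nrow(pts)), tri)
    dist <- sqrt((pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2)
    if (any(dist < r * (1 - tol))) return(FALSE)
  }
  TRUE
}

## Numerical minimisation of the similarity-alignment residual over
## (angle, log-scale, translation), refined from a coarse angle grid.
oracle_procrustes_distance <- function(source, target) {
  rss <- function(par) {
    th <- par[1]; s <- exp(par[2])
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    mapped <- s * source %*% t(R) +
      matrix(par[3:4], nrow(source), 2, byrow = TRUE)
    sum((mapped - target)^2)
  }
  best <- Inf
  for (th0 in seq(-pi, pi, length.out = 25)) {
    fit <- optim(c(th0, 0, 0, 0), rss, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  sqrt(best / nrow(source))
}

## A small cohort with planted AND-structure on the two growth features:
## the positive arm satisfies weight < w_thr and birth weight >= b_thr with
## a clear margin; the negative arm violates exactly one condition.
make_planted_cohort <- function(n_per_arm = 60, w_thr = -2.4, b_thr = -4.4,
                                margin = 0.5, seed = 42) {
  set.seed(seed)
  pos <- data.frame(
    weight_sd = runif(n_per_arm, -5, w_thr - margin),
    birth_weight_sd = runif(n_per_arm, b_thr + margin, 0),
    label = "NIPBL", stringsAsFactors = FALSE)
  n1 <- n_per_arm %/% 2
  neg <- data.frame(
    weight_sd = c(runif(n1, w_thr + margin, 1),
                  runif(n_per_arm - n1, -5, w_thr - margin)),
    birth_weight_sd = c(runif(n1, b_thr + margin, 0),
                        runif(n_per_arm - n1, -7, b_thr - margin)),
    label = "other", stringsAsFactors = FALSE)
  rbind(pos, neg)
}
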