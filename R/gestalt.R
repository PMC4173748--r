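#' Extract a gestalt rating panel
#'
#' A gestalt panel is a numeric matrix of facial gestalt scores, rows =
#' patients, columns = raters, entries in \[1, 10\] (10 = highly typical of
#' the syndrome) or `NA` for unrated. Accepts a matrix/data frame of ratings
#' or a `cdls_cohort`, from which the `gestalt_*` columns are taken.
#'
#' @param x ratings matrix, data frame, or `cdls_cohort`.
#' @return numeric matrix of class `gestalt_panel` with one column per rater.
#' @export
gestalt_panel <- function(x) {
  if (inherits(x, "cdls_cohort")) {
    cols <- gestalt_columns(x)
    if (!length(cols)) stop("cohort has no gestalt rating columns")
    m <- as.matrix(as.data.frame(x)[cols])
    rownames(m) <- x$patient_id
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
  }
  bad <- !is.na(m) & (m < 1 | m > 10)
  if (any(bad)) stop("gestalt ratings must lie in [1, 10]")
  structure(m, class = c("gestalt_panel", class(m)))
}

#' Per-patient mean gestalt score
#'
#' The score used for downstream analysis is the arithmetic mean of the
#' ratings available for each patient. Patients with no rating at all get
#' `NA` and a warning.
#'
#' @param panel a [gestalt_panel()] (or coercible).
#' @return numeric vector of mean scores, one per patient.
#' @export
aggregate_ratings <- function(panel) {
  panel <- gestalt_panel(unclass(panel))
  out <- rowMeans(panel, na.rm = TRUE)
  none <- !rowSums(!is.na(panel))
  if (any(none)) {
    out[none] <- NA_real_
    warning(sum(none), " patient(s) have no gestalt rating; mean score is NA")
  }
  out
}

#' Inter-rater concordance of gestalt scores
#'
#' Pearson correlation for every pair of raters, computed on pairwise-complete
#' observations, with a pass/fail gate at a correlation threshold (default
#' 0.60). The per-pair p-value (two-sided test of zero correlation) is
#' reported for reference but does not enter the gate, since it depends on
#' the number of shared ratings. A rater whose shared ratings are constant
#' has undefined correlation, reported as `NA` (and failing the gate).
#'
#' @param panel a [gestalt_panel()] with at least two raters.
#' @param threshold minimum pairwise correlation required to pass.
#' @return list of class `concordance_report`: `pairs` (data frame with
#'   `rater_a`, `rater_b`, `n`, `r`, `p`), `threshold`, and `pass`.
#' @export
rater_concordance <- function(panel, threshold = 0.60) {
  panel <- gestalt_panel(unclass(panel))
  k <- ncol(panel)
  if (k < 2) stop("concordance needs at least two raters")
  idx <- utils::combn(k, 2)
  pairs <- data.frame(rater_a = idx[1, ], rater_b = idx[2, ],
                      n = NA_integer_, r = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(idx))) {
    a <- panel[, idx[1, i]]
    b <- panel[, idx[2, i]]
    ok <- !is.na(a) & !is.na(b)
    pairs$n[i] <- sum(ok)
    if (pairs$n[i] < 3)
      stop("rater pair (", idx[1, i], ", ", idx[2, i], ") shares only ",
           pairs$n[i], " rated patients; need at least 3")
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next  # r undefined
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    pairs$r[i] <- unname(ct$estimate)
    pairs$p[i] <- ct$p.value
  }
  structure(list(pairs = pairs, threshold = threshold,
                 pass = all(!is.na(pairs$r) & pairs$r >= threshold)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Inter-rater concordance (Pearson, pairwise-complete)\n")
  print(x$pairs, row.names = FALSE)
  cat(if (x$pass) "PASS" else "FAIL",
      sprintf(": all pairwise r >= %.2f is %s\n", x$threshold,
              tolower(as.character(x$pass))))
  invisible(x)
}
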