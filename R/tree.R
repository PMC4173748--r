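#' Configuration for classification-tree fitting
#'
#' Defaults mirror the shallow trees used in CdLS genotype-phenotype work:
#' nodes with fewer than 3 observations are not split and the tree grows at
#' most 3 edges deep (root at depth 0, so up to 8 leaves).
#'
#' @param minsplit minimum number of observations a node must hold to be
#'   considered for splitting (>= 2).
#' @param maxdepth maximum tree depth in edges from the root (>= 1).
#' @param missing how records with a missing value for a split feature are
#'   routed: `"exclude"` drops them from the subtree (mirroring
#'   complete-case reporting), `"majority"` sends them with the larger
#'   child branch.
#' @return list of class `tree_config`.
#' @export
tree_config <- function(minsplit = 3L, maxdepth = 3L,
                        missing = c("exclude", "majority")) {
  missing <- match.arg(missing)
  if (minsplit < 2) stop("minsplit must be >= 2")
  if (maxdepth < 1) stop("maxdepth must be >= 1")
  structure(list(minsplit = as.integer(minsplit),
                 maxdepth = as.integer(maxdepth),
                 missing = missing), class = "tree_config")
}

#' Gini impurity of a node
#'
#' `1 - sum(p_k^2)` over class proportions; 0 for a pure node, at most
#' `1 - 1/K` for K classes.
#'
#' @param class_counts non-negative class counts, not all zero.
#' @return Gini impurity in \[0, 1 - 1/K\].
#' @examples
#' gini_impurity(c(5, 5))      # 0.5
#' gini_impurity(c(2, 3, 5))   # 0.62
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  n <- sum(class_counts)
  if (n == 0) stop("all class counts are zero")
  1 - sum((class_counts / n)^2)
}

## Best (feature, threshold) split of the rows `idx`, or NULL. Gain is the
## Gini decrease on the rows with an observed feature value, weighted by the
## observed fraction so features with heavy missingness are penalised.
## Ties: lowest feature index, then smallest threshold (strict > to replace).
best_split <- function(x, y, idx, features, minsplit) {
  best <- NULL
  n_node <- length(idx)
  for (j in seq_along(features)) {
    v <- x[idx, features[j]]
    obs <- is.finite(v)
    if (sum(obs) < 2) next
    vo <- v[obs]
    yo <- y[idx][obs]
    parent <- gini_impurity(tabulate(yo, nlevels(y)))
    uv <- sort(unique(vo))
    if (length(uv) < 2) next
    thresholds <- (uv[-length(uv)] + uv[-1]) / 2
    for (t in thresholds) {
      left <- vo < t
      nl <- sum(left); nr <- sum(!left)
      if (nl == 0 || nr == 0) next
      gl <- gini_impurity(tabulate(yo[left], nlevels(y)))
      gr <- gini_impurity(tabulate(yo[!left], nlevels(y)))
      gain <- (sum(obs) / n_node) *
        (parent - (nl * gl + nr * gr) / (nl + nr))
      if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12))
        best <- list(feature = features[j], threshold = t, gain = gain)
    }
  }
  best
}

#' Fit a CART-style classification tree
#'
#' Greedy recursive binary partitioning by Gini impurity decrease. Candidate
#' thresholds are the midpoints between consecutive distinct observed values
#' of each feature; a record goes left when its value is strictly below the
#' threshold and right otherwise (ties at the threshold go right). Splitting
#' stops at a pure node, at the depth limit, when a node holds fewer than
#' `minsplit` observations, or when no split reduces impurity. Among
#' equal-gain splits the lowest feature index and then the smallest threshold
#' wins, so fitting is deterministic. No surrogate splits and no pruning.
#'
#' @param data data frame holding the feature columns and the label column.
#' @param features character vector of numeric feature column names.
#' @param label name of the class label column.
#' @param config a [tree_config()].
#' @return object of class `cdls_tree`: nested nodes (`$root`), class
#'   `levels`, `features`, and the `config` used.
#' @seealso [predict.cdls_tree()], [branch_purity()]
#' @export
fit_tree <- function(data, features, label, config = tree_config()) {
  stopifnot(inherits(config, "tree_config"))
  if (!nrow(data)) stop("no records to fit")
  missing_cols <- setdiff(c(features, label), names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  y <- factor(data[[label]])
  x <- data[features]
  for (f in features)
    if (!is.numeric(x[[f]])) stop("feature '", f, "' is not numeric")
  leaf_id <- 0L

  make_leaf <- function(idx) {
    leaf_id <<- leaf_id + 1L
    counts <- tabulate(y[idx], nlevels(y))
    names(counts) <- levels(y)
    list(type = "leaf", id = leaf_id, n = length(idx),
         class = levels(y)[which.max(counts)], counts = counts)
  }

  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], nlevels(y))
    if (length(idx) < config$minsplit || depth >= config$maxdepth ||
        sum(counts > 0) <= 1)
      return(make_leaf(idx))
    sp <- best_split(x, y, idx, features, config$minsplit)
    if (is.null(sp)) return(make_leaf(idx))
    v <- x[idx, sp$feature]
    obs <- is.finite(v)
    go_left <- obs & v < sp$threshold
    go_right <- obs & v >= sp$threshold
    if (config$missing == "majority" && any(!obs)) {
      if (sum(go_left) > sum(go_right)) go_left[!obs] <- TRUE
      else go_right[!obs] <- TRUE        # tie goes right, as at the threshold
    }
    names(counts) <- levels(y)
    list(type = "split", feature = sp$feature, threshold = sp$threshold,
         n = length(idx), counts = counts, gain = sp$gain,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[go_right], depth + 1L))
  }

  structure(list(root = grow(seq_len(nrow(data)), 0L),
                 levels = levels(y), features = features, label = label,
                 config = config),
            class = "cdls_tree")
}

#' Predict classes from a fitted tree
#'
#' Routes each record down the tree: strictly below the threshold goes left,
#' at or above goes right. Records with a missing split feature are handled
#' per the tree's missing-value policy: under `"exclude"` the prediction is
#' `NA` with leaf `NA` (the record is reported as excluded); under
#' `"majority"` it follows the branch that held more training records.
#'
#' @param object a fitted `cdls_tree`.
#' @param newdata data frame containing the tree's feature columns.
#' @param ... unused.
#' @return data frame with columns `class` (predicted label, `NA` if
#'   excluded) and `leaf` (leaf id).
#' @export
predict.cdls_tree <- function(object, newdata, ...) {
  route <- function(node, row) {
    if (node$type == "leaf") return(list(class = node$class, leaf = node$id))
    v <- row[[node$feature]]
    if (!is.finite(v)) {
      if (object$config$missing == "exclude")
        return(list(class = NA_character_, leaf = NA_integer_))
      # majority policy: follow the branch that held more training records
      return(route(if (node$left$n > node$right$n) node$left else node$right,
                   row))
    }
    route(if (v < node$threshold) node$left else node$right, row)
  }
  out <- lapply(seq_len(nrow(newdata)), function(i)
    route(object$root, newdata[i, , drop = FALSE]))
  data.frame(class = vapply(out, `[[`, character(1), "class"),
             leaf = vapply(out, function(z) as.integer(z$leaf), integer(1)),
             stringsAsFactors = FALSE)
}

#' @export
print.cdls_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "leaf ", node$id, ": ", node$class, " (",
          paste(node$counts, collapse = "/"), ")\n", sep = "")
    } else {
      cat(pad, node$feature, " < ", format(node$threshold), " ?\n", sep = "")
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  cat("Classification tree over [", paste(x$features, collapse = ", "),
      "] -> ", x$label, "\n", sep = "")
  rec(x$root, 0)
  invisible(x)
}

#' Serialise a fitted tree to JSON
#'
#' @param tree a `cdls_tree`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (node$type == "leaf")
      list(type = "leaf", id = node$id, n = node$n, class = node$class,
           counts = as.list(node$counts))
    else
      list(type = "split", feature = node$feature, threshold = node$threshold,
           n = node$n, counts = as.list(node$counts),
           left = strip(node$left), right = strip(node$right))
  }
  js <- jsonlite::toJSON(list(levels = tree$levels, features = tree$features,
                              config = unclass(tree$config),
                              root = strip(tree$root)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Purity of a tree branch as a whole-number percentage
#'
#' Fraction of branch members carrying the target label, reported truncated
#' toward zero (44 of 56 is 78%).
#'
#' @param n_target number of target-labelled records in the branch.
#' @param n_branch total records in the branch (> 0).
#' @return integer percentage.
#' @export
branch_purity <- function(n_target, n_branch) {
  if (n_branch <= 0) stop("empty branch")
  if (n_target < 0 || n_target > n_branch)
    stop("target count must lie in [0, n_branch]")
  percent_truncated(n_target, n_branch, 0L)
}

#' The two-threshold NIPBL-like growth filter
#'
#' The discriminative rule read off the growth-based classification tree:
#' weight at last assessment below -2.4 SD (strict) AND birth weight at or
#' above -4.4 SD. Applied to mutation-negative cases it flags individuals
#' whose growth trajectory matches the NIPBL-positive profile (normal-ish
#' prenatal growth followed by marked postnatal growth failure), i.e. cases
#' likely to harbour an undetected mosaic NIPBL mutation.
#'
#' @param weight_threshold weight z-score upper bound, exclusive
#'   (default -2.4).
#' @param birth_weight_threshold birth-weight z-score lower bound, inclusive
#'   (default -4.4).
#' @return list of class `nipbl_like_filter`.
#' @export
nipbl_like_filter <- function(weight_threshold = -2.4,
                              birth_weight_threshold = -4.4) {
  stopifnot(is.finite(weight_threshold), is.finite(birth_weight_threshold))
  structure(list(weight_threshold = weight_threshold,
                 birth_weight_threshold = birth_weight_threshold),
            class = "nipbl_like_filter")
}

#' Apply the NIPBL-like filter to a cohort
#'
#' Flags records with `weight_sd < weight_threshold` and
#' `birth_weight_sd >= birth_weight_threshold`. Records missing either value
#' are never flagged but remain in the denominator, so the reported fraction
#' is conservative.
#'
#' @param cohort data frame with `weight_sd` and `birth_weight_sd` columns.
#' @param filter a [nipbl_like_filter()].
#' @return list with `flagged` (logical vector), `n_flagged`, `n`, and
#'   `percent` (whole-number truncated percentage).
#' @export
apply_nipbl_like_filter <- function(cohort, filter = nipbl_like_filter()) {
  if (!nrow(cohort)) stop("empty cohort")
  stopifnot(inherits(filter, "nipbl_like_filter"))
  w <- cohort$weight_sd
  b <- cohort$birth_weight_sd
  flagged <- !is.na(w) & !is.na(b) &
    w < filter$weight_threshold & b >= filter$birth_weight_threshold
  list(flagged = flagged, n_flagged = sum(flagged), n = nrow(cohort),
       percent = percent_truncated(sum(flagged), nrow(cohort), 0L))
}
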