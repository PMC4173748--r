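test_that("gini impurity evaluates correctly", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(2, 3, 5)), 0.62)
  expect_error(gini_impurity(c(0, 0)), "zero")
})

test_that("perfectly separable data yields a depth-1 tree at the gap midpoint", {
  d <- data.frame(x = c(rep(-3, 5), rep(0, 5)),
                  y = rep(c("pos", "neg"), each = 5))
  tr <- fit_tree(d, "x", "y")
  expect_equal(tr$root$type, "split")
  expect_equal(tr$root$threshold, -1.5)
  expect_equal(tr$root$left$type, "leaf")
  pred <- predict(tr, d)
  expect_equal(pred$class, d$y)              # 100% training accuracy
})

test_that("uniform labels give a single leaf; records route by the >= convention", {
  d <- data.frame(x = rnorm(8), y = "same")
  tr <- fit_tree(d, "x", "y")
  expect_equal(tr$root$type, "leaf")
  expect_equal(predict(tr, data.frame(x = 99))$class, "same")

  d2 <- data.frame(x = c(0, 0, 0, 1, 1, 1), y = rep(c("a", "b"), each = 3))
  tr2 <- fit_tree(d2, "x", "y")
  expect_equal(tr2$root$threshold, 0.5)
  at_thr <- predict(tr2, data.frame(x = 0.5))  # tie at threshold goes right
  expect_equal(at_thr$class, "b")
})

test_that("missing split features follow the configured policy", {
  d <- data.frame(x = c(-2, -2, -2, 1, 1), y = c("a", "a", "a", "b", "b"))
  tr <- fit_tree(d, "x", "y")                 # default: exclude
  p <- predict(tr, data.frame(x = NA_real_))
  expect_true(is.na(p$class))
  trm <- fit_tree(d, "x", "y", tree_config(missing = "majority"))
  pm <- predict(trm, data.frame(x = NA_real_))
  expect_equal(pm$class, "a")                 # majority branch held 3 of 5
})

test_that("impurity never increases along splits and depth respects the cap", {
  set.seed(31)
  d <- data.frame(a = rnorm(40), b = rnorm(40),
                  y = sample(c("u", "v", "w"), 40, replace = TRUE))
  tr <- fit_tree(d, c("a", "b"), "y", tree_config(maxdepth = 3))
  walk <- function(node, depth) {
    expect_lte(depth, 3)
    if (node$type == "leaf") return(invisible())
    parent_g <- gini_impurity(node$counts)
    child_g <- (sum(node$left$counts) * gini_impurity(node$left$counts) +
                  sum(node$right$counts) * gini_impurity(node$right$counts)) /
      (sum(node$left$counts) + sum(node$right$counts))
    expect_lte(child_g, parent_g + 1e-12)
    walk(node$left, depth + 1)
    walk(node$right, depth + 1)
  }
  walk(tr$root, 0)
})

test_that("training predictions reproduce the stored leaf counts", {
  set.seed(17)
  d <- data.frame(a = rnorm(30), b = rnorm(30),
                  y = sample(c("p", "q"), 30, replace = TRUE))
  tr <- fit_tree(d, c("a", "b"), "y")
  pred <- predict(tr, d)
  leaves <- new.env()
  collect <- function(node) {
    if (node$type == "leaf") assign(as.character(node$id), node$counts, leaves)
    else { collect(node$left); collect(node$right) }
  }
  collect(tr$root)
  for (id in ls(leaves)) {
    stored <- get(id, leaves)
    seen <- table(factor(d$y[!is.na(pred$leaf) & pred$leaf == as.integer(id)],
                         levels = names(stored)))
    expect_equal(as.integer(seen), as.integer(stored), label = paste("leaf", id))
  }
})

test_that("depth-1 fit agrees with the exhaustive-split oracle on random data", {
  set.seed(99)
  for (i in seq_len(25)) {
    n <- sample(5:20, 1)
    d <- data.frame(f1 = round(rnorm(n), 1), f2 = round(rnorm(n), 1),
                    f3 = round(runif(n, -3, 3), 1),
                    y = sample(c("a", "b"), n, replace = TRUE))
    tr <- fit_tree(d, c("f1", "f2", "f3"), "y", tree_config(maxdepth = 1))
    oracle <- oracle_best_stump(d, c("f1", "f2", "f3"), "y")
    if (is.null(oracle)) {
      expect_equal(tr$root$type, "leaf", label = paste("case", i))
    } else {
      expect_equal(tr$root$feature, oracle$feature, label = paste("case", i))
      expect_equal(tr$root$threshold, oracle$threshold,
                   label = paste("case", i))
    }
  }
})

test_that("branch purity uses whole-number truncation", {
  expect_equal(branch_purity(44, 56), 78)
  expect_equal(branch_purity(32, 34), 94)
  expect_equal(branch_purity(0, 9), 0)
  expect_error(branch_purity(1, 0), "empty")
  expect_error(branch_purity(5, 4), "0, n_branch")
})

test_that("the NIPBL-like filter applies both growth conditions", {
  co <- cdls_cohort(c("a", "b", "c", "d"),
                    weight_sd = c(-3.0, -2.4, -3.0, NA),
                    birth_weight_sd = c(-2.0, -2.0, -5.0, -2.0))
  res <- apply_nipbl_like_filter(co)
  expect_equal(res$flagged, c(TRUE, FALSE, FALSE, FALSE))
  # -2.4 itself not flagged (strict <); birth -5.0 fails >= -4.4;
  # missing weight never flagged but stays in the denominator
  expect_equal(res$n, 4)
  expect_equal(res$percent, 25)
})

test_that("filter counts respond monotonically to threshold relaxation", {
  set.seed(8)
  co <- cdls_cohort(sprintf("m%d", 1:200),
                    weight_sd = rnorm(200, -2, 1.5),
                    birth_weight_sd = rnorm(200, -2.5, 1.5))
  base <- apply_nipbl_like_filter(co)$n_flagged
  ## more negative weight threshold -> fewer or equal flagged
  for (wt in c(-2.8, -3.5, -5)) {
    expect_lte(apply_nipbl_like_filter(co, nipbl_like_filter(wt, -4.4))$n_flagged,
               base)
  }
  ## more negative birth-weight threshold -> more or equal flagged
  prev <- base
  for (bt in c(-5, -6, -8)) {
    cur <- apply_nipbl_like_filter(co, nipbl_like_filter(-2.4, bt))$n_flagged
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("tree serialises to JSON with nodes, thresholds and counts", {
  d <- data.frame(x = c(-3, -3, -3, 0, 0, 0), y = rep(c("p", "n"), each = 3))
  tr <- fit_tree(d, "x", "y")
  js <- jsonlite::fromJSON(tree_to_json(tr), simplifyVector = FALSE)
  expect_equal(js$root$feature, "x")
  expect_equal(js$root$threshold, -1.5)
  expect_equal(js$root$left$class, "p")
  expect_output(print(tr), "x < -1.5")
})
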