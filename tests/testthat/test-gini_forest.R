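# An independent recursive path-walker used as the prediction oracle.
walk_oracle <- function(node, x) {
  if (node$type == "leaf") return(node$class)
  if (x[node$feature_col] <= node$threshold) walk_oracle(node$left, x)
  else walk_oracle(node$right, x)
}

test_that("gini_impurity matches brute force and its closed cases", {
  expect_identical(gini_impurity(c(4, 0)), 0)
  expect_identical(gini_impurity(c(2, 2)), 0.5)
  expect_identical(gini_impurity(c(3, 1)), 0.375)
  for (n in 1:50) for (k in 0:n) {
    brute <- 1 - ((k / n)^2 + ((n - k) / n)^2)
    expect_equal(gini_impurity(c(k, n - k)), brute, tolerance = 1e-12)
  }
  expect_error(gini_impurity(c(0, 0)), "empty")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
})

test_that("binary impurity increases towards balance", {
  for (n in c(6L, 11L, 40L)) {
    path <- vapply(0:(n %/% 2), function(k) gini_impurity(c(k, n - k)),
                   numeric(1))
    expect_true(all(diff(path) > 0))
  }
})

test_that("the square-root candidate rule rounds up and caps", {
  expect_identical(max_candidate_features(36), 6L)
  expect_identical(max_candidate_features(1), 1L)
  expect_identical(max_candidate_features(10), 4L)  # ceil(3.162...)
  expect_identical(max_candidate_features(2), 2L)   # capped at n
  expect_error(max_candidate_features(0), ">= 1")
})

test_that("bootstrap_rows is uniform-with-replacement and seeded", {
  expect_identical(bootstrap_rows(1L), 1L)
  set.seed(31); a <- bootstrap_rows(50L)
  set.seed(31); b <- bootstrap_rows(50L)
  expect_identical(a, b)
  expect_length(a, 50L)
  # expected distinct fraction 1 - (1 - 1/n)^n ~ 0.632 at n = 1000
  set.seed(99)
  frac <- mean(vapply(1:1000, function(i)
    length(unique(bootstrap_rows(1000L))) / 1000, numeric(1)))
  expect_lt(abs(frac - (1 - (1 - 1 / 1000)^1000)), 0.02)
})

test_that("draw_split_candidate draws uniformly over rows and columns", {
  expect_identical(draw_split_candidate(matrix(0.7), 1L),
                   list(feature_col = 1L, threshold = 0.7))
  Pc <- cbind(rep(0.3, 5), runif(5))
  set.seed(8)
  for (i in 1:20) {
    d <- draw_split_candidate(Pc, 1:5)
    if (d$feature_col == 1L) expect_identical(d$threshold, 0.3)
  }
  # empirical (column, row-value) distribution vs the exact uniform pmf
  set.seed(12)
  P <- matrix(runif(30), 10, 3)
  rows <- 1:10
  draws <- replicate(10000, {
    d <- draw_split_candidate(P, rows)
    which(P[rows, d$feature_col] == d$threshold) + 10 * (d$feature_col - 1)
  })
  expect_gt(stats::chisq.test(tabulate(draws, 30))$p.value, 0.01)
  expect_error(draw_split_candidate(P, integer(0)), "non-empty")
})

test_that("best_split finds the perfect threshold on the 1-D example", {
  P <- matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1)
  y <- c(0L, 0L, 1L, 1L)
  sp <- best_split(P, y, 1:4, forest_params(candidates_per_node = "all"))
  expect_identical(sp$score, 0)
  expect_identical(sp$threshold, 0.2)  # only zero-impurity cut point
  # degenerate: constant feature admits no split
  expect_null(best_split(matrix(0.5, 4, 1), y, 1:4,
                         forest_params(candidates_per_node = "all")))
})

test_that("exhaustive best_split equals an independent full search", {
  # oracle: score every (row, column) candidate from scratch
  exhaustive_oracle <- function(P, y, rows) {
    best <- Inf
    for (col in seq_len(ncol(P))) for (r in rows) {
      thr <- P[r, col]
      left <- rows[P[rows, col] <= thr]; right <- setdiff(rows, left)
      if (!length(left) || !length(right)) next
      g <- function(s) { cnt <- tabulate(y[s] + 1L, 2L)
                         1 - sum((cnt / sum(cnt))^2) }
      sc <- (length(left) * g(left) + length(right) * g(right)) /
        length(rows)
      if (sc < best) best <- sc
    }
    if (is.infinite(best)) NULL else best
  }
  set.seed(17)
  for (rep in 1:25) {
    nr <- sample(4:20, 1); nc <- sample(1:5, 1)
    P <- matrix(round(runif(nr * nc), 2), nr, nc)
    y <- sample(0:1, nr, replace = TRUE)
    if (length(unique(y)) < 2L) y[1] <- 1L - y[1]
    rows <- sort(sample(nr, sample(3:nr, 1)))
    if (length(unique(y[rows])) < 2L) next
    sp <- best_split(P, y, rows, forest_params(candidates_per_node = "all"))
    oracle <- exhaustive_oracle(P, y, rows)
    if (is.null(oracle)) expect_null(sp)
    else expect_equal(sp$score, oracle, tolerance = 1e-12)
  }
})

test_that("sampled best_split never beats its own candidates", {
  set.seed(23)
  P <- matrix(runif(60), 20, 3)
  y <- sample(0:1, 20, replace = TRUE)
  for (rep in 1:20) {
    seed <- 100 + rep
    set.seed(seed)
    sp <- best_split(P, y, 1:20, forest_params(candidates_per_node = 2L))
    # replay the same candidate draws and rescore independently
    set.seed(seed)
    cand_scores <- replicate(2, {
      d <- draw_split_candidate(P, 1:20)
      cnnforest:::split_score(P, y, 1:20, d$feature_col, d$threshold)
    })
    if (all(is.infinite(cand_scores))) expect_null(sp)
    else expect_equal(sp$score, min(cand_scores), tolerance = 1e-12)
  }
})

test_that("grow_tree handles pure roots and fits the 1-D example", {
  P <- matrix(runif(6), ncol = 1)
  pure <- grow_tree(P, rep(1L, 6), forest_params(bootstrap = FALSE))
  expect_identical(pure$type, "leaf")
  expect_identical(pure$class, 1L)

  P4 <- matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1)
  y4 <- c(0L, 0L, 1L, 1L)
  set.seed(2)
  tree <- grow_tree(P4, y4,
                    forest_params(candidates_per_node = "all",
                                  bootstrap = FALSE))
  expect_identical(tree$type, "internal")
  expect_identical(tree$left$type, "leaf")
  expect_identical(tree$right$type, "leaf")
  preds <- vapply(1:4, function(i) predict_tree(tree, P4[i, ]), integer(1))
  expect_identical(preds, y4)
  expect_error(grow_tree(P4, y4[1:3]), "one entry per row")
})

test_that("unbootstrapped pure-grown trees memorise distinct samples", {
  set.seed(77)
  for (rep in 1:5) {
    P <- matrix(runif(40), 10, 4)
    y <- sample(0:1, 10, replace = TRUE)
    set.seed(rep)
    tree <- grow_tree(P, y, forest_params(bootstrap = FALSE,
                                          candidates_per_node = "all"))
    preds <- vapply(1:10, function(i) predict_tree(tree, P[i, ]),
                    integer(1))
    expect_identical(preds, y)
  }
})

test_that("predict_tree agrees with an independent recursive walker", {
  set.seed(55)
  for (t in 1:100) {
    tree <- random_tree(n_features = 4L, depth = 5L)
    X <- matrix(runif(100 * 4), 100, 4)
    for (i in 1:100)
      expect_identical(predict_tree(tree, X[i, ]), walk_oracle(tree, X[i, ]))
  }
})

test_that("predict_forest counts votes with the documented tie-break", {
  leaf <- function(cls) list(type = "leaf", class = cls, counts = c(1L, 1L))
  forest <- structure(list(trees = list(leaf(1L), leaf(1L), leaf(0L)),
                           n_features = 2L, params = forest_params(3L)),
                      class = "cnn_forest")
  p <- predict_forest(forest, c(0, 0))
  expect_identical(p$class, 1L)
  expect_equal(p$vote_fraction, 2 / 3)
  # even split predicts the negative class
  forest2 <- forest; forest2$trees <- list(leaf(1L), leaf(0L))
  expect_identical(predict_forest(forest2, c(0, 0))$class, 0L)
  expect_error(predict_forest(structure(list(trees = list(),
                                             n_features = 2L),
                                        class = "cnn_forest"), c(0, 0)),
               "empty")
  expect_error(predict_forest(forest, c(0, 0, 0)), "length")
})

test_that("a forest of one unbootstrapped tree is that tree", {
  set.seed(6)
  P <- matrix(runif(60), 20, 3)
  y <- sample(0:1, 20, replace = TRUE)
  model <- grow_forest(P, y, forest_params(n_trees = 1L, bootstrap = FALSE,
                                           rng_seed = 5L))
  tree <- model$trees[[1]]
  X <- matrix(runif(50 * 3), 50, 3)
  for (i in 1:50) {
    p <- predict_forest(model, X[i, ])
    expect_identical(p$class, predict_tree(tree, X[i, ]))
    expect_true(p$vote_fraction %in% c(0, 1))
  }
})

test_that("15-tree binary voting admits no ties", {
  set.seed(41)
  P <- matrix(runif(40 * 4), 40, 4)
  y <- rep(c(0L, 1L), 20)
  model <- grow_forest(P, y, forest_params(n_trees = 15L, rng_seed = 2L))
  fracs <- predict(model, matrix(runif(200 * 4), 200, 4))$vote_fraction
  expect_true(all(fracs != 0.5))
})

test_that("forest serialisation round-trips predictions exactly", {
  set.seed(13)
  P <- matrix(runif(30 * 3), 30, 3)
  y <- sample(0:1, 30, replace = TRUE)
  model <- grow_forest(P, y, forest_params(n_trees = 7L, rng_seed = 3L))
  path <- withr::local_tempfile(fileext = ".json")
  forest_write(model, path)
  back <- forest_read(path)
  X <- matrix(runif(40 * 3), 40, 3)
  expect_identical(predict(back, X), predict(model, X))
})
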