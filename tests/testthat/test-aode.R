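random_aode_instance <- function(n_feat = NULL, n_train = NULL) {
  p <- n_feat %||% sample(2:4, 1)
  v <- sample(2:3, p, replace = TRUE)
  n <- n_train %||% sample(4:50, 1)
  bins <- sapply(seq_len(p), function(i) sample.int(v[i], n, replace = TRUE))
  bins <- matrix(as.integer(bins), nrow = n)
  labels <- sample(c("positive", "negative"), n, replace = TRUE)
  # guarantee both classes
  labels[1] <- "positive"
  labels[2] <- "negative"
  x <- vapply(seq_len(p), function(i) sample.int(v[i], 1L), integer(1))
  list(bins = bins, labels = labels, v = v, x = x)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fitting counts match hand counts and validates inputs", {
  bins <- matrix(c(1L, 2L,
                   2L, 1L), nrow = 2, byrow = TRUE)
  labels <- c("positive", "negative")
  m <- aode_fit(bins, labels, c(2L, 2L))
  expect_equal(m$F1[[1]][1, ], c(1, 0), ignore_attr = TRUE)  # pos: f1=1
  expect_equal(m$F1[[1]][2, ], c(0, 1), ignore_attr = TRUE)  # neg: f1=2
  expect_equal(m$F2[[1]][[2]][1, 1, 2], 1)                   # pos: (1,2)
  expect_equal(m$F2[[1]][[2]][2, 2, 1], 1)                   # neg: (2,1)
  expect_equal(m$m, c(2L, 2L))
  expect_equal(m$m2[1, 2], 2L)

  expect_error(aode_fit(bins[0, , drop = FALSE], character(), c(2L, 2L)),
               "empty")
  expect_error(aode_fit(matrix(3L, 1, 1), "positive", 2L), "class")
  expect_error(aode_fit(matrix(c(3L, 1L), 2, 1),
                        c("positive", "negative"), 2L), "out of range")
})

test_that("duplicating the training set doubles every count", {
  set.seed(2)
  inst <- random_aode_instance()
  m1 <- aode_fit(inst$bins, inst$labels, inst$v)
  m2 <- aode_fit(rbind(inst$bins, inst$bins), rep(inst$labels, 2), inst$v)
  for (i in seq_along(inst$v)) {
    expect_equal(m2$F1[[i]], 2 * m1$F1[[i]], ignore_attr = TRUE)
  }
  expect_equal(m2$m, 2L * m1$m)
  expect_equal(m2$m2, 2L * m1$m2)
  # posteriors on the doubled model agree with the oracle on doubled data
  p_pkg <- aode_predict_proba(m2, inst$x)
  p_orc <- oracle_aode(rbind(inst$bins, inst$bins), rep(inst$labels, 2),
                       inst$v, inst$x)
  expect_equal(p_pkg, p_orc, tolerance = 1e-12)
})

test_that("smoothed probability estimates follow the stated formulas", {
  # model with data only for feature 2: feature 1 stays at the uniform prior
  bins <- matrix(c(NA, 1L, NA, 2L), nrow = 2, byrow = TRUE)
  m <- aode_fit(bins, c("positive", "negative"), c(2L, 2L))
  expect_equal(joint_prob(m, "positive", 1, 1), 1 / 4)  # (0+1)/(0+2*2)
  expect_equal(joint_prob(m, "negative", 1, 2), 1 / 4)

  # F1 = 3, m_i = 10, v_i = 2, k = 2 -> 4/14
  bins2 <- matrix(c(rep(1L, 3), rep(2L, 7)), ncol = 1)
  labels2 <- c(rep("positive", 3), rep("negative", 7))
  m2 <- aode_fit(bins2, labels2, 2L)
  expect_equal(joint_prob(m2, "positive", 1, 1), 4 / 14)
  # normalization identity: joints sum to 1 when all vectors are known
  total <- sum(vapply(c("positive", "negative"), function(cl)
    joint_prob(m2, cl, 1, 1) + joint_prob(m2, cl, 1, 2), numeric(1)))
  expect_equal(total, 1)

  # empty-data pair probability is uniform 1/(k v_i v_j); conditional 1/2
  m3 <- aode_fit(matrix(c(1L, NA, NA, 1L, NA, NA), nrow = 2, byrow = TRUE),
                 c("positive", "negative"), c(2L, 2L, 2L))
  expect_equal(pair_prob(m3, "positive", 2, 1, 3, 2), 1 / 8)
  expect_equal(cond_prob(m3, 3, 2, "positive", 2, 1), (1 / 8) / (1 / 4))
  expect_equal(pair_prob(m3, "positive", 2, 1, 3, 2),
               pair_prob(m3, "positive", 3, 2, 2, 1))  # slot symmetry
  expect_error(pair_prob(m3, "positive", 2, 1, 2, 1), "distinct")
})

test_that("posteriors normalize, respect symmetry, and match the oracle", {
  set.seed(14)
  # class-symmetric training data forces 1/2 on a symmetric query
  bins <- matrix(c(1L, 1L, 2L, 2L, 1L, 2L, 2L, 1L), ncol = 2, byrow = TRUE)
  labels <- c("positive", "negative", "positive", "negative")
  m <- aode_fit(bins, labels, c(2L, 2L))
  expect_equal(aode_predict_proba(m, c(1L, 1L)) +
                 aode_predict_proba(m, c(2L, 2L)), 1, tolerance = 1e-12)

  # p(+) + p(-) = 1 via the shared denominator, random instances
  for (r in 1:20) {
    inst <- random_aode_instance()
    m <- aode_fit(inst$bins, inst$labels, inst$v)
    p <- aode_predict_proba(m, inst$x)
    expect_gte(p, 0)
    expect_lte(p, 1)
    expect_equal(p, oracle_aode(inst$bins, inst$labels, inst$v, inst$x),
                 tolerance = 1e-10)
  }

  inst <- random_aode_instance(3)
  m <- aode_fit(inst$bins, inst$labels, inst$v)
  expect_error(aode_predict_proba(m, rep(NA_integer_, 3)), "missing")
})

test_that("permuting the feature order leaves posteriors unchanged", {
  set.seed(26)
  for (r in 1:10) {
    inst <- random_aode_instance(4)
    perm <- sample(4)
    m1 <- aode_fit(inst$bins, inst$labels, inst$v)
    m2 <- aode_fit(inst$bins[, perm], inst$labels, inst$v[perm])
    expect_equal(aode_predict_proba(m1, inst$x),
                 aode_predict_proba(m2, inst$x[perm]), tolerance = 1e-12)
  }
})

test_that("adding positive duplicates of the query never lowers its posterior", {
  set.seed(41)
  for (r in 1:15) {
    inst <- random_aode_instance()
    prev <- -Inf
    bins <- inst$bins
    labels <- inst$labels
    for (extra in 1:5) {
      bins <- rbind(bins, inst$x)
      labels <- c(labels, "positive")
      p <- aode_predict_proba(aode_fit(bins, labels, inst$v), inst$x)
      expect_gte(p, prev - 1e-12)
      prev <- p
    }
  }
})

test_that("NBC equals AODE with one feature and matches a hand posterior", {
  bins <- matrix(c(rep(1L, 3), rep(2L, 7)), ncol = 1)
  labels <- c(rep("positive", 2), "negative", rep("negative", 6),
              "positive")
  m <- aode_fit(bins, labels, 2L)
  for (a in 1:2) {
    expect_equal(nbc_predict_proba(m, a),
                 aode_predict_proba(m, a), tolerance = 1e-12)
  }

  # two binary features, hand-computed Bayes posterior with shared smoothing
  bins2 <- matrix(c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L), ncol = 2, byrow = TRUE)
  labels2 <- c("positive", "positive", "negative", "negative")
  m2 <- aode_fit(bins2, labels2, c(2L, 2L))
  # P(c)^(1-2) * P(c,f1=1) * P(c,f2=1); priors (2+1)/(4+2) = 1/2
  sc <- function(F1a, F1b) ((F1a + 1) / 8) * ((F1b + 1) / 8) / (1 / 2)
  s_pos <- sc(2, 1)  # pos: f1=1 twice, f2=1 once
  s_neg <- sc(0, 1)  # neg: f1=1 never, f2=1 once
  expect_equal(nbc_predict_proba(m2, c(1L, 1L)), s_pos / (s_pos + s_neg),
               tolerance = 1e-12)

  # symmetric training data -> 1/2
  expect_equal(nbc_predict_proba(aode_fit(
    matrix(c(1L, 1L), ncol = 1), c("positive", "negative"), 2L), 1L), 0.5)
})

test_that("classification uses the >= threshold rule", {
  expect_equal(classify(0.293, 0.293), "positive")
  expect_equal(classify(0.0, 0.0), "positive")
  expect_equal(classify(0.5, 0.7), "negative")
  expect_equal(classify(c(0.2, 0.9), 0.5), c("negative", "positive"))
  expect_error(classify(0.5, 1.5))
})
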