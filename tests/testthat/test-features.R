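test_that("mincov is positives over the longer sequence, clipped to [0,1]", {
  expect_equal(compute_mincov(50, 100, 80), 0.5)
  expect_equal(compute_mincov(0, 100, 80), 0)
  expect_equal(compute_mincov(100, 100, 100), 1)
  # gapped alignments can push positives past the longer length: clipped
  expect_equal(compute_mincov(130, 100, 120), 1)
  expect_error(compute_mincov(10, 0, 50))
})

test_that("fseq selects the template pair with the smallest joint e-value norm", {
  hitsA <- data.frame(subject_id = "t1", evalue = 1e-30, mincov = 0.9)
  hitsB <- data.frame(subject_id = "t2", evalue = 1e-20, mincov = 0.8)
  fs <- fseq_feature(hitsA, hitsB, pair_key("t1", "t2"))
  expect_equal(unname(fs), c(1e-30, 0.9, 1e-20, 0.8))

  # no interacting template pair: stated defaults
  expect_equal(unname(fseq_feature(hitsA, hitsB, character())),
               c(100, 0, 100, 0))
  expect_equal(unname(fseq_feature(hitsA[0, ], hitsB, pair_key("t1", "t2"))),
               c(100, 0, 100, 0))

  # joint norm decides: sqrt(1^2+1^2) < sqrt(0.5^2+2^2)
  hA <- data.frame(subject_id = c("u1", "u2"), evalue = c(1, 0.5),
                   mincov = c(0.5, 0.5))
  hB <- data.frame(subject_id = c("v1", "v2"), evalue = c(1, 2),
                   mincov = c(0.5, 0.5))
  keys <- c(pair_key("u1", "v1"), pair_key("u2", "v2"))
  fs2 <- fseq_feature(hA, hB, keys)
  expect_equal(unname(fs2[c(1, 3)]), c(1, 1))

  # hits above the cutoff are invisible
  hA$evalue <- c(200, 0.5)
  expect_equal(unname(fseq_feature(hA, hB, keys)[c(1, 3)]), c(0.5, 2))
})

test_that("fseq agrees with brute-force enumeration on random hit tables", {
  set.seed(71)
  subjects <- paste0("t", 1:12)
  for (rep in 1:40) {
    hA <- random_hit_table(sample(1:20, 1), subjects)
    hB <- random_hit_table(sample(1:20, 1), subjects)
    n_pos <- sample(1:10, 1)
    keys <- unique(pair_key(sample(subjects, n_pos, TRUE),
                            sample(subjects, n_pos, TRUE)))
    expect_equal(fseq_feature(hA, hB, keys), oracle_fseq(hA, hB, keys),
                 info = paste("rep", rep))
  }
})

test_that("propensity table matches hand computation and explicit counting", {
  # one positive pair with domains {d1}x{d2}, one negative with {d3}x{d4}:
  # propensity(d1,d2) = ln(((1+1)/(1+2)) / ((0+1)/(1+2))) = ln 2
  pairs <- data.frame(idA = c("a", "c"), idB = c("b", "d"),
                      label = c("positive", "negative"))
  doms <- list(a = "d1", b = "d2", c = "d3", d = "d4")
  tab <- build_propensity_table(pairs, doms)
  expect_equal(unname(tab$propensity[pair_key("d1", "d2")]), log(2))
  expect_equal(unname(tab$propensity[pair_key("d3", "d4")]), -log(2))

  # equal smoothed class-relative frequencies -> propensity 0
  pairs2 <- data.frame(idA = c("a", "a"), idB = c("b", "b"),
                       label = c("positive", "negative"))
  tab2 <- build_propensity_table(pairs2, doms)
  expect_equal(unname(tab2$propensity[pair_key("d1", "d2")]), 0)

  # 5-pair toy set against explicit counting
  set.seed(9)
  ids <- letters[1:6]
  doms5 <- setNames(lapply(ids, function(i)
    sort(sample(paste0("d", 1:4), sample(0:3, 1)))), ids)
  pairs5 <- data.frame(idA = sample(ids, 5, TRUE), idB = sample(ids, 5, TRUE),
                       label = sample(c("positive", "negative"), 5, TRUE))
  tab5 <- build_propensity_table(pairs5, doms5)
  count_oracle <- function(key, label) {
    total <- 0
    for (r in seq_len(nrow(pairs5))) {
      if (pairs5$label[r] != label) next
      dA <- doms5[[pairs5$idA[r]]]
      dB <- doms5[[pairs5$idB[r]]]
      if (length(dA) == 0 || length(dB) == 0) next
      seen <- unique(pair_key(rep(dA, each = length(dB)),
                              rep(dB, length(dA))))
      if (key %in% seen) total <- total + 1
    }
    total
  }
  for (key in names(tab5$propensity)) {
    Fp <- count_oracle(key, "positive")
    Fn <- count_oracle(key, "negative")
    expect_equal(unname(tab5$F_pos[key]), Fp)
    expect_equal(unname(tab5$F_neg[key]), Fn)
    n <- length(tab5$propensity)
    expect_equal(unname(tab5$propensity[key]),
                 log(((Fp + 1) / (tab5$pos_total + n)) /
                       ((Fn + 1) / (tab5$neg_total + n))))
  }
  # conservation: unsmoothed totals equal domain-pair incidences per class
  expect_equal(sum(tab5$F_pos), tab5$pos_total)
  expect_equal(sum(tab5$F_neg), tab5$neg_total)
})

test_that("fdom averages propensities over all domain pairs", {
  pairs <- data.frame(idA = c("a", "c"), idB = c("b", "d"),
                      label = c("positive", "negative"))
  doms <- list(a = "d1", b = "d2", c = "d3", d = "d4")
  tab <- build_propensity_table(pairs, doms)

  expect_equal(fdom_score(character(), "d2", tab), 0)
  expect_equal(fdom_score("d1", "d2", tab),
               unname(tab$propensity[pair_key("d1", "d2")]))
  # unseen pairs contribute 0 but count in the denominator
  expect_equal(fdom_score(c("d1", "d9"), "d2", tab),
               unname(tab$propensity[pair_key("d1", "d2")]) / 2)
  # symmetric in the two proteins
  expect_equal(fdom_score(c("d1", "d3"), "d2", tab),
               fdom_score("d2", c("d1", "d3"), tab))
})
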