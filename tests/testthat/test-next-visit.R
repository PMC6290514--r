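test_that("feature schemes produce the documented vectors", {
  m <- toy_model(8, 4, dim = 5, seed = 2)
  v <- toy_visit(codes = c(9, 11), words = c(1, 3, 1, 0, 4))
  expect_length(visit_features(m, v, "concat_avg"), 10) # 2T
  expect_equal(visit_features(m, v, "codes_avg"),
               colMeans(m$V[c(9, 11), ]))
  # word average counts occurrences with multiplicity, skipping sentinels
  expect_equal(visit_features(m, v, "words_avg"),
               colMeans(m$V[c(1, 3, 1, 4), ]))
  # a single-code visit's codes_avg is exactly that code's row
  expect_equal(visit_features(m, toy_visit(codes = 10, words = 2), "codes_avg"),
               unname(m$V[10, ]))
  oh <- visit_features(m, v, "concat_onehot")
  expect_length(oh, 12)
  expect_equal(sum(oh), 5) # 3 distinct words + 2 codes
  expect_equal(which(oh == 1), c(1, 3, 4, 9, 11))
  expect_error(visit_features(m, v, "pca"), "unknown feature scheme")
  # empty code set under an averaging scheme: zero block, reported
  expect_message(z <- visit_features(m, toy_visit(words = 2), "codes_avg"), "no codes")
  expect_equal(z, numeric(5))
})

test_that("labeled pairs follow admission order within patients", {
  mk <- function(p, v, t, codes) toy_visit(codes, words = 1,
                                           patient_id = p, visit_id = v, admit_time = t)
  visits <- list(mk("a", "a3", "2010-03-01", 12), mk("a", "a1", "2010-01-01", 10),
                 mk("a", "a2", "2010-02-01", 11), mk("b", "b1", "2010-01-05", 10),
                 mk("c", "c1", "2010-01-01", 10), mk("c", "c2", "2010-02-01", 13))
  pairs <- make_labeled_pairs(visits)
  expect_length(pairs, 3) # a: 2 pairs, b: none (single visit), c: 1
  expect_equal(pairs[[1]]$current$visit_id, "a1")
  expect_equal(pairs[[1]]$next_codes, 11)
  expect_equal(pairs[[2]]$current$visit_id, "a2")
  expect_equal(pairs[[2]]$next_codes, 12)
  expect_equal(pairs[[3]]$next_codes, 13)

  # duplicate admit times: deterministic visit_id tiebreak with warning
  dup <- list(mk("d", "d2", "2010-01-01", 20), mk("d", "d1", "2010-01-01", 21))
  expect_warning(p2 <- make_labeled_pairs(dup), "duplicate admit_time")
  expect_equal(p2[[1]]$current$visit_id, "d1")

  # a later visit with no codes yields no example
  nc <- list(mk("e", "e1", "2010-01-01", 10), toy_visit(integer(0), words = 2,
             patient_id = "e", visit_id = "e2", admit_time = "2010-02-01"))
  expect_length(make_labeled_pairs(nc), 0)
})

test_that("softmax predictor learns a deterministic code map", {
  # separable toy task: one-hot feature of current code, next code is a
  # fixed permutation of it
  n_codes <- 6
  perm <- c(3L, 1L, 5L, 6L, 2L, 4L)
  examples <- lapply(rep(seq_len(n_codes), 8), function(ci) {
    x <- numeric(n_codes); x[ci] <- 1
    list(x = x, labels = perm[ci])
  })
  sm <- train_softmax(examples, n_codes, epochs = 100, lr = 0.5, seed = 2)
  for (ci in seq_len(n_codes)) {
    x <- numeric(n_codes); x[ci] <- 1
    expect_equal(predict_topk(sm, x, 1), perm[ci])
  }
  # cross-entropy decreases monotonically early in training
  expect_true(all(diff(sm$loss[1:10]) < 0))
  # determinism
  sm2 <- train_softmax(examples, n_codes, epochs = 100, lr = 0.5, seed = 2)
  expect_identical(sm$Z, sm2$Z)
})

test_that("an untrained softmax predicts the uniform distribution", {
  sm <- structure(list(Z = matrix(0, 5, 3)), class = "jsg_softmax")
  p <- jointsg:::softmax(as.numeric(sm$Z %*% c(1, 2, 3)))
  expect_equal(p, rep(0.2, 5))
  # all-tie top-k falls back to ascending code ids
  expect_equal(predict_topk(sm, c(1, 2, 3), 3), 1:3)
  expect_equal(predict_topk(sm, c(1, 2, 3), 99), 1:5) # k > |C|
})

test_that("softmax probabilities normalize and top-k ordering follows logits", {
  set.seed(4)
  for (i in 1:20) {
    p <- jointsg:::softmax(rnorm(sample(2:40, 1), sd = sample(c(1, 50), 1)))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  sm <- structure(list(Z = diag(3)), class = "jsg_softmax")
  expect_equal(predict_topk(sm, c(2, 1, 0), 2), 1:2)
})

test_that("topk_recall equals brute-force intersection counting", {
  expect_equal(topk_recall(c(1, 9), c(1, 2, 3, 4)), 0.25)
  expect_equal(topk_recall(1:10, c(2, 4)), 1.0)
  expect_equal(topk_recall(1:3, c(7, 8)), 0.0)
  expect_error(topk_recall(1:3, integer(0)), "nonempty")
  set.seed(10)
  for (i in 1:200) {
    pred <- sample(40, sample(1:20, 1))
    truth <- sample(40, sample(1:10, 1))
    brute <- sum(!is.na(match(unique(truth), pred))) / length(unique(truth))
    expect_equal(topk_recall(pred, truth), brute)
  }
})

test_that("recall evaluation reports macro mean, stderr, and k-monotonicity", {
  # identical examples: stderr must be exactly 0
  sm <- structure(list(Z = rbind(c(1, 0), c(0, 1), c(-1, -1))), class = "jsg_softmax")
  exs <- rep(list(list(x = c(1, 0.5), labels = c(1L, 2L))), 4)
  out <- evaluate_topk_recall(sm, exs, ks = c(1, 2, 3))
  expect_equal(out$stderr, rep(0, 3))
  expect_equal(out$n, rep(4, 3))
  expect_true(all(diff(out$mean_recall) >= 0)) # nested predictions
  expect_true(all(out$mean_recall >= 0 & out$mean_recall <= 1))
  expect_equal(out$mean_recall[3], 1)
})

test_that("external feature matrices load and score through the harness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(id = c("e1", "e2"), a = c(0.5, 1.5), b = c(-1, 2)),
              path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  M <- read_feature_matrix(path)
  expect_equal(dim(M), c(2, 2))
  expect_equal(rownames(M), c("e1", "e2"))
  expect_equal(M[2, ], c(1.5, 2))
})
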