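#' Visit feature vector
#'
#' Builds the predictor feature vector for a visit under one of the
#' evaluation schemes: `codes_avg` (mean of the visit codes' input
#' vectors, length T), `words_avg` (mean over note word occurrences,
#' length T), `concat_avg` (both concatenated, length 2T), or
#' `concat_onehot` (binary indicators over words then codes, length
#' `n_words + n_codes`).  An empty token set under an averaging scheme
#' yields a zero block (reported via a message).
#'
#' @param model A `jsg_model`.
#' @param visit An indexed visit.
#' @param scheme One of `"codes_avg"`, `"words_avg"`, `"concat_avg"`,
#'   `"concat_onehot"`.
#' @return Numeric feature vector.
#' @export
visit_features <- function(model, visit,
                           scheme = c("concat_avg", "codes_avg", "words_avg",
                                      "concat_onehot")) {
  if (length(scheme) != 1 || !scheme %in% c("concat_avg", "codes_avg", "words_avg", "concat_onehot"))
    stop("unknown feature scheme: ", paste(scheme, collapse = "/"))
  T <- ncol(model$V)
  words <- visit$words[visit$words != BOUNDARY]
  avg <- function(ids, what) {
    if (!length(ids)) {
      message("visit ", visit$visit_id, ": no ", what, "; zero feature block")
      return(numeric(T))
    }
    colMeans(model$V[ids, , drop = FALSE])
  }
  switch(scheme,
         codes_avg = avg(visit$codes, "codes"),
         words_avg = avg(words, "words"),
         concat_avg = c(avg(visit$codes, "codes"), avg(words, "words")),
         concat_onehot = {
           x <- numeric(nrow(model$V))
           x[unique(c(visit$codes, words))] <- 1
           x
         })
}

#' Consecutive-visit labeled pairs
#'
#' Sorts each patient's visits by admission time and emits one
#' (earlier visit, next-visit code set) pair per consecutive pair of
#' visits.  Patients with a single visit emit nothing; pairs whose
#' later visit has no codes are skipped (the label set must be
#' nonempty).  Duplicate admission times within a patient are broken
#' deterministically by visit id, with a warning.
#'
#' @param visits Indexed visits (fields `patient_id`, `admit_time`,
#'   `visit_id`, `codes`, `words`).
#' @return List of elements `list(current = visit, next_codes =
#'   integer ids)`.
#' @export
make_labeled_pairs <- function(visits) {
  pid <- vapply(visits, `[[`, character(1), "patient_id")
  out <- list()
  for (p in unique(pid)) {
    vs <- visits[pid == p]
    at <- vapply(vs, `[[`, character(1), "admit_time")
    vi <- vapply(vs, `[[`, character(1), "visit_id")
    if (anyDuplicated(at))
      warning("patient ", p, ": duplicate admit_time; ordering by visit_id")
    vs <- vs[order(at, vi, method = "radix")]
    if (length(vs) < 2) next
    for (i in seq_len(length(vs) - 1)) {
      nxt <- vs[[i + 1]]$codes
      if (!length(nxt)) next
      out[[length(out) + 1]] <- list(current = vs[[i]], next_codes = nxt)
    }
  }
  out
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Train the softmax next-visit code predictor
#'
#' Minimizes categorical cross-entropy by per-example stochastic
#' gradient descent with seeded shuffling.  An example's target
#' distribution is uniform over its true next-visit codes.
#'
#' @param examples List of `list(x = features, labels = integer code
#'   indices in 1..n_codes)`.
#' @param n_codes Number of code classes |C|.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param seed Integer seed for shuffling.
#' @return Object of class `jsg_softmax` with weight matrix `Z`
#'   (`n_codes x length(x)`) and per-epoch mean loss in `loss`.
#' @export
train_softmax <- function(examples, n_codes, epochs = 100L, lr = 0.5, seed = 1L) {
  stopifnot(length(examples) > 0, n_codes >= 2)
  d <- length(examples[[1]]$x)
  X <- t(vapply(examples, function(e) as.numeric(e$x), numeric(d)))
  labs <- lapply(examples, function(e) {
    l <- as.integer(e$labels)
    stopifnot(length(l) > 0, all(l >= 1), all(l <= n_codes))
    l
  })
  Z <- matrix(0, nrow = n_codes, ncol = d)
  n <- length(examples)
  loss <- numeric(epochs)
  orders <- with_local_seed(seed, function()
    lapply(seq_len(epochs), function(e) sample.int(n)))
  for (e in seq_len(epochs)) {
    tot <- 0
    for (i in orders[[e]]) {
      x <- X[i, ]
      p <- softmax(as.numeric(Z %*% x))
      y <- numeric(n_codes)
      y[labs[[i]]] <- 1 / length(labs[[i]])
      tot <- tot - sum(y * log(pmax(p, 1e-300)))
      Z <- Z - lr * tcrossprod(p - y, x)
    }
    loss[e] <- tot / n
    if (!is.finite(loss[e]))
      stop("softmax training diverged (non-finite loss); try a smaller lr")
  }
  structure(list(Z = Z, epochs = epochs, lr = lr, seed = seed, loss = loss),
            class = "jsg_softmax")
}

#' Top-k next-visit code prediction
#'
#' Softmax over `Z x`; returns the `k` most probable code indices,
#' ties broken by ascending code index.  `k` beyond the class count
#' returns all codes.
#'
#' @param sm A `jsg_softmax`.
#' @param x Feature vector (length must match `ncol(Z)`).
#' @param k Number of codes to recommend.
#' @return Integer vector of code indices, most probable first.
#' @export
predict_topk <- function(sm, x, k) {
  stopifnot(length(x) == ncol(sm$Z))
  p <- softmax(as.numeric(sm$Z %*% x))
  ord <- order(-p, seq_along(p), method = "radix")
  ord[seq_len(min(k, length(ord)))]
}

#' Top-k recall
#'
#' Fraction of the true next-visit codes recovered among the `k`
#' recommended codes: `|predicted intersect true| / |true|`.
#'
#' @param predicted Ordered predicted code indices.
#' @param true_set Nonempty set of true code indices.
#' @return Recall in `[0, 1]`.
#' @export
topk_recall <- function(predicted, true_set) {
  true_set <- unique(true_set)
  if (!length(true_set)) stop("true_set must be nonempty")
  length(intersect(predicted, true_set)) / length(true_set)
}

#' Evaluate a next-visit predictor by top-k recall
#'
#' Macro-averages per-example top-k recall over a labeled example set
#' and reports the standard error of the mean (`sd / sqrt(n)`).
#'
#' @param sm A `jsg_softmax`.
#' @param examples Labeled examples (as for [train_softmax()]).
#' @param ks Integer vector of cutoffs.
#' @return data.frame with columns `k`, `mean_recall`, `stderr`, `n`.
#' @export
evaluate_topk_recall <- function(sm, examples, ks = c(20L, 30L, 40L)) {
  stopifnot(length(examples) > 0)
  n_codes <- nrow(sm$Z)
  preds <- lapply(examples, function(e) predict_topk(sm, e$x, max(c(ks, 0))))
  rows <- lapply(ks, function(k) {
    r <- vapply(seq_along(examples), function(i)
      topk_recall(preds[[i]][seq_len(min(k, n_codes))], examples[[i]]$labels),
      numeric(1))
    data.frame(k = k, mean_recall = mean(r),
               stderr = if (length(r) > 1) sd(r) / sqrt(length(r)) else 0,
               n = length(r))
  })
  do.call(rbind, rows)
}

#' Full next-visit prediction experiment
#'
#' Builds labeled consecutive-visit pairs, splits patients into
#' train/test (patient-level, seeded), constructs features under the
#' requested scheme, trains the softmax predictor on the training
#' examples, and scores top-k recall on the test examples.  Labels are
#' local code indices `1..n_codes` (global id minus `n_words`).
#'
#' @param model A trained `jsg_model` (supplies features and the code
#'   vocabulary).
#' @param visits Indexed visits.
#' @param scheme Feature scheme (see [visit_features()]).
#' @param ks Recall cutoffs.
#' @param epochs,lr Softmax training settings.
#' @param seed Seed for the patient split and training shuffles.
#' @param test_fraction Fraction of multi-visit patients held out.
#' @param features Optional externally computed feature matrix (rows
#'   aligned with the labeled pairs) overriding `scheme`.
#' @return List with `results` (data.frame `scheme, k, mean_recall,
#'   stderr, n`), the fitted `softmax` model, and example counts.
#' @export
next_visit_experiment <- function(model, visits, scheme = "concat_avg",
                                  ks = c(20L, 30L, 40L), epochs = 100L,
                                  lr = 0.5, seed = 1L, test_fraction = 0.2,
                                  features = NULL) {
  pairs <- make_labeled_pairs(visits)
  if (!length(pairs)) stop("no patient has two or more visits with coded follow-up")
  n_words <- model$vocab$n_words
  n_codes <- model$vocab$n_codes
  exs <- lapply(seq_along(pairs), function(i) {
    x <- if (is.null(features)) visit_features(model, pairs[[i]]$current, scheme)
         else as.numeric(features[i, ])
    list(x = x, labels = pairs[[i]]$next_codes - n_words,
         patient_id = pairs[[i]]$current$patient_id)
  })
  pts <- unique(vapply(exs, `[[`, character(1), "patient_id"))
  n_test <- max(1L, round(test_fraction * length(pts)))
  test_pts <- with_local_seed(seed, function() sample(pts, n_test))
  is_test <- vapply(exs, function(e) e$patient_id %in% test_pts, TRUE)
  train <- exs[!is_test]; test <- exs[is_test]
  if (!length(train) || !length(test))
    stop("train/test split left one side empty; adjust test_fraction")
  sm <- train_softmax(train, n_codes, epochs = epochs, lr = lr, seed = seed)
  res <- evaluate_topk_recall(sm, test, ks)
  res <- cbind(scheme = scheme, res, stringsAsFactors = FALSE)
  list(results = res, softmax = sm, n_train = length(train), n_test = length(test))
}

#' Read an externally computed feature matrix
#'
#' TSV with an example id in the first column and the feature values
#' in the remaining columns, so that feature sets built by other
#' decomposition methods can be scored by the same harness.
#'
#' @param path TSV path.
#' @return Numeric matrix with example ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df[[1]])
  colnames(M) <- NULL
  M
}
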