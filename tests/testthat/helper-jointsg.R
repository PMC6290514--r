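# shared fixtures and independent oracles, built in code at test time

# indexed visit built directly (codes/words are global integer ids;
# 0 in words is the note-boundary sentinel)
toy_visit <- function(codes = integer(0), words = integer(0),
                      patient_id = "p1", visit_id = "v1",
                      admit_time = "2010-01-01T00:00:00") {
  list(patient_id = patient_id, visit_id = visit_id, admit_time = admit_time,
       codes = as.integer(codes), words = as.integer(words))
}

# raw (reader-format) visit record
raw_visit <- function(patient_id, visit_id, admit_time, codes, notes) {
  list(patient_id = patient_id, visit_id = visit_id, admit_time = admit_time,
       codes = codes, notes = notes, tokenized = FALSE)
}

toy_vocab <- function(n_words, n_codes, word_counts = NULL, code_counts = NULL) {
  structure(list(
    tokens = c(sprintf("w%02d", seq_len(n_words)),
               paste0("ICD9:", sprintf("%03d", 100 + seq_len(n_codes) - 1))),
    counts = as.integer(c(word_counts %||% rep(10L, n_words),
                          code_counts %||% rep(10L, n_codes))),
    n_words = as.integer(n_words), n_codes = as.integer(n_codes)),
    class = "jsg_vocab")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small embedding model with reproducible entries
toy_model <- function(n_words, n_codes, dim, seed = 1) {
  vocab <- toy_vocab(n_words, n_codes)
  n <- n_words + n_codes
  set.seed(seed)
  V <- matrix(rnorm(n * dim), n, dim)
  U <- matrix(rnorm(n * dim), n, dim)
  rownames(V) <- rownames(U) <- vocab$tokens
  structure(list(V = V, U = U, vocab = vocab,
                 config = list(mode = "joint", dim = dim)),
            class = "jsg_model")
}

# Independent context-pair oracle: a literal, quadratic transcription
# of the two context definitions, deliberately written as plain
# nested loops over index pairs.
oracle_code_pairs <- function(codes, words) {
  codes <- sort(codes)
  real_words <- words[words != 0L]
  out <- NULL
  for (ci in codes) {
    for (cj in codes) if (cj != ci) out <- rbind(out, c(ci, cj))
    for (w in real_words) out <- rbind(out, c(ci, w))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("target", "context")
  out
}

oracle_word_pairs <- function(codes, words, q) {
  codes <- sort(codes)
  seg <- cumsum(words == 0L)
  out <- NULL
  for (i in seq_along(words)) {
    if (words[i] == 0L) next
    for (j in seq_along(words)) {
      if (j == i || words[j] == 0L) next
      if (abs(j - i) <= q && seg[j] == seg[i])
        out <- rbind(out, c(words[i], words[j]))
    }
    # the loop above emits neighbours in position order because j runs
    # left to right; codes follow in ascending id order
    for (cj in codes) out <- rbind(out, c(words[i], cj))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("target", "context")
  out
}

# unit axis for a topic id; NA (noise tokens) map to the last axis,
# which no topic uses as long as topic count < dim
topic_axis <- function(topic, dim) {
  ax <- numeric(dim)
  ax[if (is.na(topic)) dim else topic] <- 1
  ax
}

# small two-topic corpus with deterministic structure, used by the
# quick training-quality checks
two_topic_corpus <- function(n_visits_per_topic = 40, seed = 42) {
  cfg <- synth_config(n_patients = n_visits_per_topic, visits_min = 2,
                      visits_max = 2, n_topics = 2, codes_per_topic = 3,
                      words_per_topic = 10, codes_per_visit = 2,
                      note_length = 12, noise_word_fraction = 0.1,
                      noise_pool_size = 5, seed = seed)
  corpus <- generate_corpus(cfg)
  pcfg <- preprocess_config(min_word_count = 2, min_code_count = 2)
  pv <- preprocess_visits(corpus$visits, pcfg)
  vocab <- build_vocabulary(pv, pcfg)
  list(corpus = corpus, vocab = vocab,
       visits = index_visits(pv, vocab), pcfg = pcfg)
}

# memoized heavy fixture shared by the phenotype-recovery and
# next-visit acceptance checks: the default 500-patient five-topic
# cohort and a joint model trained on it for 30 epochs
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (!is.null(.acceptance_cache$fx)) return(.acceptance_cache$fx)
  cfg <- synth_config(seed = 20260930L)
  corpus <- generate_corpus(cfg)
  pcfg <- preprocess_config()
  pv <- preprocess_visits(corpus$visits, pcfg)
  vocab <- build_vocabulary(pv, pcfg)
  visits <- index_visits(pv, vocab)
  model <- jsg_train(visits, vocab,
                     training_config(epochs = 30L, seed = 20260930L))
  .acceptance_cache$fx <- list(corpus = corpus, vocab = vocab,
                               visits = visits, model = model)
  .acceptance_cache$fx
}
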