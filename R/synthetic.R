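#' Synthetic EHR corpus configuration
#'
#' Parameters of the generator in [generate_corpus()].  The defaults
#' describe a cohort of 500 patients whose visits are driven by 5
#' latent topics, each owning 8 diagnosis codes and 40 note words,
#' with a shared pool of topic-free noise words making up 20% of note
#' text and a sticky Markov chain (stay probability 0.8) carrying a
#' patient's topic from visit to visit.
#'
#' @param n_patients Number of patients.
#' @param visits_min,visits_max Per-patient visit count is uniform on
#'   this range.
#' @param n_topics Number of latent topics.
#' @param codes_per_topic,words_per_topic Tokens owned by each topic.
#' @param codes_per_visit Codes drawn (without replacement) from the
#'   visit topic's code pool.
#' @param note_length Words per visit note.
#' @param noise_word_fraction Probability a note word comes from the
#'   shared noise pool instead of the topic pool.
#' @param noise_pool_size Size of the shared noise-word pool.
#' @param topic_transition_stickiness Probability the next visit keeps
#'   the current topic; otherwise the topic is redrawn uniformly.
#' @param long_codes Emit 4-5 character ICD-9-like codes (exercises
#'   three-character grouping); default emits 3-character codes for
#'   which grouping is the identity.
#' @param seed Integer seed; generation is a pure function of the
#'   whole configuration.
#' @return A list of class `jsg_synth_config`.
#' @export
synth_config <- function(n_patients = 500L, visits_min = 1L, visits_max = 4L,
                         n_topics = 5L, codes_per_topic = 8L,
                         words_per_topic = 40L, codes_per_visit = 3L,
                         note_length = 40L, noise_word_fraction = 0.2,
                         noise_pool_size = words_per_topic,
                         topic_transition_stickiness = 0.8,
                         long_codes = FALSE, seed = 1L) {
  stopifnot(n_patients >= 1, visits_min >= 1, visits_max >= visits_min,
            n_topics >= 1, n_topics <= 26, codes_per_topic >= 1, words_per_topic >= 1,
            codes_per_visit >= 1, codes_per_visit <= codes_per_topic,
            note_length >= 1, noise_word_fraction >= 0, noise_word_fraction < 1,
            noise_pool_size >= 1,
            topic_transition_stickiness >= 0, topic_transition_stickiness <= 1,
            n_topics * codes_per_topic <= 900)
  structure(list(n_patients = as.integer(n_patients),
                 visits_min = as.integer(visits_min),
                 visits_max = as.integer(visits_max),
                 n_topics = as.integer(n_topics),
                 codes_per_topic = as.integer(codes_per_topic),
                 words_per_topic = as.integer(words_per_topic),
                 codes_per_visit = as.integer(codes_per_visit),
                 note_length = as.integer(note_length),
                 noise_word_fraction = noise_word_fraction,
                 noise_pool_size = as.integer(noise_pool_size),
                 topic_transition_stickiness = topic_transition_stickiness,
                 long_codes = isTRUE(long_codes), seed = as.integer(seed)),
            class = "jsg_synth_config")
}

# letter-only token names so the tokenizer passes them through
alpha_index <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k] - 1L
    s <- ""
    repeat {
      s <- paste0(letters[n %% 26L + 1L], s)
      n <- n %/% 26L
      if (n == 0) break
      n <- n - 1L
    }
    out[k] <- s
  }
  out
}

#' Generate a synthetic EHR corpus with known topic structure
#'
#' Each patient's first visit topic is uniform; later visits keep the
#' topic with the configured stickiness, else redraw uniformly.  A
#' visit draws `codes_per_visit` distinct codes from its topic's code
#' pool and a note of `note_length` words, each word coming from the
#' shared noise pool with probability `noise_word_fraction` and from
#' the topic's word pool otherwise.  Admission times increase strictly
#' within each patient.
#'
#' @param cfg A [synth_config()].
#' @return List with `visits` (records in the JSON-lines layout
#'   accepted by [read_visits()]) and `truth`, a list with
#'   `topic_of` (named vector mapping every non-noise word and grouped
#'   code to its topic; noise words map to `NA`) and
#'   `patient_topics` (per-patient visit topic sequences).
#' @export
generate_corpus <- function(cfg = synth_config()) {
  with_local_seed(cfg$seed, function() generate_corpus_impl(cfg))
}

generate_corpus_impl <- function(cfg) {
  topics <- seq_len(cfg$n_topics)
  topic_words <- lapply(topics, function(t)
    paste0("t", letters[(t - 1L) %% 26L + 1L], "w", alpha_index(seq_len(cfg$words_per_topic))))
  noise_words <- paste0("zz", alpha_index(seq_len(cfg$noise_pool_size)))
  base_codes <- sprintf("%03d", 100L + seq_len(cfg$n_topics * cfg$codes_per_topic) - 1L)
  topic_codes <- split(base_codes, rep(topics, each = cfg$codes_per_topic))

  topic_of <- c(stats::setNames(rep(topics, each = cfg$words_per_topic),
                                unlist(topic_words)),
                stats::setNames(rep(NA_integer_, length(noise_words)), noise_words),
                stats::setNames(rep(topics, each = cfg$codes_per_topic), base_codes))

  visits <- list()
  patient_topics <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("p%04d", p)
    nv <- if (cfg$visits_max > cfg$visits_min)
      sample(cfg$visits_min:cfg$visits_max, 1L) else cfg$visits_min
    tseq <- integer(nv)
    tseq[1] <- sample(topics, 1L)
    if (nv > 1) for (k in 2:nv) {
      tseq[k] <- if (stats::runif(1) < cfg$topic_transition_stickiness)
        tseq[k - 1] else sample(topics, 1L)
    }
    patient_topics[[pid]] <- tseq
    for (k in seq_len(nv)) {
      t <- tseq[k]
      codes <- sample(topic_codes[[t]], cfg$codes_per_visit)
      if (cfg$long_codes) {
        extra <- vapply(codes, function(cd)
          paste0(cd, paste(sample(0:9, sample(1:2, 1L), replace = TRUE), collapse = "")),
          character(1))
        codes <- unname(extra)
      }
      from_noise <- stats::runif(cfg$note_length) < cfg$noise_word_fraction
      note <- character(cfg$note_length)
      n_noise <- sum(from_noise)
      if (n_noise) note[from_noise] <- sample(noise_words, n_noise, replace = TRUE)
      if (n_noise < cfg$note_length)
        note[!from_noise] <- sample(topic_words[[t]], cfg$note_length - n_noise,
                                    replace = TRUE)
      visits[[length(visits) + 1]] <- list(
        patient_id = pid,
        visit_id = sprintf("%s-v%02d", pid, k),
        admit_time = format(as.Date("2010-01-01") + (p - 1L) %% 7L + (k - 1L) * 30L,
                            "%Y-%m-%dT00:00:00"),
        codes = codes,
        notes = paste(note, collapse = " "),
        tokenized = FALSE)
    }
  }
  list(visits = visits,
       truth = list(topic_of = topic_of, patient_topics = patient_topics),
       config = cfg)
}

#' Topic-retrieval precision of a trained model
#'
#' For every code with a known topic, retrieves its `k` nearest words
#' in the embedding space and scores the fraction that belong to the
#' same topic (noise words never match); returns the macro average
#' over codes.  Quantifies phenotype-retrieval quality on synthetic
#' corpora where the token-topic assignment is known.
#'
#' @param model A trained `jsg_model`.
#' @param truth Ground truth from [generate_corpus()].
#' @param k Neighbors per code.
#' @return Macro-averaged precision in `[0, 1]`.
#' @export
retrieval_precision <- function(model, truth, k = 15L) {
  tokens <- model$vocab$tokens
  codes <- strip_code_prefix(tokens[is_code_token(tokens)])
  codes <- codes[codes %in% names(truth$topic_of)]
  codes <- codes[!is.na(truth$topic_of[codes])]
  if (!length(codes)) stop("no code in the model has a known topic")
  per_code <- vapply(codes, function(cd) {
    nb <- nearest_words_to_code(model, cd, k)
    wt <- truth$topic_of[nb$token]
    mean(!is.na(wt) & wt == truth$topic_of[[cd]])
  }, numeric(1))
  mean(per_code)
}

#' Within- versus cross-topic code-word cosine gap
#'
#' Mean cosine similarity between code and word vectors sharing a
#' topic minus the mean across different topics.  Positive gaps mean
#' the joint space groups each topic's codes with its words.
#'
#' @inheritParams retrieval_precision
#' @return List with `within`, `cross`, and `gap = within - cross`.
#' @export
topic_cosine_gap <- function(model, truth) {
  tokens <- model$vocab$tokens
  code_ids <- which(is_code_token(tokens))
  word_ids <- which(!is_code_token(tokens))
  ct <- truth$topic_of[strip_code_prefix(tokens[code_ids])]
  wt <- truth$topic_of[tokens[word_ids]]
  code_ids <- code_ids[!is.na(ct)]; ct <- ct[!is.na(ct)]
  word_ids <- word_ids[!is.na(wt)]; wt <- wt[!is.na(wt)]
  Vn <- model$V / sqrt(rowSums(model$V^2))
  S <- Vn[code_ids, , drop = FALSE] %*% t(Vn[word_ids, , drop = FALSE])
  same <- outer(ct, wt, `==`)
  list(within = mean(S[same]), cross = mean(S[!same]),
       gap = mean(S[same]) - mean(S[!same]))
}
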