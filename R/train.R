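#' Training configuration
#'
#' Hyperparameters of the embedding trainer.  Defaults follow the
#' study conditions the model was developed under: 200-dimensional
#' vectors, 40 epochs, context window 5, 5 negative samples per
#' positive pair, and word-only pretraining on roughly 10% of visits.
#'
#' @param dim Vector dimensionality T.
#' @param epochs Passes over the corpus.
#' @param window Word context window half-width q.
#' @param negatives Negative samples K per (target, context) pair.
#' @param initial_lr Initial learning rate.
#' @param lr_schedule `"linear-decay"` (to `initial_lr/100` over all
#'   scheduled updates) or `"constant"`.
#' @param noise_power Exponent applied to marginal counts in the
#'   negative-sampling distribution.
#' @param mode `"joint"` trains codes and words with both context
#'   types; `"words_only"` / `"codes_only"` are the plain skip-gram
#'   restrictions to one namespace.
#' @param seed Integer seed driving initialization, shuffling and
#'   negative draws.
#' @param pretrain_fraction Fraction of visits used to pretrain word
#'   vectors before joint training (0 disables).
#' @param pretrain_epochs Epochs of the pretraining phase.
#' @return A list of class `jsg_training_config`.
#' @export
training_config <- function(dim = 200L, epochs = 40L, window = 5L,
                            negatives = 5L, initial_lr = 0.025,
                            lr_schedule = c("linear-decay", "constant"),
                            noise_power = 0.75,
                            mode = c("joint", "words_only", "codes_only"),
                            seed = 1L, pretrain_fraction = 0.10,
                            pretrain_epochs = 5L) {
  lr_schedule <- match.arg(lr_schedule)
  mode <- match.arg(mode)
  stopifnot(dim >= 1, epochs >= 1, window >= 1, negatives >= 0,
            initial_lr > 0, noise_power > 0, noise_power <= 1,
            pretrain_fraction >= 0, pretrain_fraction <= 1,
            pretrain_epochs >= 0)
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 window = as.integer(window), negatives = as.integer(negatives),
                 initial_lr = initial_lr, lr_schedule = lr_schedule,
                 noise_power = noise_power, mode = mode,
                 seed = as.integer(seed),
                 pretrain_fraction = pretrain_fraction,
                 pretrain_epochs = as.integer(pretrain_epochs)),
            class = "jsg_training_config")
}

# numerically stable log(sigmoid(x)); exact to within 1 ulp for
# |x| up to well past 1e4
log_sigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

sigmoid <- function(x) ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))

#' Negative-sampling objective of one training pair
#'
#' The per-pair term of the training objective:
#' `log sigma(V_t . U_c) + sum_n log(1 - sigma(V_t . U_n))` over the
#' drawn negatives `n`, with `sigma` the logistic function.  Training
#' ascends this quantity.
#'
#' @param model A `jsg_model` (or any list with matrices `V`, `U`).
#' @param target,context Integer row ids.
#' @param negatives Integer row ids of the negative samples (same
#'   namespace as `context`).
#' @return The objective value (finite for dot products up to about
#'   1e4 in magnitude).
#' @export
pair_objective <- function(model, target, context, negatives = integer(0)) {
  v <- model$V[target, ]
  pos <- log_sigmoid(sum(v * model$U[context, ]))
  neg <- 0
  if (length(negatives)) {
    dots <- as.numeric(model$U[negatives, , drop = FALSE] %*% v)
    neg <- sum(log_sigmoid(-dots)) # log(1 - sigma(x)) = log sigma(-x)
  }
  pos + neg
}

#' One stochastic gradient-ascent step on a training pair
#'
#' Moves the target's input row and the context/negative context rows
#' along the analytic gradient of [pair_objective()], all partials
#' evaluated at the current point (simultaneous update).
#'
#' @inheritParams pair_objective
#' @param lr Learning rate (step size).
#' @return The updated model.
#' @export
sgd_pair_update <- function(model, target, context, negatives = integer(0), lr) {
  stopifnot(lr >= 0)
  v <- model$V[target, ]
  # every sigmoid is evaluated at the current point before any row
  # moves, so the step is the exact analytic gradient even when a
  # negative coincides with the context row
  g_pos <- 1 - sigmoid(sum(v * model$U[context, ]))
  acc <- g_pos * model$U[context, ]
  rows <- context
  coefs <- g_pos
  for (n in unique(negatives)) {
    reps <- sum(negatives == n)
    g_n <- -reps * sigmoid(sum(v * model$U[n, ]))
    acc <- acc + g_n * model$U[n, ]
    rows <- c(rows, n)
    coefs <- c(coefs, g_n)
  }
  for (i in seq_along(rows))
    model$U[rows[i], ] <- model$U[rows[i], ] + lr * coefs[i] * v
  model$V[target, ] <- v + lr * acc
  if (!all(is.finite(model$V[target, ])))
    stop("non-finite update; training aborted (target id ", target, ")")
  model
}

# ---- full training -------------------------------------------------

mode_code <- function(mode) match(mode, c("joint", "words_only", "codes_only")) - 1L

noise_cumsums <- function(vocab, power) {
  wc <- vocab$counts[seq_len(vocab$n_words)]
  cc <- vocab$counts[vocab$n_words + seq_len(vocab$n_codes)]
  list(word = if (length(wc)) cumsum(as.numeric(wc)^power / sum(as.numeric(wc)^power)) else numeric(0),
       code = if (length(cc)) cumsum(as.numeric(cc)^power / sum(as.numeric(cc)^power)) else numeric(0))
}

new_model <- function(V, U, vocab, cfg) {
  rownames(V) <- rownames(U) <- vocab$tokens
  structure(list(V = V, U = U, vocab = vocab, config = cfg),
            class = "jsg_model")
}

#' @export
print.jsg_model <- function(x, ...) {
  cat("<jsg_model> ", nrow(x$V), " tokens (", x$vocab$n_words, " words, ",
      x$vocab$n_codes, " codes) x ", ncol(x$V), " dims, mode=",
      x$config$mode, "\n", sep = "")
  invisible(x)
}

run_cpp_train <- function(visits, Vt, Ut, vocab, cum, cfg, mode, epochs, seed) {
  code_sets <- lapply(visits, function(v) as.integer(v$codes) - 1L)
  word_seqs <- lapply(visits, function(v) as.integer(v$words) - 1L) # boundary 0 -> -1
  cpp_train(code_sets, word_seqs, Vt, Ut, vocab$n_words,
            cum$word, cum$code, mode_code(mode), as.integer(epochs),
            cfg$window, cfg$negatives, cfg$initial_lr,
            cfg$initial_lr / 100, cfg$lr_schedule == "linear-decay",
            as.integer(seed), FALSE)
  invisible(NULL)
}

#' Train the joint embedding model
#'
#' Runs stochastic gradient ascent on the negative-sampling objective
#' over `cfg$epochs` shuffled passes of the corpus.  In `"joint"` mode
#' each code target sees the visit's other codes and all note words as
#' context, and each word target sees its window words and all visit
#' codes; `"words_only"` / `"codes_only"` restrict targets and
#' contexts to one namespace, recovering plain skip-gram.  Each
#' positive pair is contrasted against `cfg$negatives` tokens drawn
#' from the noise distribution of the context's namespace.  When
#' `cfg$pretrain_fraction > 0` in joint mode, word vectors are first
#' pretrained words-only on a seeded visit subsample.
#'
#' Identical configurations (including seed) give byte-identical
#' models.
#'
#' @param visits Indexed visits from [index_visits()].
#' @param vocab The `jsg_vocab` the visits were indexed against.
#' @param cfg A [training_config()].
#' @return A `jsg_model` with input matrix `V` and context matrix `U`,
#'   both `(n_words + n_codes) x dim`, rows named by token.
#' @export
jsg_train <- function(visits, vocab, cfg = training_config()) {
  stopifnot(length(visits) > 0)
  n_tokens <- vocab$n_words + vocab$n_codes
  cum <- noise_cumsums(vocab, cfg$noise_power)
  Vt <- cpp_init_vectors(cfg$dim, n_tokens, cfg$seed)
  Ut <- matrix(0, nrow = cfg$dim, ncol = n_tokens)
  if (cfg$mode == "joint" && cfg$pretrain_fraction > 0 && cfg$pretrain_epochs > 0) {
    sub <- pretrain_sample(length(visits), cfg$pretrain_fraction, cfg$seed)
    run_cpp_train(visits[sub], Vt, Ut, vocab, cum, cfg,
                  mode = "words_only", epochs = cfg$pretrain_epochs,
                  seed = cfg$seed + 1L)
  }
  run_cpp_train(visits, Vt, Ut, vocab, cum, cfg,
                mode = cfg$mode, epochs = cfg$epochs, seed = cfg$seed)
  new_model(t(Vt), t(Ut), vocab, cfg)
}

pretrain_sample <- function(n, fraction, seed) {
  k <- min(n, as.integer(ceiling(fraction * n)))
  with_local_seed(seed, function() sort(sample.int(n, k)))
}

#' Pretrain word vectors only
#'
#' The standalone word pretraining phase: words-only skip-gram on a
#' seeded sample of `ceiling(pretrain_fraction * n)` visits for
#' `pretrain_epochs` epochs.  Word rows of `V` and `U` are trained;
#' code rows stay at their initialization.
#'
#' @inheritParams jsg_train
#' @return A `jsg_model` (word rows trained, code rows initialized).
#' @export
pretrain_words <- function(visits, vocab, cfg = training_config()) {
  if (cfg$pretrain_fraction == 0 || cfg$pretrain_epochs == 0) {
    Vt <- cpp_init_vectors(cfg$dim, vocab$n_words + vocab$n_codes, cfg$seed)
    Ut <- matrix(0, nrow = cfg$dim, ncol = vocab$n_words + vocab$n_codes)
    return(new_model(t(Vt), t(Ut), vocab, cfg))
  }
  n_tokens <- vocab$n_words + vocab$n_codes
  cum <- noise_cumsums(vocab, cfg$noise_power)
  Vt <- cpp_init_vectors(cfg$dim, n_tokens, cfg$seed)
  Ut <- matrix(0, nrow = cfg$dim, ncol = n_tokens)
  sub <- pretrain_sample(length(visits), cfg$pretrain_fraction, cfg$seed)
  run_cpp_train(visits[sub], Vt, Ut, vocab, cum, cfg,
                mode = "words_only", epochs = cfg$pretrain_epochs,
                seed = cfg$seed + 1L)
  new_model(t(Vt), t(Ut), vocab, cfg)
}

# trainer-emitted pair stream (same code path as training, recording
# instead of updating); internal, used for auditing and tests
trainer_pair_stream <- function(visits, vocab, cfg) {
  code_sets <- lapply(visits, function(v) as.integer(v$codes) - 1L)
  word_seqs <- lapply(visits, function(v) as.integer(v$words) - 1L)
  n_tokens <- vocab$n_words + vocab$n_codes
  Vt <- matrix(0, cfg$dim, n_tokens)
  Ut <- matrix(0, cfg$dim, n_tokens)
  cum <- noise_cumsums(vocab, cfg$noise_power)
  res <- cpp_train(code_sets, word_seqs, Vt, Ut, vocab$n_words,
                   cum$word, cum$code, mode_code(cfg$mode), cfg$epochs,
                   cfg$window, cfg$negatives, cfg$initial_lr,
                   cfg$initial_lr / 100, cfg$lr_schedule == "linear-decay",
                   cfg$seed, TRUE)
  p <- res$pairs
  colnames(p) <- c("target", "context")
  p
}
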