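#' Enumerate code-target training pairs for one visit
#'
#' Every code in the visit's code set is a target whose context is
#' every other code in the set plus every note word occurrence
#' (counted with multiplicity).  Emission order is deterministic:
#' targets in ascending id order; per target, other codes in ascending
#' id order, then words in sequence order.
#'
#' @param visit An indexed visit from [index_visits()].
#' @return Integer matrix with columns `target`, `context` (possibly
#'   zero rows).
#' @export
code_target_contexts <- function(visit) {
  D <- sort(visit$codes)
  N <- visit$words[visit$words != BOUNDARY]
  if (length(D) == 0) return(empty_pairs())
  ctx_per_target <- length(D) - 1L + length(N)
  if (ctx_per_target == 0) return(empty_pairs())
  tgt <- rep(D, each = ctx_per_target)
  ctx <- unlist(lapply(D, function(ci) c(D[D != ci], N)), use.names = FALSE)
  cbind(target = tgt, context = as.integer(ctx))
}

#' Enumerate word-target training pairs for one visit
#'
#' Every note word occurrence is a target whose context is the words
#' within `q` positions on either side (never crossing a note
#' boundary) plus every code in the visit's code set.  Per target,
#' window words come in position order, then codes in ascending id
#' order.
#'
#' @param visit An indexed visit from [index_visits()].
#' @param q Window half-width (positions each side).
#' @return Integer matrix with columns `target`, `context`.
#' @export
word_target_contexts <- function(visit, q = 5L) {
  stopifnot(q >= 1)
  N <- visit$words
  D <- sort(visit$codes)
  if (length(N) == 0) return(empty_pairs())
  seg <- cumsum(N == BOUNDARY)
  rows <- lapply(seq_along(N), function(i) {
    if (N[i] == BOUNDARY) return(NULL)
    j <- max(1L, i - q):min(length(N), i + q)
    j <- j[j != i & N[j] != BOUNDARY & seg[j] == seg[i]]
    ctx <- c(N[j], D)
    if (!length(ctx)) return(NULL)
    cbind(target = rep(N[i], length(ctx)), context = as.integer(ctx))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_pairs())
  do.call(rbind, rows)
}

empty_pairs <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("target", "context")))
}

#' Shuffled visit schedule used by training
#'
#' The deterministic per-epoch visit order the trainer follows for a
#' given seed: each epoch is an independent Fisher-Yates shuffle of
#' `1..n_visits` from a seeded generator.
#'
#' @param n_visits Number of visits.
#' @param epochs Number of epochs.
#' @param seed Integer seed.
#' @return Integer vector of length `n_visits * epochs` (1-based visit
#'   indices, epoch blocks concatenated).
#' @export
visit_schedule <- function(n_visits, epochs, seed) {
  cpp_visit_schedule(as.integer(n_visits), as.integer(epochs), as.integer(seed))
}

#' Emitted (target, context) stream of a training run
#'
#' Replays the exact pair stream a training run with configuration
#' `cfg` processes: visits in the order of [visit_schedule()], and
#' within each visit the mode's pair enumeration.  Useful for auditing
#' the objective a run optimizes.
#'
#' @param visits Indexed visits from [index_visits()].
#' @param cfg A [training_config()].
#' @return Integer matrix with columns `target`, `context`.
#' @export
emit_training_pairs <- function(visits, cfg = training_config()) {
  sched <- visit_schedule(length(visits), cfg$epochs, cfg$seed)
  mode <- cfg$mode
  rows <- lapply(sched, function(v) {
    vis <- visits[[v]]
    p <- NULL
    if (mode %in% c("joint", "codes_only")) {
      if (mode == "codes_only") vis_c <- modifyList(vis, list(words = integer(0)))
      else vis_c <- vis
      p <- rbind(p, code_target_contexts(vis_c))
    }
    if (mode %in% c("joint", "words_only")) {
      if (mode == "words_only") vis_w <- modifyList(vis, list(codes = integer(0)))
      else vis_w <- vis
      p <- rbind(p, word_target_contexts(vis_w, cfg$window))
    }
    p
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_pairs())
  do.call(rbind, rows)
}
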