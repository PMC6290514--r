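#' Negative-sampling noise distribution
#'
#' Normalized sampling weights over one token namespace, obtained by
#' raising the marginal (unigram) counts to `power` and normalizing.
#' `power = 1` is the marginal distribution itself; the default 0.75
#' is the usual skip-gram smoothing that lifts rare tokens.
#'
#' @param counts Named nonnegative counts for one namespace (all
#'   words, or all codes).
#' @param power Exponent in (0, 1].
#' @return Object of class `jsg_noise` with `tokens` and `probs`
#'   (summing to 1).
#' @export
build_noise_distribution <- function(counts, power = 0.75) {
  if (!length(counts)) stop("empty counts: cannot build a noise distribution")
  if (any(counts <= 0)) stop("all counts must be positive")
  w <- as.numeric(counts)^power
  structure(list(tokens = names(counts), probs = w / sum(w)),
            class = "jsg_noise")
}
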