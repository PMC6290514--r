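#' Cosine similarity
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

resolve_token <- function(model, token) {
  tokens <- model$vocab$tokens
  id <- match(token, tokens)
  if (is.na(id)) id <- match(paste0(CODE_PREFIX, token), tokens)
  if (is.na(id)) {
    codes <- strip_code_prefix(tokens[is_code_token(tokens)])
    if (length(codes)) {
      d <- utils::adist(token, codes)[1, ]
      near <- codes[order(d, codes, method = "radix")][seq_len(min(5, length(codes)))]
      stop("unknown token '", token, "'; nearest known codes: ",
           paste(near, collapse = ", "))
    }
    stop("unknown token '", token, "'")
  }
  id
}

#' Nearest neighbors of a token in the embedding space
#'
#' Ranks candidate tokens by cosine similarity between rows of the
#' input matrix `V` (the representation used for all queries; `U` is
#' kept only to resume training).  The query itself is excluded; ties
#' break lexicographically on the token string.
#'
#' @param model A `jsg_model`.
#' @param token Query token: a word, or a (grouped) ICD-9 code with or
#'   without its namespace prefix.
#' @param k Number of neighbors (capped at the candidate count).
#' @param namespace Restrict candidates to `"words"`, `"codes"`, or
#'   `"both"`.
#' @return A data.frame with columns `token` (prefix stripped),
#'   `similarity` (non-increasing), and attribute `query`.
#' @export
nearest_neighbors <- function(model, token, k = 15L,
                              namespace = c("both", "words", "codes")) {
  namespace <- match.arg(namespace)
  id <- resolve_token(model, token)
  q <- model$V[id, ]
  if (all(q == 0)) stop("query token has a zero vector")
  code <- is_code_token(model$vocab$tokens)
  cand <- switch(namespace,
                 words = which(!code),
                 codes = which(code),
                 both = seq_along(model$vocab$tokens))
  cand <- setdiff(cand, id)
  M <- model$V[cand, , drop = FALSE]
  norms <- sqrt(rowSums(M^2))
  ok <- norms > 0
  cand <- cand[ok]; M <- M[ok, , drop = FALSE]; norms <- norms[ok]
  sims <- as.numeric(M %*% q) / (norms * sqrt(sum(q^2)))
  disp <- strip_code_prefix(model$vocab$tokens[cand])
  ord <- order(-sims, disp, method = "radix")
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(token = disp[keep], similarity = sims[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "query") <- strip_code_prefix(model$vocab$tokens[id])
  out
}

#' Nearest words to a diagnosis code (text-based phenotype)
#'
#' Retrieves the `k` words closest to a diagnosis code in the joint
#' space; the ranked word list serves as a textual description of the
#' condition the code denotes.
#'
#' @param model A `jsg_model` trained in joint mode.
#' @param code A grouped ICD-9 code (e.g. `"570"`), with or without
#'   the namespace prefix.
#' @param k Number of words to retrieve.
#' @return A data.frame of `token`, `similarity` (see
#'   [nearest_neighbors()]).
#' @export
nearest_words_to_code <- function(model, code, k = 15L) {
  id <- resolve_token(model, code)
  if (!is_code_token(model$vocab$tokens[id]))
    stop("'", code, "' resolves to a word, not a code")
  nearest_neighbors(model, code, k, namespace = "words")
}
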