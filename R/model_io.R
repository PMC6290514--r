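#' Save a trained model to a directory
#'
#' Writes `V.txt` and `U.txt` in the word2vec text format (header
#' `"n_tokens dim"`, then one line per token: token followed by its
#' vector, space-separated), `vocab.tsv` (token, id, count), and a
#' JSON snapshot of the training configuration.  Code tokens keep
#' their namespace prefix in the files so they can never collide with
#' words.
#'
#' @param model A `jsg_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_w2v(model$V, model$vocab$tokens, file.path(dir, "V.txt"))
  write_w2v(model$U, model$vocab$tokens, file.path(dir, "U.txt"))
  write_vocabulary(model$vocab, file.path(dir, "vocab.tsv"))
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

write_w2v <- function(M, tokens, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(M), ncol(M)), con)
  body <- vapply(seq_len(nrow(M)), function(i)
    paste(tokens[i], paste(formatC(M[i, ], format = "g", digits = 9), collapse = " ")),
    character(1))
  writeLines(body, con)
}

read_w2v <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("format error: empty embedding file ", path)
  hdr <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr))))
    stop("format error: malformed header in ", path)
  n <- as.integer(hdr[[1]]); d <- as.integer(hdr[[2]])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop("format error: header announces ", n, " rows but file has ", length(body))
  parts <- strsplit(body, "[[:space:]]+")
  len <- lengths(parts)
  if (any(len != d + 1))
    stop("format error: row ", which(len != d + 1)[1], " has ",
         len[which(len != d + 1)[1]] - 1, " values, expected ", d)
  tokens <- vapply(parts, `[[`, character(1), 1)
  M <- matrix(as.numeric(unlist(lapply(parts, `[`, -1), use.names = FALSE)),
              nrow = n, ncol = d, byrow = TRUE)
  if (anyNA(M)) stop("format error: non-numeric vector entry in ", path)
  rownames(M) <- tokens
  M
}

#' Load a model saved by [save_model()]
#'
#' `V.txt` is required; `U.txt` and `vocab.tsv` are used when present
#' (a file written by any word2vec text-format writer with namespaced
#' code tokens loads too, with counts unknown).  If word and code rows
#' are interleaved they are reordered into the words-then-codes block
#' layout, preserving relative order.
#'
#' @param dir Model directory.
#' @return A `jsg_model`.
#' @export
load_model <- function(dir) {
  vpath <- file.path(dir, "V.txt")
  if (!file.exists(vpath)) stop("model file not found: ", vpath)
  V <- read_w2v(vpath)
  U <- if (file.exists(file.path(dir, "U.txt"))) read_w2v(file.path(dir, "U.txt")) else NULL
  tokens <- rownames(V)
  code <- is_code_token(tokens)
  ord <- order(code, method = "radix") # stable: words first, original order kept
  V <- V[ord, , drop = FALSE]
  if (!is.null(U)) {
    if (!identical(rownames(U), tokens))
      stop("format error: V.txt and U.txt token sets differ")
    U <- U[ord, , drop = FALSE]
  } else {
    U <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  }
  vpathv <- file.path(dir, "vocab.tsv")
  if (file.exists(vpathv)) {
    vocab <- read_vocabulary(vpathv)
    if (!identical(vocab$tokens, rownames(V)))
      stop("format error: vocab.tsv does not match V.txt tokens")
  } else {
    vocab <- structure(list(tokens = rownames(V),
                            counts = rep(NA_integer_, nrow(V)),
                            n_words = sum(!code), n_codes = sum(code)),
                       class = "jsg_vocab")
  }
  cfgpath <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfgpath)) jsonlite::read_json(cfgpath, simplifyVector = TRUE) else list(mode = "unknown")
  new_model(V, U, vocab, cfg)
}
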