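#' @importFrom jsonlite fromJSON toJSON
NULL

CODE_PREFIX <- "ICD9:"
BOUNDARY <- 0L # note-boundary sentinel id in indexed word sequences

#' Preprocessing configuration
#'
#' Settings controlling note tokenization, ICD-9 grouping and
#' vocabulary frequency filtering.  Words occurring fewer than
#' `min_word_count` times (default 50) and codes occurring fewer than
#' `min_code_count` times (default 5) across the corpus are removed.
#' Codes are grouped by their first three characters when
#' `group_codes` is `TRUE`, so e.g. "2901", "2902" and "2903" all
#' collapse to "290".
#'
#' @param min_word_count Minimum corpus frequency for a word to be
#'   kept (inclusive).
#' @param min_code_count Minimum corpus frequency for a code to be
#'   kept (inclusive).
#' @param group_codes Group ICD-9 codes by their first three
#'   characters before counting.
#' @param dictionary_words Optional character vector of admissible
#'   words; tokens outside it are dropped (the standard-vocabulary
#'   regime used for phenotype discovery).  `NULL` keeps every
#'   surviving token, which also admits nonstandard clinical terms
#'   such as drug names (the treatment-discovery regime).
#' @param stopword_list Character vector of stopwords to drop;
#'   defaults to the English list shipped with the package.
#' @param lowercase Lowercase note text before tokenizing.
#' @return A list of class `jsg_preprocess_config`.
#' @export
preprocess_config <- function(min_word_count = 50L, min_code_count = 5L,
                              group_codes = TRUE, dictionary_words = NULL,
                              stopword_list = default_stopwords(),
                              lowercase = TRUE) {
  stopifnot(min_word_count >= 1, min_code_count >= 1)
  structure(list(min_word_count = as.integer(min_word_count),
                 min_code_count = as.integer(min_code_count),
                 group_codes = isTRUE(group_codes),
                 dictionary_words = dictionary_words,
                 stopword_list = stopword_list,
                 lowercase = isTRUE(lowercase)),
            class = "jsg_preprocess_config")
}

#' Default English stopword list
#'
#' The Snowball English stopword list shipped with the package, used
#' by [tokenize_note()] unless another list is supplied.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "jointsg")
  if (!nzchar(path)) stop("bundled stopword list not found")
  readLines(path, encoding = "UTF-8")
}

#' Read visits from a JSON-lines file
#'
#' Each line holds one visit object with fields `patient_id`,
#' `visit_id`, `admit_time`, `codes` (array of ICD-9 strings) and
#' `notes` (array of note texts, or arrays of tokens when the record
#' carries `"tokenized": true`).
#'
#' @param path Path to a JSON-lines file.
#' @return List of visit records in file order; raw code strings and
#'   note texts are returned untouched.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) stop("visit file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  required <- c("patient_id", "visit_id", "admit_time", "codes", "notes")
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(fromJSON(lines[[i]], simplifyVector = TRUE, simplifyDataFrame = FALSE),
                    error = function(e) stop("parse error at line ", i, ": ", conditionMessage(e), call. = FALSE))
    missing <- setdiff(required, names(rec))
    if (length(missing))
      stop("schema error at line ", i, ": missing field '", missing[[1]], "'", call. = FALSE)
    tokenized <- isTRUE(rec$tokenized)
    notes <- rec$notes
    if (tokenized) {
      if (!is.list(notes)) notes <- list(as.character(notes))
      notes <- lapply(notes, as.character)
    } else {
      notes <- as.character(unlist(notes))
    }
    list(patient_id = as.character(rec$patient_id),
         visit_id = as.character(rec$visit_id),
         admit_time = as.character(rec$admit_time),
         codes = as.character(unlist(rec$codes)),
         notes = notes,
         tokenized = tokenized)
  })
}

#' Write visits to a JSON-lines file
#'
#' @param visits List of visit records as produced by [read_visits()],
#'   [generate_corpus()] or [preprocess_visits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (v in visits) {
    rec <- list(patient_id = v$patient_id, visit_id = v$visit_id,
                admit_time = v$admit_time, codes = as.list(as.character(v$codes)))
    if (isTRUE(v$tokenized)) {
      rec$notes <- lapply(v$notes, as.list)
      rec$tokenized <- TRUE
    } else {
      rec$notes <- as.list(as.character(v$notes))
    }
    writeLines(toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Tokenize a clinical note
#'
#' Splits on any non-alphanumeric character, lowercases (per config),
#' drops every token containing a digit, drops stopwords, and, when a
#' dictionary word list is configured, drops tokens absent from it.
#'
#' @param raw_text A single note as a string.
#' @param cfg A [preprocess_config()].
#' @return Character vector of surviving tokens in note order (may be
#'   empty).
#' @export
tokenize_note <- function(raw_text, cfg = preprocess_config()) {
  if (is.na(raw_text) || !nzchar(raw_text)) return(character(0))
  if (cfg$lowercase) raw_text <- tolower(raw_text)
  toks <- strsplit(raw_text, "[^A-Za-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("[0-9]", toks)]
  toks <- toks[!toks %in% cfg$stopword_list]
  if (!is.null(cfg$dictionary_words)) toks <- toks[toks %in% cfg$dictionary_words]
  toks
}

#' Group an ICD-9 code by its first three characters
#'
#' Strips whitespace and dots, truncates to three characters, and
#' attaches the internal code namespace prefix so a code string can
#' never collide with a word string.  V and E codes follow the same
#' uniform rule (e.g. "V3000" becomes "V30").
#'
#' @param code Raw ICD-9 code string(s).
#' @return Grouped, namespaced code token(s).
#' @export
group_icd9 <- function(code) {
  stopifnot(length(code) >= 1, all(nzchar(code)))
  # idempotent: an already namespaced grouped token passes through
  code <- sub(paste0("^", CODE_PREFIX), "", code)
  clean <- gsub("[[:space:].]", "", code)
  short <- nchar(clean) < 3
  if (any(short))
    warning("code(s) shorter than 3 characters kept whole: ",
            paste(unique(clean[short]), collapse = ", "))
  out <- ifelse(short, clean, substr(clean, 1L, 3L))
  paste0(CODE_PREFIX, out)
}

strip_code_prefix <- function(tokens) sub(paste0("^", CODE_PREFIX), "", tokens)
is_code_token <- function(tokens) startsWith(tokens, CODE_PREFIX)

#' Tokenize notes and group codes for a whole corpus
#'
#' Applies [tokenize_note()] to every note (already-tokenized records
#' are passed through) and [group_icd9()] to every code, deduplicating
#' each visit's code set.
#'
#' @param visits List of visit records from [read_visits()].
#' @param cfg A [preprocess_config()].
#' @return Visits with `notes` as lists of token vectors
#'   (`tokenized = TRUE`) and namespaced grouped codes.
#' @export
preprocess_visits <- function(visits, cfg = preprocess_config()) {
  lapply(visits, function(v) {
    if (isTRUE(v$tokenized)) notes <- v$notes
    else notes <- lapply(as.character(v$notes), tokenize_note, cfg = cfg)
    codes <- as.character(v$codes)
    codes <- codes[nzchar(codes)]
    if (length(codes)) {
      codes <- if (cfg$group_codes) group_icd9(codes)
               else paste0(CODE_PREFIX, sub(paste0("^", CODE_PREFIX), "", codes))
      codes <- unique(codes)
    }
    list(patient_id = v$patient_id, visit_id = v$visit_id,
         admit_time = v$admit_time, codes = codes, notes = notes,
         tokenized = TRUE)
  })
}

#' Build the word and code vocabulary
#'
#' Counts token occurrences over the whole corpus (each visit's code
#' set counts each code once; words count with multiplicity), drops
#' tokens below the frequency thresholds, and assigns integer ids
#' deterministically: words first, then codes, each block ordered by
#' descending count with lexicographic tie-break.
#'
#' @param visits Tokenized visits from [preprocess_visits()].
#' @param cfg A [preprocess_config()].
#' @return An object of class `jsg_vocab` with fields `tokens`,
#'   `counts`, `n_words`, `n_codes`.  Word ids are `1..n_words`, code
#'   ids `n_words+1 .. n_words+n_codes`.
#' @export
build_vocabulary <- function(visits, cfg = preprocess_config()) {
  words <- unlist(lapply(visits, function(v) unlist(v$notes, use.names = FALSE)),
                  use.names = FALSE)
  codes <- unlist(lapply(visits, function(v) unique(as.character(v$codes))),
                  use.names = FALSE)
  wc <- table_counts(words)
  cc <- table_counts(codes)
  wc <- wc[wc >= cfg$min_word_count]
  cc <- cc[cc >= cfg$min_code_count]
  if (length(wc) + length(cc) == 0)
    stop("configuration error: no token survives the frequency thresholds")
  wc <- wc[order(-wc, names(wc), method = "radix")]
  cc <- cc[order(-cc, names(cc), method = "radix")]
  structure(list(tokens = c(names(wc), names(cc)),
                 counts = as.integer(c(wc, cc)),
                 n_words = length(wc), n_codes = length(cc)),
            class = "jsg_vocab")
}

# deterministic named count vector (C-locale name order internally)
table_counts <- function(x) {
  if (!length(x)) return(stats::setNames(integer(0), character(0)))
  t <- table(x)
  stats::setNames(as.integer(t), names(t))
}

#' @export
print.jsg_vocab <- function(x, ...) {
  cat("<jsg_vocab> ", x$n_words, " words + ", x$n_codes, " codes = ",
      length(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

vocab_id <- function(vocab, tokens) match(tokens, vocab$tokens)

#' Persist / load a vocabulary as TSV
#'
#' Tab-separated columns `token`, `id`, `count`, sorted by id, UTF-8.
#'
#' @param vocab A `jsg_vocab`.
#' @param path File path.
#' @return `write_vocabulary`: `path` invisibly; `read_vocabulary`:
#'   a `jsg_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(token = vocab$tokens, id = seq_along(vocab$tokens),
                   count = vocab$counts, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   colClasses = c("character", "integer", "integer"))
  df <- df[order(df$id), , drop = FALSE]
  code <- is_code_token(df$token)
  if (any(code) && any(!code) && min(which(code)) < max(which(!code)))
    stop("format error: word and code id blocks are interleaved")
  structure(list(tokens = df$token, counts = df$count,
                 n_words = sum(!code), n_codes = sum(code)),
            class = "jsg_vocab")
}

#' Index visits against a vocabulary
#'
#' Maps tokens to integer ids, dropping out-of-vocabulary words (order
#' preserved) and codes.  Per visit, notes are concatenated into one
#' id sequence with a boundary sentinel (`0`) between notes so that
#' context windows never span two notes.  Visits left with no codes
#' and no words are dropped.
#'
#' @param visits Tokenized visits from [preprocess_visits()].
#' @param vocab A `jsg_vocab`.
#' @return List of indexed visits, each with integer `codes` (sorted,
#'   unique, global ids) and `words` (id sequence with `0` sentinels).
#' @export
index_visits <- function(visits, vocab) {
  out <- lapply(visits, function(v) {
    note_ids <- lapply(v$notes, function(n) {
      ids <- vocab_id(vocab, n)
      ids[!is.na(ids)]
    })
    note_ids <- note_ids[vapply(note_ids, length, 1L) > 0]
    words <- if (length(note_ids)) {
      sep <- lapply(note_ids, function(x) c(x, BOUNDARY))
      w <- unlist(sep, use.names = FALSE)
      w[-length(w)] # no trailing sentinel
    } else integer(0)
    codes <- vocab_id(vocab, as.character(v$codes))
    codes <- sort(unique(codes[!is.na(codes)]))
    list(patient_id = v$patient_id, visit_id = v$visit_id,
         admit_time = v$admit_time, codes = as.integer(codes),
         words = as.integer(words))
  })
  keep <- vapply(out, function(v) length(v$codes) > 0 || length(v$words) > 0, TRUE)
  out[keep]
}
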