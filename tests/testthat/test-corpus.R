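test_that("tokenize_note lowercases, drops digit tokens, stopwords and dictionary misses", {
  cfg <- preprocess_config(stopword_list = c("to", "the"))
  expect_equal(tokenize_note("Gave 40mg lasix to the patient", cfg),
               c("gave", "lasix", "patient"))
  expect_equal(tokenize_note("", cfg), character(0))
  expect_equal(tokenize_note("THE the The", cfg), character(0))
  # dictionary filtering keeps only listed words
  cfg_dict <- preprocess_config(stopword_list = character(0),
                                dictionary_words = c("liver", "failure"))
  expect_equal(tokenize_note("acute liver failure hepatorenal", cfg_dict),
               c("liver", "failure"))
  # punctuation splits; digits inside a token kill the whole token
  expect_equal(tokenize_note("x-ray q4h, stable.", preprocess_config(stopword_list = character(0))),
               c("x", "ray", "stable"))
})

test_that("group_icd9 truncates to three characters with a namespace prefix", {
  expect_equal(group_icd9("2901"), "ICD9:290")
  expect_equal(group_icd9("570"), "ICD9:570")
  expect_equal(group_icd9("V3000"), paste0("ICD9:", substr("V3000", 1, 3)))
  expect_equal(group_icd9("E8790"), "ICD9:E87")
  expect_equal(group_icd9("290.1"), "ICD9:290") # dots stripped first
  expect_warning(out <- group_icd9("V3"), "shorter than 3")
  expect_equal(out, "ICD9:V3")
})

test_that("group_icd9 is idempotent on arbitrary codes", {
  set.seed(5)
  codes <- c(replicate(25, paste0(sample(c(LETTERS[1:5], 0:9), sample(3:5, 1),
                                         replace = TRUE), collapse = "")),
             "2901", "V3000", "E8790")
  once <- group_icd9(codes)
  expect_identical(group_icd9(once), once)
})

test_that("read_visits parses JSON-lines and reports malformed input precisely", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  lines <- c(
    '{"patient_id":"p1","visit_id":"v1","admit_time":"2010-01-01T00:00:00","codes":["2901"],"notes":["liver failure"]}',
    '{"patient_id":"p1","visit_id":"v2","admit_time":"2010-02-01T00:00:00","codes":[],"notes":["better now"]}',
    '{"patient_id":"p2","visit_id":"v3","admit_time":"2010-01-15T00:00:00","codes":["570","5712"],"notes":[]}')
  writeLines(lines, path)
  vs <- read_visits(path)
  expect_length(vs, 3)
  expect_equal(vs[[1]]$codes, "2901")
  expect_equal(vs[[3]]$codes, c("570", "5712"))
  expect_equal(vs[[1]]$notes, "liver failure")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_length(read_visits(empty), 0)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(lines[1], '{"patient_id":"p3","visit_id":"v4","admit_time":"t","notes":[]}'), bad)
  expect_error(read_visits(bad), "schema error at line 2.*codes")

  mangled <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(lines[1], "{not json"), mangled)
  expect_error(read_visits(mangled), "parse error at line 2")
})

test_that("visit round trip through write_visits preserves content", {
  vs <- list(raw_visit("p1", "v1", "2010-01-01T00:00:00", c("2901", "570"),
                       "liver failure today"),
             raw_visit("p2", "v2", "2010-02-01T00:00:00", character(0),
                       c("note one", "note two")))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_visits(vs, path)
  back <- read_visits(path)
  expect_equal(back[[1]]$codes, c("2901", "570"))
  expect_equal(back[[2]]$notes, c("note one", "note two"))
  expect_length(back[[2]]$codes, 0)
})

test_that("build_vocabulary applies inclusive-keep thresholds and deterministic ids", {
  # "liver" occurs 50 times, "hepatik" 49: the 50-threshold keeps only liver
  mk_note <- function(word, n) rep(word, n)
  visits <- list(
    list(patient_id = "p1", visit_id = "v1", admit_time = "t1",
         codes = c(rep("ICD9:290", 1)),
         notes = list(c(mk_note("liver", 50), mk_note("hepatik", 49))),
         tokenized = TRUE))
  cfg <- preprocess_config(min_word_count = 50, min_code_count = 1)
  vocab <- build_vocabulary(visits, cfg)
  expect_true("liver" %in% vocab$tokens)
  expect_false("hepatik" %in% vocab$tokens)

  # codes count once per visit; {290: 5 visits, 291: 4 visits}, threshold 5
  visits2 <- c(
    lapply(1:5, function(i) list(patient_id = "p", visit_id = paste0("a", i),
                                 admit_time = "t", codes = "ICD9:290",
                                 notes = list("x"), tokenized = TRUE)),
    lapply(1:4, function(i) list(patient_id = "p", visit_id = paste0("b", i),
                                 admit_time = "t", codes = "ICD9:291",
                                 notes = list("x"), tokenized = TRUE)))
  v2 <- build_vocabulary(visits2, preprocess_config(min_word_count = 1, min_code_count = 5))
  codes <- v2$tokens[v2$n_words + seq_len(v2$n_codes)]
  expect_equal(codes, "ICD9:290")

  # determinism: byte-identical across runs; order desc count then lexicographic
  v2b <- build_vocabulary(visits2, preprocess_config(min_word_count = 1, min_code_count = 5))
  expect_identical(v2, v2b)

  visits3 <- list(list(patient_id = "p", visit_id = "v", admit_time = "t",
                       codes = character(0),
                       notes = list(c(rep("beta", 3), rep("alpha", 3), rep("gamma", 5))),
                       tokenized = TRUE))
  v3 <- build_vocabulary(visits3, preprocess_config(min_word_count = 1, min_code_count = 1))
  expect_equal(v3$tokens, c("gamma", "alpha", "beta"))

  expect_error(build_vocabulary(visits3, preprocess_config(min_word_count = 100,
                                                           min_code_count = 100)),
               "configuration error")
})

test_that("kept vocabulary counts conserve corpus token occurrences", {
  corpus <- generate_corpus(synth_config(n_patients = 20, note_length = 15, seed = 3))
  pcfg <- preprocess_config(min_word_count = 3, min_code_count = 2)
  pv <- preprocess_visits(corpus$visits, pcfg)
  vocab <- build_vocabulary(pv, pcfg)
  all_words <- unlist(lapply(pv, function(v) unlist(v$notes)))
  kept <- vocab$tokens[seq_len(vocab$n_words)]
  expect_equal(sum(vocab$counts[seq_len(vocab$n_words)]),
               sum(all_words %in% kept))
  expect_true(all(vocab$counts[seq_len(vocab$n_words)] >= 3))
  expect_true(all(vocab$counts[vocab$n_words + seq_len(vocab$n_codes)] >= 2))
})

test_that("index_visits filters OOV tokens, inserts note boundaries, drops empty visits", {
  vocab <- toy_vocab(3, 2) # words w01..w03 ids 1..3, codes ids 4..5
  visits <- list(
    list(patient_id = "p", visit_id = "v1", admit_time = "t",
         codes = "ICD9:100", notes = list(c("w01", "zzz", "w01")), tokenized = TRUE),
    list(patient_id = "p", visit_id = "v2", admit_time = "t",
         codes = "ICD9:999", notes = list("w02"), tokenized = TRUE),
    list(patient_id = "p", visit_id = "v3", admit_time = "t",
         codes = "ICD9:999", notes = list("zzz"), tokenized = TRUE),
    list(patient_id = "p", visit_id = "v4", admit_time = "t",
         codes = c("ICD9:101", "ICD9:100"), notes = list(c("w01", "w02"), "w03"),
         tokenized = TRUE))
  iv <- index_visits(visits, vocab)
  expect_length(iv, 3) # v3 dropped: no codes, no words survive
  expect_equal(iv[[1]]$words, c(1L, 1L)) # order-preserving OOV removal
  expect_equal(iv[[2]]$codes, integer(0)) # OOV code removed, visit kept
  expect_equal(iv[[2]]$words, 2L)
  expect_equal(iv[[3]]$words, c(1L, 2L, 0L, 3L)) # boundary sentinel between notes
  expect_equal(iv[[3]]$codes, c(4L, 5L)) # sorted ids
})

test_that("vocabulary TSV round trip is exact", {
  vocab <- toy_vocab(4, 3, word_counts = c(40L, 30L, 20L, 10L),
                     code_counts = c(9L, 8L, 7L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_identical(back$tokens, vocab$tokens)
  expect_identical(back$counts, vocab$counts)
  expect_identical(back$n_words, vocab$n_words)
  expect_identical(back$n_codes, vocab$n_codes)
})

test_that("preprocessing is a pure function of corpus and config", {
  corpus <- generate_corpus(synth_config(n_patients = 15, seed = 9))
  pcfg <- preprocess_config(min_word_count = 2, min_code_count = 1)
  run <- function() {
    pv <- preprocess_visits(corpus$visits, pcfg)
    vocab <- build_vocabulary(pv, pcfg)
    list(vocab = vocab, iv = index_visits(pv, vocab))
  }
  expect_identical(run(), run())
})
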