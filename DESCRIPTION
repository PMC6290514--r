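Package: jointsg
Title: Joint Embedding of Diagnosis Codes and Clinical Note Words
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns low-dimensional vector representations of ICD-9
    diagnosis codes and clinical note words in a single vector space
    using a joint skip-gram model trained by stochastic gradient ascent
    with negative sampling. Each hospital visit contributes a code set
    and a note word sequence; codes use all co-visit codes and note
    words as context, words use a sliding window plus all co-visit
    codes. Includes corpus preprocessing (tokenization, frequency
    filtering, ICD-9 three-character grouping), cosine-similarity
    queries for text-based phenotype and treatment discovery, a softmax
    next-visit diagnosis predictor evaluated by top-k recall, and a
    synthetic EHR corpus generator with known latent topic structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
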