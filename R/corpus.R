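#' Benchmark corpus generator configuration
#'
#' Controls the seeded synthetic corpus: one synthetic address per
#' document, mutated by `mutator` and wrapped in lorem-ipsum filler. The
#' defaults emulate the reference benchmark setup: 1000 documents whose
#' addresses carry 7-10 tokens (mean about 8.5, i.e. roughly 8500 gold
#' address tokens per 1000 documents) inside 3-8 filler sentences.
#'
#' @param n_docs Number of documents.
#' @param tokens_per_address Integer range `c(min, max)` of address length
#'   in tokens; must lie within `[3, 15]`.
#' @param filler_sentences Integer range `c(min, max)` of surrounding
#'   filler sentences.
#' @param mutator A [mutator_spec()] applied to each address before
#'   embedding. A per-spec seed is ignored here: the corpus seed drives a
#'   single RNG stream so that mutations stay independent across documents.
#' @param seed Integer seed; identical configuration implies an identical
#'   corpus.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_docs = 1000L,
                             tokens_per_address = c(7L, 10L),
                             filler_sentences = c(3L, 8L),
                             mutator = mutator_spec("none"),
                             seed = 42L) {
  stopifnot(n_docs >= 1L,
            length(tokens_per_address) == 2L,
            tokens_per_address[1] >= 3L, tokens_per_address[2] <= 15L,
            tokens_per_address[1] <= tokens_per_address[2],
            length(filler_sentences) == 2L, filler_sentences[1] >= 0L,
            filler_sentences[1] <= filler_sentences[2],
            inherits(mutator, "mutator_spec"))
  mutator$seed <- NULL
  structure(
    list(n_docs = as.integer(n_docs),
         tokens_per_address = as.integer(tokens_per_address),
         filler_sentences = as.integer(filler_sentences),
         mutator = mutator, seed = as.integer(seed)),
    class = "generator_config"
  )
}

random_postcode <- function() {
  # UK-style outward/inward token pair, e.g. "SE5" "8AF"
  lt <- function(n) paste(sample(LETTERS, n, replace = TRUE), collapse = "")
  dg <- function() as.character(sample.int(9L, 1L))
  c(paste0(lt(2L), dg()), paste0(dg(), lt(2L)))
}

#' Generate one synthetic PHI address record
#'
#' Draws an address from a fixed grammar emulating UK-style postal
#' addresses: house number (1-999), one or two street-name words, a
#' thoroughfare type, a district word, a town word, zero to two region
#' words, and a two-token postcode. Words come from bundled synthetic
#' wordlists; the thoroughfare list mixes abbreviable types (Street, Road,
#' ...) with non-abbreviable ones (Way, Close, ...).
#'
#' Uses the current RNG state (see [generate_corpus()] for the seeded
#' entry point).
#'
#' @param record_id Identifier for the record.
#' @param config A [generator_config()]; its `tokens_per_address` range is
#'   enforced by rejection sampling over the grammar's random arities.
#' @return A [phi_record()].
#' @export
generate_address <- function(record_id = "r1", config = generator_config()) {
  rng_tokens <- function() {
    n_name <- sample.int(2L, 1L)
    n_region <- sample(0:2, 1L)
    c(as.character(sample.int(999L, 1L)),
      sample(read_wordlist("street_words.txt"), n_name),
      sample(read_wordlist("thoroughfares.txt"), 1L),
      sample(read_wordlist("locality_words.txt"), 2L),
      if (n_region > 0L) sample(read_wordlist("region_words.txt"), n_region),
      random_postcode())
  }
  rng <- config$tokens_per_address
  for (i in 1:100) {
    toks <- rng_tokens()
    if (length(toks) >= rng[1] && length(toks) <= rng[2]) break
  }
  phi_record(record_id, toks)
}

filler_sentence_vec <- function(n_sentences) {
  lex <- read_wordlist("filler_lexicon.txt")
  vapply(seq_len(n_sentences), function(i) {
    words <- sample(lex, sample(5:12, 1L), replace = TRUE)
    words[1] <- paste0(toupper(substr(words[1], 1, 1)), substring(words[1], 2))
    paste0(paste(words, collapse = " "), ".")
  }, character(1))
}

#' Generate lorem-ipsum filler text
#'
#' Pseudo-Latin sentences of 5-12 words from a fixed bundled lexicon
#' (no digits), capitalized and period-terminated, simulating the non-PHI
#' narrative surrounding an address.
#'
#' @param n_sentences Number of sentences (0 gives empty text).
#' @return A single string.
#' @export
generate_filler <- function(n_sentences) {
  stopifnot(n_sentences >= 0L)
  if (n_sentences == 0L) return("")
  paste(filler_sentence_vec(n_sentences), collapse = " ")
}

#' Build one benchmark document from a PHI record
#'
#' Applies the configured mutator to the address tokens, embeds the mutated
#' tokens (space-joined, period-terminated) at a random sentence boundary
#' of freshly generated filler, and records one gold annotation per
#' surviving mutated token with its exact character offsets. The document
#' links to the original, unmutated record: the masker only ever sees the
#' clean queries.
#'
#' @param phi A [phi_record()] with the clean address.
#' @param config A [generator_config()].
#' @param doc_id Identifier for the document.
#' @return A [document()] with gold annotations.
#' @export
build_document <- function(phi, config = generator_config(), doc_id = "d1") {
  stopifnot(inherits(phi, "phi_record"))
  mutated <- apply_mutator(phi$address_tokens, config$mutator)
  source_idx <- as.integer(names(mutated))
  n_sent <- sample(config$filler_sentences[1]:config$filler_sentences[2], 1L)
  sentences <- filler_sentence_vec(n_sent)
  k <- sample(0:n_sent, 1L)

  addr_str <- paste(mutated, collapse = " ")
  pre <- paste(sentences[seq_len(k)], collapse = " ")
  post <- paste(sentences[seq_len(n_sent) > k], collapse = " ")
  parts <- c(if (nzchar(pre)) pre, paste0(addr_str, "."),
             if (nzchar(post)) post)
  text <- paste(parts, collapse = " ")

  addr_start <- if (nzchar(pre)) cp_length(pre) + 1L else 0L
  lens <- cp_length(mutated)
  rel_start <- cumsum(c(0L, head(lens, -1L) + 1L))
  gold <- gold_annotations(start = addr_start + rel_start,
                           end = addr_start + rel_start + lens,
                           token = unname(mutated),
                           source_index = source_idx)
  date <- as.Date("2016-01-01") + sample(0:365, 1L)
  document(doc_id, phi$record_id, date, text, gold)
}

#' Generate a seeded benchmark corpus
#'
#' Produces `config$n_docs` documents, one synthetic address each, plus the
#' paired table of clean PHI records. Fully determined by `config$seed`;
#' because string manipulations are triggered by the random number
#' generator, the total number of gold PHI tokens varies between seeds but
#' is identical for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A list with elements `documents` (list of [document()]) and
#'   `phi_records` (list of [phi_record()]).
#' @examples
#' corp <- generate_corpus(generator_config(n_docs = 3, seed = 1))
#' corp$documents[[1]]
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  width <- max(4L, nchar(as.character(config$n_docs)))
  docs <- vector("list", config$n_docs)
  phis <- vector("list", config$n_docs)
  for (i in seq_len(config$n_docs)) {
    rid <- sprintf("r%0*d", width, i)
    phi <- generate_address(rid, config)
    phis[[i]] <- phi
    docs[[i]] <- build_document(phi, config, doc_id = sprintf("d%0*d", width, i))
  }
  list(documents = docs, phi_records = phis)
}
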