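#' Mutation model specification
#'
#' Describes which string-mutation model is applied to address tokens
#' before they are embedded in a benchmark document, emulating real-world
#' divergence between an administrative record and its appearance in text.
#'
#' Models:
#' * `keyboard` - per-character typographic substitution with a QWERTY
#'   physical-neighbour confusion set (`char_rate`).
#' * `alias` - swap full address tokens with their common abbreviations and
#'   vice versa (`token_rate`).
#' * `truncate` - drop tokens from the end of the address down to
#'   `min_tokens` (`token_rate`).
#' * `ocr` - keyboard substitution at `char_rate` plus interior whitespace
#'   insertion at `ws_rate`, mimicking poor-quality OCR.
#' * `none` - identity.
#'
#' @param kind One of `"keyboard"`, `"alias"`, `"truncate"`, `"ocr"`,
#'   `"none"`.
#' @param char_rate Per-character substitution probability.
#' @param ws_rate Per-gap whitespace-insertion probability (OCR only).
#' @param token_rate Per-token application probability (alias, truncate).
#' @param min_tokens Minimum address length kept by truncation.
#' @param seed Optional integer; when set, [apply_mutator()] seeds the RNG
#'   so identical spec + input give identical output.
#' @return An object of class `mutator_spec`.
#' @export
mutator_spec <- function(kind = c("none", "keyboard", "alias", "truncate", "ocr"),
                         char_rate = 0, ws_rate = 0, token_rate = 1,
                         min_tokens = 3L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(char_rate >= 0, char_rate <= 1, ws_rate >= 0, ws_rate <= 1,
            token_rate >= 0, token_rate <= 1, min_tokens >= 1L)
  structure(
    list(kind = kind, char_rate = char_rate, ws_rate = ws_rate,
         token_rate = token_rate, min_tokens = as.integer(min_tokens),
         seed = seed),
    class = "mutator_spec"
  )
}

#' QWERTY physical-adjacency map
#'
#' Named list mapping each lower-case alphanumeric key to the vector of its
#' physically adjacent alphanumeric keys, loaded from the bundled data file
#' so alternative confusion priors can be swapped in.
#'
#' @return A named list of character vectors.
#' @export
qwerty_neighbors <- function() {
  if (is.null(.phimask_cache$qwerty)) {
    lines <- read_wordlist("qwerty_neighbors.txt")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    keys <- vapply(parts, `[[`, character(1), 1L)
    vals <- lapply(parts, function(p) strsplit(p[[2]], "")[[1]])
    names(vals) <- keys
    .phimask_cache$qwerty <- vals
  }
  .phimask_cache$qwerty
}

#' Alias dictionary for address tokens
#'
#' Involutive, case-insensitive map between full address tokens and their
#' abbreviations (Road/Rd, Street/St, ...). `alias_lookup(alias_lookup(x))`
#' returns `x` for every dictionary entry.
#'
#' @return A named character vector keyed by lower-cased token, with the
#'   canonical counterpart as value.
#' @export
alias_dictionary <- function() {
  if (is.null(.phimask_cache$alias)) {
    lines <- read_wordlist("alias_dictionary.txt")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    full <- vapply(parts, `[[`, character(1), 1L)
    abbr <- vapply(parts, `[[`, character(1), 2L)
    dict <- c(abbr, full)
    names(dict) <- tolower(c(full, abbr))
    .phimask_cache$alias <- dict
  }
  .phimask_cache$alias
}

#' Look up the alias counterpart of a token
#'
#' @param token A single token.
#' @param dict Dictionary from [alias_dictionary()].
#' @return The canonical counterpart, or `NA_character_` when the token has
#'   no dictionary entry.
#' @export
alias_lookup <- function(token, dict = alias_dictionary()) {
  out <- dict[tolower(token)]
  unname(out)
}

#' Keyboard-typo mutator
#'
#' Each alphanumeric character is independently replaced, with probability
#' `rate`, by a key drawn uniformly from its QWERTY physical-adjacency set;
#' case is preserved and non-alphanumerics are left untouched, so token
#' length and tokenization never change.
#'
#' Uses the current RNG state; seed via [set.seed()] or [mutator_spec()]'s
#' `seed` for reproducibility.
#'
#' @param token A single token.
#' @param rate Per-character substitution probability.
#' @return The mutated token.
#' @export
mutate_keyboard <- function(token, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || !nzchar(token)) return(token)
  nb <- qwerty_neighbors()
  chars <- strsplit(token, "")[[1]]
  lower <- tolower(chars)
  eligible <- lower %in% names(nb)
  hit <- eligible & (runif(length(chars)) < rate)
  for (i in which(hit)) {
    cand <- nb[[lower[i]]]
    repl <- cand[[sample.int(length(cand), 1L)]]
    if (chars[i] %in% LETTERS || (grepl("[[:upper:]]", chars[i]))) {
      repl <- toupper(repl)
    }
    chars[i] <- repl
  }
  paste(chars, collapse = "")
}

#' Alias-substitution mutator
#'
#' Each token with a dictionary entry is replaced by its counterpart
#' (full form to abbreviation or vice versa) with probability `token_rate`;
#' all other tokens are untouched. List length is preserved.
#'
#' @param tokens Character vector of address tokens.
#' @param dict Dictionary from [alias_dictionary()].
#' @param token_rate Per-token replacement probability.
#' @return The mutated token vector.
#' @export
mutate_alias <- function(tokens, dict = alias_dictionary(), token_rate = 1) {
  stopifnot(token_rate >= 0, token_rate <= 1)
  if (length(tokens) == 0L || token_rate == 0) return(tokens)
  counterpart <- alias_lookup(tokens, dict)
  hit <- !is.na(counterpart) & (runif(length(tokens)) < token_rate)
  tokens[hit] <- counterpart[hit]
  tokens
}

#' Address-truncation mutator
#'
#' With probability `token_rate` the address is truncated from the end to
#' exactly `min(length(tokens), min_tokens)` tokens, replicating partially
#' recorded addresses (missing supplemental address lines); otherwise it is
#' returned unchanged.
#'
#' @param tokens Character vector of address tokens.
#' @param min_tokens Minimum address length kept.
#' @param token_rate Application probability.
#' @return The (possibly truncated) token vector.
#' @export
mutate_truncate <- function(tokens, min_tokens = 3L, token_rate = 1) {
  stopifnot(min_tokens >= 1L, token_rate >= 0, token_rate <= 1)
  if (token_rate > 0 && runif(1) < token_rate) {
    head(tokens, min(length(tokens), min_tokens))
  } else {
    tokens
  }
}

#' Simulated poor-OCR mutator
#'
#' First applies [mutate_keyboard()] at `char_rate`, then inserts a single
#' space after each interior character (every gap except after the last
#' character) independently with probability `ws_rate`. Output length is
#' at least the input length; stripping the inserted spaces at
#' `char_rate = 0` recovers the input.
#'
#' @param token A single token.
#' @param char_rate Per-character substitution probability.
#' @param ws_rate Per-gap whitespace-insertion probability.
#' @return The mutated token, possibly containing internal spaces.
#' @export
mutate_ocr <- function(token, char_rate, ws_rate) {
  stopifnot(ws_rate >= 0, ws_rate <= 1)
  out <- mutate_keyboard(token, char_rate)
  n <- cp_length(out)
  if (ws_rate > 0 && n >= 2L) {
    chars <- strsplit(out, "")[[1]]
    split_after <- runif(n - 1L) < ws_rate
    sep <- c(ifelse(split_after, " ", ""), "")
    out <- paste0(paste0(chars, sep), collapse = "")
  }
  out
}

#' Apply a mutation model to an address token list
#'
#' Token-list models (`alias`, `truncate`) act on the list; character
#' models (`keyboard`, `ocr`) act on each surviving token independently.
#' When `spec$seed` is set the RNG is seeded first, making the output a
#' pure function of (input, spec).
#'
#' @param tokens Character vector of clean address tokens.
#' @param spec A [mutator_spec()].
#' @return Character vector of mutated surface tokens (OCR output may
#'   contain internal spaces). For `truncate` the vector may be shorter
#'   than the input; its names give the 0-based source index of each
#'   surviving token.
#' @export
apply_mutator <- function(tokens, spec) {
  stopifnot(inherits(spec, "mutator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  out <- switch(spec$kind,
    none = tokens,
    keyboard = vapply(tokens, mutate_keyboard, character(1),
                      rate = spec$char_rate, USE.NAMES = FALSE),
    alias = mutate_alias(tokens, token_rate = spec$token_rate),
    truncate = mutate_truncate(tokens, min_tokens = spec$min_tokens,
                               token_rate = spec$token_rate),
    ocr = vapply(tokens, mutate_ocr, character(1),
                 char_rate = spec$char_rate, ws_rate = spec$ws_rate,
                 USE.NAMES = FALSE)
  )
  names(out) <- as.character(seq_along(out) - 1L)
  out
}
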