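#' De-identification configuration
#'
#' Parameters of the sliding-window masker. A PHI token of length `L` is
#' compared against every window `text[i, i + w)` for every character
#' offset `i` and every width `w` in `[max(1, L - D), L + D]` with
#' `D = ceiling(width_slack_fraction * L)`; windows with normalised
#' Levenshtein similarity at or above `theta` are masked.
#'
#' The defaults are the calibrated benchmark configuration shipped with the
#' package (calibrated once against the 3% keyboard-substitution condition;
#' see the methods vignette).
#'
#' @param theta Similarity threshold in `[0, 1]`.
#' @param width_slack_fraction Window-width tolerance in `[0, 1)`; slack
#'   `D = ceiling(width_slack_fraction * L)` windows per token length `L`.
#' @param min_token_length PHI tokens shorter than this are skipped as
#'   queries (guards against masking explosions from 1-2 character tokens).
#' @param mask_char Single masking character.
#' @param case_fold Compare case-insensitively?
#' @param whitespace_barrier When `TRUE` (default) candidate windows never
#'   span whitespace: PHI tokens contain no internal whitespace, so a
#'   window holding a space cannot be a token occurrence. Matching then
#'   happens within each whitespace-delimited run of the text, which also
#'   keeps a single match from bleeding across word boundaries.
#' @return An object of class `deid_config`.
#' @export
deid_config <- function(theta = 0.63, width_slack_fraction = 0,
                        min_token_length = 3L, mask_char = "X",
                        case_fold = TRUE, whitespace_barrier = TRUE) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1,
            is.numeric(width_slack_fraction), width_slack_fraction >= 0,
            width_slack_fraction < 1,
            min_token_length >= 1L,
            is.character(mask_char), nchar(mask_char) == 1L,
            is.logical(case_fold))
  structure(
    list(theta = theta, width_slack_fraction = width_slack_fraction,
         min_token_length = as.integer(min_token_length),
         mask_char = mask_char, case_fold = isTRUE(case_fold),
         whitespace_barrier = isTRUE(whitespace_barrier)),
    class = "deid_config"
  )
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions (unit costs) transforming `a` into `b`. Operates on
#' Unicode code points. Symmetric; `edit_distance("", x)` is `nchar(x)`.
#'
#' @param a,b Strings.
#' @return A non-negative integer.
#' @examples
#' edit_distance("Meadow", "Meagow") # 1
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  lev_distance_cpp(utf8ToInt(a), utf8ToInt(b))
}

#' Normalised Levenshtein similarity
#'
#' `1 - edit_distance(a, b) / max(nchar(a), nchar(b))`; defined as 1 when
#' both strings are empty. Equals 1 exactly when `a == b`.
#'
#' @inheritParams edit_distance
#' @return A value in `[0, 1]`.
#' @examples
#' lev_similarity("Meadow", "Meagow") # 5/6
#' @export
lev_similarity <- function(a, b) {
  mx <- max(cp_length(a), cp_length(b))
  if (mx == 0L) return(1.0)
  1 - edit_distance(a, b) / mx
}

token_widths <- function(L, slack) {
  d <- as.integer(ceiling(slack * L))
  c(wmin = max(1L, L - d), wmax = L + d)
}

#' Scan one PHI token across a document
#'
#' Slides `token` across every character offset of `text`, over window
#' widths `L` plus/minus the configured slack, and returns every window
#' whose similarity reaches `config$theta`. All qualifying windows are
#' returned; downstream masking takes their union.
#'
#' @param text Document text.
#' @param token PHI token (the caller is expected to skip tokens shorter
#'   than `config$min_token_length`).
#' @param config A [deid_config()].
#' @return A tibble with columns `start`, `end` (0-based half-open
#'   code-point offsets) and `similarity`.
#' @examples
#' scan_token("xx Meagow xx", "Meadow", deid_config(theta = 0.8))
#' @export
scan_token <- function(text, token, config = deid_config()) {
  stopifnot(inherits(config, "deid_config"))
  if (config$case_fold) {
    text <- tolower(text)
    token <- tolower(token)
  }
  L <- cp_length(token)
  w <- token_widths(L, config$width_slack_fraction)
  hits <- scan_token_cpp(utf8ToInt(text), utf8ToInt(token),
                         config$theta, w[["wmin"]], w[["wmax"]],
                         config$whitespace_barrier)
  tibble::tibble(start = as.integer(hits$start), end = as.integer(hits$end),
                 similarity = as.numeric(hits$similarity))
}

#' Version hash of a PHI record and document date
#'
#' SHA-256 over the canonical serialization `record_id`, newline, canonical
#' address string, newline, ISO-8601 date. Deterministic across runs and
#' platforms; changing the date or any identifier changes the digest, which
#' makes it usable for version control of de-identified output.
#'
#' @param phi A [phi_record()].
#' @param date Document date.
#' @return A 64-character hex digest.
#' @export
version_hash <- function(phi, date) {
  stopifnot(inherits(phi, "phi_record"))
  payload <- paste(phi$record_id, canonical_address(phi),
                   format(as.Date(date), "%Y-%m-%d"), sep = "\n")
  digest::digest(payload, algo = "sha256", serialize = FALSE)
}

# every PHI token of sufficient length, with its index in the query list
phi_query_tokens <- function(phi, min_len) {
  toks <- c(phi$address_tokens, unlist(phi$other_phis, use.names = FALSE))
  keep <- cp_length(toks) >= min_len
  list(tokens = toks[keep], index = which(keep) - 1L)
}

#' De-identify one document against its PHI record
#'
#' Runs [scan_token()] for every sufficiently long PHI token (address
#' tokens plus any `other_phis` tokens), unions all qualifying window
#' spans, and replaces every character in the union with
#' `config$mask_char`. The output text has exactly the length of the
#' input, so all downstream offsets stay valid.
#'
#' @param doc A [document()].
#' @param phi The matching [phi_record()] (`record_id`s must agree).
#' @param config A [deid_config()].
#' @return An object of class `masked_document`: a list with `doc_id`,
#'   `text` (masked), `masked_offsets` (0-based integer offsets),
#'   `spans` (tibble `start`, `end`, `similarity`, `token_index`) and
#'   `version_hash`.
#' @examples
#' doc <- document("d1", "r1", "2016-12-01", "Call 100 Meadow Street now")
#' phi <- phi_record("r1", c("100", "Meadow", "Street"))
#' deidentify(doc, phi)$text
#' @export
deidentify <- function(doc, phi, config = deid_config()) {
  stopifnot(inherits(doc, "deid_document"), inherits(phi, "phi_record"),
            inherits(config, "deid_config"))
  if (doc$record_id != phi$record_id) {
    stop("record linkage mismatch: document '", doc$doc_id, "' links to '",
         doc$record_id, "', PHI record is '", phi$record_id, "'")
  }
  q <- phi_query_tokens(phi, config$min_token_length)
  spans <- lapply(seq_along(q$tokens), function(k) {
    s <- scan_token(doc$text, q$tokens[[k]], config)
    s$token_index <- q$index[[k]]
    s
  })
  spans <- if (length(spans)) do.call(rbind, spans) else
    tibble::tibble(start = integer(), end = integer(),
                   similarity = numeric(), token_index = integer())
  n <- cp_length(doc$text)
  masked <- logical(n)
  if (nrow(spans) > 0L) {
    for (i in seq_len(nrow(spans))) {
      masked[(spans$start[i] + 1L):spans$end[i]] <- TRUE
    }
  }
  cps <- utf8ToInt(doc$text)
  cps[masked] <- utf8ToInt(config$mask_char)
  structure(
    list(doc_id = doc$doc_id,
         text = if (n > 0L) intToUtf8(cps) else doc$text,
         masked_offsets = which(masked) - 1L,
         spans = spans,
         version_hash = version_hash(phi, doc$date)),
    class = "masked_document"
  )
}

#' @export
print.masked_document <- function(x, ...) {
  cat("<masked_document>", x$doc_id, "-", length(x$masked_offsets),
      "offsets masked by", nrow(x$spans), "window matches\n")
  invisible(x)
}

#' Write masked documents as JSONL
#'
#' Mirrors the input document schema plus the masked text, the matched
#' window spans and the version hash.
#'
#' @param masked List of `masked_document` objects (see [deidentify()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masked_documents <- function(masked, path) {
  lines <- vapply(masked, function(m) {
    jsonlite::toJSON(
      list(doc_id = m$doc_id, text = m$text,
           masked_offsets = m$masked_offsets,
           spans = as.data.frame(m$spans),
           version_hash = m$version_hash),
      auto_unbox = TRUE, dataframe = "rows", digits = NA
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
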