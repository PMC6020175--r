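#' Scoring configuration
#'
#' Defines when a token counts as detected: at least
#' `coverage_threshold` of its characters must be masked. The default
#' (0.3) is part of the calibrated benchmark configuration (see the
#' methods vignette).
#'
#' @param coverage_threshold Proportion in `(0, 1]`.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(coverage_threshold = 0.3) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(coverage_threshold = coverage_threshold),
            class = "scoring_config")
}

# Maximal runs of non-whitespace inside a gold span, as absolute 0-based
# half-open spans. An OCR-split gold token contributes one unit per
# whitespace-delimited fragment, so the gold universe matches how a reader
# of the final text would count tokens.
gold_fragments <- function(gold, text) {
  if (nrow(gold) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- lapply(seq_len(nrow(gold)), function(i) {
    chars <- strsplit(gold$token[i], "")[[1]]
    solid <- !grepl("[[:space:]]", chars)
    r <- rle(solid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(start = gold$start[i] + starts[keep],
               end = gold$start[i] + ends[keep])
  })
  do.call(rbind, out)
}

#' Score one masked document against its gold annotations
#'
#' Per-token counting: each whitespace-delimited fragment of a gold span is
#' a true positive when at least `scoring$coverage_threshold` of its
#' characters are masked, otherwise a false negative. False positives are
#' the non-gold whitespace-delimited tokens of the document (tokens with no
#' alphanumeric character are ignored) whose masked fraction reaches the
#' same threshold.
#'
#' @param gold [gold_annotations()] for the document.
#' @param masked_offsets 0-based integer offsets masked by the
#'   de-identifier (from [deidentify()]).
#' @param doc_text The original document text.
#' @param scoring A [scoring_config()].
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_tokens <- function(gold, masked_offsets, doc_text,
                         scoring = scoring_config()) {
  stopifnot(inherits(scoring, "scoring_config"))
  n <- cp_length(doc_text)
  if (length(masked_offsets) &&
      (min(masked_offsets) < 0L || max(masked_offsets) >= n)) {
    stop("masked offsets outside document bounds")
  }
  masked <- logical(n)
  masked[masked_offsets + 1L] <- TRUE
  cov <- scoring$coverage_threshold
  frac <- function(s, e) if (e > s) mean(masked[(s + 1L):e]) else 0

  frags <- gold_fragments(gold, doc_text)
  tp <- 0L; fn <- 0L
  for (i in seq_len(nrow(frags))) {
    if (frac(frags$start[i], frags$end[i]) >= cov) tp <- tp + 1L else fn <- fn + 1L
  }

  fp <- 0L
  m <- gregexpr("\\S+", doc_text)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
    words <- substring(doc_text, starts + 1L, ends)
    for (i in seq_along(starts)) {
      if (!grepl("[[:alnum:]]", words[i])) next
      overlaps_gold <- nrow(gold) > 0L &&
        any(gold$start < ends[i] & gold$end > starts[i])
      if (overlaps_gold) next
      if (frac(starts[i], ends[i]) >= cov) fp <- fp + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn)
}

default_conditions <- function() {
  list(
    list(condition = "Character substitution (3%)",
         mutator = mutator_spec("keyboard", char_rate = 0.03)),
    list(condition = "Character substitution (10%)",
         mutator = mutator_spec("keyboard", char_rate = 0.10)),
    list(condition = "Character substitution (20%)",
         mutator = mutator_spec("keyboard", char_rate = 0.20)),
    list(condition = "Address alias substitution",
         mutator = mutator_spec("alias", token_rate = 1)),
    list(condition = "Address token removal",
         mutator = mutator_spec("truncate", token_rate = 1, min_tokens = 3L)),
    list(condition = "OCR (3% char. sub., 3% white space)",
         mutator = mutator_spec("ocr", char_rate = 0.03, ws_rate = 0.03)),
    list(condition = "OCR (10% char. sub., 10% white space)",
         mutator = mutator_spec("ocr", char_rate = 0.10, ws_rate = 0.10)),
    list(condition = "OCR (20% char. sub., 20% white space)",
         mutator = mutator_spec("ocr", char_rate = 0.20, ws_rate = 0.20))
  )
}

#' Evaluate the masker over one corpus
#'
#' De-identifies every document of a corpus against its clean PHI record
#' and pools per-token counts corpus-wide (micro-averaging).
#'
#' @param corpus A list as returned by [generate_corpus()].
#' @param config A [deid_config()].
#' @param scoring A [scoring_config()].
#' @return An [eval_result()].
#' @export
evaluate_corpus <- function(corpus, config = deid_config(),
                            scoring = scoring_config()) {
  phis <- corpus$phi_records
  names(phis) <- vapply(phis, `[[`, character(1), "record_id")
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (doc in corpus$documents) {
    phi <- phis[[doc$record_id]]
    if (is.null(phi)) stop("no PHI record for '", doc$record_id, "'")
    m <- deidentify(doc, phi, config)
    tot <- tot + match_tokens(doc$gold, m$masked_offsets, doc$text, scoring)
  }
  eval_result(tot[["tp"]], tot[["fp"]], tot[["fn"]])
}

#' Run the eight-condition de-identification benchmark
#'
#' For each condition - keyboard substitution at 3/10/20%, alias
#' substitution at token rate 1, truncation to three tokens, and OCR at
#' (3,3)/(10,10)/(20,20)% - a fresh seeded corpus is generated, every
#' document is de-identified against its clean record, and pooled
#' per-token counts are scored.
#'
#' @param config A [deid_config()].
#' @param scoring A [scoring_config()].
#' @param n_docs Documents per condition.
#' @param seed Base seed; condition `i` uses corpus seed `seed + i`.
#' @param conditions List of `list(condition =, mutator =)` entries;
#'   defaults to the eight benchmark conditions in reference-report order.
#' @return A `benchmark_report` tibble with columns `condition`, `tp`,
#'   `fp`, `fn`, `precision`, `recall` (proportions), carrying the seed and
#'   configurations as attributes.
#' @export
run_benchmark <- function(config = deid_config(), scoring = scoring_config(),
                          n_docs = 1000L, seed = 42L,
                          conditions = default_conditions()) {
  rows <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    corp <- generate_corpus(generator_config(
      n_docs = n_docs, mutator = cond$mutator, seed = seed + i))
    r <- evaluate_corpus(corp, config, scoring)
    tibble::tibble(condition = cond$condition, tp = r$tp, fp = r$fp, fn = r$fn,
                   precision = r$precision, recall = r$recall)
  })
  report <- do.call(rbind, rows)
  attr(report, "seed") <- seed
  attr(report, "deid_config") <- config
  attr(report, "scoring_config") <- scoring
  class(report) <- c("benchmark_report", class(report))
  report
}

#' Published reference benchmark results
#'
#' The per-condition token counts and rounded precision/recall percentages
#' reported for the original implementation of this masking algorithm on
#' its 1000-document simulated corpora; used by [compare_to_reference()]
#' and shipped as plain CSV in `extdata`.
#'
#' @return A tibble with columns `condition`, `tp`, `fp`, `fn`,
#'   `precision`, `recall` (percentages as printed, one decimal).
#' @export
reference_results <- function() {
  tab <- read.csv(phimask_extdata("reference_results.csv"),
                  colClasses = c(condition = "character"))
  tibble::as_tibble(tab)
}

#' Compare a benchmark report against the reference results
#'
#' Joins by condition and reports precision/recall (percentages) side by
#' side with their differences in percentage points.
#'
#' @param report A report from [run_benchmark()].
#' @param path Optional path; when given the comparison is also written
#'   as CSV.
#' @return A tibble with columns `condition`, `precision`, `recall`,
#'   `ref_precision`, `ref_recall`, `d_precision`, `d_recall`.
#' @export
compare_to_reference <- function(report, path = NULL) {
  ref <- reference_results()
  idx <- match(report$condition, ref$condition)
  out <- tibble::tibble(
    condition = report$condition,
    precision = round(100 * report$precision, 1),
    recall = round(100 * report$recall, 1),
    ref_precision = ref$precision[idx],
    ref_recall = ref$recall[idx],
    d_precision = round(100 * report$precision - ref$precision[idx], 1),
    d_recall = round(100 * report$recall - ref$recall[idx], 1)
  )
  if (!is.null(path)) write.csv(as.data.frame(out), path, row.names = FALSE)
  out
}
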