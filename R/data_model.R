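#' Construct a structured PHI record
#'
#' A `phi_record` carries the clean identifiers known for one patient as
#' held in an administrative table: an ordered list of address tokens
#' (the masking queries for the benchmark) and, optionally, further
#' identifier categories such as names or phone numbers.
#'
#' @param record_id Opaque identifier, unique within a collection.
#' @param address_tokens Character vector of address tokens. Each token must
#'   be non-empty and contain no internal whitespace.
#' @param other_phis Optional named list mapping a category name
#'   (`first_name`, `last_name`, `phone`, `nhs_number`, `date_of_birth`)
#'   to a character vector of tokens.
#' @return An object of class `phi_record`.
#' @examples
#' phi_record("r1", c("100", "Meadow", "Street"))
#' @export
phi_record <- function(record_id, address_tokens, other_phis = NULL) {
  stopifnot(is.character(record_id), length(record_id) == 1L, nzchar(record_id))
  address_tokens <- as.character(address_tokens)
  if (length(address_tokens) == 0L) {
    stop("phi_record '", record_id, "': address_tokens must be non-empty")
  }
  if (any(!nzchar(address_tokens)) || any(grepl("[[:space:]]", address_tokens))) {
    stop("phi_record '", record_id,
         "': address tokens must be non-empty and contain no whitespace")
  }
  if (!is.null(other_phis)) {
    stopifnot(is.list(other_phis), !is.null(names(other_phis)))
    other_phis <- lapply(other_phis, as.character)
  }
  structure(
    list(record_id = record_id, address_tokens = address_tokens,
         other_phis = other_phis),
    class = "phi_record"
  )
}

#' Canonical address string of a PHI record
#'
#' Joins the address tokens with single spaces. The result round-trips to
#' the token list under whitespace splitting.
#'
#' @param phi A [phi_record()].
#' @return A single string.
#' @export
canonical_address <- function(phi) {
  stopifnot(inherits(phi, "phi_record"))
  paste(phi$address_tokens, collapse = " ")
}

#' @export
print.phi_record <- function(x, ...) {
  cat("<phi_record>", x$record_id, "-", canonical_address(x), "\n")
  invisible(x)
}

#' Gold annotation table
#'
#' Builds the validated annotation table carried by a [document()]: one row
#' per embedded PHI token, with 0-based half-open code-point offsets.
#'
#' @param start,end Integer offsets, 0-based, half-open `[start, end)`.
#' @param token The annotated surface string; must equal the text slice.
#'   May contain internal whitespace only when produced by the OCR mutator.
#' @param source_index 0-based position of the originating token in the
#'   unmutated address.
#' @return A `tibble` with columns `start`, `end`, `token`, `source_index`.
#' @export
gold_annotations <- function(start = integer(), end = integer(),
                             token = character(), source_index = integer()) {
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 token = as.character(token),
                 source_index = as.integer(source_index))
}

validate_gold <- function(gold, text, doc_id = "?") {
  if (nrow(gold) == 0L) return(invisible(gold))
  n <- cp_length(text)
  bad <- gold$start < 0L | gold$end > n | gold$end <= gold$start
  if (any(bad)) {
    stop("document '", doc_id, "': gold span out of bounds or empty")
  }
  if (is.unsorted(gold$start, strictly = TRUE) ||
      any(gold$start[-1L] < gold$end[-nrow(gold)])) {
    stop("document '", doc_id, "': gold spans must be sorted and non-overlapping")
  }
  slices <- substring(text, gold$start + 1L, gold$end)
  if (any(slices != gold$token)) {
    i <- which(slices != gold$token)[1L]
    stop("document '", doc_id, "': gold token ", i, " ('", gold$token[i],
         "') disagrees with text slice ('", slices[i], "')")
  }
  invisible(gold)
}

#' Construct a document
#'
#' A free-text document linked to the patient record whose identifiers it
#' may contain. Optionally carries gold annotations (the evaluation ground
#' truth): character-offset spans of embedded, possibly mutated, PHI tokens.
#'
#' @param doc_id Opaque document identifier.
#' @param record_id Link to the [phi_record()] for the same patient.
#' @param date Document date (`Date` or ISO-8601 string).
#' @param text Document text. Offsets into it count Unicode code points.
#' @param gold Optional [gold_annotations()] table; validated against `text`.
#' @return An object of class `deid_document`.
#' @export
document <- function(doc_id, record_id, date, text, gold = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(record_id), length(record_id) == 1L,
            is.character(text), length(text) == 1L)
  date <- as.Date(date)
  if (is.null(gold)) gold <- gold_annotations()
  gold <- tibble::as_tibble(gold)
  validate_gold(gold, text, doc_id)
  structure(
    list(doc_id = doc_id, record_id = record_id, date = date,
         text = text, gold = gold),
    class = "deid_document"
  )
}

#' @export
print.deid_document <- function(x, ...) {
  cat("<document>", x$doc_id, "record:", x$record_id,
      "date:", format(x$date), "gold tokens:", nrow(x$gold), "\n")
  invisible(x)
}

#' Read documents from a JSONL file
#'
#' One JSON object per line with fields `doc_id`, `record_id`, `date`
#' (ISO-8601), `text` and optionally `gold` (array of
#' `{start, end, token, source_index}`). Gold spans are validated against
#' the text on read.
#'
#' @param path Path to a JSONL file.
#' @return A list of [document()] objects, in file order.
#' @export
read_documents <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) read_document_line(lines[[i]], i))
}

#' Write documents to a JSONL file
#'
#' Inverse of [read_documents()]: `read_documents(write_documents(x))`
#' reproduces every field, including gold offsets.
#'
#' @param docs List of [document()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(
      list(doc_id = d$doc_id, record_id = d$record_id,
           date = format(d$date), text = d$text,
           gold = as.data.frame(d$gold)),
      auto_unbox = TRUE, dataframe = "rows", digits = NA
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

tokenize_address_field <- function(address) {
  toks <- strsplit(trimws(address), "[[:space:]]+")[[1]]
  # the field is comma-separated prose; strip list punctuation off token edges
  toks <- gsub("^[,;]+|[,;]+$", "", toks)
  toks[nzchar(toks)]
}

#' Read structured PHI records
#'
#' Accepts either a CSV with header `record_id,address` (the address field
#' is whitespace-tokenized, with commas stripped from token edges) or a
#' JSONL file of `{record_id, address_tokens, other_phis?}` objects.
#'
#' @param path Path to the file. Format is inferred from the `.csv`
#'   extension unless `format` is given.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer.
#' @return A list of [phi_record()] objects. Duplicate `record_id`s are an
#'   error.
#' @export
read_phi_records <- function(path, format = NULL) {
  stopifnot(file.exists(path))
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  recs <- if (format == "csv") {
    tab <- read.csv(path, colClasses = "character")
    stopifnot(all(c("record_id", "address") %in% names(tab)))
    lapply(seq_len(nrow(tab)), function(i) {
      toks <- tokenize_address_field(tab$address[i])
      if (length(toks) == 0L) {
        stop("record '", tab$record_id[i], "': empty address")
      }
      phi_record(tab$record_id[i], toks)
    })
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      obj <- tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
        error = function(e) stop("parse error at line ", i, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      phi_record(obj$record_id, obj$address_tokens,
                 other_phis = obj$other_phis)
    })
  }
  ids <- vapply(recs, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record_id: ", ids[duplicated(ids)][1L])
  }
  recs
}

#' Write PHI records as CSV
#'
#' @param phis List of [phi_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phi_records <- function(phis, path) {
  tab <- data.frame(
    record_id = vapply(phis, `[[`, character(1), "record_id"),
    address = vapply(phis, canonical_address, character(1))
  )
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Per-token evaluation counts
#'
#' Wraps true-positive, false-positive and false-negative token counts and
#' derives precision `tp / (tp + fp)` and recall `tp / (tp + fn)` as
#' proportions, `NA` when the denominator is zero.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return An object of class `eval_result`.
#' @examples
#' eval_result(6969, 271, 1537) # precision 0.963, recall 0.819
#' @export
eval_result <- function(tp, fp, fn) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  if (any(c(tp, fp, fn) < 0L) || anyNA(c(tp, fp, fn))) {
    stop("counts must be non-negative integers")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> tp=%d fp=%d fn=%d precision=%s recall=%s\n",
              x$tp, x$fp, x$fn, format_pct(x$precision), format_pct(x$recall)))
  invisible(x)
}

# one-decimal percentage, "" when undefined
format_pct <- function(p) {
  ifelse(is.na(p), "", formatC(100 * p, format = "f", digits = 1))
}

#' Write a benchmark report as CSV
#'
#' Columns `condition,tp,fp,fn,precision,recall`, with precision and recall
#' printed as percentages to one decimal place (empty when undefined).
#'
#' @param report A [benchmark_report] tibble (see [run_benchmark()]), or any
#'   data frame with columns `condition`, `tp`, `fp`, `fn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(nrow(report) >= 1L)
  prec <- format_pct(ifelse(report$tp + report$fp > 0,
                            report$tp / (report$tp + report$fp), NA))
  rec <- format_pct(ifelse(report$tp + report$fn > 0,
                           report$tp / (report$tp + report$fn), NA))
  lines <- c("condition,tp,fp,fn,precision,recall",
             sprintf('"%s",%d,%d,%d,%s,%s',
                     gsub('"', '""', report$condition),
                     as.integer(report$tp), as.integer(report$fp),
                     as.integer(report$fn), prec, rec))
  writeLines(lines, path)
  invisible(path)
}

#' Read a benchmark report written by [write_report()]
#'
#' Precision and recall are recomputed from the counts, so the round trip
#' `read_report(write_report(x))` reproduces `x`.
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `condition`, `tp`, `fp`, `fn`,
#'   `precision`, `recall` (proportions).
#' @export
read_report <- function(path) {
  tab <- read.csv(path, colClasses = c(condition = "character"))
  tibble::tibble(
    condition = tab$condition,
    tp = as.integer(tab$tp), fp = as.integer(tab$fp), fn = as.integer(tab$fn),
    precision = ifelse(tab$tp + tab$fp > 0, tab$tp / (tab$tp + tab$fp), NA_real_),
    recall = ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn), NA_real_)
  )
}

#' Write a benchmark report as JSON
#'
#' @inheritParams write_report
#' @export
write_report_json <- function(report, path) {
  stopifnot(nrow(report) >= 1L)
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, na = "null")
  invisible(path)
}
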