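#' Partition a job into balanced contiguous ranges
#'
#' Splits `[0, n_items)` into at most `n_partitions` contiguous half-open
#' ranges whose sizes differ by at most one. An empty job yields zero
#' ranges.
#'
#' @param n_items Number of work items (>= 0).
#' @param n_partitions Requested number of partitions (>= 1).
#' @return A list of `c(start, end)` integer pairs (0-based, half-open).
#' @examples
#' partition_job(10, 3) # [0,4) [4,7) [7,10)
#' @export
partition_job <- function(n_items, n_partitions) {
  stopifnot(n_items >= 0L)
  if (n_partitions < 1L) stop("n_partitions must be >= 1")
  n_items <- as.integer(n_items)
  if (n_items == 0L) return(list())
  k <- min(as.integer(n_partitions), n_items)
  base <- n_items %/% k
  extra <- n_items %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- ends - sizes
  lapply(seq_len(k), function(i) c(start = starts[i], end = ends[i]))
}

read_job_state <- function(path) {
  if (is.null(path) || !file.exists(path)) {
    return(list(high_water_mark = NULL, jobs = list()))
  }
  st <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(st$high_water_mark)) {
    st$high_water_mark <- as.Date(st$high_water_mark)
  }
  st
}

write_job_state <- function(state, path) {
  st <- state
  if (!is.null(st$high_water_mark)) {
    st$high_water_mark <- format(st$high_water_mark)
  }
  jsonlite::write_json(st, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Run an incremental, partitioned de-identification job
#'
#' Implements a single-process version of a master/worker batch model:
#' documents dated strictly after the stored high-water mark are selected,
#' split into balanced partitions, and each partition is de-identified
#' independently. Partition failures are isolated: the failing partition
#' is recorded as `failed`, the others still complete, the job as a whole
#' is marked failed, and the high-water mark is not advanced - so the next
#' run retries the unprocessed documents. Only when every partition
#' completes is the job marked complete and the mark advanced to the
#' newest processed document date.
#'
#' @param documents_path JSONL of documents (see [read_documents()]).
#' @param phis_path PHI record table (see [read_phi_records()]).
#' @param out_path Output JSONL of masked documents; appended to across
#'   incremental runs.
#' @param config A [deid_config()].
#' @param n_partitions Number of work partitions.
#' @param state_path Optional JSON job-state file (the job repository);
#'   read if present, updated on every run.
#' @return A `job_state` list: `job_id`, `n_selected`, `partitions`
#'   (tibble with `start`, `end`, `status`), `status`, `high_water_mark`.
#' @export
run_job <- function(documents_path, phis_path, out_path,
                    config = deid_config(), n_partitions = 4L,
                    state_path = NULL) {
  state <- read_job_state(state_path)
  phis <- read_phi_records(phis_path)
  names(phis) <- vapply(phis, `[[`, character(1), "record_id")

  # lenient read: a malformed line becomes a poison item that fails its
  # partition at processing time instead of aborting the whole job
  lines <- readLines(documents_path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  items <- lapply(seq_along(lines), function(i) {
    tryCatch(read_document_line(lines[[i]], i),
             error = function(e) structure(list(line = i,
                                                message = conditionMessage(e)),
                                           class = "poison_document"))
  })

  hwm <- state$high_water_mark
  selected <- Filter(function(d) {
    inherits(d, "poison_document") || is.null(hwm) || d$date > hwm
  }, items)

  parts <- partition_job(length(selected), n_partitions)
  statuses <- character(length(parts))
  outputs <- vector("list", length(parts))
  max_date <- as.Date(NA)
  for (p in seq_along(parts)) {
    rng <- parts[[p]]
    res <- tryCatch({
      chunk <- selected[(rng[["start"]] + 1L):rng[["end"]]]
      lapply(chunk, function(doc) {
        if (inherits(doc, "poison_document")) {
          stop("malformed document at line ", doc$line, ": ", doc$message)
        }
        phi <- phis[[doc$record_id]]
        if (is.null(phi)) stop("no PHI record for '", doc$record_id, "'")
        deidentify(doc, phi, config)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      statuses[p] <- "failed"
    } else {
      statuses[p] <- "complete"
      outputs[[p]] <- res
      dates <- as.Date(vapply(selected[(rng[["start"]] + 1L):rng[["end"]]],
                              function(d) format(d$date), character(1)))
      if (length(dates)) max_date <- max(max_date, max(dates), na.rm = TRUE)
    }
  }

  done <- lapply(outputs[statuses == "complete"], identity)
  masked <- unlist(done, recursive = FALSE)
  if (length(masked)) {
    con <- file(out_path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    lines_out <- vapply(masked, function(m) {
      jsonlite::toJSON(list(doc_id = m$doc_id, text = m$text,
                            masked_offsets = m$masked_offsets,
                            spans = as.data.frame(m$spans),
                            version_hash = m$version_hash),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
    }, character(1))
    writeLines(lines_out, con, useBytes = TRUE)
  }

  job_status <- if (length(parts) == 0L || all(statuses == "complete")) {
    "complete"
  } else {
    "failed"
  }
  new_hwm <- hwm
  if (job_status == "complete" && !is.na(max_date)) new_hwm <- max_date

  job <- list(
    job_id = sprintf("job-%s-%04d", format(Sys.Date()), length(state$jobs) + 1L),
    n_selected = length(selected),
    partitions = tibble::tibble(
      start = vapply(parts, `[[`, integer(1), "start"),
      end = vapply(parts, `[[`, integer(1), "end"),
      status = statuses),
    status = job_status,
    high_water_mark = new_hwm
  )
  class(job) <- "job_state"

  if (!is.null(state_path)) {
    state$high_water_mark <- new_hwm
    state$jobs <- c(state$jobs, list(list(
      job_id = job$job_id, status = job_status,
      n_selected = length(selected),
      partition_status = as.list(statuses))))
    write_job_state(state, state_path)
  }
  job
}

# parse one JSONL document line (shared with read_documents semantics)
read_document_line <- function(line, lineno) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e) stop("parse error at line ", lineno,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  gold <- obj$gold
  if (is.null(gold) || length(gold) == 0L) {
    gold <- gold_annotations()
  } else {
    gold <- gold_annotations(gold$start, gold$end, gold$token,
                             gold$source_index)
  }
  document(obj$doc_id, obj$record_id, obj$date, obj$text, gold)
}

#' @export
print.job_state <- function(x, ...) {
  cat("<job_state>", x$job_id, "-", x$status, "-", x$n_selected,
      "documents in", nrow(x$partitions), "partitions; high-water mark:",
      if (is.null(x$high_water_mark)) "none" else format(x$high_water_mark),
      "\n")
  invisible(x)
}
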