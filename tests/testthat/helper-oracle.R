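# Independent oracles used to cross-check the package's matching core.
# They never call into the package's own distance or scan code.

# exhaustive-recursion Levenshtein distance (memoised)
oracle_lev <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- min(rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + (A[[i]] != B[[j]]))
    memo[[key]] <- v
    v
  }
  rec(length(A), length(B))
}

random_string <- function(n, alphabet = c("a", "b", "c", "d")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force scan over every offset and width, using utils::adist as the
# independent distance; mirrors the scan contract including the optional
# whitespace barrier
oracle_scan <- function(text, token, theta, slack, case_fold = TRUE,
                        barrier = TRUE) {
  if (case_fold) {
    text <- tolower(text)
    token <- tolower(token)
  }
  L <- nchar(token)
  d <- as.integer(ceiling(slack * L))
  wmin <- max(1L, L - d)
  wmax <- L + d
  n <- nchar(text)
  out <- list()
  for (i in 0:(n - 1L)) {
    for (w in wmin:wmax) {
      if (i + w > n) next
      win <- substr(text, i + 1L, i + w)
      if (barrier && grepl("[[:space:]]", win)) next
      sim <- 1 - adist(token, win)[1, 1] / max(L, w)
      if (sim >= theta) {
        out[[length(out) + 1L]] <- c(start = i, end = i + w, sim = sim)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), sim = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# tiny corpus helper for evaluation tests
tiny_corpus <- function(n_docs, mutator = mutator_spec("none"), seed = 1L) {
  generate_corpus(generator_config(n_docs = n_docs, mutator = mutator,
                                   seed = seed))
}
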