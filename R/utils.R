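# Seeding and small I/O helpers. All randomness in the package flows from a
# master seed through named substreams so that every pipeline stage is
# reproducible independently of evaluation order.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state, so
#' scripted pipelines can draw reproducible subsamples without disturbing
#' the global stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @export
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed
#'
#' Combines a master seed with any number of integer or character tags into a
#' deterministic 31-bit seed, so independent pipeline stages draw from
#' unrelated streams.
#'
#' @param master integer master seed.
#' @param ... tags (integers or strings) naming the substream.
#' @return integer in `[0, 2^31)`.
#' @export
substream_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.double(master %% 2147483647)
  mix <- function(h, v) ((h * 69069 + v) %% 2147483647)
  for (tag in tags) {
    if (is.character(tag)) {
      for (ch in utf8ToInt(tag)) h <- mix(h, ch)
    } else {
      h <- mix(h, as.double(tag) %% 2147483647)
    }
  }
  as.integer(h)
}

write_jsonl <- function(records, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (rec in records)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"), con)
  invisible(path)
}

read_jsonl <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
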