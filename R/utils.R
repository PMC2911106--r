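# Internal interval helpers. All coordinates are 0-based half-open [start, end).

# Merge possibly overlapping 0-based half-open intervals into disjoint sorted ones.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(list(start = integer(), end = integer()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Intersect a set of 0-based half-open intervals with a single window [ws, we).
clip_intervals <- function(start, end, ws, we) {
  s <- pmax(start, ws)
  e <- pmin(end, we)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}

# Largest run of bases in [ws, we) not covered by the (merged) intervals given.
max_uncovered_run <- function(start, end, ws, we) {
  if (we <= ws) return(0L)
  cl <- clip_intervals(start, end, ws, we)
  if (length(cl$start) == 0L) return(we - ws)
  m <- merge_intervals(cl$start, cl$end)
  gaps <- c(m$start[1] - ws, diff_gaps(m$start, m$end), we - m$end[length(m$end)])
  as.integer(max(gaps))
}

diff_gaps <- function(start, end) {
  k <- length(start)
  if (k < 2L) return(integer())
  start[-1L] - end[-k]
}

# Seed-scoped evaluation: run `expr` under `seed` without disturbing the
# caller's RNG stream; NULL seed means use the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic TSV writer used for every pipeline artifact.
write_tsv_strict <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
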