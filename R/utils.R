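# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a semicolon-joined field into a character vector; "" -> character(0).
split_semi <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_semi <- function(x) vapply(x, paste, character(1), collapse = ";")

# Write a data.frame as TSV with numeric columns rendered at full double
# precision so that write -> read round trips are exact.
write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("NA", ""), ...)
}

# Row-wise mean/variance with NA handling, without apply() overhead.
row_means_na <- function(m) rowMeans(m, na.rm = TRUE)

row_vars_na <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  v <- ss / (n - 1)
  v[n < 2] <- NA_real_
  v
}

# 0-based half-open interval merge per chromosome. Input/output:
# data.frame(chrom, start, end). Uses IRanges::reduce for the merging.
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end")])
  parts <- split(intervals, intervals$chrom)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  invisible(x)
}
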