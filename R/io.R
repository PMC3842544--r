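# Readers and writers for the remaining external formats: BED intervals,
# plain-text PWMs, GMT gene sets, expression matrices, and the tabular
# result records (site statistics and enrichment records).

#' Read a BED3/BED4 interval file
#'
#' Standard BED semantics: 0-based, half-open intervals. Output is sorted by
#' (chrom, start). A row with `start >= end` is a hard error.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`
#'   (empty string when the file has no name column).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t| +")
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop("BED line ", which(ncols < 3)[1], " has fewer than 3 columns",
         call. = FALSE)
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end) || any(start < 0))
    stop("malformed BED coordinates at line ",
         which(is.na(start) | is.na(end) | start < 0)[1], call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end", call. = FALSE)
  name <- ifelse(ncols >= 4, vapply(parts, `[`, character(1), 4), "")
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` and optional
#'   `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) cols <- c(cols, list(intervals$name))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Construct a position weight matrix
#'
#' @param probs L x 4 numeric matrix of base probabilities over (A, C, G, T);
#'   each row must sum to 1 within 1e-9.
#' @param motif_id Motif identifier.
#' @param background Length-4 background base frequencies (default uniform).
#' @param pseudocount Small non-negative regularizer applied as
#'   `(p + pc) / (1 + 4 pc)` per row before log-odds scoring; 0 scores the
#'   raw probabilities.
#' @return Object of class `pwm`.
#' @export
pwm <- function(probs, motif_id = "motif", background = rep(0.25, 4),
                pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4)
    stop("PWM must have 4 columns (A, C, G, T)", call. = FALSE)
  if (any(probs < 0))
    stop("PWM probabilities must be non-negative", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("PWM rows must sum to 1", call. = FALSE)
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 positive frequencies", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, probs = probs,
                 background = background / sum(background),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Build a sharp PWM from a consensus sequence
#'
#' @param consensus DNA string over ACGT.
#' @param match_prob Probability of the consensus base at each position;
#'   the remainder is spread over the other three bases.
#' @inheritParams pwm
#' @export
pwm_from_consensus <- function(consensus, motif_id = consensus,
                               match_prob = 0.97, pseudocount = 0.001) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus must be over ACGT", call. = FALSE)
  probs <- matrix((1 - match_prob) / 3, nrow = length(bases), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <-
    match_prob
  pwm(probs, motif_id = motif_id, pseudocount = pseudocount)
}

#' Read plain-text PWMs
#'
#' Format: an optional `>motif_id` header line followed by one row per motif
#' position with four whitespace-separated probabilities (A C G T). Multiple
#' motifs may be concatenated, each with its own header.
#'
#' @param path File path.
#' @param ... Passed to [pwm()] (e.g. `pseudocount`).
#' @return Named list of `pwm` objects.
#' @export
read_pwm <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- startsWith(lines, ">")
  if (!any(heads)) {
    grp <- rep(1L, length(lines))
    ids <- "motif1"
  } else {
    if (!heads[1]) stop("PWM file: rows before first '>' header",
                        call. = FALSE)
    grp <- cumsum(heads)
    ids <- sub("^>\\s*", "", lines[heads])
  }
  out <- lapply(split(lines[!heads], grp[!heads]), function(rows) {
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    m
  })
  pwms <- Map(function(m, id) pwm(m, motif_id = id, ...), out,
              ids[as.integer(names(out))])
  setNames(pwms, vapply(pwms, `[[`, character(1), "motif_id"))
}

#' Write PWMs as plain text
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param path Output path.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id),
      apply(p$probs, 1, function(r) paste(sprintf("%.17g", r),
                                          collapse = "\t")))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a normalized expression matrix with its sample sheet
#'
#' Tab-separated, first column `gene_id`, one column per sample; values are
#' log2 intensities and must be finite.
#'
#' @param path Expression matrix path.
#' @param sample_sheet_path Sample sheet path ([read_sample_sheet()]).
#' @return Object of class `expression_matrix`: list with `values`
#'   (genes x samples matrix) and `samples`.
#' @export
read_expression_matrix <- function(path, sample_sheet_path) {
  samples <- read_sample_sheet(sample_sheet_path)
  tab <- read_tsv(path)
  if (names(tab)[1] != "gene_id")
    stop("expression matrix must have first column 'gene_id'", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  expression_matrix(m, samples)
}

#' Construct an expression matrix
#'
#' @param values Genes x samples numeric matrix of log2 intensities.
#' @param samples Sample sheet `data.frame`.
#' @export
expression_matrix <- function(values, samples) {
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (!setequal(colnames(values), samples$sample_id))
    stop("expression columns do not match the sample sheet", call. = FALSE)
  values <- values[, samples$sample_id, drop = FALSE]
  structure(list(values = values,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' Write an expression matrix
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param sample_sheet_path Optional sample sheet output path.
#' @export
write_expression_matrix <- function(expr, path, sample_sheet_path = NULL) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_exact(df, path)
  if (!is.null(sample_sheet_path))
    write.table(expr$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

.sitestat_cols <- c("cpg_id", "delta", "s2", "df", "t_mod", "p", "adj_p",
                    "direction")
.enrichment_cols <- c("category", "k", "n", "K", "N", "fold", "p", "test")

#' Write site statistics or enrichment records
#'
#' Writes a homogeneous record table as TSV with a fixed header; the file
#' round-trips through [read_results()]. Site-statistic tables carry the
#' columns `cpg_id, delta, s2, df, t_mod, p, adj_p, direction`; enrichment
#' tables carry `category, k, n, K, N, fold, p, test` (plus an optional
#' leading `direction` column for context profiles).
#'
#' @param records `data.frame` of one record kind.
#' @param path Output path.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records))
    stop("'records' must be a data.frame of one record kind", call. = FALSE)
  is_site <- all(.sitestat_cols %in% names(records))
  is_enr <- all(.enrichment_cols %in% names(records))
  if (is_site == is_enr)
    stop("records must be exactly one of: site statistics, enrichment records",
         call. = FALSE)
  keep <- if (is_site) .sitestat_cols else
    intersect(c("direction", .enrichment_cols), names(records))
  write_tsv_exact(records[, keep, drop = FALSE], path)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' The record kind is inferred from the header.
#'
#' @param path File path.
#' @export
read_results <- function(path) {
  tab <- read_tsv(path)
  if (all(.sitestat_cols %in% names(tab))) {
    tab$direction <- as.character(tab$direction)
  } else if (all(.enrichment_cols %in% names(tab))) {
    for (col in c("k", "n", "K", "N")) tab[[col]] <- as.integer(tab[[col]])
  } else {
    stop("unrecognized results header in ", path, call. = FALSE)
  }
  tab
}
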