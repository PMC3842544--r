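# Beta-value matrix container: sites x samples methylation fractions in
# [0, 1] (missing values allowed and flagged), plus a sample sheet mapping
# each sample to its donor and condition. Stored as a plain numeric matrix
# with a data.frame sample sheet, in the style of array-analysis packages.

#' Construct a beta-value matrix
#'
#' @param values Numeric matrix (sites x samples) with rownames `cpg_id` and
#'   colnames matching `samples$sample_id`. Values in `[0, 1]`; `NA` marks a
#'   missing measurement.
#' @param samples `data.frame` with columns `sample_id`, `donor`,
#'   `condition`. The (donor, condition) pairs must be unique.
#' @return An object of class `beta_matrix`: a list with elements `values`
#'   and `samples`.
#' @export
beta_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have site rownames and sample colnames",
         call. = FALSE)
  need <- c("sample_id", "donor", "condition")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns sample_id, donor, condition",
         call. = FALSE)
  if (!setequal(colnames(values), samples$sample_id))
    stop("matrix columns do not match the sample sheet", call. = FALSE)
  values <- values[, samples$sample_id, drop = FALSE]
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value %g out of [0,1] at site %s, sample %s",
                 values[bad[1, 1], bad[1, 2]],
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate site ids in beta matrix", call. = FALSE)
  key <- paste(samples$donor, samples$condition, sep = "\r")
  if (anyDuplicated(key))
    stop("(donor, condition) pairs must be unique in the sample sheet",
         call. = FALSE)
  structure(list(values = values,
                 samples = as.data.frame(samples,
                                         stringsAsFactors = FALSE)),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d sites x %d samples (%d conditions, %d donors)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$condition)),
              length(unique(x$samples$donor))))
  invisible(x)
}

#' Read a sample sheet
#'
#' @param path Tab-separated file with columns `sample_id`, `donor`,
#'   `condition`.
#' @export
read_sample_sheet <- function(path) {
  sh <- read_tsv(path, colClasses = "character")
  need <- c("sample_id", "donor", "condition")
  miss <- setdiff(need, names(sh))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sh[, need]
}

#' Read a beta-value matrix with its sample sheet
#'
#' The matrix file is tab-separated with first column `cpg_id` and one
#' column per sample; `NA` or empty cells are flagged missing. Values
#' outside `[0, 1]` are a hard error naming the offending cell.
#'
#' @param path Beta matrix path.
#' @param sample_sheet_path Sample sheet path (see [read_sample_sheet()]).
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sample_sheet_path) {
  samples <- read_sample_sheet(sample_sheet_path)
  tab <- read_tsv(path)
  if (names(tab)[1] != "cpg_id")
    stop("beta matrix must have first column 'cpg_id'", call. = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!setequal(colnames(m), samples$sample_id))
    stop("beta matrix columns do not match the sample sheet", call. = FALSE)
  beta_matrix(m, samples)
}

#' Write a beta-value matrix (and optionally its sample sheet)
#'
#' @param bm A [beta_matrix()].
#' @param path Output path for the matrix.
#' @param sample_sheet_path Optional output path for the sample sheet.
#' @export
write_beta_matrix <- function(bm, path, sample_sheet_path = NULL) {
  df <- data.frame(cpg_id = rownames(bm$values), bm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_exact(df, path)
  if (!is.null(sample_sheet_path))
    write.table(bm$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Per-sample beta-value summary
#'
#' Mean, median and a 20-bin histogram of the non-missing beta values of
#' each sample. Bins are equal width on `[0, 1]`; the last bin is
#' right-closed so that a beta of exactly 1 falls in bin 20.
#'
#' @param bm A [beta_matrix()].
#' @return List with `samples` (a `data.frame` of `sample_id`,
#'   `n_nonmissing`, `mean`, `median`) and `hist` (samples x 20 count
#'   matrix; rows sum to `n_nonmissing`).
#' @export
summarize_beta <- function(bm) {
  v <- bm$values
  n_ok <- colSums(!is.na(v))
  if (any(n_ok == 0))
    stop("sample with no non-missing beta values: ",
         colnames(v)[which(n_ok == 0)[1]], call. = FALSE)
  hist_counts <- t(apply(v, 2, function(x) {
    x <- x[!is.na(x)]
    b <- pmin(floor(x * 20) + 1L, 20L)
    tabulate(b, nbins = 20L)
  }))
  colnames(hist_counts) <- sprintf("bin%02d", 1:20)
  list(
    samples = data.frame(
      sample_id = colnames(v),
      n_nonmissing = n_ok,
      mean = colMeans(v, na.rm = TRUE),
      median = apply(v, 2, median, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE),
    hist = hist_counts
  )
}

#' Positional methylation profile of one gene
#'
#' Compiles all CpG sites affiliated with a gene, ordered by genomic
#' position, and averages beta values per condition (mean over the donors of
#' each condition), mirroring per-gene methylation track plots.
#'
#' @param gene_id Gene identifier.
#' @param man Manifest `data.frame` (see [read_manifest()]).
#' @param bm A [beta_matrix()].
#' @return `data.frame` with `cpg_id`, `pos`, `region` and one mean-beta
#'   column per condition.
#' @export
gene_profile <- function(gene_id, man, bm) {
  aff <- manifest_affiliations(man)
  aff <- aff[!is.na(aff$gene_id) & aff$gene_id == gene_id, , drop = FALSE]
  if (nrow(aff) == 0)
    stop("unknown gene: ", gene_id, call. = FALSE)
  idx <- match(aff$cpg_id, man$cpg_id)
  ord <- order(man$pos[idx])
  aff <- aff[ord, , drop = FALSE]
  idx <- idx[ord]
  rows <- match(aff$cpg_id, rownames(bm$values))
  if (anyNA(rows))
    stop("gene has CpGs absent from the beta matrix", call. = FALSE)
  out <- data.frame(cpg_id = aff$cpg_id, pos = man$pos[idx],
                    region = aff$region, stringsAsFactors = FALSE)
  for (cond in unique(bm$samples$condition)) {
    cols <- bm$samples$sample_id[bm$samples$condition == cond]
    out[[cond]] <- rowMeans(bm$values[rows, cols, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Build a donor-paired two-condition design
#'
#' Pairs samples of two conditions by donor: each donor present in both
#' conditions contributes one (sample_in_a, sample_in_b) pair. At least two
#' pairs are required for a paired test.
#'
#' @param samples Sample sheet `data.frame` (or a [beta_matrix()], whose
#'   sheet is used).
#' @param condition_a Reference condition (differences are `b - a`).
#' @param condition_b Test condition.
#' @return Object of class `paired_design`: list with `condition_a`,
#'   `condition_b` and `pairs` (`data.frame` of `donor`, `sample_a`,
#'   `sample_b`).
#' @export
paired_design <- function(samples, condition_a, condition_b) {
  if (inherits(samples, "beta_matrix") ||
      (is.list(samples) && !is.data.frame(samples) &&
       !is.null(samples$samples)))
    samples <- samples$samples
  for (cond in c(condition_a, condition_b))
    if (!cond %in% samples$condition)
      stop("condition not present in sample sheet: ", cond, call. = FALSE)
  a <- samples[samples$condition == condition_a, ]
  b <- samples[samples$condition == condition_b, ]
  donors <- intersect(a$donor, b$donor)
  pairs <- data.frame(
    donor = donors,
    sample_a = a$sample_id[match(donors, a$donor)],
    sample_b = b$sample_id[match(donors, b$donor)],
    stringsAsFactors = FALSE)
  if (nrow(pairs) < 2)
    stop("paired design needs at least 2 donor pairs", call. = FALSE)
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 pairs = pairs),
            class = "paired_design")
}
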