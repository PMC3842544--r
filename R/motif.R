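# Motif scanning and peak co-location around hypermethylated CpGs.
# Windows are total-width intervals centered on the CpG (a 124 bp window
# spans +/- 62 bp). PWM hits are scored by log2 odds against the background
# base composition; a hit requires a score of at least threshold_fraction
# times the maximum attainable score (and an informative PWM).

#' Extract fixed-width windows centered on CpG sites
#'
#' The window for a CpG at 0-based position `pos` is
#' `[pos - width/2, pos + width/2)`, so the C of the CpG sits at offset
#' `width/2`. Sites whose window would run off the end of their sequence
#' are dropped with a message.
#'
#' @param man Manifest `data.frame` (uses `cpg_id`, `chrom`, `pos`).
#' @param sequences `Biostrings::DNAStringSet` named by chromosome.
#' @param width Even window width in bp (default 124).
#' @return `DNAStringSet` of window sequences named by `cpg_id`.
#' @export
extract_windows <- function(man, sequences, width = 124) {
  if (width %% 2 != 0 || width < 2)
    stop("width must be a positive even number", call. = FALSE)
  if (!all(man$chrom %in% names(sequences)))
    stop("no sequence for chromosome(s): ",
         paste(setdiff(unique(man$chrom), names(sequences)), collapse = ", "),
         call. = FALSE)
  half <- width %/% 2
  start <- man$pos - half          # 0-based
  end <- start + width
  chrlen <- setNames(Biostrings::width(sequences), names(sequences))
  ok <- start >= 0 & end <= chrlen[man$chrom]
  if (any(!ok))
    message(sum(!ok), " window(s) dropped at sequence boundaries")
  out <- vector("list", length(unique(man$chrom[ok])))
  names(out) <- unique(man$chrom[ok])
  for (ch in names(out)) {
    sel <- which(ok & man$chrom == ch)
    ss <- Biostrings::DNAStringSet(sequences[[ch]],
                                   start = start[sel] + 1L,
                                   end = end[sel])
    names(ss) <- man$cpg_id[sel]
    out[[ch]] <- ss
  }
  res <- do.call(c, unname(out))
  res[order(match(names(res), man$cpg_id))]
}

# Log2-odds score matrix (L x 4) of a pwm after pseudocount regularization.
pwm_score_matrix <- function(p) {
  probs <- (p$probs + p$pseudocount) / (1 + 4 * p$pseudocount)
  log2(sweep(probs, 2, p$background, "/"))
}

# Reverse-complement of a pwm: reverse positions, swap A<->T and C<->G.
pwm_revcomp <- function(p) {
  rc <- p$probs[rev(seq_len(nrow(p$probs))), c(4, 3, 2, 1), drop = FALSE]
  colnames(rc) <- c("A", "C", "G", "T")
  pwm(rc, motif_id = p$motif_id, background = rev(p$background),
      pseudocount = p$pseudocount)
}

# Scores of one strand for all offsets: windows as an n x W base-index
# matrix (1..4, NA for non-ACGT), smat an L x 4 log-odds matrix.
.scan_one_strand <- function(bmat, smat) {
  L <- nrow(smat)
  W <- ncol(bmat)
  n_off <- W - L + 1L
  scores <- matrix(NA_real_, nrow(bmat), n_off)
  srows <- lapply(seq_len(L), function(j) smat[j, ])
  for (o in seq_len(n_off)) {
    sc <- srows[[1]][bmat[, o]]
    if (L > 1) for (j in 2:L) sc <- sc + srows[[j]][bmat[, o + j - 1L]]
    scores[, o] <- sc
  }
  scores
}

#' Scan windows for PWM motif occurrences
#'
#' Log2-odds scoring per offset: `sum(log2(p_base / background))` over motif
#' positions. An offset is a hit iff its score reaches `threshold_fraction`
#' times the maximum attainable score and the PWM is informative (maximum
#' score > 0); an uninformative PWM never produces hits. With
#' `both_strands`, the reverse complement is scanned as well, and the hit
#' set is strand-symmetric. Offsets covering a non-ACGT base are skipped.
#' Overlapping hits are all reported.
#'
#' @param windows `DNAStringSet` (or named character vector) of equal-width
#'   window sequences.
#' @param p A [pwm()].
#' @param threshold_fraction Fraction of the maximum attainable score
#'   required for a hit (default 0.8).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return `data.frame` of hits: `window_id`, `motif_id`, `offset`
#'   (0-based within the window), `strand`, `score`.
#' @export
scan_pwm <- function(windows, p, threshold_fraction = 0.8,
                     both_strands = TRUE) {
  stopifnot(inherits(p, "pwm"))
  nm <- names(windows)
  seqs <- as.character(windows)
  names(seqs) <- if (is.null(nm)) sprintf("window%d", seq_along(seqs)) else nm
  W <- unique(nchar(seqs))
  if (length(W) != 1)
    stop("windows must have equal width", call. = FALSE)
  L <- nrow(p$probs)
  if (W < L)
    stop("window length must be >= motif length", call. = FALSE)

  bmat <- matrix(match(unlist(strsplit(toupper(seqs), "")),
                       c("A", "C", "G", "T")),
                 nrow = length(seqs), ncol = W, byrow = TRUE)
  smat <- pwm_score_matrix(p)
  max_score <- sum(apply(smat, 1, max))
  thr <- threshold_fraction * max_score

  collect <- function(scores, strand) {
    hit <- !is.na(scores) & max_score > 0 & scores >= thr
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) == 0)
      return(data.frame(window_id = character(), motif_id = character(),
                        offset = integer(), strand = character(),
                        score = numeric(), stringsAsFactors = FALSE))
    data.frame(window_id = names(seqs)[idx[, 1]], motif_id = p$motif_id,
               offset = idx[, 2] - 1L, strand = strand,
               score = scores[idx], stringsAsFactors = FALSE)
  }
  out <- collect(.scan_one_strand(bmat, smat), "+")
  if (both_strands) {
    smat_rc <- pwm_score_matrix(pwm_revcomp(p))
    out <- rbind(out, collect(.scan_one_strand(bmat, smat_rc), "-"))
  }
  out <- out[order(out$window_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment of hypermethylated windows vs the array background
#'
#' The counting unit is the window: a window is motif-positive iff it
#' carries at least one hit. Enrichment of positive windows among the
#' hypermethylated windows relative to all background windows is tested
#' with the exact upper-tail hypergeometric
#' ([hypergeometric_enrichment()]).
#'
#' @param hyper_windows Windows around hypermethylated CpGs (names must be
#'   a subset of the background names).
#' @param background_windows Windows around all array CpGs.
#' @inheritParams scan_pwm
#' @return One-row enrichment record `data.frame`.
#' @export
motif_enrichment <- function(hyper_windows, background_windows, p,
                             threshold_fraction = 0.8, both_strands = TRUE) {
  if (length(background_windows) == 0)
    stop("empty background window set", call. = FALSE)
  hn <- names(hyper_windows)
  bn <- names(background_windows)
  if (is.null(hn) || is.null(bn) || !all(hn %in% bn))
    stop("hyper windows must be a named subset of the background windows",
         call. = FALSE)
  hits <- scan_pwm(background_windows, p, threshold_fraction, both_strands)
  positive <- unique(hits$window_id)
  hypergeometric_enrichment(hn, positive, bn, category = p$motif_id)
}

#' Peak co-location around hypermethylated CpGs at multiple window widths
#'
#' A CpG is peak-positive at width `w` iff any (merged) peak interval
#' intersects `[pos - w/2, pos + w/2)`. For each width, the 2x2 table
#' (hyper vs non-hyper sites x peak-positive vs not) is tested one-sided
#' for enrichment with Fisher's exact test. Peak-positivity is monotone in
#' width (nested windows), so the reported proportions are non-decreasing.
#'
#' @param hyper_ids CpG ids called hypermethylated (subset of the manifest).
#' @param man Manifest `data.frame` — all its CpGs form the background.
#' @param peaks Peak intervals `data.frame` (`chrom`, `start`, `end`),
#'   e.g. from [read_bed()]; merged before intersection.
#' @param widths Co-location window widths in bp
#'   (default `c(124, 200, 500, 1000)`).
#' @return `data.frame` with one row per width: `width`, `n_hyper`,
#'   `n_background`, `prop_hyper`, `prop_background` (proportion among all
#'   array CpGs), `p`.
#' @export
peak_colocation <- function(hyper_ids, man, peaks,
                            widths = c(124, 200, 500, 1000)) {
  if (!all(hyper_ids %in% man$cpg_id))
    stop("hyper sites must be a subset of the manifest", call. = FALSE)
  is_hyper <- man$cpg_id %in% hyper_ids
  n_h <- sum(is_hyper)
  n_all <- nrow(man)
  merged <- merge_intervals(peaks)
  out <- lapply(widths, function(w) {
    if (nrow(merged) == 0)
      return(data.frame(width = w, n_hyper = n_h, n_background = n_all,
                        prop_hyper = 0, prop_background = 0, p = 1))
    positive <- logical(n_all)
    half <- w %/% 2
    for (ch in unique(man$chrom)) {
      sel <- which(man$chrom == ch)
      pk <- merged[merged$chrom == ch, , drop = FALSE]
      if (nrow(pk) == 0) next
      positive[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(man$pos[sel] - half + 1L,
                         man$pos[sel] - half + w),
        IRanges::IRanges(pk$start + 1L, pk$end))
    }
    a <- sum(positive & is_hyper)
    b <- n_h - a
    c_ <- sum(positive & !is_hyper)
    d <- (n_all - n_h) - c_
    p <- if (n_h == 0) 1 else
      fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                  alternative = "greater")$p.value
    data.frame(width = w, n_hyper = n_h, n_background = n_all,
               prop_hyper = if (n_h == 0) 0 else a / n_h,
               prop_background = sum(positive) / n_all, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
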