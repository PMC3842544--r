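# Paired differential methylation: variance confinement, moderated paired
# t-testing, FDR adjustment, direction calls and cross-contrast overlaps.

#' Confine sites to the most variable fraction
#'
#' Retains the `ceil(keep_fraction * n_sites)` sites with the highest
#' across-sample variance of beta (unbiased sample variance over all
#' samples of all conditions, missing values excluded). Ties at the cutoff
#' are broken by site order; the order of retained sites is preserved.
#'
#' @param bm A [beta_matrix()].
#' @param keep_fraction Fraction of sites to keep, in `(0, 1]`.
#' @return A [beta_matrix()] restricted to the retained sites.
#' @export
variance_filter <- function(bm, keep_fraction) {
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      is.na(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  if (ncol(bm$values) < 2)
    stop("variance filter needs at least 2 samples", call. = FALSE)
  v <- row_vars_na(bm$values)
  v[is.na(v)] <- -Inf
  m <- ceiling(keep_fraction * nrow(bm$values))
  keep <- sort(order(-v, seq_along(v))[seq_len(m)])
  beta_matrix(bm$values[keep, , drop = FALSE], bm$samples)
}

#' Paired moderated t-test per CpG site
#'
#' For each site, computes the mean `delta` of per-pair beta differences
#' (`condition_b - condition_a`), the sample variance `s2` of those
#' differences, and a moderated t-statistic with posterior variance
#' `(d0 s0^2 + df s2) / (d0 + df)` on `d0 + df` degrees of freedom. With
#' `prior_df = 0` this is the ordinary paired t-test. Donor pairs missing
#' either value at a site are excluded pairwise; sites with fewer than two
#' complete pairs are dropped (with a message).
#'
#' @param bm A [beta_matrix()].
#' @param design A [paired_design()].
#' @param moderation `"estimate"` (moment-matched hyperparameters,
#'   default), `"none"` (ordinary paired t), or a [moderation_params()].
#' @return `data.frame` of site statistics (`cpg_id`, `delta`, `s2`, `df`,
#'   `t_mod`, `p`, `adj_p` = NA, `direction` = NA), with the moderation used
#'   attached as attribute `"moderation"` and the number of dropped sites as
#'   attribute `"n_dropped"`.
#' @export
paired_moderated_t <- function(bm, design, moderation = "estimate") {
  stopifnot(inherits(design, "paired_design"))
  a <- bm$values[, design$pairs$sample_a, drop = FALSE]
  b <- bm$values[, design$pairs$sample_b, drop = FALSE]
  core <- paired_stats_core(b - a, moderation)
  n_dropped <- sum(!core$testable)
  if (n_dropped == nrow(bm$values))
    stop("no site has >= 2 complete donor pairs", call. = FALSE)
  if (n_dropped > 0)
    message(n_dropped, " site(s) dropped with < 2 complete pairs")
  keep <- core$testable
  out <- data.frame(
    cpg_id = rownames(bm$values)[keep],
    delta = core$delta[keep],
    s2 = core$s2[keep],
    df = core$df[keep],
    t_mod = core$t_mod[keep],
    p = core$p[keep],
    adj_p = NA_real_,
    direction = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "moderation") <- core$moderation
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control. Input p-values must lie in
#' `(0, 1]`; adjusted values are monotone in rank, never smaller than the
#' raw value, and capped at 1.
#'
#' @param pvals Numeric vector of raw p-values. A p-value of exactly 0 is
#'   accepted (it arises from the zero-variance policy) and stays 0.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(pvals) {
  if (any(is.na(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Call hyper/hypo/ns directions
#'
#' A site is `hyper` iff `adj_p < alpha` and `delta > 0`, `hypo` iff
#' `adj_p < alpha` and `delta < 0`, otherwise `ns`.
#'
#' @param stats Site-statistics `data.frame` with `adj_p` set.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return The input with `direction` filled in; counts are attached as
#'   attribute `"summary"` (`n_hyper`, `n_hypo`, `n_ns`).
#' @export
call_directions <- function(stats, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(is.na(stats$adj_p)))
    stop("adj_p must be set before calling directions", call. = FALSE)
  sig <- stats$adj_p < alpha
  stats$direction <- ifelse(sig & stats$delta > 0, "hyper",
                            ifelse(sig & stats$delta < 0, "hypo", "ns"))
  attr(stats, "summary") <- c(n_hyper = sum(stats$direction == "hyper"),
                              n_hypo = sum(stats$direction == "hypo"),
                              n_ns = sum(stats$direction == "ns"))
  stats
}

#' Full differential-methylation pipeline for one contrast
#'
#' Convenience wrapper: [variance_filter()] then [paired_moderated_t()],
#' [adjust_pvalues()] and [call_directions()].
#'
#' @inheritParams paired_moderated_t
#' @inheritParams variance_filter
#' @inheritParams call_directions
#' @return Site statistics with directions called (see [call_directions()]).
#' @export
differential_methylation <- function(bm, design, keep_fraction = 0.5,
                                     alpha = 0.05, moderation = "estimate") {
  bm <- variance_filter(bm, keep_fraction)
  stats <- paired_moderated_t(bm, design, moderation)
  stats$adj_p <- adjust_pvalues(stats$p)
  call_directions(stats, alpha)
}

#' Venn decomposition of direction-call sets
#'
#' Given named sets of CpG ids (one per contrast), counts every region of
#' the Venn decomposition: for each non-empty subset of contrasts, the
#' number of ids in all members of the subset and none of the others. The
#' counts sum to the size of the union.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return `data.frame` with columns `members` (contrast names joined by
#'   `&`), `n_sets` and `count`.
#' @export
overlap_comparisons <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("need >= 2 named sets", call. = FALSE)
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    apply(utils::combn(names(sets), k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = combos))
  data.frame(members = combos,
             n_sets = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
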