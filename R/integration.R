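# Methylation-expression integration: paired differential expression,
# extreme-expression deciles, context-resolved methylation of gene sets,
# and the promoter-hypermethylation x down-regulation quadrant test.

#' Paired differential expression per gene
#'
#' Paired (moderated) t-test on log2 intensities, donor-matched as in
#' [paired_moderated_t()]; Benjamini-Hochberg adjustment and up/down/ns
#' direction calls. With `moderation = "none"` this is the classical paired
#' t-test. Genes with zero variance of pair differences and a nonzero fold
#' change get `p = 0` under the zero-variance policy (with a prior the
#' posterior variance is positive and the policy never triggers).
#'
#' @param expr An [expression_matrix()].
#' @param design A [paired_design()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param moderation `"estimate"`, `"none"`, or [moderation_params()].
#' @return `data.frame`: `gene_id`, `lfc` (mean paired log2 fold change),
#'   `s2`, `df`, `t_mod`, `p`, `adj_p`, `direction` (`up`/`down`/`ns`).
#' @export
differential_expression <- function(expr, design, alpha = 0.05,
                                    moderation = "estimate") {
  stopifnot(inherits(design, "paired_design"))
  if (nrow(design$pairs) < 2)
    stop("differential expression needs >= 2 pairs", call. = FALSE)
  a <- expr$values[, design$pairs$sample_a, drop = FALSE]
  b <- expr$values[, design$pairs$sample_b, drop = FALSE]
  core <- paired_stats_core(b - a, moderation)
  out <- data.frame(
    gene_id = rownames(expr$values),
    lfc = core$delta, s2 = core$s2, df = core$df,
    t_mod = core$t_mod, p = core$p,
    adj_p = NA_real_, direction = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
  out$adj_p <- adjust_pvalues(out$p)
  sig <- out$adj_p < alpha
  out$direction <- ifelse(sig & out$lfc > 0, "up",
                          ifelse(sig & out$lfc < 0, "down", "ns"))
  attr(out, "moderation") <- core$moderation
  out
}

#' Extreme-expression gene deciles
#'
#' Ranks genes by mean signal intensity across all samples and returns the
#' top and bottom 10 percent (ceiling). Ties are broken deterministically
#' by gene id.
#'
#' @param expr An [expression_matrix()].
#' @return List with character vectors `top` (highest expression) and
#'   `bottom`.
#' @export
expression_deciles <- function(expr) {
  if (nrow(expr$values) < 10)
    stop("need at least 10 genes", call. = FALSE)
  ids <- rownames(expr$values)
  m <- rowMeans(expr$values)
  k <- ceiling(0.1 * length(ids))
  top <- ids[order(-m, ids)[seq_len(k)]]
  bottom <- ids[order(m, ids)[seq_len(k)]]
  list(top = top, bottom = bottom)
}

#' Mean methylation of a gene set by genomic context
#'
#' Averages beta values over all (site, sample) observations of CpGs
#' affiliated with the gene set, stratified by gene-region label and
#' CGI-relation class. A CpG affiliated with a set gene under several
#' labels contributes to each of its label cells.
#'
#' @param gene_set Character vector of gene ids.
#' @param man Manifest `data.frame`.
#' @param bm A [beta_matrix()].
#' @return `data.frame` with `region`, `cgi_relation`, `mean_beta` and `n`
#'   (number of non-missing site-sample observations in the cell).
#' @export
mean_dnam_by_context <- function(gene_set, man, bm) {
  aff <- manifest_affiliations(man)
  aff <- aff[!is.na(aff$gene_id) & aff$gene_id %in% gene_set, , drop = FALSE]
  aff <- aff[aff$cpg_id %in% rownames(bm$values), , drop = FALSE]
  if (nrow(aff) == 0)
    stop("gene set has no CpG in the manifest/beta matrix", call. = FALSE)
  aff$cgi <- man$cgi_relation[match(aff$cpg_id, man$cpg_id)]
  aff <- unique(aff[, c("cpg_id", "region", "cgi")])
  cells <- unique(aff[, c("region", "cgi")])
  cells <- cells[order(match(cells$region, REGION_LABELS),
                       match(cells$cgi, CGI_CLASSES)), , drop = FALSE]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sites <- aff$cpg_id[aff$region == cells$region[i] &
                          aff$cgi == cells$cgi[i]]
    v <- bm$values[sites, , drop = FALSE]
    data.frame(region = cells$region[i], cgi_relation = cells$cgi[i],
               mean_beta = mean(v, na.rm = TRUE), n = sum(!is.na(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Promoter hypermethylation vs expression down-regulation
#'
#' Joins differential methylation and differential expression by gene id
#' and tests, over the joined gene universe, whether genes carrying a
#' hypermethylated CpG in the given region label are enriched among
#' down-regulated genes (one-sided Fisher's exact test on the 2x2
#' quadrant table).
#'
#' The expression side classifies a gene as down-regulated by raw p-value
#' (`p < de_alpha` and negative fold change) by default, matching the
#' figure-style `p < 0.05` criterion of scatter analyses; set
#' `down_rule = "adjusted"` to require a BH-called `down` direction
#' instead.
#'
#' @param dm Site statistics with directions ([call_directions()]).
#' @param de Differential-expression table ([differential_expression()]).
#' @param man Manifest `data.frame`.
#' @param region_filter Gene-region label restricting the methylation side
#'   (default `"TSS200"`).
#' @param de_alpha Significance level for the down-regulation call
#'   (default 0.05).
#' @param down_rule `"raw"` (raw p, default) or `"adjusted"` (BH-called
#'   direction).
#' @return List with `table` (2x2 integer matrix, rows hyper-in-region
#'   yes/no, columns down-regulated yes/no), `p` (one-sided Fisher),
#'   `n_genes`, and `genes` (the per-gene indicator `data.frame`).
#' @export
dm_de_association <- function(dm, de, man, region_filter = "TSS200",
                              de_alpha = 0.05,
                              down_rule = c("raw", "adjusted")) {
  down_rule <- match.arg(down_rule)
  if (!region_filter %in% REGION_LABELS)
    stop("unknown region label: ", region_filter, call. = FALSE)
  aff <- manifest_affiliations(man)
  aff <- aff[!is.na(aff$gene_id), , drop = FALSE]
  universe <- intersect(unique(aff$gene_id), de$gene_id)
  if (length(universe) == 0)
    stop("empty gene join between methylation and expression",
         call. = FALSE)
  hyper_sites <- dm$cpg_id[dm$direction == "hyper"]
  hyper_genes <- unique(aff$gene_id[aff$region == region_filter &
                                      aff$cpg_id %in% hyper_sites])
  down_genes <- if (down_rule == "raw")
    de$gene_id[de$p < de_alpha & de$lfc < 0]
  else de$gene_id[de$direction == "down"]
  genes <- data.frame(
    gene_id = universe,
    hyper_in_region = universe %in% hyper_genes,
    down_regulated = universe %in% down_genes,
    stringsAsFactors = FALSE)
  tab <- matrix(c(
    sum(genes$hyper_in_region & genes$down_regulated),
    sum(!genes$hyper_in_region & genes$down_regulated),
    sum(genes$hyper_in_region & !genes$down_regulated),
    sum(!genes$hyper_in_region & !genes$down_regulated)), nrow = 2,
    dimnames = list(hyper = c("yes", "no"), down = c("yes", "no")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p = p, n_genes = length(universe), genes = genes)
}
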