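# Genomic-context assignment and enrichment: CGI island/shore/shelf
# classification by distance to merged island edges, strand-aware
# gene-region labels from gene models, and exact hypergeometric / one-sided
# Fisher enrichment against the array background.

#' Classify positions relative to CpG islands
#'
#' Islands are merged first (adjacent or overlapping intervals cannot split
#' a classification). A position inside an island is `Island`; within
#' `shore_width` bp outside the nearest island edge, `Shore`; within the
#' next `shelf_width` bp, `Shelf`; otherwise `OpenSea`. Distance is counted
#' in bases outside the island, so the first base past an edge has
#' distance 1.
#'
#' @param chrom,pos Parallel vectors of chromosome and 0-based position.
#' @param cgi `data.frame` of island intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_bed()].
#' @param shore_width,shelf_width Zone widths in bp (defaults 2000 each).
#' @return Character vector over [CGI_CLASSES].
#' @export
assign_cgi_relation <- function(chrom, pos, cgi, shore_width = 2000,
                                shelf_width = 2000) {
  merged <- merge_intervals(cgi)
  out <- rep("OpenSea", length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    isl <- merged[merged$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0) next
    s <- isl$start; e <- isl$end
    p <- pos[sel]
    idx <- findInterval(p, s)          # last island starting at or before p
    inside <- idx >= 1L & p < e[pmax(idx, 1L)]
    d_left <- ifelse(idx >= 1L, p - e[pmax(idx, 1L)] + 1L, Inf)
    d_right <- ifelse(idx < length(s), s[pmin(idx + 1L, length(s))] - p, Inf)
    d <- pmin(d_left, d_right)
    cls <- ifelse(inside, "Island",
                  ifelse(d <= shore_width, "Shore",
                         ifelse(d <= shore_width + shelf_width, "Shelf",
                                "OpenSea")))
    out[sel] <- cls
  }
  out
}

#' Construct a gene-model table
#'
#' One row per gene with strand-annotated transcription start site and the
#' 0-based half-open bounds of its 5'UTR, first exon, body and 3'UTR. The
#' promoter zones TSS200 (0-200 bp upstream of the TSS) and TSS1500
#' (200-1500 bp upstream) are derived from `tss` and `strand`.
#'
#' @param gene_id,chrom,strand,tss Per-gene vectors; `tss` is the 0-based
#'   position of the first transcribed base.
#' @param utr5_start,utr5_end,exon1_start,exon1_end,body_start,body_end,utr3_start,utr3_end
#'   Zone bounds (0-based half-open).
#' @export
gene_models <- function(gene_id, chrom, strand, tss,
                        utr5_start, utr5_end, exon1_start, exon1_end,
                        body_start, body_end, utr3_start, utr3_end) {
  gm <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = tss,
                   utr5_start = utr5_start, utr5_end = utr5_end,
                   exon1_start = exon1_start, exon1_end = exon1_end,
                   body_start = body_start, body_end = body_end,
                   utr3_start = utr3_start, utr3_end = utr3_end,
                   stringsAsFactors = FALSE)
  if (any(!gm$strand %in% c("+", "-")))
    stop("gene model strand must be '+' or '-'", call. = FALSE)
  bounds <- gm[, grep("_(start|end)$", names(gm))]
  if (any(bounds < 0) || any(gm[, grep("_start$", names(gm))] >=
                             gm[, grep("_end$", names(gm))]))
    stop("malformed gene model bounds", call. = FALSE)
  gm
}

# Long table of labeled zones for a gene-model table.
gene_zones <- function(gm) {
  plus <- gm$strand == "+"
  z <- function(label, s, e) data.frame(gene_id = gm$gene_id,
                                        chrom = gm$chrom, label = label,
                                        start = s, end = e,
                                        stringsAsFactors = FALSE)
  zones <- rbind(
    z("TSS200", ifelse(plus, gm$tss - 200L, gm$tss + 1L),
      ifelse(plus, gm$tss, gm$tss + 201L)),
    z("TSS1500", ifelse(plus, gm$tss - 1500L, gm$tss + 201L),
      ifelse(plus, gm$tss - 200L, gm$tss + 1501L)),
    z("UTR5", gm$utr5_start, gm$utr5_end),
    z("Exon1", gm$exon1_start, gm$exon1_end),
    z("Body", gm$body_start, gm$body_end),
    z("UTR3", gm$utr3_start, gm$utr3_end)
  )
  zones$start <- pmax(zones$start, 0L)
  zones[zones$start < zones$end, , drop = FALSE]
}

#' Assign gene-region labels to positions
#'
#' Strand-aware: TSS200 is the 200 bp immediately upstream of the TSS,
#' TSS1500 the following 200-1500 bp; the remaining labels come from the
#' gene-model bounds. Positions covered by zones of several genes
#' accumulate all labels; positions covered by none are `Intergenic`.
#'
#' @param chrom,pos Parallel vectors (0-based positions).
#' @param gm A [gene_models()] table.
#' @return `data.frame` with columns `idx` (index into `pos`), `gene_id`
#'   (`NA` for intergenic) and `region`; one row per (position, gene, zone)
#'   assignment plus one `Intergenic` row per unassigned position.
#' @export
assign_gene_region <- function(chrom, pos, gm) {
  zones <- gene_zones(gm)
  hits <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    zn <- zones[zones$chrom == ch, , drop = FALSE]
    if (nrow(zn) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(pos[sel] + 1L, width = 1L),
      IRanges::IRanges(zn$start + 1L, zn$end))
    if (length(ov) == 0) next
    hits[[ch]] <- data.frame(
      idx = sel[S4Vectors::queryHits(ov)],
      gene_id = zn$gene_id[S4Vectors::subjectHits(ov)],
      region = zn$label[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(idx = integer(), gene_id = character(),
               region = character(), stringsAsFactors = FALSE)
  orphan <- setdiff(seq_along(pos), hits$idx)
  if (length(orphan))
    hits <- rbind(hits, data.frame(idx = orphan, gene_id = NA_character_,
                                   region = "Intergenic",
                                   stringsAsFactors = FALSE))
  hits <- hits[order(hits$idx, hits$gene_id, hits$region), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Exact hypergeometric enrichment of a selection in a category
#'
#' Upper-tail probability `P(X >= k)` for `k` category members among the
#' selection, drawn without replacement from a background of `N` sites of
#' which `K` are in the category. Computed exactly via the hypergeometric
#' distribution (no normal approximation). Fold enrichment is
#' `(k/n) / (K/N)`.
#'
#' @param selected Character vector of selected ids (subset of
#'   `background`).
#' @param category_members Character vector of category ids (subset of
#'   `background`).
#' @param background Character vector: the array background.
#' @param category Category name carried into the record.
#' @return One-row `data.frame`: `category, k, n, K, N, fold, p, test`.
#' @export
hypergeometric_enrichment <- function(selected, category_members, background,
                                      category = "category") {
  background <- unique(background)
  selected <- unique(selected)
  category_members <- unique(category_members)
  if (!all(selected %in% background))
    stop("selected sites must be a subset of the background", call. = FALSE)
  if (!all(category_members %in% background))
    stop("category members must be a subset of the background",
         call. = FALSE)
  N <- length(background)
  K <- length(category_members)
  n <- length(selected)
  k <- length(intersect(selected, category_members))
  p <- if (n == 0) 1 else
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
  data.frame(category = category, k = k, n = n, K = K, N = N,
             fold = fold, p = p, test = "hypergeometric",
             stringsAsFactors = FALSE)
}

#' Context-enrichment profile of direction calls
#'
#' For each direction (`hyper`, `hypo`) and each category — the seven
#' gene-region labels and the four CGI-relation classes — tests enrichment
#' of the called CpG sites against all CpG sites of the manifest (the array
#' background) with [hypergeometric_enrichment()].
#'
#' @param stats Site statistics with directions called
#'   ([call_directions()]); all tested sites must be present in `man`.
#' @param man Manifest `data.frame`.
#' @return `data.frame` of enrichment records with a leading `direction`
#'   column.
#' @export
category_enrichment_profile <- function(stats, man) {
  if (!all(stats$cpg_id %in% man$cpg_id))
    stop("direction calls contain sites absent from the manifest",
         call. = FALSE)
  background <- man$cpg_id
  region_sets <- manifest_region_sets(man)
  members <- c(
    lapply(setNames(REGION_LABELS, REGION_LABELS), function(lab) {
      man$cpg_id[vapply(region_sets, function(s) lab %in% s, logical(1))]
    }),
    lapply(setNames(CGI_CLASSES, CGI_CLASSES), function(cls) {
      man$cpg_id[man$cgi_relation == cls]
    })
  )
  out <- lapply(c("hyper", "hypo"), function(dir) {
    sel <- stats$cpg_id[stats$direction == dir]
    recs <- do.call(rbind, lapply(names(members), function(cat) {
      hypergeometric_enrichment(sel, members[[cat]], background, cat)
    }))
    cbind(direction = dir, recs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher gene-set enrichment
#'
#' Tests each gene set for over-representation of the selected genes within
#' the gene universe using the one-sided Fisher's exact test on the 2x2
#' table (in set x selected). Genes are counted once regardless of how many
#' CpGs they carry. Sets with no member in the universe are skipped with a
#' message.
#'
#' @param selected_genes Character vector (subset of `universe_genes`).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe_genes Character vector of background genes.
#' @return `data.frame` of enrichment records (`test = "fisher"`).
#' @export
gene_set_enrichment <- function(selected_genes, gene_sets, universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0)
    stop("empty gene universe", call. = FALSE)
  selected_genes <- unique(intersect(selected_genes, universe_genes))
  N <- length(universe_genes)
  n <- length(selected_genes)
  recs <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe_genes)
    if (length(set) == 0) {
      message("gene set skipped (no member in universe): ", nm)
      return(NULL)
    }
    K <- length(set)
    k <- length(intersect(set, selected_genes))
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(category = nm, k = k, n = n, K = K, N = N,
               fold = if (n == 0) NA_real_ else (k / n) / (K / N),
               p = p, test = "fisher", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p = numeric(), test = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
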