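# CpG manifest: one row per array probe, with gene affiliations, gene-region
# labels (parallel to the gene list) and CpG-island relation. Coordinates are
# 0-based internally; the on-disk manifest carries 1-based positions in the
# Illumina convention and is converted on read/write.

.region_synonyms <- c(
  "TSS1500" = "TSS1500", "TSS200" = "TSS200",
  "UTR5" = "UTR5", "5'UTR" = "UTR5", "5UTR" = "UTR5",
  "Exon1" = "Exon1", "1stExon" = "Exon1",
  "Body" = "Body",
  "UTR3" = "UTR3", "3'UTR" = "UTR3", "3UTR" = "UTR3",
  "Intergenic" = "Intergenic"
)

.cgi_synonyms <- setNames(
  c("Island", "Shore", "Shore", "Shore", "Shelf", "Shelf", "Shelf",
    "OpenSea", "OpenSea"),
  c("Island", "Shore", "N_Shore", "S_Shore", "Shelf", "N_Shelf", "S_Shelf",
    "OpenSea", ""))

#' Read a CpG manifest
#'
#' Parses a tab-separated probe manifest with columns `ID`, `CHR`, `POS`
#' (1-based), `STRAND`, `GENES` (semicolon list, possibly empty), `REGIONS`
#' (semicolon list parallel to `GENES`) and `CGI_RELATION`. Region and CGI
#' synonyms in common manifest dialects (`1stExon`, `5'UTR`, `N_Shore`, ...)
#' are normalized to the package vocabulary ([REGION_LABELS], [CGI_CLASSES]).
#' Probes without a gene affiliation are labeled `Intergenic`.
#'
#' @param path Path to the tab-separated manifest file.
#' @return A `data.frame` with columns `cpg_id`, `chrom`, `pos` (0-based
#'   position of the C of the CpG), `strand`, `genes`, `regions`
#'   (semicolon-joined, parallel to `genes`) and `cgi_relation`.
#' @export
read_manifest <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  need <- c("ID", "CHR", "POS", "STRAND", "GENES", "REGIONS", "CGI_RELATION")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  man <- data.frame(
    cpg_id = tab$ID, chrom = tab$CHR,
    pos = suppressWarnings(as.integer(tab$POS)) - 1L,
    strand = tab$STRAND,
    genes = tab$GENES, regions = tab$REGIONS,
    cgi_relation = tab$CGI_RELATION,
    stringsAsFactors = FALSE
  )
  normalize_manifest(man)
}

# Normalize tokens and enforce the manifest invariants. Row numbers in error
# messages refer to data rows of the file (header excluded).
normalize_manifest <- function(man) {
  dup <- man$cpg_id[duplicated(man$cpg_id)]
  if (length(dup))
    stop("duplicate cpg_id in manifest: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_pos <- which(is.na(man$pos) | man$pos < 0L)
  if (length(bad_pos))
    stop("invalid position at manifest row ", bad_pos[1], call. = FALSE)
  bad_strand <- which(!man$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("invalid strand at manifest row ", bad_strand[1], call. = FALSE)

  genes <- split_semi(man$genes)
  regions <- split_semi(man$regions)
  for (i in seq_along(regions)) {
    if (length(genes[[i]]) == 0L) {
      # No gene affiliation: forced Intergenic. A gene-region token without a
      # gene is an inconsistent row.
      if (length(regions[[i]]) &&
          any(!regions[[i]] %in% c("Intergenic", "")))
        stop("manifest row ", i, ": gene-region label without a gene",
             call. = FALSE)
      regions[[i]] <- "Intergenic"
      next
    }
    if (length(regions[[i]]) != length(genes[[i]]))
      stop("manifest row ", i, ": REGIONS not parallel to GENES",
           call. = FALSE)
    tok <- .region_synonyms[regions[[i]]]
    if (anyNA(tok))
      stop("manifest row ", i, ": unknown region token '",
           regions[[i]][which(is.na(tok))[1]], "'", call. = FALSE)
    if (any(tok == "Intergenic"))
      stop("manifest row ", i,
           ": Intergenic is mutually exclusive with gene labels",
           call. = FALSE)
    regions[[i]] <- unname(tok)
  }
  cgi_in <- ifelse(is.na(man$cgi_relation) | man$cgi_relation == "",
                   "OpenSea", man$cgi_relation)
  cgi <- .cgi_synonyms[cgi_in]
  if (anyNA(cgi))
    stop("unknown CGI relation token '",
         man$cgi_relation[which(is.na(cgi))[1]], "' at manifest row ",
         which(is.na(cgi))[1], call. = FALSE)

  man$genes <- join_semi(genes)
  man$regions <- join_semi(regions)
  man$cgi_relation <- unname(cgi)
  man
}

#' Write a CpG manifest
#'
#' Inverse of [read_manifest()]; positions are written 1-based.
#'
#' @param man Manifest `data.frame` as returned by [read_manifest()].
#' @param path Output path.
#' @export
write_manifest <- function(man, path) {
  out <- data.frame(ID = man$cpg_id, CHR = man$chrom, POS = man$pos + 1L,
                    STRAND = man$strand, GENES = man$genes,
                    REGIONS = man$regions, CGI_RELATION = man$cgi_relation,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long view of manifest gene affiliations
#'
#' Expands the semicolon-joined gene/region fields into one row per
#' (probe, gene) affiliation. Intergenic probes get `gene_id = NA` and
#' `region = "Intergenic"`.
#'
#' @param man Manifest `data.frame`.
#' @return `data.frame` with columns `cpg_id`, `gene_id`, `region`.
#' @export
manifest_affiliations <- function(man) {
  genes <- split_semi(man$genes)
  regions <- split_semi(man$regions)
  nrep <- pmax(lengths(genes), 1L)
  gid <- unlist(lapply(genes, function(g) if (length(g)) g else NA_character_))
  reg <- unlist(regions)
  data.frame(cpg_id = rep(man$cpg_id, nrep), gene_id = gid, region = reg,
             stringsAsFactors = FALSE)
}

# Per-site list of unique region labels.
manifest_region_sets <- function(man) {
  lapply(split_semi(man$regions), unique)
}
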