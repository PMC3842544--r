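# YAML-configured end-to-end pipeline: simulate -> differential
# methylation -> context/gene-set enrichment -> motif scan -> peak
# co-location -> expression integration, writing every stage product and a
# JSON run manifest into a run directory. Outputs are a pure function of
# the config: every stochastic stage is seeded from the config seed, no
# wall-clock state is recorded, and re-running reproduces the files byte
# for byte.

.default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_cpg = 10000L, n_genes = 300L, n_donors = 3L),
    dm = list(contrasts = NULL, keep_fraction = 0.5, alpha = 0.05,
              moderation = "estimate"),
    enrich = list(),
    motif = list(threshold_fraction = 0.8),
    colocate = list(widths = c(124L, 200L, 500L, 1000L)),
    integrate = list(region = "TSS200")
  )
}

# Validate the config before any stage runs; returns the merged config.
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  merged <- utils::modifyList(.default_pipeline_config(), config)
  if (is.null(merged$seed)) stop("config must set a seed", call. = FALSE)
  sim_args <- merged$simulate
  sim_args$seed <- merged$seed
  scfg <- do.call(sim_config, sim_args)
  contrasts <- merged$dm$contrasts
  if (is.null(contrasts))
    contrasts <- lapply(scfg$conditions[-1],
                        function(b) c(scfg$conditions[1], b))
  for (ct in contrasts) {
    if (length(ct) != 2)
      stop("each contrast must name two conditions", call. = FALSE)
    bad <- setdiff(ct, scfg$conditions)
    if (length(bad))
      stop("contrast names unknown condition: ", bad[1], call. = FALSE)
  }
  kf <- merged$dm$keep_fraction
  if (kf <= 0 || kf > 1) stop("dm.keep_fraction must be in (0, 1]",
                              call. = FALSE)
  if (merged$dm$alpha <= 0 || merged$dm$alpha >= 1)
    stop("dm.alpha must be in (0, 1)", call. = FALSE)
  if (!merged$integrate$region %in% REGION_LABELS)
    stop("integrate.region must be a gene-region label", call. = FALSE)
  merged$dm$contrasts <- contrasts
  merged$sim_config <- scfg
  merged
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages: simulate (manifest, beta matrix, windows, peaks, expression,
#' gene sets written as the standard text formats), differential
#' methylation per contrast, overlap of direction calls, context and
#' gene-set enrichment, motif enrichment, peak co-location, and
#' methylation-expression integration. Every stage reads its inputs back
#' from the files written by the previous stages, so the run directory is
#' self-contained, and a `run_manifest.json` records parameters, seed,
#' package version and per-stage row counts.
#'
#' @param config Path to a YAML config or an equivalent list. Sections:
#'   `seed`, `simulate` (arguments of [sim_config()]), `dm`
#'   (`contrasts`, `keep_fraction`, `alpha`, `moderation`), `motif`
#'   (`threshold_fraction`), `colocate` (`widths`), `integrate`
#'   (`region`).
#' @param outdir Run directory (created; files are overwritten).
#' @return Invisibly, the run directory path.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- validate_pipeline_config(config)
  scfg <- cfg$sim_config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- file.path(outdir, "inputs")
  dir.create(inp, showWarnings = FALSE)
  counts <- list()
  stage <- function(name) message("[cpgdrift] stage: ", name)

  # --- simulate -------------------------------------------------------
  stage("simulate")
  sim <- simulate_manifest(scfg)
  sb <- simulate_beta(scfg, sim)
  sp <- simulate_sequences_and_peaks(scfg, sim, sb$truth)
  se <- simulate_expression(scfg, sim, sp$truth)
  truth <- se$truth
  sets <- simulate_gene_sets(scfg, sim, truth)

  write_manifest(sim$manifest, file.path(inp, "manifest.tsv"))
  write_bed(sim$cgi, file.path(inp, "cgi.bed"))
  write_beta_matrix(sb$beta, file.path(inp, "beta.tsv"),
                    file.path(inp, "samples.tsv"))
  Biostrings::writeXStringSet(sp$windows, file.path(inp, "windows.fa"))
  write_bed(sp$peaks, file.path(inp, "peaks.bed"))
  write_expression_matrix(se$expr, file.path(inp, "expression.tsv"),
                          file.path(inp, "expr_samples.tsv"))
  write_gmt(sets, file.path(inp, "gene_sets.gmt"))
  write_tsv_exact(
    data.frame(cpg_id = truth$planted_sites,
               true_delta = unname(truth$true_delta),
               stringsAsFactors = FALSE),
    file.path(inp, "truth_planted.tsv"))
  counts$simulate <- list(n_cpg = nrow(sim$manifest),
                          n_samples = ncol(sb$beta$values),
                          n_peaks = nrow(sp$peaks),
                          n_genes = nrow(se$expr$values))

  # --- differential methylation --------------------------------------
  stage("dm")
  man <- read_manifest(file.path(inp, "manifest.tsv"))
  bm <- read_beta_matrix(file.path(inp, "beta.tsv"),
                         file.path(inp, "samples.tsv"))
  dm_list <- list()
  for (ct in cfg$dm$contrasts) {
    design <- paired_design(bm$samples, ct[1], ct[2])
    dm <- differential_methylation(bm, design,
                                   keep_fraction = cfg$dm$keep_fraction,
                                   alpha = cfg$dm$alpha,
                                   moderation = cfg$dm$moderation)
    nm <- paste(ct[1], ct[2], sep = "__vs__")
    dm_list[[nm]] <- dm
    write_results(dm, file.path(outdir, paste0("dm_", nm, ".tsv")))
    s <- attr(dm, "summary")
    counts[[paste0("dm_", nm)]] <- as.list(s)
  }
  hyper_sets <- lapply(dm_list, function(d) d$cpg_id[d$direction == "hyper"])
  if (length(hyper_sets) >= 2) {
    ov <- overlap_comparisons(hyper_sets)
    write.table(ov, file.path(outdir, "overlap_hyper.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts$overlap_hyper <- list(n_regions = nrow(ov))
  }
  dm1 <- dm_list[[1]]

  # --- context + gene-set enrichment ---------------------------------
  stage("enrich")
  prof <- category_enrichment_profile(dm1, man)
  write_results(prof, file.path(outdir, "context_enrichment.tsv"))
  aff <- manifest_affiliations(man)
  aff <- aff[!is.na(aff$gene_id), ]
  hyper_genes <- unique(aff$gene_id[aff$cpg_id %in%
                                      dm1$cpg_id[dm1$direction == "hyper"]])
  gse <- gene_set_enrichment(hyper_genes,
                             read_gmt(file.path(inp, "gene_sets.gmt")),
                             unique(aff$gene_id))
  write_results(gse, file.path(outdir, "gene_set_enrichment.tsv"))
  counts$enrich <- list(n_categories = nrow(prof), n_gene_sets = nrow(gse))

  # --- motif enrichment ----------------------------------------------
  stage("motif")
  windows <- Biostrings::readDNAStringSet(file.path(inp, "windows.fa"))
  hyper_ids <- dm1$cpg_id[dm1$direction == "hyper"]
  pw <- pwm_from_consensus(scfg$motif_consensus)
  me <- motif_enrichment(windows[intersect(hyper_ids, names(windows))],
                         windows, pw,
                         threshold_fraction = cfg$motif$threshold_fraction)
  write_results(me, file.path(outdir, "motif_enrichment.tsv"))
  counts$motif <- list(k = me$k, n = me$n, K = me$K)

  # --- peak co-location ----------------------------------------------
  stage("colocate")
  peaks <- read_bed(file.path(inp, "peaks.bed"))
  coloc <- peak_colocation(hyper_ids, man, peaks,
                           widths = cfg$colocate$widths)
  write_tsv_exact(coloc, file.path(outdir, "peak_colocation.tsv"))
  counts$colocate <- list(n_widths = nrow(coloc))

  # --- expression integration ----------------------------------------
  stage("integrate")
  expr <- read_expression_matrix(file.path(inp, "expression.tsv"),
                                 file.path(inp, "expr_samples.tsv"))
  ect <- cfg$dm$contrasts[[1]]
  if (!all(ect %in% expr$samples$condition))
    ect <- c(expr$samples$condition[1],
             setdiff(unique(expr$samples$condition),
                     expr$samples$condition[1])[1])
  de_design <- paired_design(expr$samples, ect[1], ect[2])
  de <- differential_expression(expr, de_design, alpha = cfg$dm$alpha)
  write_tsv_exact(de, file.path(outdir, "differential_expression.tsv"))
  assoc <- dm_de_association(dm1, de, man,
                             region_filter = cfg$integrate$region)
  dec <- expression_deciles(expr)
  ctx_top <- mean_dnam_by_context(dec$top, man, bm)
  ctx_bottom <- mean_dnam_by_context(dec$bottom, man, bm)
  write_tsv_exact(cbind(decile = "top", ctx_top),
                  file.path(outdir, "context_top_decile.tsv"))
  write_tsv_exact(cbind(decile = "bottom", ctx_bottom),
                  file.path(outdir, "context_bottom_decile.tsv"))
  assoc_df <- data.frame(
    region = cfg$integrate$region,
    hyper_down = assoc$table[1, 1], nohyper_down = assoc$table[2, 1],
    hyper_other = assoc$table[1, 2], nohyper_other = assoc$table[2, 2],
    n_genes = assoc$n_genes, p = assoc$p)
  write_tsv_exact(assoc_df, file.path(outdir, "dm_de_association.tsv"))
  counts$integrate <- list(n_genes = assoc$n_genes,
                           p = assoc$p)

  # --- run manifest ---------------------------------------------------
  run_manifest <- list(
    package = "cpgdrift",
    version = as.character(utils::packageVersion("cpgdrift")),
    seed = cfg$seed,
    parameters = list(
      simulate = cfg$simulate,
      dm = list(contrasts = lapply(cfg$dm$contrasts, identity),
                keep_fraction = cfg$dm$keep_fraction,
                alpha = cfg$dm$alpha, moderation = cfg$dm$moderation),
      motif = cfg$motif, colocate = cfg$colocate,
      integrate = cfg$integrate),
    counts = counts)
  jsonlite::write_json(run_manifest,
                       file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report(outdir)
  invisible(outdir)
}

#' Render the plain-text run report
#'
#' Summarizes a completed run directory: per-contrast hyper/hypo counts,
#' the top context-enrichment categories, the motif, co-location and
#' integration tables. Every number is read from a stage output file;
#' regenerating the report from the same directory is byte-identical.
#'
#' @param run_dir Run directory produced by [run_pipeline()].
#' @return Invisibly, the report path.
#' @export
report <- function(run_dir) {
  need <- c("run_manifest.json", "context_enrichment.tsv",
            "motif_enrichment.tsv", "peak_colocation.tsv",
            "dm_de_association.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run, missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rm_json <- jsonlite::read_json(file.path(run_dir, "run_manifest.json"))
  lines <- c("cpgdrift run report",
             "===================",
             sprintf("seed: %s", rm_json$seed), "")
  dm_files <- sort(list.files(run_dir, pattern = "^dm_.*__vs__.*\\.tsv$"))
  for (f in dm_files) {
    dm <- read_results(file.path(run_dir, f))
    lines <- c(lines, sprintf(
      "%s: %d hyper, %d hypo, %d ns (of %d tested)",
      sub("^dm_", "", sub("\\.tsv$", "", f)),
      sum(dm$direction == "hyper"), sum(dm$direction == "hypo"),
      sum(dm$direction == "ns"), nrow(dm)))
  }
  prof <- read_results(file.path(run_dir, "context_enrichment.tsv"))
  hyper <- prof[prof$direction == "hyper", ]
  hyper <- hyper[order(hyper$p), ]
  lines <- c(lines, "", "top hyper-enriched categories (category, fold, p):")
  for (i in seq_len(min(5, nrow(hyper))))
    lines <- c(lines, sprintf("  %-10s fold=%.3f p=%.3g", hyper$category[i],
                              hyper$fold[i], hyper$p[i]))
  hypo <- prof[prof$direction == "hypo", ]
  lines <- c(lines, sprintf("hypo calls in profile: %d",
                            if (nrow(hypo)) hypo$n[1] else 0L))
  me <- read_results(file.path(run_dir, "motif_enrichment.tsv"))
  lines <- c(lines, "", sprintf(
    "motif %s: %d/%d hyper windows vs %d/%d background, p=%.3g",
    me$category, me$k, me$n, me$K, me$N, me$p))
  coloc <- read_tsv(file.path(run_dir, "peak_colocation.tsv"))
  lines <- c(lines, "", "peak co-location (width, prop_hyper, prop_bg, p):")
  for (i in seq_len(nrow(coloc)))
    lines <- c(lines, sprintf("  %4d  %.4f  %.4f  %.3g", coloc$width[i],
                              coloc$prop_hyper[i], coloc$prop_background[i],
                              coloc$p[i]))
  assoc <- read_tsv(file.path(run_dir, "dm_de_association.tsv"))
  lines <- c(lines, "", sprintf(
    "%s hyper x down-regulation: [[%d,%d],[%d,%d]] over %d genes, p=%.3g",
    assoc$region, assoc$hyper_down, assoc$hyper_other, assoc$nohyper_down,
    assoc$nohyper_other, assoc$n_genes, assoc$p))
  path <- file.path(run_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
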