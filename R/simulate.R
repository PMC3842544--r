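# Synthetic-data generator with planted ground truth. Each gene occupies an
# isolated 30 kb tile: a promoter CpG island covers TSS200/5'UTR/first
# exon, so TSS1500 CpGs fall on the island shore by construction and the
# long gene body spans shore, shelf and open sea; an intergenic band hosts
# open-sea CpGs plus, in every third tile, an intergenic island with its
# own shore/shelf neighborhood. Beta values are logit-normal with
# site-specific baselines (islands low, open sea high), donor random
# effects shared across conditions (the paired structure), and a planted
# beta-scale hypermethylation shift in the cultured conditions.

.TILE <- 30000L
.GENE_LEN <- 12400L
.UTR5_LEN <- 120L
.EXON1_LEN <- 300L
.UTR3_LEN <- 400L

.default_region_mixture <- c(TSS1500 = 0.12, TSS200 = 0.07, UTR5 = 0.05,
                             Exon1 = 0.05, Body = 0.41, UTR3 = 0.05,
                             Intergenic = 0.25)

#' Simulation configuration
#'
#' Defaults mirror the study design: four conditions (fresh CD34+ cells and
#' three culture-expanded fractions), three donors, hypermethylation of
#' `+0.15` beta planted in 10 percent of the TSS1500/shore CpGs of every
#' cultured condition, a PU.1-like consensus planted in 30 percent of
#' hypermethylated windows vs 1 percent background, and expression of
#' promoter-hypermethylated genes down-coupled with slope -4 per unit beta.
#'
#' @param n_cpg Number of CpG probes (>= 100).
#' @param n_genes Number of genes (one per 30 kb tile).
#' @param n_donors Number of donors (paired across all conditions).
#' @param conditions Condition names; the first is the uncultured baseline.
#' @param effect_conditions Conditions receiving the planted shift
#'   (default: all but the baseline).
#' @param region_mixture Named probabilities over [REGION_LABELS] for probe
#'   placement.
#' @param effect_categories Region labels and/or CGI classes eligible for
#'   planting.
#' @param effect_fraction Fraction of eligible CpGs planted, in `(0, 1]`.
#' @param effect_delta Beta-scale shift planted in the effect conditions.
#' @param noise_sd,donor_sd Logit-scale measurement noise and donor
#'   random-effect standard deviations.
#' @param motif_consensus Consensus sequence planted in windows.
#' @param motif_plant_rate_fg,motif_plant_rate_bg Planting probabilities in
#'   windows of planted (foreground) vs other (background) CpGs.
#' @param peak_plant_rate_fg,peak_plant_rate_bg Peak planting
#'   probabilities; a planted peak of width `peak_width` is centered within
#'   62 bp of the site.
#' @param peak_width Peak interval width in bp.
#' @param window_width Motif/co-location window width in bp.
#' @param expression_coupling Slope linking planted promoter (TSS200/first
#'   exon) beta shift to differential log2 expression (negative:
#'   hypermethylation represses).
#' @param expression_noise_sd,expression_donor_sd Log2-scale expression
#'   noise and donor effect standard deviations.
#' @param expression_conditions Conditions profiled for expression
#'   (default: the first three, as in the study's 9 arrays).
#' @param seed Integer master seed; every generator draws from a stream
#'   derived from it, so equal configs reproduce output bit for bit.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_cpg = 10000, n_genes = 300, n_donors = 3,
                       conditions = c("CD34pos_d0", "CD34pos_woMSC",
                                      "CD34neg_woMSC", "CD34pos_wMSC"),
                       effect_conditions = NULL,
                       region_mixture = .default_region_mixture,
                       effect_categories = c("TSS1500", "Shore"),
                       effect_fraction = 0.1, effect_delta = 0.15,
                       noise_sd = 0.15, donor_sd = 0.10,
                       motif_consensus = "AAGAGGAAGTG",
                       motif_plant_rate_fg = 0.3, motif_plant_rate_bg = 0.01,
                       peak_plant_rate_fg = 0.3, peak_plant_rate_bg = 0.01,
                       peak_width = 150, window_width = 124,
                       expression_coupling = -4,
                       expression_noise_sd = 0.15,
                       expression_donor_sd = 0.10,
                       expression_conditions = NULL,
                       seed = 1) {
  if (n_cpg < 100) stop("n_cpg must be >= 100", call. = FALSE)
  if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
  if (n_donors < 2) stop("n_donors must be >= 2", call. = FALSE)
  if (length(conditions) < 2 || anyDuplicated(conditions))
    stop("need >= 2 distinct conditions", call. = FALSE)
  if (is.null(effect_conditions)) effect_conditions <- conditions[-1]
  if (!all(effect_conditions %in% conditions[-1]))
    stop("effect_conditions must be non-baseline conditions", call. = FALSE)
  if (is.null(expression_conditions))
    expression_conditions <- conditions[seq_len(min(3, length(conditions)))]
  if (!all(expression_conditions %in% conditions))
    stop("unknown expression condition", call. = FALSE)
  if (!setequal(names(region_mixture), REGION_LABELS) ||
      any(region_mixture < 0) || abs(sum(region_mixture) - 1) > 1e-8)
    stop("region_mixture must be probabilities over the 7 region labels",
         call. = FALSE)
  if (!all(effect_categories %in% c(REGION_LABELS, CGI_CLASSES)))
    stop("unknown effect category", call. = FALSE)
  if (effect_fraction <= 0 || effect_fraction > 1)
    stop("effect_fraction must be in (0, 1]", call. = FALSE)
  for (r in c(motif_plant_rate_fg, motif_plant_rate_bg,
              peak_plant_rate_fg, peak_plant_rate_bg))
    if (r < 0 || r > 1) stop("plant rates must be in [0, 1]", call. = FALSE)
  if (!grepl("^[ACGT]+$", motif_consensus))
    stop("motif_consensus must be over ACGT", call. = FALSE)
  if (window_width %% 2 != 0 || window_width < 2)
    stop("window_width must be even and positive", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 1000)
    stop("seed must be an integer below 2^31 - 1000", call. = FALSE)
  structure(list(
    n_cpg = as.integer(n_cpg), n_genes = as.integer(n_genes),
    n_donors = as.integer(n_donors), conditions = conditions,
    effect_conditions = effect_conditions,
    region_mixture = region_mixture[REGION_LABELS],
    effect_categories = effect_categories,
    effect_fraction = effect_fraction, effect_delta = effect_delta,
    noise_sd = noise_sd, donor_sd = donor_sd,
    motif_consensus = motif_consensus,
    motif_plant_rate_fg = motif_plant_rate_fg,
    motif_plant_rate_bg = motif_plant_rate_bg,
    peak_plant_rate_fg = peak_plant_rate_fg,
    peak_plant_rate_bg = peak_plant_rate_bg,
    peak_width = as.integer(peak_width),
    window_width = as.integer(window_width),
    expression_coupling = expression_coupling,
    expression_noise_sd = expression_noise_sd,
    expression_donor_sd = expression_donor_sd,
    expression_conditions = expression_conditions,
    seed = seed), class = "sim_config")
}

# Gene-model table for the tiled layout: alternating strands, two
# chromosomes, one gene per tile.
.sim_gene_models <- function(n_genes) {
  g <- seq_len(n_genes)
  half_n <- as.integer(ceiling(n_genes / 2))
  chrom <- ifelse(g <= half_n, "chr1", "chr2")
  tile_idx <- ifelse(chrom == "chr1", g, g - half_n) - 1L
  T0 <- tile_idx * .TILE
  plus <- g %% 2L == 1L
  tss <- ifelse(plus, T0 + 2000L, T0 + 2000L + .GENE_LEN - 1L)
  gene_models(
    gene_id = sprintf("gene%04d", g), chrom = chrom,
    strand = ifelse(plus, "+", "-"), tss = tss,
    utr5_start = ifelse(plus, tss, tss - .UTR5_LEN + 1L),
    utr5_end = ifelse(plus, tss + .UTR5_LEN, tss + 1L),
    exon1_start = ifelse(plus, tss + .UTR5_LEN,
                         tss - .UTR5_LEN - .EXON1_LEN + 1L),
    exon1_end = ifelse(plus, tss + .UTR5_LEN + .EXON1_LEN,
                       tss - .UTR5_LEN + 1L),
    body_start = ifelse(plus, tss + .UTR5_LEN + .EXON1_LEN,
                        T0 + 2000L + .UTR3_LEN),
    body_end = ifelse(plus, T0 + 2000L + .GENE_LEN - .UTR3_LEN,
                      tss - .UTR5_LEN - .EXON1_LEN + 1L),
    utr3_start = ifelse(plus, T0 + 2000L + .GENE_LEN - .UTR3_LEN,
                        T0 + 2000L),
    utr3_end = ifelse(plus, T0 + 2000L + .GENE_LEN, T0 + 2000L + .UTR3_LEN)
  )
}

# CGI intervals of the layout: every promoter carries an island flanking
# the TSS; every third tile carries an intergenic island.
.sim_cgis <- function(gm) {
  plus <- gm$strand == "+"
  prom <- data.frame(
    chrom = gm$chrom,
    start = ifelse(plus, gm$tss - 200L, gm$tss - 499L),
    end = ifelse(plus, gm$tss + 500L, gm$tss + 201L),
    stringsAsFactors = FALSE)
  T0 <- ifelse(plus, gm$tss - 2000L, gm$tss - 2000L - .GENE_LEN + 1L)
  inter_sel <- seq_len(nrow(gm)) %% 3L == 0L
  inter <- data.frame(chrom = gm$chrom[inter_sel],
                      start = T0[inter_sel] + 22000L,
                      end = T0[inter_sel] + 22600L,
                      stringsAsFactors = FALSE)
  out <- rbind(prom, inter)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("CGI_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Simulate a CpG manifest, CGI intervals and genome sequences
#'
#' Draws each probe's gene-region label from `region_mixture`, places it
#' uniformly (without replacement, at even offsets so no two CpGs overlap)
#' in a matching zone of a random gene tile, and derives its CGI relation
#' from the layout's islands. Every CpG position carries a CG dinucleotide
#' in the generated genome.
#'
#' @param config A [sim_config()].
#' @param emit_sequences Generate genome sequences (the last random draws
#'   of the op, so skipping them does not change positions or labels).
#' @return List with `manifest`, `cgi` (interval `data.frame` with names),
#'   `genome` (`DNAStringSet` by chromosome, or `NULL`), `gene_models` and
#'   `config`.
#' @export
simulate_manifest <- function(config, emit_sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  gm <- .sim_gene_models(config$n_genes)
  cgi <- .sim_cgis(gm)
  zones <- gene_zones(gm)
  plus <- gm$strand == "+"
  tile0 <- ifelse(plus, gm$tss - 2000L, gm$tss - 2000L - .GENE_LEN + 1L)

  labels <- sample(REGION_LABELS, config$n_cpg, replace = TRUE,
                   prob = config$region_mixture)
  gene_of <- sample.int(config$n_genes, config$n_cpg, replace = TRUE)

  # Zone bounds per probe: gene zone for gene labels, intergenic band for
  # Intergenic (the band is open sea except around the intergenic island).
  zkey <- paste(gm$gene_id[gene_of], labels)
  zs <- integer(config$n_cpg); ze <- integer(config$n_cpg)
  inter <- labels == "Intergenic"
  zs[inter] <- tile0[gene_of[inter]] + 18700L
  ze[inter] <- tile0[gene_of[inter]] + 27500L
  if (any(!inter)) {
    zi <- match(zkey[!inter], paste(zones$gene_id, zones$label))
    if (anyNA(zi)) stop("internal: zone lookup failed", call. = FALSE)
    zs[!inter] <- zones$start[zi]
    ze[!inter] <- zones$end[zi]
  }
  pos <- integer(config$n_cpg)
  for (idx in split(seq_len(config$n_cpg), zkey)) {
    s <- zs[idx[1]]; e <- ze[idx[1]]
    n_slots <- (e - 1L - s) %/% 2L + 1L
    if (length(idx) > n_slots)
      stop("zone too small for the requested probe density: ", zkey[idx[1]],
           call. = FALSE)
    pos[idx] <- s + 2L * (sample.int(n_slots, length(idx)) - 1L)
  }

  chrom <- gm$chrom[gene_of]
  cgi_rel <- assign_cgi_relation(chrom, pos, cgi)
  ord <- order(chrom, pos)
  man <- data.frame(
    cpg_id = sprintf("cg%06d", seq_len(config$n_cpg)),
    chrom = chrom[ord], pos = as.integer(pos[ord]),
    strand = ifelse(labels[ord] == "Intergenic", "+",
                    gm$strand[gene_of[ord]]),
    genes = ifelse(labels[ord] == "Intergenic", "",
                   gm$gene_id[gene_of[ord]]),
    regions = labels[ord],
    cgi_relation = cgi_rel[ord],
    stringsAsFactors = FALSE)

  genome <- NULL
  if (emit_sequences) {
    genome <- Biostrings::DNAStringSet(vapply(
      unique(gm$chrom), function(ch) {
        len <- max(tile0[gm$chrom == ch]) + .TILE
        chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        p <- man$pos[man$chrom == ch]
        chars[p + 1L] <- "C"
        chars[p + 2L] <- "G"
        paste(chars, collapse = "")
      }, character(1)))
  }
  list(manifest = man, cgi = cgi, genome = genome, gene_models = gm,
       config = config)
}

#' Simulate paired beta values with planted hypermethylation
#'
#' Beta is the inverse logit of (site baseline + donor effect + noise);
#' baselines depend on the CGI relation (islands hypomethylated, open sea
#' methylated). A fraction `effect_fraction` of the CpGs in
#' `effect_categories` is planted: their beta in every effect condition is
#' shifted by `effect_delta` (clamped to `[0, 1]`), so the expected paired
#' difference against the baseline condition equals `effect_delta`.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_manifest()].
#' @return List with `beta` (a [beta_matrix()]) and `truth` (class
#'   `ground_truth`: `planted_sites`, `true_delta`, `effect_conditions`).
#' @export
simulate_beta <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  if (config$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (config$donor_sd < 0) stop("donor_sd must be >= 0", call. = FALSE)
  man <- sim$manifest
  n <- nrow(man)
  set.seed(config$seed + 202L)

  base_mu <- c(Island = -2.2, Shore = -1.0, Shelf = 0.0, OpenSea = 0.8)
  base_sd <- c(Island = 0.5, Shore = 0.6, Shelf = 0.6, OpenSea = 0.6)
  mu <- rnorm(n, base_mu[man$cgi_relation], base_sd[man$cgi_relation])

  region_sets <- manifest_region_sets(man)
  eligible <- which(
    vapply(region_sets, function(s) any(s %in% config$effect_categories),
           logical(1)) |
      man$cgi_relation %in% config$effect_categories)
  if (length(eligible) == 0)
    stop("no CpG falls in the configured effect categories", call. = FALSE)
  n_plant <- max(1L, round(config$effect_fraction * length(eligible)))
  planted <- sort(sample(eligible, n_plant))

  donors <- sprintf("D%d", seq_len(config$n_donors))
  samples <- expand.grid(donor = donors, condition = config$conditions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("donor", "condition")]
  samples$sample_id <- paste(samples$condition, samples$donor, sep = "_")
  samples <- samples[, c("sample_id", "donor", "condition")]

  donor_eff <- matrix(rnorm(n * config$n_donors, 0, config$donor_sd), n)
  values <- matrix(NA_real_, n, nrow(samples),
                   dimnames = list(man$cpg_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    dj <- match(samples$donor[j], donors)
    v <- inv_logit(mu + donor_eff[, dj] + rnorm(n, 0, config$noise_sd))
    if (samples$condition[j] %in% config$effect_conditions)
      v[planted] <- pmin(pmax(v[planted] + config$effect_delta, 0), 1)
    values[, j] <- v
  }
  truth <- structure(list(
    planted_sites = man$cpg_id[planted],
    true_delta = setNames(rep(config$effect_delta, n_plant),
                          man$cpg_id[planted]),
    effect_conditions = config$effect_conditions,
    motif_window_ids = NULL, motif_fg_ids = NULL,
    peak_site_ids = NULL, peak_fg_ids = NULL,
    coupled_genes = NULL), class = "ground_truth")
  list(beta = beta_matrix(values, samples), truth = truth)
}

#' Simulate window sequences with planted motifs and ChIP-seq-like peaks
#'
#' Extracts windows around every manifest CpG from the simulated genome,
#' plants the consensus (at a random offset avoiding the central CG) into
#' `motif_plant_rate_fg` of the planted-site windows and
#' `motif_plant_rate_bg` of the rest, and plants peak intervals centered
#' within 62 bp of `peak_plant_rate_fg` / `peak_plant_rate_bg` of the
#' planted / other sites.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_manifest()] (with sequences).
#' @param truth Ground truth from [simulate_beta()].
#' @return List with `windows` (`DNAStringSet` named by cpg_id), `peaks`
#'   (interval `data.frame`) and the extended `truth`.
#' @export
simulate_sequences_and_peaks <- function(config, sim, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sim$genome))
    stop("simulate_manifest() was run without sequences", call. = FALSE)
  W <- config$window_width
  L <- nchar(config$motif_consensus)
  if (L > W) stop("motif consensus longer than the window", call. = FALSE)
  set.seed(config$seed + 303L)
  man <- sim$manifest
  windows <- extract_windows(man, sim$genome, width = W)

  ids <- names(windows)
  fg <- ids %in% truth$planted_sites
  plant <- ifelse(fg, runif(length(ids)) < config$motif_plant_rate_fg,
                  runif(length(ids)) < config$motif_plant_rate_bg)
  c1 <- W %/% 2 + 1L                        # 1-based C of the central CpG
  starts <- seq_len(W - L + 1L)
  allowed <- starts[starts + L - 1L < c1 | starts > c1 + 1L]
  if (length(allowed) == 0) allowed <- starts
  if (any(plant)) {
    s <- allowed[sample.int(length(allowed), sum(plant), replace = TRUE)]
    repl <- Biostrings::DNAStringSet(rep(config$motif_consensus, sum(plant)))
    w2 <- windows[plant]
    Biostrings::subseq(w2, start = s, width = L) <- repl
    windows[plant] <- w2
  }

  peak <- ifelse(fg, runif(length(ids)) < config$peak_plant_rate_fg,
                 runif(length(ids)) < config$peak_plant_rate_bg)
  pk <- NULL
  if (any(peak)) {
    sel <- match(ids[peak], man$cpg_id)
    center <- man$pos[sel] + sample(-62:62, sum(peak), replace = TRUE)
    half <- config$peak_width %/% 2
    pk <- data.frame(chrom = man$chrom[sel],
                     start = pmax(center - half, 0L),
                     end = center - half + config$peak_width,
                     stringsAsFactors = FALSE)
    pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    pk$name <- sprintf("peak_%05d", seq_len(nrow(pk)))
    rownames(pk) <- NULL
  } else {
    pk <- data.frame(chrom = character(), start = integer(),
                     end = integer(), name = character(),
                     stringsAsFactors = FALSE)
  }
  truth$motif_window_ids <- ids[plant]
  truth$motif_fg_ids <- ids[plant & fg]
  truth$peak_site_ids <- ids[peak]
  truth$peak_fg_ids <- ids[peak & fg]
  list(windows = windows, peaks = pk, truth = truth)
}

#' Simulate expression coupled to planted promoter hypermethylation
#'
#' Log2 intensities are gene baseline + donor effect + noise; genes with a
#' planted CpG labeled TSS200 or Exon1 ("coupled" genes) additionally get
#' `expression_coupling * effect_delta` added in every effect condition, so
#' promoter hypermethylation represses expression when the coupling is
#' negative.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_manifest()].
#' @param truth Ground truth from [simulate_beta()].
#' @return List with `expr` (an [expression_matrix()]) and the extended
#'   `truth` (field `coupled_genes`).
#' @export
simulate_expression <- function(config, sim, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  gm <- sim$gene_models
  aff <- manifest_affiliations(sim$manifest)
  coupled <- unique(aff$gene_id[!is.na(aff$gene_id) &
                                  aff$cpg_id %in% truth$planted_sites &
                                  aff$region %in% c("TSS200", "Exon1")])
  n_genes <- nrow(gm)
  donors <- sprintf("D%d", seq_len(config$n_donors))
  samples <- expand.grid(donor = donors,
                         condition = config$expression_conditions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$condition, samples$donor, sep = "_")
  samples <- samples[, c("sample_id", "donor", "condition")]

  mu <- rnorm(n_genes, 7, 1.5)
  donor_eff <- matrix(rnorm(n_genes * config$n_donors, 0,
                            config$expression_donor_sd), n_genes)
  shift <- config$expression_coupling * config$effect_delta
  values <- matrix(NA_real_, n_genes, nrow(samples),
                   dimnames = list(gm$gene_id, samples$sample_id))
  is_coupled <- gm$gene_id %in% coupled
  for (j in seq_len(nrow(samples))) {
    dj <- match(samples$donor[j], donors)
    v <- mu + donor_eff[, dj] + rnorm(n_genes, 0, config$expression_noise_sd)
    if (samples$condition[j] %in% config$effect_conditions)
      v[is_coupled] <- v[is_coupled] + shift
    values[, j] <- v
  }
  truth$coupled_genes <- coupled
  list(expr = expression_matrix(values, samples), truth = truth)
}

#' Simulate gene sets for enrichment testing
#'
#' One set holds the genes carrying any planted CpG (enriched by
#' construction among hypermethylated genes); the rest are random draws
#' from all genes.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_manifest()].
#' @param truth Ground truth from [simulate_beta()].
#' @param n_random Number of random sets.
#' @param set_size Size of each random set.
#' @return Named list of gene-id vectors.
#' @export
simulate_gene_sets <- function(config, sim, truth, n_random = 3,
                               set_size = 30) {
  set.seed(config$seed + 505L)
  aff <- manifest_affiliations(sim$manifest)
  planted_genes <- unique(aff$gene_id[!is.na(aff$gene_id) &
                                        aff$cpg_id %in% truth$planted_sites])
  all_genes <- sim$gene_models$gene_id
  sets <- c(list(PLANTED_GENES = planted_genes),
            setNames(lapply(seq_len(n_random), function(i)
              sort(sample(all_genes, min(set_size, length(all_genes))))),
              sprintf("RANDOM_SET_%d", seq_len(n_random))))
  sets
}
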