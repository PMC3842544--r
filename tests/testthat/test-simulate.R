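test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7)
  s1 <- simulate_manifest(cfg)
  s2 <- simulate_manifest(cfg)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$cgi, s2$cgi)
  expect_identical(as.character(s1$genome), as.character(s2$genome))

  b1 <- simulate_beta(cfg, s1)
  b2 <- simulate_beta(cfg, s2)
  expect_identical(b1$beta$values, b2$beta$values)
  expect_identical(b1$truth$planted_sites, b2$truth$planted_sites)

  p1 <- simulate_sequences_and_peaks(cfg, s1, b1$truth)
  p2 <- simulate_sequences_and_peaks(cfg, s2, b2$truth)
  expect_identical(as.character(p1$windows), as.character(p2$windows))
  expect_identical(p1$peaks, p2$peaks)

  e1 <- simulate_expression(cfg, s1, p1$truth)
  e2 <- simulate_expression(cfg, s2, p2$truth)
  expect_identical(e1$expr$values, e2$expr$values)

  # skipping sequence generation does not change positions or labels
  s3 <- simulate_manifest(cfg, emit_sequences = FALSE)
  expect_null(s3$genome)
  expect_identical(s3$manifest, s1$manifest)
})

test_that("generated coordinates respect the layout invariants", {
  cfg <- small_config(seed = 5)
  sim <- simulate_manifest(cfg)
  man <- sim$manifest

  # every Shore site lies within (0, 2000] of a merged island edge
  merged <- merge_intervals(sim$cgi)
  shore <- man[man$cgi_relation == "Shore", ]
  for (ch in unique(shore$chrom)) {
    sel <- shore[shore$chrom == ch, ]
    expect_true(all(brute_cgi_class(sel$pos,
                                    merged[merged$chrom == ch, ]) == "Shore"))
  }

  # every CpG position carries a CG dinucleotide in the genome
  for (ch in unique(man$chrom)) {
    seqch <- as.character(sim$genome[[ch]])
    p <- man$pos[man$chrom == ch]
    expect_true(all(substring(seqch, p + 1, p + 2) == "CG"))
  }

  # all positions unique and non-adjacent (a CpG occupies two bases)
  expect_false(any(duplicated(paste(man$chrom, man$pos))))
  byc <- split(man$pos, man$chrom)
  expect_true(all(unlist(lapply(byc, function(p) diff(sort(p)) >= 2))))

  # region labels are single per probe here and Intergenic probes carry no gene
  inter <- man$regions == "Intergenic"
  expect_true(all(man$genes[inter] == ""))
  expect_true(all(man$genes[!inter] != ""))
})

test_that("label counts match the configured mixture within 3 sd", {
  cfg <- sim_config(n_cpg = 6000, n_genes = 200, seed = 11)
  sim <- simulate_manifest(cfg, emit_sequences = FALSE)
  counts <- table(factor(sim$manifest$regions, levels = REGION_LABELS))
  expected <- cfg$n_cpg * cfg$region_mixture
  sds <- sqrt(cfg$n_cpg * cfg$region_mixture * (1 - cfg$region_mixture))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("planted beta effects have the configured size", {
  # noiseless limit: observed delta equals effect_delta within 1e-6
  cfg0 <- small_config(seed = 2, noise_sd = 1e-8, donor_sd = 0)
  sim0 <- simulate_manifest(cfg0, emit_sequences = FALSE)
  sb0 <- simulate_beta(cfg0, sim0)
  v <- sb0$beta$values
  sm0 <- sb0$beta$samples
  planted <- sb0$truth$planted_sites
  d0 <- rowMeans(v[planted, sm0$condition == "CD34pos_woMSC",
                   drop = FALSE]) -
    rowMeans(v[planted, sm0$condition == "CD34pos_d0", drop = FALSE])
  expect_true(all(abs(d0 - cfg0$effect_delta) < 1e-6))

  # stochastic case: mean planted delta within 3 standard errors of +0.15
  cfg <- sim_config(n_cpg = 10000, n_genes = 300, seed = 4)
  sim <- simulate_manifest(cfg, emit_sequences = FALSE)
  sb <- simulate_beta(cfg, sim)
  vv <- sb$beta$values
  a <- vv[, sb$beta$samples$condition == "CD34pos_d0"]
  b <- vv[, sb$beta$samples$condition == "CD34pos_woMSC"]
  deltas <- rowMeans(b - a)[sb$truth$planted_sites]
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 0.15), 3 * se)
  # unplanted sites are centered at zero
  null_delta <- rowMeans(b - a)[setdiff(rownames(vv), sb$truth$planted_sites)]
  expect_lt(abs(mean(null_delta)), 3 * sd(null_delta) / sqrt(length(null_delta)))

  # all betas in range, planted sites a subset of the manifest
  expect_true(all(vv >= 0 & vv <= 1))
  expect_true(all(sb$truth$planted_sites %in% sim$manifest$cpg_id))

  expect_error(simulate_beta(small_config(noise_sd = 0),
                             sim0), "noise_sd")
})

test_that("motif and peak planting hit their configured rates", {
  # extreme rates: every planted window carries the consensus, none other
  cfg1 <- small_config(seed = 6, motif_plant_rate_fg = 1,
                       motif_plant_rate_bg = 0)
  sim1 <- simulate_manifest(cfg1)
  sb1 <- simulate_beta(cfg1, sim1)
  sp1 <- simulate_sequences_and_peaks(cfg1, sim1, sb1$truth)
  wchar <- as.character(sp1$windows)
  has_fwd <- grepl(cfg1$motif_consensus, wchar, fixed = TRUE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cfg1$motif_consensus)))
  has_any <- has_fwd | grepl(rc, wchar, fixed = TRUE)
  fg <- names(sp1$windows) %in% sb1$truth$planted_sites
  expect_true(all(has_any[fg]))
  expect_false(any(has_any[!fg]))
  expect_setequal(sp1$truth$motif_fg_ids, names(sp1$windows)[fg])

  # binomial check on the foreground plant count at rate 0.3
  cfg2 <- sim_config(n_cpg = 8000, n_genes = 250, seed = 8,
                     effect_fraction = 0.5)
  sim2 <- simulate_manifest(cfg2)
  sb2 <- simulate_beta(cfg2, sim2)
  sp2 <- simulate_sequences_and_peaks(cfg2, sim2, sb2$truth)
  n_fg <- length(sb2$truth$planted_sites)
  k_fg <- length(sp2$truth$motif_fg_ids)
  expect_lt(abs(k_fg - 0.3 * n_fg), 3 * sqrt(n_fg * 0.3 * 0.7))
  k_pk <- length(sp2$truth$peak_fg_ids)
  expect_lt(abs(k_pk - 0.3 * n_fg), 3 * sqrt(n_fg * 0.3 * 0.7))

  # peaks BED round-trips through the reader
  path <- tempfile(fileext = ".bed")
  write_bed(sp2$peaks, path)
  back <- read_bed(path)
  expect_equal(nrow(back), nrow(sp2$peaks))
  expect_true(all(back$start < back$end))

  # consensus longer than the window is rejected
  cfg_bad <- small_config(window_width = 8,
                          motif_consensus = "AAGAGGAAGTG")
  sim_bad <- simulate_manifest(cfg_bad)
  sb_bad <- simulate_beta(cfg_bad, sim_bad)
  expect_error(simulate_sequences_and_peaks(cfg_bad, sim_bad, sb_bad$truth),
               "longer than the window")
})

test_that("expression coupling shifts coupled genes by the configured amount", {
  cfg <- sim_config(n_cpg = 6000, n_genes = 250, seed = 12,
                    effect_categories = c("TSS200", "Exon1"),
                    expression_coupling = -4)
  sim <- simulate_manifest(cfg, emit_sequences = FALSE)
  sb <- simulate_beta(cfg, sim)
  se <- simulate_expression(cfg, sim, sb$truth)
  v <- se$expr$values
  sm <- se$expr$samples
  d <- rowMeans(v[, sm$condition == "CD34pos_woMSC"]) -
    rowMeans(v[, sm$condition == "CD34pos_d0"])
  coupled <- rownames(v) %in% se$truth$coupled_genes
  expect_gt(sum(coupled), 5)
  m <- mean(d[coupled])
  se_m <- sd(d[coupled]) / sqrt(sum(coupled))
  expect_lt(abs(m - (-4 * 0.15)), 3 * se_m)     # E[dlog2] = -0.6

  # null coupling: no systematic difference
  cfg0 <- sim_config(n_cpg = 6000, n_genes = 250, seed = 12,
                     effect_categories = c("TSS200", "Exon1"),
                     expression_coupling = 0)
  se0 <- simulate_expression(cfg0, sim, sb$truth)
  d0 <- rowMeans(se0$expr$values[, sm$condition == "CD34pos_woMSC"]) -
    rowMeans(se0$expr$values[, sm$condition == "CD34pos_d0"])
  t0 <- t.test(d0[coupled], d0[!coupled])
  expect_gt(t0$p.value, 0.001)
})

test_that("generated files round-trip through the package readers", {
  cfg <- small_config(seed = 9)
  sim <- simulate_manifest(cfg)
  sb <- simulate_beta(cfg, sim)
  dir <- tempfile(); dir.create(dir)

  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  expect_identical(read_manifest(file.path(dir, "manifest.tsv")),
                   sim$manifest)

  write_beta_matrix(sb$beta, file.path(dir, "beta.tsv"),
                    file.path(dir, "samples.tsv"))
  back <- read_beta_matrix(file.path(dir, "beta.tsv"),
                           file.path(dir, "samples.tsv"))
  expect_equal(back$values, sb$beta$values, tolerance = 0)
  expect_equal(back$samples, sb$beta$samples)

  write_bed(sim$cgi, file.path(dir, "cgi.bed"))
  cgi_back <- read_bed(file.path(dir, "cgi.bed"))
  expect_equal(cgi_back$start, sim$cgi$start)

  se <- simulate_expression(cfg, sim, sb$truth)
  write_expression_matrix(se$expr, file.path(dir, "expr.tsv"),
                          file.path(dir, "expr_samples.tsv"))
  eback <- read_expression_matrix(file.path(dir, "expr.tsv"),
                                  file.path(dir, "expr_samples.tsv"))
  expect_equal(eback$values, se$expr$values, tolerance = 0)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_cpg = 50), "n_cpg")
  expect_error(sim_config(effect_fraction = 0), "effect_fraction")
  expect_error(sim_config(effect_fraction = 1.5), "effect_fraction")
  expect_error(sim_config(motif_plant_rate_fg = 2), "plant rates")
  expect_error(sim_config(effect_categories = "Promoter"), "category")
  expect_error(sim_config(motif_consensus = "ACGU"), "ACGT")
  expect_error(sim_config(conditions = "only_one"), "conditions")
  # demanding effects where no eligible site exists
  cfg <- small_config(region_mixture = c(TSS1500 = 0, TSS200 = 0.1,
                                         UTR5 = 0.1, Exon1 = 0.1,
                                         Body = 0.4, UTR3 = 0.1,
                                         Intergenic = 0.2),
                      effect_categories = "TSS1500")
  sim <- simulate_manifest(cfg, emit_sequences = FALSE)
  expect_error(simulate_beta(cfg, sim), "effect categories")
})
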