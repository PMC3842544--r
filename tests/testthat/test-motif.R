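random_dna <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 124, replace = TRUE), collapse = ""),
    character(1))
}

test_that("window extraction centers on the CpG with half-open bounds", {
  set.seed(2)
  chr <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  man <- data.frame(cpg_id = c("cgA", "cgB"), chrom = "chr1",
                    pos = c(1000L, 40L), strand = "+", genes = "",
                    regions = "Intergenic", cgi_relation = "OpenSea",
                    stringsAsFactors = FALSE)
  expect_message(w <- extract_windows(man, genome, width = 124), "dropped")
  expect_equal(names(w), "cgA")             # cgB runs off the start
  expect_equal(as.character(w[[1]]), substr(chr, 939, 1062))  # [938, 1062)
  # the site's C sits at offset width/2 (0-based)
  expect_equal(substr(as.character(w[[1]]), 63, 63), substr(chr, 1001, 1001))

  # minimal width: [pos - 1, pos + 1), keeping the C at offset width/2
  w2 <- extract_windows(man[1, ], genome, width = 2)
  expect_equal(as.character(w2[[1]]), substr(chr, 1000, 1001))
  expect_error(extract_windows(man, genome, width = 5), "even")
})

test_that("PWM scanning scores log-odds and finds the consensus", {
  consensus <- "TTGACGTCAA"
  p <- pwm_from_consensus(consensus, pseudocount = 0)
  win <- paste0(strrep("A", 30), consensus, strrep("C", 30))
  hits <- scan_pwm(c(w1 = win), p, both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 30)
  expect_equal(hits$score, 10 * log2(0.97 / 0.25), tolerance = 1e-10)

  # two-position worked example: "AG" scored pseudocount-free
  p2 <- pwm(rbind(c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.01, 0.97, 0.01)),
            motif_id = "AG", pseudocount = 0)
  h2 <- scan_pwm(c(w = "AG"), p2, both_strands = FALSE)
  expect_equal(h2$score, 2 * log2(0.97 / 0.25), tolerance = 1e-10)
  expect_equal(h2$score, 3.912114, tolerance = 1e-5)

  # an uninformative PWM never produces hits
  pu <- pwm(matrix(0.25, 4, 4), motif_id = "uniform")
  expect_equal(nrow(scan_pwm(c(w1 = win), pu)), 0)

  # non-ACGT bases skip the covering offsets without error
  winN <- paste0(strrep("N", 124 - 40), strrep("A", 30), consensus)
  hN <- scan_pwm(c(w1 = winN), p, both_strands = FALSE)
  expect_equal(nrow(hN), 1)
  expect_equal(hN$offset, 114)
})

test_that("PWM hit sets are strand-symmetric", {
  p <- pwm_from_consensus("AGGAAGT")
  wins <- Biostrings::DNAStringSet(random_dna(40, seed = 9))
  names(wins) <- sprintf("w%02d", 1:40)
  # plant forward and reverse-complement occurrences in a few windows
  Biostrings::subseq(wins[1:3], start = 10, width = 7) <-
    Biostrings::DNAStringSet(rep("AGGAAGT", 3))
  Biostrings::subseq(wins[4:6], start = 80, width = 7) <-
    Biostrings::DNAStringSet(rep(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString("AGGAAGT"))), 3))

  fwd <- scan_pwm(wins, p, threshold_fraction = 0.8)
  rev <- scan_pwm(Biostrings::reverseComplement(wins), p,
                  threshold_fraction = 0.8)
  expect_true(all(sprintf("w%02d", 1:6) %in% fwd$window_id))
  # same hits per window, offsets mirrored (o -> W - L - o), strands swapped
  key <- function(h, mirror) {
    off <- if (mirror) 124 - 7 - h$offset else h$offset
    strand <- if (mirror) chartr("+-", "-+", h$strand) else h$strand
    sort(paste(h$window_id, off, strand, round(h$score, 9)))
  }
  expect_equal(key(rev, TRUE), key(fwd, FALSE))
})

test_that("motif enrichment counts windows and hits the extremes", {
  bg <- random_dna(60, seed = 11)
  names(bg) <- sprintf("w%02d", 1:60)
  consensus <- "TTGACGTCAA"
  fg_ids <- names(bg)[1:10]
  for (id in fg_ids)                       # plant in every foreground window
    substr(bg[id], 20, 29) <- consensus
  p <- pwm_from_consensus(consensus)
  rec <- motif_enrichment(bg[fg_ids], bg, p)
  expect_equal(rec$k, 10)
  expect_equal(rec$n, 10)
  expect_equal(rec$p, choose_tail_p(60, rec$K, 10, 10), tolerance = 1e-12)
  expect_lt(rec$p, 1e-10)

  # motif absent everywhere: k = 0, p = 1
  p_absent <- pwm_from_consensus("ACACACACACAC")
  rec0 <- motif_enrichment(bg[fg_ids], bg, p_absent)
  expect_equal(rec0$k, 0)
  expect_equal(rec0$p, 1)

  expect_error(motif_enrichment(bg[1:2], bg[0], p), "background")
})

test_that("motif enrichment p-values are calibrated under equal plant rates", {
  # 200 null replicates: consensus planted at the same rate in foreground
  # and background, so enrichment is absent. Exact hypergeometric p-values
  # are discrete and super-uniform; calibration is checked one-sided (no
  # excess of small p-values).
  consensus <- "TTGACGTCAAT"
  p <- pwm_from_consensus(consensus)
  set.seed(61)
  pvals <- vapply(1:200, function(r) {
    wins <- vapply(1:120, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
            collapse = ""), character(1))
    names(wins) <- sprintf("w%03d", seq_along(wins))
    plant <- runif(120) < 0.08
    for (id in which(plant)) substr(wins[id], 10, 20) <- consensus
    motif_enrichment(wins[1:30], wins, p)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("peak co-location tests the 2x2 by width with nested windows", {
  man <- data.frame(cpg_id = sprintf("cg%03d", 1:100), chrom = "chr1",
                    pos = seq(10000L, by = 10000L, length.out = 100),
                    strand = "+", genes = "", regions = "Intergenic",
                    cgi_relation = "OpenSea", stringsAsFactors = FALSE)
  hyper <- man$cpg_id[1:10]
  # peaks directly at 3 hyper sites and 1 background site
  peaks <- data.frame(chrom = "chr1",
                      start = man$pos[c(1, 2, 3, 50)] - 20L,
                      end = man$pos[c(1, 2, 3, 50)] + 20L)
  res <- peak_colocation(hyper, man, peaks)
  expect_equal(res$width, c(124, 200, 500, 1000))
  expect_equal(res$prop_hyper, rep(0.3, 4))
  expect_equal(res$prop_background, rep(0.04, 4))
  # table [[3,7],[1,89]]: one-sided p by exhaustive enumeration
  expect_equal(res$p[1], choose_tail_p(100, 4, 10, 3), tolerance = 1e-12)
  # a peak at the site is caught at every width (nesting)
  expect_true(all(diff(res$prop_hyper) >= 0))
  expect_true(all(diff(res$prop_background) >= 0))

  empty <- peak_colocation(hyper, man, peaks[0, ])
  expect_equal(empty$prop_hyper, rep(0, 4))
  expect_equal(empty$p, rep(1, 4))
})

test_that("co-location proportions rise with width on simulated peaks", {
  cfg <- sim_config(n_cpg = 2000, n_genes = 80, seed = 23)
  sim <- simulate_manifest(cfg)
  sb <- simulate_beta(cfg, sim)
  sp <- simulate_sequences_and_peaks(cfg, sim, sb$truth)
  res <- peak_colocation(sb$truth$planted_sites, sim$manifest, sp$peaks,
                         widths = c(124, 200, 500, 1000, 4000))
  expect_true(all(diff(res$prop_hyper) >= 0))
  expect_true(all(diff(res$prop_background) >= 0))
  # every peak-planted foreground site is caught at the narrowest width
  idx <- match(sb$truth$planted_sites, sim$manifest$cpg_id)
  planted_peaks <- sp$truth$peak_fg_ids
  expect_gte(res$prop_hyper[1],
             length(planted_peaks) / length(sb$truth$planted_sites))
})
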