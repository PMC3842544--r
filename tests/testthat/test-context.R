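test_that("CGI classification follows the island/shore/shelf distance rule", {
  cgi <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  pos <- c(10500, 11000 + 1499, 11000 + 2999, 11000 + 9999,
           10000 - 1500, 10000 - 2500, 10000 - 6000)
  cls <- assign_cgi_relation(rep("chr1", length(pos)), pos, cgi)
  expect_equal(cls, c("Island",
                      "Shore",    # 1500 bp from the edge
                      "Shelf",    # 3000 bp
                      "OpenSea",  # 10000 bp
                      "Shore", "Shelf", "OpenSea"))

  # boundary bases: the 2000th base outside is still shore, the 2001st shelf
  b <- assign_cgi_relation(rep("chr1", 4), c(11000, 11000 + 1999,
                                             11000 + 2000, 9999),
                           cgi)
  expect_equal(b, c("Shore", "Shore", "Shelf", "Shore"))

  # chromosome without islands is open sea
  expect_equal(assign_cgi_relation("chr9", 5, cgi), "OpenSea")
})

test_that("CGI classification matches a brute-force nearest-edge scan", {
  set.seed(31)
  for (rep in 1:5) {
    n_isl <- sample(2:5, 1)
    starts <- sort(sample(seq(0, 80000, by = 100), n_isl))
    isl <- data.frame(chrom = "chr1", start = starts,
                      end = starts + sample(300:2000, n_isl, replace = TRUE))
    merged <- merge_intervals(isl)
    pos <- sample(0:90000, 300)
    got <- assign_cgi_relation(rep("chr1", 300), pos, isl)
    expect_equal(got, brute_cgi_class(pos, merged))
    # every position gets exactly one of the four classes
    expect_true(all(got %in% CGI_CLASSES))
  }
})

test_that("CGI classification is invariant to interval order and 0-gap splits", {
  cgi <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                    end = c(2000L, 5600L))
  shuffled <- cgi[2:1, ]
  split0 <- data.frame(chrom = "chr1", start = c(5000L, 1000L, 1400L),
                       end = c(5600L, 1400L, 2000L))  # [1000,2000) split
  pos <- seq(0, 9000, by = 37)
  ref <- assign_cgi_relation(rep("chr1", length(pos)), pos, cgi)
  expect_equal(assign_cgi_relation(rep("chr1", length(pos)), pos, shuffled),
               ref)
  expect_equal(assign_cgi_relation(rep("chr1", length(pos)), pos, split0),
               ref)
})

test_that("gene-region assignment is strand-aware and accumulates labels", {
  gm <- gene_models(
    gene_id = c("GP", "GM"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 50000L),
    utr5_start = c(10000L, 49881L), utr5_end = c(10100L, 50001L),
    exon1_start = c(10100L, 49581L), exon1_end = c(10400L, 49881L),
    body_start = c(10400L, 41000L), body_end = c(12000L, 49581L),
    utr3_start = c(12000L, 40500L), utr3_end = c(12500L, 41000L))

  q <- function(p) {
    hits <- assign_gene_region("chr1", p, gm)
    sort(hits$region)
  }
  expect_equal(q(10000 - 100), "TSS200")    # 100 bp upstream, + strand
  expect_equal(q(10000 - 1000), "TSS1500")  # 1000 bp upstream
  expect_equal(q(10050), "UTR5")
  expect_equal(q(10200), "Exon1")
  expect_equal(q(11000), "Body")
  expect_equal(q(12100), "UTR3")
  expect_equal(q(50000 + 100), "TSS200")    # minus strand: upstream is right
  expect_equal(q(50000 + 1000), "TSS1500")
  expect_equal(q(49950), "UTR5")
  expect_equal(q(45000), "Body")
  expect_equal(q(30000), "Intergenic")

  # overlapping genes accumulate labels
  gm2 <- gene_models(
    gene_id = c("G1", "G2"), chrom = "chr1", strand = "+",
    tss = c(1000L, 3000L),
    utr5_start = c(1000L, 3000L), utr5_end = c(1100L, 3100L),
    exon1_start = c(1100L, 3100L), exon1_end = c(1400L, 3400L),
    body_start = c(1400L, 3400L), body_end = c(5000L, 6000L),
    utr3_start = c(5000L, 6000L), utr3_end = c(5400L, 6400L))
  hits <- assign_gene_region("chr1", 2840L, gm2)   # G1 body, G2 TSS200
  expect_equal(sort(paste(hits$gene_id, hits$region)),
               c("G1 Body", "G2 TSS200"))

  expect_error(gene_models("G", "chr1", "*", 10L, 1L, 2L, 2L, 3L, 3L, 4L,
                           4L, 5L), "strand")
})

test_that("generated manifests agree with coordinate-based re-annotation", {
  cfg <- small_config(seed = 3)
  sim <- simulate_manifest(cfg, emit_sequences = FALSE)
  man <- sim$manifest
  hits <- assign_gene_region(man$chrom, man$pos, sim$gene_models)
  re_regions <- vapply(split(hits$region, hits$idx),
                       function(r) paste(sort(unique(r)), collapse = ";"),
                       character(1))
  own <- vapply(manifest_region_sets(man),
                function(r) paste(sort(r), collapse = ";"), character(1))
  expect_equal(unname(re_regions[as.character(seq_len(nrow(man)))]), own)
  re_cgi <- assign_cgi_relation(man$chrom, man$pos, sim$cgi)
  expect_equal(re_cgi, man$cgi_relation)
})

test_that("hypergeometric enrichment is exact", {
  ids <- sprintf("id%02d", 1:10)
  rec <- hypergeometric_enrichment(ids[1:4], ids[1:5], ids)
  expect_equal(rec$p, 5 / 210, tolerance = 1e-14)          # N=10 K=5 n=4 k=4
  expect_equal(rec$p, enum_tail_p(10, 5, 4, 4), tolerance = 1e-14)

  # selection at exactly the expected rate: fold 1
  rec2 <- hypergeometric_enrichment(ids[c(1, 6)], ids[1:5], ids)
  expect_equal(rec2$fold, 1)

  # category is everything: p = 1, fold = 1
  rec3 <- hypergeometric_enrichment(ids[1:4], ids, ids)
  expect_equal(rec3$p, 1)
  expect_equal(rec3$fold, 1)

  expect_error(hypergeometric_enrichment(c("zz"), ids[1:5], ids), "subset")
})

test_that("gene-set Fisher enrichment matches the enumeration oracle", {
  # 2x2 table [[4,1],[6,9]]: N=20, set size 5, selection 10, overlap 4
  uni <- sprintf("g%02d", 1:20)
  sets <- list(S = uni[1:5])
  rec <- gene_set_enrichment(uni[c(1:4, 6:11)], sets, uni)
  expect_equal(rec$k, 4)
  expect_equal(rec$p, enum_tail_p(20, 5, 10, 4), tolerance = 1e-12)
  expect_equal(rec$p, 0.1517028, tolerance = 1e-6)

  # selected = universe: every set has p = 1
  expect_equal(gene_set_enrichment(uni, sets, uni)$p, 1)
  # disjoint set: k = 0, p = 1
  rec0 <- gene_set_enrichment(uni[6:10], list(S = uni[1:5]), uni)
  expect_equal(rec0$k, 0)
  expect_equal(rec0$p, 1)

  expect_message(
    out <- gene_set_enrichment(uni[1:3], list(EMPTY = "nope", S = uni[1:5]),
                               uni), "skipped")
  expect_equal(out$category, "S")
  expect_error(gene_set_enrichment("g", sets, character(0)), "universe")
})

test_that("one-sided Fisher equals the hypergeometric tail on matched margins", {
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(6:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    uni <- sprintf("u%02d", 1:N)
    sel <- c(uni[seq_len(k)],
             if (n > k) uni[K + seq_len(n - k)] else character(0))
    hyp <- hypergeometric_enrichment(sel, uni[seq_len(K)], uni)$p
    fis <- gene_set_enrichment(sel, list(S = uni[seq_len(K)]), uni)$p
    expect_equal(hyp, fis, tolerance = 1e-12)
    expect_equal(hyp, enum_tail_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("context profiles recover planted categories and stay flat for hypo", {
  cfg <- sim_config(n_cpg = 4000, n_genes = 150, seed = 17)
  sim <- simulate_manifest(cfg, emit_sequences = FALSE)
  sb <- simulate_beta(cfg, sim)
  design <- paired_design(sb$beta, "CD34pos_d0", "CD34pos_woMSC")
  dm <- differential_methylation(sb$beta, design)
  prof <- category_enrichment_profile(dm, sim$manifest)

  hyper <- prof[prof$direction == "hyper", ]
  top2 <- hyper$category[order(hyper$p)][1:2]
  expect_setequal(top2, c("TSS1500", "Shore"))

  # only hyper effects planted: no hypo category is meaningfully enriched
  hypo <- prof[prof$direction == "hypo", ]
  expect_true(all(hypo$p > 1e-4))
  expect_equal(nrow(prof), 2 * (length(REGION_LABELS) + length(CGI_CLASSES)))
})
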