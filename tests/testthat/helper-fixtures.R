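# Fixtures are built in code at test time; nothing is stored on disk.

write_toy_manifest <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "ID\tCHR\tPOS\tSTRAND\tGENES\tREGIONS\tCGI_RELATION"
  writeLines(c(header, rows), path)
  path
}

# A small in-memory manifest data.frame (already normalized, 0-based).
toy_manifest <- function() {
  data.frame(
    cpg_id = c("cg01", "cg02", "cg03", "cg04"),
    chrom = "chr1",
    pos = c(100L, 300L, 200L, 500L),
    strand = c("+", "+", "-", "+"),
    genes = c("GENE1", "GENE1", "GENE1;GENE2", ""),
    regions = c("TSS200", "Body", "TSS1500;Body", "Intergenic"),
    cgi_relation = c("Island", "Shore", "Shore", "OpenSea"),
    stringsAsFactors = FALSE)
}

toy_beta <- function(values, donors, conditions) {
  samples <- data.frame(
    sample_id = colnames(values),
    donor = donors, condition = conditions,
    stringsAsFactors = FALSE)
  beta_matrix(values, samples)
}

# Exhaustive enumeration oracle for the upper-tail hypergeometric:
# probability that a uniformly random size-n subset of 1..N contains at
# least k of the first K elements.
enum_tail_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Combinatorial tail oracle for instances too large to enumerate subsets:
# P(X >= k) written out with binomial coefficients.
choose_tail_p <- function(N, K, n, k) {
  j <- max(0, k):min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force CGI classification: scan every merged island for the
# nearest-edge distance.
brute_cgi_class <- function(pos, islands, shore = 2000, shelf = 2000) {
  vapply(pos, function(p) {
    inside <- any(p >= islands$start & p < islands$end)
    if (inside) return("Island")
    d <- min(vapply(seq_len(nrow(islands)), function(i) {
      if (p < islands$start[i]) islands$start[i] - p
      else p - islands$end[i] + 1
    }, numeric(1)))
    if (d <= shore) "Shore"
    else if (d <= shore + shelf) "Shelf"
    else "OpenSea"
  }, character(1))
}

# Small simulation config for unit tests (fast; acceptance tests use the
# full study-scale configuration).
small_config <- function(seed = 1, ...) {
  sim_config(n_cpg = 800, n_genes = 40, n_donors = 3, seed = seed, ...)
}
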