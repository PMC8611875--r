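# Small community used by several unit tests (fast to generate).
small_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_community(community_params(
        n_genera = 2, viruses_per_genus = 4, hosts_per_genus = 1,
        host_genome_len = 20000, virus_genome_len = 9000,
        genes_per_genus_pool = 8, genes_per_virus = 4,
        fragment_len = 300, fragment_insert_prob = 1, rng_seed = 11))
    cache
  }
})

# The study-scale fixture: default community (seed 7) run through the whole
# pipeline once per test session; several end-to-end checks share it.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      com <- generate_community(community_params())
      run <- run_host_prediction(
        viruses = com$viruses, hosts = com$hosts,
        known_pairs = com$known_pairs, host_taxonomy = com$host_taxonomy,
        proteins = com$proteins, protein_genome = com$protein_genome,
        rng_seed = 7)
      cache <<- list(com = com, run = run)
    }
    cache
  }
})

# independent brute-force oracle: tail P(overlap >= c) by enumerating all
# C(n, b) draws against a fixed a-set
enumerate_tail <- function(a, b, c, n) {
  if (c <= 0) return(1)
  if (c > min(a, b)) return(0)
  if (b == 0) return(0)
  draws <- utils::combn(n, b)
  mean(colSums(draws <= a) >= c)
}

# independent per-bin ECE loop
ece_oracle <- function(conf, correct, n_bins = 10) {
  total <- 0
  for (i in seq_len(n_bins)) {
    lo <- (i - 1) / n_bins
    hi <- i / n_bins
    sel <- if (i == n_bins) conf >= lo & conf <= hi else conf >= lo & conf < hi
    if (!any(sel)) next
    total <- total + sum(sel) / length(conf) *
      abs(mean(correct[sel]) - mean(conf[sel]))
  }
  total
}

random_edge_list <- function(n_nodes, p = 0.3) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
             stringsAsFactors = FALSE)
}
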