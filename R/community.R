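#' Parameters of a synthetic virus--host community
#'
#' The generator plants exactly the statistical structure the prediction
#' method exploits: viruses of one genus draw their genes from a shared
#' genus-specific gene pool (so within-genus pairs share more protein
#' clusters than between-genus pairs), a fraction of viruses carry a
#' near-verbatim fragment of their host's genome (so nucleotide alignment
#' finds them), and every genus has its own 4-mer composition bias (order-3
#' Markov chain) that both host genomes and virus backbones follow, which is
#' what the convolutional encoder learns.
#'
#' @param n_genera number of host genera.
#' @param hosts_per_genus host genomes per genus.
#' @param viruses_per_genus viruses per genus.
#' @param genes_per_genus_pool size of each genus-specific gene pool.
#' @param genes_per_virus genes each virus draws (without replacement) from
#'   its genus pool.
#' @param shared_noise_genes genes each virus additionally draws from a
#'   global pool shared by all genera (horizontal noise).
#' @param noise_pool_size size of that global pool.
#' @param gene_len_aa gene length in amino acids.
#' @param host_genome_len,virus_genome_len genome lengths in bp.
#' @param fragment_insert_prob probability that a virus carries a
#'   host-derived fragment.
#' @param fragment_len length of the inserted host fragment (bp), must be
#'   smaller than `virus_genome_len`.
#' @param point_mutation_rate per-position substitution probability applied
#'   to gene copies (amino acids) and host fragments (nucleotides).
#' @param known_pair_fraction fraction of viruses (per genus) whose true
#'   interaction is recorded in the known-pairs table; the rest are test
#'   viruses.
#' @param fanout_per_rank taxonomy fanout, see [generate_taxonomy()].
#' @param rng_seed integer seed; all outputs are deterministic given it.
#' @return a list of class `community_params`.
#' @export
community_params <- function(n_genera = 5,
                             hosts_per_genus = 2,
                             viruses_per_genus = 20,
                             genes_per_genus_pool = 30,
                             genes_per_virus = 10,
                             shared_noise_genes = 2,
                             noise_pool_size = 20,
                             gene_len_aa = 120,
                             host_genome_len = 100000,
                             virus_genome_len = 15000,
                             fragment_insert_prob = 0.3,
                             fragment_len = 500,
                             point_mutation_rate = 0.02,
                             known_pair_fraction = 0.75,
                             fanout_per_rank = 2,
                             rng_seed = 7) {
  p <- as.list(environment())
  counts <- c("n_genera", "hosts_per_genus", "viruses_per_genus",
              "genes_per_genus_pool", "genes_per_virus", "gene_len_aa",
              "host_genome_len", "virus_genome_len", "fragment_len",
              "fanout_per_rank")
  for (nm in counts)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 1 || p[[nm]] != round(p[[nm]]))
      stop(sprintf("`%s` must be a positive integer", nm))
  for (nm in c("shared_noise_genes", "noise_pool_size"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] != round(p[[nm]]))
      stop(sprintf("`%s` must be a non-negative integer", nm))
  for (nm in c("fragment_insert_prob", "point_mutation_rate", "known_pair_fraction"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", nm))
  if (p$fragment_len >= p$virus_genome_len)
    stop("`fragment_len` must be smaller than `virus_genome_len`")
  if (p$genes_per_virus > p$genes_per_genus_pool)
    stop("gene pool smaller than `genes_per_virus`")
  if (p$shared_noise_genes > 0 && p$shared_noise_genes > p$noise_pool_size)
    stop("global noise pool smaller than `shared_noise_genes`")
  structure(p, class = "community_params")
}

.BASES <- c("A", "C", "G", "T")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codons per amino acid, standard code, stop codons excluded
codons_by_aa <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      gc <- Biostrings::GENETIC_CODE
      gc <- gc[gc != "*"]
      tbl <<- split(names(gc), gc)
    }
    tbl
  }
})

# order-3 Markov genome sampler; `cum` is the 64 x 4 cumulative transition
# matrix of the genus. Uses the session RNG.
sample_genome <- function(len, cum) {
  init <- sample.int(4L, 3L, replace = TRUE) - 1L
  v <- cpp_sample_markov3(as.integer(len), cum, init)
  paste(.BASES[v + 1L], collapse = "")
}

random_markov_cum <- function(alpha = 1) {
  m <- matrix(rgamma(64 * 4, shape = alpha), nrow = 64)
  m <- m / rowSums(m)
  t(apply(m, 1, cumsum))
}

random_gene_aa <- function(len) {
  # genes start with M so that back-translated copies are callable ORFs
  paste(c("M", sample(.AA20, len - 1, replace = TRUE)), collapse = "")
}

# i.i.d. substitutions; position 1 (the start M) is kept so the open reading
# frame of every emitted copy stays intact
mutate_aa <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  hit <- hit[hit > 1]
  for (i in hit) ch[i] <- sample(setdiff(.AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

mutate_nt <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

back_translate <- function(aa) {
  tbl <- codons_by_aa()
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  cods <- tbl[ch]
  lens <- lengths(cods)
  if (any(lens == 0)) stop("cannot back-translate symbol: ", aa)
  pick <- floor(runif(length(ch)) * lens) + 1
  paste(mapply(function(v, i) v[[i]], cods, pick), collapse = "")
}

#' Generate a synthetic virus--host community
#'
#' See [community_params()] for the planted structure. All outputs are
#' deterministic given `params$rng_seed` (the function seeds the session
#' RNG).
#'
#' @param params a [community_params()] object.
#' @param tree optional [generate_taxonomy()] tree with at least
#'   `params$n_genera` genera; generated from the params if missing.
#' @return an object of class `virus_community`: named sequence vectors
#'   `hosts`, `viruses`, `proteins` (amino acid, ids `<virus_id>_<n>` in
#'   genome order), `protein_genome` (protein id -> genome id),
#'   data.frames `truth` (virus_id, host_id, phylum..genus), `known_pairs`
#'   (virus_id, host_id), `gene_truth` (protein_id, gene_id: which planted
#'   pool gene the protein is a copy of), `host_taxonomy` (host_id,
#'   phylum..genus), plus `taxonomy` and `params`.
#' @examples
#' com <- generate_community(community_params(n_genera = 2,
#'   viruses_per_genus = 2, host_genome_len = 5000, virus_genome_len = 6000,
#'   genes_per_genus_pool = 10, genes_per_virus = 3, fragment_len = 200))
#' length(com$viruses)
#' @export
generate_community <- function(params = community_params(), tree = NULL) {
  stopifnot(inherits(params, "community_params"))
  set.seed(params$rng_seed)
  if (is.null(tree))
    tree <- generate_taxonomy(params$n_genera, params$fanout_per_rank,
                              params$rng_seed)
  genera <- tree$nodes$taxon[tree$nodes$rank == "genus"]
  if (length(genera) < params$n_genera)
    stop("taxonomy tree has fewer genera than `n_genera`")
  genera <- genera[seq_len(params$n_genera)]

  # per-genus composition bias and gene pools
  cums <- lapply(genera, function(g) random_markov_cum())
  names(cums) <- genera
  pools <- lapply(genera, function(g)
    vapply(seq_len(params$genes_per_genus_pool),
           function(i) random_gene_aa(params$gene_len_aa), character(1)))
  names(pools) <- genera
  noise_pool <- vapply(seq_len(params$noise_pool_size),
                       function(i) random_gene_aa(params$gene_len_aa),
                       character(1))

  hosts <- character(0)
  for (g in genera)
    for (i in seq_len(params$hosts_per_genus))
      hosts[sprintf("host_%s_%d", g, i)] <-
        sample_genome(params$host_genome_len, cums[[g]])

  viruses <- character(0)
  proteins <- character(0)
  protein_genome <- character(0)
  gene_truth_rows <- list()
  truth_rows <- list()
  known_rows <- list()

  for (g in genera) {
    lin <- taxonomy_lineage(tree, g)
    host_ids <- sprintf("host_%s_%d", g, seq_len(params$hosts_per_genus))
    n_known <- round(params$known_pair_fraction * params$viruses_per_genus)
    known_idx <- sample.int(params$viruses_per_genus, n_known)
    for (v in seq_len(params$viruses_per_genus)) {
      vid <- sprintf("virus_%s_%02d", g, v)
      host <- sample(host_ids, 1)

      gi <- sample.int(params$genes_per_genus_pool, params$genes_per_virus)
      gene_ids <- sprintf("gene_%s_%02d", g, gi)
      aa <- vapply(pools[[g]][gi], mutate_aa, character(1),
                   rate = params$point_mutation_rate, USE.NAMES = FALSE)
      if (params$shared_noise_genes > 0) {
        ni <- sample.int(params$noise_pool_size, params$shared_noise_genes)
        gene_ids <- c(gene_ids, sprintf("noise_%02d", ni))
        aa <- c(aa, vapply(noise_pool[ni], mutate_aa, character(1),
                           rate = params$point_mutation_rate, USE.NAMES = FALSE))
      }

      # each gene block: in-frame stop before ATG so the ORF caller
      # recovers exactly the emitted protein
      blocks <- vapply(aa, function(s)
        paste0("TAA", back_translate(s), "TAA"), character(1), USE.NAMES = FALSE)
      block_is_gene <- rep(TRUE, length(blocks))

      has_frag <- runif(1) < params$fragment_insert_prob
      if (has_frag) {
        pos <- sample.int(params$host_genome_len - params$fragment_len + 1, 1)
        frag <- mutate_nt(substr(hosts[[host]], pos, pos + params$fragment_len - 1),
                          params$point_mutation_rate)
        at <- sample.int(length(blocks) + 1, 1)
        blocks <- append(blocks, frag, after = at - 1)
        block_is_gene <- append(block_is_gene, FALSE, after = at - 1)
      }

      bb_len <- params$virus_genome_len - sum(nchar(blocks))
      if (bb_len < length(blocks) + 1)
        stop("`virus_genome_len` too small for the requested gene content")
      backbone <- sample_genome(bb_len, cums[[g]])
      cuts <- sort(sample.int(bb_len - 1, length(blocks)))
      pieces <- substring(backbone, c(1, cuts + 1), c(cuts, bb_len))
      genome <- paste(c(rbind(pieces[-length(pieces)], blocks), pieces[length(pieces)]),
                      collapse = "")
      stopifnot(nchar(genome) == params$virus_genome_len)
      viruses[[vid]] <- genome

      pid <- sprintf("%s_%d", vid, seq_len(sum(block_is_gene)))
      proteins[pid] <- aa
      protein_genome[pid] <- vid
      # fragment insertion does not reorder gene blocks, so protein index
      # in genome order equals gene order in the block list
      gene_truth_rows[[vid]] <- data.frame(protein_id = pid, gene_id = gene_ids,
                                           stringsAsFactors = FALSE)
      truth_rows[[vid]] <- data.frame(virus_id = vid, host_id = host,
                                      as.list(lin), stringsAsFactors = FALSE)
      if (v %in% known_idx)
        known_rows[[vid]] <- data.frame(virus_id = vid, host_id = host,
                                        stringsAsFactors = FALSE)
    }
  }

  host_taxonomy <- do.call(rbind, lapply(genera, function(g) {
    lin <- taxonomy_lineage(tree, g)
    data.frame(host_id = sprintf("host_%s_%d", g, seq_len(params$hosts_per_genus)),
               as.list(lin), stringsAsFactors = FALSE)
  }))
  rownames(host_taxonomy) <- NULL

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  known_pairs <- do.call(rbind, known_rows)
  rownames(known_pairs) <- NULL
  gene_truth <- do.call(rbind, gene_truth_rows)
  rownames(gene_truth) <- NULL

  structure(list(params = params, taxonomy = tree,
                 hosts = hosts, viruses = viruses, proteins = proteins,
                 protein_genome = protein_genome,
                 truth = truth, known_pairs = known_pairs,
                 gene_truth = gene_truth, host_taxonomy = host_taxonomy),
            class = "virus_community")
}

#' @export
print.virus_community <- function(x, ...) {
  cat(sprintf("virus_community: %d viruses, %d hosts, %d proteins, %d genera; %d known pairs\n",
              length(x$viruses), length(x$hosts), length(x$proteins),
              x$params$n_genera, nrow(x$known_pairs)))
  invisible(x)
}

#' Write a community to disk
#'
#' Writes `host.fasta`, `virus.fasta`, `proteins.fasta`, `truth.tsv`,
#' `known_pairs.tsv`, `host_taxonomy.tsv`, `gene_truth.tsv` and a
#' `manifest.yaml` with the generator parameters.
#'
#' @param community a [generate_community()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "virus_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(community$hosts, file.path(dir, "host.fasta"))
  write_fasta(community$viruses, file.path(dir, "virus.fasta"))
  write_fasta(community$proteins, file.path(dir, "proteins.fasta"))
  tsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(community$truth, "truth.tsv")
  tsv(community$known_pairs, "known_pairs.tsv")
  tsv(community$host_taxonomy, "host_taxonomy.tsv")
  tsv(community$gene_truth, "gene_truth.tsv")
  if (requireNamespace("yaml", quietly = TRUE))
    yaml::write_yaml(unclass(community$params), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
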