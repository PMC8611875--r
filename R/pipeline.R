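#' Run the host-prediction pipeline end to end
#'
#' Orchestrates: protein extraction (ORF calling if no proteins are
#' supplied), all-vs-all protein alignment, Markov clustering into protein
#' clusters, genome profiles, virus-vs-host nucleotide alignment,
#' knowledge-graph assembly, skip-gram + CNN node encoding, host-node
#' encoding, per-rank GCN training, and prediction. Externally produced
#' alignments (12-column tabular) can be passed in to replace the built-in
#' fallback aligner at either step.
#'
#' @param viruses,hosts named character vectors of nucleotide genomes.
#' @param known_pairs data.frame `virus_id`, `host_id` (training
#'   interactions).
#' @param host_taxonomy data.frame `host_id`, `phylum`..`genus`.
#' @param proteins optional named amino-acid vector (ids
#'   `<genome>_<n>`); called from the virus genomes when `NULL`.
#' @param protein_genome optional protein id -> genome id map; derived by
#'   stripping the trailing `_<n>` when `NULL`.
#' @param protein_hits,vh_hits optional alignment data.frames.
#' @param edge_params an [edge_test_params()].
#' @param skipgram list of [train_skipgram()] arguments (k, d, ...).
#' @param cnn a [cnn_config()].
#' @param gcn a [gcn_config()].
#' @param mcl_inflation MCL inflation.
#' @param threshold SoftMax confidence threshold for [predict_hosts()].
#' @param rng_seed master seed for the learned stages.
#' @return list of class `hostnet_run`: `graph`, `clusters`, `profiles`,
#'   `embedding`, `cnn`, `models`, `predictions`, and the hit tables used.
#' @export
run_host_prediction <- function(viruses, hosts, known_pairs, host_taxonomy,
                                proteins = NULL, protein_genome = NULL,
                                protein_hits = NULL, vh_hits = NULL,
                                edge_params = edge_test_params(),
                                skipgram = list(), cnn = cnn_config(),
                                gcn = gcn_config(), mcl_inflation = 2,
                                threshold = 0, rng_seed = 1) {
  if (is.null(proteins)) {
    orfs <- lapply(names(viruses), function(v) find_orfs(viruses[[v]], v))
    orfs <- do.call(rbind, orfs)
    proteins <- setNames(orfs$protein, orfs$id)
  }
  if (is.null(protein_genome))
    protein_genome <- setNames(sub("_[0-9]+$", "", names(proteins)),
                               names(proteins))

  if (is.null(protein_hits))
    protein_hits <- all_vs_all_protein_hits(proteins)
  network <- build_protein_network(protein_hits, edge_params$tau2,
                                   proteins = names(proteins))
  clusters <- mcl(network, inflation = mcl_inflation)
  profiles <- profile_genomes(clusters, protein_genome,
                              genomes = names(viruses))

  if (is.null(vh_hits))
    vh_hits <- virus_host_nucleotide_hits(viruses, hosts)

  graph <- build_knowledge_graph(names(viruses), names(hosts), profiles,
                                 vh_hits, known_pairs, host_taxonomy,
                                 edge_params)

  # encoder: skip-gram over all virus segments, CNN over the labeled
  # (known-pair) viruses at genus rank
  seg_len <- cnn$segment_length
  all_segs <- unlist(lapply(names(viruses), function(v)
    segment_genome(viruses[[v]], v, seg_len)$sequence), use.names = FALSE)
  sg_args <- utils::modifyList(list(segments = all_segs, rng_seed = rng_seed),
                               skipgram)
  embedding <- do.call(train_skipgram, sg_args)

  train_ids <- unique(known_pairs$virus_id)
  genus_lab <- setNames(graph$labels$genus[match(train_ids, graph$labels$node_id)],
                        train_ids)
  cnn_model <- train_cnn(viruses[train_ids], genus_lab, embedding, cnn,
                         rng_seed + 101)

  feats <- encode_sequences(viruses, embedding, cnn_model)
  graph <- set_virus_features(graph, feats)
  graph <- encode_host_nodes(graph)

  models <- train_rank_models(graph, gcn, rng_seed + 201)
  predictions <- predict_hosts(graph, models, threshold)

  structure(list(graph = graph, clusters = clusters, profiles = profiles,
                 embedding = embedding, cnn = cnn_model, models = models,
                 predictions = predictions, protein_hits = protein_hits,
                 vh_hits = vh_hits),
            class = "hostnet_run")
}

#' @export
print.hostnet_run <- function(x, ...) {
  print(x$graph)
  cat(sprintf("  %d protein clusters; %d query viruses predicted\n",
              length(x$clusters), length(unique(x$predictions$virus_id))))
  invisible(x)
}

#' Held-out calibration comparison
#'
#' Trains the rank model twice per seed — once with the calibration-aware
#' loss (ECE + L2) and once with L2 only — and reports the expected
#' calibration error of the *held-out* predictions (query viruses scored
#' against the supplied truth).
#'
#' @param graph a featured knowledge graph with unlabeled query viruses.
#' @param truth data.frame `virus_id` + rank columns covering the query
#'   viruses.
#' @param rank taxonomic rank to train at.
#' @param seeds integer vector of training seeds.
#' @param config a [gcn_config()] (its `loss` field is overridden).
#' @param n_bins ECE bins for the held-out report.
#' @return data.frame: `seed`, `ece_calibrated`, `ece_l2_only`.
#' @export
compare_calibration <- function(graph, truth, rank = "genus",
                                seeds = 1:5, config = gcn_config(),
                                n_bins = 10) {
  query <- graph$ids[graph$roles == "virus" & is.na(graph$labels$genus)]
  heldout_ece <- function(model) {
    models <- setNames(list(model), rank)
    pr <- predict_hosts(graph, models, threshold = 0)
    pr <- pr[pr$rank == rank, ]
    tv <- truth[[rank]][match(pr$virus_id, truth$virus_id)]
    ece(pr$confidence, pr$taxon == tv, n_bins)$ece
  }
  do.call(rbind, lapply(seeds, function(s) {
    cfg_cal <- config; cfg_cal$loss <- "ece_l2"
    cfg_l2 <- config; cfg_l2$loss <- "l2"
    data.frame(seed = s,
               ece_calibrated = heldout_ece(train_gcn(graph, rank, cfg_cal, s)),
               ece_l2_only = heldout_ece(train_gcn(graph, rank, cfg_l2, s)))
  }))
}
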