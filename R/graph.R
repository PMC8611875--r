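#' Hypergeometric tail probability of shared clusters
#'
#' Probability that two sequences containing `a` and `b` protein clusters
#' (drawn from `n` equiprobable clusters) share at least `c` clusters:
#' `P(y >= c) = sum_{i=c}^{min(a,b)} C(a,i) C(n-a,b-i) / C(n,b)`. Computed
#' in log space. Equal cluster choice probabilities are a deliberate,
#' approximate null — cheap to evaluate and adequate for ranking.
#'
#' @param a,b cluster counts of the two sequences (`0 <= a,b <= n`).
#' @param c required shared count (`>= 0`).
#' @param n total number of protein clusters.
#' @return the tail probability; 1 when `c <= 0`, 0 when `c > min(a, b)`.
#' @export
hypergeom_tail <- function(a, b, c, n) {
  exp(hypergeom_tail_log(a, b, c, n))
}

hypergeom_tail_log <- function(a, b, c, n) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1, length(n) == 1)
  if (n < 1) stop("`n` must be >= 1")
  if (a < 0 || b < 0 || c < 0) stop("counts must be non-negative")
  if (a > n || b > n) stop("`a` and `b` cannot exceed `n`")
  if (c <= 0) return(0)
  if (c > min(a, b)) return(-Inf)
  i <- c:min(a, b)
  lt <- lchoose(a, i) + lchoose(n - a, b - i) - lchoose(n, b)
  lt <- lt[is.finite(lt)]
  if (length(lt) == 0) return(-Inf)
  mx <- max(lt)
  min(0, mx + log(sum(exp(lt - mx))))
}

#' Edge-test parameters of the knowledge graph
#'
#' @param tau1 significance threshold of the virus--virus test (an edge
#'   requires `-log(P * C(N,2)) >= tau1`, natural log).
#' @param tau2 E-value threshold of the virus--host test.
#' @param n total number of protein clusters (filled in at graph build
#'   time when `NULL`).
#' @param N total number of virus sequences used for the multiple-pair
#'   correction `C(N,2)` (filled in at build time when `NULL`; hosts carry
#'   no cluster profile and are not counted).
#' @param log_base base of the logarithm in the edge statistic.
#' @return list of class `edge_test_params`.
#' @export
edge_test_params <- function(tau1 = 1, tau2 = 1e-5, n = NULL, N = NULL,
                             log_base = exp(1)) {
  if (tau2 <= 0) stop("`tau2` must be positive")
  if (!is.null(n) && n < 1) stop("`n` must be >= 1")
  if (!is.null(N) && N < 2) stop("`N` must be >= 2")
  structure(list(tau1 = tau1, tau2 = tau2, n = n, N = N, log_base = log_base),
            class = "edge_test_params")
}

#' Virus--virus edge statistic
#'
#' `-log(P(y >= c) * C(N,2))` in the base of `params$log_base` (natural by
#' default). Large values mean the observed overlap is unlikely under the
#' equal-probability null even after correcting for the `C(N,2)` pairs
#' examined.
#'
#' @param a,b,c,n see [hypergeom_tail()].
#' @param N total number of sequences (>= 2).
#' @param log_base logarithm base.
#' @return the statistic (may be `Inf` for impossible overlaps).
#' @export
virus_virus_statistic <- function(a, b, c, n, N, log_base = exp(1)) {
  if (N < 2) stop("`N` must be >= 2")
  -(hypergeom_tail_log(a, b, c, n) + lchoose(N, 2)) / log(log_base)
}

#' Virus--virus edge decision
#'
#' @param profile_a,profile_b genome profiles from [profile_genomes()].
#' @param params an [edge_test_params()] with `n` and `N` set.
#' @return `TRUE` iff the shared-cluster count is significant; sharing
#'   nothing (`c = 0`) never creates an edge.
#' @export
virus_virus_edge <- function(profile_a, profile_b, params) {
  stopifnot(inherits(params, "edge_test_params"))
  if (is.null(params$n) || is.null(params$N))
    stop("`params$n` and `params$N` must be set")
  c <- length(intersect(profile_a$clusters, profile_b$clusters))
  if (c == 0) return(FALSE)
  virus_virus_statistic(profile_a$a, profile_b$a, c, params$n, params$N,
                        params$log_base) >= params$tau1
}

#' Virus--host edge decision
#'
#' A known interaction always connects, regardless of alignment; otherwise
#' the best alignment E-value must fall below `tau2`. At most one edge is
#' created per pair.
#'
#' @param best_evalue best alignment E-value for the pair, or `NA`/`NULL`
#'   when there is no alignment.
#' @param is_known_pair logical.
#' @param tau2 E-value threshold.
#' @return logical.
#' @export
virus_host_edge <- function(best_evalue, is_known_pair, tau2 = 1e-5) {
  if (isTRUE(is_known_pair)) return(TRUE)
  !is.null(best_evalue) && !is.na(best_evalue) && best_evalue < tau2
}

#' Build the virus--host knowledge graph
#'
#' Applies the virus--virus shared-cluster test to all virus pairs and the
#' virus--host rule to all pairs with an alignment or a known interaction.
#' Hosts are labeled with their full lineage; viruses appearing in
#' `known_pairs` inherit their host's lineage (training nodes), all other
#' viruses stay unlabeled (query nodes). Host--host edges never exist.
#'
#' @param virus_ids,host_ids node ids (disjoint).
#' @param profiles [profile_genomes()] output covering the viruses.
#' @param virus_host_hits alignment data.frame (viruses as queries, hosts
#'   as subjects); only the best E-value per pair is kept.
#' @param known_pairs data.frame with columns `virus_id`, `host_id`.
#' @param host_taxonomy data.frame with columns `host_id`,
#'   `phylum`..`genus` covering every host.
#' @param params [edge_test_params()]; `n` defaults to the number of
#'   clusters behind `profiles`, `N` to the number of viruses.
#' @return object of class `knowledge_graph`: list with `ids`, `roles`
#'   (named character), `labels` (data.frame `node_id`, `phylum`..`genus`),
#'   `edges` (data.frame `from`, `to`, `provenance`, `evalue`), `params`,
#'   and `features` (`NULL` until [set_virus_features()]).
#' @export
build_knowledge_graph <- function(virus_ids, host_ids, profiles,
                                  virus_host_hits = NULL, known_pairs = NULL,
                                  host_taxonomy, params = edge_test_params()) {
  stopifnot(inherits(params, "edge_test_params"))
  if (length(intersect(virus_ids, host_ids)) > 0)
    stop("virus and host ids must be disjoint")
  missing_tax <- setdiff(host_ids, host_taxonomy$host_id)
  if (length(missing_tax) > 0)
    stop("host without taxonomy row: ", paste(missing_tax, collapse = ", "))
  if (!is.null(known_pairs) && nrow(known_pairs) > 0) {
    bad <- setdiff(known_pairs$virus_id, virus_ids)
    bad <- c(bad, setdiff(known_pairs$host_id, host_ids))
    if (length(bad) > 0)
      stop("unknown id in known pairs: ", paste(bad, collapse = ", "))
  }

  params$n <- params$n %||% attr(profiles, "n_clusters") %||%
    length(unique(unlist(lapply(profiles, `[[`, "clusters"))))
  params$N <- params$N %||% length(virus_ids)

  prof <- lapply(virus_ids, function(v)
    profiles[[v]] %||% list(genome_id = v, clusters = character(0), a = 0L))
  names(prof) <- virus_ids
  vv <- virus_virus_edges(prof, params)
  vh <- virus_host_edges(virus_ids, host_ids, virus_host_hits, known_pairs,
                         params$tau2)
  edges <- rbind(vv, vh)

  ranks <- .RANKS
  labels <- data.frame(node_id = c(virus_ids, host_ids),
                       stringsAsFactors = FALSE)
  for (r in ranks) labels[[r]] <- NA_character_
  hrow <- match(host_ids, host_taxonomy$host_id)
  labels[match(host_ids, labels$node_id), ranks] <- host_taxonomy[hrow, ranks]
  if (!is.null(known_pairs) && nrow(known_pairs) > 0) {
    first <- known_pairs[!duplicated(known_pairs$virus_id), ]
    vrow <- match(first$virus_id, labels$node_id)
    labels[vrow, ranks] <-
      host_taxonomy[match(first$host_id, host_taxonomy$host_id), ranks]
  }

  structure(list(ids = c(virus_ids, host_ids),
                 roles = setNames(c(rep("virus", length(virus_ids)),
                                    rep("host", length(host_ids))),
                                  c(virus_ids, host_ids)),
                 labels = labels, edges = edges, params = params,
                 features = NULL),
            class = "knowledge_graph")
}

# all significant virus-virus edges via the shared-cluster membership matrix
virus_virus_edges <- function(profiles, params) {
  ids <- names(profiles)
  nv <- length(ids)
  empty <- data.frame(from = character(0), to = character(0),
                      provenance = character(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (nv < 2) return(empty)
  all_cl <- sort(unique(unlist(lapply(profiles, `[[`, "clusters"))))
  if (length(all_cl) == 0) return(empty)
  M <- matrix(0L, nv, length(all_cl))
  for (i in seq_len(nv)) {
    cl <- profiles[[i]]$clusters
    if (length(cl) > 0) M[i, match(cl, all_cl)] <- 1L
  }
  C <- tcrossprod(M)
  a <- diag(C)
  idx <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  trip <- data.frame(a = a[idx[, 1]], b = a[idx[, 2]], c = C[idx])
  key <- paste(trip$a, trip$b, trip$c)
  uk <- !duplicated(key)
  stat_u <- vapply(which(uk), function(r)
    virus_virus_statistic(trip$a[r], trip$b[r], trip$c[r], params$n,
                          params$N, params$log_base), numeric(1))
  stat <- stat_u[match(key, key[uk])]
  keep <- stat >= params$tau1
  if (!any(keep)) return(empty)
  data.frame(from = ids[idx[keep, 1]], to = ids[idx[keep, 2]],
             provenance = "virus-virus", evalue = NA_real_,
             stringsAsFactors = FALSE)
}

virus_host_edges <- function(virus_ids, host_ids, hits, known_pairs, tau2) {
  best <- list()
  if (!is.null(hits) && nrow(hits) > 0) {
    h <- hits[hits$query_id %in% virus_ids & hits$subject_id %in% host_ids, ,
              drop = FALSE]
    if (nrow(h) > 0) {
      dt <- data.table::data.table(virus = h$query_id, host = h$subject_id,
                                   evalue = h$evalue)
      dt <- dt[, list(evalue = min(evalue)), by = c("virus", "host")]
      best <- split(dt$evalue, paste(dt$virus, dt$host))
    }
  }
  known <- character(0)
  if (!is.null(known_pairs) && nrow(known_pairs) > 0)
    known <- paste(known_pairs$virus_id, known_pairs$host_id)

  keys <- union(names(best), known)
  if (length(keys) == 0)
    return(data.frame(from = character(0), to = character(0),
                      provenance = character(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(keys, function(k) {
    ev <- if (k %in% names(best)) best[[k]][1] else NA_real_
    isk <- k %in% known
    if (!virus_host_edge(ev, isk, tau2)) return(NULL)
    pair <- strsplit(k, " ", fixed = TRUE)[[1]]
    data.frame(from = pair[1], to = pair[2],
               provenance = if (isk) "virus-host-known" else "virus-host-alignment",
               evalue = ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      provenance = character(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach encoder features to virus nodes
#'
#' @param graph a [build_knowledge_graph()] object.
#' @param features numeric matrix with one row per virus id (rownames must
#'   cover all viruses in the graph).
#' @return the graph with its feature matrix allocated (host rows zero
#'   until [encode_host_nodes()]).
#' @export
set_virus_features <- function(graph, features) {
  stopifnot(inherits(graph, "knowledge_graph"))
  virus_ids <- graph$ids[graph$roles == "virus"]
  missing <- setdiff(virus_ids, rownames(features))
  if (length(missing) > 0)
    stop("missing features for viruses: ", paste(utils::head(missing, 3), collapse = ", "))
  F <- matrix(0, length(graph$ids), ncol(features),
              dimnames = list(graph$ids, NULL))
  F[virus_ids, ] <- features[virus_ids, , drop = FALSE]
  graph$features <- F
  graph
}

#' Encode host nodes from their viral neighbours
#'
#' Host feature = weighted average of the features of neighbouring virus
#' nodes, weight `-log10(max(E, 1e-180))` of the connecting edge. Known-
#' interaction edges without an alignment E-value get the maximum weight
#' (180): a confirmed interaction should dominate weak alignment
#' neighbours. A host with no viral neighbour gets the zero vector, with a
#' warning.
#'
#' @param graph a graph whose virus features are set.
#' @return the graph with host feature rows filled in.
#' @export
encode_host_nodes <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (is.null(graph$features)) stop("virus features are not set")
  vh <- graph$edges[grepl("^virus-host", graph$edges$provenance), , drop = FALSE]
  w <- -log10(pmax(vh$evalue, 1e-180))
  w[is.na(vh$evalue)] <- 180
  isolated <- character(0)
  for (h in graph$ids[graph$roles == "host"]) {
    sel <- vh$to == h
    if (!any(sel)) {
      graph$features[h, ] <- 0
      isolated <- c(isolated, h)
      next
    }
    V <- graph$features[vh$from[sel], , drop = FALSE]
    graph$features[h, ] <- colSums(V * w[sel]) / sum(w[sel])
  }
  if (length(isolated) > 0)
    warning("host(s) with no virus neighbour encoded as zero vector: ",
            paste(isolated, collapse = ", "))
  graph
}

#' Extend the knowledge graph with new host nodes
#'
#' Adds labeled host nodes (possibly from taxa absent at build time) and
#' the virus--host edges involving them; existing nodes and edges are
#' untouched, so building once with the union of inputs and building then
#' extending give the same edge set. New hosts are encoded from their
#' viral neighbours if the graph carries features.
#'
#' @param graph a [build_knowledge_graph()] object.
#' @param new_host_taxonomy data.frame `host_id`, `phylum`..`genus` for the
#'   new hosts; ids must not collide with existing nodes.
#' @param new_hits alignment data.frame covering virus vs new-host pairs.
#' @param new_known_pairs optional known interactions with the new hosts.
#' @return the extended graph.
#' @export
extend_graph <- function(graph, new_host_taxonomy, new_hits = NULL,
                         new_known_pairs = NULL) {
  stopifnot(inherits(graph, "knowledge_graph"))
  new_ids <- new_host_taxonomy$host_id
  clash <- intersect(new_ids, graph$ids)
  if (length(clash) > 0)
    stop("id collision with existing nodes: ", paste(clash, collapse = ", "))
  virus_ids <- graph$ids[graph$roles == "virus"]

  vh <- virus_host_edges(virus_ids, new_ids, new_hits, new_known_pairs,
                         graph$params$tau2)
  graph$ids <- c(graph$ids, new_ids)
  graph$roles <- c(graph$roles, setNames(rep("host", length(new_ids)), new_ids))
  newlab <- data.frame(node_id = new_ids, stringsAsFactors = FALSE)
  for (r in .RANKS) newlab[[r]] <- new_host_taxonomy[[r]]
  graph$labels <- rbind(graph$labels, newlab)
  graph$edges <- rbind(graph$edges, vh)

  if (!is.null(graph$features)) {
    F <- rbind(graph$features,
               matrix(0, length(new_ids), ncol(graph$features),
                      dimnames = list(new_ids, NULL)))
    graph$features <- F
    w <- -log10(pmax(vh$evalue, 1e-180))
    w[is.na(vh$evalue)] <- 180
    for (h in new_ids) {
      sel <- vh$to == h
      if (!any(sel)) {
        warning("new host with no virus neighbour encoded as zero vector: ", h)
        next
      }
      V <- graph$features[vh$from[sel], , drop = FALSE]
      graph$features[h, ] <- colSums(V * w[sel]) / sum(w[sel])
    }
  }
  graph
}

#' @export
print.knowledge_graph <- function(x, ...) {
  prov <- table(x$edges$provenance)
  cat(sprintf("knowledge_graph: %d viruses, %d hosts; edges: %s\n",
              sum(x$roles == "virus"), sum(x$roles == "host"),
              if (nrow(x$edges) == 0) "none"
              else paste(sprintf("%s=%d", names(prov), as.integer(prov)),
                         collapse = ", ")))
  invisible(x)
}
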