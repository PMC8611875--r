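#' Build the protein similarity network
#'
#' Nodes are proteins; an edge joins every pair with a best E-value below
#' `evalue_cutoff`. Reciprocal hits are merged keeping the smaller E-value.
#' Edge weight is `-log10(E)` with E clamped to `>= 1e-180` so reported
#' zero E-values stay finite.
#'
#' @param hits alignment data.frame (see [parse_tabular_alignments()]).
#' @param evalue_cutoff E-value threshold for keeping an edge.
#' @param proteins optional character vector of all protein ids; proteins
#'   without a qualifying alignment then appear as isolated nodes (and end
#'   up as singleton clusters).
#' @return object of class `protein_network`: list with `nodes` (character)
#'   and `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_protein_network <- function(hits, evalue_cutoff = 1e-5, proteins = NULL) {
  h <- hits[hits$evalue < evalue_cutoff & hits$query_id != hits$subject_id, ,
            drop = FALSE]
  if (nrow(h) > 0) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    dt <- data.table::data.table(from = a, to = b, evalue = h$evalue)
    dt <- dt[, list(evalue = min(evalue)), by = c("from", "to")]
    edges <- data.frame(from = dt$from, to = dt$to,
                        weight = -log10(pmax(dt$evalue, 1e-180)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$from, edges$to, proteins)))
  structure(list(nodes = nodes, edges = edges), class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("protein_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Markov clustering
#'
#' Runs MCL on a weighted undirected graph: self-loops are added (weight =
#' the node's maximum incident edge weight, 1 for isolated nodes, which
#' keeps the procedure invariant to uniform rescaling of the weights), the
#' matrix is made column-stochastic, and expansion (matrix power),
#' inflation (elementwise power followed by column renormalisation) and
#' pruning of entries below `prune` are iterated until the matrix changes
#' by less than `tol` or `max_iter` is reached (with a warning). Clusters
#' are read off the limit matrix: attractor rows (non-zero diagonal) are
#' grouped into attractor systems, and every node joins the system holding
#' most of its column mass; ties go to the lexicographically smallest
#' cluster id (the smallest member of the system).
#'
#' @param network a [build_protein_network()] object, or any list with
#'   `nodes` and `edges` (`from`, `to`, `weight`).
#' @param inflation inflation exponent.
#' @param expansion matrix power used for expansion.
#' @param max_iter iteration cap.
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute change.
#' @return list of character vectors (disjoint node sets covering all
#'   nodes), ordered by cluster id; the membership vector is attached as
#'   attribute `membership`.
#' @export
mcl <- function(network, inflation = 2, expansion = 2, max_iter = 100,
                prune = 1e-5, tol = 1e-8) {
  nodes <- network$nodes
  K <- length(nodes)
  if (K == 0) return(structure(list(), membership = character(0)))
  M <- matrix(0, K, K, dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e) > 0) {
    i <- match(e$from, nodes)
    j <- match(e$to, nodes)
    M[cbind(i, j)] <- e$weight
    M[cbind(j, i)] <- e$weight
  }
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (p in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0
    if (any(dead)) {  # fully pruned column: keep the node on itself
      Minf[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Minf <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iter; interpreting current matrix")

  eps <- 1e-6
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(K)
  # attractor systems: connected components among attractor nodes
  sys_id <- seq_along(attractors)
  amat <- (M[attractors, attractors, drop = FALSE] > eps) |
    t(M[attractors, attractors, drop = FALSE] > eps)
  repeat {
    changed <- FALSE
    for (a in seq_along(attractors)) {
      nb <- which(amat[a, ])
      if (length(nb) > 0) {
        mn <- min(sys_id[c(a, nb)])
        if (any(sys_id[c(a, nb)] != mn)) {
          sys_id[c(a, nb)] <- mn
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  systems <- split(attractors, sys_id)
  sys_names <- vapply(systems, function(s) min(nodes[s]), character(1))
  ord <- order(sys_names)
  systems <- systems[ord]
  sys_names <- sys_names[ord]

  mass <- matrix(0, length(systems), K)
  for (si in seq_along(systems))
    mass[si, ] <- colSums(M[systems[[si]], , drop = FALSE])
  membership <- character(K)
  for (v in seq_len(K)) {
    mx <- max(mass[, v])
    if (mx <= 0) {
      membership[v] <- nodes[v]  # no attractor mass: singleton
    } else {
      cand <- which(mass[, v] >= mx - 1e-12)
      membership[v] <- min(sys_names[cand])
    }
  }
  names(membership) <- nodes
  clusters <- split(nodes, membership)
  clusters <- clusters[order(names(clusters))]
  clusters <- lapply(clusters, sort)
  structure(unname(clusters), names = names(clusters), membership = membership)
}

#' Per-genome protein-cluster profiles
#'
#' @param clusters clustering as returned by [mcl()] (named list of protein
#'   id vectors).
#' @param protein_genome named character vector mapping protein id ->
#'   genome id; every clustered protein must be present.
#' @param genomes optional character vector of genome ids to profile;
#'   genomes without proteins get an empty profile (`a = 0`).
#' @return named list of profiles, each a list with `genome_id`, `clusters`
#'   (character vector of cluster ids) and `a` (their count). The total
#'   number of clusters is attached as attribute `n_clusters`.
#' @export
profile_genomes <- function(clusters, protein_genome, genomes = NULL) {
  cluster_ids <- names(clusters)
  if (is.null(cluster_ids)) cluster_ids <- as.character(seq_along(clusters))
  prot <- unlist(clusters, use.names = FALSE)
  cl <- rep(cluster_ids, lengths(clusters))
  unknown <- setdiff(prot, names(protein_genome))
  if (length(unknown) > 0)
    stop("proteins with unknown genome: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  genome <- unname(protein_genome[prot])
  per <- split(cl, genome)
  genomes <- genomes %||% sort(unique(genome))
  out <- lapply(genomes, function(g) {
    cls <- sort(unique(per[[g]])) %||% character(0)
    list(genome_id = g, clusters = cls, a = length(cls))
  })
  names(out) <- genomes
  attr(out, "n_clusters") <- length(clusters)
  out
}
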