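#' Generate a host taxonomy tree
#'
#' Builds a five-rank taxonomy (phylum, class, order, family, genus) whose
#' leaves are exactly `n_genera` genera. Higher ranks are formed by grouping
#' `fanout_per_rank` children under each parent, collapsing upward, so the
#' number of taxa shrinks by that factor at every rank until a single phylum
#' remains (or more than one, if there are enough genera).
#'
#' @param n_genera number of genus leaves (>= 1).
#' @param fanout_per_rank maximum number of children per parent taxon (>= 1).
#' @param rng_seed integer seed; the construction is deterministic, the seed
#'   is part of the interface so callers can treat it like the other
#'   generators.
#' @return an object of class `taxonomy_tree`: a list with `ranks` (ordered
#'   character vector, phylum first) and `nodes` (data.frame with columns
#'   `taxon`, `rank`, `parent`; phyla have `NA` parents).
#' @examples
#' tr <- generate_taxonomy(4, 2)
#' subset(tr$nodes, rank == "family")
#' @export
generate_taxonomy <- function(n_genera, fanout_per_rank = 2, rng_seed = 0) {
  if (!is.numeric(n_genera) || n_genera < 1 || n_genera != round(n_genera))
    stop("`n_genera` must be a positive integer")
  if (!is.numeric(fanout_per_rank) || fanout_per_rank < 1 ||
      fanout_per_rank != round(fanout_per_rank))
    stop("`fanout_per_rank` must be a positive integer")

  ranks <- .RANKS
  prefixes <- c(phylum = "p", class = "c", order = "o", family = "f", genus = "g")
  counts <- integer(length(ranks))
  names(counts) <- ranks
  counts["genus"] <- as.integer(n_genera)
  for (r in rev(seq_len(length(ranks) - 1)))
    counts[r] <- as.integer(ceiling(counts[r + 1] / fanout_per_rank))

  name_at <- function(rank, i) sprintf("%s%02d", prefixes[[rank]], i)
  nodes <- do.call(rbind, lapply(seq_along(ranks), function(ri) {
    rank <- ranks[ri]
    i <- seq_len(counts[rank])
    parent <- if (ri == 1) NA_character_
      else name_at(ranks[ri - 1], ceiling(i / fanout_per_rank))
    data.frame(taxon = name_at(rank, i), rank = rank, parent = parent,
               stringsAsFactors = FALSE)
  }))
  rownames(nodes) <- NULL
  structure(list(ranks = ranks, nodes = nodes), class = "taxonomy_tree")
}

#' Full lineage of a genus
#'
#' @param tree a [generate_taxonomy()] tree.
#' @param genus a genus name present in the tree.
#' @return named character vector over the five ranks, phylum first.
#' @export
taxonomy_lineage <- function(tree, genus) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  nodes <- tree$nodes
  out <- character(length(tree$ranks))
  names(out) <- tree$ranks
  cur <- genus
  for (r in rev(seq_along(tree$ranks))) {
    row <- nodes[nodes$taxon == cur & nodes$rank == tree$ranks[r], ]
    if (nrow(row) != 1)
      stop(sprintf("taxon '%s' not found at rank '%s'", cur, tree$ranks[r]))
    out[r] <- cur
    cur <- row$parent
  }
  out
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  counts <- table(factor(x$nodes$rank, levels = x$ranks))
  cat("taxonomy_tree:",
      paste(sprintf("%d %s", as.integer(counts), names(counts)), collapse = ", "),
      "\n")
  invisible(x)
}

# parent lookup tables (one per rank below phylum) built from a set of
# lineage rows; used for conflict resolution and truth checks
lineage_parent_maps <- function(lineages) {
  ranks <- .RANKS
  maps <- list()
  for (ri in 2:length(ranks)) {
    pairs <- unique(lineages[, c(ranks[ri - 1], ranks[ri])])
    pairs <- pairs[!is.na(pairs[[2]]), ]
    maps[[ranks[ri]]] <- setNames(pairs[[1]], pairs[[2]])
  }
  maps
}
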