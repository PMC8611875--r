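#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `Abar = D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree
#' matrix of `A + I`. All eigenvalues lie in `[-1, 1]` and the diagonal is
#' positive, so repeated application in the graph convolution cannot blow
#' up activations.
#'
#' @param edges data.frame with columns `from`, `to` (self-edges ignored;
#'   each undirected edge listed once).
#' @param node_ids character vector fixing the node order.
#' @return sparse symmetric matrix (class from the Matrix package) with
#'   dimnames `node_ids`.
#' @export
normalize_adjacency <- function(edges, node_ids) {
  K <- length(node_ids)
  i <- match(edges$from, node_ids)
  j <- match(edges$to, node_ids)
  if (anyNA(i) || anyNA(j)) stop("edge references unknown node")
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  A <- Matrix::sparseMatrix(i = c(i, j, seq_len(K)), j = c(j, i, seq_len(K)),
                            x = 1, dims = c(K, K), use.last.ij = TRUE)
  A@x[] <- 1  # duplicate edges collapse to weight 1
  d <- Matrix::rowSums(A)
  Dh <- Matrix::Diagonal(K, 1 / sqrt(d))
  Ab <- Dh %*% A %*% Dh
  dimnames(Ab) <- list(node_ids, node_ids)
  methods::as(Ab, "CsparseMatrix")
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Two-layer graph convolution forward pass
#'
#' `H^(l+1) = ReLU(Abar H^(l) theta^(l))` for `l = 0, 1`, followed by a
#' dense layer and a row-wise SoftMax.
#'
#' @param H0 node feature matrix (K x d).
#' @param Abar normalized adjacency from [normalize_adjacency()].
#' @param params list with `theta0`, `theta1`, `theta_dense`.
#' @return list with `probs` (K x C, rows sum to 1) and the
#'   pre-activations/hidden layers used for backpropagation.
#' @export
gcn_forward <- function(H0, Abar, params) {
  if (ncol(H0) != nrow(params$theta0)) stop("feature/theta0 shape mismatch")
  M1 <- as.matrix(Abar %*% (H0 %*% params$theta0))
  H1 <- pmax(M1, 0)
  M2 <- as.matrix(Abar %*% (H1 %*% params$theta1))
  H2 <- pmax(M2, 0)
  Z <- H2 %*% params$theta_dense
  list(probs = row_softmax(Z), M1 = M1, H1 = H1, M2 = M2, H2 = H2, Z = Z)
}

#' Expected calibration error
#'
#' Confidences are binned into `n_bins` equal-width bins (`[i/N, (i+1)/N)`,
#' top bin closed); `ECE = sum_i (T_i/T) |Acc_i - conf_i|` over non-empty
#' bins, where `Acc_i` is the bin's accuracy and `conf_i` its mean
#' confidence.
#'
#' @param confidences numeric in `[0, 1]`.
#' @param correct logical (or 0/1) of the same length.
#' @param n_bins number of bins.
#' @return object of class `calibration_report`: list with `ece`, `n` and
#'   `bins` (data.frame `bin`, `lower`, `upper`, `count`, `accuracy`,
#'   `confidence`; accuracy/confidence are `NA` for empty bins).
#' @export
ece <- function(confidences, correct, n_bins = 10) {
  if (length(confidences) == 0) stop("empty input")
  if (length(confidences) != length(correct)) stop("length mismatch")
  if (any(confidences < 0 | confidences > 1)) stop("confidences must be in [0, 1]")
  correct <- as.numeric(correct)
  bin <- pmin(floor(confidences * n_bins) + 1L, n_bins)
  count <- tabulate(bin, n_bins)
  acc <- conf <- rep(NA_real_, n_bins)
  for (i in which(count > 0)) {
    sel <- bin == i
    acc[i] <- mean(correct[sel])
    conf[i] <- mean(confidences[sel])
  }
  nz <- count > 0
  e <- sum((count[nz] / length(confidences)) * abs(acc[nz] - conf[nz]))
  structure(list(ece = e, n = length(confidences),
                 bins = data.frame(bin = seq_len(n_bins),
                                   lower = (seq_len(n_bins) - 1) / n_bins,
                                   upper = seq_len(n_bins) / n_bins,
                                   count = count, accuracy = acc,
                                   confidence = conf)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report: ECE = %.4f over %d samples, %d bins\n",
              x$ece, x$n, nrow(x$bins)))
  invisible(x)
}

#' Training loss of the calibrated GCN
#'
#' `L = ECE + L2` over the labeled (masked) nodes: `L2` is the mean over
#' masked nodes of the mean squared difference between the SoftMax row and
#' the one-hot label; `ECE` uses each masked node's maximum SoftMax value
#' as confidence and argmax-vs-label as correctness.
#'
#' @param probs SoftMax matrix (K x C).
#' @param labels_idx integer class index per node (`NA` for unlabeled).
#' @param mask integer indices of labeled nodes entering the loss.
#' @param n_bins ECE bins.
#' @param include_ece if `FALSE`, the loss is L2 only.
#' @return list with `loss`, `l2`, `ece`.
#' @export
gcn_loss <- function(probs, labels_idx, mask, n_bins = 10, include_ece = TRUE) {
  if (length(mask) == 0) stop("empty mask")
  C <- ncol(probs)
  P <- probs[mask, , drop = FALSE]
  y <- labels_idx[mask]
  Y <- matrix(0, length(mask), C)
  Y[cbind(seq_along(mask), y)] <- 1
  l2 <- mean(rowMeans((P - Y)^2))
  conf <- apply(P, 1, max)
  pred <- max.col(P, ties.method = "first")
  e <- if (include_ece) ece(conf, pred == y, n_bins)$ece else 0
  list(loss = l2 + e, l2 = l2, ece = e)
}

#' GCN training configuration
#'
#' @param hidden1,hidden2 graph-convolution layer widths.
#' @param epochs full-batch Adam steps.
#' @param learning_rate Adam step size.
#' @param n_bins ECE bins in the loss.
#' @param loss `"ece_l2"` (calibration-aware, the default) or `"l2"`.
#' @param ece_include_hosts whether host nodes (always correct by
#'   construction once the model fits them) enter the ECE bins.
#' @return list of class `gcn_config`.
#' @export
gcn_config <- function(hidden1 = 256, hidden2 = 128, epochs = 200,
                       learning_rate = 1e-3, n_bins = 10,
                       loss = c("ece_l2", "l2"), ece_include_hosts = TRUE) {
  loss <- match.arg(loss)
  structure(list(hidden1 = hidden1, hidden2 = hidden2, epochs = epochs,
                 learning_rate = learning_rate, n_bins = n_bins, loss = loss,
                 ece_include_hosts = ece_include_hosts),
            class = "gcn_config")
}

adam_new <- function(p) list(m = p * 0, v = p * 0)
adam_step <- function(state, p, g, lr, t) {
  state$m <- 0.9 * state$m + 0.1 * g
  state$v <- 0.999 * state$v + 0.001 * g^2
  p <- p - lr * (state$m / (1 - 0.9^t)) /
    (sqrt(state$v / (1 - 0.999^t)) + 1e-8)
  list(state = state, p = p)
}

glorot <- function(nr, nc) {
  matrix((runif(nr * nc) * 2 - 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Train the per-rank graph convolutional classifier
#'
#' Full-batch Adam on `L = ECE + L2` (or L2 alone) over the labeled nodes:
#' all hosts plus the training viruses. The ECE term is differentiated
#' straight-through — bin membership and per-bin accuracies are treated as
#' constants within a step, so the gradient moves each sample's confidence
#' toward its bin's accuracy. Node features are standardized column-wise
#' before training (the scaling is stored in the model).
#'
#' @param graph a [build_knowledge_graph()] object with features set.
#' @param rank one of phylum, class, order, family, genus.
#' @param config a [gcn_config()].
#' @param rng_seed integer seed for the parameter initialisation.
#' @return object of class `gcn_model`.
#' @export
train_gcn <- function(graph, rank = "genus", config = gcn_config(),
                      rng_seed = 1) {
  stopifnot(inherits(graph, "knowledge_graph"), rank %in% .RANKS)
  if (is.null(graph$features)) stop("graph features are not set")
  lab <- graph$labels[[rank]]
  vocab <- sort(unique(lab[!is.na(lab)]))
  if (length(vocab) < 2)
    stop("need >= 2 label classes at rank '", rank, "'")
  y <- match(lab, vocab)
  mask <- which(!is.na(y))
  K <- length(graph$ids)
  C <- length(vocab)

  center <- colMeans(graph$features)
  scale <- apply(graph$features, 2, stats::sd)
  scale[scale == 0] <- 1
  H0 <- sweep(sweep(graph$features, 2, center), 2, scale, "/")
  Abar <- normalize_adjacency(graph$edges, graph$ids)

  set.seed(rng_seed)
  params <- list(theta0 = glorot(ncol(H0), config$hidden1),
                 theta1 = glorot(config$hidden1, config$hidden2),
                 theta_dense = glorot(config$hidden2, C))
  opt <- lapply(params, adam_new)

  Tm <- length(mask)
  Y <- matrix(0, Tm, C)
  Y[cbind(seq_len(Tm), y[mask])] <- 1
  ece_mask_sel <- if (config$ece_include_hosts) seq_len(Tm)
    else which(graph$roles[graph$ids[mask]] == "virus")

  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fw <- gcn_forward(H0, Abar, params)
    P <- fw$probs
    Pm <- P[mask, , drop = FALSE]
    dP <- matrix(0, K, C)
    dP[mask, ] <- (2 / (Tm * C)) * (Pm - Y)
    l2 <- mean(rowMeans((Pm - Y)^2))
    e <- 0
    if (config$loss == "ece_l2" && length(ece_mask_sel) > 0) {
      conf <- apply(Pm[ece_mask_sel, , drop = FALSE], 1, max)
      pred <- max.col(Pm[ece_mask_sel, , drop = FALSE], ties.method = "first")
      correct <- pred == y[mask][ece_mask_sel]
      rep_ <- ece(conf, correct, config$n_bins)
      e <- rep_$ece
      bin <- pmin(floor(conf * config$n_bins) + 1L, config$n_bins)
      gap_sign <- sign(rep_$bins$confidence[bin] - rep_$bins$accuracy[bin])
      rows <- mask[ece_mask_sel]
      dP[cbind(rows, pred)] <- dP[cbind(rows, pred)] +
        gap_sign / length(ece_mask_sel)
    }
    history[ep] <- l2 + e

    # backprop through the row softmax: dZ = P * (dP - rowSums(dP * P))
    dZ <- P * (dP - rowSums(dP * P))
    dthd <- crossprod(fw$H2, dZ)
    dH2 <- dZ %*% t(params$theta_dense)
    dM2 <- dH2 * (fw$M2 > 0)
    AH1 <- as.matrix(Abar %*% fw$H1)
    dth1 <- crossprod(AH1, dM2)
    dH1 <- as.matrix(Abar %*% dM2) %*% t(params$theta1)
    dM1 <- dH1 * (fw$M1 > 0)
    dth0 <- crossprod(as.matrix(Abar %*% H0), dM1)

    for (nm_g in list(c("theta0", "dth0"), c("theta1", "dth1"),
                      c("theta_dense", "dthd"))) {
      nm <- nm_g[1]
      g <- get(nm_g[2])
      st <- adam_step(opt[[nm]], params[[nm]], g, config$learning_rate, ep)
      opt[[nm]] <- st$state
      params[[nm]] <- st$p
    }
  }

  fw <- gcn_forward(H0, Abar, params)
  Pm <- fw$probs[mask, , drop = FALSE]
  conf <- apply(Pm, 1, max)
  pred <- max.col(Pm, ties.method = "first")
  calibration <- ece(conf, pred == y[mask], config$n_bins)

  structure(list(rank = rank, vocab = vocab, params = params,
                 config = config, rng_seed = rng_seed,
                 loss_history = history, calibration = calibration,
                 node_ids = graph$ids, center = center, scale = scale),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("gcn_model [%s]: %d classes, %d nodes, final loss %.4f, training ECE %.4f\n",
              x$rank, length(x$vocab), length(x$node_ids),
              utils::tail(x$loss_history, 1), x$calibration$ece))
  invisible(x)
}

# degenerate rank: a single taxon among the labeled nodes; the only
# consistent output is that taxon, reported with full confidence
constant_rank_model <- function(rank, taxon) {
  structure(list(rank = rank, vocab = taxon), class = "constant_rank_model")
}

#' Train one model per taxonomic rank
#'
#' Trains phylum first, genus last, reusing the same graph with
#' rank-specific labels. Ranks with a single labeled taxon get a constant
#' predictor (the degenerate SoftMax case the GCN cannot be trained on).
#'
#' @param graph a featured [build_knowledge_graph()] object.
#' @param config a [gcn_config()].
#' @param rng_seed base seed; rank `r` trains with `rng_seed + r - 1`.
#' @return named list of models, phylum first.
#' @export
train_rank_models <- function(graph, config = gcn_config(), rng_seed = 1) {
  models <- list()
  for (ri in seq_along(.RANKS)) {
    rank <- .RANKS[ri]
    lab <- graph$labels[[rank]]
    vocab <- sort(unique(lab[!is.na(lab)]))
    models[[rank]] <- if (length(vocab) < 2)
      constant_rank_model(rank, vocab)
    else train_gcn(graph, rank, config, rng_seed + ri - 1)
  }
  models
}

#' Resolve cross-rank conflicts in a predicted lineage
#'
#' Walks the ranks from phylum downward; at the first rank whose predicted
#' taxon is missing (abstained) or is not a child of the taxon reported at
#' the rank above, the report is truncated — the higher rank is kept, that
#' rank and everything below are dropped.
#'
#' @param lineage named character vector over the five ranks (NA =
#'   abstained).
#' @param lineages data.frame of known lineages (columns `phylum`..
#'   `genus`) used to derive parent relations; every non-NA predicted
#'   taxon must occur in it.
#' @return named character vector with `NA` from the truncation point on.
#' @export
resolve_conflicts <- function(lineage, lineages) {
  maps <- lineage_parent_maps(lineages)
  out <- setNames(rep(NA_character_, length(.RANKS)), .RANKS)
  prev <- NULL
  for (ri in seq_along(.RANKS)) {
    r <- .RANKS[ri]
    t <- lineage[[r]]
    if (is.na(t)) break
    if (ri == 1) {
      if (!t %in% lineages$phylum) stop("predicted taxon not in taxonomy: ", t)
    } else {
      if (!t %in% names(maps[[r]])) stop("predicted taxon not in taxonomy: ", t)
      if (maps[[r]][[t]] != prev) break  # conflict: keep the higher ranks
    }
    out[r] <- t
    prev <- t
  }
  out
}

#' Predict host taxa for the query viruses
#'
#' For every unlabeled virus and every rank, the argmax SoftMax taxon with
#' its value as confidence. Ranks with confidence below `threshold`
#' abstain. The conflict-resolved lineage is flagged in the `reported`
#' column; viruses with no edges at all are flagged `no_neighbors` (their
#' prediction rests on their own features via the self-loop only).
#'
#' @param graph the graph the models were trained on.
#' @param models list from [train_rank_models()].
#' @param threshold SoftMax confidence threshold in `[0, 1]`.
#' @return data.frame of class `host_predictions`: `virus_id`, `rank`,
#'   `taxon`, `confidence`, `abstained`, `reported`, `no_neighbors`.
#' @export
predict_hosts <- function(graph, models, threshold = 0) {
  stopifnot(inherits(graph, "knowledge_graph"))
  query <- graph$ids[graph$roles == "virus" & is.na(graph$labels$genus)]
  if (length(query) == 0) stop("no unlabeled virus nodes to predict")
  connected <- unique(c(graph$edges$from, graph$edges$to))
  Abar <- NULL
  rows <- list()
  for (rank in .RANKS) {
    m <- models[[rank]]
    if (is.null(m)) next
    if (inherits(m, "constant_rank_model")) {
      taxon <- rep(m$vocab, length(query))
      conf <- rep(1, length(query))
    } else {
      if (!identical(m$node_ids, graph$ids))
        stop("model was trained on a different node set")
      if (is.null(Abar)) Abar <- normalize_adjacency(graph$edges, graph$ids)
      H0 <- sweep(sweep(graph$features, 2, m$center), 2, m$scale, "/")
      P <- gcn_forward(H0, Abar, m$params)$probs
      Pq <- P[match(query, graph$ids), , drop = FALSE]
      taxon <- m$vocab[max.col(Pq, ties.method = "first")]
      conf <- apply(Pq, 1, max)
    }
    rows[[rank]] <- data.frame(virus_id = query, rank = rank, taxon = taxon,
                               confidence = conf,
                               abstained = conf < threshold,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  host_lineages <- graph$labels[graph$roles[graph$labels$node_id] == "host",
                                .RANKS]
  out$reported <- FALSE
  for (v in query) {
    sel <- out$virus_id == v
    lin <- setNames(out$taxon[sel][match(.RANKS, out$rank[sel])], .RANKS)
    lin[out$abstained[sel][match(.RANKS, out$rank[sel])]] <- NA
    rep_lin <- resolve_conflicts(lin, host_lineages)
    out$reported[sel] <- !is.na(rep_lin[out$rank[sel]])
  }
  out$no_neighbors <- !(out$virus_id %in% connected)
  structure(out, class = c("host_predictions", "data.frame"),
            threshold = threshold)
}

#' Per-rank prediction rate and accuracy
#'
#' Prediction rate is the fraction of query viruses with a (non-abstained)
#' prediction at the rank; accuracy is computed only over those, and is
#' `NA` when nothing was predicted.
#'
#' @param predictions a [predict_hosts()] data.frame.
#' @param truth data.frame with `virus_id` and the five rank columns.
#' @return data.frame: `rank`, `n_total`, `n_predicted`,
#'   `prediction_rate`, `accuracy`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  n_total <- length(unique(predictions$virus_id))
  do.call(rbind, lapply(.RANKS, function(r) {
    p <- predictions[predictions$rank == r & !predictions$abstained, ,
                     drop = FALSE]
    tv <- truth[[r]][match(p$virus_id, truth$virus_id)]
    if (anyNA(tv)) stop("truth table does not cover all evaluated viruses")
    data.frame(rank = r, n_total = n_total, n_predicted = nrow(p),
               prediction_rate = nrow(p) / n_total,
               accuracy = if (nrow(p) == 0) NA_real_ else mean(p$taxon == tv),
               stringsAsFactors = FALSE)
  }))
}
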