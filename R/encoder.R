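all_kmers <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  do.call(paste0, g)
}

# 1-based tokens in 1..4^k, 0 for windows containing non-ACGT characters
kmer_tokens <- function(sequence, k) {
  code <- kmer_codes(sequence, k)
  tok <- code + 1L
  tok[is.na(tok)] <- 0L
  tok
}

#' Train a skip-gram k-mer embedding
#'
#' Skip-gram with negative sampling over the overlapping k-mer streams of
#' the supplied segments, mapping contextually similar k-mers to nearby
#' vectors. N-containing k-mers are masked (they later embed as zero
#' rows).
#'
#' @param segments character vector of nucleotide segments.
#' @param k k-mer length (vocabulary `4^k`).
#' @param d embedding dimension.
#' @param window context half-width.
#' @param negatives negative samples per context.
#' @param epochs passes over the token streams.
#' @param learning_rate initial SGD rate (decays linearly).
#' @param rng_seed integer seed; training is deterministic given it.
#' @return object of class `kmer_embedding`: list with `k`, `d` and
#'   `table` (a `4^k x d` matrix, rownames the k-mers).
#' @export
train_skipgram <- function(segments, k = 3, d = 100, window = 3,
                           negatives = 5, epochs = 3, learning_rate = 0.05,
                           rng_seed = 1) {
  stopifnot(length(segments) >= 1, k >= 1)
  if (any(nchar(segments) < k)) stop("`k` larger than a segment")
  streams <- lapply(segments, kmer_tokens, k = k)
  set.seed(rng_seed)
  tab <- cpp_skipgram_train(streams, 4L^k, as.integer(d), as.integer(window),
                            as.integer(negatives), as.integer(epochs),
                            learning_rate)
  rownames(tab) <- all_kmers(k)
  structure(list(k = k, d = d, table = tab), class = "kmer_embedding")
}

#' Embed a segment as a k-mer matrix
#'
#' Row `t` is the embedding of the k-mer starting at position `t`
#' (`L - k + 1` rows in total); windows containing N embed as zero rows.
#'
#' @param segment nucleotide string.
#' @param embedding a [train_skipgram()] embedding.
#' @return numeric matrix of shape `(L - k + 1) x d`.
#' @export
embed_segment <- function(segment, embedding) {
  stopifnot(inherits(embedding, "kmer_embedding"))
  tok <- kmer_tokens(segment, embedding$k)
  M <- matrix(0, length(tok), embedding$d)
  nz <- tok > 0
  M[nz, ] <- embedding$table[tok[nz], , drop = FALSE]
  M
}

#' Convolutional encoder configuration
#'
#' @param widths filter widths of the parallel convolutional layers
#'   (multi-scale motif capture).
#' @param n_filters filters per width.
#' @param dense1 first dense layer size — this is the node-feature
#'   dimension of the knowledge graph.
#' @param dense2 second dense layer size.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param segment_length genome segment length in bp.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(widths = c(4, 8, 16), n_filters = 64, dense1 = 512,
                       dense2 = 256, epochs = 15, batch_size = 32,
                       learning_rate = 2e-3, segment_length = 2000) {
  structure(as.list(environment()), class = "cnn_config")
}

genomes_to_tokens <- function(genomes, embedding, L) {
  segs <- lapply(names(genomes), function(id)
    segment_genome(genomes[[id]], id, L))
  seg_df <- do.call(rbind, segs)
  tok <- t(vapply(seg_df$sequence, kmer_tokens, integer(L - embedding$k + 1),
                  k = embedding$k, USE.NAMES = FALSE))
  list(tokens = tok, parent = seg_df$parent_id)
}

#' Train the segment classifier used as sequence encoder
#'
#' Genomes are cut into fixed-length segments which inherit the genome's
#' genus label; parallel convolutions of several widths over the skip-gram
#' embedded segment are globally max-pooled, concatenated and passed
#' through two ReLU dense layers to a SoftMax over genera, trained with
#' cross-entropy. The first dense layer is the encoding later used for
#' graph nodes. Genomes are processed in sorted-id order, so training is
#' invariant to the input order given the same seed.
#'
#' @param genomes named character vector of nucleotide genomes.
#' @param labels named character vector (genus per genome id).
#' @param embedding a [train_skipgram()] embedding.
#' @param config a [cnn_config()].
#' @param rng_seed integer seed.
#' @return object of class `cnn_model`: the layer weights, the class
#'   vocabulary, the config and the per-epoch training loss.
#' @export
train_cnn <- function(genomes, labels, embedding, config = cnn_config(),
                      rng_seed = 1) {
  stopifnot(inherits(embedding, "kmer_embedding"),
            inherits(config, "cnn_config"))
  labels <- labels[names(genomes)]
  if (anyNA(labels)) stop("every genome needs a label")
  classes <- sort(unique(unname(labels)))
  if (length(classes) < 2)
    stop("need >= 2 classes to train the encoder (SoftMax is degenerate)")
  genomes <- genomes[order(names(genomes))]
  gt <- genomes_to_tokens(genomes, embedding, config$segment_length)
  y <- match(labels[gt$parent], classes)
  set.seed(rng_seed)
  w <- cpp_cnn_train(gt$tokens, as.integer(y), embedding$table,
                     as.integer(config$widths), as.integer(config$n_filters),
                     as.integer(config$dense1), as.integer(config$dense2),
                     length(classes), as.integer(config$epochs),
                     as.integer(config$batch_size), config$learning_rate)
  structure(list(weights = w[names(w) != "epoch_loss"],
                 epoch_loss = w$epoch_loss, classes = classes,
                 config = config, k = embedding$k),
            class = "cnn_model")
}

#' Encode a sequence as a node feature vector
#'
#' Encoding mode: each segment's first-dense-layer activation (post-ReLU)
#' is computed and the segment vectors are averaged, so the encoding is
#' invariant to segment order and has only non-negative entries.
#'
#' @param sequence nucleotide string.
#' @param embedding the embedding used at training time.
#' @param cnn a [train_cnn()] model.
#' @return numeric vector of length `config$dense1`.
#' @export
encode_sequence <- function(sequence, embedding, cnn) {
  stopifnot(inherits(cnn, "cnn_model"))
  seg <- segment_genome(sequence, "x", cnn$config$segment_length)
  tok <- t(vapply(seg$sequence, kmer_tokens,
                  integer(cnn$config$segment_length - embedding$k + 1),
                  k = embedding$k, USE.NAMES = FALSE))
  H <- cpp_cnn_first_dense(tok, embedding$table, cnn$weights)
  colMeans(H)
}

#' Encode many sequences
#'
#' @param genomes named character vector.
#' @inheritParams encode_sequence
#' @return matrix with one row per genome (rownames = ids).
#' @export
encode_sequences <- function(genomes, embedding, cnn) {
  t(vapply(genomes, encode_sequence, numeric(cnn$config$dense1),
           embedding = embedding, cnn = cnn))
}

#' Train-mode SoftMax output per segment
#'
#' @param segments character vector of segments (length
#'   `config$segment_length`).
#' @inheritParams encode_sequence
#' @return matrix of class probabilities (columns follow `cnn$classes`).
#' @export
cnn_predict_segments <- function(segments, embedding, cnn) {
  stopifnot(inherits(cnn, "cnn_model"))
  tok <- t(vapply(segments, kmer_tokens,
                  integer(nchar(segments[1]) - embedding$k + 1),
                  k = embedding$k, USE.NAMES = FALSE))
  p <- cpp_cnn_predict(tok, embedding$table, cnn$weights)
  colnames(p) <- cnn$classes
  p
}
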