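toy_embedding <- function(k = 3, d = 8) {
  set.seed(99)
  tab <- matrix(rnorm(4^k * d), 4^k, d)
  rownames(tab) <- hostnet:::all_kmers(k)
  structure(list(k = k, d = d, table = tab), class = "kmer_embedding")
}

test_that("skip-gram covers the 4^k vocabulary and is seed-deterministic", {
  segs <- replicate(6, paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                             collapse = ""))
  e1 <- train_skipgram(segs, k = 3, d = 10, epochs = 1, rng_seed = 5)
  e2 <- train_skipgram(segs, k = 3, d = 10, epochs = 1, rng_seed = 5)
  e3 <- train_skipgram(segs, k = 3, d = 10, epochs = 1, rng_seed = 6)
  expect_equal(dim(e1$table), c(64, 10))
  expect_identical(e1$table, e2$table)
  expect_false(identical(e1$table, e3$table))
  expect_error(train_skipgram("ACG", k = 5), "larger than a segment")
})

test_that("k-mers sharing contexts embed closer than unrelated k-mers", {
  # two interchangeable motifs embedded in a fixed context: AAA and CCC
  # always appear between GGG...GGG, TTT never does
  set.seed(2)
  segs <- replicate(300, {
    core <- sample(c("AAA", "CCC"), 1)
    paste0("GGGGGG", core, "GGGGGG")
  })
  emb <- train_skipgram(segs, k = 3, d = 12, window = 2, epochs = 10,
                        rng_seed = 3)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  tab <- emb$table
  expect_gt(cosine(tab["AAA", ], tab["CCC", ]),
            cosine(tab["AAA", ], tab["TTT", ]))
})

test_that("segment embedding has L-k+1 rows and zeros for N windows", {
  emb <- toy_embedding()
  M <- embed_segment(strrep("N", 50), emb)
  expect_equal(dim(M), c(48, 8))
  expect_true(all(M == 0))
  M2 <- embed_segment(paste0(strrep("A", 10), "N", strrep("C", 10)), emb)
  expect_equal(nrow(M2), 19)
  expect_true(all(M2[9:11, ] == 0))          # windows covering the N
  expect_equal(M2[1, ], emb$table["AAA", ])  # poly-A rows identical
  expect_equal(M2[2, ], M2[1, ])
})

train_toy_cnn <- function(seed = 1, genomes = NULL, epochs = 6) {
  com <- small_community()
  emb <- toy_embedding()
  lab <- setNames(com$truth$genus, com$truth$virus_id)
  genomes <- genomes %||% com$viruses
  cfg <- cnn_config(widths = c(4, 8), n_filters = 8, dense1 = 32, dense2 = 16,
                    epochs = epochs, batch_size = 16)
  list(com = com, emb = emb,
       cnn = train_cnn(genomes, lab, emb, cfg, rng_seed = seed))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("CNN training is deterministic and invariant to genome order", {
  f1 <- train_toy_cnn(seed = 4)
  f2 <- train_toy_cnn(seed = 4, genomes = rev(small_community()$viruses))
  expect_equal(f1$cnn$epoch_loss, f2$cnn$epoch_loss, tolerance = 1e-10)
  expect_lt(f1$cnn$epoch_loss[6], f1$cnn$epoch_loss[1])  # it learns
})

test_that("CNN refuses a single class", {
  com <- small_community()
  emb <- toy_embedding()
  lab <- setNames(rep("g01", length(com$viruses)), names(com$viruses))
  expect_error(train_cnn(com$viruses, lab, emb, cnn_config(), 1), "2 classes")
})

test_that("SoftMax rows sum to one and held-out segments beat chance", {
  com <- small_community()
  emb <- toy_embedding()
  lab <- setNames(com$truth$genus, com$truth$virus_id)
  heldout <- c("virus_g01_04", "virus_g02_04")
  cfg <- cnn_config(widths = c(4, 8), n_filters = 8, dense1 = 32, dense2 = 16,
                    epochs = 30, batch_size = 16)
  cnn <- train_cnn(com$viruses[setdiff(names(com$viruses), heldout)], lab,
                   emb, cfg, rng_seed = 2)
  segs <- unlist(lapply(heldout, function(v)
    segment_genome(com$viruses[[v]], v)$sequence))
  p <- cnn_predict_segments(segs, emb, cnn)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  truth <- rep(lab[heldout], each = nrow(p) / 2)
  acc <- mean(colnames(p)[max.col(p)] == truth)
  expect_gt(acc, 1 / 2 + 0.2)
})

test_that("encoding averages segments, is order-invariant and non-negative", {
  f <- train_toy_cnn(seed = 7)
  v <- f$com$viruses[[1]]
  enc <- encode_sequence(v, f$emb, f$cnn)
  expect_length(enc, 32)
  expect_true(all(enc >= 0))
  # a genome that is one segment repeated twice encodes like the segment
  seg <- segment_genome(v, "x")$sequence[1]
  enc1 <- encode_sequence(seg, f$emb, f$cnn)
  enc2 <- encode_sequence(paste0(seg, seg), f$emb, f$cnn)
  expect_equal(enc1, enc2, tolerance = 1e-12)
})

test_that("train and encode modes are consistent for a single segment", {
  f <- train_toy_cnn(seed = 3)
  seg <- segment_genome(f$com$viruses[[2]], "x")$sequence[1]
  enc <- encode_sequence(seg, f$emb, f$cnn)  # ReLU(first dense layer)
  w <- f$cnn$weights
  a2 <- pmax(as.numeric(enc %*% w$w1) + as.numeric(w$b1), 0)
  z3 <- as.numeric(a2 %*% w$w2) + as.numeric(w$b2)
  p_manual <- exp(z3 - max(z3)) / sum(exp(z3 - max(z3)))
  p_train <- cnn_predict_segments(seg, f$emb, f$cnn)[1, ]
  expect_equal(unname(p_train), p_manual, tolerance = 1e-9)
})
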