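test_that("normalized adjacency matches the two-node worked case", {
  ed <- data.frame(from = "a", to = "b")
  Ab <- normalize_adjacency(ed, c("a", "b"))
  expect_equal(as.matrix(Ab), matrix(0.5, 2, 2, dimnames = list(c("a", "b"),
                                                                c("a", "b"))))
  # edgeless graph: identity
  Ab0 <- normalize_adjacency(ed[0, ], c("x", "y", "z"))
  expect_equal(unname(as.matrix(Ab0)), diag(3))
})

test_that("normalized adjacency is symmetric with spectral radius <= 1", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    ed <- random_edge_list(n)
    Ab <- as.matrix(normalize_adjacency(ed, sprintf("n%02d", seq_len(n))))
    expect_equal(Ab, t(Ab), tolerance = 1e-12)
    ev <- eigen(Ab, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
    expect_true(all(diag(Ab) > 0))
  }
})

random_gcn_params <- function(d, h1, h2, C) {
  list(theta0 = matrix(rnorm(d * h1), d, h1),
       theta1 = matrix(rnorm(h1 * h2), h1, h2),
       theta_dense = matrix(rnorm(h2 * C), h2, C))
}

test_that("forward pass yields simplex rows and per-node independence without edges", {
  set.seed(21)
  K <- 6
  H0 <- matrix(rnorm(K * 10), K, 10)
  prm <- random_gcn_params(10, 7, 5, 3)
  ed <- random_edge_list(K, 0.5)
  Ab <- normalize_adjacency(ed, sprintf("n%02d", 1:K))
  P <- gcn_forward(H0, Ab, prm)$probs
  expect_equal(unname(rowSums(P)), rep(1, K), tolerance = 1e-9)

  # identity adjacency: changing node 1's feature leaves other rows alone
  I6 <- normalize_adjacency(ed[0, ], sprintf("n%02d", 1:K))
  P1 <- gcn_forward(H0, I6, prm)$probs
  H0b <- H0; H0b[1, ] <- rnorm(10)
  P2 <- gcn_forward(H0b, I6, prm)$probs
  expect_equal(P1[-1, ], P2[-1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(P1[1, ], P2[1, ])))
})

test_that("forward pass is permutation-equivariant", {
  set.seed(31)
  K <- 6
  ids <- sprintf("n%02d", 1:K)
  ed <- random_edge_list(K, 0.5)
  H0 <- matrix(rnorm(K * 8), K, 8, dimnames = list(ids, NULL))
  prm <- random_gcn_params(8, 6, 4, 3)
  P <- gcn_forward(H0, normalize_adjacency(ed, ids), prm)$probs
  perm <- sample(K)
  P2 <- gcn_forward(H0[perm, ], normalize_adjacency(ed, ids[perm]), prm)$probs
  expect_equal(P2, P[perm, ], tolerance = 1e-10)
})

test_that("ece matches the hand-computed example and an independent loop", {
  r <- ece(c(0.95, 0.85, 0.65, 0.30), c(TRUE, TRUE, FALSE, TRUE), 10)
  expect_equal(r$ece, (0.05 + 0.15 + 0.65 + 0.70) / 4, tolerance = 1e-12)
  expect_equal(ece(rep(1, 5), rep(TRUE, 5))$ece, 0)
  # all samples in one bin with Acc == conf exactly
  expect_equal(ece(c(0.5, 0.5), c(FALSE, TRUE))$ece, 0, tolerance = 1e-12)
  # two half-full bins: 0.5*|0 - 0.6| + 0.5*|1 - 0.7|
  expect_equal(ece(c(0.6, 0.7), c(FALSE, TRUE))$ece, 0.45, tolerance = 1e-12)
  set.seed(13)
  conf <- runif(1000)
  correct <- runif(1000) < conf
  expect_equal(ece(conf, correct)$ece, ece_oracle(conf, correct),
               tolerance = 1e-12)
  expect_equal(sum(ece(conf, correct)$bins$count), 1000)
  expect_error(ece(numeric(0), logical(0)), "empty")
  expect_error(ece(1.2, TRUE), "0, 1")
})

test_that("loss is zero for perfect one-hot output and matches the closed form", {
  P <- diag(3)
  l <- gcn_loss(P, labels_idx = 1:3, mask = 1:3)
  expect_equal(l$loss, 0)
  # uniform outputs, all nodes labeled class 1
  C <- 4
  P <- matrix(1 / C, 5, C)
  l2 <- gcn_loss(P, labels_idx = rep(1, 5), mask = 1:5, include_ece = FALSE)
  expect_equal(l2$l2, ((1 - 1 / C)^2 + (C - 1) / C^2) / C, tolerance = 1e-12)
  # masking out a node changes the loss iff it is labeled differently
  P2 <- rbind(diag(3), c(0.2, 0.3, 0.5))
  la <- c(1, 2, 3, 1)
  expect_false(gcn_loss(P2, la, 1:4)$loss == gcn_loss(P2, la, 1:3)$loss)
  expect_error(gcn_loss(P2, la, integer(0)), "empty mask")
})

test_that("conflicting lineages are truncated at the first inconsistency", {
  lineages <- data.frame(phylum = c("p1", "p1"), class = c("c1", "c1"),
                         order = c("o1", "o2"), family = c("f1", "f2"),
                         genus = c("g1", "g2"), stringsAsFactors = FALSE)
  ok <- setNames(c("p1", "c1", "o1", "f1", "g1"), hostnet:::.RANKS)
  expect_equal(resolve_conflicts(ok, lineages), ok)
  # genus from the other family: truncated after family
  mix <- setNames(c("p1", "c1", "o1", "f1", "g2"), hostnet:::.RANKS)
  out <- resolve_conflicts(mix, lineages)
  expect_equal(unname(out[c("family", "genus")]), c("f1", NA))
  # conflict at class level leaves only the phylum
  lineages2 <- rbind(lineages,
                     data.frame(phylum = "p2", class = "c9", order = "o9",
                                family = "f9", genus = "g9"))
  mix2 <- setNames(c("p1", "c9", "o9", "f9", "g9"), hostnet:::.RANKS)
  out2 <- resolve_conflicts(mix2, lineages2)
  expect_equal(unname(out2), c("p1", NA, NA, NA, NA))
  expect_error(resolve_conflicts(setNames(c("p1", "cX", NA, NA, NA),
                                          hostnet:::.RANKS), lineages),
               "not in taxonomy")
})

test_that("evaluation implements rate and accuracy per rank", {
  pred <- data.frame(
    virus_id = rep(sprintf("v%02d", 1:10), each = 1), rank = "genus",
    taxon = c(rep("g1", 6), rep("g2", 2), "g1", "g1"),
    confidence = c(rep(0.9, 8), 0.2, 0.2),
    abstained = c(rep(FALSE, 8), TRUE, TRUE),
    reported = c(rep(TRUE, 8), FALSE, FALSE), no_neighbors = FALSE,
    stringsAsFactors = FALSE)
  truth <- data.frame(virus_id = sprintf("v%02d", 1:10), phylum = "p",
                      class = "c", order = "o", family = "f",
                      genus = c(rep("g1", 6), rep("g9", 4)),
                      stringsAsFactors = FALSE)
  ev <- evaluate_predictions(pred, truth)
  g <- ev[ev$rank == "genus", ]
  expect_equal(g$prediction_rate, 0.8)
  expect_equal(g$accuracy, 0.75)
  # all abstained: rate 0, accuracy missing
  pred$abstained <- TRUE
  ev0 <- evaluate_predictions(pred, truth)
  expect_equal(ev0$prediction_rate[ev0$rank == "genus"], 0)
  expect_true(is.na(ev0$accuracy[ev0$rank == "genus"]))
})

test_that("GCN training separates two feature blobs and abstention is monotone", {
  # tiny hand-built graph: two host hubs, labeled and unlabeled viruses
  set.seed(42)
  nv <- 16
  vid <- sprintf("v%02d", 1:nv)
  genus <- rep(c("gA", "gB"), each = nv / 2)
  tax <- data.frame(host_id = c("hA", "hB"), phylum = "p1", class = "c1",
                    order = "o1", family = "f1", genus = c("gA", "gB"),
                    stringsAsFactors = FALSE)
  known <- data.frame(virus_id = vid[c(1:5, 9:13)],
                      host_id = rep(c("hA", "hB"), each = 5))
  profiles <- setNames(lapply(vid, function(v)
    list(genome_id = v, clusters = character(0), a = 0)), vid)
  attr(profiles, "n_clusters") <- 10
  g <- build_knowledge_graph(vid, c("hA", "hB"), profiles, NULL, known, tax,
                             edge_test_params())
  feats <- matrix(rnorm(nv * 6, mean = rep(ifelse(genus == "gA", 2, -2), 6)),
                  nv, 6, dimnames = list(vid, NULL))
  g <- set_virus_features(g, feats)
  g <- encode_host_nodes(g)
  m <- train_gcn(g, "genus", gcn_config(hidden1 = 16, hidden2 = 8,
                                        epochs = 120), rng_seed = 1)
  models <- list(phylum = hostnet:::constant_rank_model("phylum", "p1"),
                 class = hostnet:::constant_rank_model("class", "c1"),
                 order = hostnet:::constant_rank_model("order", "o1"),
                 family = hostnet:::constant_rank_model("family", "f1"),
                 genus = m)
  pr0 <- predict_hosts(g, models, threshold = 0)
  expect_true(all(!pr0$abstained))
  truth <- data.frame(virus_id = vid, phylum = "p1", class = "c1",
                      order = "o1", family = "f1", genus = genus,
                      stringsAsFactors = FALSE)
  ev <- evaluate_predictions(pr0, truth)
  expect_equal(ev$prediction_rate, rep(1, 5))
  expect_gte(ev$accuracy[ev$rank == "genus"], 0.8)

  # threshold sweep: number of predictions never increases
  rates <- vapply(seq(0, 1, 0.1), function(th) {
    p <- predict_hosts(g, models, th)
    sum(!p$abstained[p$rank == "genus"])
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  pr1 <- predict_hosts(g, list(genus = m), threshold = 1)
  expect_true(all(pr1$abstained))  # non-degenerate SoftMax < 1 everywhere

  # determinism and early monotone loss decrease
  m2 <- train_gcn(g, "genus", gcn_config(hidden1 = 16, hidden2 = 8,
                                         epochs = 120), rng_seed = 1)
  expect_identical(m$params, m2$params)
  expect_error(predict_hosts(g, list(genus = structure(
    modifyList(unclass(m), list(node_ids = rev(m$node_ids))),
    class = "gcn_model"))), "different node set")
})

test_that("single-class ranks are rejected by train_gcn", {
  com <- small_community()
  expect_error(train_gcn(structure(list(
    ids = "v", roles = c(v = "virus"),
    labels = data.frame(node_id = "v", phylum = "p", class = "c", order = "o",
                        family = "f", genus = "g"),
    edges = data.frame(), params = NULL,
    features = matrix(0, 1, 4, dimnames = list("v", NULL))),
    class = "knowledge_graph"), "genus"), "2 label classes")
})
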