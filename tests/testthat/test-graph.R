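test_that("hypergeometric tail matches exhaustive enumeration for n <= 8", {
  for (n in c(2, 4, 6, 8)) {
    for (a in 0:n) for (b in 0:a) {
      # one enumeration pass per (n, a, b), compared at every c
      for (c in 0:(min(a, b) + 1)) {
        expect_equal(hypergeom_tail(a, b, c, n), enumerate_tail(a, b, c, n),
                     tolerance = 1e-12,
                     label = sprintf("a=%d b=%d c=%d n=%d", a, b, c, n))
      }
    }
  }
})

test_that("hypergeometric tail edge cases and monotonicity in c", {
  expect_equal(hypergeom_tail(5, 3, 0, 10), 1)
  expect_equal(hypergeom_tail(1, 1, 1, 2), 0.5)
  expect_equal(hypergeom_tail(2, 2, 1, 4), 5 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_tail(3, 4, 5, 10), 0)   # c > min(a, b)
  p <- vapply(0:6, function(c) hypergeom_tail(6, 6, c, 12), numeric(1))
  expect_true(all(diff(p) <= 1e-12))
  # cross-check against the distribution function in stats
  expect_equal(hypergeom_tail(6, 4, 2, 12),
               stats::phyper(1, 6, 6, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(hypergeom_tail(13, 4, 2, 12), "exceed")
})

test_that("virus-virus statistic reproduces the worked example and c = 0 never connects", {
  expect_equal(virus_virus_statistic(2, 2, 1, 4, 3), -log(5 / 6 * 3),
               tolerance = 1e-12)
  p <- list(genome_id = "x", clusters = c("c1", "c2"), a = 2)
  q <- list(genome_id = "y", clusters = c("c2", "c3"), a = 2)
  prm <- edge_test_params(n = 4, N = 3)
  expect_false(virus_virus_edge(p, q, prm))      # statistic ~ -0.916 < 1
  q0 <- list(genome_id = "z", clusters = c("c5", "c6"), a = 2)
  prm6 <- edge_test_params(n = 1000, N = 3)
  expect_false(virus_virus_edge(p, q0, prm6))    # c = 0
  rich <- list(genome_id = "r", clusters = sprintf("k%02d", 1:10), a = 10)
  expect_true(virus_virus_edge(rich, rich, prm6))  # a=b=c=10, n=1000
  expect_error(edge_test_params(N = 1), ">= 2")
})

test_that("virus-host edge rule follows known pairs and tau2", {
  expect_true(virus_host_edge(NULL, TRUE, 1e-5))
  expect_true(virus_host_edge(1e-6, FALSE, 1e-5))
  expect_false(virus_host_edge(1e-2, FALSE, 1e-5))
  expect_false(virus_host_edge(NA, FALSE, 1e-5))
})

fixture_graph <- function() {
  profiles <- list(
    v1 = list(genome_id = "v1", clusters = sprintf("c%02d", 1:10), a = 10),
    v2 = list(genome_id = "v2", clusters = sprintf("c%02d", 1:10), a = 10),
    v3 = list(genome_id = "v3", clusters = sprintf("c%02d", 40:44), a = 5))
  attr(profiles, "n_clusters") <- 200
  tax <- data.frame(host_id = "h1", phylum = "p01", class = "c01",
                    order = "o01", family = "f01", genus = "g01",
                    stringsAsFactors = FALSE)
  hits <- data.frame(query_id = c("v1", "v1"), subject_id = c("h1", "h1"),
                     pct_identity = 95, align_len = 400, mismatch = 10,
                     gap_open = 0, q_start = 1, q_end = 400, s_start = 1,
                     s_end = 400, evalue = c(1e-8, 1e-12), bitscore = 300,
                     stringsAsFactors = FALSE)
  known <- data.frame(virus_id = "v2", host_id = "h1", stringsAsFactors = FALSE)
  build_knowledge_graph(c("v1", "v2", "v3"), "h1", profiles, hits, known, tax,
                        edge_test_params(N = 3))
}

test_that("graph assembly matches the hand-built edge list", {
  g <- fixture_graph()
  ed <- g$edges[order(g$edges$provenance), ]
  # v1-v2 share 10 of 10 clusters out of 200: overwhelmingly significant;
  # v3 shares none; v1-h1 by alignment (min E kept); v2-h1 known
  expect_equal(nrow(ed), 3)
  expect_true(any(ed$provenance == "virus-virus" & ed$from == "v1" & ed$to == "v2"))
  al <- ed[ed$provenance == "virus-host-alignment", ]
  expect_equal(al$evalue, 1e-12)   # duplicate hits collapse to min E-value
  expect_true(any(ed$provenance == "virus-host-known"))
  # labels: v2 labeled via known pair, v1/v3 unlabeled queries
  expect_equal(g$labels$genus[g$labels$node_id == "v2"], "g01")
  expect_true(is.na(g$labels$genus[g$labels$node_id == "v1"]))
  expect_true(all(!is.na(g$labels$genus[g$roles[g$labels$node_id] == "host"])))
})

test_that("no hits and no known pairs give an edgeless graph with all nodes", {
  profiles <- list(v1 = list(genome_id = "v1", clusters = "c1", a = 1),
                   v2 = list(genome_id = "v2", clusters = "c2", a = 1))
  attr(profiles, "n_clusters") <- 10
  tax <- data.frame(host_id = "h1", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", stringsAsFactors = FALSE)
  g <- build_knowledge_graph(c("v1", "v2"), "h1", profiles, NULL, NULL, tax,
                             edge_test_params())
  expect_equal(nrow(g$edges), 0)
  expect_length(g$ids, 3)
  expect_error(build_knowledge_graph(c("v1", "v2"), "h2", profiles, NULL, NULL,
                                     tax, edge_test_params()), "taxonomy")
  bad_known <- data.frame(virus_id = "vX", host_id = "h1")
  expect_error(build_knowledge_graph(c("v1", "v2"), "h1", profiles, NULL,
                                     bad_known, tax, edge_test_params()),
               "unknown id")
})

test_that("edges are symmetric in meaning and never host-host", {
  g <- fixture_graph()
  roles <- g$roles
  expect_false(any(roles[g$edges$from] == "host" & roles[g$edges$to] == "host"))
  expect_false(any(g$edges$from == g$edges$to))
})

test_that("host encoding is the weighted average of viral neighbours", {
  g <- fixture_graph()
  feats <- matrix(rep(c(1, 5, 9), each = 4), nrow = 3, byrow = TRUE,
                  dimnames = list(c("v1", "v2", "v3"), NULL))
  g <- set_virus_features(g, feats)
  g <- encode_host_nodes(g)
  # v1 edge E = 1e-12 -> w 12; v2 known -> w 180
  expected <- (12 * 1 + 180 * 5) / 192
  expect_equal(unname(g$features["h1", ]), rep(expected, 4), tolerance = 1e-12)
})

test_that("single-neighbour hosts copy the virus feature; isolated hosts get zeros", {
  profiles <- list(v1 = list(genome_id = "v1", clusters = "c1", a = 1))
  attr(profiles, "n_clusters") <- 10
  tax <- data.frame(host_id = c("h1", "h2"), phylum = "p", class = "c",
                    order = "o", family = "f", genus = "g",
                    stringsAsFactors = FALSE)
  known <- data.frame(virus_id = "v1", host_id = "h1")
  g <- build_knowledge_graph("v1", c("h1", "h2"), profiles, NULL, known, tax,
                             edge_test_params())
  g <- set_virus_features(g, matrix(1:4, 1, dimnames = list("v1", NULL)))
  expect_warning(g <- encode_host_nodes(g), "no virus neighbour")
  expect_equal(unname(g$features["h1", ]), 1:4)
  expect_equal(unname(g$features["h2", ]), rep(0, 4))
})

test_that("building once equals building then extending, for edges and labels", {
  com <- small_community()
  hits <- all_vs_all_protein_hits(com$proteins)
  net <- build_protein_network(hits, 1e-5, proteins = names(com$proteins))
  profiles <- profile_genomes(mcl(net), com$protein_genome,
                              genomes = names(com$viruses))
  vh <- virus_host_nucleotide_hits(com$viruses, com$hosts)
  hosts <- names(com$hosts)
  keep <- hosts[1]
  held <- hosts[2]
  prm <- edge_test_params()

  full <- build_knowledge_graph(names(com$viruses), hosts, profiles, vh,
                                com$known_pairs, com$host_taxonomy, prm)
  base <- build_knowledge_graph(
    names(com$viruses), keep, profiles, vh,
    com$known_pairs[com$known_pairs$host_id == keep, ],
    com$host_taxonomy[com$host_taxonomy$host_id == keep, ], prm)
  ext <- extend_graph(base, com$host_taxonomy[com$host_taxonomy$host_id == held, ],
                      vh, com$known_pairs[com$known_pairs$host_id == held, ])

  key <- function(g) sort(paste(g$edges$from, g$edges$to, g$edges$provenance))
  expect_equal(key(ext), key(full))
  expect_setequal(ext$ids, full$ids)
  # genus vocabulary grows by the new host's genus
  expect_setequal(unique(stats::na.omit(ext$labels$genus)),
                  unique(stats::na.omit(full$labels$genus)))
  expect_error(extend_graph(base, com$host_taxonomy), "collision")
})
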