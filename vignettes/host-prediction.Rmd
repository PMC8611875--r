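---
title: "Calibrated semi-supervised host prediction for prokaryotic viruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated semi-supervised host prediction for prokaryotic viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Phages and archaeal viruses vastly outnumber the experimentally confirmed
virus–host interactions, and roughly half of known viruses share no
alignable region with their host's genome. `hostnet` therefore treats host
prediction as semi-supervised node classification on a heterogeneous
*knowledge graph*: viruses with known hosts, query viruses, and candidate
host genomes all become nodes, and information flows along two kinds of
edges — shared protein content between viruses, and local nucleotide
similarity (or a recorded interaction) between a virus and a host. One
graph convolutional network (GCN) per taxonomic rank, trained with a
calibration-aware objective, assigns each query virus a host lineage from
phylum down to genus together with a confidence that can honestly be
thresholded.

This vignette explains the model, the choices behind every tunable
parameter, and what the synthetic data generator does and does not
emulate.

## The knowledge graph

**Virus–virus edges.** Proteins from all viruses are aligned all-against-all
and the resulting similarity network (edge weight `-log10(E)`, E-values
clamped to `>= 1e-180`) is clustered with an in-package Markov clustering
(MCL) implementation. Two viruses containing `a` and `b` protein clusters
and sharing `c` of them are connected when

```
-ln( P(y >= c) * choose(N, 2) ) >= tau1,     tau1 = 1 by default
```

where `P(y >= c)` is the hypergeometric tail probability under the
simplifying null that all `n` clusters are equally likely to be chosen, and
`N` is the number of virus sequences (the `choose(N, 2)` factor corrects
for the number of pairs examined). The equal-probability null is knowingly
approximate — cluster sizes vary — but it is cheap and only used to rank
pair overlaps. Sharing nothing (`c = 0`) never creates an edge.

Two conventions are deliberate and configurable:

* the statistic uses the natural logarithm (`log_base` in
  `edge_test_params()`); with `tau1 = 1` an edge then requires a corrected
  tail probability below `exp(-1) ~ 0.37`, a permissive regime in which the
  overlap count `c` does the real work;
* `N` counts virus sequences only — hosts carry no protein-cluster profile
  in this pipeline, so they do not enter the pair correction.

**Virus–host edges.** A virus connects to a host if their genomes share a
local alignment with E-value below `tau2 = 1e-5`, or unconditionally if the
interaction is recorded in the known-pairs table. Multiple alignments for
one pair collapse to a single edge keeping the best E-value. Host–host
edges never exist.

**MCL.** The column-stochastic matrix gets self-loops equal to each node's
maximum incident weight (1 for isolated nodes), which makes the procedure
invariant to uniform rescaling of all weights; expansion (matrix square),
inflation (elementwise power 2.0, then column renormalisation) and pruning
of entries below `1e-5` iterate until the matrix changes by less than
`1e-8`. Attractor rows are grouped into attractor systems and every node
joins the system holding most of its column mass, ties going to the
lexicographically smallest cluster id — a deterministic reading of the
limit matrix. Inflation 2.0 is the customary default in gene-sharing
network practice and is exposed as a parameter.

## Node features

**Virus nodes.** Genomes are cut into 2 kbp segments. A genome shorter than
2 kbp becomes a single N-padded segment; a trailing remainder of at least
1 kbp is kept N-padded, shorter remainders are dropped. This keeps
short-contig information without letting mostly-N segments dilute the
features; N-containing k-mer windows embed as zero vectors, so padding is
neutral.

A skip-gram model with negative sampling over the overlapping k-mer stream
(default `k = 3`, 64-token vocabulary, `d = 100` dimensions) gives every
k-mer a context-aware embedding; an embedded segment is the
`(2000 - k + 1) x d` matrix of its k-mer vectors. A convolutional network
with parallel filter widths {4, 8, 16} (64 filters each, capturing motifs
of several scales), global max pooling, and two ReLU dense layers
(512, then 256 units) is trained with cross-entropy to classify segments
by the genus of the virus's host; segments inherit their genome's label.
The *first dense layer* (512 units, post-ReLU) is the node feature: in
encoding mode each segment's 512-vector is computed and the per-segment
vectors are averaged, making the encoding segment-order invariant and
non-negative. `k`, the widths, filter counts and epochs are configurable
(`cnn_config()`); the defaults train in about a minute on one CPU at the
scale of the bundled generator.

The row count of the embedded matrix is `L - k + 1`, the sliding-window
count. Because every row of the embedded segment is one of only `4^k`
embedding rows, the convolution is implemented as a sum of token-indexed
lookup tables — mathematically identical to the dense convolution but an
order of magnitude cheaper, which is what makes CPU training practical.

**Host nodes.** Hosts are encoded as the weighted average of their viral
neighbours' features, weight `-log10(max(E, 1e-180))` of the connecting
edge. Known-interaction edges without an alignment get the maximum weight
(180): a confirmed interaction should dominate weak alignment neighbours.
A host with no viral neighbour gets the zero vector (with a warning) but
still participates in training through its label. Encoding hosts from
viruses, rather than from their own sequence, is what lets entirely new
host taxa be added to the graph without retraining the encoder.

## The per-rank GCN and its calibration-aware loss

With `Abar = D^{-1/2}(A + I)D^{-1/2}` the symmetrically normalized
adjacency with self-loops (all eigenvalues in `[-1, 1]`), the classifier is

```
H1 = ReLU(Abar H0 theta0)        512 -> 256
H2 = ReLU(Abar H1 theta1)        256 -> 128
Out = SoftMax(H2 theta_dense)    128 -> C
```

One model is trained per rank, phylum first, genus last, re-using the same
graph with rank-specific labels; label vocabularies are the taxa present
among labeled nodes at that rank. Only labeled nodes (all hosts plus the
known-pair viruses) enter the loss

```
L = ECE + L2
```

where `L2` is the mean over labeled nodes of the mean squared difference
between the SoftMax row and the one-hot label (mean over classes keeps the
term scale-free in the class count), and ECE is the expected calibration
error of the labeled nodes' maximum SoftMax values over 10 equal-width
bins: `sum_i (T_i/T) |Acc_i - conf_i|`. `conf_i` is the bin's mean
confidence — the denominator of that mean is the bin's sample count. The
ECE term is differentiated straight-through: bin membership and the bin
accuracies are treated as constants within a step, so the gradient moves
every sample's confidence toward its bin's accuracy. That is the only
differentiable reading of "minimise ECE during training"; correctness
flags come from the training labels, and host nodes are included in the
bins by default (`ece_include_hosts = FALSE` restricts them to viruses).

Training is full-batch Adam (rate `1e-3`, 200 epochs), seeded and
deterministic. Features are standardized column-wise before training and
the scaling is stored in the model. Hidden sizes 256/128 are unremarkable
defaults exposed in `gcn_config()`.

Two normalisation details are deliberate: the adjacency uses the standard
*symmetric* renormalisation (a non-symmetric variant with a positive
right-hand exponent would not keep the spectrum bounded and does not match
the GCN formulation this layer is based on), and a rank whose labeled
nodes carry a single taxon cannot be trained through a SoftMax at all —
`train_gcn()` refuses it, and the pipeline substitutes a constant
predictor reporting that taxon with confidence 1.

## Prediction, thresholding, conflicts, evaluation

Every unlabeled virus receives, per rank, the argmax taxon with its
SoftMax value as confidence; ranks below the user's confidence threshold
abstain. Prediction rate (predicted / total) and accuracy
(correct / predicted) are computed per rank over non-abstained
predictions, so at threshold 0 the prediction rate is exactly 1 and
raising the threshold can only remove predictions. The user-facing
lineage is made internally consistent afterwards: walking from phylum
down, the first rank whose taxon is abstained or is not a child of the
taxon above truncates the report (the `reported` flag). Viruses with no
edges at all are still predicted — the self-loop passes their own
features through — but carry a `no_neighbors` flag, since the
semi-supervised signal is absent for them.

## Extending the graph to new host taxa

`extend_graph()` adds labeled host nodes — possibly of taxa absent from
the training data — together with the virus–host edges involving them;
existing nodes and edges are untouched, so build-then-extend equals
building once with the union of inputs. New hosts are encoded from their
viral neighbours, the rank vocabularies grow, and retraining propagates
the new labels through the topology. Known pairs passed at extension time
only create edges; query viruses stay unlabeled, which is the intended
use (the new hosts are the information, the viruses remain queries).

## The synthetic community generator

`generate_community()` plants exactly the structure the method exploits:

* viruses of one genus draw `genes_per_virus = 10` genes (mutated copies,
  2% substitutions) from a genus-specific pool of 30, plus 2 noise genes
  from a global pool of 20 — within-genus pairs therefore share more
  protein clusters than between-genus pairs;
* 30% of viruses carry a 500 bp fragment of their actual host's genome
  (2% mutated), giving alignment-based virus–host edges; a minority is
  realistic — in real collections many viruses have no detectable host
  alignment, which is precisely the regime the graph is meant to rescue;
* every genus has its own 4-mer composition (an order-3 Markov chain with
  Dirichlet(1) rows) followed by host genomes and virus backbones, so the
  encoder has a learnable composition signal; Dirichlet(1) gives
  pronounced between-genus differences so that desk-scale training
  converges in minutes;
* genes are emitted both as protein FASTA and back-translated into the
  virus genome between in-frame stop codons, so the naive ORF caller
  recovers exactly the emitted proteins and both protein entry paths are
  exercised;
* 75% of viruses per genus get a recorded interaction (training nodes);
  the remaining 25% are the query set with known truth.

Defaults: 5 genera, 2 hosts/genus (100 kbp), 20 viruses/genus (15 kbp),
taxonomy fanout 2 (3 families, 2 orders, 1 class, 1 phylum), seed 7. All
outputs are byte-deterministic given the seed.

What the generator does **not** emulate: realistic phage genome
architecture, codon usage or GC skew, sequencing error, polyvalent hosts,
shared genes between genera beyond the small noise pool, or hosts whose
composition does not track their genus. Passing tests on this material
shows the machinery is correct and that the method recovers planted
signal; it does not certify accuracy figures on real virome data, where
signals are weaker and confounded.

## Built-in fallback aligner

For desk-scale runs without external aligners, the package seeds candidate
protein pairs with shared 5-mers and candidate genomic regions with shared
13-mers grouped by diagonal, then re-aligns locally with affine gaps
(BLOSUM62, open 11 / extend 1 for proteins; +2/−3, open 5 / extend 2 for
nucleotides) via `Biostrings::pairwiseAlignment`, converting scores to
bit scores and E-values with ungapped Karlin–Altschul constants
(`E ~ m n 2^{-S'}`). A genomic diagonal band must collect 25 seeds before
it is re-aligned — a conserved region of a few hundred bases contributes a
seed at almost every position, while sporadic composition-driven matches
do not — and at most 4 bands per pair are aligned. The E-value dialect is
approximate by construction; externally produced 12-column tabular
alignments are accepted everywhere instead and take precedence when
supplied.

## Problem sizes and numerical choices

The bundled experiments run on the default community: 100 viruses, 10
hosts, ~1200 proteins, ~170 protein clusters, a 110-node graph. At that
size the full pipeline (alignment, clustering, embedding, CNN, five GCNs)
takes a few minutes on one CPU, which is the scale the defaults are tuned
for. Worth knowing:

* E-values are clamped at `1e-180` before `-log10`, so reported zeros get
  weight 180 — also the weight of known-interaction edges;
* the hypergeometric tail is computed in log space (`lchoose` +
  log-sum-exp), exact against enumeration to `1e-12` for small `n`;
* MCL uses dense matrices — protein networks of a few thousand nodes are
  well inside that envelope;
* ECE bins are half-open `[i/10, (i+1)/10)` with the top bin closed;
* ties in the SoftMax argmax resolve to the first class in sorted
  vocabulary order; all stochastic stages take explicit seeds and are
  reproducible bit-for-bit.

## Limitations

The Eq-style significance test inherits the equal-probability null; very
large, promiscuous protein clusters inflate apparent overlap. The ECE term
is computed on training labels, so a model that overfits its training
nodes can be confidently calibrated there yet less so on queries — the
held-out comparison in `compare_calibration()` measures exactly that gap.
Prediction is single-label per rank: polyvalent phages receive one
lineage. And the fallback aligner is a convenience, not a BLAST
replacement; for real data, supply external alignment tables.
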