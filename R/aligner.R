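# Built-in fallback aligner.
#
# Desk-scale replacement for an external protein/nucleotide aligner:
# exact k-mer seeds select candidate pairs (proteins) or diagonal bands
# (virus vs host genomes), candidates are aligned locally with affine gaps
# via Biostrings::pairwiseAlignment, and scores are converted to BLAST-style
# bit scores and E-values with ungapped Karlin-Altschul constants
# (E ~ m * n * 2^-bitscore, bitscore = (lambda*S - ln K)/ln 2). The E-value
# dialect is approximate by construction; externally produced 12-column
# tabular files are accepted everywhere instead.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Karlin-Altschul constants: BLOSUM62 gap 11/1, and blastn +2/-3 gap 5/2
.KA_PROT <- c(lambda = 0.267, K = 0.041)
.KA_NUCL <- c(lambda = 0.625, K = 0.41)

bit_score <- function(raw, ka) (ka[["lambda"]] * raw - log(ka[["K"]])) / log(2)
e_value <- function(bits, m, n) m * n * 2^(-bits)

hit_row <- function(query_id, subject_id, pa, qoff, soff, evalue, bits) {
  alen <- Biostrings::nchar(pa)
  nmat <- Biostrings::nmatch(pa)
  nmis <- Biostrings::nmismatch(pa)
  ins <- Biostrings::indel(pa)
  ngap <- length(ins@insertion[[1]]) + length(ins@deletion[[1]])
  data.frame(
    query_id = query_id, subject_id = subject_id,
    pct_identity = round(100 * nmat / alen, 2), align_len = alen,
    mismatch = nmis, gap_open = ngap,
    q_start = Biostrings::start(Biostrings::pattern(pa)) + qoff,
    q_end = Biostrings::end(Biostrings::pattern(pa)) + qoff,
    s_start = Biostrings::start(Biostrings::subject(pa)) + soff,
    s_end = Biostrings::end(Biostrings::subject(pa)) + soff,
    evalue = evalue, bitscore = round(bits, 1),
    stringsAsFactors = FALSE)
}

#' All-against-all protein alignment (built-in fallback)
#'
#' Exact `seed_k`-mer seeding selects candidate pairs, which are then
#' aligned locally (BLOSUM62, affine gap open 11 / extend 1). Each
#' unordered pair appears at most once. The database size for E-values is
#' the total residue count of `proteins`.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param seed_k seed length in residues.
#' @param max_evalue hits above this E-value are not reported.
#' @return alignment data.frame in the 12-column layout of
#'   [parse_tabular_alignments()].
#' @export
all_vs_all_protein_hits <- function(proteins, seed_k = 5, max_evalue = 1e-3) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  if (length(proteins) < 2) return(empty_hits())
  ids <- names(proteins)
  n_db <- sum(nchar(proteins))

  # candidate pairs sharing at least one exact seed
  seed_dt <- data.table::rbindlist(lapply(seq_along(proteins), function(i) {
    s <- proteins[[i]]
    m <- nchar(s) - seed_k + 1
    if (m < 1) return(NULL)
    data.table::data.table(seed = unique(substring(s, 1:m, seed_k:nchar(s))),
                           idx = i)
  }))
  pairs <- merge(seed_dt, seed_dt, by = "seed", allow.cartesian = TRUE)
  pairs <- unique(pairs[pairs$idx.x < pairs$idx.y, c("idx.x", "idx.y")])
  if (nrow(pairs) == 0) return(empty_hits())

  b62 <- .blosum62()
  rows <- vector("list", nrow(pairs))
  r <- 0
  for (j in sort(unique(pairs$idx.y))) {
    qi <- pairs$idx.x[pairs$idx.y == j]
    subj <- Biostrings::AAString(proteins[[j]])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[qi]), subj, type = "local",
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(pa)
    bits <- bit_score(sc, .KA_PROT)
    ev <- e_value(bits, nchar(proteins[qi]), n_db)
    keep <- which(ev <= max_evalue)
    for (ki in keep) {
      r <- r + 1
      rows[[r]] <- hit_row(ids[qi[ki]], ids[j], pa[ki], 0, 0, ev[ki], bits[ki])
    }
  }
  if (r == 0) return(empty_hits())
  out <- do.call(rbind, rows[seq_len(r)])
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  setNames(data.frame(matrix(nrow = 0, ncol = 12)), .HIT_COLS)
}

#' Virus-vs-host nucleotide alignment (built-in fallback)
#'
#' For every virus/host pair, exact `seed_k`-mer matches are grouped into
#' diagonal bands; bands with at least `min_seeds` seeds are re-aligned
#' locally (match +2, mismatch -3, gap open 5 / extend 2) on a window
#' around the band. The best-scoring window per pair yields one hit.
#'
#' @param viruses,hosts named character vectors of nucleotide sequences.
#' @param seed_k seed length in bp.
#' @param min_seeds minimum seeds a diagonal band must collect before it is
#'   re-aligned (a conserved region of a few hundred bp contributes seeds at
#'   almost every position, so true hits clear this easily while sporadic
#'   composition-driven matches do not).
#' @param band diagonal tolerance in bp when merging seed diagonals.
#' @param max_bands at most this many bands (richest in seeds first) are
#'   re-aligned per virus/host pair.
#' @param flank window extension around the seed cluster in bp.
#' @param max_window longest window re-aligned, in bp.
#' @param max_evalue hits above this E-value are not reported.
#' @return alignment data.frame in the 12-column layout (one row per
#'   virus/host pair at most).
#' @export
virus_host_nucleotide_hits <- function(viruses, hosts, seed_k = 13,
                                       min_seeds = 25, band = 15,
                                       max_bands = 4, flank = 60,
                                       max_window = 2000, max_evalue = 10) {
  stopifnot(is.character(viruses), is.character(hosts))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE)
  rows <- list()
  host_dts <- lapply(hosts, function(h) {
    code <- kmer_codes(h, seed_k)
    dt <- data.table::data.table(code = code, spos = seq_along(code))
    dt <- dt[!is.na(dt$code), ]
    data.table::setkey(dt, code)
    dt
  })
  for (vid in names(viruses)) {
    vseq <- viruses[[vid]]
    vcode <- kmer_codes(vseq, seed_k)
    vdt <- data.table::data.table(code = vcode, vpos = seq_along(vcode))
    vdt <- vdt[!is.na(vdt$code), ]
    for (hid in names(hosts)) {
      hdt <- host_dts[[hid]]
      seeds <- hdt[vdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(seeds) < min_seeds) next
      seeds$diag <- seeds$spos - seeds$vpos
      data.table::setorderv(seeds, c("diag", "vpos"))
      grp <- cumsum(c(1L, diff(seeds$diag) > band))
      groups <- split(seq_len(nrow(seeds)), grp)
      groups <- groups[lengths(groups) >= min_seeds]
      if (length(groups) == 0) next
      groups <- groups[order(-lengths(groups))]
      if (length(groups) > max_bands) groups <- groups[seq_len(max_bands)]
      best <- NULL
      for (g in groups) {
        sv <- seeds[g, ]
        v1 <- max(1L, min(sv$vpos) - flank)
        v2 <- min(nchar(vseq), max(sv$vpos) + seed_k - 1L + flank)
        s1 <- max(1L, min(sv$spos) - flank)
        s2 <- min(nchar(hosts[[hid]]), max(sv$spos) + seed_k - 1L + flank)
        if (v2 - v1 > max_window) v2 <- v1 + max_window
        if (s2 - s1 > max_window) s2 <- s1 + max_window
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(substr(vseq, v1, v2)),
          Biostrings::DNAString(substr(hosts[[hid]], s1, s2)),
          type = "local", substitutionMatrix = submat,
          gapOpening = 5, gapExtension = 2)
        sc <- Biostrings::score(pa)
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, pa = pa, v1 = v1, s1 = s1)
      }
      if (is.null(best)) next
      bits <- bit_score(best$score, .KA_NUCL)
      ev <- e_value(bits, nchar(vseq), nchar(hosts[[hid]]))
      if (ev <= max_evalue)
        rows[[length(rows) + 1]] <-
          hit_row(vid, hid, best$pa, best$v1 - 1L, best$s1 - 1L, ev, bits)
    }
  }
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
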