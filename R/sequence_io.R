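#' Read a FASTA file
#'
#' @param path FASTA file.
#' @param role `"virus"` or `"host"`; attached as an attribute.
#' @param type `"nucleotide"` or `"protein"` (controls nothing at read time
#'   beyond the attribute; wildcards N/X are always permitted).
#' @return named character vector of uppercased sequences, names are the
#'   first whitespace-delimited token of each header, in file order.
#'   Duplicated ids are an error; an empty file yields an empty vector with
#'   a warning.
#' @export
read_fasta <- function(path, role = c("virus", "host"),
                       type = c("nucleotide", "protein")) {
  role <- match.arg(role)
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(structure(setNames(character(0), character(0)),
                     role = role, type = type))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicated FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(set))
  names(out) <- ids
  structure(out, role = role, type = type)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Split a genome into fixed-length segments
#'
#' Produces `floor(n/L)` full segments. A trailing remainder of at least
#' `L/2` is kept and N-padded to length `L`; shorter remainders are
#' dropped. A whole sequence shorter than `L` yields a single padded
#' segment, so short contigs are never lost.
#'
#' @param sequence nucleotide string.
#' @param parent_id id recorded for the segments.
#' @param L segment length in bp.
#' @return data.frame with columns `parent_id`, `index` (0-based,
#'   contiguous) and `sequence` (all exactly `L` characters).
#' @export
segment_genome <- function(sequence, parent_id = "seq", L = 2000) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  if (n < L) {
    segs <- paste0(sequence, strrep("N", L - n))
  } else {
    full <- n %/% L
    starts <- (seq_len(full) - 1) * L + 1
    segs <- substring(sequence, starts, starts + L - 1)
    rem <- n - full * L
    if (rem >= L / 2)
      segs <- c(segs, paste0(substring(sequence, full * L + 1, n),
                             strrep("N", L - rem)))
  }
  data.frame(parent_id = parent_id, index = seq_along(segs) - 1L,
             sequence = segs, stringsAsFactors = FALSE)
}

# base letters -> 0..3, anything else NA
.base_codes <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1] <- 0L
  v[utf8ToInt("C") + 1] <- 1L
  v[utf8ToInt("G") + 1] <- 2L
  v[utf8ToInt("T") + 1] <- 3L
  v
})

# integer codes of all k-mers of `sequence`; NA where the window contains a
# non-ACGT character. k <= 15 keeps codes inside integer range.
kmer_codes <- function(sequence, k) {
  stopifnot(k >= 1, k <= 15)
  a <- .base_codes[utf8ToInt(sequence) + 1]
  n <- length(a)
  if (n < k) return(integer(0))
  m <- n - k + 1
  code <- numeric(m)
  for (j in 0:(k - 1))
    code <- code + a[(1 + j):(m + j)] * 4^(k - 1 - j)
  as.integer(code)
}

.codon_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      gc <- Biostrings::GENETIC_CODE
      full <- rep("X", 64)
      names(full) <- names(gc)
      full[names(gc)] <- unname(gc)
      tbl <<- full
    }
    tbl
  }
})

translate_codons <- function(codons) {
  tbl <- .codon_table()
  aa <- tbl[codons]
  aa[is.na(aa)] <- "X"  # codons containing N or other wildcards
  unname(aa)
}

revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", sequence), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Find open reading frames
#'
#' Six-frame scan with the standard genetic code. An ORF runs from an ATG
#' to the next in-frame stop codon (the stop is required) and must encode
#' at least `min_len_aa` residues. Within a stop-to-stop region only the
#' first ATG is reported. This is a deliberately simple stand-in for a
#' trained gene finder; externally produced protein FASTA can be supplied
#' anywhere the pipeline takes proteins.
#'
#' @param sequence nucleotide string.
#' @param parent_id id prefix; ORFs are named `<parent_id>_<n>` ordered by
#'   the genomic coordinate of their start codon.
#' @param min_len_aa minimum protein length (excluding the stop).
#' @return data.frame with columns `id`, `start` (position of the first
#'   base of the ATG on the forward strand), `strand` (+/-), `protein`.
#'   May have zero rows.
#' @export
find_orfs <- function(sequence, parent_id = "seq", min_len_aa = 60) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < min_len_aa + 1) next
      starts <- f + 3 * (seq_len(ncod) - 1) + 1
      aa <- translate_codons(substring(s, starts, starts + 2))
      stops <- which(aa == "*")
      region_start <- 1L
      for (st in stops) {
        if (st - region_start >= min_len_aa) {
          region <- region_start:(st - 1)
          m <- region[match("M", aa[region])]
          if (!is.na(m) && st - m >= min_len_aa) {
            # genomic coordinate of the ATG on the forward strand
            off <- f + 3 * (m - 1)  # 0-based offset on the scanned strand
            pos <- if (strand == "+") off + 1L else n - off
            hits[[length(hits) + 1]] <- data.frame(
              start = pos, strand = strand,
              protein = paste(aa[m:(st - 1)], collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
        region_start <- st + 1L
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(id = character(0), start = integer(0),
                      strand = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out <- cbind(id = sprintf("%s_%d", parent_id, seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

.HIT_COLS <- c("query_id", "subject_id", "pct_identity", "align_len",
               "mismatch", "gap_open", "q_start", "q_end", "s_start",
               "s_end", "evalue", "bitscore")

#' Parse BLAST-style tabular alignments
#'
#' Reads the 12-column "outfmt 6" dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Self-hits
#' (query == subject) are dropped. Scientific-notation E-values are parsed;
#' a reported `0.0` is kept as zero (downstream weighting clamps it).
#'
#' @param path tab-separated alignment file.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_len`, `mismatch`, `gap_open`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
parse_tabular_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0)
    return(setNames(data.frame(matrix(nrow = 0, ncol = 12)), .HIT_COLS))
  bad <- which(nf != 12)
  if (length(bad) > 0)
    stop(sprintf("expected 12 tab-separated columns, found %d on line %d",
                 nf[bad[1]], bad[1]))
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", rep("numeric", 10)))
  names(df) <- .HIT_COLS
  df <- df[df$query_id != df$subject_id, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write alignments in BLAST tabular format
#'
#' @param hits data.frame as returned by [parse_tabular_alignments()] or
#'   the built-in aligner.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tabular_alignments <- function(hits, path) {
  stopifnot(all(.HIT_COLS %in% names(hits)))
  write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
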