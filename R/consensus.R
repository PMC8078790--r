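# UMI extraction, family grouping in "ab/ba" form, and single-strand
# consensus sequence (SSCS) assembly.

#' Extract UMI tags and trim locus primers from read pairs
#'
#' The first `umi_len` bases of each mate are taken as the tag; the following
#' bases are checked against the expected locus primer allowing up to
#' `max_primer_mismatch` mismatches, then trimmed. Pairs failing the primer
#' check (or too short) are rejected with counted reason codes.
#'
#' @param reads data frame with columns `read_id`, `mate1`, `mate2` (e.g.
#'   from [read_fastq_pair()] or [render_reads()]).
#' @param config a [simulation_config()] supplying `umi_len`, `fwd_primer`,
#'   `rev_primer`.
#' @param max_primer_mismatch maximum mismatches tolerated per primer.
#' @return list with `pairs` (data frame `read_id`, `umi_a`, `umi_b`, `seq1`,
#'   `seq2`) and `rejected` (named counts: `too_short`, `primer_mismatch`).
#' @export
extract_umi_pairs <- function(reads, config, max_primer_mismatch = 2L) {
  u <- config$umi_len
  p1 <- config$fwd_primer; p2 <- config$rev_primer
  min1 <- u + nchar(p1); min2 <- u + nchar(p2)
  too_short <- nchar(reads$mate1) < min1 + 1L | nchar(reads$mate2) < min2 + 1L
  ok <- !too_short
  mm1 <- mm2 <- integer(nrow(reads))
  if (any(ok)) {
    mm1[ok] <- mismatch_counts_cpp(substr(reads$mate1[ok], u + 1L, min1), p1)$mismatches
    mm2[ok] <- mismatch_counts_cpp(substr(reads$mate2[ok], u + 1L, min2), p2)$mismatches
  }
  primer_bad <- ok & (mm1 > max_primer_mismatch | mm2 > max_primer_mismatch)
  keep <- ok & !primer_bad
  pairs <- data.frame(
    read_id = reads$read_id[keep],
    umi_a = substr(reads$mate1[keep], 1L, u),
    umi_b = substr(reads$mate2[keep], 1L, u),
    seq1 = substr(reads$mate1[keep], min1 + 1L, nchar(reads$mate1[keep])),
    seq2 = substr(reads$mate2[keep], min2 + 1L, nchar(reads$mate2[keep])),
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       rejected = c(too_short = sum(too_short), primer_mismatch = sum(primer_bad)))
}

#' Group tagged pairs into UMI families
#'
#' The family key is the ordered tag pair `(a, b)` ("ab" form; reads from the
#' opposite strand orientation would form the "ba" family, available through
#' the duplex confirmation mode of the caller). Output order is
#' lexicographic by key, so grouping is deterministic regardless of read
#' input order.
#'
#' @param pairs data frame from [extract_umi_pairs()] (`$pairs`).
#' @return a `umi_families` object: list with `keys`, `sizes`, and `index`
#'   (list of row indices into `pairs`, one per family).
#' @export
group_families <- function(pairs) {
  key <- paste(pairs$umi_a, pairs$umi_b, sep = "-")
  index <- split(seq_along(key), key)  # split sorts keys
  structure(list(keys = names(index),
                 sizes = lengths(index, use.names = FALSE),
                 index = unname(index)),
            class = "umi_families")
}

#' @export
print.umi_families <- function(x, ...) {
  cat(sprintf("<umi_families> %d families, %d pairs, size range %s-%s\n",
              length(x$keys), sum(x$sizes),
              if (length(x$sizes)) min(x$sizes) else 0,
              if (length(x$sizes)) max(x$sizes) else 0))
  invisible(x)
}

#' Assemble single-strand consensus sequences (SSCS)
#'
#' Families smaller than `min_family_size` are rejected (counted, not an
#' error). For the rest, each mate's consensus is the per-position modal base
#' when its fraction among contributing members reaches
#' `consensus_threshold`, else `N`; consensus length is the modal member
#' length and minority-length members contribute only up to that length.
#'
#' Defaults (`min_family_size = 3`, `consensus_threshold = 0.7`) are chosen
#' so a lone sequencing error can never flip a consensus base in a family of
#' three.
#'
#' @param families a `umi_families` object.
#' @param pairs the tagged-pair data frame the families index into.
#' @param min_family_size minimum reads per family.
#' @param consensus_threshold minimum modal-base fraction.
#' @return data frame (one row per accepted family): `key`, `umi_a`, `umi_b`,
#'   `family_size`, `mate1`, `mate2`, `agreement1`, `agreement2`, with
#'   attribute `rejected_families` (count below size threshold).
#' @export
sscs_consensus <- function(families, pairs, min_family_size = 3L,
                           consensus_threshold = 0.7) {
  stopifnot(inherits(families, "umi_families"),
            min_family_size >= 1, consensus_threshold > 0, consensus_threshold <= 1)
  keep <- families$sizes >= min_family_size
  n <- sum(keep)
  out <- data.frame(key = families$keys[keep],
                    umi_a = character(n), umi_b = character(n),
                    family_size = families$sizes[keep],
                    mate1 = character(n), mate2 = character(n),
                    agreement1 = numeric(n), agreement2 = numeric(n),
                    stringsAsFactors = FALSE)
  ki <- which(keep)
  for (i in seq_len(n)) {
    rows <- families$index[[ki[i]]]
    out$umi_a[i] <- pairs$umi_a[rows[1]]
    out$umi_b[i] <- pairs$umi_b[rows[1]]
    c1 <- sscs_cpp(pairs$seq1[rows], consensus_threshold)
    c2 <- sscs_cpp(pairs$seq2[rows], consensus_threshold)
    out$mate1[i] <- c1$consensus; out$agreement1[i] <- c1$agreement
    out$mate2[i] <- c2$consensus; out$agreement2[i] <- c2$agreement
  }
  attr(out, "rejected_families") <- sum(!keep)
  out
}

#' Write / read the consensus table
#'
#' @param consensus data frame from [sscs_consensus()].
#' @param path TSV path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_consensus_tsv <- function(consensus, path) {
  write.table(consensus, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus_tsv
#' @export
read_consensus_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
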