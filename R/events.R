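# Event extraction from alignments and indel left-normalization.

empty_mutation_events <- function() {
  data.frame(kind = character(0), start = integer(0), length = integer(0),
             inserted = character(0), ref = character(0), alt = character(0),
             amb_left = integer(0), amb_right = integer(0),
             stringsAsFactors = FALSE)
}

#' Extract mutation events from an alignment
#'
#' Each mismatch position becomes one SNV, each insertion/deletion operation
#' one indel event, all in reference coordinates. Wildcard (`N`) positions
#' never produce SNVs. Query overhangs beyond the reference ends (end-gap
#' insertions) are not events.
#'
#' @param aln an `amplicon_alignment` from [semiglobal_align()].
#' @return data frame with columns `kind` (`deletion`/`insertion`/`SNV`),
#'   `start` (0-based reference coordinate; for insertions, the position
#'   before which the bases are inserted), `length`, `inserted`, `ref`,
#'   `alt`, `amb_left`, `amb_right` (ambiguity span filled by
#'   [left_align_indels()]).
#' @export
extract_events <- function(aln) {
  stopifnot(inherits(aln, "amplicon_alignment"))
  ops <- aln$ops
  out <- list()
  rlen <- nchar(aln$reference)
  for (i in seq_len(nrow(ops))) {
    o <- ops[i, ]
    if (o$op == "match") next
    if (o$op == "mismatch") {
      pos <- o$ref_pos + seq_len(o$length) - 1L
      qpos <- o$query_pos + seq_len(o$length) - 1L
      out[[length(out) + 1L]] <- data.frame(
        kind = "SNV", start = pos, length = 1L, inserted = "",
        ref = substring(aln$reference, pos + 1L, pos + 1L),
        alt = substring(aln$query, qpos + 1L, qpos + 1L),
        amb_left = pos, amb_right = pos, stringsAsFactors = FALSE)
    } else if (o$op == "insertion") {
      # end-gap overhang: insertion butted against a reference end
      if (o$ref_pos == 0L || o$ref_pos == rlen) next
      out[[length(out) + 1L]] <- data.frame(
        kind = "insertion", start = o$ref_pos, length = o$length,
        inserted = substr(aln$query, o$query_pos + 1L, o$query_pos + o$length),
        ref = "", alt = "", amb_left = o$ref_pos, amb_right = o$ref_pos,
        stringsAsFactors = FALSE)
    } else {  # deletion
      out[[length(out) + 1L]] <- data.frame(
        kind = "deletion", start = o$ref_pos, length = o$length,
        inserted = "", ref = "", alt = "",
        amb_left = o$ref_pos, amb_right = o$ref_pos, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_mutation_events())
  do.call(rbind, out)
}

# leftmost equivalent placement of one indel; returns list(start, inserted,
# amb_left, amb_right)
normalize_one_indel <- function(kind, start, len, inserted, ref_chars) {
  g <- length(ref_chars)
  if (kind == "deletion") {
    s <- start; e <- start + len
    while (s > 0 && ref_chars[s] == ref_chars[e]) { s <- s - 1L; e <- e - 1L }
    left <- s
    s2 <- start; e2 <- start + len
    while (e2 < g && ref_chars[s2 + 1L] == ref_chars[e2 + 1L]) {
      s2 <- s2 + 1L; e2 <- e2 + 1L
    }
    list(start = left, inserted = "", amb_left = left, amb_right = s2)
  } else {  # insertion
    p <- strsplit(inserted, "", fixed = TRUE)[[1]]
    s <- start; pl <- p
    while (s > 0 && ref_chars[s] == pl[length(pl)]) {
      pl <- c(ref_chars[s], pl[-length(pl)])
      s <- s - 1L
    }
    left <- s; left_seq <- paste(pl, collapse = "")
    s2 <- start; pr <- p
    while (s2 < g && ref_chars[s2 + 1L] == pr[1L]) {
      pr <- c(pr[-1L], ref_chars[s2 + 1L])
      s2 <- s2 + 1L
    }
    list(start = left, inserted = left_seq, amb_left = left, amb_right = s2)
  }
}

#' Left-normalize indel events
#'
#' Shifts every indel to its leftmost equivalent position (the edited
#' sequence is unchanged) and records the ambiguity span
#' `[amb_left, amb_right]` of equivalent start positions, mirroring the
#' formal placement ambiguity of insertions in repeated context. Idempotent;
#' SNVs pass through unchanged.
#'
#' @param events event data frame from [extract_events()].
#' @param reference reference DNA string or [amplicon_spec()].
#' @return the events with normalized `start`/`inserted` and filled
#'   ambiguity spans.
#' @export
left_align_indels <- function(events, reference) {
  if (inherits(reference, "amplicon_spec")) reference <- reference$sequence
  if (nrow(events) == 0) return(events)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(events))) {
    if (!events$kind[i] %in% c("deletion", "insertion")) next
    nm <- normalize_one_indel(events$kind[i], events$start[i],
                              events$length[i], events$inserted[i], ref_chars)
    events$start[i] <- nm$start
    if (events$kind[i] == "insertion") events$inserted[i] <- nm$inserted
    events$amb_left[i] <- nm$amb_left
    events$amb_right[i] <- nm$amb_right
  }
  events
}

#' Export normalized events as VCF
#'
#' Left-aligned, anchor-base convention for indels, 1-based positions.
#'
#' @param events normalized event data frame (with a `key` column if from
#'   [call_molecules()]; used as sample annotation in INFO).
#' @param amplicon an [amplicon_spec()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_vcf <- function(events, amplicon, path) {
  ref <- amplicon$sequence
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", amplicon$name, amplicon$length),
              "##INFO=<ID=MOL,Number=1,Type=String,Description=\"Molecule key\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  lines <- character(0)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind == "SNV") {
      pos <- e$start + 1L; refa <- e$ref; alta <- e$alt
    } else if (e$kind == "deletion") {
      pos <- e$start  # anchor base before the deletion (1-based = start)
      if (pos < 1L) next  # deletion at position 0 has no anchor; skip in VCF
      refa <- substr(ref, pos, e$start + e$length)
      alta <- substr(ref, pos, pos)
    } else {
      pos <- e$start
      if (pos < 1L) next
      anchor <- substr(ref, pos, pos)
      refa <- anchor
      alta <- paste0(anchor, e$inserted)
    }
    info <- if (!is.null(e$key)) sprintf("MOL=%s", e$key) else "."
    lines <- c(lines, paste(amplicon$name, pos, ".", refa, alta, ".", "PASS",
                            info, sep = "\t"))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
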