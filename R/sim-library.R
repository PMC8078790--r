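# Library simulation: molecules with ground truth, UMI tagging, PCR and
# sequencing error layers, and FASTQ rendering.

# Synthetic 323 bp amplicon (the genomic insert scale of a 2x~268 nt MiSeq
# amplicon design; labelled synthetic, not a genomic sequence). Two CRISPR
# target sites are embedded 35 bp apart on opposite strands:
#   site A: top-strand protospacer TATGGCACGCTTTTCTTGCG + PAM TGG, cut = 160
#   site B: bottom-strand protospacer GTACTCAGTCATCACTTGTC + PAM CGG, cut = 125
# The sequence is constructed so that position 149 is the only 'A' adjacent
# to the deletion zone [150, 185) (left-normalization cannot move a zone
# deletion 5' of position 150), the zone is non-repetitive enough that
# left-normalization preserves the 3'-heavy footprint asymmetry, and the cut
# context is T|G so a +1G insertion reproduces the canonical TGG placement
# ambiguity.
SYNTHETIC_AMPLICON <- paste0(
  "GACGTGGTTGCTACACTGTCACTAAACCGCTCCGGCCAAACGGGAGATGGATGACGTCGAAGGGCGGGCA",
  "GAAGCTGTCAAGTGTATTACGGGTGAAGCGGATATCATAGGTGTACCTACCGGACAAGTGATGACTGAGT",
  "ACCTATGGCACGCTTTTCTTGCGTGGGGCCTGCCTCCCCTCTCGCGCTTTGAGCTACTGTAGCTCTGTCT",
  "GGACAATTTCGCTTAAGAGCCCATTTGAGGCACCGGCTGGAACTACACAAACGAACACGAGGCCTGTATG",
  "TCAGTCCACTTAACTGGTCGGCCTTCACTTTCGCATAGCTTAG")

#' Default synthetic amplicon
#'
#' A 323 bp synthetic reference with two embedded CRISPR target sites 35 bp
#' apart on opposite strands (cuts at 160 and 125), mimicking the geometry of
#' a dual-guide amplicon design. See [default_target_site()].
#'
#' @return an [amplicon_spec()].
#' @export
default_amplicon <- function() {
  amplicon_spec("synthetic_amplicon_323", SYNTHETIC_AMPLICON)
}

#' Target sites embedded in the default synthetic amplicon
#'
#' @param which `"A"` (top-strand protospacer, cut at 160) or `"B"`
#'   (bottom-strand protospacer 35 bp upstream, cut at 125).
#' @param mode cleavage mode passed to [locate_cut_site()].
#' @return a `target_site`.
#' @export
default_target_site <- function(which = c("A", "B"),
                                mode = c("nick_bottom", "nick_top", "dsb")) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  amp <- default_amplicon()
  if (which == "A") {
    locate_cut_site(amp, "TATGGCACGCTTTTCTTGCG", "TGG", "top", mode)
  } else {
    locate_cut_site(amp, "GTACTCAGTCATCACTTGTC", "CGG", "bottom", mode)
  }
}

random_umis <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a library of molecules with ground truth
#'
#' Draws `n_molecules` ground-truth events, applies them to the reference,
#' and attaches a UMI pair per molecule (drawn uniformly over `4^umi_len`
#' tags per end; one tag pair per molecule, as in single-round UMI tagging).
#'
#' @param config a [simulation_config()].
#' @param amplicon an [amplicon_spec()].
#' @param site a `target_site`.
#' @return data frame (one row per molecule): `molecule_id`, `umi_a`,
#'   `umi_b`, `kind`, `start`, `length`, `inserted`, `ref_base`, `alt_base`,
#'   `derived_sequence`.
#' @export
simulate_library <- function(config, amplicon, site) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_molecules
  ev <- draw_events(n, config, amplicon, site)
  seqs <- character(n)
  unedited <- ev$kind == "none"
  seqs[unedited] <- amplicon$sequence
  for (i in which(!unedited)) {
    seqs[i] <- apply_event(amplicon$sequence, ev[i, ])
  }
  data.frame(molecule_id = sprintf("mol%06d", seq_len(n)),
             umi_a = random_umis(n, config$umi_len),
             umi_b = random_umis(n, config$umi_len),
             ev,
             derived_sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Simulate a co-targeted (dual-site) library
#'
#' Each molecule independently draws an event at site A (per `config_a`) and
#' at site B (per `config_b`), emulating co-transfection with two guides at
#' levels where editing events at the two sites are independent. If the two
#' drawn event footprints overlap (vanishingly rare for well-separated
#' sites), the site-B event is dropped for that molecule.
#'
#' @param config_a,config_b [simulation_config()]s for the two sites (use
#'   mirrored deletion/SNV extents for opposite-strand nicks).
#' @param amplicon an [amplicon_spec()].
#' @param site_a,site_b the two `target_site`s.
#' @return data frame with `molecule_id`, `umi_a`, `umi_b`, `kind_a`,
#'   `kind_b`, `derived_sequence`.
#' @export
simulate_dual_library <- function(config_a, config_b, amplicon,
                                  site_a, site_b) {
  n <- config_a$n_molecules
  ev_a <- draw_events(n, config_a, amplicon, site_a)
  ev_b <- draw_events(n, config_b, amplicon, site_b)
  seqs <- character(n)
  for (i in seq_len(n)) {
    both <- rbind(ev_a[i, ], ev_b[i, ])
    both <- both[both$kind != "none", , drop = FALSE]
    if (nrow(both) == 2) {
      fa <- c(both$start[1], both$start[1] + max(both$length[1], 1L))
      fb <- c(both$start[2], both$start[2] + max(both$length[2], 1L))
      if (fa[1] < fb[2] && fb[1] < fa[2]) both <- both[1, , drop = FALSE]
    }
    seqs[i] <- apply_events(amplicon$sequence, both)
  }
  data.frame(molecule_id = sprintf("mol%06d", seq_len(n)),
             umi_a = random_umis(n, config_a$umi_len),
             umi_b = random_umis(n, config_a$umi_len),
             kind_a = ev_a$kind, kind_b = ev_b$kind,
             derived_sequence = seqs, stringsAsFactors = FALSE)
}

#' Write / read the ground-truth table
#'
#' @param molecules data frame from [simulate_library()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(molecules, path) {
  cols <- c("molecule_id", "umi_a", "umi_b", "kind", "start", "length",
            "inserted", "ref_base", "alt_base")
  write.table(molecules[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(inserted = "character", ref_base = "character",
                            alt_base = "character"))
}

# Substitute bases at random positions at the given per-base rate.
# Returns the mutated strings; draws are per string then per position.
inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Render paired-end reads from simulated molecules
#'
#' Read layout: mate 1 = `umi_a` + forward locus primer + molecule prefix;
#' mate 2 = `umi_b` + reverse locus primer + reverse complement of the
#' molecule suffix. Per-molecule read counts come from the family-size
#' distribution. PCR substitutions (rate `e_pcr`) are applied once per
#' molecule lineage and shared by all of its reads; sequencing substitutions
#' (rate `e_seq`) are applied independently per read over the whole read
#' including UMI and primer.
#'
#' @param molecules data frame from [simulate_library()].
#' @param config a [simulation_config()].
#' @return data frame (one row per read pair): `read_id`, `molecule_id`,
#'   `mate1`, `mate2`.
#' @export
render_reads <- function(molecules, config) {
  stopifnot(inherits(config, "simulation_config"))
  pl <- payload_lengths(config)
  if (any(pl < 1)) stop("read_len too short to include UMI + primer")
  n <- nrow(molecules)
  lineage <- inject_substitutions(molecules$derived_sequence, config$e_pcr)
  fam <- 1L + rpois(n, config$family_lambda)
  p1 <- substr(lineage, 1L, pl[["mate1"]])
  p2 <- revcomp(substr(lineage, pmax(1L, nchar(lineage) - pl[["mate2"]] + 1L),
                       nchar(lineage)))
  idx <- rep.int(seq_len(n), fam)
  m1 <- paste0(molecules$umi_a[idx], config$fwd_primer, p1[idx])
  m2 <- paste0(molecules$umi_b[idx], config$rev_primer, p2[idx])
  m1 <- inject_substitutions(m1, config$e_seq)
  m2 <- inject_substitutions(m2, config$e_seq)
  rep_i <- sequence(fam)
  data.frame(read_id = sprintf("%s:r%03d", molecules$molecule_id[idx], rep_i),
             molecule_id = molecules$molecule_id[idx],
             mate1 = m1, mate2 = m2, stringsAsFactors = FALSE)
}

#' Write / read a paired FASTQ file set
#'
#' Standard 4-line FASTQ records, Phred+33, constant quality; gzip output is
#' selected by a `.gz` suffix and gzip input is autodetected.
#'
#' @param reads data frame with columns `read_id`, `mate1`, `mate2`.
#' @param path1,path2 output (or input) FASTQ paths for mates 1 and 2.
#' @param phred_char constant quality character.
#' @return `c(path1, path2)` invisibly; for the reader, a data frame with
#'   columns `read_id`, `mate1`, `mate2`.
#' @export
write_fastq_pair <- function(reads, path1, path2, phred_char = "F") {
  write_one <- function(seqs, ids, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    qual <- Biostrings::BStringSet(strrep(phred_char, nchar(seqs)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                                compress = endsWith(path, ".gz"))
  }
  write_one(reads$mate1, reads$read_id, path1)
  write_one(reads$mate2, reads$read_id, path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) stop("mate FASTQ files differ in read count")
  if (length(r1) == 0) stop("empty FASTQ input")
  ids1 <- sub("\\s.*$", "", names(r1))
  ids2 <- sub("\\s.*$", "", names(r2))
  if (!identical(ids1, ids2)) stop("mate FASTQ files are not in matching order")
  data.frame(read_id = ids1, mate1 = as.character(r1),
             mate2 = as.character(r2), stringsAsFactors = FALSE)
}
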