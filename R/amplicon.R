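# Amplicon coordinate model: reference sequence, cut-site location from a
# protospacer + PAM, and scoring windows.
#
# Coordinates are 0-based, half-open, on the top strand of the amplicon.
# A cut coordinate `cut` names the phosphodiester bond between reference
# positions cut-1 and cut.

#' Construct an amplicon reference
#'
#' @param name identifier for the amplicon (used in SAM/VCF export).
#' @param sequence top-strand DNA sequence (uppercase A/C/G/T).
#' @return an `amplicon_spec` object with fields `name`, `sequence`, `length`.
#' @export
#' @examples
#' amp <- amplicon_spec("toy", "ACGTACGTACGT")
#' amp$length
amplicon_spec <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("amplicon sequence must be non-empty")
  assert_dna(sequence, "amplicon sequence")
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("<amplicon_spec> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' Read a single-record FASTA file as an amplicon reference
#'
#' @param path FASTA file with exactly one record.
#' @return an [amplicon_spec()].
#' @export
read_amplicon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) {
    stop(sprintf("expected a single-record FASTA, found %d records", length(ss)))
  }
  amplicon_spec(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]))
}

#' Locate a CRISPR cut site from a protospacer and PAM
#'
#' Finds the unique occurrence of the protospacer + PAM on the stated strand
#' of the amplicon and places the cut 3 nt 5' of the PAM within the
#' protospacer (the blunt Cas9 / Cas9 D10A cleavage position), reported in
#' top-strand coordinates regardless of target strand. For a bottom-strand
#' target, the top strand carries `revcomp(pam)` followed by
#' `revcomp(protospacer)` and the cut falls 6 nt 3' of the start of that
#' match; for a top-strand target the cut falls 17 nt 3' of the protospacer
#' start.
#'
#' @param amplicon an [amplicon_spec()].
#' @param protospacer 20 nt protospacer, written 5'->3' on the target strand.
#' @param pam 3 nt PAM, written 5'->3' on the target strand.
#' @param strand `"top"` or `"bottom"`: the strand carrying protospacer + PAM.
#' @param mode cleavage mode: `"nick_top"`, `"nick_bottom"` or `"dsb"`.
#' @return a `target_site` object with fields `protospacer`, `pam`, `strand`,
#'   `cut` (0-based bond coordinate), `mode`, `match_start`.
#' @export
#' @examples
#' amp <- default_amplicon()
#' locate_cut_site(amp, "CGTCTGAGCCGCTGGCTGGC", "TGG", "top")$cut
locate_cut_site <- function(amplicon, protospacer, pam,
                            strand = c("top", "bottom"),
                            mode = c("nick_bottom", "nick_top", "dsb")) {
  stopifnot(inherits(amplicon, "amplicon_spec"))
  strand <- match.arg(strand)
  mode <- match.arg(mode)
  protospacer <- toupper(protospacer); pam <- toupper(pam)
  if (nchar(protospacer) != 20) stop("protospacer must be 20 nt")
  if (nchar(pam) != 3) stop("PAM must be 3 nt")
  assert_dna(protospacer, "protospacer"); assert_dna(pam, "PAM")
  pattern <- if (strand == "top") {
    paste0(protospacer, pam)
  } else {
    paste0(revcomp(pam), revcomp(protospacer))
  }
  hits <- gregexpr(pattern, amplicon$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    stop(sprintf("target not found: protospacer+PAM absent from the %s strand of '%s'",
                 strand, amplicon$name))
  }
  if (length(hits) > 1) {
    stop(sprintf("ambiguous target: protospacer+PAM occurs %d times on the %s strand",
                 length(hits), strand))
  }
  s <- hits[1] - 1L  # 0-based match start
  cut <- if (strand == "top") s + 17L else s + 6L
  if (cut <= 0 || cut >= amplicon$length) {
    stop("cut coordinate falls on the amplicon boundary; extend the amplicon")
  }
  structure(list(protospacer = protospacer, pam = pam, strand = strand,
                 cut = as.integer(cut), mode = mode, match_start = s),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s strand, cut at %d (%s)\n", x$strand, x$cut, x$mode))
  invisible(x)
}

#' Scoring window around a cut site
#'
#' Half-open interval of the requested width centered on the cut bond:
#' `[cut - floor(width/2), cut - floor(width/2) + width)`. For odd widths the
#' 3' side holds one more position than the 5' side; even widths are balanced.
#' Windows extending past the amplicon are clipped with a warning.
#'
#' @param site a `target_site`, or a bare integer cut coordinate.
#' @param width window width in bases (default 65).
#' @param amplicon optional [amplicon_spec()] used for clipping.
#' @return a `scoring_window`: integer vector `c(start, end)`, 0-based half-open.
#' @export
#' @examples
#' scoring_window(240L, width = 65)
scoring_window <- function(site, width = 65L, amplicon = NULL) {
  cut <- if (inherits(site, "target_site")) site$cut else as.integer(site)
  stopifnot(length(cut) == 1, !is.na(cut), width >= 1)
  width <- as.integer(width)
  start <- cut - width %/% 2L
  end <- start + width
  if (!is.null(amplicon)) {
    stopifnot(inherits(amplicon, "amplicon_spec"))
    g <- amplicon$length
    if (start < 0L || end > g) {
      warning(sprintf("scoring window [%d,%d) clipped to amplicon [0,%d)", start, end, g))
      start <- max(0L, start); end <- min(g, end)
    }
  } else if (start < 0L) {
    warning(sprintf("scoring window [%d,%d) clipped at 0", start, end))
    start <- 0L
  }
  if (start >= end) stop("scoring window is empty after clipping")
  structure(c(start = start, end = end), class = "scoring_window")
}

window_positions <- function(window) seq.int(window[["start"]], window[["end"]] - 1L)
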