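# Simulation configuration: the study conditions the generator emulates.

#' Configure the synthetic amplicon library generator
#'
#' Defaults describe a nick-targeted library in control cells: 2.2% of
#' molecules carry a repair event, deletions dominate the class mix, deletion
#' and SNV footprints occupy an asymmetric zone reaching ~10 bp 5' and
#' ~25 bp 3' of the cut, insertions are 1 bp (+1G at the default site), 25%
#' of SNVs are transversions, reads are 268 nt with a 10 nt UMI, and UMI
#' family sizes are 1 + Poisson(4) (mean 5, minimum 1).
#'
#' @param n_molecules number of original molecules to simulate.
#' @param p_mut probability a molecule carries a repair event.
#' @param class_mix named probabilities over `deletion`, `insertion`, `SNV`,
#'   `donor_HDR`; must sum to 1.
#' @param del_extent_5,del_extent_3 maximum deletion reach 5'/3' of the cut.
#' @param del_q5,del_q3 per-side truncated-geometric extent parameters: the
#'   per-side extent L has P(L = k) proportional to q^k on 0..cap.
#' @param p_del_1bp probability a deletion is forced to exactly 1 bp at the cut.
#' @param ins_base base identity for insertions.
#' @param ins_len_probs named numeric vector of insertion-length probabilities
#'   (names are lengths); default point mass at 1.
#' @param snv_zone_5,snv_zone_3 SNV placement zone reach 5'/3' of the cut.
#' @param transversion_fraction probability an SNV is a transversion.
#' @param donor_edit optional donor-templated replacement:
#'   `list(start =, end =, replacement =)` in 0-based half-open reference
#'   coordinates. Required when `class_mix["donor_HDR"] > 0`.
#' @param umi_len UMI length in bases.
#' @param family_lambda UMI family sizes are drawn as `1 + rpois(family_lambda)`.
#' @param e_pcr per-base probability of an early-cycle PCR substitution shared
#'   by the whole UMI family (the error mode consensus cannot remove).
#' @param e_seq per-base per-read sequencing substitution probability.
#' @param read_len total read length including UMI and locus primer.
#' @param fwd_primer,rev_primer locus primer sequences following the UMI on
#'   mates 1 and 2.
#' @param phred_char constant quality character written to FASTQ.
#' @param amplicon,site optional [amplicon_spec()] and `target_site`; when
#'   both are given the read-pair geometry is validated at construction (the
#'   default 65 bp scoring window must lie inside the mate overlap).
#' @return a `simulation_config` object (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_molecules = 100, p_mut = 0)
simulation_config <- function(n_molecules = 10000L,
                              p_mut = 0.022,
                              class_mix = c(deletion = 0.7, insertion = 0.1,
                                            SNV = 0.2, donor_HDR = 0),
                              del_extent_5 = 10L, del_extent_3 = 25L,
                              del_q5 = 0.85, del_q3 = 0.85,
                              p_del_1bp = 0.15,
                              ins_base = "G",
                              ins_len_probs = c("1" = 1),
                              snv_zone_5 = 10L, snv_zone_3 = 25L,
                              transversion_fraction = 0.25,
                              donor_edit = NULL,
                              umi_len = 10L,
                              family_lambda = 4,
                              e_pcr = 1e-5,
                              e_seq = 1e-3,
                              read_len = 268L,
                              fwd_primer = "ACTTCGGTCCGCCATCCTCGTC",
                              rev_primer = "GCAAATCCCAGCCCTGCTTTC",
                              phred_char = "F",
                              amplicon = NULL, site = NULL) {
  cfg <- list(n_molecules = as.integer(n_molecules), p_mut = p_mut,
              class_mix = class_mix,
              del_extent_5 = as.integer(del_extent_5),
              del_extent_3 = as.integer(del_extent_3),
              del_q5 = del_q5, del_q3 = del_q3, p_del_1bp = p_del_1bp,
              ins_base = toupper(ins_base), ins_len_probs = ins_len_probs,
              snv_zone_5 = as.integer(snv_zone_5),
              snv_zone_3 = as.integer(snv_zone_3),
              transversion_fraction = transversion_fraction,
              donor_edit = donor_edit,
              umi_len = as.integer(umi_len), family_lambda = family_lambda,
              e_pcr = e_pcr, e_seq = e_seq, read_len = as.integer(read_len),
              fwd_primer = toupper(fwd_primer), rev_primer = toupper(rev_primer),
              phred_char = phred_char)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  if (!is.null(amplicon) && !is.null(site)) {
    check_sim_geometry(cfg, amplicon, site)
  }
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_molecules >= 1,
              is_probability(p_mut), is_probability(class_mix),
              is_probability(c(del_q5, del_q3, p_del_1bp,
                               transversion_fraction, e_pcr, e_seq)),
              del_extent_5 >= 0, del_extent_3 >= 0,
              del_extent_5 + del_extent_3 >= 1,
              snv_zone_5 >= 0, snv_zone_3 >= 1,
              umi_len >= 1, family_lambda >= 0, read_len >= 1,
              nchar(phred_char) == 1)
    if (!setequal(names(class_mix), c("deletion", "insertion", "SNV", "donor_HDR")))
      stop("class_mix must be named deletion/insertion/SNV/donor_HDR")
    if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
    if (abs(sum(ins_len_probs) - 1) > 1e-9) stop("ins_len_probs must sum to 1")
    if (any(as.integer(names(ins_len_probs)) < 1)) stop("insertion lengths must be >= 1")
    if (!ins_base %in% c("A", "C", "G", "T")) stop("ins_base must be one of A/C/G/T")
    if (class_mix[["donor_HDR"]] > 0 && is.null(donor_edit))
      stop("donor_edit must be supplied when class_mix['donor_HDR'] > 0")
    if (!is.null(donor_edit)) {
      stopifnot(is.list(donor_edit),
                all(c("start", "end", "replacement") %in% names(donor_edit)),
                donor_edit$start < donor_edit$end)
      assert_dna(donor_edit$replacement, "donor replacement")
    }
  })
  invisible(cfg)
}

# Payload lengths: read bases remaining after UMI + locus primer.
payload_lengths <- function(cfg) {
  c(mate1 = cfg$read_len - cfg$umi_len - nchar(cfg$fwd_primer),
    mate2 = cfg$read_len - cfg$umi_len - nchar(cfg$rev_primer))
}

# The caller's dual-strand SNV confirmation requires the scoring window to sit
# inside the region covered by both mates; event zones must fit the amplicon.
check_sim_geometry <- function(cfg, amplicon, site, window_width = 65L) {
  stopifnot(inherits(amplicon, "amplicon_spec"), inherits(site, "target_site"))
  pl <- payload_lengths(cfg)
  if (any(pl < 1)) stop("read_len too short to include UMI + primer")
  g <- amplicon$length
  win <- suppressWarnings(scoring_window(site, window_width, amplicon))
  m1_span <- c(0L, min(pl[["mate1"]], g))
  m2_span <- c(max(0L, g - pl[["mate2"]]), g)
  if (win[["start"]] < m2_span[1] || win[["end"]] > m1_span[2]) {
    stop(sprintf(paste0("read pair does not jointly cover the %d bp scoring ",
                        "window in the mate overlap: mate1 covers [0,%d), mate2 ",
                        "covers [%d,%d), window [%d,%d)"),
                 window_width, m1_span[2], m2_span[1], g,
                 win[["start"]], win[["end"]]))
  }
  if (site$cut - cfg$del_extent_5 < 0 || site$cut + cfg$del_extent_3 > g ||
      site$cut - cfg$snv_zone_5 < 0 || site$cut + cfg$snv_zone_3 > g) {
    stop("deletion/SNV zone exceeds the amplicon")
  }
  invisible(TRUE)
}

#' Uncut-control simulation preset
#'
#' A background-only library: no repair events (`p_mut = 0`), with the PCR
#' lineage error rate raised so the called SNV floor over a 65 bp window
#' approximates the ~0.26% per-molecule SNV background of an uncut-control
#' amplicon panel (65 positions x 4e-5 per base; PCR lineage errors pass
#' consensus and dual-strand confirmation, unlike sequencing errors). This
#' is a recipe for emulating an error floor, not a guarantee; indel
#' background is not simulated.
#'
#' @param n_molecules number of control molecules.
#' @param ... further overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
uncut_control_config <- function(n_molecules = 10000L, ...) {
  simulation_config(n_molecules = n_molecules, p_mut = 0, e_pcr = 4e-5, ...)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d molecules, p_mut=%g, mix ",
                     "del/ins/SNV/HDR = %s\n  del zone -%d/+%d, e_pcr=%g, ",
                     "e_seq=%g, read_len=%d, umi=%d\n"),
              x$n_molecules, x$p_mut,
              paste(signif(x$class_mix, 3), collapse = "/"),
              x$del_extent_5, x$del_extent_3, x$e_pcr, x$e_seq,
              x$read_len, x$umi_len))
  invisible(x)
}
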