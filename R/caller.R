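# Per-molecule variant calling: window restriction, indel merging across
# mates, dual-strand SNV confirmation, and donor-edit (a-HDR) classification.

#' Calling rules
#'
#' @param snv_confirmation `"mate_overlap"` (default; an SNV is kept only
#'   when the position is covered by both mates and both report the same
#'   alternative base — the dual-strand confirmation rule applied at the
#'   mate level), `"duplex"` (confirmation against the reciprocal "ba" UMI
#'   family when present) or `"single"` (no confirmation).
#' @param require_window_coverage exclude molecules whose mates do not both
#'   cover the scoring window from all frequency denominators.
#' @param donor_edit optional donor replacement
#'   (`list(start =, end =, replacement =)`) enabling a-HDR classification.
#' @return a `call_rules` list.
#' @export
call_rules <- function(snv_confirmation = c("mate_overlap", "duplex", "single"),
                       require_window_coverage = TRUE,
                       donor_edit = NULL) {
  structure(list(snv_confirmation = match.arg(snv_confirmation),
                 require_window_coverage = require_window_coverage,
                 donor_edit = donor_edit),
            class = "call_rules")
}

# Expected left-normalized events of the donor replacement, computed by
# aligning the donor-edited reference against the reference.
donor_expected_events <- function(amplicon, donor_edit,
                                  scheme = scoring_scheme()) {
  edited <- apply_event(amplicon$sequence,
                        list(kind = "donor_HDR", start = donor_edit$start,
                             length = donor_edit$end - donor_edit$start,
                             inserted = donor_edit$replacement))
  aln <- semiglobal_align(edited, amplicon$sequence, scheme)
  left_align_indels(extract_events(aln), amplicon$sequence)
}

event_sig <- function(ev) {
  paste(ev$kind, ev$start, ev$length, ev$inserted, ev$alt, sep = "|")
}

# footprint interval of an event as c(start, end) half-open; insertions get
# a zero-width footprint at their position
event_footprint <- function(ev) {
  end <- ifelse(ev$kind == "deletion", ev$start + ev$length, ev$start + (ev$kind == "SNV"))
  cbind(start = ev$start, end = end)
}

intersects_window <- function(ev, window) {
  ws <- window[["start"]]; we <- window[["end"]]
  ifelse(ev$kind == "deletion",
         ev$start < we & (ev$start + ev$length) > ws,
         ev$start >= ws & ev$start < we)
}

#' Classify a molecule as a donor-templated (a-HDR) repair product
#'
#' True iff the molecule's confirmed events contain every expected donor
#' event and nothing else within the donor edit footprint.
#'
#' @param events confirmed event data frame for one molecule.
#' @param donor_events expected donor events from the donor edit.
#' @param donor_edit the donor edit definition.
#' @return logical scalar.
#' @export
classify_hdr <- function(events, donor_events, donor_edit) {
  if (nrow(donor_events) == 0) return(FALSE)
  have <- event_sig(events) %in% event_sig(donor_events)
  if (!all(event_sig(donor_events) %in% event_sig(events))) return(FALSE)
  others <- events[!have, , drop = FALSE]
  if (nrow(others) == 0) return(TRUE)
  fp <- event_footprint(others)
  !any(fp[, "start"] < donor_edit$end & fp[, "end"] > donor_edit$start |
         (others$kind == "insertion" &
            others$start >= donor_edit$start & others$start <= donor_edit$end))
}

# Call one molecule from its two mate event sets and alignment spans.
call_one <- function(ev1, ev2, span1, span2, window, rules, donor_events) {
  ws <- window[["start"]]; we <- window[["end"]]
  ev1 <- ev1[intersects_window(ev1, window), , drop = FALSE]
  ev2 <- ev2[intersects_window(ev2, window), , drop = FALSE]

  # indels: union across mates, deduplicated on the normalized signature
  ind1 <- ev1[ev1$kind != "SNV", , drop = FALSE]
  ind2 <- ev2[ev2$kind != "SNV", , drop = FALSE]
  ind <- rbind(ind1, ind2)
  src <- rep(c(1L, 2L), c(nrow(ind1), nrow(ind2)))
  if (nrow(ind) > 0) {
    keep <- !duplicated(event_sig(ind))
    ind <- ind[keep, , drop = FALSE]
    src <- src[keep]
  }
  discordant <- FALSE
  if (nrow(ind) > 1) {
    conflicts <- function(a, b) {
      ka <- ind$kind[a]; kb <- ind$kind[b]
      sa <- ind$start[a]; sb <- ind$start[b]
      ea <- sa + ind$length[a]; eb <- sb + ind$length[b]
      if (ka == "deletion" && kb == "deletion") return(sa < eb && sb < ea)
      if (ka == "insertion" && kb == "insertion") return(sa == sb)
      if (ka == "insertion") return(sa > sb && sa < eb)  # insertion inside deletion
      sb > sa && sb < ea
    }
    for (a in seq_len(nrow(ind) - 1L)) {
      for (b in seq(a + 1L, nrow(ind))) {
        if (src[a] != src[b] && conflicts(a, b)) discordant <- TRUE
      }
    }
  }

  # SNVs under the selected confirmation rule
  s1 <- ev1[ev1$kind == "SNV", , drop = FALSE]
  s2 <- ev2[ev2$kind == "SNV", , drop = FALSE]
  snv <- switch(rules$snv_confirmation,
    single = ,
    duplex = {  # duplex cross-family confirmation is applied by the batch caller
      s <- rbind(s1, s2)
      s[!duplicated(event_sig(s)), , drop = FALSE]
    },
    mate_overlap = {
      both <- intersect(event_sig(s1), event_sig(s2))
      cand <- s1[event_sig(s1) %in% both, , drop = FALSE]
      covered <- cand$start >= max(span1[1], span2[1]) &
        cand$start < min(span1[2], span2[2])
      cand[covered, , drop = FALSE]
    })

  # SNVs inside a deletion footprint are unalignable noise: suppress
  del <- ind[ind$kind == "deletion", , drop = FALSE]
  if (nrow(snv) > 0 && nrow(del) > 0) {
    inside <- vapply(snv$start, function(p)
      any(p >= del$start & p < del$start + del$length), logical(1))
    snv <- snv[!inside, , drop = FALSE]
  }

  events <- rbind(ind, snv)
  is_hdr <- FALSE
  if (!is.null(rules$donor_edit) && nrow(donor_events) > 0) {
    is_hdr <- classify_hdr(events, donor_events, rules$donor_edit)
    if (is_hdr) {
      events <- events[!event_sig(events) %in% event_sig(donor_events), ,
                       drop = FALSE]
    }
  }
  list(events = events, discordant = discordant, is_hdr = is_hdr)
}

#' Call variants for every consensus molecule
#'
#' Aligns both consensus mates to the reference (mate 2 is reverse
#' complemented first), extracts and left-normalizes events, restricts them
#' to the scoring window, merges indels across mates, applies the configured
#' SNV confirmation rule, suppresses SNVs inside deletion footprints, and
#' classifies donor-templated repair.
#'
#' @param consensus data frame from [sscs_consensus()].
#' @param amplicon an [amplicon_spec()].
#' @param window a [scoring_window()].
#' @param rules a [call_rules()].
#' @param scheme a [scoring_scheme()].
#' @return list with `calls` (one row per molecule: flags and coverage) and
#'   `events` (confirmed events with molecule `key`), plus counts in
#'   attributes `n_discordant`, `n_no_coverage`.
#' @export
call_molecules <- function(consensus, amplicon, window,
                           rules = call_rules(), scheme = scoring_scheme()) {
  stopifnot(inherits(amplicon, "amplicon_spec"), inherits(rules, "call_rules"))
  n <- nrow(consensus)
  ws <- window[["start"]]; we <- window[["end"]]
  donor_events <- if (!is.null(rules$donor_edit)) {
    donor_expected_events(amplicon, rules$donor_edit, scheme)
  } else empty_mutation_events()

  calls <- data.frame(key = consensus$key,
                      family_size = consensus$family_size,
                      m1_covers = logical(n), m2_covers = logical(n),
                      covered = logical(n), discordant = logical(n),
                      is_mutant = logical(n), has_deletion = logical(n),
                      has_insertion = logical(n), has_snv = logical(n),
                      is_hdr = logical(n), n_events = integer(n),
                      stringsAsFactors = FALSE)
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    a1 <- semiglobal_align(consensus$mate1[i], amplicon$sequence, scheme)
    a2 <- semiglobal_align(revcomp(consensus$mate2[i]), amplicon$sequence, scheme)
    e1 <- left_align_indels(extract_events(a1), amplicon$sequence)
    e2 <- left_align_indels(extract_events(a2), amplicon$sequence)
    res <- call_one(e1, e2, a1$ref_span, a2$ref_span, window, rules, donor_events)
    calls$m1_covers[i] <- a1$ref_span[[1]] <= ws && a1$ref_span[[2]] >= we
    calls$m2_covers[i] <- a2$ref_span[[1]] <= ws && a2$ref_span[[2]] >= we
    calls$discordant[i] <- res$discordant
    calls$is_hdr[i] <- res$is_hdr
    ev <- res$events
    calls$n_events[i] <- nrow(ev)
    calls$has_deletion[i] <- any(ev$kind == "deletion")
    calls$has_insertion[i] <- any(ev$kind == "insertion")
    calls$has_snv[i] <- any(ev$kind == "SNV")
    calls$is_mutant[i] <- nrow(ev) > 0 || res$is_hdr
    if (nrow(ev) > 0) {
      ev$key <- consensus$key[i]
      ev_list[[i]] <- ev
    }
  }
  calls$covered <- if (rules$require_window_coverage) {
    calls$m1_covers & calls$m2_covers
  } else rep(TRUE, n)
  # discordant molecules are excluded from denominators
  calls$covered <- calls$covered & !calls$discordant

  events <- if (any(!vapply(ev_list, is.null, logical(1)))) {
    do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  } else {
    cbind(empty_mutation_events(), data.frame(key = character(0)))
  }

  if (rules$snv_confirmation == "duplex") {
    res <- confirm_duplex_snvs(calls, events)
    calls <- res$calls; events <- res$events
  }

  structure(list(calls = calls, events = events),
            n_discordant = sum(calls$discordant),
            n_no_coverage = sum(!(calls$m1_covers & calls$m2_covers)),
            class = "molecule_calls")
}

# Duplex confirmation: an SNV survives only if the reciprocal (b,a) family
# exists and reports the same normalized SNV.
confirm_duplex_snvs <- function(calls, events) {
  split_key <- strsplit(calls$key, "-", fixed = TRUE)
  partner <- vapply(split_key, function(k) paste(k[2], k[1], sep = "-"), character(1))
  keep <- rep(TRUE, nrow(events))
  for (i in which(events$kind == "SNV")) {
    p <- partner[match(events$key[i], calls$key)]
    prows <- events$key == p & events$kind == "SNV" &
      events$start == events$start[i] & events$alt == events$alt[i]
    keep[i] <- any(prows)
  }
  events <- events[keep, , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    evi <- events[events$key == calls$key[i], , drop = FALSE]
    calls$has_snv[i] <- any(evi$kind == "SNV")
    calls$n_events[i] <- nrow(evi)
    calls$is_mutant[i] <- nrow(evi) > 0 || calls$is_hdr[i]
  }
  list(calls = calls, events = events)
}

#' @export
print.molecule_calls <- function(x, ...) {
  cat(sprintf("<molecule_calls> %d molecules (%d in denominator), %d mutant, %d events\n",
              nrow(x$calls), sum(x$calls$covered), sum(x$calls$is_mutant),
              nrow(x$events)))
  invisible(x)
}

#' Write / read molecule calls
#'
#' Two TSVs: per-molecule flags and the confirmed event list.
#'
#' @param mc a `molecule_calls` object.
#' @param calls_path,events_path output TSV paths.
#' @return paths invisibly; the reader returns a `molecule_calls` object.
#' @export
write_calls_tsv <- function(mc, calls_path, events_path) {
  write.table(mc$calls, calls_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mc$events, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(calls_path, events_path))
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(calls_path, events_path) {
  calls <- read.delim(calls_path, stringsAsFactors = FALSE)
  events <- read.delim(events_path, stringsAsFactors = FALSE,
                       colClasses = c(inserted = "character", ref = "character",
                                      alt = "character"))
  structure(list(calls = calls, events = events),
            n_discordant = sum(calls$discordant),
            n_no_coverage = sum(!(calls$m1_covers & calls$m2_covers)),
            class = "molecule_calls")
}
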