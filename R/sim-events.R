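# Ground-truth repair events: drawing them from the configured mixture and
# applying them to the reference sequence.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Is a ref->alt substitution a transversion?
#'
#' Transversions exchange a purine for a pyrimidine (A/G <-> C/T); transitions
#' stay within class (A<->G, C<->T).
#'
#' @param ref,alt single reference and alternative bases (vectorized).
#' @return logical vector.
#' @export
is_transversion <- function(ref, alt) {
  purine <- c("A", "G")
  (ref %in% purine) != (alt %in% purine)
}

# Truncated geometric draw on 0..cap with P(k) proportional to q^k.
rtruncgeom <- function(n, q, cap) {
  if (cap == 0) return(rep.int(0L, n))
  pmf <- q ^ (0:cap)
  sample.int(cap + 1L, n, replace = TRUE, prob = pmf) - 1L
}

empty_events <- function(n = 0) {
  data.frame(kind = rep.int("none", n), start = rep.int(NA_integer_, n),
             length = rep.int(0L, n), inserted = rep.int("", n),
             ref_base = rep.int("", n), alt_base = rep.int("", n),
             stringsAsFactors = FALSE)
}

#' Draw ground-truth repair events
#'
#' With probability `1 - p_mut` a molecule is unedited (`kind = "none"`).
#' Otherwise the event class follows `class_mix`. Deletions remove
#' `[cut - L5, cut + L3)` with per-side extents drawn from truncated
#' geometrics (at least one side >= 1); with probability `p_del_1bp` the
#' deletion is instead exactly the single base 3' of the cut. Insertions add
#' `ins_base` repeated to the drawn length at the cut. SNVs pick a position
#' uniformly in the asymmetric zone `[cut - snv_zone_5, cut + snv_zone_3)`
#' and an alternative base that is a transversion with probability
#' `transversion_fraction` (uniform among eligible alternatives within the
#' chosen class). Donor-HDR events carry the configured donor replacement.
#'
#' @param n number of events to draw.
#' @param config a [simulation_config()].
#' @param amplicon an [amplicon_spec()].
#' @param site a `target_site` from [locate_cut_site()].
#' @return data frame with columns `kind`, `start`, `length`, `inserted`,
#'   `ref_base`, `alt_base` (0-based `start`).
#' @export
draw_events <- function(n, config, amplicon, site) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(amplicon, "amplicon_spec"), inherits(site, "target_site"))
  check_sim_geometry(config, amplicon, site)
  cut <- site$cut
  ev <- empty_events(n)
  if (n == 0) return(ev)
  mutant <- runif(n) < config$p_mut
  k <- sum(mutant)
  if (k == 0) return(ev)
  classes <- sample(names(config$class_mix), k, replace = TRUE,
                    prob = config$class_mix)
  ev$kind[mutant] <- classes
  idx <- which(mutant)

  # deletions
  di <- idx[classes == "deletion"]
  if (length(di) > 0) {
    nd <- length(di)
    one_bp <- runif(nd) < config$p_del_1bp
    l5 <- rtruncgeom(nd, config$del_q5, config$del_extent_5)
    l3 <- rtruncgeom(nd, config$del_q3, config$del_extent_3)
    zero <- which(!one_bp & l5 + l3 == 0)
    while (length(zero) > 0) {  # at least one side must reach >= 1
      l5[zero] <- rtruncgeom(length(zero), config$del_q5, config$del_extent_5)
      l3[zero] <- rtruncgeom(length(zero), config$del_q3, config$del_extent_3)
      zero <- zero[l5[zero] + l3[zero] == 0]
    }
    l5[one_bp] <- 0L; l3[one_bp] <- 1L
    ev$start[di] <- cut - l5
    ev$length[di] <- l5 + l3
  }

  # insertions
  ii <- idx[classes == "insertion"]
  if (length(ii) > 0) {
    lens <- as.integer(names(config$ins_len_probs))
    drawn <- if (length(lens) == 1) rep.int(lens, length(ii)) else
      sample(lens, length(ii), replace = TRUE, prob = config$ins_len_probs)
    ev$start[ii] <- cut
    ev$length[ii] <- drawn
    ev$inserted[ii] <- strrep(config$ins_base, drawn)
  }

  # SNVs
  si <- idx[classes == "SNV"]
  if (length(si) > 0) {
    ns <- length(si)
    pos <- cut - config$snv_zone_5 +
      sample.int(config$snv_zone_5 + config$snv_zone_3, ns, replace = TRUE) - 1L
    refb <- substring(amplicon$sequence, pos + 1L, pos + 1L)
    tv <- runif(ns) < config$transversion_fraction
    altb <- character(ns)
    altb[tv] <- vapply(refb[tv], function(b)
      sample(TRANSVERSIONS[[b]], 1), character(1))
    altb[!tv] <- TRANSITIONS[refb[!tv]]
    ev$start[si] <- pos
    ev$length[si] <- 1L
    ev$ref_base[si] <- refb
    ev$alt_base[si] <- altb
  }

  # donor-templated edits
  hi <- idx[classes == "donor_HDR"]
  if (length(hi) > 0) {
    de <- config$donor_edit
    ev$start[hi] <- as.integer(de$start)
    ev$length[hi] <- as.integer(de$end - de$start)
    ev$inserted[hi] <- de$replacement
  }
  ev
}

#' Apply a ground-truth event to a reference sequence
#'
#' Deterministic string surgery: deletions remove `[start, start + length)`;
#' insertions place `inserted` before position `start`; SNVs substitute one
#' base (the stored `ref_base` is checked); donor-HDR replaces
#' `[start, start + length)` with the stored replacement; `kind = "none"`
#' returns the reference unchanged.
#'
#' @param reference reference DNA string.
#' @param event one event: a list or single-row data frame with the columns
#'   produced by [draw_events()].
#' @return the edited sequence.
#' @export
#' @examples
#' apply_event("ACGTGC", list(kind = "deletion", start = 2, length = 2))
apply_event <- function(reference, event) {
  stopifnot(is.character(reference), length(reference) == 1)
  kind <- as.character(event$kind)
  g <- nchar(reference)
  s <- as.integer(event$start)
  len <- as.integer(event$length %||% 0L)
  switch(kind,
    none = reference,
    deletion = {
      if (s < 0 || s + len > g || len < 1) stop("deletion footprint out of range")
      paste0(substr(reference, 1, s), substr(reference, s + len + 1, g))
    },
    insertion = {
      ins <- as.character(event$inserted)
      if (s < 0 || s > g || nchar(ins) < 1) stop("insertion out of range or empty")
      paste0(substr(reference, 1, s), ins, substr(reference, s + 1, g))
    },
    SNV = {
      if (s < 0 || s >= g) stop("SNV position out of range")
      # accept both the simulator's ref_base/alt_base and the caller's ref/alt
      refb <- event$ref_base %||% event$ref %||% ""
      altb <- event$alt_base %||% event$alt
      rb <- substr(reference, s + 1, s + 1)
      if (nzchar(refb) && rb != refb)
        stop(sprintf("SNV ref base mismatch at %d: reference has %s, event says %s",
                     s, rb, refb))
      if (rb == altb) stop("SNV ref and alt are identical")
      paste0(substr(reference, 1, s), altb, substr(reference, s + 2, g))
    },
    donor_HDR = {
      if (s < 0 || s + len > g) stop("donor edit footprint out of range")
      paste0(substr(reference, 1, s), as.character(event$inserted),
             substr(reference, s + len + 1, g))
    },
    stop(sprintf("unknown event kind '%s'", kind))
  )
}

# Apply all rows of an event frame to one reference, right-to-left so earlier
# coordinates stay valid. Events must not overlap.
apply_events <- function(reference, events) {
  if (nrow(events) == 0) return(reference)
  events <- events[order(-events$start), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    reference <- apply_event(reference, events[i, ])
  }
  reference
}
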