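# Report surface: background-subtracted category frequencies, per-position
# maps, length distributions, insertion composition, asymmetry, dual-site
# partitioning, normalized SNV frequencies, and coverage.

denominator_calls <- function(mc) mc$calls[mc$calls$covered, , drop = FALSE]

denominator_events <- function(mc) {
  keys <- mc$calls$key[mc$calls$covered]
  mc$events[mc$events$key %in% keys, , drop = FALSE]
}

#' Representative uncut-control background fractions
#'
#' Per-category error floors (insertions 0.47%, deletions 0.3%, SNVs 0.26%)
#' of a representative uncut-control amplicon panel, usable as the
#' subtraction baseline when no matched uncut control is sequenced.
#'
#' @return named numeric vector of fractions.
#' @export
default_background_panel <- function() {
  c(deletion = 0.003, insertion = 0.0047, SNV = 0.0026)
}

#' Measure background category fractions from an uncut-control run
#'
#' @param mc `molecule_calls` from an uncut-control library.
#' @return named fractions (`deletion`, `insertion`, `SNV`).
#' @export
measure_background <- function(mc) {
  cc <- denominator_calls(mc)
  if (nrow(cc) == 0) stop("no molecules in the control denominator")
  c(deletion = mean(cc$has_deletion), insertion = mean(cc$has_insertion),
    SNV = mean(cc$has_snv))
}

#' Library-level condition summary
#'
#' Per-category molecule frequencies (a molecule with at least one event of
#' a category counts once toward that category), total mutant frequency,
#' a-HDR frequency, transversion fraction among confirmed SNV events, and
#' background-subtracted frequencies floored at zero.
#'
#' @param mc `molecule_calls` from [call_molecules()].
#' @param background named per-category background fractions
#'   (`deletion`, `insertion`, `SNV`); default zero.
#' @param counting `"molecule"` (default) or `"event"`: event counting
#'   reports events per denominator molecule instead of molecule fractions.
#' @return a `condition_summary` list.
#' @export
condition_summary <- function(mc, background = c(deletion = 0, insertion = 0,
                                                 SNV = 0),
                              counting = c("molecule", "event")) {
  counting <- match.arg(counting)
  stopifnot(all(c("deletion", "insertion", "SNV") %in% names(background)),
            is_probability(background))
  cc <- denominator_calls(mc)
  n <- nrow(cc)
  if (n == 0) stop("empty call set: no molecules pass window coverage")
  ev <- denominator_events(mc)
  observed <- if (counting == "molecule") {
    c(deletion = mean(cc$has_deletion), insertion = mean(cc$has_insertion),
      SNV = mean(cc$has_snv))
  } else {
    c(deletion = sum(ev$kind == "deletion") / n,
      insertion = sum(ev$kind == "insertion") / n,
      SNV = sum(ev$kind == "SNV") / n)
  }
  snvs <- ev[ev$kind == "SNV", , drop = FALSE]
  tv <- if (nrow(snvs) > 0) mean(is_transversion(snvs$ref, snvs$alt)) else NA_real_
  structure(list(
    n_molecules = n,
    freq_deletion = observed[["deletion"]],
    freq_insertion = observed[["insertion"]],
    freq_SNV = observed[["SNV"]],
    freq_hdr = mean(cc$is_hdr),
    freq_mutant = mean(cc$is_mutant),
    background = background[c("deletion", "insertion", "SNV")],
    subtracted = setNames(pmax(0, observed - background[names(observed)]),
                          names(observed)),
    transversion_fraction = tv,
    counting = counting), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(paste0("<condition_summary> n=%d (%s counting)\n",
                     "  mutant %.4f | del %.4f ins %.4f SNV %.4f hdr %.4f\n",
                     "  subtracted: del %.4f ins %.4f SNV %.4f | transversion %.3f\n"),
              x$n_molecules, x$counting, x$freq_mutant, x$freq_deletion,
              x$freq_insertion, x$freq_SNV, x$freq_hdr,
              x$subtracted[["deletion"]], x$subtracted[["insertion"]],
              x$subtracted[["SNV"]], x$transversion_fraction))
  invisible(x)
}

position_profile_skeleton <- function(window, amplicon, n_covering) {
  pos <- window_positions(window)
  data.frame(position = pos,
             ref = substring(amplicon$sequence, pos + 1L, pos + 1L),
             covering = n_covering, lost = 0L, frac_lost = 0,
             altA = 0L, altC = 0L, altG = 0L, altT = 0L,
             stringsAsFactors = FALSE)
}

#' Per-position fractional base-loss map
#'
#' For each window position, the fraction of denominator molecules whose
#' deletion footprint includes that position (the per-position map of the
#' fractional decrease in base calls).
#'
#' @param mc `molecule_calls`.
#' @param window a [scoring_window()].
#' @param amplicon an [amplicon_spec()].
#' @return a `position_profile` data frame: `position`, `ref`, `covering`,
#'   `lost`, `frac_lost`, `altA`..`altT`.
#' @export
fractional_decrease_map <- function(mc, window, amplicon) {
  cc <- denominator_calls(mc)
  prof <- position_profile_skeleton(window, amplicon, nrow(cc))
  dels <- denominator_events(mc)
  dels <- dels[dels$kind == "deletion", , drop = FALSE]
  if (nrow(dels) > 0) {
    tab <- table(unlist(mapply(function(s, l) seq.int(s, s + l - 1L),
                               dels$start, dels$length, SIMPLIFY = FALSE)))
    hit <- match(as.integer(names(tab)), prof$position)
    ok <- !is.na(hit)
    prof$lost[hit[ok]] <- as.integer(tab)[ok]
  }
  prof$frac_lost <- ifelse(prof$covering > 0, prof$lost / prof$covering, 0)
  class(prof) <- c("position_profile", "data.frame")
  prof
}

#' Per-position SNV spectrum map
#'
#' Counts of each alternative base at each window position among confirmed
#' SNVs, with the reference base identity for spectrum grouping.
#'
#' @inheritParams fractional_decrease_map
#' @return a `position_profile` data frame (see [fractional_decrease_map()]).
#' @export
snv_spectrum_map <- function(mc, window, amplicon) {
  cc <- denominator_calls(mc)
  prof <- position_profile_skeleton(window, amplicon, nrow(cc))
  snvs <- denominator_events(mc)
  snvs <- snvs[snvs$kind == "SNV", , drop = FALSE]
  for (b in c("A", "C", "G", "T")) {
    tab <- table(snvs$start[snvs$alt == b])
    hit <- match(as.integer(names(tab)), prof$position)
    ok <- !is.na(hit)
    prof[[paste0("alt", b)]][hit[ok]] <- as.integer(tab)[ok]
  }
  class(prof) <- c("position_profile", "data.frame")
  prof
}

length_histogram <- function(lengths) {
  fine <- vapply(1:6, function(k) sum(lengths == k), integer(1))
  names(fine) <- 1:6
  maxlen <- if (length(lengths)) max(lengths) else 0L
  nbins <- max(1L, ceiling(maxlen / 10))
  decade <- vapply(seq_len(nbins), function(b)
    sum(lengths > (b - 1L) * 10L & lengths <= b * 10L), integer(1))
  names(decade) <- sprintf("%d-%d", (seq_len(nbins) - 1L) * 10L + 1L,
                           seq_len(nbins) * 10L)
  structure(list(fine = fine, decade = decade, max_length = maxlen,
                 n = length(lengths)), class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> n=%d, max %d\n  1-6 bp: %s\n  decades: %s\n",
              x$n, x$max_length, paste(x$fine, collapse = " "),
              paste(sprintf("%s:%d", names(x$decade), x$decade), collapse = " ")))
  invisible(x)
}

#' Deletion / insertion length distributions
#'
#' Counts keyed by total event length: individual bins for 1-6 bp and decade
#' bins (1-10, 11-20, ...).
#'
#' @param mc `molecule_calls`.
#' @return a `length_histogram` with fields `fine` (1-6), `decade`,
#'   `max_length`, `n`.
#' @export
deletion_length_histogram <- function(mc) {
  ev <- denominator_events(mc)
  length_histogram(ev$length[ev$kind == "deletion"])
}

#' @rdname deletion_length_histogram
#' @export
insertion_length_histogram <- function(mc) {
  ev <- denominator_events(mc)
  length_histogram(nchar(ev$inserted[ev$kind == "insertion"]))
}

#' Composition of 1 bp insertions around the cut
#'
#' Among molecules carrying a single-base insertion whose left-normalized
#' position lies within `span` bases of the cut: (i) counts of the inserted
#' base identity, and (ii) the observed bases at positions -2, -1, +1, +2
#' relative to the nick in the locally edited sequence (positions +1, +2 are
#' the first two bases 3' of the nick after the insertion).
#'
#' @param mc `molecule_calls`.
#' @param site a `target_site`.
#' @param amplicon an [amplicon_spec()].
#' @param span maximum distance of the insertion position from the cut.
#' @return list with `inserted_base` (named counts), `flanks` (data frame of
#'   observed bases per molecule) and `n`.
#' @export
insertion_composition <- function(mc, site, amplicon, span = 2L) {
  ev <- denominator_events(mc)
  ins <- ev[ev$kind == "insertion" & nchar(ev$inserted) == 1L &
              abs(ev$start - site$cut) <= span, , drop = FALSE]
  if (nrow(ins) == 0) {
    return(list(inserted_base = setNames(integer(4), c("A", "C", "G", "T")),
                flanks = data.frame(key = character(0), m2 = character(0),
                                    m1 = character(0), p1 = character(0),
                                    p2 = character(0)),
                n = 0L))
  }
  base_counts <- vapply(c("A", "C", "G", "T"),
                        function(b) sum(ins$inserted == b), integer(1))
  cut <- site$cut
  flanks <- do.call(rbind, lapply(seq_len(nrow(ins)), function(i) {
    local <- apply_event(amplicon$sequence,
                         list(kind = "insertion", start = ins$start[i],
                              length = 1L, inserted = ins$inserted[i]))
    # after a 1 bp insertion at/near the cut, the edited coordinates 3' of
    # the insertion shift by one
    shift <- as.integer(ins$start[i] <= cut)
    data.frame(key = ins$key[i],
               m2 = substr(local, cut - 1L, cut - 1L),
               m1 = substr(local, cut, cut),
               p1 = substr(local, cut + shift, cut + shift),
               p2 = substr(local, cut + shift + 1L, cut + shift + 1L),
               stringsAsFactors = FALSE)
  }))
  list(inserted_base = base_counts, flanks = flanks, n = nrow(ins))
}

#' Asymmetry index of a per-position profile
#'
#' `A = (M3 - M5) / (M3 + M5)` where `M5` and `M3` sum the chosen
#' per-position mass strictly 5' and 3' of the cut bond. `A` is in
#' `[-1, 1]`; by convention 0 (flagged via the `both_empty` attribute) when
#' both sides are empty.
#'
#' @param profile a `position_profile`.
#' @param cut cut coordinate (bond between `cut - 1` and `cut`).
#' @param measure `"lost"` (deletion mass) or `"snv"` (summed alt counts).
#' @return signed fraction with attribute `both_empty`.
#' @export
asymmetry_index <- function(profile, cut, measure = c("lost", "snv")) {
  measure <- match.arg(measure)
  mass <- if (measure == "lost") profile$lost else
    profile$altA + profile$altC + profile$altG + profile$altT
  m5 <- sum(mass[profile$position < cut])
  m3 <- sum(mass[profile$position >= cut])
  if (m5 + m3 == 0) return(structure(0, both_empty = TRUE))
  structure((m3 - m5) / (m3 + m5), both_empty = FALSE)
}

#' Bootstrap confidence interval for the deletion asymmetry index
#'
#' Resamples denominator molecules with replacement and recomputes the
#' asymmetry of the deletion footprint mass around the cut.
#'
#' @param mc `molecule_calls`.
#' @param window a [scoring_window()].
#' @param amplicon an [amplicon_spec()].
#' @param cut cut coordinate.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level (percentile interval).
#' @return list `estimate`, `lower`, `upper`, `n_boot`.
#' @export
asymmetry_bootstrap <- function(mc, window, amplicon, cut,
                                n_boot = 200L, conf = 0.99) {
  cc <- denominator_calls(mc)
  ev <- denominator_events(mc)
  dels <- ev[ev$kind == "deletion", , drop = FALSE]
  # per-molecule 5'/3' deletion-footprint mass, clipped to the window
  m5 <- setNames(numeric(nrow(cc)), cc$key)
  m3 <- m5
  for (i in seq_len(nrow(dels))) {
    posn <- seq.int(dels$start[i], dels$start[i] + dels$length[i] - 1L)
    posn <- posn[posn >= window[["start"]] & posn < window[["end"]]]
    k <- dels$key[i]
    m5[k] <- m5[k] + sum(posn < cut)
    m3[k] <- m3[k] + sum(posn >= cut)
  }
  ratio <- function(s5, s3) if (s5 + s3 == 0) 0 else (s3 - s5) / (s3 + s5)
  est <- ratio(sum(m5), sum(m3))
  n <- nrow(cc)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    ratio(sum(m5[idx]), sum(m3[idx]))
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(estimate = est, lower = qs[1], upper = qs[2], n_boot = n_boot)
}

#' Partition mutant molecules between two target-site windows
#'
#' For dual-site (co-nicking) libraries: assigns each mutant molecule to the
#' window(s) containing its events. Events whose footprint touches both
#' windows count the molecule as `both`.
#'
#' @param mc `molecule_calls` made with a window spanning both sites.
#' @param window_a,window_b two disjoint [scoring_window()]s.
#' @return named counts `c(A_only, B_only, both, neither)` over mutant
#'   molecules.
#' @export
dual_site_partition <- function(mc, window_a, window_b) {
  if (window_a[["start"]] < window_b[["end"]] &&
      window_b[["start"]] < window_a[["end"]])
    stop("dual-site windows must be disjoint")
  cc <- denominator_calls(mc)
  ev <- denominator_events(mc)
  counts <- c(A_only = 0L, B_only = 0L, both = 0L, neither = 0L)
  for (key in cc$key[cc$is_mutant]) {
    evk <- ev[ev$key == key, , drop = FALSE]
    in_a <- any(intersects_window(evk, window_a))
    in_b <- any(intersects_window(evk, window_b))
    lab <- if (in_a && in_b) "both" else if (in_a) "A_only" else
      if (in_b) "B_only" else "neither"
    counts[lab] <- counts[lab] + 1L
  }
  counts
}

#' Normalize an SNV frequency to a reference condition
#'
#' `(max(0, f_condition - b)) / (f_reference - b)`; errors when the
#' reference does not exceed the background.
#'
#' @param f_condition observed SNV frequency in the condition of interest.
#' @param f_reference observed SNV frequency in the normalization condition.
#' @param background_snv background SNV frequency.
#' @return normalized value (>= 0).
#' @export
#' @examples
#' normalize_snv_frequencies(0.02, 0.01, 0.0026)
normalize_snv_frequencies <- function(f_condition, f_reference,
                                      background_snv = 0) {
  stopifnot(is.numeric(f_condition), is.numeric(f_reference),
            is.numeric(background_snv))
  denom <- f_reference - background_snv
  if (denom <= 0) {
    stop("undefined normalization: reference frequency at or below background")
  }
  pmax(0, f_condition - background_snv) / denom
}

#' Sequencing coverage
#'
#' Fold coverage `N * L / G` from the number of aligned consensus reads
#' `N`, the average read length `L` and the amplicon size `G`.
#'
#' @param N aligned consensus read count.
#' @param L average read length (bases).
#' @param G amplicon size (bases).
#' @return fold coverage.
#' @export
#' @examples
#' coverage(120000, 268, 480)
coverage <- function(N, L, G) {
  stopifnot(N > 0, L > 0, G > 0)
  N * L / G
}

#' Round coverage for display
#'
#' @param x fold coverage.
#' @param nearest rounding grain (default 500).
#' @return rounded value.
#' @export
round_coverage <- function(x, nearest = 500) round(x / nearest) * nearest
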