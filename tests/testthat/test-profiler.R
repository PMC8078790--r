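# Report surface: summaries, maps, histograms, composition, asymmetry,
# dual-site partitioning, normalization and coverage.

amp <- default_amplicon()
site <- default_target_site("A")
window <- scoring_window(site, 65, amp)

# molecule_calls built directly from a truth event table (noise-free path)
calls_from_truth <- function(events_list, n_total) {
  n_ev <- length(events_list)
  keys <- sprintf("K%04d-K%04d", seq_len(n_total), seq_len(n_total))
  ev <- do.call(rbind, lapply(seq_len(n_ev), function(i) {
    e <- events_list[[i]]
    data.frame(kind = e$kind, start = e$start, length = e$length %||% 1L,
               inserted = e$inserted %||% "", ref = e$ref %||% "",
               alt = e$alt %||% "", amb_left = e$start, amb_right = e$start,
               key = keys[i], stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) ev <- cbind(nickmut:::empty_mutation_events(),
                               data.frame(key = character(0)))
  has <- function(kind) keys %in% ev$key[ev$kind == kind]
  calls <- data.frame(key = keys, family_size = 3L,
                      m1_covers = TRUE, m2_covers = TRUE, covered = TRUE,
                      discordant = FALSE,
                      is_mutant = keys %in% ev$key,
                      has_deletion = has("deletion"),
                      has_insertion = has("insertion"),
                      has_snv = has("SNV"),
                      is_hdr = FALSE,
                      n_events = as.integer(keys %in% ev$key),
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, events = ev), n_discordant = 0L,
            n_no_coverage = 0L, class = "molecule_calls")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("condition summary counts molecules and floors subtraction at zero", {
  mc <- calls_from_truth(c(
    replicate(7, list(kind = "deletion", start = 158L, length = 3L),
              simplify = FALSE),
    replicate(3, list(kind = "SNV", start = 162L, ref = "G", alt = "T"),
              simplify = FALSE)), 100)
  s <- condition_summary(mc)
  expect_identical(s$n_molecules, 100L)
  expect_equal(s$freq_mutant, 0.10)
  expect_equal(s$freq_deletion, 0.07)
  expect_equal(s$freq_SNV, 0.03)
  expect_equal(unname(s$subtracted["deletion"]), 0.07)
  # floor: observed 0.03 SNV below a 0.26 background reports 0
  s2 <- condition_summary(mc, background = c(deletion = 0, insertion = 0,
                                             SNV = 0.26))
  expect_equal(unname(s2$subtracted["SNV"]), 0)
  # G->T is a transversion
  expect_equal(s$transversion_fraction, 1)
  none_covered <- calls_from_truth(list(), 1)
  none_covered$calls$covered <- FALSE
  expect_error(condition_summary(none_covered), "empty")
})

test_that("event counting reports events, molecule counting reports molecules", {
  # one molecule with two deletions counted once per molecule, twice per event
  ev <- cbind(nickmut:::empty_mutation_events()[0, ],
              data.frame(key = character(0)))
  mc <- calls_from_truth(list(list(kind = "deletion", start = 150L, length = 2L)),
                         10)
  extra <- mc$events[1, ]; extra$start <- 170L
  mc$events <- rbind(mc$events, extra)
  s_mol <- condition_summary(mc, counting = "molecule")
  s_ev <- condition_summary(mc, counting = "event")
  expect_equal(s_mol$freq_deletion, 0.1)
  expect_equal(s_ev$freq_deletion, 0.2)
})

test_that("fractional decrease map localizes deletion footprints", {
  mc0 <- calls_from_truth(list(), 10)
  prof0 <- fractional_decrease_map(mc0, window, amp)
  expect_true(all(prof0$frac_lost == 0))
  expect_identical(nrow(prof0), 65L)

  mc <- calls_from_truth(list(list(kind = "deletion", start = site$cut - 2L,
                                   length = 5L)), 10)
  prof <- fractional_decrease_map(mc, window, amp)
  hot <- prof$position %in% seq(site$cut - 2L, site$cut + 2L)
  expect_true(all(prof$frac_lost[hot] == 0.1))
  expect_true(all(prof$frac_lost[!hot] == 0))
  expect_true(all(prof$covering == 10L))
})

test_that("map mass integrates to deletion frequency times mean length", {
  set.seed(60)
  cfg <- simulation_config(n_molecules = 400, p_mut = 0.4,
                           class_mix = c(deletion = 1, insertion = 0,
                                         SNV = 0, donor_HDR = 0))
  ev <- draw_events(400, cfg, amp, site)
  evl <- lapply(which(ev$kind == "deletion"), function(i)
    list(kind = "deletion", start = ev$start[i], length = ev$length[i]))
  mc <- calls_from_truth(evl, 400)
  prof <- fractional_decrease_map(mc, window, amp)
  dels <- ev[ev$kind == "deletion", ]
  expect_equal(sum(prof$frac_lost),
               (nrow(dels) / 400) * mean(dels$length))
})

test_that("SNV spectrum map places alt-base counts at configured positions", {
  mc0 <- calls_from_truth(list(), 5)
  prof0 <- snv_spectrum_map(mc0, window, amp)
  expect_true(all(prof0$altA + prof0$altC + prof0$altG + prof0$altT == 0))
  mc <- calls_from_truth(list(list(kind = "SNV", start = 150L, ref = "G",
                                   alt = "A")), 5)
  prof <- snv_spectrum_map(mc, window, amp)
  expect_identical(prof$altA[prof$position == 150L], 1L)
  expect_identical(sum(prof$altA + prof$altC + prof$altG + prof$altT), 1L)
  expect_identical(prof$ref[prof$position == 150L],
                   substr(amp$sequence, 151, 151))
})

test_that("length histograms bin 1-6 individually and by decades", {
  mc <- calls_from_truth(list(
    list(kind = "deletion", start = 160L, length = 1L),
    list(kind = "deletion", start = 158L, length = 4L),
    list(kind = "deletion", start = 150L, length = 17L),
    list(kind = "insertion", start = 160L, length = 1L, inserted = "G")), 50)
  dh <- deletion_length_histogram(mc)
  expect_identical(unname(dh$fine[c("1", "4")]), c(1L, 1L))
  expect_identical(unname(dh$decade), c(2L, 1L))
  expect_identical(names(dh$decade), c("1-10", "11-20"))
  expect_identical(dh$max_length, 17L)
  ih <- insertion_length_histogram(mc)
  expect_identical(unname(ih$fine["1"]), 1L)
  expect_identical(ih$n, 1L)
  empty <- deletion_length_histogram(calls_from_truth(list(), 5))
  expect_true(all(empty$fine == 0L))
})

test_that("1 bp deletion fraction follows the configured p_del_1bp", {
  set.seed(61)
  cfg <- simulation_config(n_molecules = 4000, p_mut = 1, p_del_1bp = 0.3,
                           class_mix = c(deletion = 1, insertion = 0,
                                         SNV = 0, donor_HDR = 0))
  ev <- draw_events(4000, cfg, amp, site)
  evl <- lapply(seq_len(nrow(ev)), function(i)
    list(kind = "deletion", start = ev$start[i], length = ev$length[i]))
  dh <- deletion_length_histogram(calls_from_truth(evl, 4000))
  frac1 <- dh$fine[["1"]] / dh$n
  # truncated-geometric draws also produce some 1 bp deletions on top of the
  # forced point mass; the exact rate follows by direct summation
  pmf <- function(q, cap) { p <- q ^ (0:cap); p / sum(p) }
  p5 <- pmf(cfg$del_q5, 10); p3 <- pmf(cfg$del_q3, 25)
  joint <- outer(p5, p3); joint[1, 1] <- 0; joint <- joint / sum(joint)
  p_geom_1 <- joint[1, 2] + joint[2, 1]
  p1 <- 0.3 + 0.7 * p_geom_1
  expect_lt(abs(frac1 - p1), 3 * sqrt(p1 * (1 - p1) / 4000))
})

test_that("insertion composition reports base identity and cut flanks", {
  mc <- calls_from_truth(c(
    replicate(3, list(kind = "insertion", start = site$cut, length = 1L,
                      inserted = "G"), simplify = FALSE),
    list(list(kind = "insertion", start = site$cut, length = 1L,
              inserted = "T"))), 20)
  comp <- insertion_composition(mc, site, amp)
  expect_identical(unname(comp$inserted_base[c("G", "T")]), c(3L, 1L))
  expect_identical(comp$n, 4L)
  # +1G at the T|G cut: -1 base T, +1 base G (the insertion), +2 base G
  g_rows <- comp$flanks[1:3, ]
  expect_true(all(g_rows$m1 == "T"))
  expect_true(all(g_rows$p1 == "G"))
  expect_true(all(g_rows$p2 == "G"))
  empty <- insertion_composition(calls_from_truth(list(), 5), site, amp)
  expect_identical(empty$n, 0L)
})

test_that("asymmetry index is signed, bounded and zero on mirrored profiles", {
  prof <- data.frame(position = 156:165, ref = "A", covering = 10,
                     lost = c(0, 0, 2, 3, 3, 2, 0, 0, 0, 0),
                     frac_lost = 0, altA = 0L, altC = 0L, altG = 0L, altT = 0L)
  # symmetric around the bond at 160: positions 158,159 vs 160,161
  expect_equal(as.numeric(asymmetry_index(prof, 160L)), 0)
  all3 <- prof; all3$lost <- c(0, 0, 0, 0, 0, 1, 2, 1, 0, 0)
  expect_equal(as.numeric(asymmetry_index(all3, 160L)), 1)
  all5 <- prof; all5$lost <- rev(all3$lost)
  expect_equal(as.numeric(asymmetry_index(all5, 161L)), -1)
  zero <- prof; zero$lost <- 0
  a0 <- asymmetry_index(zero, 160L)
  expect_equal(as.numeric(a0), 0)
  expect_true(attr(a0, "both_empty"))
})

test_that("asymmetry reflects and follows the configured deletion caps", {
  draw_profile <- function(ext5, ext3) {
    cfg <- simulation_config(n_molecules = 3000, p_mut = 1, p_del_1bp = 0,
                             del_extent_5 = ext5, del_extent_3 = ext3,
                             snv_zone_5 = ext5, snv_zone_3 = ext3,
                             class_mix = c(deletion = 1, insertion = 0,
                                           SNV = 0, donor_HDR = 0))
    ev <- draw_events(3000, cfg, amp, site)
    evl <- lapply(seq_len(nrow(ev)), function(i)
      list(kind = "deletion", start = ev$start[i], length = ev$length[i]))
    fractional_decrease_map(calls_from_truth(evl, 3000), window, amp)
  }
  set.seed(62)
  a_asym <- as.numeric(asymmetry_index(draw_profile(10, 25), site$cut))
  set.seed(62)
  a_swap <- as.numeric(asymmetry_index(draw_profile(25, 10), site$cut))
  expect_gt(a_asym, 0)
  expect_lt(a_swap, 0)
})

test_that("dual-site partition assigns mutant molecules to site windows", {
  site_b <- default_target_site("B")
  win_a <- scoring_window(site, 24, amp)
  win_b <- scoring_window(site_b, 24, amp)
  expect_error(dual_site_partition(calls_from_truth(list(), 1),
                                   win_a, scoring_window(site, 30, amp)),
               "disjoint")
  mc <- calls_from_truth(list(
    list(kind = "deletion", start = site$cut - 1L, length = 2L),
    list(kind = "SNV", start = site_b$cut + 2L, ref = "A", alt = "C"),
    list(kind = "deletion", start = site_b$cut - 2L, length = 40L)), 10)
  counts <- dual_site_partition(mc, win_a, win_b)
  expect_identical(counts,
                   c(A_only = 1L, B_only = 1L, both = 1L, neither = 0L))
})

test_that("co-editing at two sites stays near the independence product", {
  # independent per-site editing at low p: 'both' fraction ~ p_a * p_b
  set.seed(63)
  n <- 4000; p_a <- 0.05; p_b <- 0.04
  site_b <- default_target_site("B")
  win_a <- scoring_window(site, 24, amp)
  win_b <- scoring_window(site_b, 24, amp)
  ed_a <- runif(n) < p_a
  ed_b <- runif(n) < p_b
  evl <- list(); keyi <- integer(0)
  for (i in seq_len(n)) {
    if (ed_a[i]) { evl <- c(evl, list(list(kind = "deletion",
                                           start = site$cut - 1L, length = 2L)))
                   keyi <- c(keyi, i) }
    if (ed_b[i]) { evl <- c(evl, list(list(kind = "deletion",
                                           start = site_b$cut - 1L, length = 2L)))
                   keyi <- c(keyi, i) }
  }
  # assemble a molecule_calls with per-molecule keys (possibly two events)
  keys <- sprintf("K%05d-K%05d", seq_len(n), seq_len(n))
  ev <- do.call(rbind, lapply(seq_along(evl), function(j) {
    e <- evl[[j]]
    data.frame(kind = e$kind, start = e$start, length = e$length,
               inserted = "", ref = "", alt = "", amb_left = e$start,
               amb_right = e$start, key = keys[keyi[j]],
               stringsAsFactors = FALSE)
  }))
  calls <- data.frame(key = keys, family_size = 3L, m1_covers = TRUE,
                      m2_covers = TRUE, covered = TRUE, discordant = FALSE,
                      is_mutant = keys %in% ev$key, has_deletion = keys %in% ev$key,
                      has_insertion = FALSE, has_snv = FALSE, is_hdr = FALSE,
                      n_events = 0L, stringsAsFactors = FALSE)
  mc <- structure(list(calls = calls, events = ev), n_discordant = 0L,
                  n_no_coverage = 0L, class = "molecule_calls")
  counts <- dual_site_partition(mc, win_a, win_b)
  both_frac <- counts[["both"]] / n
  se <- sqrt(p_a * p_b * (1 - p_a * p_b) / n)
  expect_lt(abs(both_frac - p_a * p_b), 3 * se)
})

test_that("SNV normalization floors, scales and rejects degenerate references", {
  expect_equal(normalize_snv_frequencies(0.01, 0.01, 0), 1)
  expect_equal(normalize_snv_frequencies(0.0026, 0.01, 0.0026), 0)
  expect_error(normalize_snv_frequencies(0.01, 0.002, 0.0026), "undefined")
  # simulated 2x SNV-rate condition against a reference condition
  set.seed(64)
  n <- 6000
  f_ref <- rbinom(1, n, 0.02) / n
  f_cond <- rbinom(1, n, 0.04) / n
  norm <- normalize_snv_frequencies(f_cond, f_ref, 0)
  # delta-method SD of the binomial ratio is ~0.11 here; allow 3 SD
  sd_ratio <- 2 * sqrt(0.04 * 0.96 / (n * 0.04^2) + 0.02 * 0.98 / (n * 0.02^2))
  expect_lt(abs(norm - 2), 3 * sd_ratio)
})

test_that("coverage follows N*L/G and rounds as printed", {
  expect_equal(coverage(120000, 268, 480), 67000)
  expect_equal(coverage(78000, 268, 480), 43550)
  expect_equal(round_coverage(43550), 43500)
  expect_equal(coverage(480, 1, 480), 1)
  expect_error(coverage(0, 268, 480))
})

test_that("reported frequencies stay in [0,1] and subtraction is monotone", {
  set.seed(65)
  mc <- calls_from_truth(replicate(30, list(kind = "deletion", start = 155L,
                                            length = 3L), simplify = FALSE), 200)
  for (bg in c(0, 0.05, 0.2, 0.5)) {
    s <- condition_summary(mc, background = c(deletion = bg, insertion = 0,
                                              SNV = 0))
    expect_true(all(unlist(s[c("freq_deletion", "freq_insertion", "freq_SNV",
                               "freq_mutant", "freq_hdr")]) >= 0))
    expect_true(all(s$subtracted >= 0 & s$subtracted <= 1))
  }
  subs <- vapply(c(0, 0.05, 0.1, 0.14, 0.2),
                 function(bg) condition_summary(
                   mc, c(deletion = bg, insertion = 0, SNV = 0)
                 )$subtracted[["deletion"]], numeric(1))
  expect_true(all(diff(subs) <= 0))
})
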