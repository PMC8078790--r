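# Synthetic-data generator: event drawing, event application, library
# simulation and read rendering.

amp <- default_amplicon()
site <- default_target_site("A")

test_that("apply_event performs exact string surgery", {
  expect_identical(apply_event("ACGTGC", list(kind = "none")), "ACGTGC")
  expect_identical(apply_event("ACGTGC",
                               list(kind = "deletion", start = 2, length = 2)),
                   "ACGC")
  expect_identical(apply_event("ACGTGC",
                               list(kind = "insertion", start = 3, inserted = "TT")),
                   "ACGTTTGC")
  expect_identical(apply_event("ACGTGC",
                               list(kind = "SNV", start = 1, ref_base = "C",
                                    alt_base = "A")),
                   "AAGTGC")
  expect_identical(apply_event("ACGTGC",
                               list(kind = "donor_HDR", start = 1, length = 3,
                                    inserted = "TTT")),
                   "ATTTGC")
  expect_error(apply_event("ACGT", list(kind = "deletion", start = 3, length = 5)),
               "out of range")
  expect_error(apply_event("ACGT", list(kind = "SNV", start = 1, ref_base = "G",
                                        alt_base = "A")),
               "ref base mismatch")
  # length bookkeeping: |out| = |ref| - del + ins
  set.seed(42)
  cfg <- simulation_config(n_molecules = 10, p_mut = 1)
  ev <- draw_events(200, cfg, amp, site)
  for (i in seq_len(nrow(ev))) {
    out <- apply_event(amp$sequence, ev[i, ])
    delta <- switch(ev$kind[i], none = 0, SNV = 0,
                    deletion = -ev$length[i],
                    insertion = nchar(ev$inserted[i]))
    expect_identical(nchar(out), amp$length + as.integer(delta))
  }
})

test_that("p_mut = 0 yields only unedited molecules", {
  set.seed(7)
  cfg <- simulation_config(n_molecules = 100, p_mut = 0)
  mols <- simulate_library(cfg, amp, site)
  expect_identical(nrow(mols), 100L)
  expect_true(all(mols$kind == "none"))
  expect_true(all(mols$derived_sequence == amp$sequence))
})

test_that("+1G insertion events create the TGG cut context", {
  set.seed(8)
  cfg <- simulation_config(n_molecules = 10, p_mut = 1,
                           class_mix = c(deletion = 0, insertion = 1,
                                         SNV = 0, donor_HDR = 0),
                           ins_base = "G")
  mols <- simulate_library(cfg, amp, site)
  expect_true(all(mols$kind == "insertion"))
  expect_true(all(substr(mols$derived_sequence, site$cut, site$cut + 2) == "TGG"))
})

test_that("deletion extents follow the truncated geometric (exact-moment oracle)", {
  set.seed(123)
  cfg <- simulation_config(n_molecules = 10000, p_mut = 1,
                           class_mix = c(deletion = 1, insertion = 0,
                                         SNV = 0, donor_HDR = 0),
                           p_del_1bp = 0, del_q5 = 0.5, del_q3 = 0.5)
  ev <- draw_events(10000, cfg, amp, site)
  l5 <- site$cut - ev$start
  l3 <- ev$start + ev$length - site$cut
  expect_true(all(l5 >= 0 & l5 <= 10))
  expect_true(all(l3 >= 0 & l3 <= 25))
  expect_true(all(l5 + l3 >= 1))
  # the (L5, L3) pair is conditioned on L5 + L3 >= 1; compute conditional
  # moments from the exact independent pmfs by direct summation
  pmf <- function(q, cap) { p <- q ^ (0:cap); p / sum(p) }
  p5 <- pmf(0.5, 10); p3 <- pmf(0.5, 25)
  joint <- outer(p5, p3)
  joint[1, 1] <- 0; joint <- joint / sum(joint)
  mu5 <- sum((0:10) * rowSums(joint))
  mu3 <- sum((0:25) * colSums(joint))
  v5 <- sum(outer((0:10 - mu5)^2, rep(1, 26)) * joint)
  v3 <- sum(outer(rep(1, 11), (0:25 - mu3)^2) * joint)
  expect_lt(abs(mean(l5) - mu5), 3 * sqrt(v5 / length(l5)))
  expect_lt(abs(mean(l3) - mu3), 3 * sqrt(v3 / length(l3)))
})

test_that("mutant counts, class mix and UMI uniqueness behave as configured", {
  set.seed(99)
  cfg <- simulation_config(n_molecules = 10000, p_mut = 0.022)
  mols <- simulate_library(cfg, amp, site)
  n_mut <- sum(mols$kind != "none")
  expect_gte(n_mut, qbinom(0.005, 10000, 0.022))
  expect_lte(n_mut, qbinom(0.995, 10000, 0.022))
  # class proportions: chi-square GOF against the configured mix
  mix <- c(deletion = 0.7, insertion = 0.1, SNV = 0.2)
  obs <- table(factor(mols$kind[mols$kind != "none"], levels = names(mix)))
  gof <- suppressWarnings(chisq.test(obs, p = mix))
  expect_gt(gof$p.value, 0.01)
  # UMI pair collisions: birthday expectation over 4^20 keys is ~1e-5
  keys <- paste(mols$umi_a, mols$umi_b)
  expect_gte(length(unique(keys)), 10000 - 3)
  # alphabet closed under simulation
  expect_true(all(grepl("^[ACGT]+$", mols$derived_sequence)))
})

test_that("SNV zone and transversion fraction are respected", {
  set.seed(4)
  cfg <- simulation_config(n_molecules = 4000, p_mut = 1,
                           class_mix = c(deletion = 0, insertion = 0,
                                         SNV = 1, donor_HDR = 0),
                           transversion_fraction = 0.7)
  ev <- draw_events(4000, cfg, amp, site)
  expect_true(all(ev$start >= site$cut - 10 & ev$start < site$cut + 25))
  expect_true(all(ev$ref_base != ev$alt_base))
  tv <- mean(is_transversion(ev$ref_base, ev$alt_base))
  expect_lt(abs(tv - 0.7), 3 * sqrt(0.7 * 0.3 / 4000))
})

test_that("noiseless reads reconstruct their molecules after trimming", {
  set.seed(21)
  nr <- noiseless_reads(simulation_config(p_mut = 0.5), amp, site, n = 40)
  cfg <- nr$config
  u <- cfg$umi_len
  p1 <- nchar(cfg$fwd_primer); p2 <- nchar(cfg$rev_primer)
  pl <- c(cfg$read_len - u - p1, cfg$read_len - u - p2)
  for (i in seq_len(nrow(nr$reads))) {
    mol <- nr$molecules[nr$molecules$molecule_id == nr$reads$molecule_id[i], ]
    expect_identical(substr(nr$reads$mate1[i], 1, u), mol$umi_a)
    expect_identical(substr(nr$reads$mate1[i], u + 1, u + p1), cfg$fwd_primer)
    pay1 <- substr(nr$reads$mate1[i], u + p1 + 1, nchar(nr$reads$mate1[i]))
    expect_identical(pay1, substr(mol$derived_sequence, 1, pl[1]))
    pay2 <- substr(nr$reads$mate2[i], u + p2 + 1, nchar(nr$reads$mate2[i]))
    g <- nchar(mol$derived_sequence)
    expect_identical(revcomp(pay2), substr(mol$derived_sequence,
                                           max(1, g - pl[2] + 1), g))
  }
})

test_that("sequencing errors hit reads at the configured binomial rate", {
  set.seed(31)
  cfg <- simulation_config(n_molecules = 2000, p_mut = 0, e_pcr = 0,
                           e_seq = 0.001, family_lambda = 0)
  mols <- simulate_library(cfg, amp, site)
  reads <- render_reads(mols, cfg)
  clean <- {
    cfg0 <- simulation_config(n_molecules = 2000, p_mut = 0, e_pcr = 0,
                              e_seq = 0, family_lambda = 0)
    set.seed(31)
    mols0 <- simulate_library(cfg0, amp, site)
    render_reads(mols0, cfg0)
  }
  mm <- mismatch_counts(reads$mate1, clean$mate1)$mismatches +
    mismatch_counts(reads$mate2, clean$mate2)$mismatches
  per_read <- sum(mm) / (2 * nrow(reads))
  expected <- 268 * 0.001
  se <- sqrt(268 * 0.001 * 0.999 / (2 * nrow(reads)))
  expect_lt(abs(per_read - expected), 3 * se)
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- simulation_config(n_molecules = 50, p_mut = 0.3)
  set.seed(5); m1 <- simulate_library(cfg, amp, site); r1 <- render_reads(m1, cfg)
  set.seed(5); m2 <- simulate_library(cfg, amp, site); r2 <- render_reads(m2, cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  g1 <- tempfile(fileext = ".fastq"); g2 <- tempfile(fileext = ".fastq")
  write_fastq_pair(r1, f1, f2)
  write_fastq_pair(r2, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  back <- read_fastq_pair(f1, f2)
  expect_identical(back$mate1, r1$mate1)
  expect_identical(back$mate2, r1$mate2)
})

test_that("donor-HDR molecules carry exactly the donor replacement", {
  donor <- list(start = 150L, end = 153L, replacement = "TTT")
  set.seed(77)
  cfg <- simulation_config(n_molecules = 50, p_mut = 1,
                           class_mix = c(deletion = 0, insertion = 0,
                                         SNV = 0, donor_HDR = 1),
                           donor_edit = donor)
  mols <- simulate_library(cfg, amp, site)
  expected <- apply_event(amp$sequence, list(kind = "donor_HDR", start = 150,
                                             length = 3, inserted = "TTT"))
  expect_true(all(mols$derived_sequence == expected))
})
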