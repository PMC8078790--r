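# Independent oracles and fixture builders used across the suite.

# Plain-R affine-gap semi-global DP (score only): free end gaps on the
# reference, gap of length k costs go + k*ge, N is a zero-reward wildcard.
# Written independently of the package's C++ kernel; used to validate scores.
oracle_semiglobal_score <- function(q, r, match = 2, mismatch = 4,
                                    go = 6, ge = 1) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(rc)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  I <- matrix(NEG, m + 1, n + 1)
  D <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  if (m >= 1) for (i in 2:(m + 1)) I[i, 1] <- -(go + (i - 1) * ge)
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- if (qc[i - 1] == "N" || rc[j - 1] == "N") 0 else
        if (qc[i - 1] == rc[j - 1]) match else -mismatch
      M[i, j] <- max(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]) + s
      I[i, j] <- max(M[i - 1, j] - go - ge, D[i - 1, j] - go - ge,
                     I[i - 1, j] - ge)
      D[i, j] <- max(M[i, j - 1] - go - ge, I[i, j - 1] - go - ge,
                     D[i, j - 1] - ge)
    }
  }
  max(M[m + 1, ], I[m + 1, ], D[m + 1, ])
}

# Exact moments of the truncated geometric P(L = k) ~ q^k on 0..cap,
# by direct summation over the support.
truncgeom_moments <- function(q, cap) {
  k <- 0:cap
  p <- q ^ k / sum(q ^ k)
  mu <- sum(k * p)
  list(mean = mu, var = sum((k - mu)^2 * p))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# A molecules-only library (no reads) for truth-level checks.
tiny_config <- function(...) {
  simulation_config(n_molecules = 200L, ...)
}

# Noise-free read pairs straight from a molecule table (family size 1).
noiseless_reads <- function(cfg, amp, site, n = 50) {
  molcfg <- simulation_config(n_molecules = n, p_mut = cfg$p_mut,
                              e_pcr = 0, e_seq = 0, family_lambda = 0)
  mols <- simulate_library(molcfg, amp, site)
  list(molecules = mols, reads = render_reads(mols, molcfg), config = molcfg)
}

# Run simulate -> consensus -> call in memory with the given configs.
pipeline_calls <- function(cfg, amp, site, window_width = 65,
                           rules = call_rules(), min_family_size = 3) {
  mols <- simulate_library(cfg, amp, site)
  reads <- render_reads(mols, cfg)
  tagged <- extract_umi_pairs(reads, cfg)
  fams <- group_families(tagged$pairs)
  cons <- sscs_consensus(fams, tagged$pairs, min_family_size = min_family_size)
  window <- scoring_window(site, window_width, amp)
  list(molecules = mols,
       consensus = cons,
       window = window,
       mc = call_molecules(cons, amp, window, rules))
}
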