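# Run orchestration: staged pipeline with one RNG stream per stage, a
# manifest, and TSV/JSON outputs. Each stage reads its inputs from the run
# directory, so stages can be run individually or through run_all().

#' Assemble a run configuration
#'
#' Exactly one of `sim` (a [simulation_config()], to generate reads) or
#' `fastq1`/`fastq2` (existing paired FASTQ) must be supplied.
#'
#' @param amplicon an [amplicon_spec()] (default [default_amplicon()]).
#' @param site a `target_site` (default [default_target_site()]).
#' @param sim optional [simulation_config()].
#' @param fastq1,fastq2 optional input FASTQ paths (gzip autodetected).
#' @param background named per-category background fractions subtracted in
#'   the summary (default zero; see [measure_background()] and
#'   [default_background_panel()]).
#' @param window_width scoring window width (default 65).
#' @param min_family_size,consensus_threshold,max_primer_mismatch consensus
#'   thresholds (see [sscs_consensus()], [extract_umi_pairs()]).
#' @param rules a [call_rules()].
#' @param scheme a [scoring_scheme()].
#' @param seed master seed; every stage derives its own RNG stream from it.
#' @return a `run_config` list.
#' @export
run_config <- function(amplicon = default_amplicon(),
                       site = default_target_site("A"),
                       sim = simulation_config(),
                       fastq1 = NULL, fastq2 = NULL,
                       background = c(deletion = 0, insertion = 0, SNV = 0),
                       window_width = 65L,
                       min_family_size = 3L,
                       consensus_threshold = 0.7,
                       max_primer_mismatch = 2L,
                       rules = call_rules(),
                       scheme = scoring_scheme(),
                       seed = 1L) {
  has_sim <- !is.null(sim); has_fq <- !is.null(fastq1) || !is.null(fastq2)
  if (has_sim == has_fq) {
    stop("supply exactly one of `sim` or an input FASTQ pair")
  }
  if (has_fq && (is.null(fastq1) || is.null(fastq2))) {
    stop("both fastq1 and fastq2 are required")
  }
  if (has_sim) check_sim_geometry(sim, amplicon, site, window_width)
  cfg <- list(amplicon = amplicon, site = site, sim = sim,
              fastq1 = fastq1, fastq2 = fastq2,
              background = background, window_width = as.integer(window_width),
              min_family_size = as.integer(min_family_size),
              consensus_threshold = consensus_threshold,
              max_primer_mismatch = as.integer(max_primer_mismatch),
              rules = rules, scheme = scheme, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

config_fingerprint <- function(config) {
  content_hash(paste(deparse(unclass(config)), collapse = ""))
}

run_paths <- function(outdir) {
  list(fastq1 = file.path(outdir, "reads_R1.fastq"),
       fastq2 = file.path(outdir, "reads_R2.fastq"),
       truth = file.path(outdir, "truth.tsv"),
       consensus = file.path(outdir, "consensus.tsv"),
       rejections = file.path(outdir, "rejections.json"),
       calls = file.path(outdir, "calls.tsv"),
       events = file.path(outdir, "events.tsv"),
       profile = file.path(outdir, "profile.tsv"),
       del_hist = file.path(outdir, "deletion_lengths.tsv"),
       ins_hist = file.path(outdir, "insertion_lengths.tsv"),
       summary = file.path(outdir, "summary.json"),
       manifest = file.path(outdir, "manifest.json"))
}

#' Pipeline stages
#'
#' `run_simulate()` writes a simulated FASTQ pair and ground-truth table;
#' `run_consensus()` extracts UMIs and writes the SSCS consensus table;
#' `run_call()` writes per-molecule calls and confirmed events;
#' `run_profile()` writes the summary JSON, per-position profile and length
#' histograms; `run_all()` chains all stages and writes a manifest. All
#' randomness derives from `config$seed` through per-stage streams, so a
#' repeated run is byte-identical.
#'
#' @param config a [run_config()].
#' @param outdir run directory (created if needed).
#' @return each stage returns its main result invisibly; `run_all()` returns
#'   a list with `summary`, `calls`, `consensus` and the manifest.
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$sim)) stop("run_simulate requires a simulation block")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- run_paths(outdir)
  set.seed(stage_seed(config$seed, "simulate"))
  mols <- simulate_library(config$sim, config$amplicon, config$site)
  set.seed(stage_seed(config$seed, "render"))
  reads <- render_reads(mols, config$sim)
  write_truth_tsv(mols, p$truth)
  write_fastq_pair(reads, p$fastq1, p$fastq2, config$sim$phred_char)
  invisible(list(molecules = mols, reads = reads))
}

#' @rdname run_simulate
#' @export
run_consensus <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  p <- run_paths(outdir)
  if (!is.null(config$fastq1)) {
    reads <- read_fastq_pair(config$fastq1, config$fastq2)
  } else {
    if (!file.exists(p$fastq1)) stop("no FASTQ in run directory; run_simulate first")
    reads <- read_fastq_pair(p$fastq1, p$fastq2)
  }
  sim <- config$sim %||% simulation_config()
  tagged <- extract_umi_pairs(reads, sim, config$max_primer_mismatch)
  fams <- group_families(tagged$pairs)
  cons <- sscs_consensus(fams, tagged$pairs, config$min_family_size,
                         config$consensus_threshold)
  write_consensus_tsv(cons, p$consensus)
  stats <- list(read_pairs = nrow(reads),
                accepted_pairs = nrow(tagged$pairs),
                rejected_pairs = as.list(tagged$rejected),
                families = length(fams$keys),
                rejected_families = attr(cons, "rejected_families"),
                consensus_molecules = nrow(cons))
  jsonlite::write_json(stats, p$rejections, auto_unbox = TRUE, pretty = TRUE)
  invisible(cons)
}

#' @rdname run_simulate
#' @export
run_call <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  p <- run_paths(outdir)
  if (!file.exists(p$consensus)) stop("no consensus table; run_consensus first")
  cons <- read_consensus_tsv(p$consensus)
  window <- scoring_window(config$site, config$window_width, config$amplicon)
  mc <- call_molecules(cons, config$amplicon, window, config$rules,
                       config$scheme)
  write_calls_tsv(mc, p$calls, p$events)
  invisible(mc)
}

#' @rdname run_simulate
#' @export
run_profile <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  p <- run_paths(outdir)
  if (!file.exists(p$calls)) stop("no calls; run_call first")
  mc <- read_calls_tsv(p$calls, p$events)
  window <- scoring_window(config$site, config$window_width, config$amplicon)
  summ <- condition_summary(mc, config$background)
  prof <- fractional_decrease_map(mc, window, config$amplicon)
  spec <- snv_spectrum_map(mc, window, config$amplicon)
  prof[, c("altA", "altC", "altG", "altT")] <-
    spec[, c("altA", "altC", "altG", "altT")]
  dh <- deletion_length_histogram(mc)
  ih <- insertion_length_histogram(mc)
  asym <- asymmetry_index(prof, config$site$cut, "lost")

  write.table(prof, p$profile, sep = "\t", quote = FALSE, row.names = FALSE)
  hist_df <- function(h) data.frame(bin = c(names(h$fine), names(h$decade)),
                                    scope = rep(c("single", "decade"),
                                                c(length(h$fine), length(h$decade))),
                                    count = c(unname(h$fine), unname(h$decade)),
                                    n_events = h$n)
  write.table(hist_df(dh), p$del_hist, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(hist_df(ih), p$ins_hist, sep = "\t", quote = FALSE, row.names = FALSE)

  out <- list(
    seed = config$seed,
    n_molecules = summ$n_molecules,
    frequencies = list(mutant = summ$freq_mutant, deletion = summ$freq_deletion,
                       insertion = summ$freq_insertion, SNV = summ$freq_SNV,
                       hdr = summ$freq_hdr),
    background = as.list(summ$background),
    subtracted = as.list(summ$subtracted),
    transversion_fraction = summ$transversion_fraction,
    asymmetry_index = as.numeric(asym),
    window = list(start = unname(window[["start"]]), end = unname(window[["end"]])),
    discordant_excluded = attr(mc, "n_discordant"),
    no_window_coverage = attr(mc, "n_no_coverage"))
  jsonlite::write_json(out, p$summary, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(summary = out, profile = prof, del_hist = dh, ins_hist = ih))
}

#' @rdname run_simulate
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- run_paths(outdir)
  if (!is.null(config$sim)) run_simulate(config, outdir)
  cons <- run_consensus(config, outdir)
  mc <- run_call(config, outdir)
  prof <- run_profile(config, outdir)
  produced <- Filter(file.exists, unlist(p[names(p) != "manifest"]))
  manifest <- list(
    tool = "nickmut",
    version = as.character(packageVersion("nickmut")),
    seed = config$seed,
    config_fingerprint = config_fingerprint(config),
    files = lapply(setNames(basename(produced), names(produced)), identity),
    file_hashes = lapply(setNames(nm = names(produced)),
                         function(k) file_hash(produced[[k]])))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = prof$summary, profile = prof$profile,
                 calls = mc, consensus = cons, manifest = manifest))
}
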