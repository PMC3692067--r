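# End-to-end orchestration: pre-processing (features + profile), baseline
# calibration, Monte Carlo simulation, pooling, clustering and reporting.

#' Run a complete design job
#'
#' Mirrors the three-stage server flow: (i) pre-processing — read and
#' validate the scaffold, reconstruct the backbone if C-alpha only, assign
#' reference features, align the homolog library and build the evolutionary
#' profile; (ii) simulation — calibrate the random-sequence baseline and
#' run the Metropolis trajectories; (iii) clustering and selection — pool
#' the decoys, cluster them and emit ranked design reports.
#'
#' @param scaffold a `protein_structure` or path to a PDB file.
#' @param library list of `protein_structure` objects, a directory of PDB
#'   files, or NULL for self-profile mode (profile from the scaffold
#'   sequence alone).
#' @param config a [design_config()].
#' @param constraints a [design_constraints()].
#' @param out_dir optional output directory; when given, designs (FASTA),
#'   per-design text reports, the summary TSV, the profile and the decoy
#'   archive are written there.
#' @param verbose log one line per stage with wall time (default TRUE).
#' @return a `job_result`: list with `reports` (a `design_report`),
#'   `threshold_used`, `profile`, `features`, `pool_size`, `baseline`,
#'   `binding_site`, and `provenance` (config, seeds, stage timings).
#' @export
run_job <- function(scaffold, library = NULL, config = design_config(),
                    constraints = design_constraints(), out_dir = NULL,
                    verbose = TRUE) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, t0) {
    timings[[name]] <<- tic() - t0
    if (verbose) message(sprintf("[%s] %.1fs", name, timings[[name]]))
  }

  t0 <- tic()
  if (is.character(scaffold)) {
    scaffold <- read_pdb(scaffold, min_len = config$min_len)
  }
  stopifnot(inherits(scaffold, "protein_structure"))
  if (n_residues(scaffold) < config$min_len) {
    stop("scaffold too short: ", n_residues(scaffold), " residues; at least ",
         config$min_len, " are required for a meaningful fold")
  }
  if (is_ca_only(scaffold)) scaffold <- reconstruct_backbone(scaffold)
  feats <- assign_features(scaffold)
  scaffold_seq <- structure_sequence(scaffold)
  log_stage("features", t0)

  t0 <- tic()
  if (is.character(library)) {
    paths <- list.files(library, pattern = "\\.pdb$", full.names = TRUE)
    library <- lapply(paths, read_pdb, min_len = 3L)
  }
  if (is.null(library) || length(library) == 0L) {
    sel <- list(alignments = list(), threshold_used = NA_real_)
  } else {
    sel <- select_homologs(scaffold, library, tm_hi = config$tm_hi,
                           tm_lo = config$tm_lo,
                           min_homologs = config$min_homologs,
                           step = config$tm_step)
  }
  msa <- build_msa(scaffold, sel$alignments)
  profile <- build_profile(msa, pseudocount = config$pseudocount,
                           tm_threshold_used = sel$threshold_used)
  log_stage("profile", t0)

  t0 <- tic()
  model <- if (inherits(config$predictor, "feature_predictor")) {
    config$predictor
  } else {
    propensity_predictor(config$window)
  }
  trajectories <- run_design(feats, profile, config, constraints,
                             model = model, scaffold_seq = scaffold_seq)
  baseline <- attr(trajectories, "baseline")
  log_stage("simulation", t0)

  t0 <- tic()
  pool <- pool_decoys(trajectories, burn_in = config$burn_in)
  clusters <- cluster_decoys(pool, cluster_frac = config$cluster_frac,
                             t_step = config$t_step,
                             subsample_cap = config$subsample_cap,
                             seed = config$seed + 7L)
  bsite <- binding_site_residues(scaffold, radius = config$binding_radius)
  reports <- select_designs(clusters, scaffold_seq, scaffold_feats = feats,
                            model = model, binding_site = bsite)
  log_stage("clustering", t0)

  job <- structure(list(reports = reports, threshold_used = sel$threshold_used,
                        profile = profile, features = feats,
                        pool_size = nrow(pool), baseline = baseline,
                        binding_site = bsite, scaffold_seq = scaffold_seq,
                        provenance = list(config = config,
                                          trajectory_seeds = vapply(
                                            trajectories, `[[`, integer(1), "seed"),
                                          timings = timings)),
                   class = "job_result")
  if (!is.null(out_dir)) {
    write_job_outputs(job, pool, out_dir)
  }
  job
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("job_result: %d designs from %d pooled decoys (TM threshold %s)\n",
              nrow(x$reports), x$pool_size,
              ifelse(is.na(x$threshold_used), "self-profile",
                     sprintf("%.2f", x$threshold_used))))
  print(utils::head(as.data.frame(x$reports)[, c("rank", "design_score",
                                                 "identity_pct", "nre_ss",
                                                 "cluster_size")], 10))
  invisible(x)
}

#' Write the output bundle of a design job
#'
#' Writes ranked designs as multi-FASTA, a per-design alignment-style text
#' report (secondary-structure line, scaffold sequence, identity marks,
#' design sequence), a summary TSV and the profile.
#'
#' @param job a `job_result`.
#' @param pool the `decoy_pool` (archived as gzipped TSV); NULL to skip.
#' @param dir output directory.
#' @export
write_job_outputs <- function(job, pool = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- job$reports
  seqs <- Biostrings::AAStringSet(rep$sequence)
  names(seqs) <- sprintf("design_%d score=%.3f identity=%.1f%%",
                         rep$rank, rep$design_score, rep$identity_pct)
  Biostrings::writeXStringSet(seqs, file.path(dir, "designs.fasta"))
  utils::write.table(as.data.frame(rep)[, setdiff(colnames(rep), "sequence")],
                     file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_profile(job$profile, file.path(dir, "profile.tsv"))
  con <- file(file.path(dir, "designs.txt"), "w")
  ss_line <- paste(job$features$ss, collapse = "")
  sc <- job$scaffold_seq
  if (length(job$binding_site)) {
    writeLines(paste("binding-site residues:",
                     paste(names(job$binding_site), collapse = " ")), con)
  }
  for (r in seq_len(nrow(rep))) {
    ident <- ifelse(strsplit(sc, "")[[1]] == strsplit(rep$sequence[r], "")[[1]],
                    "|", " ")
    writeLines(c(sprintf("> design %d  score %.3f  identity %.1f%%",
                         rep$rank[r], rep$design_score[r], rep$identity_pct[r]),
                 ss_line, sc, paste(ident, collapse = ""), rep$sequence[r], ""),
               con)
  }
  close(con)
  if (!is.null(pool)) write_decoys(pool, file.path(dir, "decoys.tsv.gz"))
  invisible(dir)
}
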