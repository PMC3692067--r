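# Metropolis Monte Carlo search over sequence space, guided by the Z-score
# of the evolutionary energy, with frozen-position and excluded-residue
# constraints, multi-trajectory orchestration and per-sweep decoy records.
#
# One sweep = L attempted single-position substitutions (position uniform
# over mutable positions, proposal uniform over the allowed residues other
# than the current one); the chain state after each sweep is recorded as
# one decoy. Temperature is constant.

#' Design constraints
#'
#' @param frozen integer positions (1-based) kept at the scaffold identity.
#' @param excluded named list mapping position (as character or via names)
#'   to a character vector of forbidden amino acids; no position may
#'   exclude all 20.
#' @return a `design_constraints` object.
#' @export
design_constraints <- function(frozen = integer(0), excluded = list()) {
  frozen <- sort(unique(as.integer(frozen)))
  if (length(excluded)) {
    if (is.null(names(excluded))) stop("excluded must be a named list (names = positions)")
    for (nm in names(excluded)) {
      aa <- excluded[[nm]]
      if (!all(aa %in% AA_ALPHABET)) stop("unknown amino acid in exclusions at ", nm)
      if (length(unique(aa)) >= 20L) {
        stop("position ", nm, " excludes all 20 amino acids")
      }
    }
  }
  structure(list(frozen = frozen, excluded = excluded),
            class = "design_constraints")
}

# 20 x L logical matrix of residues allowed at each position
allowed_matrix <- function(L, constraints, scaffold_seq) {
  allowed <- matrix(TRUE, 20L, L)
  rownames(allowed) <- AA_ALPHABET
  for (nm in names(constraints$excluded)) {
    p <- as.integer(nm)
    if (is.na(p) || p < 1 || p > L) stop("excluded position out of range: ", nm)
    allowed[match(constraints$excluded[[nm]], AA_ALPHABET), p] <- FALSE
  }
  if (length(constraints$frozen)) {
    if (any(constraints$frozen < 1 | constraints$frozen > L)) {
      stop("frozen position out of range")
    }
    idx <- seq_to_int(scaffold_seq)
    for (p in constraints$frozen) {
      allowed[, p] <- FALSE
      allowed[idx[p], p] <- TRUE
    }
  }
  if (any(colSums(allowed) == 0L)) stop("constraints leave no allowed residue")
  allowed
}

#' Random starting sequence under constraints
#'
#' @param L sequence length.
#' @param constraints a [design_constraints] object.
#' @param seed RNG seed.
#' @param scaffold_seq scaffold sequence (required when positions are
#'   frozen).
#' @export
random_start <- function(L, constraints = design_constraints(), seed = 1L,
                         scaffold_seq = NULL) {
  if (length(constraints$frozen) && is.null(scaffold_seq)) {
    stop("frozen positions require the scaffold sequence")
  }
  allowed <- allowed_matrix(L, constraints,
                            scaffold_seq %||% paste(rep("A", L), collapse = ""))
  set.seed(seed)
  paste(vapply(seq_len(L), function(p) {
    opts <- AA_ALPHABET[allowed[, p]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One Metropolis sweep (reference implementation)
#'
#' Pure-R sweep over an arbitrary scoring function; used for custom or
#' physics-augmented scorers and as the readable counterpart of the
#' compiled engine that [run_design()] uses.
#'
#' @param seq current sequence (string).
#' @param z_fn function(sequence) -> Z-score.
#' @param temperature Metropolis temperature.
#' @param constraints a [design_constraints] object.
#' @param scaffold_seq scaffold sequence for frozen positions.
#' @return list with the post-sweep `sequence`, its `z`, and the sweep
#'   `n_accepted`.
#' @export
mc_sweep <- function(seq, z_fn, temperature, constraints = design_constraints(),
                     scaffold_seq = NULL) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  allowed <- allowed_matrix(L, constraints, scaffold_seq %||% seq)
  mutable <- which(!(seq_len(L) %in% constraints$frozen) & colSums(allowed) > 1L)
  if (length(mutable) == 0L) stop("no mutable positions under the given constraints")
  z_cur <- z_fn(paste(chars, collapse = ""))
  acc <- 0L
  for (att in seq_len(L)) {
    p <- mutable[sample.int(length(mutable), 1L)]
    opts <- setdiff(AA_ALPHABET[allowed[, p]], chars[p])
    aa_new <- opts[sample.int(length(opts), 1L)]
    prop <- chars
    prop[p] <- aa_new
    z_new <- z_fn(paste(prop, collapse = ""))
    if (metropolis_accept(z_new - z_cur, temperature, stats::runif(1))) {
      chars <- prop
      z_cur <- z_new
      acc <- acc + 1L
    }
  }
  list(sequence = paste(chars, collapse = ""), z = z_cur, n_accepted = acc)
}

# per-trajectory seeds derived deterministically from the master seed so
# serial and parallel execution agree
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the multi-trajectory Monte Carlo design search
#'
#' Calibrates the random-sequence baseline (unless supplied), then runs
#' `config$n_traj` independent trajectories of `config$n_sweeps` sweeps
#' from different random starting sequences, recording one decoy per sweep.
#'
#' @param scaffold_feats a [scaffold_features] object.
#' @param profile a `design_profile` of matching length.
#' @param config a [design_config] object.
#' @param constraints a [design_constraints] object.
#' @param model a `feature_predictor`; default per `config$predictor`.
#' @param baseline optional precomputed `energy_baseline`.
#' @param scaffold_seq scaffold sequence (needed when positions are frozen).
#' @return list of `trajectory` objects, each with `decoys` (data.frame:
#'   sweep, sequence, z, e_profile, e_ss, e_ta, e_sa), `seed` and
#'   `acceptance_rate`. The baseline used is attached as attribute
#'   `baseline`.
#' @export
run_design <- function(scaffold_feats, profile, config = design_config(),
                       constraints = design_constraints(), model = NULL,
                       baseline = NULL, scaffold_seq = NULL) {
  stopifnot(inherits(scaffold_feats, "scaffold_features"),
            inherits(profile, "design_profile"))
  L <- profile$L
  if (length(scaffold_feats$ss) != L) stop("profile / feature length mismatch")
  if (is.null(model)) {
    model <- if (inherits(config$predictor, "feature_predictor")) {
      config$predictor
    } else {
      propensity_predictor(config$window)
    }
  }
  if (is.null(baseline)) {
    baseline <- calibrate_baseline(function(s) {
      evo_energy(s, profile, scaffold_feats, model = model,
                 term_weights = config$term_weights)$total
    }, L = L, n = config$n_baseline, seed = config$seed + 101L)
  }
  allowed <- allowed_matrix(L, constraints,
                            scaffold_seq %||% paste(rep("A", L), collapse = ""))
  frozen <- seq_len(L) %in% constraints$frozen
  ss_idx <- match(scaffold_feats$ss, SS_STATES) - 1L
  seeds <- derive_seeds(config$seed, config$n_traj)
  trajectories <- vector("list", config$n_traj)
  for (k in seq_len(config$n_traj)) {
    start <- random_start(L, constraints, seed = seeds[k],
                          scaffold_seq = scaffold_seq)
    set.seed(seeds[k])
    out <- run_trajectory_cpp(seq_to_int(start) - 1L, profile$log_odds,
                              ss_idx, scaffold_feats$rsa,
                              scaffold_feats$phi, scaffold_feats$psi,
                              model$cpp, config$term_weights,
                              baseline$mean, baseline$std,
                              config$temperature, config$n_sweeps,
                              frozen, allowed)
    comps <- out$components
    trajectories[[k]] <- structure(list(
      decoys = data.frame(sweep = seq_len(config$n_sweeps),
                          sequence = as.character(out$sequences),
                          z = out$z,
                          e_profile = comps[, 1], e_ss = comps[, 2],
                          e_ta = comps[, 3], e_sa = comps[, 4],
                          stringsAsFactors = FALSE),
      seed = seeds[k],
      acceptance_rate = out$acceptance_rate), class = "trajectory")
  }
  attr(trajectories, "baseline") <- baseline
  attr(trajectories, "model") <- model
  trajectories
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d sweeps, acceptance %.3f, final Z %.3f\n",
              nrow(x$decoys), x$acceptance_rate, x$decoys$z[nrow(x$decoys)]))
  invisible(x)
}

#' Pool decoys across trajectories, discarding the burn-in
#'
#' @param trajectories list of `trajectory` objects from [run_design()].
#' @param burn_in per-trajectory sweeps discarded as close-to-random
#'   (default 1000).
#' @return a `decoy_pool` data.frame with columns trajectory, sweep,
#'   sequence, z. With the defaults (10 trajectories, 30,000 sweeps,
#'   burn-in 1000) the pool holds 290,000 decoys.
#' @export
pool_decoys <- function(trajectories, burn_in = 1000L) {
  n_sweeps <- nrow(trajectories[[1]]$decoys)
  if (burn_in >= n_sweeps) stop("burn_in must be smaller than the sweep count")
  keep <- (burn_in + 1L):n_sweeps
  parts <- lapply(seq_along(trajectories), function(k) {
    d <- trajectories[[k]]$decoys[keep, c("sweep", "sequence", "z")]
    d$trajectory <- k
    d
  })
  pool <- do.call(rbind, parts)
  rownames(pool) <- NULL
  class(pool) <- c("decoy_pool", "data.frame")
  pool
}

#' Write / read a decoy archive (tab-separated, optionally gzipped)
#'
#' @param pool a `decoy_pool`.
#' @param path output path; a ".gz" suffix compresses.
#' @export
write_decoys <- function(pool, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(pool[, c("trajectory", "sweep", "z", "sequence")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decoys
#' @export
read_decoys <- function(path) {
  pool <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(pool) <- c("decoy_pool", "data.frame")
  pool
}
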