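# The four-term evolutionary design energy, the physics-scorer hook, and
# Z-score normalization against a random-sequence baseline.
#
# All terms are per-residue-normalized costs (lower = better):
#   e_profile = -(1/L) sum_j log_odds[j, seq_j]
#   e_ss      =  (1/L) sum_j (1 - ss_prob_j[ss_scaffold_j])
#   e_ta      =  (1/L) sum_j sqrt(dphi_j^2 + dpsi_j^2) / 180  (wrapped,
#                over defined scaffold angles; single-angle termini use
#                |d|/180)
#   e_sa      =  (1/L) sum_j |rsa_pred_j - rsa_scaffold_j|
# The total is a linear combination under `term_weights`. The Monte Carlo
# search is guided by Z = (E - mean)/sd against 1000 random sequences, plus
# an optionally weighted, separately Z-scored physics term.

#' Design run configuration
#'
#' Bundles every tunable of the pipeline with its default value:
#' temperature 0.03, 10 trajectories of 30,000 sweeps with a burn-in of
#' 1000, baselines of 1000 random sequences, TM-score schedule 0.7 -> 0.5,
#' more-than-10 homologs, 40% primary-cluster expansion, 8 A binding-site
#' radius, 30-residue minimum scaffold, physics weight w = -2.44 when a
#' physics scorer is used and 0 otherwise.
#'
#' @param w physics-term weight (use -2.44 with a registered physics
#'   scorer, 0 without).
#' @param temperature Metropolis temperature (Z-score units).
#' @param n_traj,n_sweeps,burn_in trajectory count, sweeps per trajectory,
#'   and per-trajectory burn-in discarded before pooling.
#' @param n_baseline random sequences per baseline calibration.
#' @param tm_hi,tm_lo,min_homologs,tm_step homolog-selection schedule.
#' @param cluster_frac primary-cluster stop fraction.
#' @param t_step distance-threshold expansion step for clustering.
#' @param subsample_cap clustering subsample ceiling.
#' @param binding_radius hetero-atom binding-site radius (Angstrom).
#' @param min_len minimum scaffold length.
#' @param term_weights weights of (profile, ss, ta, sa) terms.
#' @param pseudocount profile pseudocount strength.
#' @param window predictor window length.
#' @param predictor "propensity" or a trained `feature_predictor`.
#' @param seed master RNG seed; all per-stage seeds derive from it.
#' @return a `design_config` list.
#' @export
design_config <- function(w = 0, temperature = 0.03, n_traj = 10L,
                          n_sweeps = 30000L, burn_in = 1000L,
                          n_baseline = 1000L, tm_hi = 0.7, tm_lo = 0.5,
                          min_homologs = 10L, tm_step = 0.05,
                          cluster_frac = 0.4, t_step = 0.25,
                          subsample_cap = 5000L, binding_radius = 8,
                          min_len = 30L, term_weights = c(1, 1, 1, 1),
                          pseudocount = 5, window = 15L,
                          predictor = "propensity", seed = 42L) {
  stopifnot(temperature > 0, cluster_frac > 0, cluster_frac < 1,
            n_sweeps > burn_in, length(term_weights) == 4)
  structure(list(w = w, temperature = temperature, n_traj = as.integer(n_traj),
                 n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
                 n_baseline = as.integer(n_baseline), tm_hi = tm_hi,
                 tm_lo = tm_lo, min_homologs = as.integer(min_homologs),
                 tm_step = tm_step, cluster_frac = cluster_frac,
                 t_step = t_step, subsample_cap = as.integer(subsample_cap),
                 binding_radius = binding_radius, min_len = as.integer(min_len),
                 term_weights = term_weights, pseudocount = pseudocount,
                 window = as.integer(window), predictor = predictor,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Evolutionary energy of a sequence against a scaffold
#'
#' @param seq amino-acid sequence (string or character vector).
#' @param profile a `design_profile`.
#' @param scaffold_feats a [scaffold_features] object.
#' @param pred a `feature_prediction` for `seq` (computed via
#'   [predict_features()] when omitted, in which case `model` is required).
#' @param term_weights weights of (profile, ss, ta, sa).
#' @param model `feature_predictor` used when `pred` is missing.
#' @return list of class `energy_components`: `e_profile`, `e_ss`, `e_ta`,
#'   `e_sa`, and the weighted `total`.
#' @export
evo_energy <- function(seq, profile, scaffold_feats, pred = NULL,
                       term_weights = c(1, 1, 1, 1), model = NULL) {
  idx <- seq_to_int(seq)
  L <- length(idx)
  if (L != profile$L) stop("sequence length ", L, " != profile length ", profile$L)
  if (L != length(scaffold_feats$ss)) {
    stop("sequence length ", L, " != scaffold feature length ",
         length(scaffold_feats$ss))
  }
  if (is.null(pred)) {
    if (is.null(model)) stop("either pred or model must be supplied")
    pred <- predict_features(seq, model)
  }
  e_profile <- -sum(profile$log_odds[cbind(seq_len(L), idx)]) / L
  ss_idx <- match(scaffold_feats$ss, SS_STATES)
  e_ss <- sum(1 - pred$ss_prob[cbind(seq_len(L), ss_idx)]) / L
  dphi <- angle_diff(pred$phi, scaffold_feats$phi)
  dpsi <- angle_diff(pred$psi, scaffold_feats$psi)
  per <- ifelse(!is.na(dphi) & !is.na(dpsi), sqrt(dphi^2 + dpsi^2),
         ifelse(!is.na(dphi), dphi, ifelse(!is.na(dpsi), dpsi, 0))) / 180
  e_ta <- sum(per) / L
  e_sa <- sum(abs(pred$rsa - scaffold_feats$rsa)) / L
  terms <- c(e_profile, e_ss, e_ta, e_sa)
  structure(list(e_profile = e_profile, e_ss = e_ss, e_ta = e_ta, e_sa = e_sa,
                 total = sum(term_weights * terms)),
            class = "energy_components")
}

#' Calibrate a random-sequence energy baseline
#'
#' Draws n i.i.d. uniform-composition random sequences of length L,
#' evaluates `energy_fn` on each, and returns the sample mean and
#' (n-1)-denominator standard deviation used for Z-scoring.
#'
#' @param energy_fn function(sequence string) -> numeric energy.
#' @param L sequence length.
#' @param n number of random sequences (default 1000).
#' @param seed RNG seed (results are deterministic given it).
#' @return an `energy_baseline`: list with `mean`, `std`, `n`, `seed`.
#' @export
calibrate_baseline <- function(energy_fn, L, n = 1000L, seed = 1L) {
  stopifnot(n >= 2, L >= 1)
  set.seed(seed)
  e <- vapply(seq_len(n), function(i) {
    s <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    as.numeric(energy_fn(s))
  }, numeric(1))
  std <- stats::sd(e)
  if (!is.finite(std) || std <= 0) {
    stop("degenerate baseline: all random-sequence energies are equal; ",
         "the profile carries no positional signal")
  }
  structure(list(mean = mean(e), std = std, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "energy_baseline")
}

#' @export
print.energy_baseline <- function(x, ...) {
  cat(sprintf("energy_baseline: mean %.4f, sd %.4f (n = %d, seed %d)\n",
              x$mean, x$std, x$n, x$seed))
  invisible(x)
}

#' Z-score of a decoy energy
#'
#' Z = (E_evo - mean_evo)/sd_evo + w * (E_phys - mean_phys)/sd_phys. The
#' physics term is Z-scored separately so both contributions are
#' dimensionless; it is active only when `w != 0`, which requires a
#' physics baseline and a physics energy. Lower Z = better design.
#'
#' @param e_evo total evolutionary energy (or an `energy_components`).
#' @param base_evo evolutionary `energy_baseline`.
#' @param e_phys physics energy of the same sequence (optional).
#' @param base_phys physics `energy_baseline` (required when `w != 0`).
#' @param w physics weight (-2.44 with physics, 0 without).
#' @export
z_score <- function(e_evo, base_evo, e_phys = NULL, base_phys = NULL, w = 0) {
  if (inherits(e_evo, "energy_components")) e_evo <- e_evo$total
  z <- (e_evo - base_evo$mean) / base_evo$std
  if (w != 0) {
    if (is.null(base_phys) || is.null(e_phys)) {
      stop("physics weighting requested (w != 0) but no physics scorer/",
           "baseline is registered")
    }
    z <- z + w * (e_phys - base_phys$mean) / base_phys$std
  }
  z
}

#' Metropolis acceptance decision
#'
#' Accepts when dZ <= 0, otherwise with probability exp(-dZ/T).
#' @param dz Z-score change of the proposed move.
#' @param temperature Metropolis temperature.
#' @param u uniform random number in (0, 1); drawn internally if missing.
#' @export
metropolis_accept <- function(dz, temperature, u = stats::runif(length(dz))) {
  dz <= 0 | u < exp(-dz / temperature)
}
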