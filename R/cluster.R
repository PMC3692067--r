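# Clustering of the decoy pool under a BLOSUM62-derived sequence distance,
# seed-design extraction and the per-design quality report.
#
# The clustering follows the largest-neighbor-ball scheme of structure-decoy
# clustering: the distance threshold starts at zero and expands in fixed
# steps until the primary cluster (the largest ball of decoys around any
# center) holds at least the target fraction of the pool; the primary
# cluster is then removed and the procedure repeats at the stopping
# threshold for up to 10 clusters.

# per-pair distance table from BLOSUM62:
# d(a, b) = (B(a,a) + B(b,b) - 2 B(a,b)) / 2  -> 0 on identity, symmetric
blosum_dist_table <- function() {
  if (is.null(.pkg_cache$dtab)) {
    B <- blosum62()
    dg <- diag(B)
    .pkg_cache$dtab <- (outer(dg, dg, "+") - 2 * B) / 2
  }
  .pkg_cache$dtab
}

#' BLOSUM62-derived distance between two sequences
#'
#' d(a, b) = (1/L) sum_j (B(a_j, a_j) + B(b_j, b_j) - 2 B(a_j, b_j)) / 2,
#' with B the BLOSUM62 substitution matrix: zero on identical sequences,
#' symmetric and non-negative.
#'
#' @param a,b equal-length amino-acid sequences.
#' @export
seq_distance <- function(a, b) {
  ia <- seq_to_int(a)
  ib <- seq_to_int(b)
  if (length(ia) != length(ib)) stop("sequences differ in length")
  mean(blosum_dist_table()[cbind(ia, ib)])
}

# full pairwise distance matrix over integer-coded sequences
seq_distance_matrix <- function(seqs) {
  mat <- t(vapply(seqs, seq_to_int, integer(nchar(seqs[[1]]))))
  seq_dist_matrix_cpp(mat - 1L, blosum_dist_table())
}

#' Cluster a decoy pool by threshold expansion
#'
#' @param pool a `decoy_pool` from [pool_decoys()] (or any data.frame with
#'   `sequence` and `z` columns).
#' @param cluster_frac stop once the primary cluster holds at least this
#'   fraction of the (sub)pool (default 0.4).
#' @param t_step distance-threshold expansion step (default 0.25).
#' @param max_clusters clusters extracted at the stopping threshold
#'   (default 10).
#' @param subsample_cap pools larger than this are uniformly subsampled
#'   before the all-pairs distance computation (default 5000, seeded).
#' @param seed subsampling seed.
#' @return list of `decoy_cluster` objects ordered by decreasing size; each
#'   has `members` (row indices into the returned attribute `subpool`),
#'   `seed_decoy` (the member of lowest Z), `size` and `threshold_at_stop`.
#' @export
cluster_decoys <- function(pool, cluster_frac = 0.4, t_step = 0.25,
                           max_clusters = 10L, subsample_cap = 5000L,
                           seed = 1L) {
  stopifnot(nrow(pool) >= 1, cluster_frac > 0, cluster_frac < 1)
  sub <- pool
  if (nrow(pool) > subsample_cap) {
    set.seed(seed)
    sub <- pool[sort(sample.int(nrow(pool), subsample_cap)), , drop = FALSE]
    rownames(sub) <- NULL
  }
  n <- nrow(sub)
  D <- seq_distance_matrix(sub$sequence)
  target <- cluster_frac * n
  t <- 0
  repeat {
    counts <- .colSums(D <= t, n, n)
    if (max(counts) >= target) break
    t <- t + t_step
    if (t > max(D) + t_step) break
  }
  clusters <- list()
  remaining <- seq_len(n)
  while (length(remaining) > 0L && length(clusters) < max_clusters) {
    Dr <- D[remaining, remaining, drop = FALSE]
    counts <- .colSums(Dr <= t, length(remaining), length(remaining))
    center <- remaining[which.max(counts)]   # ties: lowest index wins
    members <- remaining[Dr[, which.max(counts)] <= t]
    zs <- sub$z[members]
    ord <- order(zs, sub$sequence[members])
    clusters[[length(clusters) + 1L]] <- structure(list(
      members = members,
      seed_decoy = members[ord[1]],
      size = length(members),
      threshold_at_stop = t), class = "decoy_cluster")
    remaining <- setdiff(remaining, members)
  }
  clusters <- clusters[order(-vapply(clusters, `[[`, integer(1), "size"))]
  attr(clusters, "subpool") <- sub
  attr(clusters, "threshold_at_stop") <- t
  clusters
}

#' @export
print.decoy_cluster <- function(x, ...) {
  cat(sprintf("decoy_cluster: %d members at threshold %.2f\n",
              x$size, x$threshold_at_stop))
  invisible(x)
}

#' Percent sequence identity between two equal-length sequences
#' @param a,b sequences.
#' @export
sequence_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("sequences differ in length")
  100 * mean(ca == cb)
}

#' Rank clusters into design reports
#'
#' Reports are ordered by decreasing cluster size (at most 10); the design
#' sequence of each is its cluster seed (lowest-Z member) and the design
#' score is that seed's Z (lower = more confident; the ranking, not an
#' absolute calibration).
#'
#' @param clusters output of [cluster_decoys()].
#' @param scaffold_seq scaffold sequence for identity/NRE computation.
#' @param scaffold_feats optional [scaffold_features]; enables NRE columns.
#' @param model optional `feature_predictor` for the NRE columns.
#' @param binding_site optional integer positions (e.g. from
#'   [binding_site_residues()]); adds per-residue conservation flags.
#' @return data.frame of class `design_report` with one row per design:
#'   rank, design_score, identity_pct, nre_ss, nre_sa, nre_phi, nre_psi,
#'   cluster_size, sequence; binding-site conservation is attached as the
#'   `binding_conserved` attribute (list of named logical vectors).
#' @export
select_designs <- function(clusters, scaffold_seq, scaffold_feats = NULL,
                           model = NULL, binding_site = integer(0)) {
  stopifnot(length(clusters) >= 1)
  sub <- attr(clusters, "subpool")
  k <- min(length(clusters), 10L)
  rows <- vector("list", k)
  conserved <- vector("list", k)
  for (r in seq_len(k)) {
    cl <- clusters[[r]]
    seq_r <- sub$sequence[cl$seed_decoy]
    nre <- c(nre_ss = NA_real_, nre_sa = NA_real_,
             nre_phi = NA_real_, nre_psi = NA_real_)
    if (!is.null(scaffold_feats) && !is.null(model)) {
      nre <- unlist(compute_nre(seq_r, scaffold_seq, scaffold_feats, model))
    }
    rows[[r]] <- data.frame(
      rank = r, design_score = sub$z[cl$seed_decoy],
      identity_pct = sequence_identity(seq_r, scaffold_seq),
      nre_ss = nre[["nre_ss"]], nre_sa = nre[["nre_sa"]],
      nre_phi = nre[["nre_phi"]], nre_psi = nre[["nre_psi"]],
      cluster_size = cl$size, sequence = seq_r, stringsAsFactors = FALSE)
    if (length(binding_site)) {
      sc <- strsplit(scaffold_seq, "")[[1]]
      dc <- strsplit(seq_r, "")[[1]]
      flags <- dc[binding_site] == sc[binding_site]
      names(flags) <- names(binding_site) %||% as.character(binding_site)
      conserved[[r]] <- flags
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("design_report", "data.frame")
  attr(report, "binding_conserved") <- conserved
  report
}

# NRE = (EDS - ETS)/ETS; undefined (NA), not infinite, when ETS = 0
nre_from_errors <- function(eds, ets) {
  if (!is.finite(ets) || ets == 0) NA_real_ else (eds - ets) / ets
}

# feature-prediction errors of a sequence against the scaffold assignment
prediction_errors <- function(seq, scaffold_feats, model) {
  pred <- predict_features(seq, model)
  ss_idx <- match(scaffold_feats$ss, SS_STATES)
  pred_ss <- apply(pred$ss_prob, 1, which.max)
  dphi <- angle_diff(pred$phi, scaffold_feats$phi)
  dpsi <- angle_diff(pred$psi, scaffold_feats$psi)
  list(ss = mean(pred_ss != ss_idx),
       sa = mean(abs(pred$rsa - scaffold_feats$rsa)),
       phi = mean(dphi, na.rm = TRUE),
       psi = mean(dpsi, na.rm = TRUE))
}

#' Normalized relative error of a design sequence
#'
#' NRE = (EDS - ETS)/ETS per feature, where EDS is the feature-prediction
#' error of the design sequence against the scaffold structure assignment
#' and ETS the error of the scaffold's own sequence. Negative NRE means the
#' design sequence is predicted to match the scaffold structure better than
#' the native sequence. NA when ETS = 0 (undefined, not infinite).
#'
#' @param design_seq,scaffold_seq equal-length sequences.
#' @param scaffold_feats a [scaffold_features] object.
#' @param model a `feature_predictor`.
#' @return list with `nre_ss`, `nre_sa`, `nre_phi`, `nre_psi`.
#' @export
compute_nre <- function(design_seq, scaffold_seq, scaffold_feats, model) {
  if (nchar(design_seq) != nchar(scaffold_seq)) {
    stop("design and scaffold sequences differ in length")
  }
  eds <- prediction_errors(design_seq, scaffold_feats, model)
  ets <- prediction_errors(scaffold_seq, scaffold_feats, model)
  list(nre_ss = nre_from_errors(eds$ss, ets$ss),
       nre_sa = nre_from_errors(eds$sa, ets$sa),
       nre_phi = nre_from_errors(eds$phi, ets$phi),
       nre_psi = nre_from_errors(eds$psi, ets$psi))
}
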