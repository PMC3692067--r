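# Shared fixtures, built once per test run. Everything is generated in
# code under fixed seeds; no files are read from disk.

# idealized 20-residue alpha helix (full backbone)
ideal_helix <- function(L = 20L) {
  bb <- profdesign:::build_backbone_from_torsions(rep(-62, L), rep(-41, L))
  profdesign:::structure_from_backbone(bb, rep("A", L))
}

# CA-only copy of a structure
ca_only_copy <- function(s) {
  a <- s$atoms[s$atoms$elety == "CA", ]
  a$res_idx <- match(a$res_idx, sort(unique(a$res_idx)))
  profdesign:::new_structure(a, het = s$het, chain = s$chain)
}

# rigid-body rotate + translate a structure (for superposition invariance)
transform_structure <- function(s, angles = c(0.4, 1.1, -0.7),
                                shift = c(5, -3, 12)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  het <- s$het
  if (nrow(het)) {
    hx <- as.matrix(het[, c("x", "y", "z")]) %*% t(R)
    het[, c("x", "y", "z")] <- sweep(hx, 2, shift, "+")
  }
  profdesign:::new_structure(a, het = het, chain = s$chain)
}

# small homolog family shared across tests (built lazily, cached)
fixture_env <- new.env()

shared_family <- function() {
  if (is.null(fixture_env$fam)) {
    fixture_env$fam <- make_family(family_spec(n_members = 15,
                                               mutation_rate = 0.2,
                                               topology = "helix_bundle",
                                               length = 40, seed = 11))
  }
  fixture_env$fam
}

shared_profile_setup <- function() {
  if (is.null(fixture_env$setup)) {
    fam <- shared_family()
    feats <- assign_features(fam$scaffold)
    sel <- select_homologs(fam$scaffold, fam$library)
    prof <- build_profile(build_msa(fam$scaffold, sel$alignments),
                          tm_threshold_used = sel$threshold_used)
    fixture_env$setup <- list(fam = fam, feats = feats, sel = sel,
                              prof = prof,
                              seq = structure_sequence(fam$scaffold))
  }
  fixture_env$setup
}

# independent Kabsch superposition (test oracle, written separately from
# the package implementation)
oracle_superpose_rmsd_dists <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- A %*% t(R)
  sqrt(rowSums((fit - B)^2))
}

random_aa_seq <- function(L) {
  paste(sample(profdesign:::AA_ALPHABET, L, replace = TRUE), collapse = "")
}

# toy profile with positional signal
toy_profile <- function(L = 10L, seed = 1L) {
  set.seed(seed)
  lo <- matrix(stats::rnorm(L * 20, 0, 1), L, 20)
  lo <- lo - log(rowSums(exp(lo) * rep(profdesign:::BLOSUM62_BACKGROUND, each = L)))
  structure(list(L = L, log_odds = lo, counts = NULL,
                 background = profdesign:::BLOSUM62_BACKGROUND,
                 n_homologs = 1L, tm_threshold_used = NA_real_),
            class = "design_profile")
}

# one-hot scaffold features + perfectly matching prediction
onehot_fixture <- function(L = 10L) {
  ss <- rep(c("H", "C"), length.out = L)
  phi <- c(NA, rep(-62, L - 1))
  psi <- c(rep(-41, L - 1), NA)
  rsa <- rep(0.5, L)
  feats <- scaffold_features(ss, phi, psi, rsa)
  ssp <- matrix(0, L, 3, dimnames = list(NULL, c("H", "E", "C")))
  ssp[cbind(seq_len(L), match(ss, c("H", "E", "C")))] <- 1
  pred <- structure(list(ss_prob = ssp, rsa = rsa, phi = ifelse(is.na(phi), -62, phi),
                         psi = ifelse(is.na(psi), -41, psi)),
                    class = "feature_prediction")
  list(feats = feats, pred = pred)
}
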