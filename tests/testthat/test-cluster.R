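# BLOSUM62 sequence distance, decoy clustering and design reports

test_that("BLOSUM62 distance is zero on identity and matches hand lookup", {
  set.seed(1)
  for (rep in 1:5) {
    s <- random_aa_seq(12)
    expect_equal(seq_distance(s, s), 0)
  }
  # d(A, W) = (B(A,A) + B(W,W) - 2 B(A,W)) / 2 = (4 + 11 + 6) / 2 = 10.5
  expect_equal(seq_distance("A", "W"), 10.5)
  # symmetry on random pairs
  for (rep in 1:5) {
    a <- random_aa_seq(15); b <- random_aa_seq(15)
    expect_equal(seq_distance(a, b), seq_distance(b, a))
    expect_gte(seq_distance(a, b), 0)
  }
  expect_error(seq_distance("ACD", "AC"), "length")
})

test_that("identical decoys collapse into one cluster at threshold zero", {
  pool <- data.frame(sequence = rep(strrep("ADKL", 5), 40),
                     z = rnorm(40), stringsAsFactors = FALSE)
  cl <- cluster_decoys(pool)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 40L)
  expect_equal(cl[[1]]$threshold_at_stop, 0)
})

test_that("a 60/40 two-family pool resolves into its families", {
  s1 <- strrep("AAAAKKKKLLLL", 2)
  s2 <- strrep("WWWWPPPPGGGG", 2)
  pool <- data.frame(sequence = c(rep(s1, 60), rep(s2, 40)),
                     z = c(rnorm(60, 1), rnorm(60 + 40, 0)[61:100]),
                     stringsAsFactors = FALSE)
  cl <- cluster_decoys(pool)
  expect_equal(cl[[1]]$size, 60L)
  expect_equal(cl[[2]]$size, 40L)
  sub <- attr(cl, "subpool")
  expect_identical(sub$sequence[cl[[1]]$seed_decoy], s1)
  # the cluster seed is its lowest-Z member
  expect_equal(sub$z[cl[[1]]$seed_decoy], min(sub$z[cl[[1]]$members]))
})

test_that("membership matches the brute-force neighbor-count oracle", {
  set.seed(13)
  base <- vapply(1:3, function(i) random_aa_seq(18), character(1))
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(profdesign:::AA_ALPHABET, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- unlist(lapply(c(200, 120, 80), function(n) {
    i <- which(c(200, 120, 80) == n)
    vapply(seq_len(n), function(j) mutate(base[i], 2), character(1))
  }))
  pool <- data.frame(sequence = seqs, z = rnorm(length(seqs)),
                     stringsAsFactors = FALSE)
  cl <- cluster_decoys(pool, cluster_frac = 0.4, t_step = 0.25)
  t_stop <- attr(cl, "threshold_at_stop")
  # O(n^2) oracle: distances by direct double loop over seq_distance
  n <- nrow(pool)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- seq_distance(pool$sequence[i], pool$sequence[j])
  }
  counts <- rowSums(D <= t_stop)
  center <- which.max(counts)
  expect_equal(sort(cl[[1]]$members), sort(which(D[center, ] <= t_stop)))
  expect_gte(cl[[1]]$size, 0.4 * n)
})

test_that("clusters are disjoint and sizes are pool-bounded", {
  setup <- shared_profile_setup()
  cfg <- design_config(n_traj = 2, n_sweeps = 150, burn_in = 30, seed = 17)
  tr <- run_design(setup$feats, setup$prof, cfg, scaffold_seq = setup$seq)
  pool <- pool_decoys(tr, 30)
  cl <- cluster_decoys(pool)
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  expect_lte(length(members), nrow(attr(cl, "subpool")))
  sizes <- vapply(cl, `[[`, integer(1), "size")
  expect_true(all(diff(sizes) <= 0))
})

test_that("shuffling the pool changes no cluster sizes", {
  set.seed(23)
  seqs <- c(rep(strrep("ILVY", 4), 50), rep(strrep("GSNP", 4), 30),
            rep(strrep("KRDE", 4), 20))
  z <- rnorm(100)
  pool <- data.frame(sequence = seqs, z = z, stringsAsFactors = FALSE)
  perm <- sample(100)
  pool_shuf <- pool[perm, ]
  sizes <- function(p) sort(vapply(cluster_decoys(p), `[[`, integer(1), "size"))
  expect_identical(sizes(pool), sizes(pool_shuf))
})

test_that("reports are ranked by cluster size and capped at 10", {
  # 12 singleton families of mutually distant sequences
  set.seed(5)
  fams <- vapply(1:12, function(i) random_aa_seq(30), character(1))
  counts <- c(40, 35, 30, 25, 20, 15, 12, 10, 8, 6, 4, 2)
  pool <- data.frame(sequence = rep(fams, counts),
                     z = rnorm(sum(counts)), stringsAsFactors = FALSE)
  cl <- cluster_decoys(pool, cluster_frac = 0.15)
  rep10 <- select_designs(cl, scaffold_seq = random_aa_seq(30))
  expect_lte(nrow(rep10), 10L)
  expect_identical(rep10$rank, seq_len(nrow(rep10)))
  expect_true(all(diff(rep10$cluster_size) <= 0))
  one <- cluster_decoys(data.frame(sequence = rep(fams[1], 5), z = rnorm(5)))
  expect_equal(nrow(select_designs(one, fams[1])), 1L)
})

test_that("NRE is zero for the scaffold sequence and tracks the formula", {
  expect_equal(profdesign:::nre_from_errors(2, 1), 1.0)
  expect_equal(profdesign:::nre_from_errors(0.5, 1), -0.5)
  expect_true(is.na(profdesign:::nre_from_errors(1, 0)))

  setup <- shared_profile_setup()
  m <- propensity_predictor()
  nre_self <- compute_nre(setup$seq, setup$seq, setup$feats, m)
  expect_equal(nre_self$nre_ss, 0)
  expect_equal(nre_self$nre_sa, 0)
  expect_equal(nre_self$nre_phi, 0)
  expect_equal(nre_self$nre_psi, 0)
  # NRE of an arbitrary design equals the error-ratio definition
  design <- random_aa_seq(40)
  eds <- profdesign:::prediction_errors(design, setup$feats, m)
  ets <- profdesign:::prediction_errors(setup$seq, setup$feats, m)
  nre <- compute_nre(design, setup$seq, setup$feats, m)
  expect_equal(nre$nre_sa, (eds$sa - ets$sa) / ets$sa)
  expect_error(compute_nre("ACD", setup$seq, setup$feats, m), "length")
})

test_that("a profile-consistent design can out-predict the scaffold sequence", {
  # scaffold sequence scrambled away from helix preference; the helix-rich
  # design should match the (helical) scaffold assignment better
  s <- ideal_helix(30)
  feats <- assign_features(s)
  m <- propensity_predictor()
  helix_lover <- strrep("A", 30)
  sheet_lover <- strrep("V", 30)
  nre <- compute_nre(helix_lover, sheet_lover, feats, m)
  expect_lt(nre$nre_ss, 0)
})
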