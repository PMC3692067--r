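# Structural alignment, homolog selection and profile construction

test_that("self-alignment gives TM-score 1 over all positions", {
  s <- make_ideal_structure("mixed", 40, seed = 5)
  a <- tm_align(s, s)
  expect_equal(a$tm_score, 1.0, tolerance = 1e-6)
  expect_equal(nrow(a$pairs), 40L)
  expect_equal(a$rmsd_aligned, 0, tolerance = 1e-6)
})

test_that("TM-score formula gives exactly 0.5 when every distance equals d0", {
  for (L in c(30L, 52L, 120L)) {
    expect_identical(tm_score(rep(tm_d0(L), L), L), 0.5)
  }
  expect_equal(tm_d0(15), 0.5)  # clamp floor
})

test_that("noisy copies score higher than unrelated folds", {
  fam <- shared_family()
  noisy_tm <- tm_align(fam$scaffold, fam$library[[1]])$tm_score
  other <- make_ideal_structure("beta_hairpin", 40, seed = 99)
  expect_gt(noisy_tm, tm_align(fam$scaffold, other)$tm_score)
})

test_that("reported TM-score matches the superposition oracle on small toys", {
  # toys where the full pair set is the alignment: the reported score must
  # equal the TM formula under an independently computed Kabsch fit
  for (seed in 1:3) {
    set.seed(seed)
    X <- cbind(cumsum(runif(8, 3.6, 3.9)), rnorm(8, 0, 0.8), rnorm(8, 0, 0.8))
    Y <- X + matrix(rnorm(24, 0, 0.15), ncol = 3)
    sX <- profdesign:::structure_from_backbone(list(CA = X), rep("A", 8))
    sY <- profdesign:::structure_from_backbone(list(CA = Y), rep("A", 8))
    a <- tm_align(sX, sY)
    expect_equal(nrow(a$pairs), 8L)
    d <- oracle_superpose_rmsd_dists(X[a$pairs[, 1], ], Y[a$pairs[, 2], ])
    expect_equal(a$tm_score, tm_score(d, 8), tolerance = 1e-6)
  }
})

test_that("threshold relaxation stops high when homologs are plentiful", {
  setup <- shared_profile_setup()
  expect_equal(setup$sel$threshold_used, 0.7)
  expect_gt(length(setup$sel$alignments), 10)
})

test_that("threshold relaxes to the floor when nothing aligns", {
  fam <- shared_family()
  strangers <- lapply(1:3, function(i)
    make_ideal_structure("beta_hairpin", 40, seed = 100 + i))
  sel <- select_homologs(fam$scaffold, strangers)
  expect_equal(sel$threshold_used, 0.5)
  expect_length(sel$alignments, 0L)
  # degenerate single-threshold schedule
  sel2 <- select_homologs(fam$scaffold, fam$library, tm_hi = 0.6, tm_lo = 0.6)
  expect_equal(sel2$threshold_used, 0.6)
  expect_error(select_homologs(fam$scaffold, list()), "self-profile")
})

test_that("accepted homolog count is monotone in the threshold floor", {
  fam <- make_family(family_spec(n_members = 8, coordinate_noise = 1.2,
                                 mutation_rate = 0.2, length = 40, seed = 21))
  n_at <- function(lo) length(select_homologs(fam$scaffold, fam$library,
                                              tm_hi = 0.7, tm_lo = lo,
                                              min_homologs = 100L)$alignments)
  counts <- vapply(c(0.7, 0.65, 0.6, 0.55, 0.5), n_at, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("master-slave MSA maps homolog residues onto scaffold columns", {
  s <- make_ideal_structure("mixed", 40, seed = 5)
  self_aln <- tm_align(s, s)
  msa <- build_msa(s, list(self_aln))
  expect_identical(msa[1, ], msa[2, ])

  # partial alignment: only the first 10 positions mapped
  part <- self_aln
  part$pairs <- part$pairs[1:10, ]
  msa2 <- build_msa(s, list(part))
  expect_identical(msa2[2, 1:10], residue_letters(s)[1:10])
  expect_true(all(msa2[2, 11:40] == "-"))

  # hand-built alignments against a 6-residue toy scaffold
  toy_sc <- c("A", "C", "D", "E", "F", "G")
  a1 <- structure(list(pairs = cbind(1:6, 1:6),
                       homolog_seq = c("A", "C", "D", "E", "F", "G")),
                  class = "struct_alignment")
  a2 <- structure(list(pairs = cbind(c(2, 3, 5), c(1, 2, 3)),
                       homolog_seq = c("W", "Y", "V")),
                  class = "struct_alignment")
  a3 <- structure(list(pairs = cbind(c(1, 6), c(2, 3)),
                       homolog_seq = c("K", "L", "M")),
                  class = "struct_alignment")
  msa3 <- build_msa(toy_sc, list(a1, a2, a3))
  expect_identical(unname(msa3[3, ]), c("-", "W", "Y", "-", "V", "-"))
  expect_identical(unname(msa3[4, ]), c("L", "-", "-", "-", "-", "M"))
})

test_that("profile log-odds match a brute-force recomputation", {
  msa <- rbind(c("A", "C", "D"), c("A", "C", "E"))
  beta <- 5
  prof <- build_profile(msa, pseudocount = beta)
  # independent recomputation: Henikoff weights then diversity pseudocounts
  AA <- profdesign:::AA_ALPHABET
  bg <- profdesign:::BLOSUM62_BACKGROUND[AA]
  n <- nrow(msa)
  w <- numeric(n)
  for (j in seq_len(ncol(msa))) {
    syms <- msa[, j]
    r <- length(unique(syms))
    for (k in seq_len(n)) w[k] <- w[k] + 1 / (r * sum(syms == syms[k]))
  }
  w <- w / sum(w)
  for (j in seq_len(ncol(msa))) {
    f <- vapply(AA, function(a) sum(w[msa[, j] == a]), numeric(1))
    f <- f / sum(f)
    n_eff <- length(unique(msa[, j]))
    p <- (n_eff * f + beta * bg) / (n_eff + beta)
    expect_equal(unname(prof$log_odds[j, ]), unname(log(p / bg)),
                 tolerance = 1e-12)
  }
})

test_that("profile columns renormalize and dominance picks the majority", {
  setup <- shared_profile_setup()
  prof <- setup$prof
  bg <- prof$background
  for (j in seq_len(prof$L)) {
    expect_equal(sum(exp(prof$log_odds[j, ]) * bg), 1, tolerance = 1e-9)
  }
  # a column observing only alanine must argmax at A
  msa <- matrix("A", nrow = 12, ncol = 1)
  p1 <- build_profile(msa)
  expect_identical(names(which.max(p1$log_odds[1, ])), "A")
  expect_error(build_profile(msa, pseudocount = 0), "pseudocount")
})

test_that("duplicating a homolog row barely moves the profile", {
  setup <- shared_profile_setup()
  msa <- build_msa(setup$fam$scaffold, setup$sel$alignments)
  p1 <- build_profile(msa)
  p2 <- build_profile(rbind(msa, msa[2, , drop = FALSE]))
  expect_lt(max(abs(p1$log_odds - p2$log_odds)), 0.05)
})

test_that("profile text export round-trips the log-odds", {
  setup <- shared_profile_setup()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(setup$prof, path)
  p2 <- read_profile(path)
  expect_equal(p2$log_odds, setup$prof$log_odds, tolerance = 1e-5)
})
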