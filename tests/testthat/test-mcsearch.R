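# Metropolis Monte Carlo search: constraints, kernel behavior, pooling

test_that("random starts honor constraints and differ across seeds", {
  scaffold_seq <- strrep("ACDEFGHIKL", 4)
  all_frozen <- design_constraints(frozen = 1:40)
  expect_identical(random_start(40, all_frozen, seed = 1,
                                scaffold_seq = scaffold_seq), scaffold_seq)
  s1 <- random_start(50, seed = 1)
  s2 <- random_start(50, seed = 2)
  expect_false(identical(s1, s2))
  # 19 exclusions force the single remaining residue
  excl <- design_constraints(excluded = list(
    `3` = setdiff(profdesign:::AA_ALPHABET, "W")))
  for (seed in 1:5) {
    expect_identical(substr(random_start(10, excl, seed = seed), 3, 3), "W")
  }
  expect_error(design_constraints(excluded = list(`1` = profdesign:::AA_ALPHABET)),
               "excludes all 20")
})

test_that("zero-cost proposals are always accepted", {
  expect_true(all(metropolis_accept(rep(0, 100), 0.03)))
  expect_true(all(metropolis_accept(c(-5, -0.1, 0), 0.03)))
})

test_that("a flat landscape accepts every move", {
  fx <- onehot_fixture(10)
  prof <- toy_profile(10)
  prof$log_odds[] <- 0        # flat profile
  flat_feats <- fx$feats
  m <- propensity_predictor()
  # flat total: zero out all feature terms via term weights
  cfg <- design_config(n_traj = 1, n_sweeps = 50, burn_in = 10,
                       term_weights = c(1, 0, 0, 0), seed = 3)
  bl <- structure(list(mean = 0, std = 1, n = 1000L, seed = 1L),
                  class = "energy_baseline")
  tr <- run_design(flat_feats, prof, cfg, model = m, baseline = bl)
  expect_equal(tr[[1]]$acceptance_rate, 1.0)
})

test_that("decoy pool arithmetic follows n_traj x (n_sweeps - burn_in)", {
  setup <- shared_profile_setup()
  cfg <- design_config(n_traj = 2, n_sweeps = 100, burn_in = 0, seed = 5)
  tr <- run_design(setup$feats, setup$prof, cfg, scaffold_seq = setup$seq)
  expect_equal(nrow(pool_decoys(tr, 0)), 200L)
  expect_equal(nrow(pool_decoys(tr, 99)), 2L)      # boundary burn-in
  expect_error(pool_decoys(tr, 100), "burn_in")
  one <- tr[1]
  expect_equal(nrow(pool_decoys(one, 0)), 100L)
})

test_that("trajectories are deterministic and make downhill progress", {
  setup <- shared_profile_setup()
  cfg <- design_config(n_traj = 2, n_sweeps = 100, burn_in = 10, seed = 42)
  t1 <- run_design(setup$feats, setup$prof, cfg, scaffold_seq = setup$seq)
  t2 <- run_design(setup$feats, setup$prof, cfg, scaffold_seq = setup$seq)
  expect_identical(t1[[1]]$decoys, t2[[1]]$decoys)
  expect_identical(t1[[2]]$decoys, t2[[2]]$decoys)
  d <- t1[[1]]$decoys
  expect_lt(mean(d$z[91:100]), mean(d$z[1:10]))
  # recorded Z agrees with the R-side energy route
  bl <- attr(t1, "baseline")
  e <- evo_energy(d$sequence[100], setup$prof, setup$feats,
                  model = attr(t1, "model"))
  expect_equal(d$z[100], (e$total - bl$mean) / bl$std, tolerance = 1e-9)
})

test_that("frozen and excluded constraints hold in every decoy", {
  setup <- shared_profile_setup()
  frozen <- c(1L, 7L, 20L)
  banned <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  cons <- design_constraints(frozen = frozen,
                             excluded = list(`5` = banned))
  cfg <- design_config(n_traj = 2, n_sweeps = 60, burn_in = 0, seed = 9)
  tr <- run_design(setup$feats, setup$prof, cfg, constraints = cons,
                   scaffold_seq = setup$seq)
  sc <- strsplit(setup$seq, "")[[1]]
  for (t in tr) {
    mat <- do.call(rbind, strsplit(t$decoys$sequence, ""))
    for (p in frozen) expect_true(all(mat[, p] == sc[p]))
    expect_false(any(mat[, 5] %in% banned))
  }
})

test_that("acceptance rate rises with temperature on the same landscape", {
  setup <- shared_profile_setup()
  rate_at <- function(temp) {
    cfg <- design_config(n_traj = 1, n_sweeps = 150, burn_in = 0,
                         temperature = temp, seed = 11)
    run_design(setup$feats, setup$prof, cfg,
               scaffold_seq = setup$seq)[[1]]$acceptance_rate
  }
  expect_gte(rate_at(0.3), rate_at(0.03))
})

test_that("the reference R sweep respects the Metropolis rule", {
  # deterministic downhill move on a 1D landscape counting "A" residues
  z_fn <- function(s) -lengths(regmatches(s, gregexpr("A", s)))
  set.seed(2)
  out <- mc_sweep(strrep("C", 10), z_fn, temperature = 1e-6)
  expect_gte(out$n_accepted, 1)
  expect_lte(out$z, z_fn(strrep("C", 10)))
})

test_that("decoy archives round-trip through the TSV format", {
  setup <- shared_profile_setup()
  cfg <- design_config(n_traj = 1, n_sweeps = 30, burn_in = 0, seed = 2)
  tr <- run_design(setup$feats, setup$prof, cfg, scaffold_seq = setup$seq)
  pool <- pool_decoys(tr, 5)
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_decoys(pool, path)
  p2 <- read_decoys(path)
  expect_equal(p2$sequence, pool$sequence)
  expect_equal(p2$z, pool$z, tolerance = 1e-12)
})
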