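# Deterministic generators of synthetic structures, structure families and
# predictor training data. These emulate the study conditions at desk
# scale: idealized backbones built from canonical torsions, families
# derived from a scaffold by coordinate jitter and sequence mutation, with
# the generating per-position residue distribution returned as ground
# truth for profile-recovery checks.

TOPOLOGIES <- c("helix_bundle", "beta_hairpin", "mixed")

# residue pools biased by local state, used to give synthetic chains a
# learnable sequence-structure relationship
SEGMENT_POOLS <- list(
  H = c("A", "E", "L", "K", "M", "Q", "R"),
  E = c("V", "I", "Y", "T", "F", "W", "C"),
  C = c("G", "S", "P", "N", "D", "H")
)

# per-topology segment plan: list of (state, length share)
segment_plan <- function(topology, length) {
  plan <- switch(topology,
    helix_bundle = list(c("H", 0.42), c("C", 0.08), c("H", 0.42), c("C", 0.08)),
    beta_hairpin = list(c("E", 0.40), c("C", 0.20), c("E", 0.40)),
    mixed = list(c("H", 0.30), c("C", 0.10), c("E", 0.22),
                 c("C", 0.10), c("H", 0.28)),
    stop("unknown topology: ", topology, "; use one of ",
         paste(TOPOLOGIES, collapse = ", ")))
  states <- vapply(plan, `[`, character(1), 1)
  shares <- as.numeric(vapply(plan, `[`, character(1), 2))
  lens <- floor(shares * length)
  lens[length(lens)] <- lens[length(lens)] + (length - sum(lens))
  rep(states, lens)
}

#' Build an idealized synthetic structure
#'
#' Constructs a full-backbone structure from canonical phi/psi torsions for
#' the requested topology (helix -62/-41, strand -140/135, loops near
#' -75/150 with slight jitter), with a topology-biased random sequence.
#' Deterministic for a given seed.
#'
#' @param topology one of "helix_bundle", "beta_hairpin", "mixed".
#' @param length chain length (>= 30).
#' @param seed RNG seed.
#' @param torsion_jitter sd (degrees) of Gaussian jitter on torsions
#'   (default 4).
#' @param min_len smallest accepted chain (default 30).
#' @return a `protein_structure` with attribute `plan` (the per-residue
#'   generating state).
#' @export
make_ideal_structure <- function(topology, length, seed = 1L,
                                 torsion_jitter = 4, min_len = 30L) {
  if (length < min_len) {
    stop("length ", length, " below the minimum scaffold size ", min_len)
  }
  plan <- segment_plan(topology, length)
  set.seed(seed)
  tor <- cbind(phi = numeric(length), psi = numeric(length))
  tor[plan == "H", ] <- rep(SS_BIN_CENTERS["H", ], each = sum(plan == "H"))
  tor[plan == "E", 1] <- -140
  tor[plan == "E", 2] <- 135
  tor[plan == "C", ] <- rep(SS_BIN_CENTERS["C", ], each = sum(plan == "C"))
  tor <- tor + matrix(stats::rnorm(2 * length, 0, torsion_jitter), ncol = 2)
  bb <- build_backbone_from_torsions(tor[, 1], tor[, 2])
  seqs <- vapply(plan, function(st) sample(SEGMENT_POOLS[[st]], 1L), character(1))
  s <- structure_from_backbone(bb, seqs)
  attr(s, "plan") <- plan
  s
}

#' Family specification for synthetic homolog libraries
#'
#' @param n_members library size.
#' @param coordinate_noise per-atom Gaussian jitter sd (Angstrom).
#' @param mutation_rate per-position substitution probability.
#' @param topology structure topology (see [make_ideal_structure()]).
#' @param length chain length (>= 30).
#' @param seed RNG seed.
#' @export
family_spec <- function(n_members = 15L, coordinate_noise = 0.5,
                        mutation_rate = 0.1, topology = "helix_bundle",
                        length = 40L, seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, coordinate_noise >= 0,
            length >= 30)
  structure(list(n_members = as.integer(n_members),
                 coordinate_noise = coordinate_noise,
                 mutation_rate = mutation_rate, topology = topology,
                 length = as.integer(length), seed = as.integer(seed)),
            class = "family_spec")
}

jitter_structure <- function(s, sd) {
  if (sd <= 0) return(s)
  a <- s$atoms
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(a), 0, sd), ncol = 3)
  new_structure(a, het = s$het, chain = s$chain)
}

mutate_sequence <- function(aa, rate) {
  hit <- stats::runif(length(aa)) < rate
  for (p in which(hit)) {
    aa[p] <- sample(setdiff(AA_ALPHABET, aa[p]), 1L)
  }
  aa
}

#' Generate a synthetic scaffold + homolog family
#'
#' Members are copies of the scaffold with seeded per-atom coordinate
#' jitter and per-position sequence mutations (uniform over the 19
#' alternatives). The generating per-position residue distribution,
#' (1 - m) on the scaffold residue and m/19 elsewhere, is returned as
#' `true_profile` so profile-recovery tests have ground truth.
#'
#' @param spec a [family_spec()].
#' @return list with `scaffold` (a `protein_structure`), `library` (list of
#'   members), and `true_profile` (L x 20 probability matrix).
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  scaffold <- make_ideal_structure(spec$topology, spec$length, seed = spec$seed)
  set.seed(spec$seed + 1L)
  members <- vector("list", spec$n_members)
  for (k in seq_len(spec$n_members)) {
    m <- jitter_structure(scaffold, spec$coordinate_noise)
    aa <- mutate_sequence(residue_letters(scaffold), spec$mutation_rate)
    m$aa <- aa
    m$atoms$aa <- aa[m$atoms$res_idx]
    members[[k]] <- m
  }
  tp <- matrix(spec$mutation_rate / 19, spec$length, 20L,
               dimnames = list(NULL, AA_ALPHABET))
  tp[cbind(seq_len(spec$length), aa_index(residue_letters(scaffold)))] <-
    1 - spec$mutation_rate
  list(scaffold = scaffold, library = members, true_profile = tp)
}

#' Two idealized antiparallel strands
#'
#' A hydrogen-bonded antiparallel strand pair built by applying the
#' two-fold rotation (about the axis perpendicular to the sheet plane) to
#' an extended strand (phi = -140, psi = 135) and translating it into
#' hydrogen-bond register. The registration offsets were fixed once from a
#' scan of the hydrogen-bond energy landscape of the ideal geometry and are
#' frozen here. Useful as a strand fixture for feature-assignment checks.
#'
#' @param n_per_strand residues per strand (default 8).
#' @param dx,dy frozen registration offsets (Angstrom).
#' @return a `protein_structure` with 2 * n_per_strand residues.
#' @export
make_paired_strands <- function(n_per_strand = 8L, dx = PAIRED_STRAND_DX,
                                dy = PAIRED_STRAND_DY) {
  n <- n_per_strand
  bbA <- build_backbone_from_torsions(rep(-140, n), rep(135, n))
  ctr <- colMeans(bbA$CA)
  rot_z <- diag(c(-1, -1, 1))
  move <- function(m) sweep(sweep(m, 2, ctr) %*% rot_z, 2, ctr + c(dx, dy, 0), "+")
  bb <- list(N = rbind(bbA$N, move(bbA$N)), CA = rbind(bbA$CA, move(bbA$CA)),
             C = rbind(bbA$C, move(bbA$C)), O = rbind(bbA$O, move(bbA$O)))
  seqs <- rep(c("V", "T", "I", "Y"), length.out = 2L * n)
  structure_from_backbone(bb, seqs)
}

#' Generate predictor training data
#'
#' Builds synthetic chains across the three topologies and pairs each
#' sequence with the features assigned from its own structure.
#'
#' @param n_chains number of chains (default 50).
#' @param length chain length (default 40).
#' @param seed RNG seed.
#' @return list of `list(sequence, features)` suitable for
#'   [train_predictor()].
#' @export
make_training_set <- function(n_chains = 50L, length = 40L, seed = 1L) {
  out <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    topo <- TOPOLOGIES[1L + (i - 1L) %% length(TOPOLOGIES)]
    s <- make_ideal_structure(topo, length, seed = seed + i)
    out[[i]] <- list(sequence = structure_sequence(s),
                     features = assign_features(s))
  }
  out
}

#' Write a synthetic family to a PDB directory with truth metadata
#'
#' @param spec a [family_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory. Writes `scaffold.pdb`,
#'   `homolog_XX.pdb` and `truth.json`-style TSV `true_profile.tsv`.
#' @export
write_family <- function(spec, dir) {
  fam <- make_family(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(fam$scaffold, file.path(dir, "scaffold.pdb"))
  for (k in seq_along(fam$library)) {
    write_pdb(fam$library[[k]], file.path(dir, sprintf("homolog_%02d.pdb", k)))
  }
  utils::write.table(round(fam$true_profile, 6),
                     file.path(dir, "true_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
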