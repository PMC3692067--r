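# Reference structural features of the scaffold: 3-state secondary
# structure by Kabsch-Sander style hydrogen-bond analysis, backbone phi/psi
# torsions, and relative solvent accessibility by sphere sampling.

#' Scaffold feature container
#'
#' @param ss character vector over {H, E, C}.
#' @param phi,psi numeric vectors in degrees, NA at undefined termini.
#' @param rsa numeric vector in [0, 1].
#' @return object of class `scaffold_features`.
#' @export
scaffold_features <- function(ss, phi, psi, rsa) {
  L <- length(ss)
  stopifnot(length(phi) == L, length(psi) == L, length(rsa) == L,
            all(ss %in% SS_STATES))
  if (any(rsa < -1e-9 | rsa > 1 + 1e-9, na.rm = TRUE)) stop("rsa outside [0,1]")
  structure(list(ss = ss, phi = phi, psi = psi,
                 rsa = pmin(1, pmax(0, rsa))),
            class = "scaffold_features")
}

#' @export
print.scaffold_features <- function(x, ...) {
  cat("scaffold_features over", length(x$ss), "residues\n")
  cat("  ss: ", abbreviate_seq(paste(x$ss, collapse = "")), "\n", sep = "")
  cat(sprintf("  mean rsa: %.2f  H/E/C: %d/%d/%d\n", mean(x$rsa),
              sum(x$ss == "H"), sum(x$ss == "E"), sum(x$ss == "C")))
  invisible(x)
}

# Backbone amide hydrogen positions: H sits 1.01 A from N along the bisector
# of the N->C(prev) and N->CA directions, reversed. Undefined for the first
# residue and for proline.
place_amide_h <- function(bb, aa) {
  L <- nrow(bb$N)
  H <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    if (aa[i] == "P") next
    if (anyNA(bb$C[i - 1, ]) || anyNA(bb$N[i, ]) || anyNA(bb$CA[i, ])) next
    u <- unitv(unitv(bb$N[i, ] - bb$C[i - 1, ]) + unitv(bb$N[i, ] - bb$CA[i, ]))
    H[i, ] <- bb$N[i, ] + 1.01 * u
  }
  H
}

# Electrostatic hydrogen-bond energy matrix, Kabsch-Sander model:
# E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, for the
# bond CO(i) ... HN(j). hb[i, j] is TRUE when E < -0.5 kcal/mol.
hbond_matrix <- function(bb, H) {
  L <- nrow(bb$N)
  q <- 0.084 * 332
  hb <- matrix(FALSE, L, L)
  dist1 <- function(a, b) max(0.5, vnorm(a - b))
  for (i in seq_len(L)) {           # acceptor: C=O of residue i
    if (anyNA(bb$C[i, ]) || anyNA(bb$O[i, ])) next
    for (j in seq_len(L)) {         # donor: N-H of residue j
      if (abs(i - j) < 2) next
      if (anyNA(H[j, ]) || anyNA(bb$N[j, ])) next
      e <- q * (1 / dist1(bb$O[i, ], bb$N[j, ]) + 1 / dist1(bb$C[i, ], H[j, ]) -
                1 / dist1(bb$O[i, ], H[j, ]) - 1 / dist1(bb$C[i, ], bb$N[j, ]))
      hb[i, j] <- e < -0.5
    }
  }
  hb
}

# 3-state secondary structure from the hydrogen-bond pattern. Minimal
# n-helices (two consecutive n-turns, n = 3, 4, 5 -> G, H, I) collapse to H;
# parallel/antiparallel bridge residues (B, E) collapse to E; all else C.
ss_from_hbonds <- function(hb) {
  L <- nrow(hb)
  turn <- function(n) {
    t <- rep(FALSE, L)
    idx <- seq_len(max(0, L - n))
    t[idx] <- hb[cbind(idx, idx + n)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  helix <- rep(FALSE, L)
  mark <- function(t, n) {
    for (i in 2:max(2, L)) {
      if (i > L) break
      if (i + n - 1 <= L && t[i - 1] && t[i]) helix[i:(i + n - 1)] <<- TRUE
    }
  }
  mark(t4, 4); mark(t3, 3); mark(t5, 5)
  bridge <- rep(FALSE, L)
  for (i in 2:(L - 1)) {
    for (j in 2:(L - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridge[i] <- TRUE
    }
  }
  ss <- rep("C", L)
  ss[bridge] <- "E"
  ss[helix] <- "H"   # helix takes precedence, as in the 8-state hierarchy
  ss
}

# Canonical rigid-body orientation (principal axes, signs fixed by the
# third moment) so that the sphere-sampled area is exactly invariant under
# superposition of the input coordinates.
canonical_orientation <- function(coords) {
  ctr <- colMeans(coords)
  x0 <- sweep(coords, 2, ctr)
  ev <- eigen(stats::cov(x0), symmetric = TRUE)$vectors
  y <- x0 %*% ev
  for (k in 1:3) {
    m3 <- sum(y[, k]^3)
    if (m3 < 0) y[, k] <- -y[, k]
  }
  y
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Sphere-sampling SASA with deterministic Fibonacci-lattice points.
#'
#' @param coords n x 3 atom coordinates.
#' @param radii length-n van der Waals radii.
#' @param probe probe radius (default 1.4 A).
#' @param n_points sphere points per atom (default 960).
#' @return per-atom exposed area in A^2.
#' @keywords internal
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(coords)
  coords <- canonical_orientation(coords)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_points) - 0.5
  zs <- 1 - 2 * k / n_points
  r2d <- sqrt(pmax(0, 1 - zs^2))
  th <- golden * (seq_len(n_points) - 1)
  sphere <- cbind(r2d * cos(th), r2d * sin(th), zs)
  rr <- radii + probe
  area <- numeric(n)
  cutoff <- max(rr) * 2
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rr[i], 2, coords[i, ], "+")
    d_cent <- sqrt(colSums((t(coords) - coords[i, ])^2))
    nb <- which(d_cent < rr[i] + rr & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- pts[exposed, 1, drop = TRUE] - coords[j, 1]
      dy <- pts[exposed, 2, drop = TRUE] - coords[j, 2]
      dz <- pts[exposed, 3, drop = TRUE] - coords[j, 3]
      exposed[exposed] <- (dx * dx + dy * dy + dz * dz) > rr[j]^2
    }
    area[i] <- 4 * pi * rr[i]^2 * sum(exposed) / n_points
  }
  area
}

#' Assign reference structural features to a scaffold
#'
#' Computes the three feature tracks the design energy compares against:
#' 3-state secondary structure (hydrogen-bond analysis of the backbone,
#' electrostatic H-bond energy < -0.5 kcal/mol; 8-state classes collapsed
#' as H,G,I -> H; E,B -> E; else C), backbone phi/psi dihedrals (NA at the
#' termini), and relative solvent accessibility (sphere-sampling exposed
#' area over per-residue-type maximum reference areas, clamped to [0,1]).
#'
#' @param s a `protein_structure` with full backbone (run
#'   [reconstruct_backbone()] first for C-alpha-only input).
#' @return a [scaffold_features] object.
#' @export
assign_features <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  if (is_ca_only(s)) {
    stop("structure lacks a complete backbone; call reconstruct_backbone() first")
  }
  bb <- get_backbone(s)
  L <- n_residues(s)
  miss <- which(is.na(bb$N[, 1]) | is.na(bb$CA[, 1]) | is.na(bb$C[, 1]))
  if (length(miss)) {
    stop("feature assignment failed: missing backbone atoms at residue(s) ",
         paste(s$resno[miss], collapse = ", "))
  }
  # carbonyl O can be derived from the peptide plane when absent
  for (i in seq_len(L)) {
    if (!anyNA(bb$O[i, ])) next
    nn <- if (i < L) bb$N[i + 1, ] else bb$N[i, ]
    bb$O[i, ] <- bb$C[i, ] + BOND_C_O *
      unitv(unitv(bb$C[i, ] - bb$CA[i, ]) + unitv(bb$C[i, ] - nn))
  }
  aa <- residue_letters(s)
  ss <- ss_from_hbonds(hbond_matrix(bb, place_amide_h(bb, aa)))
  phi <- psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1) phi[i] <- dihedral(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i < L) psi[i] <- dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
  }
  coords <- as.matrix(s$atoms[, c("x", "y", "z")])
  keep <- !grepl("^H", s$atoms$elety)
  area <- numeric(nrow(coords))
  area[keep] <- shrake_rupley(coords[keep, , drop = FALSE],
                              atom_radius(s$atoms$elety[keep]))
  res_area <- tapply(area, s$atoms$res_idx, sum)
  ref <- MAX_ASA[aa]
  ref[is.na(ref)] <- mean(MAX_ASA)
  rsa <- pmin(1, pmax(0, as.numeric(res_area) / unname(ref)))
  scaffold_features(ss = ss, phi = phi, psi = psi, rsa = rsa)
}
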