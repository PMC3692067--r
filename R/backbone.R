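# Backbone construction from torsion angles, and reconstruction of backbone
# heavy atoms from a C-alpha trace.
#
# Ideal internal coordinates used throughout (lengths in Angstrom, angles in
# degrees): N-CA 1.46, CA-C 1.52, C-N 1.33, C=O 1.23; N-CA-C 111.0,
# CA-C-N 116.5, C-N-CA 121.7, CA-C-O 120.5; omega fixed trans (180).

BOND_N_CA <- 1.46
BOND_CA_C <- 1.52
BOND_C_N <- 1.33
BOND_C_O <- 1.23
ANGLE_N_CA_C <- 111.0
ANGLE_CA_C_N <- 116.5
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5

#' Build ideal backbone coordinates from torsion angles
#'
#' Constructs N, CA, C, O coordinates for a chain with the given phi/psi
#' torsions under ideal bond geometry and trans peptide bonds.
#'
#' @param phi,psi numeric vectors of equal length L (degrees). `phi[1]` and
#'   `psi[L]` are not structurally determined; they are accepted and ignored
#'   except that `psi[L]` orients the terminal carbonyl oxygen.
#' @return list with L x 3 matrices `N`, `CA`, `C`, `O`.
#' @keywords internal
build_backbone_from_torsions <- function(phi, psi) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2)
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- (180 - ANGLE_N_CA_C) * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(th), sin(th), 0)
  for (i in 2:L) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  for (i in 1:L) {
    psi_i <- if (i < L) dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ]) else psi[L]
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_O, ANGLE_CA_C_O,
                         psi_i + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Local peptide-frame coordinates measured once on ideal helix and strand
# models built by build_backbone_from_torsions(); cached per session. The
# frame at C-alpha step i -> i+1 is: x along CA(i)->CA(i+1), y in the plane
# of the previous C-alpha (or the next-next one at the N terminus).
.peptide_frame_constants <- function() {
  if (!is.null(.pkg_cache$frame_const)) return(.pkg_cache$frame_const)
  measure <- function(phi, psi) {
    L <- 12L
    bb <- build_backbone_from_torsions(rep(phi, L), rep(psi, L))
    frame <- function(origin, xv, refv) {
      xh <- unitv(xv)
      v <- refv - sum(refv * xh) * xh
      yh <- unitv(v)
      cbind(xh, yh, cross3(xh, yh))
    }
    i <- 6L
    B <- frame(bb$CA[i, ], bb$CA[i + 1, ] - bb$CA[i, ], bb$CA[i - 1, ] - bb$CA[i, ])
    Bf <- frame(bb$CA[1, ], bb$CA[2, ] - bb$CA[1, ], bb$CA[3, ] - bb$CA[1, ])
    Be <- frame(bb$CA[L, ], bb$CA[L, ] - bb$CA[L - 1, ], bb$CA[L - 2, ] - bb$CA[L, ])
    list(
      C_mid = c(t(B) %*% (bb$C[i, ] - bb$CA[i, ])),
      N_next = c(t(B) %*% (bb$N[i + 1, ] - bb$CA[i + 1, ])),
      N_first = c(t(Bf) %*% (bb$N[1, ] - bb$CA[1, ])),
      C_first = c(t(Bf) %*% (bb$C[1, ] - bb$CA[1, ])),
      C_last = c(t(Be) %*% (bb$C[L, ] - bb$CA[L, ])),
      O_last = c(t(Be) %*% (bb$O[L, ] - bb$CA[L, ])),
      tau = dihedral(bb$CA[i - 1, ], bb$CA[i, ], bb$CA[i + 1, ], bb$CA[i + 2, ])
    )
  }
  .pkg_cache$frame_const <- list(
    helix = measure(SS_BIN_CENTERS["H", "phi"], SS_BIN_CENTERS["H", "psi"]),
    strand = measure(SS_BIN_CENTERS["E", "phi"], SS_BIN_CENTERS["E", "psi"]))
  .pkg_cache$frame_const
}

#' Reconstruct backbone heavy atoms from a C-alpha trace
#'
#' For structures carrying C-alpha atoms only (or an incomplete backbone),
#' places N, C and O atoms with ideal bond geometry oriented by the local
#' C-alpha trace. The orientation interpolates between reference helix and
#' strand peptide frames according to the local C-alpha pseudo-torsion, so
#' that downstream hydrogen-bond based feature assignment behaves sensibly
#' on both helical and extended traces. C-alpha positions are unchanged;
#' side chains are not built. Full-backbone input is returned unchanged.
#'
#' @param s a `protein_structure`.
#' @return a `protein_structure` with N, CA, C, O for every residue.
#' @export
reconstruct_backbone <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  if (!is_ca_only(s)) return(s)
  L <- n_residues(s)
  if (L < 3) stop("geometry underdetermined: need at least 3 residues to ",
                  "reconstruct a backbone from a C-alpha trace")
  CA <- get_ca(s)
  if (anyNA(CA)) stop("missing CA coordinates; cannot reconstruct")
  ref <- .peptide_frame_constants()
  hx <- ref$helix
  st <- ref$strand

  # per-peptide helix weight from the CA pseudo-torsion
  tau <- rep(NA_real_, L)
  for (i in 2:(L - 2)) {
    tau[i] <- dihedral(CA[i - 1, ], CA[i, ], CA[i + 1, ], CA[i + 2, ])
  }
  defined <- which(!is.na(tau))
  helix_weight <- function(i) {
    if (length(defined) == 0L) return(0.5)
    t_i <- tau[defined[which.min(abs(defined - i))]]
    dh <- angle_diff(t_i, hx$tau)
    ds <- angle_diff(t_i, st$tau)
    if (dh + ds < 1e-9) return(0.5)
    ds / (dh + ds)
  }
  mix <- function(i, field) {
    w <- helix_weight(i)
    w * hx[[field]] + (1 - w) * st[[field]]
  }
  frame_at <- function(origin, xv, refv) {
    xh <- unitv(xv)
    v <- refv - sum(refv * xh) * xh
    yh <- unitv(v)
    cbind(xh, yh, cross3(xh, yh))
  }
  at_len <- function(origin, vec, len) origin + len * unitv(vec)

  N <- C <- O <- matrix(NA_real_, L, 3)
  for (i in 1:(L - 1)) {
    B <- if (i >= 2) {
      frame_at(CA[i, ], CA[i + 1, ] - CA[i, ], CA[i - 1, ] - CA[i, ])
    } else {
      frame_at(CA[1, ], CA[2, ] - CA[1, ], CA[3, ] - CA[1, ])
    }
    C[i, ] <- at_len(CA[i, ], c(B %*% mix(i, "C_mid")), BOND_CA_C)
    N[i + 1, ] <- at_len(CA[i + 1, ], c(B %*% mix(i, "N_next")), BOND_N_CA)
  }
  Bf <- frame_at(CA[1, ], CA[2, ] - CA[1, ], CA[3, ] - CA[1, ])
  N[1, ] <- at_len(CA[1, ], c(Bf %*% mix(1, "N_first")), BOND_N_CA)
  Be <- frame_at(CA[L, ], CA[L, ] - CA[L - 1, ], CA[L - 2, ] - CA[L, ])
  C[L, ] <- at_len(CA[L, ], c(Be %*% mix(L - 1, "C_last")), BOND_CA_C)
  O[L, ] <- at_len(CA[L, ], c(Be %*% mix(L - 1, "O_last")), BOND_C_O)
  for (i in 1:(L - 1)) {
    O[i, ] <- C[i, ] + BOND_C_O *
      unitv(unitv(C[i, ] - CA[i, ]) + unitv(C[i, ] - N[i + 1, ]))
  }
  structure_from_backbone(list(N = N, CA = CA, C = C, O = O),
                          sequence = residue_letters(s),
                          resno = s$resno, icode = s$icode,
                          chain = s$chain, het = s$het)
}
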