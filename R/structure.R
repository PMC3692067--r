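# Structure container and PDB input/output.
#
# A `protein_structure` holds one chain of one model: an atom table in file
# order plus non-water HETATM records. Author residue numbering (with
# insertion codes) is preserved for I/O; internally residues are addressed
# by their 1-based position in file order.

#' Construct a protein_structure from an atom table
#'
#' @param atoms data.frame with columns `res_idx` (1-based contiguous),
#'   `resno`, `icode`, `aa` (1-letter, "X" allowed), `elety`, `x`, `y`, `z`.
#' @param het data.frame with columns `elety`, `resid`, `x`, `y`, `z`
#'   (non-water hetero atoms).
#' @param chain single chain identifier.
#' @return object of class `protein_structure`.
#' @keywords internal
new_structure <- function(atoms, het = empty_het(), chain = "A") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  idx <- sort(unique(atoms$res_idx))
  if (!identical(idx, seq_along(idx))) stop("res_idx must be 1-based contiguous")
  first <- !duplicated(atoms$res_idx)
  s <- structure(list(
    atoms = atoms,
    het = het,
    chain = chain,
    aa = atoms$aa[first],
    resno = atoms$resno[first],
    icode = atoms$icode[first]
  ), class = "protein_structure")
  has_ca <- vapply(split(atoms$elety, atoms$res_idx),
                   function(e) "CA" %in% e, logical(1))
  if (!all(has_ca)) {
    stop("residue(s) without a CA atom at position(s) ",
         paste(which(!has_ca), collapse = ", "))
  }
  s
}

empty_het <- function() {
  data.frame(elety = character(), resid = character(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

#' Number of residues in a structure
#' @param s a `protein_structure`.
#' @export
n_residues <- function(s) length(s$aa)

#' Residue letters / amino-acid sequence of a structure
#' @param s a `protein_structure`.
#' @return `residue_letters()` a character vector of 1-letter codes;
#'   `structure_sequence()` a single string.
#' @export
residue_letters <- function(s) s$aa

#' @rdname residue_letters
#' @export
structure_sequence <- function(s) paste(s$aa, collapse = "")

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, chain %s, %d atoms, %d hetero atoms\n",
              n_residues(x), x$chain, nrow(x$atoms), nrow(x$het)))
  cat("  sequence: ", abbreviate_seq(structure_sequence(x)), "\n", sep = "")
  invisible(x)
}

abbreviate_seq <- function(s) {
  if (nchar(s) <= 60) s else paste0(substr(s, 1, 57), "...")
}

#' Coordinates of one named atom per residue
#'
#' @return n_residues x 3 matrix; rows are NA where the atom is absent.
#' @keywords internal
atom_matrix <- function(s, elety) {
  m <- matrix(NA_real_, n_residues(s), 3)
  sel <- s$atoms$elety == elety
  a <- s$atoms[sel, ]
  a <- a[!duplicated(a$res_idx), ]
  m[a$res_idx, ] <- as.matrix(a[, c("x", "y", "z")])
  m
}

#' @keywords internal
get_ca <- function(s) atom_matrix(s, "CA")

#' @keywords internal
get_backbone <- function(s) {
  list(N = atom_matrix(s, "N"), CA = atom_matrix(s, "CA"),
       C = atom_matrix(s, "C"), O = atom_matrix(s, "O"))
}

#' Build a structure from backbone coordinate matrices
#'
#' @param bb list of L x 3 matrices `N`, `CA`, `C`, `O` (entries other than
#'   `CA` may be NULL or contain NA rows, which are skipped).
#' @param sequence character vector of L 1-letter codes (or single string).
#' @keywords internal
structure_from_backbone <- function(bb, sequence, resno = NULL, icode = NULL,
                                    chain = "A", het = empty_het()) {
  L <- nrow(bb$CA)
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  stopifnot(length(sequence) == L)
  if (is.null(resno)) resno <- seq_len(L)
  if (is.null(icode)) icode <- rep("", L)
  rows <- list()
  for (i in seq_len(L)) {
    for (el in c("N", "CA", "C", "O")) {
      xyz <- bb[[el]]
      if (is.null(xyz) || anyNA(xyz[i, ])) next
      rows[[length(rows) + 1L]] <- data.frame(
        res_idx = i, resno = resno[i], icode = icode[i], aa = sequence[i],
        elety = el, x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), het = het, chain = chain)
}

#' Read a scaffold or library structure from a PDB file
#'
#' Parses ATOM records of one chain (model 1 for multi-model files) into a
#' `protein_structure`, collecting non-water HETATM records as hetero atoms.
#' Residues are kept in file order; author numbering and insertion codes are
#' preserved. Residues lacking a CA atom are dropped with a warning.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default the first chain with ATOM records.
#' @param min_len minimum number of residues (default 30, the smallest
#'   scaffold that holds a meaningful fold); set lower to read fragments.
#' @return a `protein_structure`.
#' @export
read_pdb <- function(path, chain = NULL, min_len = 30L) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) stop("parse error: no ATOM records in ", path)
  if (is.null(chain)) chain <- prot$chain[1]
  if (is.na(chain)) chain <- ""
  pc <- prot$chain
  pc[is.na(pc)] <- ""
  prot <- prot[pc == chain, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no ATOM records for chain '", chain, "'")
  icode <- prot$insert
  icode[is.na(icode)] <- ""
  key <- paste(prot$resno, icode, sep = "_")
  res_idx <- match(key, unique(key))
  aa <- suppressWarnings(bio3d::aa321(prot$resid))
  aa[is.na(aa)] <- "X"
  atoms <- data.frame(res_idx = res_idx, resno = prot$resno, icode = icode,
                      aa = aa, elety = prot$elety,
                      x = prot$x, y = prot$y, z = prot$z,
                      stringsAsFactors = FALSE)
  # drop residues with no CA (e.g. partial termini)
  has_ca <- tapply(atoms$elety, atoms$res_idx, function(e) "CA" %in% e)
  if (!all(has_ca)) {
    warning("dropping ", sum(!has_ca), " residue(s) without CA atoms")
    keep <- atoms$res_idx %in% which(has_ca)
    atoms <- atoms[keep, , drop = FALSE]
    if (nrow(atoms) == 0L) stop("parse error: no residues with CA atoms")
    atoms$res_idx <- match(atoms$res_idx, sort(unique(atoms$res_idx)))
  }
  hrows <- at[at$type == "HETATM", , drop = FALSE]
  hrows <- hrows[!(hrows$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  het <- if (nrow(hrows)) {
    data.frame(elety = hrows$elety, resid = hrows$resid,
               x = hrows$x, y = hrows$y, z = hrows$z, stringsAsFactors = FALSE)
  } else empty_het()
  s <- new_structure(atoms, het = het, chain = chain)
  if (n_residues(s) < min_len) {
    stop("scaffold too short: ", n_residues(s), " residues; at least ",
         min_len, " are required for a meaningful fold")
  }
  s
}

#' Write a structure to a PDB file
#'
#' @param s a `protein_structure`.
#' @param path output file path.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  n_het <- nrow(s$het)
  resid3 <- bio3d::aa123(a$aa)
  resid3[a$aa == "X"] <- "UNK"
  type <- c(rep("ATOM", nrow(a)), rep("HETATM", n_het))
  elety <- c(a$elety, s$het$elety)
  resid <- c(resid3, s$het$resid)
  resno <- c(a$resno, rep(max(a$resno) + seq_len(n_het)))
  insert <- c(a$icode, rep("", n_het))
  insert[insert == ""] <- NA
  xyz <- c(t(as.matrix(rbind(a[, c("x", "y", "z")], s$het[, c("x", "y", "z")]))))
  bio3d::write.pdb(file = path, type = type, xyz = xyz, resno = resno,
                   resid = resid, elety = elety,
                   chain = rep(ifelse(s$chain == "", " ", s$chain), length(type)),
                   insert = insert)
  invisible(path)
}

#' Does a structure lack a complete N, CA, C backbone?
#'
#' TRUE if any residue is missing one of N, CA or C — i.e. the structure
#' must pass through [reconstruct_backbone()] before feature assignment.
#'
#' @param s a `protein_structure`.
#' @export
is_ca_only <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  ok <- vapply(split(s$atoms$elety, s$atoms$res_idx),
               function(e) all(c("N", "CA", "C") %in% e), logical(1))
  !all(ok)
}

#' Residues near hetero atoms (ligand-binding site)
#'
#' A residue is part of the binding site if any of its atoms lies within
#' `radius` of any hetero atom (CA distance when only CA is present).
#'
#' @param s a `protein_structure`.
#' @param radius sphere radius in Angstrom (default 8).
#' @return integer vector of residue positions (1-based, in chain order)
#'   with author residue numbers as names; empty when there are no hetero
#'   atoms.
#' @export
binding_site_residues <- function(s, radius = 8) {
  stopifnot(inherits(s, "protein_structure"), radius > 0)
  out <- integer(0)
  if (nrow(s$het) == 0L) return(out)
  hx <- as.matrix(s$het[, c("x", "y", "z")])
  ax <- as.matrix(s$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(hx^2), "+") - 2 * ax %*% t(hx)
  near_atom <- apply(d2 <= radius^2 + 1e-9, 1, any)
  pos <- sort(unique(s$atoms$res_idx[near_atom]))
  names(pos) <- paste0(s$resno[pos], s$icode[pos])
  pos
}
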