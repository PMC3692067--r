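# Structural alignment of library structures to the scaffold and
# construction of the position-specific evolutionary profile.
#
# The aligner is a simplified TM-align: seed alignments are refined by
# iterating Kabsch superposition on the current pair set with
# Needleman-Wunsch re-alignment under TM-score-derived position scores,
# until the pair set is stable. Equivalence with the published TM-align
# binaries is not claimed; the TM-score formula itself and monotone
# behavior on fixtures are the contract.

#' Length-dependent TM-score distance scale d0
#'
#' d0 = 1.24 (L - 15)^(1/3) - 1.8, clamped to >= 0.5.
#' @param L normalizing chain length.
#' @export
tm_d0 <- function(L) {
  d0 <- if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else 0
  max(0.5, d0)
}

#' TM-score from aligned distances
#'
#' TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2). With every d_i = d0 and
#' full coverage the score is exactly 0.5.
#'
#' @param d aligned-pair distances (Angstrom).
#' @param L_norm normalizing length (scaffold length).
#' @param d0 distance scale; default [tm_d0()] of `L_norm`.
#' @export
tm_score <- function(d, L_norm, d0 = tm_d0(L_norm)) {
  sum(1 / (1 + (d / d0)^2)) / L_norm
}

#' Structurally align a homolog onto a scaffold
#'
#' Sequence-order-preserving alignment maximizing the TM-score normalized
#' by the scaffold length.
#'
#' @param scaffold,homolog `protein_structure` objects (>= 3 residues).
#' @param max_iter iteration cap per seed (default 20).
#' @param gap Needleman-Wunsch gap penalty on the TM-score position score
#'   matrix (default -0.6).
#' @return a `struct_alignment`: list with `pairs` (2-column matrix of
#'   1-based scaffold/homolog positions), `tm_score`, `rmsd_aligned`, and
#'   the aligned homolog residues `homolog_seq`.
#' @export
tm_align <- function(scaffold, homolog, max_iter = 20L, gap = -0.6) {
  X <- get_ca(scaffold)
  Y <- get_ca(homolog)
  L1 <- nrow(X); L2 <- nrow(Y)
  if (L1 < 3 || L2 < 3) stop("structures must have at least 3 residues")
  d0 <- tm_d0(L1)

  score_pairs <- function(pairs) {
    if (nrow(pairs) < 3) return(list(tm = 0, rmsd = Inf, fit = NULL))
    fit <- kabsch(X[pairs[, 1], , drop = FALSE], Y[pairs[, 2], , drop = FALSE])
    yf <- apply_fit(fit, Y[pairs[, 2], , drop = FALSE])
    d <- sqrt(rowSums((yf - X[pairs[, 1], , drop = FALSE])^2))
    list(tm = tm_score(d, L1, d0), rmsd = fit$rmsd, fit = fit)
  }
  realign <- function(fit) {
    yf <- apply_fit(fit, Y)
    d2 <- outer(rowSums(X^2), rowSums(yf^2), "+") - 2 * X %*% t(yf)
    S <- 1 / (1 + pmax(d2, 0) / d0^2)
    nw_align_cpp(S, gap)
  }

  k <- min(L1, L2)
  seeds <- list(cbind(seq_len(k), seq_len(k)),
                cbind(seq_len(max(3, k %/% 2)), seq_len(max(3, k %/% 2))),
                cbind(L1 - seq(max(3, k %/% 2), 1) + 1,
                      L2 - seq(max(3, k %/% 2), 1) + 1))
  best <- list(tm = -Inf, pairs = NULL, rmsd = Inf)
  for (seed in seeds) {
    pairs <- seed
    prev_key <- ""
    for (it in seq_len(max_iter)) {
      sc <- score_pairs(pairs)
      if (is.null(sc$fit)) break
      if (sc$tm > best$tm) best <- list(tm = sc$tm, pairs = pairs, rmsd = sc$rmsd)
      pairs_new <- realign(sc$fit)
      key <- paste(pairs_new, collapse = ",")
      if (identical(key, prev_key) || nrow(pairs_new) < 3) break
      prev_key <- key
      pairs <- pairs_new
    }
  }
  # TM-score style refinement: refit on close pairs to tighten the core
  pairs <- best$pairs
  for (rep in 1:3) {
    sc <- score_pairs(pairs)
    if (is.null(sc$fit)) break
    yf <- apply_fit(sc$fit, Y[pairs[, 2], , drop = FALSE])
    d <- sqrt(rowSums((yf - X[pairs[, 1], , drop = FALSE])^2))
    keep <- d <= max(d0, 3.5)
    if (sum(keep) < 3 || all(keep)) break
    core <- pairs[keep, , drop = FALSE]
    fit <- kabsch(X[core[, 1], , drop = FALSE], Y[core[, 2], , drop = FALSE])
    yf_all <- apply_fit(fit, Y[pairs[, 2], , drop = FALSE])
    d_all <- sqrt(rowSums((yf_all - X[pairs[, 1], , drop = FALSE])^2))
    tm_ref <- tm_score(d_all, L1, d0)
    if (tm_ref > best$tm) best$tm <- tm_ref else break
  }
  sc <- score_pairs(best$pairs)
  structure(list(pairs = best$pairs, tm_score = max(best$tm, sc$tm),
                 rmsd_aligned = sc$rmsd,
                 homolog_seq = residue_letters(homolog)),
            class = "struct_alignment")
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf("struct_alignment: %d pairs, TM-score %.3f, aligned RMSD %.2f A\n",
              nrow(x$pairs), x$tm_score, x$rmsd_aligned))
  invisible(x)
}

#' Select structural homologs by relaxing a TM-score threshold
#'
#' Starting from `tm_hi`, the acceptance threshold decreases in `step`
#' decrements until more than `min_homologs` library members score above it
#' or the floor `tm_lo` is reached.
#'
#' @param scaffold a `protein_structure`.
#' @param library list of `protein_structure` objects.
#' @param tm_hi,tm_lo initial and floor TM-score thresholds (defaults 0.7
#'   and 0.5).
#' @param min_homologs relaxation stops once the count of accepted library
#'   members strictly exceeds this (default 10).
#' @param step threshold decrement (default 0.05).
#' @return list with `alignments` (library members passing the final
#'   threshold) and `threshold_used`.
#' @export
select_homologs <- function(scaffold, library, tm_hi = 0.7, tm_lo = 0.5,
                            min_homologs = 10L, step = 0.05) {
  if (length(library) == 0L) {
    stop("empty structure library; build the profile from the scaffold ",
         "sequence alone (self-profile mode: build_msa with no alignments)")
  }
  stopifnot(tm_hi >= tm_lo, step > 0)
  alns <- lapply(library, function(h) tm_align(scaffold, h))
  tms <- vapply(alns, function(a) a$tm_score, numeric(1))
  thresholds <- unique(c(seq(tm_hi, tm_lo, by = -step), tm_lo))
  threshold_used <- tm_lo
  for (t in thresholds) {
    threshold_used <- t
    if (sum(tms > t) > min_homologs) break
  }
  list(alignments = alns[tms > threshold_used],
       threshold_used = threshold_used)
}

#' Scaffold-anchored multiple sequence alignment
#'
#' Master-slave MSA: row 1 is the scaffold sequence; each homolog row j
#' carries, in column p, the homolog residue its structural alignment maps
#' to scaffold position p, or a gap. Homologs are never re-aligned to each
#' other.
#'
#' @param scaffold a `protein_structure` (or character vector of residues).
#' @param alignments list of `struct_alignment` objects against the scaffold.
#' @return character matrix (n_homologs + 1) x L with "-" gaps.
#' @export
build_msa <- function(scaffold, alignments = list()) {
  seq_sc <- if (inherits(scaffold, "protein_structure")) {
    residue_letters(scaffold)
  } else scaffold
  L <- length(seq_sc)
  rows <- matrix("-", nrow = length(alignments) + 1L, ncol = L)
  rows[1, ] <- seq_sc
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    ok <- a$pairs[, 1] >= 1 & a$pairs[, 1] <= L &
          a$pairs[, 2] >= 1 & a$pairs[, 2] <= length(a$homolog_seq)
    p <- a$pairs[ok, , drop = FALSE]
    rows[k + 1L, p[, 1]] <- a$homolog_seq[p[, 2]]
  }
  rownames(rows) <- c("scaffold", if (length(alignments)) {
    paste0("homolog_", seq_along(alignments))
  })
  rows
}

# Henikoff position-based sequence weights; gaps carry no weight in a
# column. Exact duplicate rows are collapsed beforehand (sharing a single
# weight), so adding a copy of a homolog never changes the profile.
henikoff_weights <- function(msa) {
  n <- nrow(msa)
  w <- numeric(n)
  for (j in seq_len(ncol(msa))) {
    col <- msa[, j]
    obs <- col %in% AA_ALPHABET
    if (!any(obs)) next
    syms <- col[obs]
    r <- length(unique(syms))
    cnt <- table(syms)
    w[obs] <- w[obs] + 1 / (r * as.numeric(cnt[syms]))
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

#' Build the position-specific log-odds profile
#'
#' Rows are weighted with Henikoff position-based weights; per-column
#' weighted frequencies are mixed with BLOSUM62 background pseudocounts
#' using a diversity-based effective count (the number of distinct residues
#' observed in the column), and converted to natural-log odds against the
#' background.
#'
#' @param msa character matrix from [build_msa()].
#' @param pseudocount pseudocount strength beta in effective counts
#'   (default 5).
#' @param tm_threshold_used recorded for provenance (optional).
#' @return a `design_profile`: list with `L`, `log_odds` (L x 20, natural
#'   log), `counts`, `background`, `n_homologs`, `tm_threshold_used`.
#' @export
build_profile <- function(msa, pseudocount = 5, tm_threshold_used = NA_real_) {
  if (is.null(dim(msa)) || nrow(msa) < 1L) stop("msa must have at least one row")
  if (pseudocount <= 0) stop("pseudocount strength must be > 0")
  n_rows_in <- nrow(msa)
  msa <- msa[!duplicated(apply(msa, 1, paste, collapse = "")), , drop = FALSE]
  L <- ncol(msa)
  w <- henikoff_weights(msa)
  log_odds <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  counts <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  bg <- BLOSUM62_BACKGROUND[AA_ALPHABET]
  for (j in seq_len(L)) {
    col <- msa[, j]
    obs <- col %in% AA_ALPHABET
    if (any(obs)) {
      m <- tapply(w[obs], factor(col[obs], levels = AA_ALPHABET), sum)
      m[is.na(m)] <- 0
      f <- as.numeric(m) / sum(m)
      n_eff <- length(unique(col[obs]))
    } else {
      f <- as.numeric(bg)
      n_eff <- 0
    }
    p <- (n_eff * f + pseudocount * bg) / (n_eff + pseudocount)
    counts[j, ] <- n_eff * f
    log_odds[j, ] <- log(p / bg)
  }
  structure(list(L = L, log_odds = log_odds, counts = counts,
                 background = bg, n_homologs = n_rows_in,
                 tm_threshold_used = tm_threshold_used),
            class = "design_profile")
}

#' @export
print.design_profile <- function(x, ...) {
  cat(sprintf("design_profile: %d positions, %d aligned sequences", x$L,
              x$n_homologs))
  if (!is.na(x$tm_threshold_used)) {
    cat(sprintf(", TM threshold %.2f", x$tm_threshold_used))
  }
  cat("\n  consensus: ",
      abbreviate_seq(paste(AA_ALPHABET[apply(x$log_odds, 1, which.max)],
                           collapse = "")), "\n", sep = "")
  invisible(x)
}

#' Export / import a profile as PSSM-like tab-separated text
#'
#' Columns: position, scaffold-anchored consensus residue, then the 20
#' natural-log odds columns in alphabet order.
#' @param profile a `design_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(pos = seq_len(profile$L),
                   consensus = AA_ALPHABET[apply(profile$log_odds, 1, which.max)],
                   round(profile$log_odds, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  lo <- as.matrix(df[, AA_ALPHABET])
  dimnames(lo) <- list(NULL, AA_ALPHABET)
  bg <- BLOSUM62_BACKGROUND[AA_ALPHABET]
  p <- exp(lo) * rep(bg, each = nrow(lo))
  structure(list(L = nrow(lo), log_odds = lo, counts = NULL,
                 background = bg, n_homologs = NA_integer_,
                 tm_threshold_used = NA_real_),
            class = "design_profile")
}

#' Write an MSA as FASTA
#' @param msa character matrix from [build_msa()].
#' @param path file path.
#' @export
write_msa_fasta <- function(msa, path) {
  seqs <- Biostrings::AAStringSet(apply(msa, 1, paste, collapse = ""))
  names(seqs) <- rownames(msa)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
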