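# Single-sequence predictors of local structural features (3-state SS,
# phi/psi, relative SA) used to score decoy sequences during the search.
#
# Two variants share one interface and one compiled forward pass:
#  * "propensity": fixed Chou-Fasman H/E/C propensities and a Kyte-Doolittle
#    exposure scale, smoothed over a sliding window. No training required.
#  * "neural": one-hidden-layer feed-forward networks (trained with nnet)
#    over one-hot encoded windows; a softmax net for SS and a logistic
#    regression net for RSA.
# phi/psi are predicted as the torsion-bin centers of the most probable
# secondary-structure state.

#' Window-propensity feature predictor
#'
#' @param window odd window length (default 15).
#' @return a `feature_predictor` object (variant "propensity").
#' @export
propensity_predictor <- function(window = 15L) {
  check_window(window)
  hw <- window %/% 2
  wts <- 1 - abs(seq_len(window) - (hw + 1)) / (hw + 1)
  model <- structure(list(variant = "propensity", window = as.integer(window),
                          wts = wts), class = "feature_predictor")
  model$cpp <- cpp_params(model)
  model
}

check_window <- function(window) {
  if (length(window) != 1L || window < 3L || window %% 2L != 1L) {
    stop("window must be a single odd integer >= 3")
  }
}

# parameter list handed to the compiled forward pass
cpp_params <- function(model) {
  base <- list(window = model$window,
               bin_phi = unname(SS_BIN_CENTERS[, "phi"]),
               bin_psi = unname(SS_BIN_CENTERS[, "psi"]))
  if (model$variant == "propensity") {
    prop <- rbind(CF_HELIX[AA_ALPHABET], CF_STRAND[AA_ALPHABET],
                  CF_COIL[AA_ALPHABET])
    c(base, list(variant = 0L, prop = unname(prop),
                 expo = unname(EXPOSURE_PROPENSITY[AA_ALPHABET]),
                 wts = model$wts))
  } else {
    c(base, list(variant = 1L,
                 W1ss = model$W1ss, b1ss = model$b1ss,
                 W2ss = model$W2ss, b2ss = model$b2ss,
                 W1sa = model$W1sa, b1sa = model$b1sa,
                 w2sa = model$w2sa, b2sa = model$b2sa))
  }
}

#' @export
print.feature_predictor <- function(x, ...) {
  cat(sprintf("feature_predictor: %s variant, window %d", x$variant, x$window))
  if (!is.null(x$q3_holdout)) cat(sprintf(", held-out Q3 %.3f", x$q3_holdout))
  cat("\n")
  invisible(x)
}

#' Predict local structural features of a sequence
#'
#' @param seq amino-acid sequence (string or character vector, 20 standard
#'   letters).
#' @param model a `feature_predictor` from [propensity_predictor()] or
#'   [train_predictor()].
#' @return a `feature_prediction`: list with `ss_prob` (L x 3 matrix over
#'   H/E/C, rows sum to 1), `rsa` in [0,1], and `phi`/`psi` in degrees.
#' @export
predict_features <- function(seq, model) {
  stopifnot(inherits(model, "feature_predictor"))
  idx <- seq_to_int(seq)
  out <- predict_features_cpp(idx - 1L, model$cpp)
  colnames(out$ss_prob) <- SS_STATES
  structure(list(ss_prob = out$ss_prob, rsa = out$rsa,
                 phi = out$phi, psi = out$psi),
            class = "feature_prediction")
}

# one-hot window encoding matching the compiled layout: feature column
# k * 21 + sym (k = 0..window-1; sym 0..19 amino acid, 20 pad)
encode_windows <- function(seq_idx, window) {
  L <- length(seq_idx)
  hw <- window %/% 2
  X <- matrix(0, L, window * 21L)
  for (k in 0:(window - 1L)) {
    q <- seq_len(L) + k - hw
    sym <- ifelse(q >= 1 & q <= L, seq_idx[pmin(pmax(q, 1L), L)] - 1L, 20L)
    X[cbind(seq_len(L), k * 21L + sym + 1L)] <- 1
  }
  X
}

# unpack an nnet weight vector into input->hidden and hidden->output blocks
unpack_nnet <- function(fit, n_in, n_hidden, n_out) {
  w <- fit$wts
  W1 <- matrix(0, n_hidden, n_in)
  b1 <- numeric(n_hidden)
  for (h in seq_len(n_hidden)) {
    blk <- w[((h - 1) * (n_in + 1) + 1):(h * (n_in + 1))]
    b1[h] <- blk[1]
    W1[h, ] <- blk[-1]
  }
  off <- n_hidden * (n_in + 1)
  W2 <- matrix(0, n_out, n_hidden)
  b2 <- numeric(n_out)
  for (o in seq_len(n_out)) {
    blk <- w[(off + (o - 1) * (n_hidden + 1) + 1):(off + o * (n_hidden + 1))]
    b2[o] <- blk[1]
    W2[o, ] <- blk[-1]
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Train the neural feature predictor
#'
#' Trains one-hidden-layer networks on (sequence, assigned features) pairs:
#' a 3-class softmax network for secondary structure and a logistic network
#' for relative solvent accessibility. Training is deterministic for a given
#' seed; a held-out chain split reports the 3-state SS accuracy (Q3).
#'
#' @param training_set list of `list(sequence = , features = )`, where
#'   `features` is a [scaffold_features] (typically from [assign_features()]
#'   on synthetic or experimental structures).
#' @param window odd window length (default 15).
#' @param hidden hidden units (default 8).
#' @param seed RNG seed controlling initial weights and the held-out split.
#' @param maxit optimizer iterations passed to nnet (default 150).
#' @param holdout_frac fraction of chains held out for Q3 (default 0.2).
#' @return a `feature_predictor` (variant "neural") with `q3_holdout`.
#' @export
train_predictor <- function(training_set, window = 15L, hidden = 8L,
                            seed = 1L, maxit = 150L, holdout_frac = 0.2) {
  check_window(window)
  if (length(training_set) == 0L) stop("empty training set")
  if (length(training_set) < 10L) {
    stop("need at least 10 training chains, got ", length(training_set))
  }
  n <- length(training_set)
  set.seed(seed)
  n_hold <- max(1L, floor(holdout_frac * n))
  hold <- sample.int(n, n_hold)
  build <- function(ids) {
    Xs <- list(); ys <- list(); yr <- list()
    for (i in ids) {
      tr <- training_set[[i]]
      idx <- seq_to_int(tr$sequence)
      Xs[[length(Xs) + 1L]] <- encode_windows(idx, window)
      ys[[length(ys) + 1L]] <- match(tr$features$ss, SS_STATES)
      yr[[length(yr) + 1L]] <- tr$features$rsa
    }
    list(X = do.call(rbind, Xs), ss = unlist(ys), rsa = unlist(yr))
  }
  train <- build(setdiff(seq_len(n), hold))
  test <- build(hold)
  n_in <- window * 21L

  y_ind <- matrix(0, nrow(train$X), 3L)
  y_ind[cbind(seq_len(nrow(train$X)), train$ss)] <- 1
  set.seed(seed + 1L)
  fit_ss <- nnet::nnet(train$X, y_ind, size = hidden, softmax = TRUE,
                       maxit = maxit, decay = 1e-3, trace = FALSE,
                       MaxNWts = 100000L)
  set.seed(seed + 2L)
  fit_sa <- nnet::nnet(train$X, train$rsa, size = hidden, linout = FALSE,
                       maxit = maxit, decay = 1e-3, trace = FALSE,
                       MaxNWts = 100000L)
  uss <- unpack_nnet(fit_ss, n_in, hidden, 3L)
  usa <- unpack_nnet(fit_sa, n_in, hidden, 1L)
  model <- structure(list(variant = "neural", window = as.integer(window),
                          hidden = as.integer(hidden), seed = as.integer(seed),
                          W1ss = uss$W1, b1ss = uss$b1,
                          W2ss = uss$W2, b2ss = uss$b2,
                          W1sa = usa$W1, b1sa = usa$b1,
                          w2sa = c(usa$W2), b2sa = usa$b2,
                          nnet_ss = fit_ss, nnet_sa = fit_sa),
                     class = "feature_predictor")
  model$cpp <- cpp_params(model)
  pred_cls <- apply(predict_features_matrix(test$X, model)$ss_prob, 1, which.max)
  model$q3_holdout <- mean(pred_cls == test$ss)
  model
}

# forward pass on pre-encoded windows (used for held-out scoring; mirrors
# the compiled pass on the same weights)
predict_features_matrix <- function(X, model) {
  z1 <- 1 / (1 + exp(-(X %*% t(model$W1ss) + rep(model$b1ss, each = nrow(X)))))
  o <- z1 %*% t(model$W2ss) + rep(model$b2ss, each = nrow(X))
  e <- exp(o - apply(o, 1, max))
  list(ss_prob = e / rowSums(e))
}

#' Save or load a feature predictor
#'
#' @param model a `feature_predictor`.
#' @param path file path.
#' @export
save_predictor <- function(model, path) {
  stopifnot(inherits(model, "feature_predictor"))
  saveRDS(model[setdiff(names(model), c("nnet_ss", "nnet_sa"))], path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "feature_predictor")
}
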