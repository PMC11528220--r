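# Kinematic decoding and evaluation: regularized Wiener filter with history,
# cross-validated regularization sweep, variance-weighted R^2, PSTH R^2, and
# phoneme error rate.

#' Build a lagged design matrix
#'
#' Row `t` concatenates feature bins `t, t-1, ..., t-history` plus a
#' constant 1 (the bias, last column). The first `history` rows are dropped;
#' `rows` maps each design row back to its feature bin so targets can be
#' aligned.
#'
#' @param features A [binned_features()] or channels x bins matrix.
#' @param history_bins Number of history bins (default 4).
#' @return A list: `X` (design matrix), `rows` (feature-bin index of each
#'   row), `n_features`, `history_bins`.
#' @export
build_design <- function(features, history_bins = 4) {
  v <- if (inherits(features, "binned_features")) features$values
       else as.matrix(features)
  nb <- ncol(v)
  if (nb <= history_bins) stop("build_design: too few bins for history")
  rows <- (history_bins + 1L):nb
  X <- matrix(0, length(rows), nrow(v) * (history_bins + 1L) + 1L)
  for (h in 0:history_bins) {
    cols <- h * nrow(v) + seq_len(nrow(v))
    X[, cols] <- t(v[, rows - h, drop = FALSE])
  }
  X[, ncol(X)] <- 1
  list(X = X, rows = rows, n_features = nrow(v),
       history_bins = history_bins)
}

#' Fit a regularized Wiener filter
#'
#' Solves `(X'X + P) W = X'y` where `P` is diagonal with the regularization
#' constant on every entry except a zero at the bias column, via a
#' symmetric positive-definite solve. `penalty = "rtr"` instead squares the
#' constant (`P = lam^2 I`), the literal reading of a regularizer supplied
#' as a diagonal matrix `R` with `lam` on its diagonal.
#'
#' @param X Design matrix from [build_design()] (bias last).
#' @param y Row-aligned target matrix (N x out dims).
#' @param lam Regularization constant (>= 0).
#' @param penalty `"diag"` (default; penalty `lam`) or `"rtr"` (`lam^2`).
#' @return A `wiener_decoder` with coefficient matrix `W`.
#' @export
fit_wiener <- function(X, y, lam, penalty = c("diag", "rtr")) {
  penalty <- match.arg(penalty)
  y <- as.matrix(y)
  if (nrow(X) != nrow(y)) stop("fit_wiener: X and y must be row-aligned")
  p <- ncol(X)
  pen <- if (penalty == "diag") lam else lam^2
  P <- diag(rep(pen, p))
  P[p, p] <- 0 # bias is not regularized
  A <- crossprod(X) + P
  if (pen == 0 && qr(A)$rank < p) {
    stop("fit_wiener: normal equations are singular (rank-deficient X with ",
         "lam = 0)")
  }
  W <- tryCatch({
    R <- chol(A)
    backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
  }, error = function(e) {
    stop("fit_wiener: normal equations are singular (rank-deficient X with ",
         "lam = ", lam, ")")
  })
  structure(list(W = W, lambda = lam, penalty = penalty,
                 n_features = p), class = "wiener_decoder")
}

#' @rdname fit_wiener
#' @param decoder A `wiener_decoder`.
#' @return For `predict_wiener`, the N x out prediction matrix.
#' @export
predict_wiener <- function(decoder, X) {
  stopifnot(inherits(decoder, "wiener_decoder"))
  X %*% decoder$W
}

#' Variance-weighted R^2
#'
#' `1 - sum_d sum_i (yhat - y)^2 / sum_d sum_i (y - ybar_d)^2` with
#' `ybar_d` the per-dimension mean of the truth: a single pooled ratio, not
#' an average of per-dimension R^2 values. May be negative on held-out data.
#'
#' @param y N x D truth matrix.
#' @param yhat N x D prediction matrix.
#' @return Scalar R^2.
#' @export
variance_weighted_r2 <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("variance_weighted_r2: shape mismatch")
  if (nrow(y) < 2) stop("variance_weighted_r2: need N >= 2")
  denom <- sum(sweep(y, 2, colMeans(y))^2)
  if (denom == 0) stop("variance_weighted_r2: zero total variance in y")
  1 - sum((yhat - y)^2) / denom
}

#' Cross-validated Wiener decoding with a regularization sweep
#'
#' Holds out the final `holdout_frac` of rows, then runs k-fold
#' cross-validation with contiguous time-block folds on the remainder,
#' sweeping the regularization grid. Rows whose history overlaps a
#' validation block are dropped from that fold's training set to prevent
#' leakage through the lagged design. The best constant (highest mean
#' validation variance-weighted R^2) is refit on all cross-validation rows
#' and scored once on the untouched holdout.
#'
#' @param features A [binned_features()] or channels x bins matrix.
#' @param targets Bins x dims target matrix on the same clock.
#' @param lam_grid Regularization grid (default 20 log-spaced values,
#'   100-1000).
#' @param k Number of folds (default 10).
#' @param history History bins (default 4).
#' @param holdout_frac Fraction of rows reserved for the final report.
#' @return A list: `best_lambda`, `r2_holdout`, `cv_table` (per-lambda mean
#'   validation R^2), `decoder`.
#' @export
cv_decode <- function(features, targets,
                      lam_grid = 10^seq(log10(100), log10(1000),
                                        length.out = 20),
                      k = 10, history = 4, holdout_frac = 0.2) {
  d <- build_design(features, history)
  y <- as.matrix(targets)[d$rows, , drop = FALSE]
  n <- nrow(d$X)
  if (n < k * (history + 2)) stop("cv_decode: too few rows for ", k, " folds")
  n_hold <- max(1L, round(holdout_frac * n))
  cv_rows <- seq_len(n - n_hold)
  hold_rows <- (n - n_hold + 1L):n
  folds <- split(cv_rows, cut(cv_rows, breaks = k, labels = FALSE))
  mean_r2 <- numeric(length(lam_grid))
  for (li in seq_along(lam_grid)) {
    r2s <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      val <- folds[[fi]]
      excl <- unique(c(val, pmin(max(cv_rows), max(val) + seq_len(history))))
      train <- setdiff(cv_rows, excl)
      dec <- fit_wiener(d$X[train, , drop = FALSE],
                        y[train, , drop = FALSE], lam_grid[li])
      pred <- predict_wiener(dec, d$X[val, , drop = FALSE])
      r2s[fi] <- variance_weighted_r2(y[val, , drop = FALSE], pred)
    }
    mean_r2[li] <- mean(r2s)
  }
  best <- which.max(mean_r2)
  dec <- fit_wiener(d$X[cv_rows, , drop = FALSE],
                    y[cv_rows, , drop = FALSE], lam_grid[best])
  pred <- predict_wiener(dec, d$X[hold_rows, , drop = FALSE])
  list(best_lambda = lam_grid[best],
       r2_holdout = variance_weighted_r2(y[hold_rows, , drop = FALSE], pred),
       cv_table = data.frame(lambda = lam_grid, mean_val_r2 = mean_r2),
       decoder = dec)
}

#' PSTH R^2 between inferred rates and empirical activity
#'
#' Smooths the reference activity (30 ms Gaussian by default; pass
#' `smooth_sd_ms = 0` when the reference is already a rate), extracts
#' alignment windows for both signals, averages within condition,
#' concatenates the condition averages along time, computes the per-channel
#' coefficient of determination of the rate trace against the reference
#' trace, and returns the uniform mean over channels.
#'
#' @param rates [binned_features()] of model rates.
#' @param spikes [binned_features()] of reference activity (spike counts or
#'   ground-truth rates) on the same clock.
#' @param trials A [trial_table()] with alignment times filled.
#' @param smooth_sd_ms Gaussian SD for the reference (default 30; 0 = none).
#' @param pre_ms,post_ms Alignment window (defaults 250/500 ms).
#' @return A list: `r2` (uniform mean over channels), `per_channel`,
#'   `n_conditions`, `n_trials`.
#' @export
psth_r2 <- function(rates, spikes, trials, smooth_sd_ms = 30,
                    pre_ms = 250, post_ms = 500) {
  stopifnot(inherits(rates, "binned_features"),
            inherits(spikes, "binned_features"))
  ref <- if (smooth_sd_ms > 0) gaussian_smooth(spikes, smooth_sd_ms)
         else spikes
  ar <- extract_aligned(rates, trials, pre_ms, post_ms)
  as_ <- extract_aligned(ref, trials, pre_ms, post_ms)
  common <- intersect(ar$trial_id, as_$trial_id)
  ir <- match(common, ar$trial_id)
  is_ <- match(common, as_$trial_id)
  cond <- ar$condition[ir]
  conds <- sort(unique(cond))
  use <- conds[vapply(conds, function(cd) sum(cond == cd) >= 2, TRUE)]
  if (length(use) < 2) {
    stop("psth_r2: need >= 2 conditions with >= 2 accepted trials each")
  }
  dropped <- setdiff(conds, use)
  if (length(dropped)) {
    warning("psth_r2: excluding conditions with < 2 trials: ",
            paste(dropped, collapse = ", "))
  }
  cat_rate <- NULL
  cat_ref <- NULL
  for (cd in use) {
    sel_r <- ir[cond == cd]
    sel_s <- is_[cond == cd]
    avg_r <- apply(ar$tensor[sel_r, , , drop = FALSE], c(2, 3), mean)
    avg_s <- apply(as_$tensor[sel_s, , , drop = FALSE], c(2, 3), mean)
    cat_rate <- cbind(cat_rate, avg_r)
    cat_ref <- cbind(cat_ref, avg_s)
  }
  per_ch <- vapply(seq_len(nrow(cat_rate)), function(ch) {
    ss_tot <- sum((cat_ref[ch, ] - mean(cat_ref[ch, ]))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((cat_rate[ch, ] - cat_ref[ch, ])^2) / ss_tot
  }, numeric(1))
  list(r2 = mean(per_ch, na.rm = TRUE), per_channel = per_ch,
       n_conditions = length(use), n_trials = length(common))
}

#' Phoneme error rate
#'
#' Levenshtein edit distance (unit-cost substitutions, insertions,
#' deletions) between the decoded and true symbol sequences, divided by the
#' true sequence length.
#'
#' @param decoded Character vector of decoded symbols.
#' @param truth Non-empty character vector of true symbols.
#' @return Error rate (0 = perfect; can exceed 1).
#' @export
phoneme_error_rate <- function(decoded, truth) {
  if (length(truth) == 0) stop("phoneme_error_rate: empty truth sequence")
  symbols <- unique(c(decoded, truth))
  if (length(symbols) > 60000) stop("phoneme_error_rate: alphabet too large")
  code <- intToUtf8(match(c(decoded, truth), symbols) + 255L,
                    multiple = TRUE)
  dec_s <- paste0(code[seq_along(decoded)], collapse = "")
  tru_s <- paste0(code[length(decoded) + seq_along(truth)], collapse = "")
  as.numeric(utils::adist(dec_s, tru_s)) / length(truth)
}
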