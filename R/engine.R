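# Internal session engine: per-block sufficient statistics for fast
# repeated PCA-regression fits over arbitrary channel subsets and block
# sets.  The covariance of any stacked feature subset is assembled from
# precomputed per-block cross-products instead of touching the epoch data,
# and only the eigenvectors above the variance-retention threshold are
# computed (LAPACK dsyevr).  Used by the SFFS criterion and by
# leave-one-block-out cross-validation; results agree with the reference
# path (stack_features / fit_basis / fit_model / estimate_behavior) up to
# numerical round-off because retention is decided by the same rule and
# predictions only depend on the retained subspace.

build_engine <- function(psd, y) {
  stopifnot(inherits(psd, "psd_timeseries"))
  d <- dim(psd$logpower)
  E <- d[1]; n_ch <- d[2]; n_f <- d[3]
  if (length(y) != E) stop("y must have one value per PSD epoch")
  if (anyNA(y)) stop("y contains NA")
  # epochs x (freqs * channels), channel-major blocks, matching stack_features
  Xfull <- matrix(aperm(psd$logpower, c(1L, 3L, 2L)), nrow = E)
  block_ids <- unique(psd$epoch_blocks)
  rows_by_block <- lapply(block_ids, function(b) which(psd$epoch_blocks == b))
  names(rows_by_block) <- as.character(block_ids)
  P <- lapply(rows_by_block, function(r) crossprod(Xfull[r, , drop = FALSE]))
  s <- lapply(rows_by_block, function(r) colSums(Xfull[r, , drop = FALSE]))
  env <- new.env(parent = emptyenv())
  structure(
    list(
      Xfull = Xfull, y = as.numeric(y), times = psd$epoch_times,
      blocks_vec = psd$epoch_blocks, block_ids = block_ids,
      rows_by_block = rows_by_block, P = P, s = s,
      n_ch = n_ch, n_f = n_f, channel_names = psd$channel_names,
      freqs = psd$freqs, cache = env
    ),
    class = "perfspec_engine"
  )
}

engine_cols <- function(engine, ch_idx) {
  as.vector(vapply(ch_idx, function(c) (c - 1L) * engine$n_f + seq_len(engine$n_f),
                   integer(engine$n_f)))
}

# training-set summaries for a block set, memoized
engine_trainset <- function(engine, blocks) {
  key <- paste(sort(blocks), collapse = ",")
  hit <- engine$cache[[key]]
  if (!is.null(hit)) return(hit)
  bidx <- as.character(blocks)
  rows <- sort(unlist(engine$rows_by_block[bidx], use.names = FALSE))
  SP <- Reduce(`+`, engine$P[bidx])
  ssum <- Reduce(`+`, engine$s[bidx])
  n <- length(rows)
  out <- list(rows = rows, SP = SP, mu = ssum / n, n = n,
              Xtrain = engine$Xfull[rows, , drop = FALSE],
              ytrain = engine$y[rows],
              blk = engine$blocks_vec[rows])
  engine$cache[[key]] <- out
  out
}

# PCA (retained eigenbasis) + OLS over a channel subset and block set.
# With `ols = FALSE` only the basis and training projections are computed
# (enough for the cross-validated criterion).
engine_fit <- function(engine, ch_idx, blocks, threshold = 0.01, ols = TRUE) {
  ch_idx <- sort(ch_idx)
  ts <- engine_trainset(engine, blocks)
  idx <- engine_cols(engine, ch_idx)
  mu <- ts$mu[idx]
  C <- (ts$SP[idx, idx] - ts$n * tcrossprod(mu)) / (ts$n - 1)
  total <- sum(diag(C))
  if (total <= 0) stop("zero-variance feature matrix")
  thr <- threshold * total
  ep <- eig_partial(C, thr * (1 - 1e-12))
  V <- ep$vectors
  Z <- ts$Xtrain[, idx, drop = FALSE] %*% V
  Z <- sweep(Z, 2L, drop(crossprod(mu, V)), "-")
  out <- list(
    ch_idx = ch_idx, idx = idx, V = V, lambda = ep$values, total_var = total,
    mu = mu, blocks = sort(blocks), threshold = threshold,
    Z = Z, ytrain = ts$ytrain, blk = ts$blk
  )
  if (ols) {
    fit <- .lm.fit(cbind(1, Z), ts$ytrain)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    out$beta <- beta[-1L]
    out$intercept <- beta[1L]
  }
  out
}

engine_predict <- function(engine, fit, rows) {
  Z <- engine$Xfull[rows, fit$idx, drop = FALSE] %*% fit$V
  Z <- sweep(Z, 2L, drop(crossprod(fit$mu, fit$V)), "-")
  drop(Z %*% fit$beta) + fit$intercept
}

# SFFS criterion: J = 1 / RMSE of the estimate under the chosen
# evaluation protocol on the training blocks.
engine_J <- function(engine, ch_idx, blocks,
                     protocol = c("inner-cv", "inner-cv-refit", "train-fit"),
                     threshold = 0.01, cap = 1e12) {
  protocol <- match.arg(protocol)
  if (length(ch_idx) == 0L) stop("channel subset is empty")
  if (protocol == "inner-cv-refit" && length(blocks) >= 2L) {
    sq <- 0; n_tot <- 0L
    for (b in blocks) {
      f <- engine_fit(engine, ch_idx, setdiff(blocks, b), threshold)
      rows <- engine$rows_by_block[[as.character(b)]]
      pred <- engine_predict(engine, f, rows)
      sq <- sq + sum((engine$y[rows] - pred)^2)
      n_tot <- n_tot + length(rows)
    }
    rmse <- sqrt(sq / n_tot)
  } else {
    f <- engine_fit(engine, ch_idx, blocks, threshold,
                    ols = (protocol == "train-fit" || length(blocks) < 2L))
    if (protocol == "inner-cv" && length(blocks) >= 2L) {
      pred <- rep(NA_real_, length(f$ytrain))
      Z1 <- cbind(1, f$Z)
      for (b in blocks) {
        te <- which(f$blk == b)
        tr <- which(f$blk != b)
        cf <- .lm.fit(Z1[tr, , drop = FALSE], f$ytrain[tr])$coefficients
        cf[is.na(cf)] <- 0
        pred[te] <- drop(Z1[te, , drop = FALSE] %*% cf)
      }
      rmse <- sqrt(mean((f$ytrain - pred)^2))
    } else {
      pred <- drop(cbind(1, f$Z) %*% c(f$intercept, f$beta))
      rmse <- sqrt(mean((f$ytrain - pred)^2))
    }
  }
  if (rmse < 1 / cap) {
    warning("criterion RMSE is zero; returning the configured cap")
    return(cap)
  }
  1 / rmse
}

# public spectral_model from an engine fit (same class as fit_model output)
as_spectral_model <- function(engine, fit, metric = "behavior") {
  channels <- engine$channel_names[fit$ch_idx]
  basis <- structure(
    list(V = fit$V, lambda = fit$lambda,
         shares = fit$lambda / fit$total_var, means = fit$mu,
         threshold = fit$threshold, channels = channels,
         freqs = engine$freqs),
    class = "spectral_basis"
  )
  structure(
    list(basis = basis, beta = fit$beta, intercept = fit$intercept,
         channels = channels, metric = metric),
    class = "spectral_model"
  )
}
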