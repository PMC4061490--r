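#' SFFS criterion function
#'
#' The channel-selection criterion J: one over the root-mean-squared error
#' of the behavioral estimate obtained from the given channel subset.  By
#' default the estimate is cross-validated within the training blocks
#' (leave one training block out for the regression stage), so that J
#' measures out-of-sample error and the floating (backward) steps of SFFS
#' have something to gain by removing channels.
#'
#' @param channels channel labels (nonempty).
#' @param psd a smoothed `psd_timeseries`.
#' @param y behavioral values aligned to the PSD epochs (or a
#'   `behavior_series`).
#' @param train_blocks block ids to evaluate on (default: all).
#' @param protocol `"inner-cv"` (default; PCA basis fit on all training
#'   blocks, regression cross-validated across them), `"inner-cv-refit"`
#'   (basis refit inside every inner fold) or `"train-fit"` (training
#'   error).
#' @param threshold explained-variance retention threshold (default 0.01).
#' @param cap value returned when the RMSE is exactly zero (default 1e12).
#' @param engine optional prebuilt engine (internal use).
#' @return positive scalar J.
#' @export
criterion_J <- function(channels, psd, y, train_blocks = NULL,
                        protocol = "inner-cv", threshold = 0.01,
                        cap = 1e12, engine = NULL) {
  if (is.null(engine)) {
    if (inherits(y, "behavior_series")) y <- align_behavior(y, psd)
    engine <- build_engine(psd, y)
  }
  if (is.null(train_blocks)) train_blocks <- engine$block_ids
  ch_idx <- match(channels, engine$channel_names)
  if (anyNA(ch_idx)) {
    stop(sprintf("unknown channel(s): %s",
                 paste(channels[is.na(ch_idx)], collapse = ", ")))
  }
  engine_J(engine, ch_idx, train_blocks, protocol = protocol,
           threshold = threshold, cap = cap)
}

#' Sequential forward floating selection of EEG channels
#'
#' Greedy channel-subset search maximizing the criterion J: the forward
#' step adds the channel whose inclusion maximizes J; after each addition
#' a conditional backward step removes the least significant channel
#' whenever doing so beats the best J recorded at the smaller subset size,
#' and such exclusions may cascade.  The search stops when the maximum
#' subset size is reached, the candidates are exhausted, or the budget of
#' criterion evaluations is spent.  Evaluated subsets are memoized, and
#' ties are broken toward the earliest channel in the candidate ordering,
#' so the search is deterministic.
#'
#' @param psd a smoothed `psd_timeseries`.
#' @param y behavioral values aligned to the PSD epochs (or a
#'   `behavior_series`).
#' @param candidates candidate channel labels (default: all PSD channels).
#' @param train_blocks block ids to search on (default: all).
#' @param k_max maximum subset size (default 12).
#' @param max_iter budget of (fresh) criterion evaluations (default 500).
#' @param protocol criterion evaluation protocol, see [criterion_J()].
#' @param threshold explained-variance retention threshold.
#' @param engine optional prebuilt engine (internal use).
#' @return An object of class `sffs_result`: `best_subset` (channel
#'   labels), `best_J`, `J_trace` (best J per subset size), `history`
#'   (accepted states), `n_evals`.
#' @export
sffs_select <- function(psd, y, candidates = NULL, train_blocks = NULL,
                        k_max = 12L, max_iter = 500L,
                        protocol = "inner-cv", threshold = 0.01,
                        engine = NULL) {
  if (is.null(engine)) {
    if (inherits(y, "behavior_series")) y <- align_behavior(y, psd)
    engine <- build_engine(psd, y)
  }
  if (is.null(train_blocks)) train_blocks <- engine$block_ids
  if (is.null(candidates)) candidates <- engine$channel_names
  cand_idx <- match(candidates, engine$channel_names)
  if (anyNA(cand_idx)) {
    stop(sprintf("unknown candidate channel(s): %s",
                 paste(candidates[is.na(cand_idx)], collapse = ", ")))
  }
  cand_idx <- sort(cand_idx)
  n_cand <- length(cand_idx)
  if (n_cand == 0L) stop("no candidate channels")
  k_lim <- min(k_max, n_cand)

  st <- new.env(parent = emptyenv())
  st$memo <- new.env(parent = emptyenv())
  st$evals <- 0L
  st$trace <- rep(NA_real_, k_lim)
  st$trace_subsets <- vector("list", k_lim)
  st$best_J <- -Inf
  st$best_subset <- integer(0)
  st$history <- list()

  jfun <- function(subset) {
    key <- paste(subset, collapse = ",")
    hit <- st$memo[[key]]
    if (!is.null(hit)) return(hit)
    if (st$evals >= max_iter) {
      stop(structure(class = c("sffs_budget", "error", "condition"),
                     list(message = "budget", call = NULL)))
    }
    st$evals <- st$evals + 1L
    val <- engine_J(engine, subset, train_blocks, protocol = protocol,
                    threshold = threshold)
    st$memo[[key]] <- val
    val
  }
  record <- function(k, J, subset, action) {
    if (is.na(st$trace[k]) || J > st$trace[k]) {
      st$trace[k] <- J
      st$trace_subsets[[k]] <- subset
    }
    if (J > st$best_J) {
      st$best_J <- J
      st$best_subset <- subset
    }
    st$history[[length(st$history) + 1L]] <-
      data.frame(action = action, k = k, J = J,
                 subset = paste(engine$channel_names[subset], collapse = "+"),
                 stringsAsFactors = FALSE)
  }

  search <- function() {
    X <- integer(0)
    k <- 0L
    repeat {
      if (k >= k_lim) break
      # forward: add the J-maximizing channel
      cand <- setdiff(cand_idx, X)
      scores <- vapply(cand, function(x) jfun(sort(c(X, x))), 0)
      x_new <- cand[which.max(scores)]
      Xk1 <- sort(c(X, x_new))
      record(k + 1L, max(scores), Xk1, "add")
      if (k + 1L <= 1L) { X <- Xk1; k <- 1L; next }
      # conditional backward: is the newcomer the least significant?
      rem_scores <- vapply(Xk1, function(x) jfun(setdiff(Xk1, x)), 0)
      i_new <- match(x_new, Xk1)
      if (rem_scores[i_new] >= max(rem_scores)) {
        X <- Xk1; k <- k + 1L; next
      }
      r <- which.max(rem_scores)
      Xp <- setdiff(Xk1, Xk1[r])
      record(length(Xp), rem_scores[r], Xp, "swap")
      # float down while removing the least significant channel improves
      # on the best recorded J at the smaller size
      repeat {
        if (length(Xp) <= 2L) break
        rs <- vapply(Xp, function(x) jfun(setdiff(Xp, x)), 0)
        s_i <- which.max(rs)
        if (rs[s_i] <= st$trace[length(Xp) - 1L]) break
        Xp <- setdiff(Xp, Xp[s_i])
        record(length(Xp), rs[s_i], Xp, "remove")
      }
      X <- Xp
      k <- length(Xp)
    }
  }
  tryCatch(search(), sffs_budget = function(e) NULL)

  sizes <- which(!is.na(st$trace))
  structure(
    list(
      best_subset = engine$channel_names[st$best_subset],
      best_J = st$best_J,
      J_trace = setNames(st$trace[sizes], sizes),
      trace_subsets = lapply(st$trace_subsets[sizes],
                             function(s) engine$channel_names[s]),
      history = do.call(rbind, st$history),
      n_evals = st$evals
    ),
    class = "sffs_result"
  )
}

#' @export
print.sffs_result <- function(x, ...) {
  cat(sprintf(
    "<sffs_result> best subset (k=%d, J=%.4g): %s; %d criterion evaluations\n",
    length(x$best_subset), x$best_J, paste(x$best_subset, collapse = ", "),
    x$n_evals
  ))
  invisible(x)
}
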