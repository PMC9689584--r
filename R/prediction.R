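#' Extract causal states at given times
#'
#' The causal state of the process at time `t` is the triple
#' `(g, x0, tau0)`: the hidden state active at `t`, the symbol currently
#' being emitted, and the time since the last symbol change.  The hidden
#' state comes from the unifilar decode of the sequence under the fit's
#' topology, with the start state chosen by likelihood under the fit's
#' dwell densities.  The boundary convention is right-continuous: at an
#' event boundary `tau0 = 0` and the new state/symbol are active.
#'
#' @param fit a `ctbsi_fit` (its topology and dwell densities are used for
#'   decoding), or `NULL` when `path` is supplied.
#' @param seq an [event_seq].
#' @param sample_times numeric times in `[0, duration)` of the sequence.
#' @param path optional pre-computed state path for `seq` (skips decoding).
#' @return data frame with columns `g`, `x0`, `tau0` and attribute
#'   `times`.
#' @export
extract_causal_states <- function(fit, seq, sample_times, path = NULL) {
  stopifnot(inherits(seq, "event_seq"))
  sample_times <- as.numeric(sample_times)
  cs <- cumsum(seq$dwell)
  dur <- cs[length(cs)]
  if (any(sample_times < 0 | sample_times >= dur))
    stop("sample times must lie within [0, duration)")
  if (is.null(path)) path <- decode_best_start(fit, seq)
  idx <- findInterval(sample_times, cs) + 1L
  start <- c(0, cs)[idx]
  structure(data.frame(g = path[idx], x0 = seq$symbol[idx],
                       tau0 = sample_times - start,
                       stringsAsFactors = FALSE),
            times = sample_times)
}

# decode with the start state maximizing the dwell log-likelihood under
# the fit's densities; distinguishes the rotations of a cycle that all
# decode the same symbol sequence
decode_best_start <- function(fit, seq) {
  stopifnot(inherits(fit, "ctbsi_fit"))
  top <- fit$model$topology
  starts <- decodable_starts(top, seq)
  if (!length(starts)) stop("sequence does not decode under the fitted topology")
  n <- n_events(seq)
  use <- if (seq_censored(seq)) seq_len(max(n - 1L, 1L)) else seq_len(n)
  best <- NULL
  for (s0 in names(starts)) {
    path <- starts[[s0]]
    ll <- 0
    for (s in top$states) {
      sel <- use[path[use] == s]
      if (length(sel))
        ll <- ll + sum(log(pmax(ddwell(fit$model$dwell[[s]],
                                       seq$dwell[sel]), 1e-300)))
    }
    if (is.null(best) || ll > best$ll) best <- list(ll = ll, path = path)
  }
  best$path
}

#' Prediction datasets
#'
#' Pairs each causal state observed at a sampling time with the real-coded
#' symbol observed a fixed horizon `T` later.  Binary symbols are coded by
#' alphabet order as 0/1 so mean-squared error is well defined.
#'
#' @param states data frame from [extract_causal_states()].
#' @param future numeric vector of future symbol codes, one per row of
#'   `states`.
#' @param horizon the common look-ahead time `T`.
#' @return a data frame of class `prediction_dataset` with columns `g`,
#'   `x0`, `tau0`, `future` and attribute `horizon`.
#' @export
prediction_dataset <- function(states, future, horizon) {
  stopifnot(nrow(states) == length(future), horizon > 0)
  structure(data.frame(states[c("g", "x0", "tau0")], future = future,
                       stringsAsFactors = FALSE),
            horizon = horizon, class = c("prediction_dataset", "data.frame"))
}

symbol_code <- function(symbol, alphabet)
  match(symbol, sort(alphabet)) - 1

symbol_at_times <- function(seq, times) {
  cs <- cumsum(seq$dwell)
  seq$symbol[findInterval(times, cs) + 1L]
}

#' Causal-state k-nearest-neighbor prediction
#'
#' Predicts the symbol a horizon `T` ahead of a query causal state as the
#' average future value of the `k` training records closest in `tau0`,
#' restricted to records whose hidden state `g` and current symbol `x0`
#' match the query exactly.  If fewer than `k` matching records exist all
#' of them are used; if none exist the global mean future value is
#' returned with a warning.  Ties in distance break deterministically
#' (smaller `tau0`, then record order).
#'
#' @param train a [prediction_dataset()].
#' @param query either a single causal state (list or one-row data frame
#'   with `g`, `x0`, `tau0`) or a data frame of them.
#' @param k neighbor count, `>= 1`.
#' @return numeric vector of predicted future values, one per query row.
#' @export
knn_predict <- function(train, query, k) {
  stopifnot(inherits(train, "prediction_dataset"), nrow(train) >= 1, k >= 1)
  if (!is.data.frame(query))
    query <- data.frame(g = query$g, x0 = query$x0, tau0 = query$tau0,
                        stringsAsFactors = FALSE)
  out <- numeric(nrow(query))
  qkey <- paste(query$g, query$x0)
  tkey <- paste(train$g, train$x0)
  global_mean <- mean(train$future)
  n_fallback <- 0L
  for (key in unique(qkey)) {
    qi <- which(qkey == key)
    ti <- which(tkey == key)
    if (!length(ti)) {
      out[qi] <- global_mean
      n_fallback <- n_fallback + length(qi)
      next
    }
    out[qi] <- knn1d_mean(train$tau0[ti], train$future[ti],
                          query$tau0[qi], as.integer(k))
  }
  if (n_fallback > 0)
    warning(sprintf(
      "%d query state(s) had no (g, x0) match in training; returned the global mean",
      n_fallback))
  out
}

#' Evaluate the causal-state predictor against the persistence baseline
#'
#' Simulates independent training and test sequences from `model`, decodes
#' them under `fit`, samples causal states on a uniform grid (spacing one
#' tenth of the smallest mean dwell), and for each horizon compares the
#' mean-squared error of [knn_predict()] with the persistence baseline
#' that forecasts the current symbol unchanged.  `k = "cv"` picks the
#' neighbor count per horizon by 5-fold cross-validation on the training
#' set over a small grid.
#'
#' @param model the generating [uhsmm] (used only to simulate data).
#' @param fit a `ctbsi_fit` used to decode hidden states.
#' @param horizons positive look-ahead times.
#' @param n_train,n_test number of sampled causal states in the training
#'   and test sets.
#' @param k neighbor count or `"cv"`.
#' @param seed optional integer seed.
#' @param spacing sampling-grid spacing; default `min mean dwell / 10`.
#' @return data frame with columns `horizon`, `method` (`"ctbsi"` /
#'   `"persistence"`), `mse`, and `k`.
#' @export
evaluate_predictor <- function(model, fit, horizons, n_train = 5000,
                               n_test = 1000, k = "cv", seed = NULL,
                               spacing = NULL) {
  stopifnot(all(horizons > 0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spacing)) {
    mu <- vapply(model$dwell, dwell_mean, numeric(1))
    spacing <- min(mu) / 10
  }
  Tmax <- max(horizons)
  alphabet <- model$topology$alphabet
  build <- function(n_pts) {
    dur <- n_pts * spacing + Tmax + spacing
    sim <- simulate(model, duration = dur)
    times <- seq(0, by = spacing, length.out = n_pts)
    states <- extract_causal_states(fit, sim$sequence, times)
    list(sim = sim, times = times, states = states)
  }
  tr <- build(n_train)
  te <- build(n_test)
  kgrid <- c(1L, 2L, 5L, 10L, 20L, 50L)
  kgrid <- kgrid[kgrid <= max(1L, floor(n_train / 4))]
  rows <- list()
  for (Th in horizons) {
    f_tr <- symbol_code(symbol_at_times(tr$sim$sequence, tr$times + Th),
                        alphabet)
    f_te <- symbol_code(symbol_at_times(te$sim$sequence, te$times + Th),
                        alphabet)
    train <- prediction_dataset(tr$states, f_tr, Th)
    kk <- if (identical(k, "cv")) cv_choose_k(train, kgrid) else as.integer(k)
    pred <- suppressWarnings(knn_predict(train, te$states, kk))
    mse_ctbsi <- mean((pred - f_te)^2)
    mse_persist <- mean((symbol_code(te$states$x0, alphabet) - f_te)^2)
    rows[[length(rows) + 1]] <- data.frame(
      horizon = Th,
      method = c("ctbsi", "persistence"),
      mse = c(mse_ctbsi, mse_persist),
      k = c(kk, NA_integer_), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

cv_choose_k <- function(train, kgrid, folds = 5L) {
  n <- nrow(train)
  fold <- rep_len(seq_len(folds), n)
  err <- vapply(kgrid, function(kk) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- train[fold != f, , drop = FALSE]
      attr(tr, "horizon") <- attr(train, "horizon")
      class(tr) <- class(train)
      ho <- train[fold == f, , drop = FALSE]
      p <- suppressWarnings(knn_predict(tr, ho, kk))
      se <- se + sum((p - ho$future)^2)
    }
    se / n
  }, numeric(1))
  kgrid[which.min(err)]
}
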