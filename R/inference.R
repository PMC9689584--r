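#' Enumerate candidate binary topologies
#'
#' For a binary alphabet the recurrent unifilar topologies with forced
#' symbol alternation are the even-length single cycles, so the candidate
#' set for model selection is the 2-, 4-, ..., `max_states`-state cycles.
#' Enumeration for larger alphabets is not implemented (the space is much
#' richer and selection over it is a separate problem).
#'
#' @param alphabet two symbols.
#' @param max_states even integer `>= 2`; the largest cycle enumerated.
#' @return list of [uhsmm_topology] objects in increasing size order.
#' @examples
#' length(enumerate_topologies(c("0", "1"), 6))  # 3
#' @export
enumerate_topologies <- function(alphabet, max_states) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) != 2)
    stop("not implemented: topology enumeration is restricted to binary alphabets")
  if (max_states < 2 || max_states %% 2 != 0)
    stop("max_states must be an even integer >= 2")
  lapply(seq(2, max_states, by = 2), cycle_topology, alphabet = sort(alphabet))
}

topology_id <- function(topology)
  sprintf("cycle%d", length(topology$states))

#' Fit one topology to an event sequence by maximum likelihood
#'
#' For every start state from which the symbol sequence decodes, the
#' hidden path is reconstructed (unifilarity makes it unique), the dwells
#' are partitioned by decoded state, each state's dwell density is fitted
#' with [fit_neural_density()], and the emission probabilities are set to
#' their closed-form maximizers, the decoded transition counts
#' \eqn{\hat p(x|s) = n(s', x|s)/n(s)}.  The log-likelihood is
#' \deqn{\log L = \sum_s \sum_j \log \hat\phi_s(\tau_j(s)) +
#'   \sum_{s,x,s'} n(s',x|s) \log \hat p(s',x|s)}
#' and the fit maximizing it over start states is returned (ties break by
#' state-label order).  A censored final dwell is excluded from density
#' fitting and from the likelihood; its symbol still contributes to the
#' emission counts.  The parameter count combines the free emission
#' probabilities with all network weights and biases of the per-state
#' density networks.
#'
#' @param topology a [uhsmm_topology].
#' @param seq an [event_seq].
#' @param density_config a [density_fit_config()].
#' @param min_dwells start states leaving any state with fewer decoded
#'   dwells than this are rejected (too few samples to fit a density).
#' @param dwell `"neural"` (the default, and the parametric family whose
#'   parameter count feeds BIC selection) or `"kernel"` for Parzen dwell
#'   fits — much cheaper, used by the entropy-rate and prediction
#'   pipelines once a topology is already chosen.  With kernel fits
#'   `n_params` counts one bandwidth per state, so cross-topology BIC
#'   comparison is not meaningful.
#' @return an object of class `ctbsi_fit`: the fitted [uhsmm], the chosen
#'   `start_state`, the decoded `state_path`, `log_likelihood`, `n_params`,
#'   `bic`, `n_events` (likelihood-bearing events) and
#'   `dwell_samples` per state.
#' @export
fit_topology <- function(topology, seq, density_config = density_fit_config(),
                         min_dwells = 10L, dwell = c("neural", "kernel")) {
  dwell <- match.arg(dwell)
  stopifnot(inherits(topology, "uhsmm_topology"), inherits(seq, "event_seq"),
            n_events(seq) >= 1)
  starts <- decodable_starts(topology, seq)
  if (!length(starts))
    stop(structure(class = c("ctbsi_incompatible_topology", "error",
                             "condition"),
                   list(message = sprintf(
                     "no start state of %s decodes the sequence",
                     topology_id(topology)), call = sys.call())))
  n <- n_events(seq)
  censored <- seq_censored(seq)
  best <- NULL
  for (s0 in names(starts)) {
    path <- starts[[s0]]
    dwell_idx <- if (censored) seq_len(n - 1L) else seq_len(n)
    samples <- split(seq$dwell[dwell_idx], factor(path[dwell_idx],
                                                  levels = topology$states))
    if (any(vapply(samples, length, integer(1)) < min_dwells)) next
    fit <- tryCatch(
      fit_states(topology, seq, path, samples, density_config, dwell),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$log_likelihood > best$log_likelihood)
      best <- c(fit, list(start_state = s0, state_path = path))
  }
  if (is.null(best))
    stop(structure(class = c("ctbsi_incompatible_topology", "error",
                             "condition"),
                   list(message = sprintf(
                     "every decodable start state of %s leaves a state with fewer than %d dwells",
                     topology_id(topology), min_dwells), call = sys.call())))
  n_lik <- if (censored) n - 1L else n
  best$n_events <- n_lik
  best$bic <- bic_score(best, n_lik)
  structure(best, class = "ctbsi_fit")
}

fit_states <- function(topology, seq, path, samples, density_config,
                       dwell_kind = "neural") {
  states <- topology$states
  # emission counts n(x | s) over all events (the final symbol is fully
  # observed even when its dwell is censored)
  emission_prob <- stats::setNames(vector("list", length(states)), states)
  loglik_emit <- 0
  for (s in states) {
    sel <- path == s
    allowed <- topology$emissions[[s]]
    cnt <- table(factor(seq$symbol[sel], levels = allowed))
    tot <- sum(cnt)
    p <- if (tot > 0) as.numeric(cnt) / tot else
      rep(1 / length(allowed), length(allowed))
    emission_prob[[s]] <- stats::setNames(p, allowed)
    loglik_emit <- loglik_emit + sum(cnt[cnt > 0] * log(p[cnt > 0]))
  }
  dwell <- stats::setNames(vector("list", length(states)), states)
  loglik_dwell <- 0
  for (s in states) {
    dwell[[s]] <- if (dwell_kind == "kernel")
      fit_kernel_density(samples[[s]])
    else
      fit_neural_density(samples[[s]], density_config)
    loglik_dwell <- loglik_dwell +
      sum(log(pmax(ddwell(dwell[[s]], samples[[s]]), 1e-300)))
  }
  n_emis <- sum(vapply(topology$emissions, length, integer(1)) - 1L)
  per_state <- if (dwell_kind == "kernel") 1L else
    nnet_param_count(density_config)
  n_par <- n_emis + length(states) * per_state
  list(model = uhsmm(topology, emission_prob, dwell),
       log_likelihood = loglik_dwell + loglik_emit,
       n_params = n_par,
       dwell_samples = samples)
}

#' @export
print.ctbsi_fit <- function(x, ...) {
  cat("<ctbsi_fit> ", topology_id(x$model$topology), ": start ",
      x$start_state, ", logLik ", format(x$log_likelihood, digits = 8),
      ", k ", x$n_params, ", BIC ", format(x$bic, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Bayesian information criterion of a fit
#'
#' `BIC = (k/2) log n - log L` with natural logarithm, `k` the parameter
#' count and `n` the number of likelihood-bearing events.  (This is half
#' the textbook scaling; the argmin over models is unchanged.)  Smaller is
#' better.
#'
#' @param fit a `ctbsi_fit`, or any list with `n_params` and
#'   `log_likelihood`.
#' @param n_events positive event count.
#' @return scalar BIC value.
#' @export
bic_score <- function(fit, n_events) {
  stopifnot(n_events >= 1)
  fit$n_params / 2 * log(n_events) - fit$log_likelihood
}

#' Select the MAP topology by BIC
#'
#' Fits every candidate topology with [fit_topology()] and returns the fit
#' minimizing BIC together with the full score table.  Candidates that
#' cannot decode the sequence (or cannot populate all their states) are
#' dropped from selection.  Ties break toward the smaller model.
#'
#' @param seq an [event_seq].
#' @param candidates list of [uhsmm_topology] objects, e.g. from
#'   [enumerate_topologies()].
#' @param density_config a [density_fit_config()].
#' @param min_dwells passed to [fit_topology()].
#' @return list with `best` (the winning `ctbsi_fit`) and `table` (a data
#'   frame with columns `topology_id`, `n_states`, `n_params`, `loglik`,
#'   `bic`, `selected`).
#' @export
select_model <- function(seq, candidates,
                         density_config = density_fit_config(),
                         min_dwells = 10L) {
  stopifnot(length(candidates) >= 1)
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    top <- candidates[[i]]
    fit <- tryCatch(
      fit_topology(top, seq, density_config, min_dwells = min_dwells),
      ctbsi_incompatible_topology = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      topology_id = topology_id(top),
      n_states = length(top$states),
      n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
      loglik = if (is.null(fit)) NA_real_ else fit$log_likelihood,
      bic = if (is.null(fit)) NA_real_ else fit$bic,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$bic)))
    stop("no candidate topology is compatible with the sequence")
  best_i <- which(tab$bic == min(tab$bic, na.rm = TRUE))[1] # tie: smaller model
  tab$selected <- seq_len(nrow(tab)) == best_i
  list(best = fits[[best_i]], table = tab)
}
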