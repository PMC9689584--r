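#' Event sequences
#'
#' An `event_seq` stores an observed continuous-time, discrete-event record:
#' an ordered list of (symbol, dwell) pairs, where the dwell is the time the
#' symbol was emitted before the next symbol change.  The final dwell may be
#' censored (the symbol was still being emitted when observation stopped).
#' Consecutive symbols must differ: a "change" to the same symbol is not an
#' observable event in this model class.
#'
#' @param symbol character (or coercible) vector of emitted symbols.
#' @param dwell numeric vector of positive dwell times, in seconds.
#' @param censored logical, is the final dwell censored (observed-so-far)?
#' @return a data frame of class `event_seq` with columns `symbol`, `dwell`
#'   and attribute `censored`.
#' @examples
#' event_seq(c("0", "1", "0"), c(1.2, 0.4, 2.2))
#' @export
event_seq <- function(symbol, dwell, censored = FALSE) {
  symbol <- as.character(symbol)
  dwell <- as.numeric(dwell)
  stopifnot(length(symbol) == length(dwell), length(symbol) >= 1,
            is.logical(censored), length(censored) == 1)
  if (any(!is.finite(dwell)) || any(dwell <= 0))
    stop("all dwell times must be positive and finite")
  if (length(symbol) > 1 && any(symbol[-1] == symbol[-length(symbol)]))
    stop("consecutive symbols must differ")
  structure(data.frame(symbol = symbol, dwell = dwell,
                       stringsAsFactors = FALSE),
            censored = censored, class = c("event_seq", "data.frame"))
}

#' @export
print.event_seq <- function(x, n = 8L, ...) {
  cat("<event_seq> ", nrow(x), " events, duration ",
      format(sum(x$dwell), digits = 6),
      if (isTRUE(attr(x, "censored"))) " (final dwell censored)", "\n",
      sep = "")
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("# ... with", nrow(x) - n, "more events\n")
  invisible(x)
}

n_events <- function(seq) nrow(seq)
seq_censored <- function(seq) isTRUE(attr(seq, "censored"))

#' Machine topologies for unifilar hidden semi-Markov models
#'
#' A topology is the discrete skeleton of a unifilar hidden semi-Markov
#' model: a finite state set, the symbols each state may emit, and a
#' deterministic successor map giving the next state for each (state,
#' emitted symbol) pair.  Unifilarity (the successor being single-valued)
#' is what makes the hidden path decodable from the observations and a
#' start state.
#'
#' @param states character vector of state labels (kept in sorted order).
#' @param alphabet character vector of at least two symbols.
#' @param emissions named list, per state, of the symbols it may emit.
#' @param successor named list of named lists: `successor[[state]][[symbol]]`
#'   is the next state after emitting `symbol` from `state`.
#' @return an object of class `uhsmm_topology`.
#' @examples
#' cycle_topology(4)
#' @export
uhsmm_topology <- function(states, alphabet, emissions, successor) {
  states <- sort(as.character(states))
  alphabet <- sort(as.character(alphabet))
  structure(list(states = states, alphabet = alphabet,
                 emissions = emissions[states],
                 successor = successor[states]),
            class = "uhsmm_topology")
}

#' @export
print.uhsmm_topology <- function(x, ...) {
  cat("<uhsmm_topology> ", length(x$states), " states over {",
      paste(x$alphabet, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Single-cycle binary topology
#'
#' The recurrent unifilar topologies over a binary alphabet are the
#' even-length single cycles with alternating emissions; this constructor
#' builds the cycle with `n_states` states labeled `A`, `B`, ... in cycle
#' order, state `i` emitting `alphabet[1]` when `i` is odd and
#' `alphabet[2]` when even.
#'
#' @param n_states even integer `>= 2`.
#' @param alphabet two symbols, default `c("0", "1")`.
#' @return a `uhsmm_topology`.
#' @export
cycle_topology <- function(n_states, alphabet = c("0", "1")) {
  stopifnot(n_states >= 2, n_states %% 2 == 0, length(alphabet) == 2)
  states <- LETTERS[seq_len(n_states)]
  if (n_states > 26) stop("at most 26 states supported by default labels")
  emissions <- successor <- stats::setNames(vector("list", n_states), states)
  for (i in seq_len(n_states)) {
    sym <- alphabet[(i - 1) %% 2 + 1]
    emissions[[i]] <- sym
    nxt <- states[i %% n_states + 1]
    successor[[i]] <- stats::setNames(list(nxt), sym)
  }
  uhsmm_topology(states, alphabet, emissions, successor)
}

#' Unifilar hidden semi-Markov models
#'
#' Bundles a topology with per-state emission probabilities and per-state
#' dwell-time models into a full generator.  Use [validate_model()] to
#' check the structural constraints and [simulate()] to draw event
#' sequences from it.
#'
#' @param topology a [uhsmm_topology].
#' @param emission_prob named list, per state, of named numeric vectors of
#'   emission probabilities over that state's allowed symbols.  May be
#'   omitted when every state emits a single symbol.
#' @param dwell named list, per state, of [dwell_model] objects.
#' @return an object of class `uhsmm`.
#' @examples
#' top <- cycle_topology(2)
#' m <- uhsmm(top, dwell = list(A = dwell_invgauss(1, 5),
#'                              B = dwell_invgauss(3, 2)))
#' validate_model(m)
#' @export
uhsmm <- function(topology, emission_prob = NULL, dwell) {
  stopifnot(inherits(topology, "uhsmm_topology"))
  if (is.null(emission_prob)) {
    emission_prob <- lapply(topology$emissions, function(sym) {
      stats::setNames(rep(1 / length(sym), length(sym)), sym)
    })
  }
  structure(list(topology = topology,
                 emission_prob = emission_prob[topology$states],
                 dwell = dwell[topology$states]),
            class = "uhsmm")
}

#' @export
print.uhsmm <- function(x, ...) {
  cat("<uhsmm> ", length(x$topology$states), " states over {",
      paste(x$topology$alphabet, collapse = ","), "}\n", sep = "")
  for (s in x$topology$states) {
    cat("  ", s, ": emits {",
        paste(names(x$emission_prob[[s]]), collapse = ","),
        "}, dwell ", x$dwell[[s]]$kind, " (mean ",
        format(dwell_mean(x$dwell[[s]]), digits = 4), ")\n", sep = "")
  }
  invisible(x)
}

# states reachable from `from` under the successor map
reachable_states <- function(topology, from) {
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(s)
      unlist(topology$successor[[s]], use.names = FALSE))))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  seen
}

#' Validate a model's structural constraints
#'
#' Checks every structural invariant of the model class and returns a
#' character vector describing each violation (empty when the model is
#' valid).  Checked: the alphabet has at least two symbols; the successor
#' map is defined exactly on each state's allowed emissions; no state can
#' be followed by a state allowed to re-emit the same symbol (which would
#' make a symbol change unobservable); every state is reachable from every
#' other (recurrence, needed for stationarity); emission probabilities are
#' nonnegative, supported on allowed symbols, and sum to one.
#'
#' @param model a [uhsmm] (or a bare [uhsmm_topology], in which case only
#'   topological constraints are checked).
#' @return character vector of violation descriptions; `character(0)` if
#'   the model is valid.  Never raises.
#' @export
validate_model <- function(model) {
  top <- if (inherits(model, "uhsmm_topology")) model else model$topology
  out <- character(0)
  if (length(top$alphabet) < 2)
    out <- c(out, "alphabet must have at least 2 symbols")
  for (s in top$states) {
    em <- top$emissions[[s]]
    succ <- top$successor[[s]]
    if (!setequal(names(succ), em))
      out <- c(out, sprintf(
        "state %s: successor map domain {%s} != allowed emissions {%s}",
        s, paste(names(succ), collapse = ","), paste(em, collapse = ",")))
    for (x in intersect(names(succ), em)) {
      nxt <- succ[[x]]
      if (!nxt %in% top$states) {
        out <- c(out, sprintf("state %s: successor for symbol %s is unknown state %s",
                              s, x, nxt))
      } else if (x %in% top$emissions[[nxt]]) {
        out <- c(out, sprintf(
          "state %s: symbol %s is still an allowed emission of its successor %s (consecutive symbols could repeat)",
          s, x, nxt))
      }
    }
  }
  for (s in top$states) {
    r <- reachable_states(top, s)
    miss <- setdiff(top$states, r)
    if (length(miss))
      out <- c(out, sprintf("states {%s} are unreachable from state %s",
                            paste(miss, collapse = ","), s))
  }
  if (inherits(model, "uhsmm")) {
    for (s in top$states) {
      p <- model$emission_prob[[s]]
      if (is.null(p)) {
        out <- c(out, sprintf("state %s: missing emission probabilities", s))
        next
      }
      if (any(p < 0))
        out <- c(out, sprintf("state %s: negative emission probability", s))
      if (abs(sum(p) - 1) > 1e-9)
        out <- c(out, sprintf(
          "state %s: emission probabilities sum to %.6g, not 1", s, sum(p)))
      bad <- setdiff(names(p)[p > 0], top$emissions[[s]])
      if (length(bad))
        out <- c(out, sprintf(
          "state %s: positive probability on disallowed symbol(s) %s",
          s, paste(bad, collapse = ",")))
      if (is.null(model$dwell[[s]]) || !inherits(model$dwell[[s]], "dwell_model"))
        out <- c(out, sprintf("state %s: missing dwell model", s))
    }
  }
  out
}

# stationary distribution of the embedded (per-event) state chain; used to
# start simulations so that event statistics are stationary from event 0.
embedded_stationary <- function(model) {
  top <- model$topology
  n <- length(top$states)
  P <- matrix(0, n, n, dimnames = list(top$states, top$states))
  for (s in top$states)
    for (x in names(model$emission_prob[[s]])) {
      nxt <- top$successor[[s]][[x]]
      P[s, nxt] <- P[s, nxt] + model$emission_prob[[s]][[x]]
    }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  stats::setNames(v / sum(v), top$states)
}

#' Simulate an event sequence from a model
#'
#' Draws from the generative procedure of the model class: starting from a
#' hidden state drawn from the stationary distribution of the embedded
#' per-event state chain (uniform on a deterministic cycle), repeatedly
#' draw a dwell from the state's dwell model and a symbol from its emission
#' probabilities, emit the symbol for the dwell, and move to the successor
#' state.  With `nsim` the sequence has exactly `nsim` fully observed
#' events; with `duration` the sequence is truncated at the time horizon
#' and the final dwell is marked censored.
#'
#' @param object a valid [uhsmm].
#' @param nsim number of events to generate (ignored when `duration` is
#'   given).
#' @param seed integer seed; if non-`NULL`, set before drawing.
#' @param duration positive time horizon; the final event is truncated at
#'   the boundary and flagged censored.
#' @param start_state optional fixed start state (default: stationary draw).
#' @param ... unused.
#' @return a list with components `sequence` (an [event_seq]) and `states`
#'   (the hidden state active during each event).
#' @examples
#' m <- uhsmm(cycle_topology(2),
#'            dwell = list(A = dwell_invgauss(1, 5), B = dwell_invgauss(3, 2)))
#' simulate(m, nsim = 5, seed = 1)$sequence
#' @export
simulate.uhsmm <- function(object, nsim = NULL, seed = NULL, duration = NULL,
                           start_state = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) {
    if (is.null(nsim) || nsim < 1) stop("nsim must be a positive integer")
  } else if (duration <= 0) stop("duration must be positive")
  top <- object$topology
  g <- if (is.null(start_state)) {
    pi0 <- embedded_stationary(object)
    sample(top$states, 1, prob = pi0)
  } else {
    stopifnot(start_state %in% top$states)
    start_state
  }
  cap <- if (is.null(duration)) nsim else max(16L, ceiling(duration * 4))
  sym <- character(cap); dw <- numeric(cap); st <- character(cap)
  i <- 0L; total <- 0; censored <- FALSE
  repeat {
    tau <- rdwell(object$dwell[[g]], 1)
    p <- object$emission_prob[[g]]
    x <- if (length(p) == 1) names(p) else sample(names(p), 1, prob = p)
    i <- i + 1L
    if (i > length(sym)) { # grow buffers
      sym <- c(sym, character(length(sym)))
      dw <- c(dw, numeric(length(dw)))
      st <- c(st, character(length(st)))
    }
    sym[i] <- x; st[i] <- g
    if (!is.null(duration) && total + tau >= duration) {
      dw[i] <- duration - total
      censored <- TRUE
      break
    }
    dw[i] <- tau; total <- total + tau
    g <- top$successor[[g]][[x]]
    if (is.null(duration) && i >= nsim) break
  }
  keep <- seq_len(i)
  list(sequence = event_seq(sym[keep], dw[keep], censored = censored),
       states = st[keep])
}

#' Decode the hidden state path of an event sequence
#'
#' By unifilarity, the observed symbols plus a start state determine the
#' hidden path uniquely: the state of event `i + 1` is the successor of the
#' state of event `i` under the emitted symbol.  If an observed symbol is
#' not an allowed emission of the current decoded state, decoding fails;
#' the error condition (class `ctbsi_decode_error`) carries the index of
#' the offending event in its `$index` field.
#'
#' @param topology a [uhsmm_topology].
#' @param seq an [event_seq].
#' @param start_state the state emitting the first event.
#' @return character vector of hidden states, one per event.
#' @export
decode_states <- function(topology, seq, start_state) {
  stopifnot(inherits(topology, "uhsmm_topology"), start_state %in% topology$states)
  n <- n_events(seq)
  path <- character(n)
  g <- start_state
  for (i in seq_len(n)) {
    x <- seq$symbol[i]
    if (!x %in% topology$emissions[[g]]) {
      cond <- structure(class = c("ctbsi_decode_error", "error", "condition"),
                        list(message = sprintf(
                          "symbol %s at event %d is not an allowed emission of state %s",
                          x, i, g), call = sys.call(-1), index = i))
      stop(cond)
    }
    path[i] <- g
    g <- topology$successor[[g]][[x]]
  }
  path
}

# all start states from which `seq` decodes, with their paths
decodable_starts <- function(topology, seq) {
  out <- list()
  for (s in topology$states) {
    p <- tryCatch(decode_states(topology, seq, s),
                  ctbsi_decode_error = function(e) NULL)
    if (!is.null(p)) out[[s]] <- p
  }
  out
}

#' Stationary state weights from mean dwells and transition statistics
#'
#' Solves the linear system
#' \deqn{p(s) = \sum_{s'} \frac{\mu_{s'}}{\mu_s}
#'   \frac{n_{s' \to s}}{n_{s'}} p(s'), \qquad \sum_s p(s) = 1,}
#' where \eqn{\mu_s} is the mean dwell of state \eqn{s} and
#' \eqn{n_{s' \to s}/n_{s'}} the (empirical or exact) probability of the
#' transition \eqn{s' \to s}.  These are the state weights used by the
#' plug-in entropy-rate formula; for a deterministic cycle they are
#' proportional to \eqn{1/\mu_s}.
#'
#' @param mu named numeric vector of positive mean dwells per state, or a
#'   [uhsmm] (in which case `transitions` is derived from the model).
#' @param transitions square matrix of transition counts or probabilities,
#'   rows = from-state, columns = to-state, with dimnames matching
#'   `names(mu)`.
#' @return named numeric vector: nonnegative weights summing to one.
#' @examples
#' m <- uhsmm(cycle_topology(4),
#'            dwell = list(A = dwell_invgauss(1, 5), B = dwell_invgauss(3, 2),
#'                         C = dwell_invgauss(3, 2), D = dwell_invgauss(1, 5)))
#' stationary_distribution(m)  # (0.375, 0.125, 0.125, 0.375)
#' @export
stationary_distribution <- function(mu, transitions = NULL) {
  if (inherits(mu, "uhsmm")) {
    model <- mu
    top <- model$topology
    states <- top$states
    mu <- vapply(model$dwell, dwell_mean, numeric(1))[states]
    transitions <- matrix(0, length(states), length(states),
                          dimnames = list(states, states))
    for (s in states)
      for (x in names(model$emission_prob[[s]]))
        transitions[s, top$successor[[s]][[x]]] <-
          transitions[s, top$successor[[s]][[x]]] +
          model$emission_prob[[s]][[x]]
  }
  states <- names(mu)
  stopifnot(!is.null(states), all(mu > 0), is.matrix(transitions),
            identical(rownames(transitions), states),
            identical(colnames(transitions), states))
  P <- transitions / rowSums(transitions)  # counts -> probabilities
  n <- length(states)
  # reachability check on the transition graph
  adj <- P > 0
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE; frontier <- s
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE; frontier <- nxt
    }
    if (!all(seen))
      stop(sprintf("transition structure is reducible: states {%s} unreachable from %s",
                   paste(states[!seen], collapse = ","), states[s]))
  }
  if (n == 1) return(stats::setNames(1, states))
  # p = M p with M[s, s'] = (mu_s'/mu_s) P[s' -> s]
  M <- t(P) * outer(1 / mu, mu)
  A <- M - diag(n)
  A[n, ] <- 1  # replace one redundant row with the normalization
  b <- c(rep(0, n - 1), 1)
  p <- solve(A, b)
  p[p < 0 & p > -1e-12] <- 0
  stats::setNames(p, states)
}

#' Exact differential entropy rate of a model
#'
#' Evaluates the plug-in entropy-rate formula with the model's own dwell
#' densities:
#' \deqn{h_\mu = -\sum_s p(s) \int_0^\infty \mu_s\, \phi_s(t) \log
#'   \phi_s(t)\, dt,}
#' with state weights \eqn{p(s)} from [stationary_distribution()] and mean
#' dwells \eqn{\mu_s = \int t \phi_s(t) dt}.  Integrals use adaptive
#' quadrature on each density's support (the result is stable to better
#' than `1e-3` under grid refinement for the parametric families shipped
#' here).  Note the formula's convention: the mean dwell multiplies the
#' integrand and the state weights are the dwell-weighted solution of the
#' linear system above, so the result is in nats; see the methods vignette
#' for a discussion of this convention.
#'
#' @param model a valid [uhsmm].
#' @param rel.tol quadrature relative tolerance.
#' @return entropy rate in nats.
#' @examples
#' m <- uhsmm(cycle_topology(4),
#'            dwell = list(A = dwell_invgauss(1, 5), B = dwell_invgauss(3, 2),
#'                         C = dwell_invgauss(3, 2), D = dwell_invgauss(1, 5)))
#' entropy_rate_exact(m)  # 1.85
#' @export
entropy_rate_exact <- function(model, rel.tol = 1e-9) {
  bad <- validate_model(model)
  if (length(bad)) stop("invalid model: ", paste(bad, collapse = "; "))
  states <- model$topology$states
  mu <- vapply(model$dwell, dwell_mean, numeric(1))[states]
  p <- stationary_distribution(model)
  H <- vapply(states, function(s) {
    h <- tryCatch(dwell_entropy(model$dwell[[s]], rel.tol = rel.tol),
                  error = function(e)
                    stop(sprintf("dwell entropy integral failed for state %s: %s",
                                 s, conditionMessage(e))))
    if (!is.finite(h))
      stop(sprintf("dwell entropy is not finite for state %s", s))
    h
  }, numeric(1))
  sum(p * mu * H)
}
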