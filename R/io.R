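#' Read and write event sequences as TSV
#'
#' The on-disk dialect is a two-column tab-separated file with header
#' `symbol<TAB>dwell`, one event per row with the dwell in seconds, and an
#' optional final comment line `# censored` marking the last dwell as
#' observed-so-far.  The reader enforces the invariants of [event_seq()]:
#' positive dwells and no repeated consecutive symbols.
#'
#' @param path file path.
#' @param seq an [event_seq].
#' @return `read_events` returns an [event_seq]; `write_events` returns
#'   `path`, invisibly.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  censored <- FALSE
  cm <- grepl("^#", lines)
  if (any(cm)) {
    censored <- any(grepl("^#\\s*censored\\s*$", lines[cm]))
    lines <- lines[!cm]
  }
  if (length(lines) < 2) stop("no events in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("symbol", "dwell")))
    stop("expected header 'symbol\\tdwell' in ", path)
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed event row in ", path)
  sym <- vapply(parts, `[`, character(1), 1)
  dw <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(dw)) stop("non-numeric dwell in ", path)
  event_seq(sym, dw, censored = censored)
}

#' @rdname read_events
#' @export
write_events <- function(seq, path) {
  stopifnot(inherits(seq, "event_seq"))
  lines <- c("symbol\tdwell",
             sprintf("%s\t%s", seq$symbol,
                     formatC(seq$dwell, digits = 17, format = "g")))
  if (seq_censored(seq)) lines <- c(lines, "# censored")
  writeLines(lines, path)
  invisible(path)
}

dwell_to_json <- function(d) {
  switch(d$kind,
    invgauss = list(kind = "invgauss", mu = d$mu, lambda = d$lambda),
    exponential = list(kind = "exponential", rate = d$rate),
    uniform = list(kind = "uniform", lo = d$lo, hi = d$hi),
    mixture = list(kind = "mixture", weights = d$weights,
                   components = lapply(d$components, dwell_to_json)),
    kernel = list(kind = "kernel", samples = d$samples, h = d$h),
    knn = list(kind = "knn", samples = d$samples, k = d$k),
    neural = list(kind = "neural", params = d$params, support = d$support,
                  log_mean = d$log_mean, log_sd = d$log_sd,
                  norm_const = d$norm_const),
    stop("cannot serialize dwell kind ", d$kind))
}

dwell_from_json <- function(j) {
  switch(j$kind,
    invgauss = dwell_invgauss(j$mu, j$lambda),
    exponential = dwell_exponential(j$rate),
    uniform = dwell_uniform(j$lo, j$hi),
    mixture = dwell_mixture(unlist(j$weights),
                            lapply(j$components, dwell_from_json)),
    kernel = dwell_kernel(unlist(j$samples), j$h),
    knn = dwell_knn(unlist(j$samples), j$k),
    neural = new_dwell("neural", list(
      params = list(W = lapply(j$params$W, function(w) as.numeric(unlist(w))),
                    b = lapply(j$params$b, function(b) as.numeric(unlist(b))),
                    u = as.numeric(unlist(j$params$u)),
                    c = as.numeric(unlist(j$params$c))),
      support = as.numeric(unlist(j$support)),
      log_mean = j$log_mean, log_sd = j$log_sd,
      norm_const = j$norm_const)),
    stop("unknown dwell kind ", j$kind))
}

#' Read and write model specifications as JSON
#'
#' Serializes a [uhsmm] (states, alphabet, allowed emissions, successor
#' map, emission probabilities, and per-state dwell models) to a JSON
#' document.  Parametric dwell kinds round-trip bit-exactly; the neural
#' kind stores its weights and support.
#'
#' @param model a [uhsmm].
#' @param path file path.
#' @return `read_model` returns a [uhsmm]; `write_model` returns `path`,
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "uhsmm"))
  top <- model$topology
  doc <- list(states = top$states, alphabet = top$alphabet,
              allowed_emissions = top$emissions,
              successor = top$successor,
              emission_prob = lapply(model$emission_prob, as.list),
              dwell = lapply(model$dwell, dwell_to_json))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  states <- unlist(doc$states)
  top <- uhsmm_topology(
    states = states, alphabet = unlist(doc$alphabet),
    emissions = lapply(doc$allowed_emissions, function(e) unlist(e)),
    successor = lapply(doc$successor, function(s) lapply(s, unlist)))
  emission_prob <- lapply(doc$emission_prob, function(p)
    stats::setNames(as.numeric(unlist(p)), names(p)))
  dwell <- lapply(doc$dwell, dwell_from_json)
  uhsmm(top, emission_prob, dwell)
}
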