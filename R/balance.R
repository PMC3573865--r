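#' State of a primer-concentration balancing round
#'
#' Couples the current per-target primer-pair concentrations with the signal
#' summary observed when every target receives the same number of
#' standardised template copies. The balancing rule then nudges
#' concentrations in fixed increments (default 0.1 uM) until all signals sit
#' within a relative band around the panel median.
#'
#' @param concentrations named numeric vector, uM per target.
#' @param signals named numeric vector of summary RFU per target (same names
#'   as `concentrations`), or `NULL` before the first measurement.
#' @param tolerance half-width of the acceptance band as a fraction of the
#'   median signal (in (0, 1)).
#' @param step concentration increment, uM (> 0).
#' @param bounds c(min, max) admissible concentration, uM.
#' @return object of class `balance_state`.
#' @export
balance_state <- function(concentrations, signals = NULL, tolerance = 0.25,
                          step = 0.1, bounds = c(0.1, 1.0)) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)),
            all(nzchar(names(concentrations))),
            tolerance > 0, tolerance < 1, step > 0,
            length(bounds) == 2L, bounds[1] < bounds[2])
  if (any(concentrations < bounds[1] - 1e-12) ||
      any(concentrations > bounds[2] + 1e-12)) {
    stop("concentrations must lie within bounds", call. = FALSE)
  }
  if (!is.null(signals)) {
    if (!setequal(names(signals), names(concentrations))) {
      stop("signals and concentrations must cover the same targets",
           call. = FALSE)
    }
    signals <- signals[names(concentrations)]
  }
  structure(list(concentrations = concentrations, signals = signals,
                 tolerance = tolerance, step = step, bounds = bounds),
            class = "balance_state")
}

signal_band <- function(state) {
  m <- stats::median(state$signals)
  c(lower = m * (1 - state$tolerance), median = m,
    upper = m * (1 + state$tolerance))
}

#' Is the multiplex panel balanced?
#'
#' @param state a [balance_state()] with signals present.
#' @return `TRUE` iff every target's summary RFU lies within
#'   `median * (1 +/- tolerance)` (closed band).
#' @export
is_balanced <- function(state) {
  stopifnot(inherits(state, "balance_state"))
  if (is.null(state$signals)) stop("no signals in state", call. = FALSE)
  b <- signal_band(state)
  all(state$signals >= b[["lower"]] & state$signals <= b[["upper"]])
}

#' Propose the next primer-concentration adjustment
#'
#' Applies the stepwise balancing rule: pairs whose signal exceeds the upper
#' band edge lose one `step` of concentration, pairs below the lower edge
#' gain one, everything else is left alone. Results are clamped to the
#' admissible bounds and every move (and clamp) is logged. The rule is
#' idempotent once [is_balanced()] holds.
#'
#' @param state a [balance_state()] with signals present.
#' @return list with `state` (the updated [balance_state()], signals cleared
#'   since they must be re-measured) and `changes` (data frame: `target`,
#'   `signal`, `old_uM`, `new_uM`, `action` in up/down/hold, `clamped`).
#' @export
propose_adjustment <- function(state) {
  stopifnot(inherits(state, "balance_state"))
  if (is.null(state$signals)) stop("no signals in state", call. = FALSE)
  b <- signal_band(state)
  conc <- state$concentrations
  action <- ifelse(state$signals > b[["upper"]], "down",
                   ifelse(state$signals < b[["lower"]], "up", "hold"))
  raw <- conc + state$step * ((action == "up") - (action == "down"))
  new <- pmin(pmax(raw, state$bounds[1]), state$bounds[2])
  changes <- data.frame(
    target = names(conc), signal = unname(state$signals),
    old_uM = unname(conc), new_uM = unname(new), action = unname(action),
    clamped = unname(abs(new - raw) > 1e-12),
    stringsAsFactors = FALSE)
  list(state = balance_state(new, NULL, state$tolerance, state$step,
                             state$bounds),
       changes = changes)
}

#' Iterate the balancing rule against a response model until balanced
#'
#' Repeatedly measures signals through `response`, checks [is_balanced()],
#' and applies [propose_adjustment()]. Stops on balance, on revisiting a
#' previously seen concentration vector (a limit cycle: surfaced, never
#' silent), or on hitting the iteration bound
#' `(bounds[2] - bounds[1]) / step * n_targets` (each target can only
#' traverse the admissible range so many times in a contractive run).
#'
#' @param concentrations named numeric start vector, uM.
#' @param response function mapping a named concentration vector to a named
#'   vector of summary RFU (e.g. a wet-lab round, or a toy model in tests).
#' @param tolerance,step,bounds see [balance_state()].
#' @param max_iter iteration bound; default as above.
#' @return list: `state` (final [balance_state()] incl. last signals),
#'   `balanced` (logical), `oscillation` (logical), `iterations`, `history`
#'   (data frame of concentrations per iteration).
#' @export
balance_until_stable <- function(concentrations, response, tolerance = 0.25,
                                 step = 0.1, bounds = c(0.1, 1.0),
                                 max_iter = NULL) {
  if (is.null(max_iter)) {
    max_iter <- ceiling((bounds[2] - bounds[1]) / step *
                          length(concentrations))
  }
  seen <- character(0)
  hist <- list()
  conc <- concentrations
  for (it in seq_len(max_iter)) {
    key <- paste(sprintf("%.6f", conc), collapse = ",")
    sig <- response(conc)
    state <- balance_state(conc, sig, tolerance, step, bounds)
    hist[[it]] <- data.frame(iteration = it, target = names(conc),
                             conc_uM = unname(conc), rfu = unname(sig[names(conc)]),
                             stringsAsFactors = FALSE)
    if (is_balanced(state)) {
      return(list(state = state, balanced = TRUE, oscillation = FALSE,
                  iterations = it, history = do.call(rbind, hist)))
    }
    if (key %in% seen) {
      warning("balancing entered a limit cycle without reaching balance",
              call. = FALSE)
      return(list(state = state, balanced = FALSE, oscillation = TRUE,
                  iterations = it, history = do.call(rbind, hist)))
    }
    seen <- c(seen, key)
    conc <- propose_adjustment(state)$state$concentrations
  }
  state <- balance_state(conc, response(conc), tolerance, step, bounds)
  list(state = state, balanced = is_balanced(state), oscillation = FALSE,
       iterations = max_iter, history = do.call(rbind, hist))
}
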