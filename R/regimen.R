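#' Dosing events and regimens
#'
#' A dose event is one oral administration (or train of administrations) of
#' venlafaxine hydrochloride.  Amounts are in mg of the labeled dose.
#' Repeated dosing is encoded NONMEM-style: `interdose_interval` (II) with
#' `n_additional_doses` (ADDL) extra doses, or a steady-state flag (SS)
#' meaning the train has run to steady state before `time`.
#'
#' A steady-state event resets the system: predictions after it are governed
#' by that established train (plus any later plain doses), not by earlier
#' history.  This matches the usual event-record semantics for
#' therapeutic-drug-monitoring records.
#'
#' @param time dosing time (h, relative to the subject's first record).
#' @param amount dose amount (mg); must be positive.
#' @param interdose_interval interval between doses in a train (h); 0 for a
#'   single dose.
#' @param n_additional_doses number of additional doses after the first.
#' @param steady_state logical; `TRUE` if the train is at steady state.
#' @return A one-row `data.frame` with class `dose_event`.
#' @export
dose_event <- function(time, amount, interdose_interval = 0,
                       n_additional_doses = 0, steady_state = FALSE) {
  if (!is.finite(amount) || amount <= 0)
    stop("dose amount must be positive", call. = FALSE)
  if (!is.finite(time) || time < 0)
    stop("dose time must be nonnegative", call. = FALSE)
  if ((n_additional_doses > 0 || steady_state) && interdose_interval <= 0)
    stop("interdose_interval must be positive for repeated or steady-state dosing",
         call. = FALSE)
  structure(data.frame(time = time, amt = amount, ii = interdose_interval,
                       addl = as.integer(n_additional_doses),
                       ss = as.integer(steady_state)),
            class = c("dose_event", "data.frame"))
}

#' Assemble a dosing regimen
#'
#' @param ... [dose_event()] objects (or data frames with the same columns).
#' @return A `pk_regimen` data frame with events ordered by time.
#' @export
pk_regimen <- function(...) {
  ev <- list(...)
  if (length(ev) == 0) stop("a regimen needs at least one dose event", call. = FALSE)
  reg <- do.call(rbind, lapply(ev, as.data.frame))
  if (is.unsorted(reg$time)) reg <- reg[order(reg$time), , drop = FALSE]
  rownames(reg) <- NULL
  structure(reg, class = c("pk_regimen", "data.frame"))
}

.regimen_matrix <- function(regimen) {
  reg <- as.data.frame(regimen)
  as.matrix(reg[, c("time", "amt", "ii", "addl", "ss")])
}

# expand a regimen into individual administration times/amounts
# (steady-state events cannot be expanded; used by the ODE path)
.expand_doses <- function(regimen) {
  reg <- as.data.frame(regimen)
  if (any(reg$ss > 0))
    stop("steady-state events cannot be expanded into discrete doses; use the closed-form predictor",
         call. = FALSE)
  out <- lapply(seq_len(nrow(reg)), function(i) {
    k <- 0:reg$addl[i]
    data.frame(time = reg$time[i] + k * reg$ii[i], amt = reg$amt[i])
  })
  out <- do.call(rbind, out)
  out[order(out$time), , drop = FALSE]
}
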