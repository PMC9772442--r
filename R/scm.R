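#' Stepwise covariate modeling
#'
#' Forward inclusion / backward elimination of covariate-parameter
#' relations by likelihood-ratio thresholds on the FOCEI objective:
#' a candidate enters the model if it lowers the objective by strictly
#' more than 6.63 points (chi-square, p < 0.01, 1 df) and survives
#' backward elimination if removing it raises the objective by strictly
#' more than 10.83 points (p < 0.001).  Ties between equally good
#' candidates are broken lexicographically on (parameter, covariate) so
#' the search is fully deterministic.
#'
#' @name scm
NULL

.default_cand_covs <- c("morbid", "form", "sex", "age", "wt", "smok",
                        "drink", "vpa", "qtp", "clz", "olz", "ris", "ami")
.continuous_covs <- c("age", "wt", "alt", "ast", "bun", "cr")

#' Default candidate grid for covariate search
#'
#' All combinations of {health status, formulation, sex, age, weight,
#' smoking, drinking, six comedications} with the four disposition
#' parameters (`cl_f`, `v_f`, `clm_f`, `vm_f`), minus structurally
#' confounded pairs: morbid state is only tested on the VEN parameters,
#' because the healthy arm contributes no metabolite observations and a
#' morbid effect on an ODV parameter would be confounded with the
#' parameter itself.  Age and weight use the power form referenced to the
#' pooled median; categorical covariates use the linear-fraction form.
#'
#' @param dataset dataset used to compute reference medians for the
#'   continuous covariates.
#' @param covariates covariate names to consider.
#' @param parameters target parameters to consider.
#' @return A list of [covariate_effect()] candidates (theta = 0).
#' @export
default_candidate_grid <- function(dataset,
                                   covariates = .default_cand_covs,
                                   parameters = c("cl_f", "v_f", "clm_f",
                                                  "vm_f")) {
  stopifnot(inherits(dataset, "pk_dataset"))
  rec <- dataset$records
  out <- list()
  for (cv in covariates) {
    for (pm in parameters) {
      if (cv == "morbid" && pm %in% c("clm_f", "vm_f")) next
      if (cv %in% .continuous_covs) {
        ref <- median(rec[[toupper(cv)]][!duplicated(rec$ID)])
        out[[length(out) + 1]] <-
          covariate_effect(pm, cv, "power", theta = 0, ref = ref)
      } else {
        out[[length(out) + 1]] <-
          covariate_effect(pm, cv, "linear", theta = 0)
      }
    }
  }
  out
}

.cand_label <- function(e) paste0(e$covariate, "->", e$parameter)

.trace_row <- function(step, candidate, ofv_ref, ofv_cand, delta, decision) {
  data.frame(step = step, candidate = candidate, ofv_reference = ofv_ref,
             ofv_candidate = ofv_cand, delta_ofv = delta,
             decision = decision, stringsAsFactors = FALSE)
}

.same_effect <- function(a, b) {
  a$parameter == b$parameter && a$covariate == b$covariate
}

#' One forward-inclusion step
#'
#' Fits every candidate added to the base model and accepts the candidate
#' with the largest objective drop, provided the drop is strictly greater
#' than `threshold` (6.63 by default).  Candidates whose fit fails are
#' skipped with a warning and recorded in the trace.
#'
#' @param dataset a `pk_dataset`.
#' @param base_fit a [focei_fit()] of the current model.
#' @param candidates list of [covariate_effect()] candidates.
#' @param threshold forward inclusion threshold on the OFV drop.
#' @param control a [focei_control()] (screening fits default to the fast
#'   profile).
#' @param fitter fitting backend, `function(dataset, model, control, start)`
#'   returning a [focei_fit()]-like object; replaceable for testing.
#' @return A list: `accepted` (the winning candidate or `NULL`), `fit`
#'   (fit of the enlarged model, or `NULL`), `trace` (data frame).
#' @export
forward_step <- function(dataset, base_fit, candidates, threshold = 6.63,
                         control = focei_control(fast = TRUE),
                         fitter = focei_fit) {
  stopifnot(inherits(base_fit, "focei_fit"))
  trace <- NULL
  fits <- vector("list", length(candidates))
  deltas <- rep(-Inf, length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    m <- base_fit$model
    m$effects <- c(m$effects, list(cand))
    fit_i <- tryCatch(fitter(dataset, m, control = control,
                             start = base_fit),
                      error = function(e) e)
    if (inherits(fit_i, "error")) {
      warning("candidate ", .cand_label(cand), " failed to fit: ",
              conditionMessage(fit_i), call. = FALSE)
      trace <- rbind(trace, .trace_row("forward", .cand_label(cand),
                                       base_fit$ofv, NA, NA, "fit-failed"))
      next
    }
    fits[[i]] <- fit_i
    deltas[i] <- base_fit$ofv - fit_i$ofv
    trace <- rbind(trace, .trace_row("forward", .cand_label(cand),
                                     base_fit$ofv, fit_i$ofv, deltas[i],
                                     "tested"))
  }
  ok <- which(deltas > threshold)
  if (length(ok) == 0)
    return(list(accepted = NULL, fit = NULL, trace = trace))
  # largest drop wins; ties broken lexicographically on (parameter, covariate)
  keys <- vapply(candidates, function(e) paste(e$parameter, e$covariate), "")
  best <- ok[order(-deltas[ok], keys[ok])][1]
  trace$decision[trace$candidate == .cand_label(candidates[[best]])] <- "accepted"
  list(accepted = candidates[[best]], fit = fits[[best]], trace = trace)
}

#' One round of backward elimination
#'
#' Each covariate effect of the full model is removed in turn and the
#' model refitted; the effect whose removal raises the objective the
#' least is dropped if that rise is not strictly greater than `threshold`
#' (10.83 by default).  Repeats until every remaining effect is supported.
#'
#' @param dataset a `pk_dataset`.
#' @param full_fit a [focei_fit()] of the full (post-forward) model.
#' @param threshold backward retention threshold on the OFV rise.
#' @param control a [focei_control()].
#' @param fitter fitting backend, replaceable for testing.
#' @param removable labels (`"covariate->parameter"`) of the effects subject
#'   to elimination; `NULL` means all.  [stepwise_search()] passes the
#'   forward-accepted effects so pre-existing base-model covariates are
#'   never removed.
#' @return A list: `fit` (final retained model fit), `trace` (data frame).
#' @export
backward_step <- function(dataset, full_fit, threshold = 10.83,
                          control = focei_control(fast = TRUE),
                          fitter = focei_fit, removable = NULL) {
  stopifnot(inherits(full_fit, "focei_fit"))
  trace <- NULL
  current <- full_fit
  repeat {
    effs <- current$model$effects
    keep_idx <- if (is.null(removable)) seq_along(effs)
      else which(vapply(effs, .cand_label, "") %in% removable)
    effs <- effs[keep_idx]
    if (length(effs) == 0) break
    rises <- rep(Inf, length(effs))
    fits <- vector("list", length(effs))
    for (i in seq_along(effs)) {
      m <- current$model
      m$effects <- m$effects[-keep_idx[i]]
      fit_i <- tryCatch(fitter(dataset, m, control = control,
                               start = current),
                        error = function(e) e)
      if (inherits(fit_i, "error")) {
        warning("removal refit failed for ", .cand_label(effs[[i]]),
                call. = FALSE)
        trace <- rbind(trace, .trace_row("backward", .cand_label(effs[[i]]),
                                         current$ofv, NA, NA, "fit-failed"))
        next
      }
      fits[[i]] <- fit_i
      rises[i] <- fit_i$ofv - current$ofv
      trace <- rbind(trace, .trace_row("backward", .cand_label(effs[[i]]),
                                       current$ofv, fit_i$ofv, rises[i],
                                       "tested"))
    }
    keys <- vapply(effs, function(e) paste(e$parameter, e$covariate), "")
    ord <- order(rises, keys)
    weakest <- ord[1]
    if (is.finite(rises[weakest]) && rises[weakest] <= threshold &&
        !is.null(fits[[weakest]])) {
      trace$decision[trace$step == "backward" &
                     trace$candidate == .cand_label(effs[[weakest]]) &
                     trace$decision == "tested" &
                     abs(trace$ofv_reference - current$ofv) < 1e-9] <- "dropped"
      current <- fits[[weakest]]
    } else break
  }
  list(fit = current, trace = trace)
}

#' Full stepwise covariate search
#'
#' Repeats [forward_step()] until no candidate clears the inclusion
#' threshold, then applies [backward_step()] to the accumulated full
#' model.  The search is deterministic given the dataset and options.
#'
#' @param dataset a `pk_dataset`.
#' @param base_model the covariate-free [model_spec()].
#' @param candidates candidate list, e.g. [default_candidate_grid()].
#' @param forward_threshold OFV drop required for inclusion (> 6.63).
#' @param backward_threshold OFV rise required for retention (> 10.83).
#' @param control a [focei_control()] for the candidate fits; defaults to
#'   the fast profile.
#' @param base_control a [focei_control()] for the base-model fit (which
#'   anchors every likelihood-ratio comparison and deserves a larger
#'   iteration budget than the screening fits).
#' @param refit_final logical: refit the final model at tight tolerance.
#' @return A list of class `scm_result`: `fit` (final model), `base_fit`,
#'   `trace` (full search trace), `selected` (labels of retained effects),
#'   `percent_effects` (signed percent change per retained categorical
#'   effect).
#' @export
stepwise_search <- function(dataset, base_model, candidates,
                            forward_threshold = 6.63,
                            backward_threshold = 10.83,
                            control = focei_control(fast = TRUE),
                            base_control = control,
                            refit_final = FALSE) {
  # fits are cached by the (sorted) set of covariate labels so that a model
  # refitted in backward elimination reuses the forward-round fit verbatim:
  # nested-model OFV differences stay internally consistent at screening
  # tolerances
  cache <- new.env(parent = emptyenv())
  cached_fitter <- function(ds, model, control, start = NULL) {
    key <- paste0("m:", paste(sort(vapply(model$effects, .cand_label, "")), collapse = "|"))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- focei_fit(ds, model, control = control, start = start)
    cache[[key]] <- out
    out
  }

  base_fit <- focei_fit(dataset, base_model, control = base_control)
  # stabilize the anchor: restart until the objective stops improving
  for (r in 1:2) {
    refit <- focei_fit(dataset, base_model, control = base_control,
                       start = base_fit)
    if (base_fit$ofv - refit$ofv < 0.1) {
      if (refit$ofv < base_fit$ofv) base_fit <- refit
      break
    }
    base_fit <- refit
  }
  cache[["m:"]] <- base_fit
  trace <- NULL
  current <- base_fit
  remaining <- candidates
  accepted <- character(0)
  repeat {
    if (length(remaining) == 0) break
    stp <- forward_step(dataset, current, remaining,
                        threshold = forward_threshold, control = control,
                        fitter = cached_fitter)
    trace <- rbind(trace, stp$trace)
    if (is.null(stp$accepted)) break
    current <- stp$fit
    accepted <- c(accepted, .cand_label(stp$accepted))
    remaining <- Filter(function(e) !.same_effect(e, stp$accepted), remaining)
  }
  bk <- backward_step(dataset, current, threshold = backward_threshold,
                      control = control, removable = accepted,
                      fitter = cached_fitter)
  trace <- rbind(trace, bk$trace)
  final <- bk$fit
  if (refit_final && length(final$model$effects) > 0)
    final <- focei_fit(dataset, final$model, control = focei_control(),
                       start = final)
  pct <- vapply(final$model$effects, function(e)
    if (e$form == "linear") percent_change(e) else NA_real_, 0)
  names(pct) <- vapply(final$model$effects, .cand_label, "")
  structure(list(fit = final, base_fit = base_fit, trace = trace,
                 selected = vapply(final$model$effects, .cand_label, ""),
                 percent_effects = pct),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate search\n")
  cat(sprintf("  base OFV %.3f -> final OFV %.3f\n", x$base_fit$ofv,
              x$fit$ofv))
  if (length(x$selected) == 0) cat("  no covariates retained\n")
  else {
    cat("  retained:\n")
    for (i in seq_along(x$selected))
      cat(sprintf("    %-18s %+.1f%%\n", x$selected[i],
                  x$percent_effects[i]))
  }
  invisible(x)
}

#' Serialize a search trace
#'
#' Writes the trace both as tab-separated text and JSON; the pair
#' round-trips through [read_scm_trace()].
#'
#' @param trace trace data frame from [stepwise_search()].
#' @param path output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_scm_trace <- function(trace, path) {
  tsv <- paste0(path, ".tsv")
  jsn <- paste0(path, ".json")
  utils::write.table(trace, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trace, jsn, digits = NA, dataframe = "columns")
  invisible(c(tsv, jsn))
}

#' @rdname write_scm_trace
#' @export
read_scm_trace <- function(path) {
  as.data.frame(jsonlite::read_json(paste0(path, ".json"),
                                    simplifyVector = TRUE))
}
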