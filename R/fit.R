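#' FOCEI estimation control settings
#'
#' Numerical settings for [focei_fit()].  The inner (empirical-Bayes)
#' problem is solved to a gradient infinity-norm below `inner_tol`; the
#' outer quasi-Newton search stops at a relative objective change of
#' `outer_rel_tol`.  `fast = TRUE` loosens the outer tolerance to 1e-5,
#' which resolves objective differences to well below the likelihood-ratio
#' thresholds used in covariate search at a fraction of the cost.
#'
#' @param inner_tol gradient tolerance of the inner Newton solver.
#' @param inner_maxit maximum inner iterations per subject per evaluation.
#' @param outer_rel_tol relative objective-change tolerance of the outer
#'   optimizer.
#' @param outer_maxit maximum outer iterations.
#' @param fd_step relative step for outer finite-difference gradients.
#' @param gradient finite-difference scheme for the outer gradient:
#'   `"central"` (accurate, 2p evaluations) or `"forward"` (p evaluations;
#'   the `fast` profile's choice).
#' @param fast logical; loose-tolerance profile for model screening.
#' @return A list of class `focei_control`.
#' @export
focei_control <- function(inner_tol = 1e-6, inner_maxit = 300,
                          outer_rel_tol = 1e-8, outer_maxit = 400,
                          fd_step = 1e-4,
                          gradient = c("central", "forward"),
                          fast = FALSE) {
  gradient <- match.arg(gradient)
  if (fast) {
    outer_rel_tol <- max(outer_rel_tol, 1e-5)
    gradient <- "forward"
  }
  structure(list(inner_tol = inner_tol, inner_maxit = inner_maxit,
                 outer_rel_tol = outer_rel_tol, outer_maxit = outer_maxit,
                 fd_step = fd_step, gradient = gradient),
            class = "focei_control")
}

# ---- parameter packing / transforms ---------------------------------------
# Outer search runs on an unconstrained scale: log for positive parameters
# (structural thetas, omega2, sigma2), logit for fp, log(1 + theta) for
# categorical covariate coefficients (keeps 1 + theta > 0), identity for
# power coefficients.

.pack_model <- function(model) {
  est_struct <- setdiff(.param_names, model$fixed)
  par <- c()
  nm <- c()
  lower <- c()
  upper <- c()
  p <- model$params
  for (s in est_struct) {
    par <- c(par, if (s == "fp") qlogis(min(max(p[[s]], 1e-12), 1 - 1e-12))
             else log(p[[s]]))
    nm <- c(nm, s)
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }
  for (i in seq_along(model$effects)) {
    e <- model$effects[[i]]
    par <- c(par, if (e$form == "linear") log1p(e$theta) else e$theta)
    nm <- c(nm, paste0("beta_", e$covariate, "_", e$parameter))
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }
  for (i in seq_along(model$random)) {
    par <- c(par, log(min(max(model$omega2[i], 1e-8), 50)))
    nm <- c(nm, paste0("omega2_", model$random[i]))
    lower <- c(lower, log(1e-8))
    upper <- c(upper, log(50))   # eta sd of 7 on the log scale is already absurd
  }
  for (i in .est_sigma_idx(model)) {
    par <- c(par, log(min(model$sigma2[i], 10)))
    nm <- c(nm, paste0("sigma2_", c("VEN", "ODV")[i]))
    lower <- c(lower, log(1e-8))
    upper <- c(upper, log(10))
  }
  names(par) <- nm
  list(par = par, lower = lower, upper = upper, est_struct = est_struct)
}

.unpack_model <- function(par, model, est_struct) {
  i <- 0
  p <- model$params
  for (s in est_struct) {
    i <- i + 1
    p[[s]] <- unname(if (s == "fp") plogis(par[i]) else exp(par[i]))
  }
  model$params <- do.call(structural_params, p[.param_names])
  if (length(model$effects) > 0)
    for (k in seq_along(model$effects)) {
      i <- i + 1
      e <- model$effects[[k]]
      model$effects[[k]]$theta <- if (e$form == "linear") expm1(par[i]) else par[i]
    }
  for (k in seq_along(model$random)) {
    i <- i + 1
    model$omega2[k] <- exp(par[i])
  }
  for (k in .est_sigma_idx(model)) {
    i <- i + 1
    model$sigma2[k] <- exp(par[i])
  }
  model
}

.est_sigma_idx <- function(model) {
  which(!c("VEN", "ODV") %in% (model$fixed_sigma %||% character(0)))
}

# ---- objective -------------------------------------------------------------

#' FOCEI objective function value
#'
#' Computes the FOCEI approximation to -2 log-likelihood (the additive
#' `n log 2 pi` constant is omitted, following the usual convention of
#' population-PK software): per subject, etas are set to their conditional
#' modes, the model is linearized around them, and the subject contributes
#' `log|C_i| + r_i' C_i^-1 r_i` with
#' `C_i = G_i Omega G_i' + diag(h_i)` and `r_i = y_i - f_i(eta) + G_i eta`.
#'
#' @param dataset a `pk_dataset`.
#' @param model a [model_spec()].
#' @param control a [focei_control()].
#' @return The objective function value (scalar).
#' @export
focei_objective <- function(dataset, model, control = focei_control()) {
  subjects <- .flatten_dataset(dataset, model)
  eta0 <- matrix(0, length(subjects), length(model$random))
  res <- cpp_focei(unname(subjects), .model_list(model), eta0,
                   control$inner_tol, control$inner_maxit)
  res$ofv
}

#' Empirical-Bayes eta modes
#'
#' Conditional (posterior-mode) estimates of the subject-level random
#' effects given the model, from the FOCEI inner problem.
#'
#' @inheritParams focei_objective
#' @return A list: `eta` (matrix, one row per subject, columns named by the
#'   random parameters) and `inner_objective` (per-subject conditional
#'   objective values).
#' @export
eta_modes <- function(dataset, model, control = focei_control()) {
  subjects <- .flatten_dataset(dataset, model)
  eta0 <- matrix(0, length(subjects), length(model$random))
  res <- cpp_focei(unname(subjects), .model_list(model), eta0,
                   control$inner_tol, control$inner_maxit)
  eta <- res$eta
  dimnames(eta) <- list(names(subjects), model$random)
  list(eta = eta, inner_objective = as.numeric(res$inner_obj))
}

#' Eta mode for a single subject
#'
#' @param dataset a `pk_dataset`.
#' @param model a [model_spec()].
#' @param subject_id subject identifier.
#' @param control a [focei_control()].
#' @return List with `eta` (named vector) and `objective` (inner objective
#'   at the mode).  A subject with no retained observations raises a
#'   condition of class `venpk_skip_subject`.
#' @export
eta_mode <- function(dataset, model, subject_id, control = focei_control()) {
  subjects <- .flatten_dataset(dataset, model)
  s <- subjects[[as.character(subject_id)]]
  if (is.null(s)) stop("unknown subject: ", subject_id, call. = FALSE)
  if (length(s$time) == 0)
    stop(structure(class = c("venpk_skip_subject", "error", "condition"),
                   list(message = paste0("subject ", subject_id,
                                         " has no retained observations"),
                        call = NULL)))
  res <- cpp_inner(s, .model_list(model), rep(0, length(model$random)),
                   control$inner_tol, control$inner_maxit)
  list(eta = setNames(as.numeric(res$eta), model$random),
       objective = res$objective, iterations = res$iterations)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the joint model by FOCEI
#'
#' Maximum-likelihood estimation under the FOCEI approximation: an outer
#' quasi-Newton search (on an unconstrained transformed scale, with
#' finite-difference gradients) over the structural typical values,
#' covariate coefficients, between-subject variances and residual
#' variances, with the per-subject eta modes re-solved (warm-started) at
#' every objective evaluation.
#'
#' @param dataset a `pk_dataset` (after [apply_blq_rules()]).
#' @param model a [model_spec()] holding the initial estimates.
#' @param control a [focei_control()].
#' @param start optional fit to warm-start from (its final model and etas).
#' @return An object of class `focei_fit`: final `model`, `ofv`, `eta`
#'   (empirical-Bayes modes), `convergence` (0 = the optimizer stopped on
#'   one of its own criteria; 1 = iteration budget or failure, best iterate
#'   returned), `message` (the optimizer's diagnostic), `counts`, and the
#'   packed estimate vector `par`.
#' @export
focei_fit <- function(dataset, model, control = focei_control(),
                      start = NULL) {
  subjects <- .flatten_dataset(dataset, model)
  ns <- length(subjects)
  n_obs <- sum(vapply(subjects, function(s) length(s$time), 0L))
  if (ns < 2) stop("FOCEI fitting needs at least 2 subjects", call. = FALSE)
  pk <- .pack_model(model)
  eta_warm <- matrix(0, ns, length(model$random))
  if (!is.null(start) && inherits(start, "focei_fit")) {
    shared <- intersect(names(pk$par), names(start$par))
    pk$par[shared] <- start$par[shared]
    if (!is.null(start$eta) && nrow(start$eta) == ns)
      eta_warm <- start$eta
  }

  env <- new.env(parent = emptyenv())
  env$eta <- eta_warm
  env$last_par <- NULL
  env$last_ofv <- NA_real_
  env$evals <- 0L
  dptr <- cpp_build_data(unname(subjects))

  objective <- function(par) {
    m <- .unpack_model(par, model, pk$est_struct)
    res <- tryCatch(
      cpp_focei(dptr, .model_list(m), env$eta,
                control$inner_tol, control$inner_maxit),
      error = function(e) NULL)
    env$evals <- env$evals + 1L
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    env$eta <- res$eta
    env$last_par <- par
    env$last_ofv <- res$ofv
    res$ofv
  }
  gradient <- function(par) {
    g <- numeric(length(par))
    if (control$gradient == "forward") {
      f0 <- if (!is.null(env$last_par) && identical(unname(par),
                                                   unname(env$last_par)))
        env$last_ofv else objective(par)
      for (i in seq_along(par)) {
        h <- control$fd_step * max(abs(par[i]), 0.1)
        pp <- par
        pp[i] <- par[i] + h
        g[i] <- (objective(pp) - f0) / h
      }
    } else {
      for (i in seq_along(par)) {
        h <- control$fd_step * max(abs(par[i]), 0.1)
        pp <- par
        pp[i] <- par[i] + h
        fp_ <- objective(pp)
        pp[i] <- par[i] - h
        fm_ <- objective(pp)
        g[i] <- (fp_ - fm_) / (2 * h)
      }
    }
    g
  }

  # a single newly introduced coefficient (a covariate candidate) gets a
  # cheap one-dimensional presolve before the full search
  if (!is.null(start) && inherits(start, "focei_fit")) {
    new_par <- setdiff(names(pk$par), names(start$par))
    if (length(new_par) == 1) {
      o1 <- stats::optimize(function(v) {
        pp <- pk$par
        pp[new_par] <- v
        objective(pp)
      }, interval = c(-1.5, 1.5), tol = 1e-3)
      pk$par[new_par] <- o1$minimum
    }
  }

  ofv0 <- objective(pk$par)
  opt <- nlminb(pk$par, objective, gradient = gradient,
                lower = pk$lower, upper = pk$upper,
                control = list(rel.tol = control$outer_rel_tol,
                               iter.max = control$outer_maxit,
                               eval.max = 4 * control$outer_maxit))
  best_par <- opt$par
  best_ofv <- opt$objective
  if (!is.finite(best_ofv) || best_ofv > ofv0) {
    best_par <- pk$par
    best_ofv <- ofv0
  }
  final_model <- .unpack_model(best_par, model, pk$est_struct)
  res <- cpp_focei(dptr, .model_list(final_model), env$eta,
                   control$inner_tol, control$inner_maxit)
  eta <- res$eta
  dimnames(eta) <- list(names(subjects), model$random)
  # nlminb's "false convergence" is routine at finite-difference noise
  # level (restarts do not move the objective); treat any self-terminated
  # stop as converged and keep the message
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|both X|singular convergence|false convergence",
          opt$message %||% "")
  structure(list(model = final_model, ofv = res$ofv, par = best_par,
                 eta = eta, ofv_i = as.numeric(res$ofv_i),
                 convergence = if (converged) 0L else 1L,
                 message = opt$message,
                 counts = c(evaluations = env$evals,
                            iterations = opt$iterations),
                 n_subjects = ns, n_obs = n_obs,
                 est_struct = pk$est_struct,
                 control = control),
            class = "focei_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.focei_fit <- function(x, ...) {
  cat(sprintf("FOCEI fit: %d subjects, %d observations\n", x$n_subjects,
              x$n_obs))
  cat(sprintf("  OFV %.3f  (%s, %d objective evaluations)\n", x$ofv,
              if (x$convergence == 0) "converged" else "NOT converged",
              x$counts["evaluations"]))
  print(x$model)
  invisible(x)
}

# natural-scale estimate vector of everything that was estimated
.natural_estimates <- function(fit) {
  m <- fit$model
  out <- c()
  for (s in fit$est_struct) out[s] <- m$params[[s]]
  for (e in m$effects)
    out[paste0("beta_", e$covariate, "_", e$parameter)] <- e$theta
  for (i in seq_along(m$random))
    out[paste0("omega2_", m$random[i])] <- m$omega2[i]
  for (i in .est_sigma_idx(m))
    out[paste0("sigma2_", c("VEN", "ODV")[i])] <- m$sigma2[i]
  out
}

.model_from_natural <- function(v, fit) {
  m <- fit$model
  i <- 0
  p <- m$params
  for (s in fit$est_struct) {
    i <- i + 1
    p[[s]] <- unname(v[i])
  }
  m$params <- do.call(structural_params, p[.param_names])
  for (k in seq_along(m$effects)) {
    i <- i + 1
    m$effects[[k]]$theta <- v[i]
  }
  for (k in seq_along(m$random)) {
    i <- i + 1
    m$omega2[k] <- v[i]
  }
  for (k in .est_sigma_idx(m)) {
    i <- i + 1
    m$sigma2[k] <- unname(v[i])
  }
  m
}

#' Central finite-difference Hessian
#'
#' @param fn scalar function.
#' @param x evaluation point.
#' @param h step sizes (vector or scalar; absolute).
#' @return Symmetric numeric matrix.
#' @export
fd_hessian <- function(fn, x, h = pmax(abs(x), 1e-2) * 1e-3) {
  n <- length(x)
  if (length(h) == 1) h <- rep(h, n)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    H[i, i] <- (fn(xp) + fn(xm) - 2 * f0) / h[i]^2
    if (i < n) for (j in seq(i + 1, n)) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      H[i, j] <- H[j, i] <-
        (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Relative standard errors of a FOCEI fit
#'
#' Standard errors from the inverse of half the numerically differentiated
#' objective-function Hessian on the natural parameter scale (the
#' observed-information estimator for a -2 log-likelihood objective);
#' `RSE% = 100 * SE / |estimate|`.  If the Hessian is not positive
#' definite the function falls back to a case-resampling (subject-level)
#' bootstrap and flags the result.  Fixed parameters (e.g. ka) are
#' reported with `NA` standard errors.
#'
#' @param fit a [focei_fit()] result.
#' @param dataset the dataset it was fitted to.
#' @param control a [focei_control()] for the re-evaluations.
#' @param nboot bootstrap replicates for the fallback path.
#' @return A data frame: `parameter`, `estimate`, `se`, `rse_pct`, `method`.
#' @export
focei_rse <- function(fit, dataset, control = focei_control(), nboot = 50) {
  stopifnot(inherits(fit, "focei_fit"))
  est <- .natural_estimates(fit)
  subjects <- .flatten_dataset(dataset, fit$model)
  dptr <- cpp_build_data(unname(subjects))
  env <- new.env(parent = emptyenv())
  env$eta <- fit$eta
  ofv_nat <- function(v) {
    m <- tryCatch(.model_from_natural(v, fit), error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    res <- tryCatch(cpp_focei(dptr, .model_list(m), env$eta,
                              control$inner_tol, control$inner_maxit),
                    error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    res$ofv
  }
  H <- fd_hessian(ofv_nat, est, h = pmax(abs(est), 1e-3) * 1e-3)
  se <- rep(NA_real_, length(est))
  method <- "hessian"
  ok <- all(is.finite(H)) && all(eigen(H, symmetric = TRUE,
                                       only.values = TRUE)$values > 0)
  if (ok) {
    se <- sqrt(diag(2 * solve(H)))
  } else {
    method <- "bootstrap"
    warning("OFV Hessian not positive definite; using case-resampling bootstrap",
            call. = FALSE)
    ids <- unique(dataset$records$ID)
    boot <- matrix(NA_real_, nboot, length(est))
    for (b in seq_len(nboot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      rec <- do.call(rbind, lapply(seq_along(take), function(k) {
        r <- dataset$records[dataset$records$ID == take[k], , drop = FALSE]
        r$ID <- k
        r
      }))
      ds_b <- .new_dataset(rec, dataset$limits)
      fb <- tryCatch(focei_fit(ds_b, fit$model,
                               control = focei_control(fast = TRUE),
                               start = fit),
                     error = function(e) NULL)
      if (!is.null(fb)) boot[b, ] <- .natural_estimates(fb)
    }
    se <- apply(boot, 2, sd, na.rm = TRUE)
  }
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = se, rse_pct = 100 * se / abs(est),
                    method = method)
  fx <- setdiff(.param_names, fit$est_struct)
  if (length(fx) > 0) {
    fixed_rows <- data.frame(parameter = fx,
                             estimate = vapply(fx, function(s)
                               fit$model$params[[s]], 0),
                             se = NA_real_, rse_pct = NA_real_,
                             method = "fixed")
    tab <- rbind(tab, fixed_rows)
  }
  rownames(tab) <- NULL
  tab
}

#' Export a fit as structured text and JSON
#'
#' @param fit a [focei_fit()].
#' @param path output path without extension; writes `<path>.txt` and
#'   `<path>.json`.
#' @param rse optional result of [focei_rse()] to include.
#' @return Invisibly, the two paths written.
#' @export
write_fit_report <- function(fit, path, rse = NULL) {
  txt <- paste0(path, ".txt")
  jsn <- paste0(path, ".json")
  con <- file(txt, "w")
  sink(con)
  print(fit)
  if (!is.null(rse)) {
    cat("\nStandard errors:\n")
    print(rse)
  }
  sink()
  close(con)
  est <- .natural_estimates(fit)
  payload <- list(ofv = fit$ofv, convergence = fit$convergence,
                  estimates = as.list(est),
                  fixed = as.list(setNames(
                    lapply(setdiff(.param_names, fit$est_struct),
                           function(s) fit$model$params[[s]]),
                    setdiff(.param_names, fit$est_struct))),
                  eta = as.data.frame(fit$eta))
  if (!is.null(rse)) payload$rse <- rse
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(txt, jsn))
}
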