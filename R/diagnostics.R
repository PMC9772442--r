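#' Goodness-of-fit table
#'
#' Per-observation population predictions (PRED: covariate-adjusted typical
#' parameters, etas at zero), individual predictions (IPRED: empirical-Bayes
#' eta modes) and conditional weighted residuals.  CWRES decorrelates the
#' FOCEI residual `y_i - (f_i(eta) - G_i eta)` with the inverse symmetric
#' square root of the linearized marginal covariance
#' `C_i = G_i Omega G_i' + diag(h_i)`.
#'
#' @param dataset a `pk_dataset`.
#' @param fit a [focei_fit()] (its model and eta modes are used).
#' @return A data frame: `subject`, `analyte`, `time` (h after first dose),
#'   `tad` (h after the most recent administered dose), `dv`, `PRED`,
#'   `IPRED`, `CWRES`.
#' @export
gof_table <- function(dataset, fit) {
  stopifnot(inherits(fit, "focei_fit"))
  model <- fit$model
  subjects <- .flatten_dataset(dataset, model)
  res <- cpp_gof(unname(subjects), .model_list(model), fit$eta)
  rows <- lapply(subjects, function(s) {
    if (length(s$time) == 0) return(NULL)
    tad <- vapply(s$time, function(t) {
      adm <- .admin_times(s$dose, t)
      if (length(adm) == 0) t else t - max(adm)
    }, 0)
    data.frame(subject = s$id, analyte = c("VEN", "ODV")[s$analyte + 1L],
               time = s$time, tad = tad, dv = s$dv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$PRED <- as.numeric(res$PRED)
  out$IPRED <- as.numeric(res$IPRED)
  out$CWRES <- as.numeric(res$CWRES)
  out
}

# administration times of a dose matrix that fall at or before t
# (steady-state trains contribute their event time)
.admin_times <- function(dose, t) {
  out <- c()
  for (r in seq_len(nrow(dose))) {
    td <- dose[r, 1]; ii <- dose[r, 3]; addl <- dose[r, 4]; ss <- dose[r, 5]
    if (td > t) next
    if (ss > 0) {
      # at steady state doses recur every ii before the event time as well
      k <- floor((t - td) / max(ii, 1e-12))
      out <- c(out, td + k * ii)
    } else if (ii > 0 && addl > 0) {
      k <- min(addl, floor((t - td) / ii))
      out <- c(out, td + k * ii)
    } else out <- c(out, td)
  }
  out
}

#' Normalized prediction distribution errors
#'
#' Simulates `K` full replicates of the dataset under the model (re-drawing
#' both etas and residual errors at the observed design), decorrelates the
#' observed and simulated vectors per subject with the inverse Cholesky
#' factor of the empirical simulation covariance, and transforms the rank
#' fraction of each observation among its simulated counterparts through
#' the standard-normal quantile function.  Rank fractions of 0 or 1 are
#' clamped to `1/(2K)` and `1 - 1/(2K)`.  Observations whose simulated
#' values are all identical (structurally fixed, e.g. pre-dose zeros) get
#' `NA` and are excluded from the summaries.
#'
#' @param dataset a `pk_dataset`.
#' @param fit a [focei_fit()] (or a list with a `model` element).
#' @param K number of simulation replicates (>= 100).
#' @param seed RNG seed for the replicates.
#' @param shrink covariance shrinkage toward the diagonal used if the
#'   empirical covariance is singular (escalated automatically).
#' @return An object of class `npde_result`: data frame `table`
#'   (`subject`, `analyte`, `time`, `pred_median`, `npde`), global `mean`,
#'   `variance`, `t_stat` (mean-zero test), `normality_p`
#'   (Shapiro-Wilk, or KS for n > 5000), `n_used`, `n_dropped`.
#' @export
npde <- function(dataset, fit, K = 1000, seed = 1L, shrink = 0.05) {
  if (K < 100) stop("K must be at least 100", call. = FALSE)
  model <- if (inherits(fit, "focei_fit")) fit$model else fit$model
  subjects <- .flatten_dataset(dataset, model)
  ns <- length(subjects)
  nobs_i <- vapply(subjects, function(s) length(s$time), 0L)
  mlist <- .model_list(model)
  neta <- length(model$random)
  n_all <- sum(nobs_i)
  anly <- unlist(lapply(subjects, function(s) s$analyte))
  sig <- sqrt(model$sigma2)[anly + 1L]

  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  dptr <- cpp_build_data(unname(subjects))
  sims <- matrix(NA_real_, K, n_all)
  for (k in seq_len(K)) {
    eta_k <- matrix(rnorm(ns * neta, 0, rep(sqrt(model$omega2), each = ns)),
                    ns, neta)
    f_k <- cpp_pop_pred(dptr, mlist, eta_k)
    eps <- rnorm(n_all, 0, sig)
    sims[k, ] <- f_k * (1 + eps)
  }

  y <- unlist(lapply(subjects, function(s) s$dv))
  npde_val <- rep(NA_real_, n_all)
  off <- 0
  for (i in seq_len(ns)) {
    ni <- nobs_i[i]
    if (ni == 0) next
    idx <- off + seq_len(ni)
    off <- off + ni
    S <- sims[, idx, drop = FALSE]
    keep <- apply(S, 2, function(col) all(is.finite(col)) &&
                    max(col) > min(col))
    if (!any(keep)) next
    S <- S[, keep, drop = FALSE]
    yi <- y[idx][keep]
    m <- colMeans(S)
    V <- cov(S)
    lam <- shrink
    L <- NULL
    repeat {
      Vs <- (1 - lam) * V + lam * diag(diag(V), nrow(V))
      L <- tryCatch(chol(Vs), error = function(e) NULL)
      if (!is.null(L)) break
      lam <- lam * 4
      if (lam > 1) {
        warning("singular simulation covariance; using diagonal decorrelation",
                call. = FALSE)
        Vs <- diag(diag(V), nrow(V))
        L <- chol(Vs)
        break
      }
    }
    if (lam > shrink && lam <= 1)
      warning("simulation covariance shrunk toward diagonal (lambda = ",
              lam, ")", call. = FALSE)
    ystar <- backsolve(L, yi, transpose = TRUE)
    Sstar <- t(backsolve(L, t(S), transpose = TRUE))
    pde <- (colSums(sweep(Sstar, 2, ystar, "<")) ) / nrow(Sstar)
    pde <- pmin(pmax(pde, 1 / (2 * K)), 1 - 1 / (2 * K))
    npde_val[idx[keep]] <- qnorm(pde)
  }

  tab <- do.call(rbind, lapply(subjects, function(s) {
    if (length(s$time) == 0) return(NULL)
    data.frame(subject = s$id, analyte = c("VEN", "ODV")[s$analyte + 1L],
               time = s$time, dv = s$dv)
  }))
  rownames(tab) <- NULL
  tab$pred_median <- apply(sims, 2, median)
  tab$npde <- npde_val
  used <- tab$npde[!is.na(tab$npde)]
  norm_p <- if (length(used) >= 3 && length(used) <= 5000)
    shapiro.test(used)$p.value
  else if (length(used) > 5000)
    ks.test(used, "pnorm")$p.value
  else NA_real_
  structure(list(table = tab,
                 mean = mean(used), variance = var(used),
                 t_stat = mean(used) / (sd(used) / sqrt(length(used))),
                 normality_p = norm_p,
                 n_used = length(used),
                 n_dropped = sum(is.na(tab$npde)),
                 K = K, seed = seed),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE (%d replicates): n = %d (%d dropped)\n", x$K, x$n_used,
              x$n_dropped))
  cat(sprintf("  mean %.4f, variance %.4f, t = %.3f, normality p = %.4f\n",
              x$mean, x$variance, x$t_stat, x$normality_p))
  invisible(x)
}

#' Export plot-ready diagnostic tables
#'
#' Writes, per analyte, four GOF panels (observed vs PRED, observed vs
#' IPRED, CWRES vs time after dose, CWRES vs PRED) and four NPDE panels
#' (QQ against N(0,1), histogram bins, NPDE vs time, NPDE vs predicted
#' median) as tab-separated files - eight files per analyte.  Output is
#' deterministic for fixed inputs.  With `render = TRUE` (and ggplot2
#' installed) PNG figures are written alongside.
#'
#' @param gof result of [gof_table()].
#' @param npde_res result of [npde()] (may be an empty result).
#' @param dir output directory (created if missing).
#' @param render also render PNG figures.
#' @return Invisibly, the vector of files written.
#' @export
diagnostic_export <- function(gof, npde_res, dir, render = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
    p
  }
  for (a in c("VEN", "ODV")) {
    g <- gof[gof$analyte == a, , drop = FALSE]
    wr(g[, c("subject", "time", "dv", "PRED")],
       paste0("gof_obs_vs_pred_", a, ".tsv"))
    wr(g[, c("subject", "time", "dv", "IPRED")],
       paste0("gof_obs_vs_ipred_", a, ".tsv"))
    wr(g[, c("subject", "tad", "CWRES")],
       paste0("gof_cwres_vs_time_", a, ".tsv"))
    wr(g[, c("subject", "PRED", "CWRES")],
       paste0("gof_cwres_vs_pred_", a, ".tsv"))
    n <- npde_res$table
    n <- n[!is.na(n$npde) & n$analyte == a, , drop = FALSE]
    qq <- if (nrow(n) > 0) {
      s <- sort(n$npde)
      data.frame(theoretical = qnorm((seq_along(s) - 0.5) / length(s)),
                 npde = s)
    } else data.frame(theoretical = numeric(0), npde = numeric(0))
    wr(qq, paste0("npde_qq_", a, ".tsv"))
    hist_df <- if (nrow(n) > 0) {
      br <- seq(floor(min(n$npde)), ceiling(max(n$npde)), by = 0.5)
      h <- graphics::hist(n$npde, breaks = br, plot = FALSE)
      data.frame(mid = h$mids, density = h$density)
    } else data.frame(mid = numeric(0), density = numeric(0))
    wr(hist_df, paste0("npde_hist_", a, ".tsv"))
    wr(n[, c("subject", "time", "npde")], paste0("npde_vs_time_", a, ".tsv"))
    wr(n[, c("subject", "pred_median", "npde")],
       paste0("npde_vs_pred_", a, ".tsv"))
  }
  if (render && requireNamespace("ggplot2", quietly = TRUE)) {
    for (a in c("VEN", "ODV")) {
      g <- gof[gof$analyte == a, , drop = FALSE]
      if (nrow(g) == 0) next
      pl <- ggplot2::ggplot(g, ggplot2::aes(x = PRED, y = dv)) +
        ggplot2::geom_point(alpha = 0.5) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::labs(x = "Population prediction (ng/ml)",
                      y = "Observed (ng/ml)", title = a)
      fp <- file.path(dir, paste0("gof_obs_vs_pred_", a, ".png"))
      ggplot2::ggsave(fp, pl, width = 5, height = 4, dpi = 120)
      files <- c(files, fp)
    }
  }
  invisible(files)
}
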