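# Independent numerical oracles used across the suite.  These deliberately
# avoid the package's closed-form/FOCEI code paths: amounts come from a
# hand-rolled fixed-step RK4 with Richardson extrapolation, marginal
# likelihoods from adaptive Gauss-Hermite quadrature, and eta modes from
# brute-force grid search.

# fixed-step classical RK4 for the amount system (expanded doses only)
rk4_amounts <- function(params, dose_times, dose_amts, t_end, n_steps) {
  kk <- derived_rates(params)
  ka <- params$ka; fp <- params$fp
  kp <- kk[["kp"]]; km <- kk[["km"]]
  deriv <- function(y) c(-ka * y[1],
                         (1 - fp) * ka * y[1] - kp * y[2],
                         fp * ka * y[1] + kp * y[2] - km * y[3])
  # integrate piecewise between dose times
  knots <- sort(unique(c(0, dose_times, t_end)))
  knots <- knots[knots <= t_end]
  y <- c(0, 0, 0)
  for (seg in seq_len(length(knots))) {
    tk <- knots[seg]
    hit <- which(abs(dose_times - tk) < 1e-12)
    if (length(hit)) y[1] <- y[1] + sum(dose_amts[hit])
    if (seg == length(knots)) break
    span <- knots[seg + 1] - tk
    if (span <= 0) next
    h <- span / n_steps
    for (i in seq_len(n_steps)) {
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  y
}

# Richardson-extrapolated RK4 reference (error ~ h^5)
rk4_richardson <- function(params, dose_times, dose_amts, t_end,
                           n_steps = 400) {
  y1 <- rk4_amounts(params, dose_times, dose_amts, t_end, n_steps)
  y2 <- rk4_amounts(params, dose_times, dose_amts, t_end, 2 * n_steps)
  (16 * y2 - y1) / 15
}

# Bateman one-compartment first-order-absorption solution (amount)
bateman_amount <- function(dose, ka, ke, t) {
  if (abs(ka - ke) < 1e-12 * ka) dose * ka * t * exp(-ka * t)
  else dose * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# --- toy subjects for the estimation oracles -------------------------------

# a one-eta toy: single subject, eta on cl_f, proportional error
make_toy <- function(seed, n_obs = 5, omega2 = 0.1, sigma2 = 0.05,
                     eta_true = NULL) {
  set.seed(seed)
  p <- default_structural_params()
  p$cl_f <- p$cl_f * exp(runif(1, -0.3, 0.3))
  p$v_f <- p$v_f * exp(runif(1, -0.3, 0.3))
  reg <- pk_regimen(dose_event(0, 50))
  times <- sort(runif(n_obs, 0.5, 24))
  if (is.null(eta_true)) eta_true <- rnorm(1, 0, sqrt(omega2))
  pi_ <- p
  pi_$cl_f <- p$cl_f * exp(eta_true)
  f <- conc_parent(do.call(structural_params, pi_[venpk:::.param_names]),
                   reg, times)
  dv <- f * (1 + rnorm(n_obs, 0, sqrt(sigma2)))
  dv <- pmax(dv, 1e-3)
  params <- do.call(structural_params, p[venpk:::.param_names])
  list(
    params = params,
    subject = list(time = times, dv = dv, analyte = rep(0L, n_obs),
                   dose = matrix(c(0, 50, 0, 0, 0), 1, 5), covx = numeric(0),
                   id = 1L),
    mlist = list(theta = venpk:::.param_vec(params), covtheta = numeric(0),
                 effpar = integer(0), efftype = integer(0),
                 effref = numeric(0), iiv = 0L, omega2 = omega2,
                 sigma2 = c(sigma2, sigma2), add2 = 0),
    omega2 = omega2, sigma2 = sigma2, regimen = reg, times = times, dv = dv)
}

# individual prediction of a toy at a given eta (R-side, closed form)
toy_pred <- function(toy, eta) {
  p <- toy$params
  p$cl_f <- p$cl_f * exp(eta)
  conc_parent(do.call(structural_params, p[venpk:::.param_names]),
              toy$regimen, toy$times)
}

# conditional objective of a toy, computed independently in R
toy_inner_obj <- function(toy, eta) {
  f <- toy_pred(toy, eta)
  h <- toy$sigma2 * f^2
  sum((toy$dv - f)^2 / h + log(h)) + eta^2 / toy$omega2
}

# -2 log marginal likelihood minus the 2*pi constant, by 64-node adaptive
# Gauss-Hermite quadrature centered and scaled at the integrand mode
agq_ofv <- function(toy, n_nodes = 64) {
  loglik_eta <- function(eta) {
    f <- toy_pred(toy, eta)
    h <- toy$sigma2 * f^2
    sum(stats::dnorm(toy$dv, f, sqrt(h), log = TRUE)) +
      stats::dnorm(eta, 0, sqrt(toy$omega2), log = TRUE)
  }
  opt <- stats::optimize(function(e) -loglik_eta(e), c(-4, 4))
  mu <- opt$minimum
  hh <- 1e-4
  curv <- -(loglik_eta(mu + hh) + loglik_eta(mu - hh) - 2 * loglik_eta(mu)) / hh^2
  s <- 1 / sqrt(max(curv, 1e-8))
  gh <- pracma::gaussHermite(n_nodes)
  lv <- vapply(seq_along(gh$x), function(k) {
    eta_k <- mu + sqrt(2) * s * gh$x[k]
    log(gh$w[k]) + gh$x[k]^2 + loglik_eta(eta_k)
  }, 0)
  mx <- max(lv)
  logL <- log(sum(exp(lv - mx))) + mx + log(sqrt(2) * s)
  -2 * logL - length(toy$dv) * log(2 * pi)
}

# brute-force grid search for the eta mode of a toy
grid_eta_mode <- function(toy, lo = -2, hi = 2, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, function(e) toy_inner_obj(toy, e), 0)
  grid[which.min(vals)]
}
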