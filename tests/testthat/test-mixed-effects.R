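# FOCEI machinery: inner problem, objective, fitting, standard errors

# dataset wrapper for a one-eta toy subject (VEN observations, no BLQ)
toy_dataset <- function(toy, id = 1) {
  as_pk_dataset(healthy_subject_records(id, toy$times, toy$dv))
}

toy_model <- function(toy) {
  model_spec(params = toy$params, random = "cl_f", omega2 = toy$omega2,
             sigma2 = c(VEN = toy$sigma2, ODV = toy$sigma2), add_sd = 0)
}

test_that("observations at the typical predictions give a (near-)zero eta mode", {
  toy <- make_toy(1, eta_true = 0)
  toy$dv <- toy_pred(toy, 0)  # noise-free at eta = 0
  ds <- toy_dataset(toy)
  # under FOCE *with interaction* the log h(eta) term pulls the mode
  # slightly off zero even for perfect data; the pull vanishes with the
  # residual variance
  em <- eta_mode(ds, toy_model(toy), 1)
  expect_lt(abs(em$eta), 0.05)
  m_tiny <- toy_model(toy)
  m_tiny$sigma2 <- c(1e-8, 1e-8)
  em2 <- eta_mode(ds, m_tiny, 1)
  expect_lt(abs(em2$eta), 1e-5)
})

test_that("a collapsing omega squeezes the eta mode to zero", {
  toy <- make_toy(2, eta_true = 0.5)
  ds <- toy_dataset(toy)
  m <- toy_model(toy)
  m$omega2 <- 1e-9
  em <- eta_mode(ds, m, 1)
  expect_lt(abs(em$eta), 1e-4)
})

test_that("eta modes match a brute-force grid search", {
  for (s in 1:3) {
    toy <- make_toy(10 + s, n_obs = 2)
    ds <- toy_dataset(toy)
    em <- eta_mode(ds, toy_model(toy), 1)
    oracle <- grid_eta_mode(toy)
    expect_lt(abs(unname(em$eta) - oracle), 2e-4)  # grid resolution 1e-4
  }
})

test_that("with no between-subject variability the objective is extended least squares", {
  toys <- lapply(1:3, function(s) make_toy(20 + s, n_obs = 6))
  rec <- do.call(rbind, lapply(seq_along(toys), function(i)
    healthy_subject_records(i, toys[[i]]$times, toys[[i]]$dv)))
  ds <- as_pk_dataset(rec)
  p <- toys[[1]]$params   # one common typical-value set
  sigma2 <- toys[[1]]$sigma2
  m <- model_spec(params = p, random = "cl_f", omega2 = 0,
                  sigma2 = c(sigma2, sigma2), add_sd = 0)
  ofv <- focei_objective(ds, m)
  els <- sum(vapply(seq_along(toys), function(i) {
    f <- conc_parent(p, toys[[i]]$regimen, toys[[i]]$times)
    h <- sigma2 * f^2
    sum(log(h) + (toys[[i]]$dv - f)^2 / h)
  }, 0))
  expect_equal(ofv, els, tolerance = 1e-10)
})

test_that("FOCEI objective stays within half a point of adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  deltas <- vapply(1:10, function(s) {
    toy <- make_toy(100 + s)
    ds <- toy_dataset(toy)
    ofv <- focei_objective(ds, toy_model(toy))
    abs(ofv - agq_ofv(toy))
  }, 0)
  expect_lt(max(deltas), 0.5)
})

test_that("the objective is additive: duplicating every subject doubles it", {
  cfg <- small_sim_config(seed = 31, n_healthy = 3, n_patient = 4)
  sim <- generate_combined(cfg, seed = 31)
  m <- truth_model_spec(cfg)
  ofv1 <- focei_objective(sim$dataset, m)
  rec <- sim$dataset$records
  rec2 <- rec
  rec2$ID <- rec2$ID + 100000L
  ds2 <- as_pk_dataset(rbind(rec, rec2), sim$dataset$limits)
  ofv2 <- focei_objective(ds2, m)
  expect_lt(abs(ofv2 - 2 * ofv1), 1e-9 * abs(ofv1))
})

test_that("the objective is invariant to subject order", {
  cfg <- small_sim_config(seed = 32, n_healthy = 3, n_patient = 4)
  sim <- generate_combined(cfg, seed = 32)
  m <- truth_model_spec(cfg)
  ofv1 <- focei_objective(sim$dataset, m)
  rec <- sim$dataset$records
  ids <- unique(rec$ID)
  perm <- rev(ids)
  rec$ID <- perm[match(rec$ID, ids)]
  ds2 <- as_pk_dataset(rec, sim$dataset$limits)
  ofv2 <- focei_objective(ds2, m)
  expect_lt(abs(ofv1 - ofv2), 1e-8)
})

test_that("fitting lowers the objective and returns an eta mode per subject", {
  cfg <- small_sim_config(seed = 33, n_healthy = 4, n_patient = 8)
  sim <- generate_combined(cfg, seed = 33)
  m0 <- truth_model_spec(cfg)
  # start away from the truth
  m0$params$cl_f <- 60
  m0$params$clm_f <- 30
  ofv_init <- focei_objective(sim$dataset, m0)
  fit <- focei_fit(sim$dataset, m0, control = focei_control(fast = TRUE))
  expect_lte(fit$ofv, ofv_init)
  expect_equal(nrow(fit$eta), 12)
  expect_true(all(is.finite(fit$eta)))
})

test_that("refitting self-simulated data recovers the generating parameters", {
  cfg <- generator_config(n_healthy = 12, n_patient = 24,
                          effects = list(), seed = 55)
  sim <- generate_combined(cfg, seed = 55)
  fit <- focei_fit(sim$dataset, truth_model_spec(cfg),
                   control = focei_control(fast = TRUE))
  est <- fit$model$params
  # bands ~ 3 between-subject standard errors at this design size
  # (36 subjects for the VEN parameters, 24 metabolite-informative
  # patients, with extra slack on clm for its correlation with fp/vm)
  expect_lt(abs(est$cl_f - 80.9) / 80.9, 3 * sqrt(0.219 / 36) + 0.02)
  expect_lt(abs(est$v_f - 628) / 628, 3 * sqrt(0.106 / 36) + 0.02)
  expect_lt(abs(est$clm_f - 22.1) / 22.1, 3 * sqrt(0.156 / 24) + 0.15)
})

test_that("fd_hessian is exact on a quadratic form", {
  A <- matrix(c(4, 1, 0.5, 1, 3, -1, 0.5, -1, 2), 3, 3)
  fn <- function(x) 0.5 * drop(t(x) %*% A %*% x) + sum(x)
  H <- fd_hessian(fn, c(0.3, -0.2, 1.4))
  expect_equal(H, A, tolerance = 1e-5)
})

test_that("standard errors: fixed ka is NA and RSEs are finite", {
  cfg <- small_sim_config(seed = 41, n_healthy = 6, n_patient = 10)
  sim <- generate_combined(cfg, seed = 41)
  fit <- focei_fit(sim$dataset, truth_model_spec(cfg))
  rse <- suppressWarnings(focei_rse(fit, sim$dataset, nboot = 6))
  ka_row <- rse[rse$parameter == "ka", ]
  expect_true(is.na(ka_row$rse_pct))
  expect_equal(ka_row$method, "fixed")
  core <- rse[rse$parameter %in% c("cl_f", "v_f", "clm_f"), ]
  expect_true(all(is.finite(core$rse_pct)))
  expect_true(all(core$rse_pct > 0))
})

test_that("quadrupling the sample size roughly halves the clearance standard error", {
  # healthy-arm-only submodel (VEN data, eta on clearance) keeps these
  # four fits and two Hessians cheap
  fit_rse <- function(n1, seed) {
    cfg <- generator_config(n_healthy = n1, effects = list(), seed = seed)
    ds <- generate_study1(cfg, seed = seed)
    m <- model_spec(fixed = c("ka", "clm_f", "vm_f", "fp"),
                    random = "cl_f", omega2 = 0.219,
                    sigma2 = c(VEN = 0.123, ODV = 0.101),
                    fixed_sigma = "ODV")
    fit <- focei_fit(ds, m)
    rse <- suppressWarnings(focei_rse(fit, ds, nboot = 8))
    rse$rse_pct[match(c("cl_f", "v_f"), rse$parameter)]
  }
  small <- fit_rse(8, 61)
  big <- fit_rse(32, 61)
  ratio <- big / small
  # CLT scaling: expect about 0.5, allow 25% slack on either side
  expect_true(all(ratio > 0.25 & ratio < 0.75))
})
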