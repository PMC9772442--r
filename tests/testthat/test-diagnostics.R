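# GOF quantities (PRED/IPRED/CWRES) and NPDE

fake_fit <- function(model, eta) {
  structure(list(model = model, eta = eta, est_struct = venpk:::.param_names),
            class = "focei_fit")
}

test_that("CWRES vanishes when observations sit exactly on the population predictions", {
  toy <- make_toy(201, n_obs = 6)
  toy$dv <- toy_pred(toy, 0)
  ds <- as_pk_dataset(healthy_subject_records(1, toy$times, toy$dv))
  m <- model_spec(params = toy$params, random = "cl_f", omega2 = 1e-10,
                  sigma2 = c(toy$sigma2, toy$sigma2), add_sd = 0)
  g <- gof_table(ds, fake_fit(m, matrix(0, 1, 1)))
  expect_equal(g$CWRES, rep(0, 6))
  expect_equal(g$PRED, g$IPRED)
  expect_equal(g$PRED, toy$dv)
})

test_that("with no between-subject variability CWRES reduces to (y - f) / (sigma f)", {
  toy <- make_toy(202, n_obs = 8)
  ds <- as_pk_dataset(healthy_subject_records(1, toy$times, toy$dv))
  m <- model_spec(params = toy$params, random = "cl_f", omega2 = 0,
                  sigma2 = c(toy$sigma2, toy$sigma2), add_sd = 0)
  g <- gof_table(ds, fake_fit(m, matrix(0, 1, 1)))
  f <- toy_pred(toy, 0)
  expect_equal(g$CWRES, (toy$dv - f) / (sqrt(toy$sigma2) * f),
               tolerance = 1e-12)
})

test_that("CWRES matches a dense linear-algebra reconstruction on a one-eta toy", {
  toy <- make_toy(203, n_obs = 5)
  ds <- as_pk_dataset(healthy_subject_records(1, toy$times, toy$dv))
  m <- model_spec(params = toy$params, random = "cl_f",
                  omega2 = toy$omega2,
                  sigma2 = c(toy$sigma2, toy$sigma2), add_sd = 0)
  em <- eta_mode(ds, m, 1)
  eta_hat <- unname(em$eta)
  g <- gof_table(ds, fake_fit(m, matrix(eta_hat, 1, 1)))
  # brute-force construction with its own finite differences
  h <- 1e-6
  G <- (toy_pred(toy, eta_hat + h) - toy_pred(toy, eta_hat - h)) / (2 * h)
  fhat <- toy_pred(toy, eta_hat)
  C <- toy$omega2 * outer(G, G) + diag(toy$sigma2 * fhat^2)
  ev <- eigen(C, symmetric = TRUE)
  Cmhalf <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  oracle <- drop(Cmhalf %*% (toy$dv - (fhat - G * eta_hat)))
  expect_equal(g$CWRES, oracle, tolerance = 1e-4)
})

test_that("CWRES is calibrated on data simulated from the true model", {
  cfg <- generator_config(n_patient = 100, seed = 210)
  ds <- generate_study2(cfg, seed = 210)
  m <- truth_model_spec(cfg)
  modes <- eta_modes(ds, m)
  g <- gof_table(ds, fake_fit(m, modes$eta))
  expect_lt(abs(mean(g$CWRES)), 0.1)
  expect_gt(var(g$CWRES), 0.8)
  expect_lt(var(g$CWRES), 1.2)
})

test_that("NPDE on model-true data is roughly standard normal and ranks behave at the clamps", {
  cfg <- generator_config(n_patient = 60, seed = 220)
  ds <- generate_study2(cfg, seed = 220)
  m <- truth_model_spec(cfg)
  res <- npde(ds, fake_fit(m, NULL), K = 400, seed = 1)
  expect_lt(abs(res$mean), 0.2)
  expect_gt(res$variance, 0.7)
  expect_lt(res$variance, 1.35)
  # an absurdly high observation is clamped at 1 - 1/(2K)
  rec <- ds$records
  first_obs <- which(rec$EVID == 0 & rec$MDV == 0)[1]
  rec$DV[first_obs] <- 1e6
  ds2 <- venpk:::.new_dataset(rec, ds$limits)
  res2 <- npde(ds2, fake_fit(m, NULL), K = 400, seed = 1)
  expect_equal(max(res2$table$npde, na.rm = TRUE), qnorm(1 - 1 / 800))
})

test_that("NPDE is invariant to analyte-wise rescaling of the concentration axis", {
  cfg <- generator_config(n_patient = 20, seed = 221)
  ds <- generate_study2(cfg, seed = 221)
  m <- truth_model_spec(cfg)
  res1 <- npde(ds, fake_fit(m, NULL), K = 200, seed = 9)
  # express ODV in tenths: scale observed DV and the model volume together
  rec <- ds$records
  odv <- rec$EVID == 0 & !is.na(rec$DVID) & rec$DVID == 2
  rec$DV[odv] <- rec$DV[odv] * 10
  # scaling clm_f and vm_f together leaves km (the dynamics) unchanged and
  # multiplies the reported ODV concentration by 10 - a pure unit change
  m2 <- m
  m2$params$vm_f <- m$params$vm_f / 10
  m2$params$clm_f <- m$params$clm_f / 10
  res2 <- npde(venpk:::.new_dataset(rec, ds$limits), fake_fit(m2, NULL),
               K = 200, seed = 9)
  expect_equal(res1$table$npde, res2$table$npde, tolerance = 1e-9)
})

test_that("structurally fixed observations (pre-dose zeros) are dropped from NPDE", {
  cfg <- generator_config(n_healthy = 6, seed = 222)
  ds <- generate_study1(cfg, seed = 222)
  m <- truth_model_spec(cfg)
  res <- npde(ds, fake_fit(m, NULL), K = 150, seed = 2)
  expect_gt(res$n_dropped, 0)   # the 12 pre-dose samples
  expect_true(all(is.finite(res$table$npde[!is.na(res$table$npde)])))
})

test_that("K below 100 is rejected", {
  cfg <- generator_config(n_patient = 3, seed = 223)
  ds <- generate_study2(cfg, seed = 223)
  expect_error(npde(ds, fake_fit(truth_model_spec(cfg), NULL), K = 50),
               "at least 100")
})

test_that("diagnostic export writes eight deterministic panels per analyte", {
  cfg <- generator_config(n_patient = 10, seed = 224)
  ds <- generate_study2(cfg, seed = 224)
  m <- truth_model_spec(cfg)
  modes <- eta_modes(ds, m)
  g <- gof_table(ds, fake_fit(m, modes$eta))
  res <- npde(ds, fake_fit(m, NULL), K = 150, seed = 3)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- diagnostic_export(g, res, dir1)
  f2 <- diagnostic_export(g, res, dir2)
  expect_length(f1, 16)
  expect_true(all(file.exists(f1)))
  # byte-identical re-export
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})

test_that("empty diagnostics still produce files with headers", {
  g <- data.frame(subject = integer(0), analyte = character(0),
                  time = numeric(0), tad = numeric(0), dv = numeric(0),
                  PRED = numeric(0), IPRED = numeric(0), CWRES = numeric(0))
  empty_npde <- structure(
    list(table = data.frame(subject = integer(0), analyte = character(0),
                            time = numeric(0), dv = numeric(0),
                            pred_median = numeric(0), npde = numeric(0)),
         mean = NaN, variance = NA_real_, t_stat = NA_real_,
         normality_p = NA_real_, n_used = 0L, n_dropped = 0L,
         K = 100, seed = 1), class = "npde_result")
  dir <- withr::local_tempdir()
  files <- diagnostic_export(g, empty_npde, dir)
  expect_length(files, 16)
  for (f in files) expect_gt(length(readLines(f)), 0)
})
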