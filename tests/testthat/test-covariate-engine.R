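# covariate effects, percent changes and the stepwise OFV-threshold search

p_def <- default_structural_params()

test_that("covariate-adjusted typical values reproduce the reported patient clearances", {
  morbid <- covariate_effect("cl_f", "morbid", "linear", -0.617)
  patient <- apply_covariates(p_def, list(morbid), list(morbid = 1))
  expect_equal(round(patient$cl_f), 31)
  ami <- covariate_effect("clm_f", "ami", "linear", 0.593)
  on_ami <- apply_covariates(p_def, list(ami), list(ami = 1, morbid = 1))
  expect_equal(round(on_ami$clm_f, 1), 35.2)
})

test_that("covariates at reference leave the parameters unchanged", {
  effs <- list(covariate_effect("cl_f", "morbid", "linear", -0.617),
               covariate_effect("v_f", "wt", "power", 0.75, ref = 62.5))
  same <- apply_covariates(p_def, effs, list(morbid = 0, wt = 62.5))
  expect_equal(unlist(same[venpk:::.param_names]),
               unlist(p_def[venpk:::.param_names]))
})

test_that("an effect that drives a parameter non-positive is rejected", {
  expect_error(covariate_effect("cl_f", "x", "linear", -1.2), "invalid-effect")
  eff <- covariate_effect("cl_f", "x", "linear", -0.9)
  # with a covariate value above 1 the linear fraction can still go negative
  expect_error(apply_covariates(p_def, list(eff), list(x = 2)),
               "invalid-effect")
  expect_error(apply_covariates(p_def, list(eff), list(y = 1)),
               "not found")
})

test_that("percent_change reports the reported signed effect sizes", {
  expect_equal(percent_change(covariate_effect("cl_f", "ami", "linear", -0.392)),
               -39.2)
  expect_equal(percent_change(covariate_effect("clm_f", "ami", "linear", 0.593)),
               59.3)
  expect_equal(percent_change(covariate_effect("cl_f", "x", "linear", 0)), 0)
})

test_that("percent_change is consistent with the applied parameter ratio", {
  for (th in c(-0.617, -0.392, 0.593, 0.25)) {
    eff <- covariate_effect("cl_f", "morbid", "linear", th)
    ratio <- apply_covariates(p_def, list(eff), list(morbid = 1))$cl_f /
      p_def$cl_f
    expect_equal(100 * (ratio - 1), percent_change(eff), tolerance = 1e-12)
  }
  pow <- covariate_effect("v_f", "wt", "power", 0.75, ref = 62.5)
  ratio <- apply_covariates(p_def, list(pow), list(wt = 80))$v_f / p_def$v_f
  expect_equal(100 * (ratio - 1), percent_change(pow, 80), tolerance = 1e-12)
})

# --- threshold logic with a stubbed fitter ---------------------------------

stub_fitter <- function(ofv_map) {
  function(dataset, model, control, start = NULL) {
    key <- paste(sort(vapply(model$effects, venpk:::.cand_label, "")),
                 collapse = "+")
    ofv <- ofv_map[[if (key == "") "base" else key]]
    if (is.null(ofv)) stop("no stubbed OFV for ", key)
    structure(list(model = model, ofv = ofv, eta = matrix(0, 2, 4),
                   par = numeric(0), convergence = 0L,
                   est_struct = venpk:::.param_names[-5]),
              class = "focei_fit")
  }
}

stub_base_fit <- function(base_model, ofv) {
  structure(list(model = base_model, ofv = ofv, eta = matrix(0, 2, 4),
                 par = numeric(0), convergence = 0L,
                 est_struct = venpk:::.param_names[-5]),
            class = "focei_fit")
}

test_that("forward inclusion requires an OFV drop strictly greater than 6.63", {
  base <- model_spec()
  cand <- list(covariate_effect("cl_f", "sex", "linear", 0),
               covariate_effect("cl_f", "smok", "linear", 0))
  # drop of exactly 6.63 is rejected, 6.64 is accepted (base at 0 keeps the
  # OFV differences exactly representable)
  f1 <- stub_fitter(list(base = 6.63, "sex->cl_f" = 0, "smok->cl_f" = 3.63))
  s1 <- forward_step(NULL, stub_base_fit(base, 6.63), cand, fitter = f1)
  expect_null(s1$accepted)
  f2 <- stub_fitter(list(base = 6.64, "sex->cl_f" = 0, "smok->cl_f" = 3.64))
  s2 <- forward_step(NULL, stub_base_fit(base, 6.64), cand, fitter = f2)
  expect_equal(venpk:::.cand_label(s2$accepted), "sex->cl_f")
  expect_equal(sum(s2$trace$decision == "accepted"), 1)
})

test_that("backward elimination retains a covariate only above a rise of 10.83", {
  m_full <- model_spec(effects = list(
    covariate_effect("cl_f", "morbid", "linear", -0.5)))
  # removal raises OFV by exactly 10.83: dropped (OFVs chosen so the
  # difference is exactly representable)
  f1 <- stub_fitter(list(base = 10.83, "morbid->cl_f" = 0))
  b1 <- backward_step(NULL, stub_base_fit(m_full, 0), fitter = f1)
  expect_length(b1$fit$model$effects, 0)
  # removal raises OFV by 10.84: retained
  f2 <- stub_fitter(list(base = 10.84, "morbid->cl_f" = 0))
  b2 <- backward_step(NULL, stub_base_fit(m_full, 0), fitter = f2)
  expect_length(b2$fit$model$effects, 1)
})

test_that("backward elimination of an empty model is a no-op with empty trace", {
  b <- backward_step(NULL, stub_base_fit(model_spec(), 500),
                     fitter = stub_fitter(list(base = 500)))
  expect_length(b$fit$model$effects, 0)
  expect_null(b$trace)
})

test_that("equal OFV drops break ties lexicographically on (parameter, covariate)", {
  base <- model_spec()
  cand <- list(covariate_effect("v_f", "ami", "linear", 0),
               covariate_effect("cl_f", "sex", "linear", 0))
  f <- stub_fitter(list(base = 1000, "ami->v_f" = 980, "sex->cl_f" = 980))
  s <- forward_step(NULL, stub_base_fit(base, 1000), cand, fitter = f)
  expect_equal(venpk:::.cand_label(s$accepted), "sex->cl_f")  # cl_f < v_f
})

# --- search behavior on simulated data -------------------------------------

test_that("a strong simulated morbid effect on clearance is selected first", {
  cfg <- generator_config(
    n_healthy = 8, n_patient = 16,
    effects = list(covariate_effect("cl_f", "morbid", "linear", -0.617)),
    seed = 71)
  sim <- generate_combined(cfg, seed = 71)
  base <- model_spec(omega2 = cfg$omega2, sigma2 = cfg$sigma2)
  base_fit <- focei_fit(sim$dataset, base,
                        control = focei_control(fast = TRUE))
  cand <- list(covariate_effect("cl_f", "morbid", "linear", 0),
               covariate_effect("cl_f", "sex", "linear", 0))
  stp <- forward_step(sim$dataset, base_fit, cand)
  expect_equal(venpk:::.cand_label(stp$accepted), "morbid->cl_f")
})

test_that("stepwise search is deterministic, lowers the OFV, and its trace round-trips", {
  cfg <- generator_config(
    n_healthy = 6, n_patient = 12,
    effects = list(covariate_effect("cl_f", "morbid", "linear", -0.617)),
    seed = 72)
  sim <- generate_combined(cfg, seed = 72)
  base <- model_spec(omega2 = cfg$omega2, sigma2 = cfg$sigma2)
  cand <- list(covariate_effect("cl_f", "morbid", "linear", 0),
               covariate_effect("v_f", "sex", "linear", 0))
  res1 <- stepwise_search(sim$dataset, base, cand)
  res2 <- stepwise_search(sim$dataset, base, cand)
  expect_identical(res1$selected, res2$selected)
  expect_equal(res1$fit$ofv, res2$fit$ofv, tolerance = 1e-10)
  expect_lte(res1$fit$ofv, res1$base_fit$ofv)
  path <- withr::local_tempfile()
  write_scm_trace(res1$trace, path)
  back <- read_scm_trace(path)
  expect_equal(back$candidate, res1$trace$candidate)
  expect_equal(back$delta_ofv, res1$trace$delta_ofv)
})

test_that("stepwise search with no candidates returns the base model", {
  cfg <- small_sim_config(seed = 73, n_healthy = 3, n_patient = 4)
  sim <- generate_combined(cfg, seed = 73)
  base <- model_spec(omega2 = cfg$omega2, sigma2 = cfg$sigma2)
  res <- stepwise_search(sim$dataset, base, list())
  expect_length(res$selected, 0)
  expect_equal(res$fit$ofv, res$base_fit$ofv)
  # pre-existing base-model covariates are not subject to elimination
  res2 <- stepwise_search(sim$dataset, truth_model_spec(cfg), list())
  expect_length(res2$fit$model$effects, 3)
  expect_equal(res2$fit$ofv, res2$base_fit$ofv)
})

test_that("the default candidate grid excludes confounded morbid-metabolite pairs", {
  cfg <- small_sim_config(seed = 74, n_healthy = 3, n_patient = 4)
  sim <- generate_combined(cfg, seed = 74)
  grid <- default_candidate_grid(sim$dataset)
  labels <- vapply(grid, venpk:::.cand_label, "")
  expect_false(any(labels %in% c("morbid->clm_f", "morbid->vm_f")))
  expect_equal(length(grid), 13 * 4 - 2)
  # continuous covariates use the power form with a pooled-median reference
  age_eff <- grid[[which(labels == "age->cl_f")[1]]]
  expect_equal(age_eff$form, "power")
  expect_true(is.finite(age_eff$ref) && age_eff$ref > 0)
})
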