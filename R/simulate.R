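#' Configuration for the synthetic study generators
#'
#' The generators emulate the two designs behind the joint VEN/ODV
#' analysis.  Study 1: an intensive single-dose crossover study in healthy
#' male volunteers (50 mg oral venlafaxine hydrochloride, 15 scheduled
#' samples over 36 h, two periods separated by a 7-day washout, VEN assay
#' only, LLOQ 0.2 ng/ml).  Study 2: naturalistic therapeutic drug
#' monitoring in psychiatric patients (steady-state morning troughs of VEN
#' and ODV, daily doses 25-300 mg, covariates at the reported frequencies,
#' assay ranges 4-400 and 20-2000 ng/ml).  The default true parameters,
#' covariate effects, between-subject variances and residual variances are
#' the published final-model estimates, so the generators double as the
#' truth for parameter-recovery experiments.  The reported variability
#' values are interpreted as variances (omega-squared / sigma-squared), the
#' conventional reporting scale of the estimation software, despite the
#' "%CV" label of the source table.
#'
#' @param params true structural parameters.
#' @param effects true covariate effects.
#' @param omega2 true between-subject variances (cl_f, v_f, clm_f, vm_f).
#' @param sigma2 true proportional residual variances (VEN, ODV).
#' @param n_healthy,n_patient arm sizes.
#' @param dose_healthy single dose (mg) of the intensive study.
#' @param schedule sampling times (h post-dose) of the intensive study.
#' @param n_periods,washout crossover structure of the intensive study.
#' @param dose_mean,dose_sd,dose_range,dose_step daily-dose distribution of
#'   the TDM arm (mg; truncated normal rounded to `dose_step`).
#' @param freq covariate frequencies of the TDM arm.
#' @param visits_range range of steady-state trough visits per patient.
#' @param trough_jitter half-width (h) of the uniform jitter around the
#'   end of the dosing interval at which troughs are drawn.
#' @param deterministic_freq logical: assign binary covariates with exact
#'   rounded counts (default) instead of independent Bernoulli draws.
#' @param limits assay quantitation limits.
#' @param seed master seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(params = default_structural_params(),
                             effects = final_model_spec()$effects,
                             omega2 = c(cl_f = 0.219, v_f = 0.106,
                                        clm_f = 0.156, vm_f = 1.38),
                             sigma2 = c(VEN = 0.123, ODV = 0.101),
                             n_healthy = 24, n_patient = 127,
                             dose_healthy = 50,
                             schedule = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4,
                                          6, 8, 10, 12, 24, 36),
                             n_periods = 2, washout = 168,
                             dose_mean = 132.86, dose_sd = 64.20,
                             dose_range = c(25, 300), dose_step = 12.5,
                             freq = c(female = 0.5512, sustained = 0.8362,
                                      smok = 0.0787, drink = 0.0472,
                                      vpa = 0.1816, qtp = 0.2338,
                                      clz = 0.1567, olz = 0.2450,
                                      ris = 0.1318, ami = 0.0547),
                             visits_range = c(2, 4),
                             trough_jitter = 1,
                             deterministic_freq = TRUE,
                             limits = default_assay_limits(),
                             seed = 978202) {
  stopifnot(inherits(params, "structural_params"))
  if (is.null(seed) || !is.finite(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(omega2 < 0) || any(sigma2 < 0))
    stop("variances must be nonnegative", call. = FALSE)
  structure(list(params = params, effects = effects,
                 omega2 = unname(omega2), sigma2 = unname(sigma2),
                 n_healthy = n_healthy, n_patient = n_patient,
                 dose_healthy = dose_healthy, schedule = schedule,
                 n_periods = n_periods, washout = washout,
                 dose_mean = dose_mean, dose_sd = dose_sd,
                 dose_range = dose_range, dose_step = dose_step,
                 freq = freq, visits_range = visits_range,
                 trough_jitter = trough_jitter,
                 deterministic_freq = deterministic_freq,
                 limits = limits, seed = as.integer(seed)),
            class = "generator_config")
}

# lab-value moments by arm (mean, sd, lower, upper)
.lab_moments <- list(
  healthy = list(ALT = c(21.67, 7.15, 7, 41), AST = c(19.21, 5.64, 15, 42),
                 BUN = c(4.35, 0.97, 2.63, 5.84), CR = c(76.13, 12.41, 51, 106)),
  patient = list(ALT = c(22.92, 18.36, 3, 112), AST = c(22.22, 14.13, 9, 116),
                 BUN = c(3.91, 1.36, 1.21, 8.61), CR = c(68.23, 16.15, 6.38, 129)))

.draw_labs <- function(n, arm) {
  mm <- .lab_moments[[arm]]
  out <- lapply(mm, function(m) round(.rtruncnorm(n, m[1], m[2], m[3], m[4]), 2))
  as.data.frame(out)
}

.assign_binary <- function(n, p, deterministic) {
  if (deterministic) {
    k <- round(p * n)
    out <- integer(n)
    if (k > 0) out[sample.int(n, k)] <- 1L
    out
  } else rbinom(n, 1, p)
}

.indiv_params <- function(config, covrow, eta) {
  p <- apply_covariates(config$params, config$effects, covrow)
  vals <- .param_vec(p)
  names(vals) <- .param_names
  vals[1:4] <- vals[1:4] * exp(eta)
  do.call(structural_params, as.list(vals))
}

.empty_record <- function(n) {
  data.frame(ID = integer(n), TIME = numeric(n), EVID = integer(n),
             AMT = rep(NA_real_, n), DVID = rep(NA_integer_, n),
             DV = rep(NA_real_, n), MDV = integer(n), SS = integer(n),
             II = numeric(n), ADDL = integer(n), BLQ = integer(n))
}

#' Generate the intensive healthy-volunteer study
#'
#' 24 healthy male subjects (ages uniform on 18-27 years, weights
#' truncated-normal 62.5 +/- 6.9 kg on 54-80 kg), a single 50 mg oral dose
#' per period, two crossover periods a washout apart, 15 scheduled VEN
#' samples per period (no ODV assay), then the quantitation-limit rules of
#' [apply_blq_rules()].  Identical seeds give byte-identical datasets.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed (defaults to the config master seed).
#' @param ids subject identifiers.
#' @return A `pk_dataset` with attributes `truth` (per-subject etas) and
#'   `blq_report`.
#' @export
generate_study1 <- function(config, seed = config$seed,
                            ids = seq_len(config$n_healthy)) {
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  n <- config$n_healthy
  cov <- data.frame(
    MORBID = 0L, SEX = 0L,
    AGE = sample(18:27, n, replace = TRUE),
    WT = round(.rtruncnorm(n, 62.5, 6.9, 54, 80), 1),
    FORM = 0L, SMOK = 0L, DRINK = 0L,
    VPA = 0L, QTP = 0L, CLZ = 0L, OLZ = 0L, RIS = 0L, AMI = 0L)
  cov <- cbind(cov, .draw_labs(n, "healthy"))
  eta <- matrix(rnorm(n * 4, 0, rep(sqrt(config$omega2), each = n)), n, 4)
  colnames(eta) <- c("cl_f", "v_f", "clm_f", "vm_f")

  recs <- list()
  for (i in seq_len(n)) {
    pi_ <- .indiv_params(config, cov[i, ], eta[i, ])
    dose_times <- (seq_len(config$n_periods) - 1) * config$washout
    reg <- do.call(pk_regimen, lapply(dose_times, function(td)
      dose_event(td, config$dose_healthy)))
    obs_t <- as.numeric(outer(config$schedule, dose_times, "+"))
    f <- conc_parent(pi_, reg, obs_t)
    dv <- f * (1 + rnorm(length(f), 0, sqrt(config$sigma2[1])))
    dv <- pmax(dv, 0)
    rd <- .empty_record(length(dose_times))
    rd$ID <- ids[i]; rd$TIME <- dose_times; rd$EVID <- 1L
    rd$AMT <- config$dose_healthy; rd$MDV <- 1L
    ro <- .empty_record(length(obs_t))
    ro$ID <- ids[i]; ro$TIME <- obs_t; ro$EVID <- 0L
    ro$DVID <- 1L; ro$DV <- dv
    rr <- rbind(rd, ro)
    rr <- cbind(rr, cov[rep(i, nrow(rr)), , drop = FALSE])
    recs[[i]] <- rr
  }
  ds <- as_pk_dataset(do.call(rbind, recs), config$limits)
  out <- apply_blq_rules(ds)
  truth <- data.frame(id = ids, eta)
  attr(out$dataset, "truth") <- truth
  attr(out$dataset, "blq_report") <- out$report
  out$dataset
}

#' Generate the sparse TDM patient study
#'
#' 127 psychiatric patients on steady-state venlafaxine: daily doses drawn
#' truncated-normal 132.86 +/- 64.2 mg on 25-300 mg and rounded to 12.5 mg
#' steps; sustained-release formulation (one daily dose) with probability
#' 0.8362, otherwise rapid-release (dose split q12h); binary covariates at
#' the reported frequencies (exact rounded counts by default); ages
#' truncated-normal 37.86 +/- 17.59 on 14-86 years.  Each patient
#' contributes 2-4 steady-state trough visits; at each visit both VEN and
#' ODV are measured at the end of the dosing interval plus a uniform
#' jitter of +/- 1 h (a late sample means the morning dose was taken after
#' sampling).  Out-of-range observations are excluded per
#' [apply_blq_rules()].
#'
#' @inheritParams generate_study1
#' @return A `pk_dataset` with attributes `truth` and `blq_report`.
#' @export
generate_study2 <- function(config, seed = config$seed,
                            ids = 1000 + seq_len(config$n_patient)) {
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  n <- config$n_patient
  fr <- config$freq
  det <- config$deterministic_freq
  cov <- data.frame(
    MORBID = 1L,
    SEX = .assign_binary(n, fr[["female"]], det),
    AGE = round(.rtruncnorm(n, 37.86, 17.59, 14, 86)),
    WT = round(.rtruncnorm(n, 61.95, 11.02, 38, 93), 1),
    FORM = .assign_binary(n, fr[["sustained"]], det),
    SMOK = .assign_binary(n, fr[["smok"]], det),
    DRINK = .assign_binary(n, fr[["drink"]], det),
    VPA = .assign_binary(n, fr[["vpa"]], det),
    QTP = .assign_binary(n, fr[["qtp"]], det),
    CLZ = .assign_binary(n, fr[["clz"]], det),
    OLZ = .assign_binary(n, fr[["olz"]], det),
    RIS = .assign_binary(n, fr[["ris"]], det),
    AMI = .assign_binary(n, fr[["ami"]], det))
  cov <- cbind(cov, .draw_labs(n, "patient"))
  daily <- .rtruncnorm(n, config$dose_mean, config$dose_sd,
                       config$dose_range[1], config$dose_range[2])
  daily <- pmin(pmax(round(daily / config$dose_step) * config$dose_step,
                     config$dose_range[1]), config$dose_range[2])
  eta <- matrix(rnorm(n * 4, 0, rep(sqrt(config$omega2), each = n)), n, 4)
  colnames(eta) <- c("cl_f", "v_f", "clm_f", "vm_f")
  nv <- sample(seq(config$visits_range[1], config$visits_range[2]), n,
               replace = TRUE)

  recs <- list()
  for (i in seq_len(n)) {
    pi_ <- .indiv_params(config, cov[i, ], eta[i, ])
    ii <- if (cov$FORM[i] == 1) 24 else 12
    amt <- if (cov$FORM[i] == 1) daily[i] else daily[i] / 2
    visit_t <- (seq_len(nv[i]) - 1) * 168
    jit <- runif(nv[i], -config$trough_jitter, config$trough_jitter)
    obs_t <- visit_t + ii + jit
    reg <- do.call(pk_regimen, lapply(visit_t, function(td)
      dose_event(td, amt, interdose_interval = ii, steady_state = TRUE)))
    fv <- conc_parent(pi_, reg, obs_t)
    fo <- conc_metabolite(pi_, reg, obs_t)
    dvv <- pmax(fv * (1 + rnorm(nv[i], 0, sqrt(config$sigma2[1]))), 0)
    dvo <- pmax(fo * (1 + rnorm(nv[i], 0, sqrt(config$sigma2[2]))), 0)
    rd <- .empty_record(nv[i])
    rd$ID <- ids[i]; rd$TIME <- visit_t; rd$EVID <- 1L
    rd$AMT <- amt; rd$MDV <- 1L; rd$SS <- 1L; rd$II <- ii
    ro <- .empty_record(2 * nv[i])
    ro$ID <- ids[i]; ro$TIME <- rep(obs_t, 2); ro$EVID <- 0L
    ro$DVID <- rep(c(1L, 2L), each = nv[i])
    ro$DV <- c(dvv, dvo)
    rr <- rbind(rd, ro)
    rr <- cbind(rr, cov[rep(i, nrow(rr)), , drop = FALSE])
    recs[[i]] <- rr
  }
  ds <- as_pk_dataset(do.call(rbind, recs), config$limits)
  out <- apply_blq_rules(ds)
  truth <- data.frame(id = ids, eta, daily_dose = daily, n_visits = nv)
  attr(out$dataset, "truth") <- truth
  attr(out$dataset, "blq_report") <- out$report
  out$dataset
}

#' Generate the combined two-study dataset with its truth record
#'
#' Concatenates a healthy intensive arm and a patient TDM arm with
#' disjoint subject ids and returns the complete simulation truth
#' (parameters, covariate effects, variances, per-subject etas) for
#' recovery experiments.
#'
#' @param config a [generator_config()].
#' @param seed master seed (study arms use `seed` and `seed + 1`).
#' @return A list: `dataset` (a `pk_dataset`, 24 + 127 subjects) and
#'   `truth`.
#' @export
generate_combined <- function(config, seed = config$seed) {
  s1 <- generate_study1(config, seed = seed)
  s2 <- generate_study2(config, seed = seed + 1L)
  rec <- rbind(s1$records, s2$records)
  ds <- as_pk_dataset(rec, config$limits)
  eff <- lapply(config$effects, function(e)
    list(parameter = e$parameter, covariate = e$covariate, form = e$form,
         theta = e$theta, ref = e$ref))
  truth <- list(params = as.list(config$params)[.param_names],
                effects = eff,
                omega2 = config$omega2, sigma2 = config$sigma2,
                eta = rbind(attr(s1, "truth")[, 1:5],
                            attr(s2, "truth")[, 1:5]),
                seed = seed)
  list(dataset = ds, truth = truth)
}

#' Write / read a simulation truth record
#'
#' @param truth truth record from [generate_combined()].
#' @param path JSON path.
#' @return `read_truth` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$eta <- as.data.frame(tr$eta)
  tr
}

#' Model specification matching the generator truth
#'
#' Convenience: the [model_spec()] whose parameters, covariate effects and
#' variances equal a generator configuration's truth (useful as the
#' final-model specification in recovery experiments).
#'
#' @param config a [generator_config()].
#' @return A [model_spec()].
#' @export
truth_model_spec <- function(config) {
  model_spec(params = config$params,
             omega2 = config$omega2,
             sigma2 = config$sigma2,
             effects = config$effects)
}
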