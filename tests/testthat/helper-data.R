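# in-code fixture builders for dataset-level tests

# minimal record data frame filled with healthy-volunteer covariates
make_records <- function(id, time, evid, amt = NA, dvid = NA, dv = NA,
                         mdv = 0, ss = 0, ii = 0, addl = 0, blq = 0,
                         morbid = 0, ami = 0) {
  n <- length(time)
  data.frame(ID = id, TIME = time, EVID = evid,
             AMT = rep_len(amt, n), DVID = rep_len(dvid, n),
             DV = rep_len(dv, n), MDV = rep_len(mdv, n),
             SS = rep_len(ss, n), II = rep_len(ii, n),
             ADDL = rep_len(addl, n), BLQ = rep_len(blq, n),
             MORBID = morbid, SEX = 0, AGE = 25, WT = 62.5, FORM = 0,
             SMOK = 0, DRINK = 0, VPA = 0, QTP = 0, CLZ = 0, OLZ = 0,
             RIS = 0, AMI = ami, ALT = 20, AST = 19, BUN = 4.3, CR = 76)
}

# one intensive healthy subject: dose at 0, observations at given times
healthy_subject_records <- function(id, times, dvs, dose = 50) {
  rbind(make_records(id, 0, 1, amt = dose, mdv = 1),
        make_records(id, times, 0, dvid = 1, dv = dvs))
}

# one TDM patient: steady-state q24 dose, paired VEN/ODV troughs
patient_subject_records <- function(id, dose, dv_ven, dv_odv, t_obs = 24,
                                    ami = 0) {
  rbind(make_records(id, 0, 1, amt = dose, mdv = 1, ss = 1, ii = 24,
                     morbid = 1, ami = ami),
        make_records(id, t_obs, 0, dvid = 1, dv = dv_ven, morbid = 1,
                     ami = ami),
        make_records(id, t_obs, 0, dvid = 2, dv = dv_odv, morbid = 1,
                     ami = ami))
}

# a small mixed dataset for smoke-level estimation tests
small_sim_config <- function(seed, n_healthy = 6, n_patient = 10) {
  generator_config(n_healthy = n_healthy, n_patient = n_patient, seed = seed)
}
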