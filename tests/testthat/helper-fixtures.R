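# Small in-code fixtures shared across the suite.

# ensemble with explicitly chosen parameter draws (vectors recycled to n)
fixed_ens <- function(alpha, beta, gamma, tmrel, diseases = "ALRI",
                      age_group = "all", n = 2) {
  df <- do.call(rbind, lapply(diseases, function(d) {
    data.frame(disease = d, age_group = age_group, draw = seq_len(n),
               alpha = rep_len(alpha, n), beta = rep_len(beta, n),
               gamma = rep_len(gamma, n), tmrel = rep_len(tmrel, n))
  }))
  as_ier_ensemble(df)
}

# baseline mortality table built directly
tiny_bm <- function(diseases, age_groups, rate = 0.01, rel = 0.2) {
  out <- do.call(rbind, lapply(diseases, function(d) {
    data.frame(disease = d, age_group = age_groups, mean = rate,
               lower = rate * (1 - rel), upper = rate * (1 + rel))
  }))
  class(out) <- c("baseline_mortality", "data.frame")
  out
}

tiny_lt <- function(age_groups, le) {
  out <- data.frame(age_group = age_groups, le = le)
  class(out) <- c("life_table", "data.frame")
  out
}

tiny_ages <- function(age_groups, fractions = NULL) {
  if (is.null(fractions)) fractions <- rep(1 / length(age_groups),
                                           length(age_groups))
  out <- data.frame(age_group = age_groups, fraction = fractions)
  class(out) <- c("age_structure", "data.frame")
  out
}

# uniform-fraction scenario set around a control field
uniform_scenario <- function(control, fractions) {
  off <- lapply(fractions, function(f) {
    gridded_field(control$values * (1 - f), control$spec, control$units)
  })
  names(off) <- names(fractions)
  scenario_set(control, off)
}

TABLE1_FRACTIONS <- c(AGR = 0.003, BBU = 0.028, DUS = 0.0002, ENE = 0.205,
                      IND = 0.16, RES = 0.50, TRA = 0.10)
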