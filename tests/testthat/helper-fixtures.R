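# in-code fixtures shared across test files

# minimal data frame accepted by primary_ancova(): randomized arms,
# ANCOVA truth beta1 on the treatment indicator, baseline effect 0.6
make_ancova_data <- function(n = 284, beta1 = 0.22, sd = 2.24,
                             seed = NULL) {
  gen <- function() {
    arm <- rep(c("TT", "ST"), length.out = n)
    pain_d0 <- sample(4:10, n, replace = TRUE)
    age <- round(rnorm(n, 62, 12))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    pain_d3 <- 1 + beta1 * (arm == "TT") + 0.6 * pain_d0 +
      0.01 * age + 0.1 * (sex == "male") + rnorm(n, 0, sd)
    data.frame(arm = arm, pain_d0 = pain_d0, age = age, sex = sex,
               pain_d3 = pain_d3, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# small complete trial: lists + dataset in one call
small_trial <- function(n_patients = 80, n_centers = 8, seed = 1, ...) {
  lists <- generate_pbr_lists(rand_config(n_centers = n_centers,
                                          seed = seed))
  generate_trial(trial_config(n_patients = n_patients, seed = seed + 1,
                              ...), lists)
}

# independent Holm oracle: direct step-down definition
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
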