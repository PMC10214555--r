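# Shared builders for small in-code fixtures.

arm <- function(study_id, treatment, n, mean, sd, outcome_label = NA_character_) {
  data.frame(study_id = study_id, treatment = treatment, n = n, mean = mean,
             sd = sd, outcome_label = outcome_label,
             follow_up = NA_character_, stringsAsFactors = FALSE)
}

two_arm_study <- function(study_id, t1, m1, s1, n1, t2, m2, s2, n2) {
  rbind(arm(study_id, t1, n1, m1, s1), arm(study_id, t2, n2, m2, s2))
}

# Literal brute-force evaluation of the DerSimonian-Laird formulas,
# independent of the package implementation.
dl_oracle <- function(y, v, z = 1.96) {
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  df <- length(y) - 1
  tau2 <- if (Q > df) (Q - df) / (sum(w) - sum(w^2) / sum(w)) else 0
  i2 <- if (Q > df) (Q - df) / Q else 0
  ws <- 1 / (v + tau2)
  md <- sum(ws * y) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  list(pooled_md = md, se = se, ci_low = md - z * se, ci_high = md + z * se,
       Q = Q, df = df, tau2 = tau2, i2 = i2)
}

# Hand-built posterior container with known draws, for summary-level tests.
fake_samples <- function(eff_free, treatments, reference, tau = 0.5) {
  free <- setdiff(treatments, reference)
  draws <- cbind(eff_free, tau = rep(tau, nrow(eff_free)))
  colnames(draws) <- c(paste0("d[", free, "]"), "tau")
  structure(
    list(model = NULL, settings = mcmc_settings(n_chains = 1, n_iter = 2,
                                                burn_in = 0, thin = 1),
         chains = list(draws), parameters = colnames(draws),
         d_names = paste0("d[", free, "]"),
         treatments = treatments, reference = reference),
    class = "nma_samples")
}

# Light MCMC settings for fast module tests (not the analysis defaults).
tiny_settings <- function(seed = 1, n_chains = 2) {
  mcmc_settings(n_chains = n_chains, n_iter = 1200, burn_in = 200, thin = 2,
                seed = seed)
}
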