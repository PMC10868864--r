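# Builders shared across test files.

one_stratum <- data.frame(sex = "M", race_eth = "White", weight = 1,
                          stringsAsFactors = FALSE)

# One continuous trait, single stratum; the workhorse for correlation and
# ACE-recovery checks.
sim_continuous <- function(n_pairs, a2, c2, seed, dz_fraction = 0.5) {
  cfg <- twin_sim_config(
    n_pairs = n_pairs, dz_fraction = dz_fraction, strata = one_stratum,
    traits = list(sim_trait("y", "continuous",
                            components = c(a2 = a2, c2 = c2, e2 = 1 - a2 - c2))),
    seed = seed)
  pair_twins(simulate_cohort(cfg))
}

sim_binary <- function(n_pairs, a2, c2, prevalence, seed, dz_fraction = 0.5) {
  cfg <- twin_sim_config(
    n_pairs = n_pairs, dz_fraction = dz_fraction, strata = one_stratum,
    traits = list(sim_trait("y", "binary", prevalence = prevalence,
                            components = c(a2 = a2, c2 = c2, e2 = 1 - a2 - c2))),
    seed = seed)
  pair_twins(simulate_cohort(cfg))
}

# Hand-built individual-level cohort rows.
make_records <- function(family_id, member_index, zygosity, sex = "M",
                         race_eth = "White", age_months = 120) {
  data.frame(family_id = family_id, member_index = member_index,
             zygosity = zygosity, sex = sex, race_eth = race_eth,
             age_months = age_months, stringsAsFactors = FALSE)
}

# Correlated binary pair data on the liability scale, family-clustered, as an
# individual-level cohort with a pair-constant group column.
sim_clustered_binary_cohort <- function(n_pairs, rho, prevalence,
                                        group_levels = c("a", "b")) {
  C <- rnorm(n_pairs)
  lat1 <- sqrt(rho) * C + sqrt(1 - rho) * rnorm(n_pairs)
  lat2 <- sqrt(rho) * C + sqrt(1 - rho) * rnorm(n_pairs)
  tau <- qnorm(1 - prevalence)
  g <- sample(group_levels, n_pairs, replace = TRUE)
  data.frame(
    family_id = rep(sprintf("f%05d", seq_len(n_pairs)), each = 2),
    y = as.numeric(rbind(lat1 > tau, lat2 > tau)),
    g = rep(g, each = 2),
    stringsAsFactors = FALSE)
}
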