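#' Simulate a same-sex twin cohort under a liability-threshold ACE model
#'
#' Generates one row per individual following the cohort schema used by
#' [read_cohort()]. For each pair a stratum and zygosity are drawn, then for
#' every configured trait a latent liability
#' `L_j = sqrt(a2)*A_j + sqrt(c2)*C + sqrt(e2)*E_j` with the additive deviates
#' `(A_1, A_2)` correlated 1 (MZ) or 0.5 (DZ), `C` shared and `E_j`
#' independent standard normals. Binary traits are thresholded at the normal
#' quantile for the target prevalence; continuous traits are rescaled to the
#' requested mean/SD.
#'
#' Traits named `"sips"` and `"intent"` are emitted as raw gated questionnaire
#' items (heard-of-alcohol and sipped for sips; the three susceptibility items
#' for intent, administered to never-sippers only) so that the phenotype
#' derivation in [derive_sips()]/[derive_intent()] is exercised end to end. A
#' small fraction (5%) of never-sippers answer "no" to the heard-of-alcohol
#' gate. Any other trait becomes a plain numeric column.
#'
#' Record defects (blanked zygosity, discordant zygosity labels, dropped
#' second member) are injected after generation at the configured rates; the
#' pristine pre-defect table is kept in `attr(cohort, "pristine")`.
#'
#' @param config A [twin_sim_config()] object.
#' @return A data.frame cohort, one row per individual, with attributes
#'   `pristine` (pre-defect cohort) and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_pairs
  st <- config$strata
  s_idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$weight)
  zyg <- ifelse(stats::runif(n) < config$dz_fraction, "DZ", "MZ")
  age <- round(stats::rnorm(n, config$age_months_mean, config$age_months_sd), 1)
  age <- pmax(age, 1)
  fam <- sprintf("fam%05d", seq_len(n))

  traits <- list()
  for (tr in config$traits) {
    comp <- tr$components
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
    if (nrow(comp) == 1) comp <- comp[rep(1, nrow(st)), , drop = FALSE]
    a2 <- comp[s_idx, 1]; c2 <- comp[s_idx, 2]; e2 <- comp[s_idx, 3]
    rho_a <- ifelse(zyg == "MZ", 1, 0.5)
    A1 <- stats::rnorm(n)
    A2 <- rho_a * A1 + sqrt(1 - rho_a^2) * stats::rnorm(n)
    C <- stats::rnorm(n)
    L1 <- sqrt(a2) * A1 + sqrt(c2) * C + sqrt(e2) * stats::rnorm(n)
    L2 <- sqrt(a2) * A2 + sqrt(c2) * C + sqrt(e2) * stats::rnorm(n)
    if (tr$type == "binary") {
      tau <- stats::qnorm(1 - tr$prevalence)
      traits[[tr$name]] <- cbind(as.numeric(L1 > tau), as.numeric(L2 > tau))
    } else {
      traits[[tr$name]] <- cbind(tr$mean + tr$sd * L1, tr$mean + tr$sd * L2)
    }
  }

  one_member <- function(j) {
    d <- data.frame(family_id = fam, member_index = j, zygosity = zyg,
                    sex = st$sex[s_idx], race_eth = st$race_eth[s_idx],
                    age_months = age, stringsAsFactors = FALSE)
    for (nm in names(traits)) d[[nm]] <- traits[[nm]][, j]
    d
  }
  cohort <- rbind(one_member(1), one_member(2))
  cohort <- cohort[order(cohort$family_id, cohort$member_index), ]
  rownames(cohort) <- NULL
  cohort <- fill_alcohol_items(cohort)

  pristine <- cohort
  counts <- round(config$defect_rates * n)
  cohort <- inject_defects(cohort, counts["missing_zygosity"],
                           counts["inconsistent_zygosity"], counts["singleton"],
                           order = sample.int(n))
  attr(cohort, "pristine") <- pristine
  attr(cohort, "config") <- config
  cohort
}

# Translate latent sips/intent phenotype columns into raw questionnaire items,
# respecting the gating (sipped asked only if heard; susceptibility items
# asked of never-sippers only). Drops the direct 0/1 columns afterwards so
# downstream phenotype derivation is the only route back.
fill_alcohol_items <- function(cohort) {
  m <- nrow(cohort)
  has_sips <- "sips" %in% names(cohort)
  has_intent <- "intent" %in% names(cohort)
  cohort$heard_alcohol <- rep(NA_character_, m)
  cohort$sipped <- rep(NA_character_, m)
  cohort$curious <- rep(NA_character_, m)
  cohort$try_soon <- rep(NA_character_, m)
  cohort$friend_offer <- rep(NA_character_, m)
  if (!has_sips && !has_intent) return(cohort)

  sips <- if (has_sips) cohort$sips else rep(0, m)
  cohort$heard_alcohol <- ifelse(sips == 1, "yes",
                                 ifelse(stats::runif(m) < 0.05, "no", "yes"))
  cohort$sipped <- ifelse(cohort$heard_alcohol == "no", NA_character_,
                          ifelse(sips == 1, "yes", "no"))
  if (has_intent) {
    never <- sips == 0
    intent <- cohort$intent
    floor_cur <- alcohol_item_levels$curious[1]
    floor_yn <- alcohol_item_levels$try_soon[1]
    cur <- ifelse(intent == 1,
                  sample(alcohol_item_levels$curious[-1], m, replace = TRUE),
                  floor_cur)
    ts <- ifelse(intent == 1,
                 sample(alcohol_item_levels$try_soon, m, replace = TRUE),
                 floor_yn)
    fo <- ifelse(intent == 1,
                 sample(alcohol_item_levels$friend_offer, m, replace = TRUE),
                 floor_yn)
    cohort$curious[never] <- cur[never]
    cohort$try_soon[never] <- ts[never]
    cohort$friend_offer[never] <- fo[never]
  }
  cohort$sips <- NULL
  cohort$intent <- NULL
  cohort
}

# Blank zygosity for the first n_missing pairs in `order`, make the next
# n_inconsistent discordant, and drop member 2 of the next n_singleton.
inject_defects <- function(cohort, n_missing, n_inconsistent, n_singleton,
                           order) {
  fams <- unique(cohort$family_id)
  stopifnot(n_missing + n_inconsistent + n_singleton <= length(fams))
  pick <- function(k, used) fams[order[seq.int(used + 1, length.out = k)]]
  miss <- pick(n_missing, 0)
  inc <- pick(n_inconsistent, n_missing)
  single <- pick(n_singleton, n_missing + n_inconsistent)
  cohort$zygosity[cohort$family_id %in% miss] <- NA_character_
  flip <- cohort$family_id %in% inc & cohort$member_index == 2
  cohort$zygosity[flip] <- ifelse(cohort$zygosity[flip] == "MZ", "DZ", "MZ")
  drop <- cohort$family_id %in% single & cohort$member_index == 2
  cohort <- cohort[!drop, ]
  rownames(cohort) <- NULL
  cohort
}

#' Deterministic cohort fixture with the study's exclusion ledger
#'
#' Builds a 1,069-pair cohort containing exactly 169 pairs with blanked
#' zygosity, 12 pairs with discordant zygosity labels between members, and 2
#' single-member families, so that [apply_exclusions()] retains 886 pairs.
#' Among the 886 clean pairs the zygosity composition is fixed at 535 DZ and
#' 351 MZ pairs (1,070 and 702 individuals, a 60.4% DZ share).
#'
#' @return A cohort data.frame (same schema as [simulate_cohort()]).
#' @export
exclusion_fixture <- function() {
  cfg <- twin_sim_config(n_pairs = 1069, seed = 20161101)
  cohort <- simulate_cohort(cfg)
  cohort <- attr(cohort, "pristine")
  fams <- unique(cohort$family_id)
  clean <- fams[seq_len(886)]
  zyg <- with_seed(20161102,
                   sample(rep(c("DZ", "MZ"), times = c(535, 351))))
  cohort$zygosity <- zyg[match(cohort$family_id, clean)]
  defect <- fams[-seq_len(886)]
  dzyg <- rep(c("DZ", "MZ"), length.out = length(defect))
  idx <- match(cohort$family_id, defect)
  cohort$zygosity[!is.na(idx)] <- dzyg[idx[!is.na(idx)]]
  cohort <- inject_defects(cohort, 169, 12, 2, order = 887:1069)
  cohort
}
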