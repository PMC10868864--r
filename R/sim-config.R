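#' @keywords internal
"_PACKAGE"

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Default sex-by-race strata for the synthetic twin cohort
#'
#' Stratum weights follow the composition of the analytic twin sample: 51.1%
#' male, and race/ethnicity split 65.4% White, 13.9% Black, 10.8% Hispanic,
#' 9.9% other, crossed independently.
#'
#' @return A data.frame with columns `sex`, `race_eth`, `weight`.
#' @export
default_strata <- function() {
  sex <- c(M = 0.511, F = 0.489)
  race <- c(White = 0.654, Black = 0.139, Hispanic = 0.108, Other = 0.099)
  g <- expand.grid(sex = names(sex), race_eth = names(race),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$weight <- as.vector(outer(sex, race))[match(
    paste(g$sex, g$race_eth),
    as.vector(outer(names(sex), names(race), paste)))]
  g$weight <- g$weight / sum(g$weight)
  g
}

#' Specify a simulated trait
#'
#' A trait is generated from a liability-threshold ACE model: each twin's
#' latent liability is `sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E` with `C` shared
#' within the pair, `E` individual, and the additive-genetic deviates `A`
#' correlated 1 within MZ and 0.5 within DZ pairs. Binary traits threshold the
#' liability at the normal quantile matching the target prevalence; continuous
#' traits rescale it to the requested mean and standard deviation.
#'
#' @param name Trait name. Traits named `"sips"` and `"intent"` are emitted as
#'   raw gated questionnaire items (see [simulate_cohort()]); any other trait
#'   becomes a plain column.
#' @param type `"binary"` or `"continuous"`.
#' @param prevalence Target prevalence (binary traits).
#' @param mean,sd Target mean and standard deviation (continuous traits).
#' @param components Length-3 numeric `c(a2, c2, e2)` summing to 1, or a matrix
#'   with one such row per stratum for stratum-specific variance components.
#' @return A `sim_trait` list.
#' @export
sim_trait <- function(name, type = c("binary", "continuous"),
                      prevalence = NULL, mean = 0, sd = 1,
                      components = c(a2 = 0.3, c2 = 0.3, e2 = 0.4)) {
  type <- match.arg(type)
  if (type == "binary" && is.null(prevalence)) {
    stop("binary trait '", name, "' needs a target prevalence")
  }
  structure(list(name = name, type = type, prevalence = prevalence,
                 mean = mean, sd = sd, components = components),
            class = "sim_trait")
}

default_traits <- function() {
  list(
    sim_trait("intent", "binary", prevalence = 0.235,
              components = c(a2 = 0.28, c2 = 0.00, e2 = 0.72)),
    sim_trait("sips", "binary", prevalence = 0.254,
              components = c(a2 = 0.04, c2 = 0.62, e2 = 0.34))
  )
}

#' Build and validate a twin-cohort simulation configuration
#'
#' Defaults emulate the baseline same-sex twin sample the analysis pipeline is
#' designed for: 886 pairs, 60.4% dizygotic, age 121.2 (SD 6.7) months, two
#' binary alcohol traits (intent, prevalence 23.5%, components 0.28/0/0.72;
#' sips, prevalence 25.4%, components 0.04/0.62/0.34), and no record defects.
#'
#' @param n_pairs Number of twin pairs to generate.
#' @param dz_fraction Probability that a pair is dizygotic.
#' @param strata Data.frame of strata (`sex`, `race_eth`, `weight`); weights
#'   must sum to 1.
#' @param traits List of [sim_trait()] specifications.
#' @param age_months_mean,age_months_sd Age distribution in months (twins in a
#'   pair share one draw).
#' @param defect_rates Named numeric: proportions of pairs given
#'   `missing_zygosity`, `inconsistent_zygosity`, or reduced to a `singleton`
#'   record. Rates must each lie in [0,1) and jointly below 1.
#' @param seed Integer RNG seed; generation is fully reproducible given the
#'   seed.
#' @return A validated `sim_config` list.
#' @export
twin_sim_config <- function(n_pairs = 886,
                            dz_fraction = 0.604,
                            strata = default_strata(),
                            traits = default_traits(),
                            age_months_mean = 121.2,
                            age_months_sd = 6.7,
                            defect_rates = c(missing_zygosity = 0,
                                             inconsistent_zygosity = 0,
                                             singleton = 0),
                            seed = NULL) {
  cfg <- structure(list(n_pairs = n_pairs, dz_fraction = dz_fraction,
                        strata = strata, traits = traits,
                        age_months_mean = age_months_mean,
                        age_months_sd = age_months_sd,
                        defect_rates = defect_rates, seed = seed),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(...) stop("invalid simulation config: ", ..., call. = FALSE)
  if (!is.numeric(cfg$n_pairs) || length(cfg$n_pairs) != 1 ||
      cfg$n_pairs < 1 || cfg$n_pairs != round(cfg$n_pairs)) {
    fail("n_pairs must be a positive integer")
  }
  if (!is.numeric(cfg$dz_fraction) || cfg$dz_fraction < 0 || cfg$dz_fraction > 1) {
    fail("dz_fraction must lie in [0, 1]")
  }
  st <- cfg$strata
  if (!is.data.frame(st) || !all(c("sex", "race_eth", "weight") %in% names(st))) {
    fail("strata must be a data.frame with sex, race_eth, weight")
  }
  if (!all(st$sex %in% c("M", "F"))) fail("stratum sex must be M or F")
  if (abs(sum(st$weight) - 1) > 1e-9) fail("stratum weights must sum to 1")
  if (any(st$weight < 0)) fail("stratum weights must be nonnegative")
  for (tr in cfg$traits) {
    comp <- tr$components
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
    if (ncol(comp) != 3) fail("trait '", tr$name, "': components must be (a2, c2, e2)")
    if (!nrow(comp) %in% c(1L, nrow(st))) {
      fail("trait '", tr$name, "': components need 1 row or one per stratum")
    }
    if (any(comp < 0)) fail("trait '", tr$name, "': components must be >= 0")
    if (any(abs(rowSums(comp) - 1) > 1e-9)) {
      fail("trait '", tr$name, "': a2 + c2 + e2 must equal 1")
    }
    if (tr$type == "binary" &&
        (tr$prevalence <= 0 || tr$prevalence >= 1)) {
      fail("trait '", tr$name, "': prevalence must lie in (0, 1)")
    }
  }
  dr <- cfg$defect_rates
  needed <- c("missing_zygosity", "inconsistent_zygosity", "singleton")
  if (!all(needed %in% names(dr))) fail("defect_rates must name ", paste(needed, collapse = ", "))
  if (any(dr < 0) || any(dr >= 1)) fail("defect rates must lie in [0, 1)")
  if (sum(dr) >= 1) fail("defect rates must jointly stay below 1")
  invisible(cfg)
}

#' Write / read a simulation configuration as a flat YAML file
#'
#' Traits and strata are flattened to scalar keys so the file stays a plain
#' key-value document.
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  flat <- list(
    n_pairs = cfg$n_pairs, dz_fraction = cfg$dz_fraction,
    age_months_mean = cfg$age_months_mean, age_months_sd = cfg$age_months_sd,
    seed = cfg$seed,
    defect_rates = as.list(cfg$defect_rates),
    strata = lapply(seq_len(nrow(cfg$strata)), function(i) as.list(cfg$strata[i, ])),
    traits = lapply(cfg$traits, function(tr) {
      tr$components <- as.list(stats::setNames(as.numeric(tr$components),
                                               c("a2", "c2", "e2")))
      unclass(tr)
    })
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  flat <- yaml::read_yaml(path)
  strata <- do.call(rbind, lapply(flat$strata, as.data.frame))
  traits <- lapply(flat$traits, function(tr) {
    sim_trait(tr$name, tr$type, prevalence = tr$prevalence,
              mean = tr$mean %||% 0, sd = tr$sd %||% 1,
              components = unlist(tr$components))
  })
  twin_sim_config(n_pairs = flat$n_pairs, dz_fraction = flat$dz_fraction,
                  strata = strata, traits = traits,
                  age_months_mean = flat$age_months_mean,
                  age_months_sd = flat$age_months_sd,
                  defect_rates = unlist(flat$defect_rates),
                  seed = flat$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
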