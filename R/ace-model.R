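#' Bivariate-normal upper orthant probability
#'
#' `P(L1 > tau1, L2 > tau2)` for standard bivariate normal liabilities with
#' correlation `rho` — the kernel of the liability-threshold pair likelihood.
#' Uses the classic reduction to a 1-D integral over the correlation,
#' `P = pnorm(-tau1) * pnorm(-tau2) + (1/2pi) * int_0^rho phi2(tau1, tau2; r) dr`,
#' evaluated by adaptive quadrature to absolute accuracy better than 1e-10.
#' `|rho| = 1` is handled by the degenerate closed forms.
#'
#' @param tau1,tau2 Thresholds.
#' @param rho Correlation in [-1, 1].
#' @return The orthant probability.
#' @export
orthant_probability <- function(tau1, tau2, rho) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (rho == 1) return(stats::pnorm(max(tau1, tau2), lower.tail = FALSE))
  if (rho == -1) return(max(0, 1 - stats::pnorm(tau1) - stats::pnorm(tau2)))
  base <- stats::pnorm(-tau1) * stats::pnorm(-tau2)
  if (rho == 0) return(base)
  integrand <- function(r) {
    om <- 1 - r^2
    exp(-(tau1^2 - 2 * r * tau1 * tau2 + tau2^2) / (2 * om)) / sqrt(om)
  }
  corr <- stats::integrate(integrand, 0, rho, rel.tol = 1e-12,
                           abs.tol = 1e-13, subdivisions = 500L)$value
  min(1, max(0, base + corr / (2 * pi)))
}

#' Falconer moment decomposition from zygosity-specific correlations
#'
#' `h2 = 2 * (r_mz - r_dz)` and `c2 = 2 * r_dz - r_mz`; negative raw
#' components are truncated to zero (and `h2 + c2` capped at 1), after which
#' `e2 = 1 - h2 - c2`. No standard errors are attached (moment method).
#'
#' @param r_mz,r_dz Within-pair correlations for MZ and DZ pairs, in [-1, 1].
#' @return A `variance_components` object with `h2`, `c2`, `e2`, the
#'   untruncated raw values, `source = "moment"`.
#' @export
falconer <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  h2_raw <- 2 * (r_mz - r_dz)
  c2_raw <- 2 * r_dz - r_mz
  h2 <- min(1, max(0, h2_raw))
  c2 <- min(1 - h2, max(0, c2_raw))
  e2 <- 1 - h2 - c2
  structure(list(h2 = h2, c2 = c2, e2 = e2,
                 raw = c(h2 = h2_raw, c2 = c2_raw),
                 r_mz = r_mz, r_dz = r_dz,
                 scale = "observed", source = "moment"),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s, %s scale)\n", x$source, x$scale))
  cat(sprintf("  h2 = %.3f  c2 = %.3f  e2 = %.3f\n", x$h2, x$c2, x$e2))
  if (!is.null(x$raw) && any(x$raw < 0)) {
    cat(sprintf("  (raw: h2 = %.3f, c2 = %.3f; negatives truncated)\n",
                x$raw["h2"], x$raw["c2"]))
  }
  invisible(x)
}

# Free variance components per model ladder rung.
model_free <- function(model) {
  switch(model,
         ACE = c(a = TRUE, c = TRUE),
         AE = c(a = TRUE, c = FALSE),
         CE = c(a = FALSE, c = TRUE),
         E = c(a = FALSE, c = FALSE),
         stop("unknown model: ", model))
}

#' Fit an ACE/AE/CE/E twin variance-component model by maximum likelihood
#'
#' Continuous traits maximize the pair-level bivariate Gaussian likelihood:
#' each pair is bivariate normal with common mean (`intercept + covariates`),
#' total variance `va + vc + ve` and within-pair covariance `va + vc` (MZ) or
#' `va/2 + vc` (DZ). Binary traits maximize the exact liability-threshold pair
#' likelihood: cell probabilities are bivariate-normal orthant probabilities
#' with liability correlation `h2 + c2` (MZ) or `h2/2 + c2` (DZ) and threshold
#' `tau - x' beta`, with `h2 + c2 + e2 = 1` enforced on the liability scale.
#'
#' Components excluded by the model are fixed at zero. Optimization runs over
#' unconstrained transforms of the nonnegative components from three
#' deterministic starts (a moment-based start plus two fixed jitters);
#' standard errors for the component proportions come from the delta method on
#' the observed information.
#'
#' @param pairs A `twin_pairs` data.frame.
#' @param trait Trait name (columns `<trait>_1`, `<trait>_2`).
#' @param model One of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param covariates Optional character vector of pair columns entering the
#'   mean (continuous) or threshold (binary). A column `<name>` applies to
#'   both members; `<name>_1`/`<name>_2` columns are used per member when
#'   present.
#' @param scale `"auto"` (liability for 0/1 traits, observed otherwise),
#'   `"liability"`, or `"observed"` (fits the Gaussian model to 0/1 data as a
#'   sensitivity analysis).
#' @return An `ace_fit` object: component estimates with SEs/CIs/p-values,
#'   `loglik`, `bic` (`-2 logLik + k log(n_pairs)`), pair counts, convergence
#'   diagnostics.
#' @export
fit_ace <- function(pairs, trait, model = c("ACE", "AE", "CE", "E"),
                    covariates = NULL, scale = c("auto", "liability", "observed")) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  x1 <- pairs[[paste0(trait, "_1")]]
  x2 <- pairs[[paste0(trait, "_2")]]
  if (is.null(x1) || is.null(x2)) stop("trait columns not found for: ", trait)
  keep <- !is.na(x1) & !is.na(x2) & pairs$zygosity %in% c("MZ", "DZ")
  x1 <- x1[keep]; x2 <- x2[keep]
  mz <- pairs$zygosity[keep] == "MZ"
  n_mz <- sum(mz); n_dz <- sum(!mz)
  binary <- all(c(x1, x2) %in% 0:1)
  if (scale == "auto") scale <- if (binary) "liability" else "observed"
  if (scale == "liability" && !binary) {
    stop("liability scale requires a 0/1 trait")
  }
  X <- covariate_matrices(pairs[keep, , drop = FALSE], covariates)
  fit <- if (scale == "liability") {
    fit_ace_binary(x1, x2, mz, model, X)
  } else {
    fit_ace_continuous(x1, x2, mz, model, X)
  }
  fit$trait <- trait
  fit$model <- model
  fit$scale <- scale
  fit$trait_type <- if (binary) "binary" else "continuous"
  fit$n_pairs <- c(MZ = n_mz, DZ = n_dz)
  fit$bic <- -2 * fit$loglik + fit$k * log(n_mz + n_dz)
  class(fit) <- "ace_fit"
  fit
}

covariate_matrices <- function(pairs, covariates) {
  n <- nrow(pairs)
  if (is.null(covariates) || !length(covariates)) {
    return(list(X1 = matrix(1, n, 1), X2 = matrix(1, n, 1),
                names = "(Intercept)"))
  }
  grab <- function(suffix) {
    cols <- lapply(covariates, function(cv) {
      per <- paste0(cv, suffix)
      v <- if (per %in% names(pairs)) pairs[[per]] else pairs[[cv]]
      if (is.null(v)) stop("covariate column not found: ", cv)
      as.numeric(v)
    })
    cbind(1, do.call(cbind, cols))
  }
  list(X1 = grab("_1"), X2 = grab("_2"),
       names = c("(Intercept)", covariates))
}

# Shared multi-start driver: minimize negll from each start (Nelder-Mead then
# BFGS polish), return the best optimum and its Hessian.
multi_start_optim <- function(negll, starts) {
  best <- NULL
  for (s in starts) {
    o <- tryCatch({
      o1 <- if (length(s) > 1) {
        stats::optim(s, negll, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 5000))
      } else {
        list(par = s, value = negll(s))
      }
      o2 <- suppressWarnings(
        stats::optim(o1$par, negll, method = "BFGS",
                     control = list(reltol = 1e-12, maxit = 500)))
      if (o2$value <= o1$value) o2 else o1
    }, error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization failed from every start")
  best$hessian <- tryCatch(stats::optimHess(best$par, negll),
                           error = function(e) NULL)
  best
}

# Delta-method SEs for proportion functions g(theta) given the negll Hessian.
delta_se <- function(hess, par, g) {
  if (is.null(hess)) return(NULL)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)) return(NULL)
  J <- pracma::jacobian(g, par)
  V <- J %*% vc %*% t(J)
  d <- diag(V)
  if (any(d < -1e-8)) return(NULL)
  sqrt(pmax(d, 0))
}

component_table <- function(est, se, free) {
  comp <- c("h2", "c2", "e2")
  keep <- c(free["a"], free["c"], TRUE)
  se_full <- rep(NA_real_, 3)
  if (!is.null(se)) se_full[keep] <- se
  data.frame(component = comp, estimate = est, se = se_full,
             lower = est - 1.96 * se_full, upper = est + 1.96 * se_full,
             p = 2 * stats::pnorm(-abs(est / se_full)),
             free = keep, stringsAsFactors = FALSE)[keep, ]
}

fit_ace_continuous <- function(x1, x2, mz, model, X) {
  if (min(sum(mz), sum(!mz)) < 10) {
    stop("need at least 10 complete pairs per zygosity")
  }
  free <- model_free(model)
  p <- ncol(X$X1)
  idx_beta <- seq_len(p)
  n_var <- 1L + sum(free)

  unpack <- function(theta) {
    beta <- theta[idx_beta]
    v <- theta[-idx_beta]^2
    i <- 1
    va <- 0; vc <- 0
    if (free["a"]) { va <- v[i]; i <- i + 1 }
    if (free["c"]) { vc <- v[i]; i <- i + 1 }
    ve <- v[i]
    list(beta = beta, va = va, vc = vc, ve = ve)
  }
  negll <- function(theta) {
    q <- unpack(theta)
    V <- q$va + q$vc + q$ve
    if (V <= 1e-12 || q$ve <= 1e-12) return(1e10)
    cv <- ifelse(mz, q$va + q$vc, q$va / 2 + q$vc)
    det <- V^2 - cv^2
    if (any(det <= 0)) return(1e10)
    d1 <- x1 - drop(X$X1 %*% q$beta)
    d2 <- x2 - drop(X$X2 %*% q$beta)
    Q <- (V * (d1^2 + d2^2) - 2 * cv * d1 * d2) / det
    ll <- sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * Q)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # moment-based start plus two deterministic jitters
  s2 <- stats::var(c(x1, x2))
  r_mz <- if (sum(mz) > 2) suppressWarnings(stats::cor(x1[mz], x2[mz])) else 0
  r_dz <- if (sum(!mz) > 2) suppressWarnings(stats::cor(x1[!mz], x2[!mz])) else 0
  if (!is.finite(r_mz)) r_mz <- 0
  if (!is.finite(r_dz)) r_dz <- 0
  mom <- falconer(max(-0.99, min(0.99, r_mz)), max(-0.99, min(0.99, r_dz)))
  clamp <- function(z) pmin(0.95, pmax(0.02, z))
  beta0 <- tryCatch(stats::qr.solve(rbind(X$X1, X$X2), c(x1, x2)),
                    error = function(e) c(mean(c(x1, x2)), rep(0, p - 1)))
  mk_start <- function(h2, c2) {
    e2 <- max(0.02, 1 - h2 - c2)
    tot <- h2 + c2 + e2
    v <- s2 * c(h2, c2, e2) / tot
    sel <- c(free["a"], free["c"], TRUE)
    c(beta0, sqrt(v[sel]))
  }
  starts <- list(mk_start(clamp(mom$h2), clamp(mom$c2)),
                 mk_start(1 / 3, 1 / 3),
                 mk_start(0.1, 0.1))

  best <- multi_start_optim(negll, starts)
  q <- unpack(best$par)
  V <- q$va + q$vc + q$ve
  est <- c(h2 = q$va / V, c2 = q$vc / V, e2 = q$ve / V)
  g <- function(theta) {
    qq <- unpack(theta)
    VV <- qq$va + qq$vc + qq$ve
    out <- c(qq$va, qq$vc, qq$ve) / VV
    out[c(free["a"], free["c"], TRUE)]
  }
  se <- delta_se(best$hessian, best$par, g)
  if (is.null(se)) {
    warning("observed information not invertible; SEs reported missing")
  }
  list(estimates = est, components = component_table(est, se, free),
       beta = stats::setNames(q$beta, X$names),
       variances = c(va = q$va, vc = q$vc, ve = q$ve),
       loglik = -best$value, k = p + n_var,
       convergence = best$convergence %||% 0L, n_starts = length(starts))
}

fit_ace_binary <- function(x1, x2, mz, model, X) {
  free <- model_free(model)
  has_cov <- ncol(X$X1) > 1
  for (z in c(TRUE, FALSE)) {
    if (length(unique(c(x1[z == mz], x2[z == mz]))) < 2) {
      stop("degenerate concordance margin in ",
           if (z) "MZ" else "DZ", " pairs")
    }
  }
  p <- ncol(X$X1)
  idx_beta <- seq_len(p)  # beta[1] is the threshold tau (sign: tau - x'beta)

  unpack <- function(theta) {
    beta <- theta[idx_beta]
    u <- theta[-idx_beta]
    i <- 1
    pa <- 0; pc <- 0
    if (free["a"]) { pa <- u[i]; i <- i + 1 }
    if (free["c"]) pc <- u[i]
    tot <- pa^2 + pc^2 + 1
    list(beta = beta, h2 = pa^2 / tot, c2 = pc^2 / tot, e2 = 1 / tot)
  }
  cell_ll <- function(n11, nd, n00, tau, rho) {
    p11 <- orthant_probability(tau, tau, rho)
    p1 <- stats::pnorm(tau, lower.tail = FALSE)
    probs <- pmax(c(p11, p1 - p11, 1 - 2 * p1 + p11), 1e-300)
    n11 * log(probs[1]) + nd * log(probs[2]) + n00 * log(probs[3])
  }
  counts <- function(z) {
    a <- x1[z]; b <- x2[z]
    c(n11 = sum(a & b), nd = sum(a != b), n00 = sum(!a & !b))
  }
  cmz <- counts(mz); cdz <- counts(!mz)

  negll <- if (!has_cov) {
    function(theta) {
      q <- unpack(theta)
      tau <- q$beta[1]
      rmz <- q$h2 + q$c2
      rdz <- q$h2 / 2 + q$c2
      if (rmz >= 1 - 1e-9) return(1e10)
      ll <- cell_ll(cmz["n11"], cmz["nd"], cmz["n00"], tau, rmz) +
        cell_ll(cdz["n11"], cdz["nd"], cdz["n00"], tau, rdz)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  } else {
    function(theta) {
      q <- unpack(theta)
      tau1 <- q$beta[1] - drop(X$X1[, -1, drop = FALSE] %*% q$beta[-1])
      tau2 <- q$beta[1] - drop(X$X2[, -1, drop = FALSE] %*% q$beta[-1])
      rho <- ifelse(mz, q$h2 + q$c2, q$h2 / 2 + q$c2)
      if (any(rho >= 1 - 1e-9)) return(1e10)
      ll <- 0
      for (i in seq_along(x1)) {
        p11 <- orthant_probability(tau1[i], tau2[i], rho[i])
        p1 <- stats::pnorm(tau1[i], lower.tail = FALSE)
        p2 <- stats::pnorm(tau2[i], lower.tail = FALSE)
        pr <- if (x1[i] && x2[i]) p11
        else if (x1[i] && !x2[i]) p1 - p11
        else if (!x1[i] && x2[i]) p2 - p11
        else 1 - p1 - p2 + p11
        ll <- ll + log(max(pr, 1e-300))
      }
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }

  prev <- mean(c(x1, x2))
  tau0 <- stats::qnorm(1 - prev)
  start_rho <- function() {
    tc <- function(z) tryCatch(suppressWarnings(tetrachoric(x1[z], x2[z]))$rho,
                               error = function(e) 0)
    mom <- falconer(max(-0.9, min(0.9, tc(mz))), max(-0.9, min(0.9, tc(!mz))))
    c(mom$h2, mom$c2)
  }
  mk_start <- function(h2, c2) {
    e2 <- max(0.05, 1 - h2 - c2)
    u <- c(sqrt(h2 / e2), sqrt(c2 / e2))
    c(tau0, rep(0, p - 1), u[c(free["a"], free["c"])])
  }
  mh <- start_rho()
  clamp <- function(z) pmin(0.9, pmax(0.02, z))
  starts <- list(mk_start(clamp(mh[1]), clamp(mh[2])),
                 mk_start(0.3, 0.3),
                 mk_start(0.05, 0.05))

  best <- multi_start_optim(negll, starts)
  q <- unpack(best$par)
  est <- c(h2 = q$h2, c2 = q$c2, e2 = q$e2)
  g <- function(theta) {
    qq <- unpack(theta)
    c(qq$h2, qq$c2, qq$e2)[c(free["a"], free["c"], TRUE)]
  }
  se <- delta_se(best$hessian, best$par, g)
  if (is.null(se)) {
    warning("observed information not invertible; SEs reported missing")
  }
  boundary <- (free["a"] && est["h2"] < 1e-6) || (free["c"] && est["c2"] < 1e-6)
  list(estimates = est, components = component_table(est, se, free),
       beta = stats::setNames(q$beta, c("threshold", X$names[-1])),
       threshold = q$beta[1],
       loglik = -best$value, k = p + sum(free),
       convergence = best$convergence %||% 0L, n_starts = length(starts),
       boundary = boundary)
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s model for '%s' (%s, %s scale)\n",
              x$model, x$trait, x$trait_type, x$scale))
  cat(sprintf("  pairs: %d MZ / %d DZ; logLik = %.3f; BIC = %.3f\n",
              x$n_pairs["MZ"], x$n_pairs["DZ"], x$loglik, x$bic))
  print(format(x$components, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Wald intervals and p-values for fitted variance components
#'
#' Delta-method standard errors with untruncated symmetric 95% intervals
#' (`estimate +/- 1.96 SE`; lower bounds may be negative even though point
#' estimates are constrained nonnegative) and two-sided Wald p-values.
#' Components fixed at zero by the model are not reported.
#'
#' @param fit An `ace_fit`, or a list with `estimates` and `se` entries.
#' @return A data.frame with `component`, `estimate`, `se`, `lower`, `upper`,
#'   `p`.
#' @export
wald_ci <- function(fit) {
  if (inherits(fit, "ace_fit")) {
    out <- fit$components
    return(out[, c("component", "estimate", "se", "lower", "upper", "p")])
  }
  est <- fit$estimates; se <- fit$se
  data.frame(component = names(est), estimate = unname(est),
             se = unname(se), lower = unname(est - 1.96 * se),
             upper = unname(est + 1.96 * se),
             p = unname(2 * stats::pnorm(-abs(est / se))),
             stringsAsFactors = FALSE)
}

#' Fit the full ACE/AE/CE/E model ladder
#'
#' @inheritParams fit_ace
#' @return Named list of `ace_fit` objects (`ACE`, `AE`, `CE`, `E`).
#' @export
fit_ace_ladder <- function(pairs, trait, covariates = NULL,
                           scale = c("auto", "liability", "observed")) {
  scale <- match.arg(scale)
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(m) {
    fit_ace(pairs, trait, model = m, covariates = covariates, scale = scale)
  })
  names(fits) <- c("ACE", "AE", "CE", "E")
  fits
}

#' Compare nested twin models and apply boundary-driven reduction
#'
#' If the full ACE fit puts the shared-environment component on the zero
#' boundary (c2 below `boundary_tol`), the AE fit is reported; symmetrically,
#' h2 on the boundary yields the CE fit. Otherwise the BIC-minimizing
#' candidate is returned. The selection rationale is attached as an attribute.
#'
#' @param fits Named list of `ace_fit` objects including `"ACE"` (e.g. from
#'   [fit_ace_ladder()]).
#' @param boundary_tol Boundary tolerance for a component (default 1e-6).
#' @return The selected `ace_fit`, with `attr(, "selection")` describing why.
#' @export
compare_and_reduce <- function(fits, boundary_tol = 1e-6) {
  if (is.null(names(fits))) names(fits) <- vapply(fits, `[[`, "", "model")
  ace <- fits[["ACE"]]
  if (is.null(ace)) stop("fits must include the full ACE model")
  pick <- function(fit, why) { attr(fit, "selection") <- why; fit }
  if (ace$estimates["c2"] < boundary_tol && !is.null(fits[["AE"]])) {
    return(pick(fits[["AE"]],
                "ACE c2 at the zero boundary; reduced to AE"))
  }
  if (ace$estimates["h2"] < boundary_tol && !is.null(fits[["CE"]])) {
    return(pick(fits[["CE"]],
                "ACE h2 at the zero boundary; reduced to CE"))
  }
  bics <- vapply(fits, `[[`, 0, "bic")
  winner <- names(bics)[which.min(bics)]
  pick(fits[[winner]],
       sprintf("interior ACE optimum; %s minimizes BIC (%.2f)",
               winner, min(bics)))
}

#' Stratified twin analysis mirroring a by-subgroup components table
#'
#' For each level of a pair-level stratifier (e.g. sex or race/ethnicity):
#' prevalence (or mean) by zygosity, zygosity-specific pair correlations, and
#' — when both zygosity groups have at least `min_pairs` complete pairs — the
#' boundary-reduced/BIC-selected variance-component fit with Wald intervals.
#' Strata below the fitting minimum get their descriptive columns and a
#' status note instead of model results.
#'
#' @param pairs A `twin_pairs` data.frame.
#' @param trait Trait name.
#' @param strata Name of a pair-level column (`"sex"`, `"race_eth"`, ...).
#' @param min_pairs Minimum complete pairs per zygosity for an ML fit
#'   (default 30).
#' @param scale Passed to [fit_ace()].
#' @param model `"reduce"` (default) reports the boundary-reduced /
#'   BIC-selected model per stratum; any of `"ACE"`, `"AE"`, `"CE"`, `"E"`
#'   reports that fixed model instead (the full ACE decomposition is what a
#'   three-component per-stratum table prints).
#' @return A data.frame with one row per stratum.
#' @export
stratified_ace <- function(pairs, trait, strata, min_pairs = 30,
                           scale = c("auto", "liability", "observed"),
                           model = c("reduce", "ACE", "AE", "CE", "E")) {
  scale <- match.arg(scale)
  model <- match.arg(model)
  sv <- pairs[[strata]]
  if (is.null(sv)) stop("strata column not found: ", strata)
  levels <- unique(sv[!is.na(sv)])
  v1 <- pairs[[paste0(trait, "_1")]]
  v2 <- pairs[[paste0(trait, "_2")]]
  rows <- lapply(levels, function(lv) {
    sub <- pairs[!is.na(sv) & sv == lv, , drop = FALSE]
    cors <- twin_correlations(sub, trait)
    grab <- function(z, col) cors[cors$zygosity == z, col]
    s1 <- sub[[paste0(trait, "_1")]]; s2 <- sub[[paste0(trait, "_2")]]
    lev_mean <- function(z) {
      vals <- c(s1[sub$zygosity == z], s2[sub$zygosity == z])
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
    binary <- all(stats::na.omit(c(s1, s2)) %in% 0:1)
    out <- data.frame(stratum = lv,
                      n_pairs_mz = grab("MZ", "n"), n_pairs_dz = grab("DZ", "n"),
                      prev_mz = if (binary) 100 * lev_mean("MZ") else lev_mean("MZ"),
                      prev_dz = if (binary) 100 * lev_mean("DZ") else lev_mean("DZ"),
                      r_mz = grab("MZ", "r"), r_dz = grab("DZ", "r"),
                      model = NA_character_, h2 = NA_real_, h2_lower = NA_real_,
                      h2_upper = NA_real_, c2 = NA_real_, c2_lower = NA_real_,
                      c2_upper = NA_real_, e2 = NA_real_, e2_lower = NA_real_,
                      e2_upper = NA_real_, bic = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    if (min(out$n_pairs_mz, out$n_pairs_dz) < min_pairs) {
      out$status <- sprintf("fewer than %d complete pairs per zygosity; descriptives only",
                            min_pairs)
      return(out)
    }
    sel <- tryCatch({
      if (model == "reduce") {
        compare_and_reduce(fit_ace_ladder(sub, trait, scale = scale))
      } else {
        fit_ace(sub, trait, model = model, scale = scale)
      }
    }, error = function(e) e)
    if (inherits(sel, "error")) {
      out$status <- paste("model fit failed:", conditionMessage(sel))
      return(out)
    }
    comp <- sel$components
    fill <- function(name, col) {
      r <- comp[comp$component == name, ]
      if (nrow(r)) r[[col]] else if (col == "estimate") 0 else NA_real_
    }
    out$model <- sel$model
    out$bic <- sel$bic
    for (nm in c("h2", "c2", "e2")) {
      out[[nm]] <- fill(nm, "estimate")
      out[[paste0(nm, "_lower")]] <- fill(nm, "lower")
      out[[paste0(nm, "_upper")]] <- fill(nm, "upper")
    }
    out
  })
  do.call(rbind, rows)
}
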