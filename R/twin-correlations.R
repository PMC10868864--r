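#' Intraclass correlation ICC(1) for twin pairs
#'
#' One-way random-effects ANOVA estimator with pairs as groups (k = 2 members
#' per group): `ICC = (MSB - MSW) / (MSB + MSW)`, clamped to [-1, 1].
#'
#' @param x1,x2 Numeric member-1 and member-2 values; pairs with any `NA` are
#'   dropped.
#' @return The ICC, or `NA` with fewer than 3 complete pairs or zero total
#'   variance.
#' @export
pair_icc <- function(x1, x2) {
  keep <- !is.na(x1) & !is.na(x2)
  x1 <- x1[keep]; x2 <- x2[keep]
  n <- length(x1)
  if (n < 3) return(NA_real_)
  pm <- (x1 + x2) / 2
  grand <- mean(pm)
  msb <- 2 * sum((pm - grand)^2) / (n - 1)
  msw <- sum((x1 - pm)^2 + (x2 - pm)^2) / n
  if (msb + msw == 0) return(NA_real_)
  max(-1, min(1, (msb - msw) / (msb + msw)))
}

#' Tetrachoric correlation of a twin concordance table
#'
#' Maximum-likelihood correlation of the latent bivariate normal generating a
#' 2x2 table, with thresholds fixed at the margin quantiles and the
#' correlation found by 1-D search over (-1, 1) to tolerance 1e-8. The
#' standard error comes from the inverse observed information (numerical
#' second derivative of the profile log-likelihood).
#'
#' @param x1,x2 0/1 member vectors, or `x1` a 2x2 table/matrix of counts with
#'   rows indexing member 1 = 1/0 and columns member 2 = 1/0 (`x2` ignored).
#' @return A list: `rho`, `se`, `tau1`, `tau2`, `n`, `loglik`, `status`
#'   (`"ok"` or `"boundary"` when a zero cell drives the estimate to the
#'   edge).
#' @export
tetrachoric <- function(x1, x2 = NULL) {
  if (is.matrix(x1) || is.table(x1)) {
    tab <- as.matrix(x1)
    stopifnot(all(dim(tab) == 2))
    n11 <- tab[1, 1]; n10 <- tab[1, 2]; n01 <- tab[2, 1]; n00 <- tab[2, 2]
  } else {
    keep <- !is.na(x1) & !is.na(x2)
    x1 <- x1[keep]; x2 <- x2[keep]
    stopifnot(all(x1 %in% 0:1), all(x2 %in% 0:1))
    n11 <- sum(x1 == 1 & x2 == 1); n10 <- sum(x1 == 1 & x2 == 0)
    n01 <- sum(x1 == 0 & x2 == 1); n00 <- sum(x1 == 0 & x2 == 0)
  }
  n <- n11 + n10 + n01 + n00
  p1 <- (n11 + n10) / n
  p2 <- (n11 + n01) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    stop("degenerate concordance table: a margin is empty")
  }
  tau1 <- stats::qnorm(1 - p1)
  tau2 <- stats::qnorm(1 - p2)
  ll <- function(rho) {
    p11 <- orthant_probability(tau1, tau2, rho)
    probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
    probs <- pmax(probs, 1e-300)
    sum(c(n11, n10, n01, n00) * log(probs))
  }
  lim <- 1 - 1e-8
  opt <- stats::optimize(ll, c(-lim, lim), maximum = TRUE, tol = 1e-9)
  rho <- opt$maximum
  boundary <- any(c(n11, n10, n01, n00) == 0) || abs(rho) > 1 - 1e-4
  se <- NA_real_
  if (!boundary) {
    h <- 1e-4
    info <- -(ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
    if (is.finite(info) && info > 0) se <- 1 / sqrt(info)
  } else {
    warning("tetrachoric estimate at the boundary (zero cell); SE not reported")
  }
  list(rho = rho, se = se, tau1 = tau1, tau2 = tau2, n = n,
       loglik = opt$objective, status = if (boundary) "boundary" else "ok")
}

#' Zygosity-specific twin-pair similarity statistics
#'
#' For each zygosity group, the Pearson correlation between member-1 and
#' member-2 trait values (the phi coefficient when the trait is 0/1) with a
#' two-sided p-value, the one-way ANOVA intraclass correlation, and (for
#' binary traits) the tetrachoric correlation with its standard error.
#'
#' Under `ordering = "single"` the member vectors follow `member_index` as
#' read and the p-value uses the exact t reference. Under `"double"` every
#' pair enters twice in both orders, which makes the estimate invariant to
#' within-pair order; its p-value is computed on the number of pairs (not the
#' doubled rows) and flagged approximate.
#'
#' @param pairs A `twin_pairs` data.frame from [pair_twins()].
#' @param trait Trait name (columns `<trait>_1`, `<trait>_2`).
#' @param ordering `"single"` (default) or `"double"`.
#' @return A data.frame with one row per zygosity: `trait`, `zygosity`, `n`,
#'   `r`, `p`, `icc`, `tetrachoric`, `tetra_se`, `status`.
#' @export
twin_correlations <- function(pairs, trait, ordering = c("single", "double")) {
  ordering <- match.arg(ordering)
  v1 <- pairs[[paste0(trait, "_1")]]
  v2 <- pairs[[paste0(trait, "_2")]]
  if (is.null(v1) || is.null(v2)) stop("trait columns not found for: ", trait)
  rows <- lapply(c("MZ", "DZ"), function(z) {
    sel <- pairs$zygosity == z & !is.na(v1) & !is.na(v2)
    x1 <- v1[sel]; x2 <- v2[sel]
    n <- length(x1)
    out <- data.frame(trait = trait, zygosity = z, n = n, r = NA_real_,
                      p = NA_real_, icc = NA_real_, tetrachoric = NA_real_,
                      tetra_se = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    if (n < 3) { out$status <- "fewer than 3 complete pairs"; return(out) }
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
      out$status <- "zero variance"; return(out)
    }
    if (ordering == "single") {
      ct <- stats::cor.test(x1, x2)
      out$r <- unname(ct$estimate); out$p <- ct$p.value
    } else {
      r <- stats::cor(c(x1, x2), c(x2, x1))
      tt <- r * sqrt((n - 2) / (1 - r^2))
      out$r <- r
      out$p <- 2 * stats::pt(-abs(tt), df = n - 2)
      out$status <- "double-entry; p approximate"
    }
    out$icc <- pair_icc(x1, x2)
    if (all(c(x1, x2) %in% 0:1)) {
      tc <- tryCatch(suppressWarnings(tetrachoric(x1, x2)),
                     error = function(e) NULL)
      if (!is.null(tc)) {
        out$tetrachoric <- tc$rho
        out$tetra_se <- tc$se
        if (tc$status != "ok" && out$status == "ok") out$status <- tc$status
      }
    }
    out
  })
  do.call(rbind, rows)
}
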