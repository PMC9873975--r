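# Gene-level RNA-seq differential expression: depth filter, median-of-ratios
# size factors and a self-contained negative-binomial Wald test.
#
# The full DESeq2 machinery (Cox-Reid dispersion MAP, LFC shrinkage,
# outlier replacement, independent filtering) is deliberately simplified to
# a transparent NB Wald path; downstream stages consume only the
# |log2FC| > 1 & q < 0.05 decision surface.

#' Drop low-depth samples
#'
#' @param counts genes x samples integer matrix.
#' @param min_total minimum column sum; samples strictly below are removed
#'   (default 100,000).
#' @return list with `counts` (filtered) and `excluded` (sample ids).
#' @export
filter_low_depth <- function(counts, min_total = 100000) {
  tot <- colSums(counts)
  drop <- colnames(counts)[tot < min_total]
  keep <- setdiff(colnames(counts), drop)
  if (!length(keep)) stop("all samples removed by the depth filter",
                          call. = FALSE)
  list(counts = counts[, keep, drop = FALSE], excluded = drop)
}

#' Median-of-ratios size factors
#'
#' factor_s = median over all-nonzero genes of count_gs / geometric mean_g,
#' rescaled so the factors have geometric mean 1. Falls back to
#' upper-quartile scaling (with a warning) when no gene is nonzero in every
#' sample.
#'
#' @param counts genes x samples matrix.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts == 0) == 0
  if (any(ok)) {
    lg <- log(counts[ok, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(exp(lg - geo), 2, stats::median)
  } else {
    warning("no gene nonzero in all samples; upper-quartile fallback")
    sf <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# method-of-moments NB dispersion per gene on size-factor-normalized counts,
# pooled within groups, shrunk halfway (log scale) toward a fitted
# mean-dispersion trend a0 + a1/mean
.estimate_dispersions <- function(counts, grp, sf) {
  q <- sweep(counts, 2, sf, "/")
  disp_mom <- vapply(seq_len(nrow(q)), function(i) {
    x <- q[i, ]
    num <- 0; den <- 0; mbar <- 0; nn <- 0
    for (g in unique(grp)) {
      xi <- x[grp == g]
      if (length(xi) < 2) next
      num <- num + (length(xi) - 1) * stats::var(xi)
      den <- den + (length(xi) - 1)
      mbar <- mbar + sum(xi); nn <- nn + length(xi)
    }
    v <- num / max(den, 1)
    mu <- mbar / max(nn, 1)
    if (mu <= 0) return(1e-8)
    max((v - mu) / mu^2, 1e-8)
  }, numeric(1))
  mu_g <- rowMeans(q)
  use <- disp_mom > 1e-7 & mu_g > 1
  if (sum(use) >= 10) {
    fit <- stats::lm(disp_mom[use] ~ I(1 / mu_g[use]))
    a0 <- max(stats::coef(fit)[1], 1e-4)
    a1 <- max(stats::coef(fit)[2], 0)
    trend <- pmax(a0 + a1 / pmax(mu_g, 1e-8), 1e-8)
  } else {
    trend <- rep(max(mean(disp_mom), 1e-8), length(disp_mom))
  }
  exp((log(disp_mom) + log(trend)) / 2)
}

# single-gene NB GLM (log link, known dispersion) by IRLS; design
# [1, group], offset log(sf); returns coef, se of the group coefficient
.nb_irls <- function(y, grp, off, disp, max_iter = 30) {
  X <- cbind(1, grp)
  beta <- c(log(mean(y / exp(off)) + 0.1), 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(pmax(exp(eta), 1e-8), 1e12)
    W <- mu / (1 + disp * mu)
    z <- eta - off + (y - mu) / mu
    XtW <- t(X * W)
    A <- XtW %*% X
    b_new <- tryCatch(drop(solve(A, XtW %*% z)), error = function(e) beta)
    b_new <- pmin(pmax(b_new, -30), 30)
    if (max(abs(b_new - beta)) < 1e-8) { beta <- b_new; break }
    beta <- b_new
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(pmax(exp(eta), 1e-8), 1e12)
  W <- mu / (1 + disp * mu)
  cov <- tryCatch(solve(t(X * W) %*% X), error = function(e)
    matrix(NA_real_, 2, 2))
  c(coef = beta[2], se = sqrt(cov[2, 2]))
}

#' Negative-binomial Wald differential expression
#'
#' Per gene: NB log-link GLM with a group indicator and log-size-factor
#' offsets; dispersion by per-gene method of moments floored at 1e-8 and
#' shrunk halfway (log scale) toward a fitted mean-dispersion trend; Wald z
#' on the group coefficient; BH across tested genes. Genes with all-zero
#' counts are excluded from testing and reported.
#'
#' @param counts genes x samples matrix.
#' @param groups per-sample labels; `case_label` vs everything else.
#' @param sf size factors (default [size_factors()] of `counts`).
#' @param case_label label of the case group (default "CLL").
#' @param lfc_threshold,fdr DEG criteria (defaults 1 and 0.05).
#' @return data.frame of class `DEGTable` with columns `gene`, `base_mean`,
#'   `log2fc` (case vs rest), `p`, `q`, `is_deg`, plus attribute
#'   `excluded_genes` (all-zero genes).
#' @export
nb_wald <- function(counts, groups, sf = NULL, case_label = "CLL",
                    lfc_threshold = 1, fdr = 0.05) {
  grp <- as.integer(groups == case_label)
  if (sum(grp) < 2 || sum(1 - grp) < 2)
    stop("need at least two samples per group", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[zero]
  y <- counts[!zero, , drop = FALSE]

  disp <- .estimate_dispersions(y, grp, sf)
  off <- log(sf)
  fits <- t(vapply(seq_len(nrow(y)), function(i)
    .nb_irls(y[i, ], grp, off, disp[i]), c(coef = 0, se = 0)))
  z <- fits[, "coef"] / fits[, "se"]
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- 1
  q <- bh_fdr(p)
  log2fc <- fits[, "coef"] / log(2)

  out <- data.frame(
    gene = rownames(y),
    base_mean = rowMeans(sweep(y, 2, sf, "/")),
    log2fc = log2fc,
    p = p,
    q = q,
    is_deg = abs(log2fc) > lfc_threshold & q < fdr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("DEGTable", "data.frame")
  attr(out, "excluded_genes") <- excluded
  out
}
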