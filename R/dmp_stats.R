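# Cohort descriptive statistics and per-probe differential methylation.
#
# The DMP criterion is the effect-size + FDR rule standard in 450K
# case-control work: |delta-beta| > 0.2 and BH q < 0.05, with the linear
# model fitted on the M scale adjusted for age and sex.

#' Benjamini-Hochberg step-up q-values
#'
#' q_i = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / j);
#' order-preserving, ties share a q.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric())
  # step-up from the largest p down; arithmetic ordered as m/i * p so
  # results are bit-identical to the usual reference implementations
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Cohort characteristics table with group tests
#'
#' Continuous variables are summarized as median (IQR) per group and tested
#' with a two-sided Wilcoxon rank-sum test (normal approximation with
#' continuity and tie correction); categorical variables are tabulated and
#' tested with a chi-square test (Yates continuity correction for 2x2).
#' Missing values are dropped per variable.
#'
#' @param sample_sheet data.frame with a `group` column.
#' @param groups the two groups to compare (default CLL vs control).
#' @param continuous,categorical column names to summarize; columns absent
#'   from the sheet are skipped.
#' @return data.frame with one row per variable: per-group summary, test
#'   name and p-value.
#' @export
cohort_table <- function(sample_sheet,
                         groups = c("CLL", "control"),
                         continuous = c("age", "WBC", "ALC"),
                         categorical = "sex") {
  g <- sample_sheet$group
  for (gr in groups)
    if (!any(g == gr)) stop("group '", gr, "' is empty", call. = FALSE)
  a <- sample_sheet[g == groups[1], , drop = FALSE]
  b <- sample_sheet[g == groups[2], , drop = FALSE]
  rows <- list()
  for (v in intersect(categorical, names(sample_sheet))) {
    tab <- table(factor(sample_sheet[[v]][g %in% groups]),
                 factor(g[g %in% groups], levels = groups))
    p <- tryCatch(
      stats::chisq.test(tab, correct = TRUE)$p.value,
      warning = function(w) suppressWarnings(
        stats::chisq.test(tab, correct = TRUE)$p.value))
    fmt <- function(x) {
      t1 <- table(x[[v]])
      paste(sprintf("%s:%d (%.0f%%)", names(t1), t1,
                    100 * t1 / sum(t1)), collapse = "; ")
    }
    rows[[v]] <- data.frame(variable = v, summary_a = fmt(a),
                            summary_b = fmt(b), test = "chi-square",
                            p = p, stringsAsFactors = FALSE)
  }
  for (v in intersect(continuous, names(sample_sheet))) {
    xa <- a[[v]][!is.na(a[[v]])]
    xb <- b[[v]][!is.na(b[[v]])]
    p <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value)
    fmt <- function(x) sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                               stats::quantile(x, 0.25),
                               stats::quantile(x, 0.75))
    rows[[v]] <- data.frame(variable = v, summary_a = fmt(xa),
                            summary_b = fmt(xb), test = "wilcoxon",
                            p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("summary_", groups)
  rownames(out) <- NULL
  out
}

#' Per-probe differential methylation (DMP calling)
#'
#' Per probe, ordinary least squares of the M-value on a group indicator
#' plus covariates; two-sided t-test on the group coefficient; BH adjustment
#' across all tested probes. Delta-beta is computed on the supplied beta
#' matrix (normalized, pre-M), and the DMP flag applies the effect-size +
#' FDR criteria. Optionally, per-probe variances are moderated by shrinking
#' toward a scaled inverse-chi-square prior fitted by moments
#' (limma-style empirical Bayes).
#'
#' @param m probes x samples M-value matrix.
#' @param sample_sheet data.frame with `sample_id`, `group` and covariates.
#' @param beta optional probes x samples beta matrix for delta-beta
#'   (defaults to `m_to_beta(m)`).
#' @param groups length-2: case then control label.
#' @param covariates covariate column names (default age and sex).
#' @param delta_beta,fdr DMP criteria (defaults 0.2 and 0.05).
#' @param moderated use empirical-Bayes variance moderation (default FALSE).
#' @return data.frame of class `DMPTable` with columns `probe_id`,
#'   `delta_beta`, `coef_m`, `p`, `q`, `direction`, `is_dmp`. Positive
#'   delta-beta means hypermethylated in the case group.
#' @export
fit_dmp <- function(m, sample_sheet, beta = NULL,
                    groups = c("CLL", "control"),
                    covariates = c("age", "sex"),
                    delta_beta = 0.2, fdr = 0.05, moderated = FALSE) {
  sheet <- sample_sheet[match(colnames(m), sample_sheet$sample_id), ,
                        drop = FALSE]
  keep <- sheet$group %in% groups
  m <- m[, keep, drop = FALSE]
  sheet <- sheet[keep, , drop = FALSE]
  grp <- as.integer(sheet$group == groups[1])
  if (sum(grp) < 3 || sum(1 - grp) < 3)
    stop("need at least three samples per group", call. = FALSE)

  covariates <- intersect(covariates, names(sheet))
  X <- cbind(intercept = 1, group = grp)
  if (length(covariates)) {
    cdat <- sheet[, covariates, drop = FALSE]
    cm <- stats::model.matrix(~ ., data = cdat)[, -1, drop = FALSE]
    X <- cbind(X, cm)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  n <- ncol(m); pdim <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- m %*% X %*% XtXinv                       # probes x p
  res <- m - B %*% t(X)
  dfres <- n - pdim
  s2 <- rowSums(res^2) / dfres
  zerovar <- s2 < 1e-12

  if (moderated && sum(!zerovar) > 2) {
    # moment-matched scaled inverse-chi-square prior on the variances
    s2ok <- s2[!zerovar]
    mv <- mean(s2ok); vv <- stats::var(s2ok)
    d0 <- if (vv > 0) max(2 * mv^2 / vv * (dfres + 2) / dfres, 0.1) else 1e6
    s02 <- mv * (d0 - 2) / d0
    if (s02 <= 0) { d0 <- 4; s02 <- mv / 2 }
    s2_post <- (d0 * s02 + dfres * s2) / (d0 + dfres)
    dft <- dfres + d0
  } else {
    s2_post <- s2
    dft <- dfres
  }

  se <- sqrt(s2_post * XtXinv[2, 2])
  tval <- B[, 2] / se
  p <- 2 * stats::pt(-abs(tval), dft)
  p[zerovar] <- 1           # zero-variance probes: p = 1 by convention
  q <- bh_fdr(p)

  if (is.null(beta)) beta <- m_to_beta(m) else
    beta <- beta[rownames(m), colnames(m), drop = FALSE]
  db <- rowMeans(beta[, grp == 1, drop = FALSE]) -
    rowMeans(beta[, grp == 0, drop = FALSE])

  out <- data.frame(
    probe_id = rownames(m),
    delta_beta = db,
    coef_m = B[, 2],
    p = p,
    q = q,
    direction = ifelse(db >= 0, "hyper", "hypo"),
    is_dmp = abs(db) > delta_beta & q < fdr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("DMPTable", "data.frame")
  out
}

#' DMP distribution over annotation categories with a goodness-of-fit test
#'
#' Tabulates DMP counts (split hyper/hypo) and percentages per CGI category
#' or genomic feature and tests the DMP category distribution against the
#' background proportions with a chi-square goodness-of-fit statistic.
#'
#' @param dmp_table a `DMPTable`.
#' @param annotation `ProbeAnnotation`.
#' @param background probe ids forming the background universe (all
#'   QC-passing probes).
#' @param by "cgi" or "feature".
#' @return list with `table` (per-category counts/percentages) and `chisq`,
#'   `df`, `p` of the goodness-of-fit test.
#' @export
feature_distribution <- function(dmp_table, annotation, background,
                                 by = c("cgi", "feature")) {
  by <- match.arg(by)
  dmps <- dmp_table[dmp_table$is_dmp, , drop = FALSE]
  if (nrow(dmps) == 0) stop("no DMPs to tabulate", call. = FALSE)
  ann_bg <- annotation[match(background, annotation$probe_id), ]
  ann_dmp <- annotation[match(dmps$probe_id, annotation$probe_id), ]
  cats <- if (by == "cgi") CGI_RELATIONS else GENOMIC_FEATURES

  bg_counts <- table(factor(ann_bg[[by]], levels = cats))
  empty <- names(bg_counts)[bg_counts == 0]
  if (length(empty)) {
    warning("background categories with zero probes dropped: ",
            paste(empty, collapse = ", "))
    cats <- setdiff(cats, empty)
    bg_counts <- bg_counts[cats]
  }
  fdmp <- factor(ann_dmp[[by]], levels = cats)
  obs <- table(fdmp)
  hyper <- table(fdmp[dmps$direction == "hyper"])
  hypo <- table(fdmp[dmps$direction == "hypo"])
  tab <- data.frame(
    category = cats,
    n_dmp = as.integer(obs),
    n_hyper = as.integer(hyper),
    n_hypo = as.integer(hypo),
    pct_dmp = 100 * as.numeric(obs) / sum(obs),
    pct_background = 100 * as.numeric(bg_counts) / sum(bg_counts),
    stringsAsFactors = FALSE
  )
  expected <- sum(obs) * as.numeric(bg_counts) / sum(bg_counts)
  chisq <- sum((as.numeric(obs) - expected)^2 / expected)
  df <- length(cats) - 1
  list(table = tab, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}
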