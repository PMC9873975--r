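# Sample/probe QC, beta<->M transformation, probe-type-aware quantile
# normalization and parametric empirical-Bayes batch correction.

#' Beta to M-value transformation
#'
#' M = log2(beta' / (1 - beta')) with beta' clipped to \[epsilon, 1-epsilon\]
#' to avoid infinities at fully (un)methylated calls.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param epsilon clipping bound in (0, 0.5); default 0.001.
#' @return M values, same shape as input.
#' @export
beta_to_m <- function(beta, epsilon = 0.001) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' M-value to beta transformation (inverse of [beta_to_m()])
#'
#' @param m M values.
#' @return beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Drop samples with high detection-p failure rates
#'
#' A sample is excluded when its fraction of probes with detection
#' p > `detection_p` exceeds `max_failed_fraction`.
#'
#' @param beta a [beta_matrix()] carrying a `detection_p` companion.
#' @param max_failed_fraction maximum tolerated failed-probe fraction
#'   (default 0.01, i.e. "over 1 percent").
#' @param detection_p per-call failure threshold (default 0.05).
#' @return list with `beta` (filtered) and `report` (a `QCReport`).
#' @export
filter_samples <- function(beta, max_failed_fraction = 0.01,
                           detection_p = 0.05) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (is.null(beta$detection_p))
    stop("filter_samples requires a detection_p companion matrix",
         call. = FALSE)
  frac <- colMeans(beta$detection_p > detection_p)
  drop <- names(frac)[frac > max_failed_fraction]
  rep <- qc_report(excluded_samples = data.frame(
    sample_id = drop, reason = rep("detection", length(drop)),
    stringsAsFactors = FALSE))
  keep <- setdiff(colnames(beta$values), drop)
  list(beta = subset_beta(beta, samples = keep), report = rep)
}

#' Flag sex mismatches from X-chromosome methylation
#'
#' Classical multidimensional scaling (2 components, Euclidean distance) on
#' X-probe betas, followed by 2-means clustering; each cluster is assigned
#' the majority recorded sex and samples disagreeing with their cluster are
#' flagged `sex_mismatch`. If the two clusters do not separate the recorded
#' sexes (no majority signal), the result is marked indeterminate and
#' nothing is flagged.
#'
#' @param beta a [beta_matrix()].
#' @param annotation `ProbeAnnotation` covering the probes.
#' @param sample_sheet data.frame with `sample_id` and `sex` ("F"/"M").
#' @return list with `report` (a `QCReport`) and `indeterminate` flag.
#' @export
sex_check <- function(beta, annotation, sample_sheet) {
  stopifnot(inherits(beta, "BetaMatrix"))
  x_probes <- annotation$probe_id[annotation$chrom == "X"]
  x_probes <- intersect(x_probes, rownames(beta$values))
  if (length(x_probes) < 2)
    stop("sex_check requires at least two X-chromosome probes", call. = FALSE)
  sex <- sample_sheet$sex[match(colnames(beta$values),
                                sample_sheet$sample_id)]
  if (any(table(sex) < 2) || length(unique(sex)) < 2)
    stop("sex_check requires at least two samples per recorded sex",
         call. = FALSE)
  xb <- t(beta$values[x_probes, , drop = FALSE])
  mds <- stats::cmdscale(stats::dist(xb), k = 2)

  # deterministic 2-means: seed centres at the two extremes of component 1
  pts <- mds
  c1 <- pts[which.min(pts[, 1]), , drop = FALSE]
  c2 <- pts[which.max(pts[, 1]), , drop = FALSE]
  cl <- rep(1L, nrow(pts))
  for (it in 1:50) {
    d1 <- rowSums(sweep(pts, 2, c1)^2)
    d2 <- rowSums(sweep(pts, 2, c2)^2)
    new_cl <- ifelse(d1 <= d2, 1L, 2L)
    if (all(new_cl == cl) && it > 1) break
    cl <- new_cl
    if (any(cl == 1)) c1 <- colMeans(pts[cl == 1, , drop = FALSE])
    if (any(cl == 2)) c2 <- colMeans(pts[cl == 2, , drop = FALSE])
  }

  indeterminate <- length(unique(cl)) < 2
  flagged <- character()
  if (!indeterminate) {
    # assign each cluster its majority recorded sex
    maj <- vapply(1:2, function(k) {
      tab <- table(sex[cl == k])
      names(tab)[which.max(tab)]
    }, character(1))
    if (maj[1] == maj[2]) {
      indeterminate <- TRUE   # clusters do not track recorded sex
    } else {
      flagged <- colnames(beta$values)[sex != maj[cl]]
    }
  }
  rep <- qc_report(excluded_samples = data.frame(
    sample_id = flagged, reason = rep("sex_mismatch", length(flagged)),
    stringsAsFactors = FALSE),
    notes = if (indeterminate) "sex_check: indeterminate clustering, no exclusions"
            else character())
  list(report = rep, indeterminate = indeterminate)
}

#' Probe-level quality filters
#'
#' Removes the union of four rule sets: probes failing detection in too many
#' samples, probes with low bead counts in too many samples, probes on the
#' sex chromosomes, and probes flagged SNP-overlapping or cross-reactive.
#' A probe matching several rules is counted under every matching reason
#' but excluded once.
#'
#' @param beta a [beta_matrix()].
#' @param annotation `ProbeAnnotation` covering all probes.
#' @param detection_p,probe_fail_frac detection rule: excluded when the
#'   fraction of samples with detection p > `detection_p` exceeds
#'   `probe_fail_frac` (defaults 0.05 and 0.01).
#' @param bead_min,bead_fail_frac bead rule: excluded when the fraction of
#'   samples with bead count < `bead_min` exceeds `bead_fail_frac`
#'   (defaults 3 and 0.05).
#' @param drop_sex_chroms drop X/Y probes (default TRUE).
#' @param drop_flagged drop SNP/cross-reactive probes (default TRUE).
#' @return list with `beta` (filtered) and `report`.
#' @export
filter_probes <- function(beta, annotation, detection_p = 0.05,
                          probe_fail_frac = 0.01, bead_min = 3,
                          bead_fail_frac = 0.05, drop_sex_chroms = TRUE,
                          drop_flagged = TRUE) {
  stopifnot(inherits(beta, "BetaMatrix"))
  probes <- rownames(beta$values)
  if (!all(probes %in% annotation$probe_id))
    stop("annotation does not cover all probes", call. = FALSE)
  ann <- annotation[match(probes, annotation$probe_id), ]

  hits <- list()
  if (!is.null(beta$detection_p)) {
    frac <- rowMeans(beta$detection_p > detection_p)
    hits$detection <- probes[frac > probe_fail_frac]
  }
  if (!is.null(beta$bead_count)) {
    frac <- rowMeans(beta$bead_count < bead_min)
    hits$beads <- probes[frac > bead_fail_frac]
  }
  if (drop_sex_chroms)
    hits$sex_chrom <- probes[ann$chrom %in% c("X", "Y")]
  if (drop_flagged)
    hits$snp_crossreactive <- probes[ann$snp_flag | ann$crossreactive_flag]

  excl <- do.call(rbind, lapply(names(hits), function(r)
    if (length(hits[[r]])) data.frame(probe_id = hits[[r]], reason = r,
                                      stringsAsFactors = FALSE)))
  rep <- qc_report(excluded_probes = excl)
  keep <- setdiff(probes, unlist(hits))
  list(beta = subset_beta(beta, probes = keep), report = rep)
}

#' Probe-type-aware quantile normalization
#'
#' Within each probe design type (I, II) separately, each sample's values
#' are replaced by the mean order statistics of its type stratum (full
#' quantile normalization across samples, average-tie handling). When
#' methylated/unmethylated intensities are supplied, the two channels are
#' normalized separately and beta recomputed as M / (M + U + offset).
#'
#' @param beta a [beta_matrix()], or NULL when intensities are given.
#' @param annotation `ProbeAnnotation` (for `design_type`).
#' @param method "type_aware_quantile" or "none".
#' @param meth,unmeth optional intensity matrices; normalized per channel.
#' @param offset Infinium-convention offset in the beta denominator
#'   (default 100).
#' @return a [beta_matrix()] with normalized values (companions carried
#'   through unchanged).
#' @export
normalize_betas <- function(beta = NULL, annotation,
                            method = c("type_aware_quantile", "none"),
                            meth = NULL, unmeth = NULL, offset = 100) {
  method <- match.arg(method)
  use_intensity <- !is.null(meth) && !is.null(unmeth)
  vals <- if (use_intensity) meth else beta$values
  if (is.null(vals)) stop("supply either beta or both intensity matrices",
                          call. = FALSE)
  if (method == "none") {
    if (use_intensity) {
      b <- meth / (meth + unmeth + offset)
      return(beta_matrix(b))
    }
    return(beta)
  }
  type <- annotation$design_type[match(rownames(vals), annotation$probe_id)]

  qn <- function(m) {
    out <- m
    for (tp in unique(type)) {
      rows <- which(type == tp)
      sub <- m[rows, , drop = FALSE]
      if (nrow(sub) < 2 || ncol(sub) < 2) next
      means <- rowMeans(apply(sub, 2, sort))
      n <- nrow(sub)
      out[rows, ] <- apply(sub, 2, function(col) {
        rk <- rank(col, ties.method = "average")
        stats::approx(seq_len(n), means, xout = rk)$y
      })
    }
    out
  }

  if (use_intensity) {
    mq <- qn(meth); uq <- qn(unmeth)
    b <- mq / (mq + uq + offset)
    dimnames(b) <- dimnames(meth)
    return(beta_matrix(b,
                       detection_p = if (!is.null(beta)) beta$detection_p,
                       bead_count = if (!is.null(beta)) beta$bead_count))
  }
  b <- qn(beta$values)
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- dimnames(beta$values)
  beta_matrix(b, detection_p = beta$detection_p,
              bead_count = beta$bead_count)
}

#' Parametric empirical-Bayes batch correction (ComBat-style)
#'
#' Location/scale adjustment of Johnson et al. (2007): per-probe
#' standardization preserving covariate effects, empirical-Bayes shrinkage
#' of per-batch location (normal prior) and scale (inverse-gamma prior)
#' estimates toward their across-probe moments, adjustment and restoration.
#' Intended for M-values.
#'
#' @param m probes x samples matrix (M scale).
#' @param batch per-sample batch labels (length = ncol(m)).
#' @param covariates optional data.frame of biological covariates to
#'   preserve (e.g. group, age, sex); one row per sample.
#' @return adjusted matrix, same shape.
#' @export
combat <- function(m, batch, covariates = NULL) {
  batch <- factor(batch)
  if (length(batch) != ncol(m))
    stop("batch labels must match sample columns", call. = FALSE)
  if (nlevels(batch) < 2) return(m)
  if (any(table(batch) < 2))
    stop("each batch needs at least two samples", call. = FALSE)

  bdes <- stats::model.matrix(~ -1 + batch)
  mod <- NULL
  if (!is.null(covariates)) {
    mod <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    mod <- mod[, -1, drop = FALSE]  # intercept lives in the batch columns
    full <- cbind(bdes, mod)
    if (qr(full)$rank < ncol(full)) {
      # identify which covariate is confounded with batch
      culprit <- NULL
      for (j in seq_len(ncol(mod))) {
        if (qr(cbind(bdes, mod[, j]))$rank < ncol(bdes) + 1) {
          culprit <- colnames(mod)[j]; break
        }
      }
      stop("batch is confounded with covariate '",
           if (is.null(culprit)) "unknown" else culprit,
           "'; cannot separate batch from biology", call. = FALSE)
    }
  }

  n <- ncol(m)
  nb <- nlevels(batch)
  n_batches <- as.numeric(table(batch))
  design <- if (is.null(mod)) bdes else cbind(bdes, mod)
  B_hat <- solve(crossprod(design), crossprod(design, t(m)))  # p x probes
  grand_mean <- crossprod(n_batches / n, B_hat[seq_len(nb), , drop = FALSE])
  resid <- m - t(design %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  var_pooled[var_pooled < 1e-12] <- 1e-12

  stand_mean <- matrix(grand_mean, nrow(m), n)
  if (!is.null(mod))
    stand_mean <- stand_mean +
      t(design[, -(seq_len(nb)), drop = FALSE] %*%
          B_hat[-(seq_len(nb)), , drop = FALSE])
  s_data <- (m - stand_mean) / sqrt(var_pooled)

  # per-batch location/scale estimates and EB priors
  gamma_hat <- matrix(0, nb, nrow(m))
  delta_hat <- matrix(0, nb, nrow(m))
  for (i in seq_len(nb)) {
    cols <- which(batch == levels(batch)[i])
    gamma_hat[i, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta_hat[i, ] <- apply(s_data[, cols, drop = FALSE], 1, stats::var)
  }
  delta_hat[is.na(delta_hat) | delta_hat < 1e-12] <- 1e-12
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  aprior <- apply(delta_hat, 1, function(d) {
    mdel <- mean(d); s2 <- stats::var(d); (2 * s2 + mdel^2) / s2
  })
  bprior <- apply(delta_hat, 1, function(d) {
    mdel <- mean(d); s2 <- stats::var(d); (mdel * s2 + mdel^3) / s2
  })

  # iterative solution for the EB-adjusted batch effects
  it_sol <- function(sdat, g_hat, d_hat, g_bar, t2i, a, b, conv = 1e-4) {
    ns <- ncol(sdat)  # number of samples in this batch (per probe, no NAs)
    g_old <- g_hat; d_old <- d_hat
    change <- 1
    while (change > conv) {
      g_new <- (t2i * ns * g_hat + d_old * g_bar) / (t2i * ns + d_old)
      sum2 <- rowSums((sdat - matrix(g_new, nrow(sdat), ns))^2)
      d_new <- (0.5 * sum2 + b) / (ns / 2 + a - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
    }
    list(gamma = g_old, delta = d_old)
  }

  adj <- s_data
  for (i in seq_len(nb)) {
    cols <- which(batch == levels(batch)[i])
    sol <- it_sol(s_data[, cols, drop = FALSE],
                  gamma_hat[i, ], delta_hat[i, ],
                  gamma_bar[i], t2[i], aprior[i], bprior[i])
    adj[, cols] <- (s_data[, cols, drop = FALSE] - sol$gamma) /
      sqrt(sol$delta)
  }
  adj * sqrt(var_pooled) + stand_mean
}
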