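# Cohort statistics, the per-probe linear model and multiple testing.

test_that("BH q-values follow the step-up formula and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)            # m = 1 -> q = p
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, -0.1)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- bh_fdr(p)
    expect_identical(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p))
    o <- order(p)
    expect_false(is.unsorted(q[o]))
  }
})

test_that("cohort table reproduces the published sex test and handles ties", {
  sheet <- data.frame(
    sample_id = sprintf("S%03d", 1:76),
    group = rep(c("CLL", "control"), c(48, 28)),
    sex = c(rep("F", 29), rep("M", 19), rep("F", 19), rep("M", 9)),
    age = c(rnorm(48, 61, 8), rnorm(28, 57, 10)))
  tab <- cohort_table(sheet, continuous = "age", categorical = "sex")
  expect_equal(round(tab$p[tab$variable == "sex"], 2), 0.69)

  # identical continuous samples: exchangeable null, p = 1
  sheet2 <- sheet
  sheet2$age <- rep(c(50, 60, 70, 80), length.out = 76)
  # make the two group age multisets identical
  sheet2$age[sheet2$group == "CLL"] <- rep(c(50, 60), 24)
  sheet2$age[sheet2$group == "control"] <- rep(c(50, 60), 14)
  tab2 <- cohort_table(sheet2, continuous = "age", categorical = character())
  expect_equal(tab2$p[tab2$variable == "age"], 1.0, tolerance = 1e-6)

  expect_error(cohort_table(sheet[sheet$group == "CLL", ]), "empty")
})

test_that("Wilcoxon approximation tracks the exact permutation null (n=4 vs 4)", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.4, 1.9, 0.8, 1.1)
  sheet <- data.frame(sample_id = sprintf("S%d", 1:8),
                      group = rep(c("CLL", "control"), each = 4),
                      val = c(x, y))
  p_pkg <- cohort_table(sheet, continuous = "val",
                        categorical = character())$p

  # brute force over all C(8,4)=70 rank splits
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[1:4])
  splits <- utils::combn(8, 4)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]))
  p_exact <- mean(abs(w_all - mean(w_all)) >= abs(w_obs - mean(w_all)))
  expect_lt(abs(p_pkg - p_exact), 0.02)
})

test_that("single-probe OLS matches the closed-form normal equations", {
  sheet <- data.frame(sample_id = sprintf("S%d", 1:6),
                      group = rep(c("CLL", "control"), each = 3),
                      age = c(61, 55, 70, 48, 52, 66),
                      sex = c("F", "M", "F", "M", "F", "M"))
  y <- c(2.1, 1.8, 2.6, 0.4, 0.9, 0.2)
  m <- matrix(rep(y, each = 2), 2, 6, byrow = FALSE,
              dimnames = list(c("cgA", "cgB"), sheet$sample_id))
  m["cgB", ] <- y + 0.5
  tab <- fit_dmp(m, sheet, covariates = c("age", "sex"))

  X <- cbind(1, c(1, 1, 1, 0, 0, 0), sheet$age,
             as.integer(sheet$sex == "M"))
  bh <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% bh
  s2 <- sum(res^2) / (6 - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  p_ref <- 2 * stats::pt(-abs(bh[2] / se), 2)
  expect_equal(tab$coef_m[1], bh[2], tolerance = 1e-10)
  expect_equal(tab$p[1], p_ref, tolerance = 1e-10)
  # an additive shift leaves the group coefficient untouched
  expect_equal(tab$coef_m[2], tab$coef_m[1], tolerance = 1e-10)
})

test_that("without covariates the OLS t equals the classical two-sample t", {
  set.seed(7)
  sheet <- data.frame(sample_id = sprintf("S%d", 1:12),
                      group = rep(c("CLL", "control"), each = 6))
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("cg%02d", 1:20), sheet$sample_id))
  tab <- fit_dmp(m, sheet, covariates = character())
  for (i in c(1, 7, 20)) {
    tt <- stats::t.test(m[i, 1:6], m[i, 7:12], var.equal = TRUE)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("fit_dmp handles degenerate inputs per contract", {
  sheet <- data.frame(sample_id = sprintf("S%d", 1:12),
                      group = rep(c("CLL", "control"), each = 6),
                      age = rep(50, 12))
  set.seed(1)
  m <- matrix(rnorm(12 * 5), 5, 12,
              dimnames = list(sprintf("cg%d", 1:5), sheet$sample_id))
  m[3, ] <- 1.5   # zero-variance probe
  tab <- fit_dmp(m, sheet, covariates = character())
  expect_equal(tab$p[3], 1)

  # constant covariate makes the design rank-deficient
  expect_error(fit_dmp(m, sheet, covariates = "age"), "collinear")
  expect_error(fit_dmp(m[, 1:5], sheet[1:5, ], covariates = character()),
               "three samples")
})

test_that("DMP calls are order-invariant and monotone in the threshold", {
  ann <- small_annotation(1000, seed = 3, chromosomes = as.character(1:2))
  des <- small_design(10, 10, 0, 1, seed = 3)
  sim <- generate_methylation(ann, des, effects = null_effects(
    affected_fraction = 0.1), seed = 5)
  m <- beta_to_m(sim$beta$values)
  b <- sim$beta$values
  t1 <- fit_dmp(m, des, beta = b, covariates = character())

  pp <- sample(nrow(m)); ss <- sample(ncol(m))
  t2 <- fit_dmp(m[pp, ss], des, beta = b[pp, ss],
                covariates = character())
  t2 <- t2[match(t1$probe_id, t2$probe_id), ]
  expect_equal(t1$p, t2$p, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(t1$is_dmp, t2$is_dmp, ignore_attr = TRUE)

  for (thr in c(0.1, 0.2, 0.3, 0.4)) {
    n_lo <- sum(fit_dmp(m, des, beta = b, covariates = character(),
                        delta_beta = thr)$is_dmp)
    n_hi <- sum(fit_dmp(m, des, beta = b, covariates = character(),
                        delta_beta = thr + 0.1)$is_dmp)
    expect_lte(n_hi, n_lo)
  }
})

test_that("moderated variant shrinks variances but keeps calls sensible", {
  ann <- small_annotation(600, seed = 13, chromosomes = "1")
  des <- small_design(10, 10, 0, 1, seed = 13)
  sim <- generate_methylation(ann, des, effects = null_effects(
    affected_fraction = 0.1), seed = 17)
  m <- beta_to_m(sim$beta$values)
  plain <- fit_dmp(m, des, beta = sim$beta$values, covariates = character())
  mod <- fit_dmp(m, des, beta = sim$beta$values, covariates = character(),
                 moderated = TRUE)
  expect_identical(plain$delta_beta, mod$delta_beta)
  led <- names(sim$ledger$dmp_probes)
  expect_gt(mean(mod$is_dmp[mod$probe_id %in% led]), 0.9)
})

test_that("feature distribution GOF matches the hand-computed chi-square", {
  # 100 DMPs all in Island against a uniform 4-category background
  ids <- sprintf("cg%03d", 1:400)
  ann <- manual_annotation(ids)
  ann$cgi <- rep(c("Island", "Shore", "Shelf", "OpenSea"), each = 100)
  dmp <- manual_dmp_table(ids[1:100], delta_beta = 0.3)
  res <- feature_distribution(dmp, ann, background = ids, by = "cgi")
  expect_equal(res$chisq, 300)   # sum (O-E)^2/E with O=(100,0,0,0), E=25
  expect_equal(res$df, 3)
  expect_equal(res$table$n_dmp[res$table$category == "Island"], 100)

  expect_error(feature_distribution(manual_dmp_table(ids[1], 0.3,
                                                     is_dmp = FALSE),
                                    ann, ids), "no DMPs")
})

test_that("GOF p-values are well calibrated under null resampling", {
  set.seed(11)
  ids <- sprintf("cg%04d", 1:2000)
  ann <- manual_annotation(ids)
  ann$cgi <- sample(c("Island", "Shore", "Shelf", "OpenSea"), 2000,
                    replace = TRUE, prob = c(0.3, 0.25, 0.1, 0.35))
  ok <- 0
  for (r in 1:100) {
    dmp <- manual_dmp_table(sample(ids, 150), delta_beta = 0.3)
    p <- feature_distribution(dmp, ann, background = ids, by = "cgi")$p
    ok <- ok + (p > 0.05)
  }
  expect_gte(ok, 90)
})
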