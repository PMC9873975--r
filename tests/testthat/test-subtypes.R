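# RBF-SVM subtype model and B-cell-differentiation subtraction.

make_reference <- function(n_per = 10, sd = 0.05, seed = 5,
                           centres = c("n-CLL" = 0.15, "i-CLL" = 0.5,
                                       "m-CLL" = 0.85)) {
  set.seed(seed)
  lab <- rep(names(centres), each = n_per)
  X <- matrix(rnorm(length(lab) * 5, 0, sd), length(lab), 5) + centres[lab]
  dimnames(X) <- list(sprintf("R%02d", seq_along(lab)),
                      sprintf("cgF%d", 1:5))
  list(X = X, lab = lab)
}

test_that("well-separated clusters are fit perfectly and deterministically", {
  ref <- make_reference()
  model <- train_subtype_model(ref$X, ref$lab)
  expect_s3_class(model, "SubtypeModel")
  expect_equal(model$C, 10)
  expect_equal(model$gamma, 0.01)
  pred <- classify_subtypes(model, t(ref$X))
  expect_equal(unname(pred), ref$lab)   # resubstitution accuracy 100%

  # duplicated training sample leaves predictions unchanged
  X2 <- rbind(ref$X, DUP = ref$X[1, ])
  model2 <- train_subtype_model(X2, c(ref$lab, ref$lab[1]))
  expect_equal(classify_subtypes(model2, t(ref$X)), pred)

  # permuting sample order permutes only the names
  shuf <- sample(nrow(ref$X))
  pred_shuf <- classify_subtypes(model, t(ref$X[shuf, ]))
  expect_equal(pred_shuf, pred[shuf])
})

test_that("training validates labels and features", {
  ref <- make_reference()
  expect_error(train_subtype_model(ref$X, rep("n-CLL", nrow(ref$X))),
               "two classes")
  expect_error(train_subtype_model(ref$X[, 1:4], ref$lab), "5 feature")
  model <- train_subtype_model(ref$X, ref$lab)
  expect_error(classify_subtypes(model, t(ref$X)[1:3, ]),
               "absent")
})

test_that("new cluster draws classify with >=95% agreement; NaN is skipped", {
  ref <- make_reference(seed = 5)
  model <- train_subtype_model(ref$X, ref$lab)
  test <- make_reference(n_per = 40, sd = 0.07, seed = 99)
  pred <- classify_subtypes(model, t(test$X))
  expect_gte(mean(pred == test$lab), 0.95)

  hole <- t(test$X)
  hole[1, 1] <- NaN
  expect_warning(pred2 <- classify_subtypes(model, hole), "skipped")
  expect_true(is.na(pred2[colnames(hole)[1]]))
  expect_equal(pred2[-1], pred[-1])
})

test_that("the model serializes to JSON and back without changing calls", {
  ref <- make_reference()
  model <- train_subtype_model(ref$X, ref$lab)
  path <- withr::local_tempfile(fileext = ".json")
  write_subtype_model(model, path)
  back <- read_subtype_model(path)
  expect_equal(classify_subtypes(back, t(ref$X)),
               classify_subtypes(model, t(ref$X)))
})

subtype_world <- function(n_sub_probes = 200, seed = 15) {
  ann <- small_annotation(3000, seed = seed, chromosomes = as.character(1:4))
  des <- generate_sample_design(30, 10, 0, 1, seed = seed)
  sim <- generate_methylation(
    ann, des,
    effects = null_effects(subtype = list(n_probes = n_sub_probes,
                                          delta = 0.3),
                           svm_markers = TRUE),
    seed = seed + 1)
  list(ann = ann, des = des, sim = sim)
}

test_that("subtype DMPs recover the injected n-CLL/m-CLL differences", {
  w <- subtype_world()
  calls <- w$sim$ledger$subtype_labels    # use ground-truth labels directly
  res <- subtype_dmps(beta_to_m(w$sim$beta$values), calls, w$des,
                      beta = w$sim$beta$values,
                      covariates = character(),
                      reference_dmps = character())
  got <- res$dmp_table$probe_id[res$dmp_table$is_dmp]
  truth <- w$sim$ledger$subtype_probes
  expect_gte(mean(truth %in% got), 0.9)
  expect_equal(res$overlap_pct, 0)        # empty reference

  # no injected subtype effect -> FDR-controlled near-zero calls
  w0 <- subtype_world(n_sub_probes = 0)
  res0 <- subtype_dmps(beta_to_m(w0$sim$beta$values),
                       w0$sim$ledger$subtype_labels, w0$des,
                       beta = w0$sim$beta$values, covariates = character())
  # the 5 SVM marker probes are subtype-differential by construction and
  # are legitimately called; beyond them the null is clean
  calls0 <- res0$dmp_table$probe_id[res0$dmp_table$is_dmp]
  expect_lte(length(setdiff(calls0, w0$sim$ledger$svm_probes)), 2)
})

bcell_world <- function(n_probes_per_subtype = 150, seed = 25) {
  ann <- small_annotation(2500, seed = seed, chromosomes = as.character(1:4))
  groups <- c(rep("mixture", 14), rep(c("NBC", "CD5+NBC", "csMBC",
                                        "ncsMBC"), each = 3))
  des <- generate_sample_design(groups = groups, seed = seed)
  sim <- generate_methylation(
    ann, des,
    effects = null_effects(bcell = list(
      n_probes_per_subtype = n_probes_per_subtype, delta = 0.5,
      pool = character(), pool_frac = 0)),
    seed = seed + 1)
  list(ann = ann, des = des, sim = sim)
}

test_that("B-cell petals recover per-subtype shifts; union is their union", {
  w <- bcell_world()
  res <- bcell_differentiation_dmps(beta_to_m(w$sim$beta$values), w$des,
                                    beta = w$sim$beta$values)
  truth <- w$sim$ledger$bcell_by_subtype
  for (sg in names(truth)) {
    expect_gte(mean(truth[[sg]] %in% res$by_subtype[[sg]]), 0.9)
    others <- setdiff(unlist(truth[names(truth) != sg]), truth[[sg]])
    expect_lte(mean(others %in% res$by_subtype[[sg]]), 0.05)
  }
  expect_identical(res$union, sort(unique(unlist(res$by_subtype))))

  # all groups drawn identically -> empty union
  w0 <- bcell_world(n_probes_per_subtype = 0)
  res0 <- bcell_differentiation_dmps(beta_to_m(w0$sim$beta$values), w0$des,
                                     beta = w0$sim$beta$values)
  expect_length(res0$union, 0)

  # a subtype with fewer than two samples is skipped with a warning
  des1 <- w$des[-(which(w$des$group == "NBC")[1:2]), ]
  expect_warning(
    bcell_differentiation_dmps(
      beta_to_m(w$sim$beta$values[, des1$sample_id]), des1,
      beta = w$sim$beta$values[, des1$sample_id]),
    "fewer than two")
})

test_that("subtraction removes B-cell probes and keeps CLL-specific ones", {
  ann <- small_annotation(2500, seed = 35, chromosomes = as.character(1:4))
  des <- generate_sample_design(20, 12, 0, 1, seed = 35)
  sim <- generate_methylation(ann, des, effects = null_effects(
    affected_fraction = 0.05), seed = 36)
  m <- beta_to_m(sim$beta$values)
  truth <- names(sim$ledger$dmp_probes)

  # empty bcell set: identical to the original run
  r0 <- subtract_and_rescreen(m, des, ann, character(),
                              beta = sim$beta$values,
                              covariates = character())
  expect_equal(r0$bcell_overlap_fraction, 0)
  full <- fit_dmp(m, des, beta = sim$beta$values,
                  covariates = character())
  expect_identical(r0$specific_dmps, full$probe_id[full$is_dmp])

  # bcell set = all called DMPs: nothing survives
  r1 <- subtract_and_rescreen(m, des, ann, r0$specific_dmps,
                              beta = sim$beta$values,
                              covariates = character())
  expect_length(r1$specific_dmps, 0)
  expect_equal(r1$bcell_overlap_fraction, 1)

  # disjoint CLL-only / bcell-only partition: the survivors are the
  # CLL-only truth and never include a subtracted probe
  bset <- setdiff(sample(rownames(m), 800), truth)
  r2 <- subtract_and_rescreen(m, des, ann, bset,
                              beta = sim$beta$values,
                              covariates = character())
  expect_length(intersect(r2$specific_dmps, bset), 0)
  jac <- length(intersect(r2$specific_dmps, truth)) /
    length(union(r2$specific_dmps, truth))
  expect_gte(jac, 0.95)

  # probe order does not matter
  pp <- sample(rownames(m))
  r3 <- subtract_and_rescreen(m[pp, ], des, ann, bset,
                              beta = sim$beta$values[pp, ],
                              covariates = character())
  expect_setequal(r3$specific_dmps, r2$specific_dmps)
  expect_error(subtract_and_rescreen(m, des, ann, rownames(m),
                                     covariates = character()),
               "empty residual")
})
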