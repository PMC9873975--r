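# Synthetic-data generator: configuration validation, ground-truth ledger
# integrity and the distributional properties downstream stages assume.

test_that("annotation generation validates its configuration", {
  expect_error(generate_annotation(0), "n_probes")
  bad_mix <- default_feature_mix(); bad_mix["Body"] <- 0.9
  expect_error(generate_annotation(100, feature_mix = bad_mix),
               "probability vector")
  expect_error(generate_annotation(100, chromosomes = c("1", "MT")),
               "chromosomes")
  names(bad_mix)[1] <- "Exon9"
  expect_error(generate_annotation(100, feature_mix = bad_mix), "named")
})

test_that("degenerate feature mix forces every probe to that feature", {
  mix <- stats::setNames(rep(0, 7), names(default_feature_mix()))
  mix["Body"] <- 1
  ann <- generate_annotation(500, feature_mix = mix, seed = 1)
  expect_true(all(ann$feature[!(ann$chrom %in% c("X", "Y"))] == "Body"))
})

test_that("annotation category counts match the mixes (3-sigma multinomial)", {
  n <- 5000
  ann <- generate_annotation(n, seed = 7)
  for (mix_info in list(list(col = "feature", mix = default_feature_mix()),
                        list(col = "cgi", mix = default_cgi_mix()))) {
    obs <- table(factor(ann[[mix_info$col]], levels = names(mix_info$mix)))
    for (cat in names(mix_info$mix)) {
      p <- mix_info$mix[[cat]]
      expect_lt(abs(obs[[cat]] - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
    }
  }
})

test_that("genes own contiguous probe runs in 5'->3' feature order", {
  ann <- generate_annotation(3000, seed = 11)
  genic <- ann[ann$gene != "", ]
  ord <- c("TSS1500" = 1, "TSS200" = 2, "5'UTR" = 3, "1stExon" = 4,
           "Body" = 5, "3'UTR" = 6)
  for (g in sample(unique(genic$gene), 25)) {
    rows <- which(ann$gene == g)
    expect_equal(rows, seq(min(rows), max(rows)))      # contiguous
    expect_false(is.unsorted(ord[ann$feature[rows]]))  # ordered
  }
  # positions sorted per chromosome
  for (ch in unique(ann$chrom))
    expect_false(is.unsorted(ann$pos[ann$chrom == ch]))
})

test_that("generation is deterministic and respects value ranges", {
  ann <- small_annotation(800, seed = 5)
  des <- small_design(8, 8, 1, 2, seed = 5)
  s1 <- generate_methylation(ann, des, seed = 9)
  s2 <- generate_methylation(ann, des, seed = 9)
  expect_identical(s1$beta$values, s2$beta$values)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$meth, s2$meth)
  b <- s1$beta$values
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(s1$beta$detection_p >= 0 & s1$beta$detection_p <= 1))
  expect_true(all(s1$beta$bead_count >= 0))
  expect_true(all(s1$meth >= 0) && all(s1$unmeth >= 0))
})

test_that("effect magnitudes outside (-1,1) are rejected", {
  ann <- small_annotation(200)
  des <- small_design(4, 4)
  expect_error(generate_methylation(ann, des,
                                    effects = list(delta_hypo = -1.2)),
               "invalid-config")
  expect_error(generate_methylation(ann, des,
                                    effects = list(no_such_knob = 1)),
               "invalid-config")
})

test_that("default beta density is bimodal with a valley in (0.25, 0.75)", {
  ann <- small_annotation(3000, seed = 2)
  des <- small_design(10, 10, 0, 1, seed = 2)
  sim <- generate_methylation(ann, des, effects = null_effects(), seed = 6)
  d <- stats::density(sim$beta$values, n = 512, from = 0, to = 1)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  modes <- d$x[is_max][order(y[is_max], decreasing = TRUE)][1:2]
  expect_true(min(modes) < 0.25 && max(modes) > 0.75)
  valley_idx <- which(d$x > min(modes) & d$x < max(modes))
  valley <- d$x[valley_idx][which.min(y[valley_idx])]
  expect_gt(valley, 0.25)
  expect_lt(valley, 0.75)
})

test_that("null effects give exchangeable case/control distributions", {
  ann <- small_annotation(1500, seed = 4, chromosomes = as.character(1:3))
  des <- small_design(15, 15, 0, 1, seed = 4)
  sim <- generate_methylation(ann, des, effects = null_effects(), seed = 8)
  b <- sim$beta$values
  cll <- des$sample_id[des$group == "CLL"]
  ctl <- des$sample_id[des$group == "control"]
  ks <- suppressWarnings(stats::ks.test(as.vector(b[, cll]),
                                        as.vector(b[, ctl])))
  expect_gt(ks$p.value, 0.01)
  expect_length(sim$ledger$dmp_probes, 0)
})

test_that("injected case effects are recovered at the stated accuracy", {
  ann <- generate_annotation(4000, seed = 1)
  des <- generate_sample_design(48, 28, 0, 1, seed = 12)
  sim <- generate_methylation(ann, des, seed = 24)
  led <- sim$ledger
  pr <- names(led$dmp_probes)
  expect_true(all(pr %in% ann$probe_id))   # ledger referential integrity
  b <- sim$beta$values
  cll <- des$sample_id[des$group == "CLL"]
  ctl <- des$sample_id[des$group == "control"]
  db <- rowMeans(b[pr, cll]) - rowMeans(b[pr, ctl])
  # the mean recovered effect per direction group sits within +/-0.05 of
  # the injected value, and individual probes track it closely
  for (d in unique(led$dmp_probes)) {
    grp <- names(led$dmp_probes)[led$dmp_probes == d]
    expect_lt(abs(mean(db[grp]) - d), 0.05)
  }
  expect_gt(mean(abs(db - led$dmp_probes) < 0.07), 0.99)
  validate_ledger(led, ann)
})

test_that("MBL attenuation 1.0 makes MBL indistinguishable from CLL", {
  ann <- small_annotation(1200, seed = 6, chromosomes = as.character(1:3))
  des <- generate_sample_design(20, 10, 20, 1, seed = 6)
  sim <- generate_methylation(
    ann, des, effects = null_effects(affected_fraction = 0.1,
                                     mbl_attenuation = 1.0), seed = 10)
  pr <- names(sim$ledger$dmp_probes)
  b <- sim$beta$values
  mbl_mean <- rowMeans(b[pr, des$sample_id[des$group == "MBL"]])
  cll_mean <- rowMeans(b[pr, des$sample_id[des$group == "CLL"]])
  expect_lt(max(abs(mbl_mean - cll_mean)), 0.1)
})

test_that("counts: null spec yields no discoveries, coupling sets classes", {
  des <- data.frame(sample_id = sprintf("S%02d", 1:20),
                    group = rep(c("CLL", "control"), each = 10))
  gc <- generate_counts(sprintf("G%03d", 1:300), des, deg_fraction = 0,
                        seed = 42)
  expect_true(all(gc$counts >= 0))
  expect_true(all(gc$counts == round(gc$counts)))
  p <- apply(gc$counts, 1, function(x)
    stats::t.test(x[1:10], x[11:20])$p.value)
  expect_equal(sum(bh_fdr(p) < 0.05), 0)

  # ledger coupling: an "83-type" gene must carry positive log2FC
  led <- cllmeth:::.new_ledger()
  led$dmeg_classes <- c(G001 = "83-type", G002 = "9-type")
  gc2 <- generate_counts(sprintf("G%03d", 1:300), des, coupling = led,
                         deg_fraction = 0, seed = 43)
  expect_gt(gc2$ledger$deg_genes[["G001"]], 0)
  expect_lt(gc2$ledger$deg_genes[["G002"]], 0)
  validate_ledger(gc2$ledger, manual_annotation("cg1", gene = "G001"),
                  counts = gc2$counts)
})

test_that("forced low-depth samples land below the filter and are flagged", {
  des <- data.frame(sample_id = c("A", "B", "C", "D"),
                    group = c("CLL", "CLL", "control", "control"))
  gc <- generate_counts(sprintf("G%03d", 1:500), des,
                        low_depth_samples = "B", seed = 3)
  expect_equal(unname(colSums(gc$counts)["B"]), 99999)
  expect_identical(gc$ledger$low_depth_samples, "B")
  expect_error(generate_counts("G1", des, dispersion = -1),
               "invalid-config")
})

test_that("dataset writer round-trips matrices and tables through TSV", {
  ann <- small_annotation(300, seed = 9, chromosomes = "1")
  des <- small_design(4, 4, 0, 1, seed = 9)
  sim <- generate_methylation(ann, des, effects = null_effects(), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(sim, ann, des, dir, seed = 2)
  b2 <- read_matrix_tsv(file.path(dir, "beta.tsv"))
  expect_equal(b2, sim$beta$values, tolerance = 1e-12)
  ann2 <- read_table_tsv(file.path(dir, "annotation.tsv"))
  expect_equal(ann2$probe_id, ann$probe_id)
})
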