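# Configurable, logged, reproducible orchestration of the full analysis:
# simulate -> qc -> normalize -> combat -> dmp -> dmr -> cna -> de ->
# replication -> integrate -> subtype -> bcell-filter -> ora.

#' Default pipeline configuration
#'
#' Every analysis threshold is a named default matching the published
#' criteria (detection p 0.05, 1 percent sample/probe failure, bead minimum
#' 3 in 5 percent of samples, |delta-beta| > 0.2 & q < 0.05, DMRs with >= 8
#' DMPs spanning > 50 bp separated by 1 kb, CNA threshold 0.2, depth filter
#' 100,000, |log2FC| > 1 & q < 0.05, SVM C = 10 / gamma = 0.01).
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    gmt = NULL,
    stages = list(simulate = TRUE, qc = TRUE, normalize = TRUE,
                  combat = TRUE, dmp = TRUE, dmr = TRUE, cna = TRUE,
                  de = TRUE, integrate = TRUE, subtype = TRUE,
                  bcell = TRUE, ora = TRUE),
    simulate = list(n_probes = 8000, n_cll = 48, n_control = 28, n_mbl = 2,
                    n_batches = 2, n_genes_expr = NULL,
                    n_cll_replication = 40, n_control_replication = 20,
                    n_cll_expr = 20, n_control_expr = 7,
                    n_mixture = 14, n_per_bcell_subtype = 3,
                    cna_probes = 300, cna_dosages = c(0.7, 1.3)),
    qc = list(detection_p = 0.05, sample_fail_frac = 0.01,
              probe_fail_frac = 0.01, bead_min = 3, bead_fail_frac = 0.05,
              drop_sex_chroms = TRUE, drop_flagged = TRUE),
    dmp = list(delta_beta = 0.2, fdr = 0.05,
               covariates = c("age", "sex"), moderated = FALSE),
    dmr = list(min_dmps = 8, min_len = 51, merge_gap = 1000),
    cna = list(threshold = 0.2, window = 50),
    de = list(min_total = 100000, lfc = 1, fdr = 0.05),
    svm = list(C = 10, gamma = 0.01),
    integrate = list(sign_only = FALSE),
    ora = list(fdr = 0.05)
  )
}

.flatten_keys <- function(x, prefix = "") {
  out <- character()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    out <- c(out, key)
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]])))
      out <- c(out, .flatten_keys(x[[nm]], key))
  }
  out
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (suggesting the closest known key),
#' checks threshold ranges and reports all problems at once.
#'
#' @param config a YAML/JSON file path, a named list, or NULL (pure
#'   defaults).
#' @return normalized configuration list, or an error listing every
#'   problem.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  def <- default_config()
  errors <- character()

  known_top <- names(def)
  merge_level <- function(defaults, user, prefix) {
    for (nm in names(user)) {
      if (!nm %in% names(defaults)) {
        pool <- names(defaults)
        sugg <- pool[utils::adist(nm, pool) <= 3]
        errors <<- c(errors, sprintf(
          "unknown key '%s%s'%s", prefix, nm,
          if (length(sugg)) sprintf(" (did you mean '%s'?)", sugg[1]) else ""))
      } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
        defaults[[nm]] <- merge_level(defaults[[nm]], user[[nm]],
                                      paste0(prefix, nm, "."))
      } else {
        defaults[[nm]] <- user[[nm]]
      }
    }
    defaults
  }
  cfg <- merge_level(def, config, "")

  in_range <- function(val, lo, hi, what, lo_open = TRUE, hi_open = TRUE) {
    bad <- if (lo_open) val <= lo else val < lo
    bad <- bad || (if (hi_open) val >= hi else val > hi)
    if (bad) errors <<- c(errors, sprintf("%s must be in %s%g,%g%s (got %g)",
                                          what, if (lo_open) "(" else "[",
                                          lo, hi, if (hi_open) ")" else "]",
                                          val))
  }
  in_range(cfg$dmp$delta_beta, 0, 1, "dmp.delta_beta")
  in_range(cfg$dmp$fdr, 0, 1, "dmp.fdr")
  in_range(cfg$de$fdr, 0, 1, "de.fdr")
  in_range(cfg$qc$detection_p, 0, 1, "qc.detection_p")
  in_range(cfg$qc$sample_fail_frac, 0, 1, "qc.sample_fail_frac",
           lo_open = FALSE, hi_open = FALSE)
  if (cfg$dmr$min_dmps < 1)
    errors <- c(errors, "dmr.min_dmps must be >= 1")
  if (cfg$cna$threshold <= 0)
    errors <- c(errors, "cna.threshold must be positive")
  if (cfg$svm$C <= 0 || cfg$svm$gamma <= 0)
    errors <- c(errors, "svm.C and svm.gamma must be positive")

  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)

  # deviations from the published defaults are surfaced at WARN level
  flag_dev <- function(path, a, b) {
    if (!isTRUE(all.equal(a, b)))
      warning("config deviates from published default: ", path,
              call. = FALSE)
  }
  flag_dev("dmp.delta_beta", cfg$dmp$delta_beta, 0.2)
  flag_dev("dmp.fdr", cfg$dmp$fdr, 0.05)
  flag_dev("dmr.min_dmps", cfg$dmr$min_dmps, 8)
  flag_dev("cna.threshold", cfg$cna$threshold, 0.2)
  flag_dev("de.lfc", cfg$de$lfc, 1)
  cfg
}

# stable 32-bit polynomial hash of a serialized object (manifest provenance)
.config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# pick per-case CNA segments covering `n` consecutive probes on the two
# autosomes with the most probes
.default_cna_segments <- function(annotation, n = 300,
                                  dosages = c(0.7, 1.3)) {
  auto <- annotation[!(annotation$chrom %in% c("X", "Y")), ]
  tab <- sort(table(auto$chrom), decreasing = TRUE)
  chroms <- names(tab)[seq_len(min(length(dosages), length(tab)))]
  segs <- list()
  for (i in seq_along(chroms)) {
    pc <- auto[auto$chrom == chroms[i], ]
    pc <- pc[order(pc$pos), ]
    take <- min(n, nrow(pc))
    segs[[i]] <- list(chrom = chroms[i], start = pc$pos[1],
                      end = pc$pos[take], dosage = dosages[i])
  }
  segs
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in order, writes the result bundle plus a
#' provenance manifest when `out_dir` is set, and aborts naming the failing
#' stage on error (partial outputs are retained).
#'
#' @param config configuration accepted by [validate_config()].
#' @return named list bundle: per-stage outputs, ground-truth ledger and
#'   manifest.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  seed <- cfg$seed
  bundle <- list(config = cfg)
  manifest <- list(package_version = as.character(
    utils::packageVersion("cllmeth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = .config_hash(cfg), seed = seed, stages = list())
  stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) {
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- "ok"
    res
  }

  ## ---- simulate -------------------------------------------------------
  sim <- stage("simulate", cfg$stages$simulate, function() {
    sc <- cfg$simulate
    ann <- generate_annotation(sc$n_probes, seed = seed)
    design <- generate_sample_design(sc$n_cll, sc$n_control, sc$n_mbl,
                                     sc$n_batches, seed = seed + 11)
    cna <- .default_cna_segments(ann, sc$cna_probes, sc$cna_dosages)
    meth <- generate_methylation(ann, design, effects = list(cna = cna),
                                 seed = seed + 23)
    list(annotation = ann, design = design, data = meth)
  })
  if (is.null(sim)) stop("the pipeline currently requires the simulate stage",
                         call. = FALSE)
  ann <- sim$annotation
  design <- sim$design
  ledger <- sim$data$ledger
  bundle$ledger <- ledger
  manifest$input_dims <- dim(sim$data$beta$values)

  ## ---- qc -------------------------------------------------------------
  beta <- sim$data$beta
  qc_rep <- qc_report()
  if (isTRUE(cfg$stages$qc)) {
    fs <- stage("qc", TRUE, function() {
      s1 <- filter_samples(beta, cfg$qc$sample_fail_frac,
                           cfg$qc$detection_p)
      sx <- sex_check(s1$beta, ann, design)
      keep <- setdiff(colnames(s1$beta$values),
                      sx$report$excluded_samples$sample_id)
      b2 <- subset_beta(s1$beta, samples = keep)
      fp <- filter_probes(b2, ann, cfg$qc$detection_p,
                          cfg$qc$probe_fail_frac, cfg$qc$bead_min,
                          cfg$qc$bead_fail_frac, cfg$qc$drop_sex_chroms,
                          cfg$qc$drop_flagged)
      list(beta = fp$beta,
           report = merge_qc(merge_qc(s1$report, sx$report), fp$report))
    })
    beta <- fs$beta
    qc_rep <- fs$report
  }
  bundle$qc <- qc_rep
  sheet <- design[design$sample_id %in% colnames(beta$values), ]
  manifest$qc_dims <- dim(beta$values)

  ## ---- normalize + combat --------------------------------------------
  if (isTRUE(cfg$stages$normalize))
    beta <- stage("normalize", TRUE, function()
      normalize_betas(beta, ann, "type_aware_quantile"))
  m <- beta_to_m(beta$values)
  if (isTRUE(cfg$stages$combat) && length(unique(sheet$batch)) > 1)
    m <- stage("combat", TRUE, function()
      combat(m, sheet$batch,
             covariates = sheet[, c("group", "age", "sex")]))
  bundle$normalized_beta <- beta

  ## ---- dmp / dmr / cna ------------------------------------------------
  dmp <- stage("dmp", cfg$stages$dmp, function()
    fit_dmp(m, sheet, beta = beta$values,
            covariates = cfg$dmp$covariates,
            delta_beta = cfg$dmp$delta_beta, fdr = cfg$dmp$fdr,
            moderated = cfg$dmp$moderated))
  bundle$dmp <- dmp

  if (!is.null(dmp)) {
    bundle$dmr <- stage("dmr", cfg$stages$dmr, function()
      call_dmrs(dmp, ann, cfg$dmr$min_dmps, cfg$dmr$min_len,
                cfg$dmr$merge_gap))
    bundle$feature_distribution <- list(
      cgi = feature_distribution(dmp, ann, dmp$probe_id, by = "cgi"),
      feature = feature_distribution(dmp, ann, dmp$probe_id,
                                     by = "feature"))
  }

  bundle$cna <- stage("cna", cfg$stages$cna, function() {
    keep_p <- rownames(beta$values)
    keep_s <- colnames(beta$values)
    profile_cna(sim$data$meth[keep_p, keep_s],
                sim$data$unmeth[keep_p, keep_s],
                sheet, ann, cfg$cna$window, cfg$cna$threshold)
  })

  ## ---- expression cohort + de ----------------------------------------
  de <- stage("de", cfg$stages$de, function() {
    sc <- cfg$simulate
    genes <- unique(ann$gene[ann$gene != ""])
    if (!is.null(sc$n_genes_expr)) genes <- genes[seq_len(sc$n_genes_expr)]
    edesign <- generate_sample_design(sc$n_cll_expr, sc$n_control_expr, 0,
                                      1, seed = seed + 31)
    gc <- generate_counts(genes, edesign, coupling = ledger,
                          seed = seed + 37)
    fl <- filter_low_depth(gc$counts, cfg$de$min_total)
    grp <- edesign$group[match(colnames(fl$counts), edesign$sample_id)]
    deg <- nb_wald(fl$counts, grp, lfc_threshold = cfg$de$lfc,
                   fdr = cfg$de$fdr)
    list(deg = deg, excluded = fl$excluded, ledger = gc$ledger)
  })
  if (!is.null(de)) {
    ledger <- de$ledger
    bundle$ledger <- ledger
    bundle$deg <- de$deg
  }

  ## ---- replication + integration -------------------------------------
  if (isTRUE(cfg$stages$integrate) && !is.null(dmp) && !is.null(de)) {
    intg <- stage("integrate", TRUE, function() {
      sc <- cfg$simulate
      rdesign <- generate_sample_design(sc$n_cll_replication,
                                        sc$n_control_replication, 0,
                                        cfg$simulate$n_batches,
                                        seed = seed + 41)
      rsim <- generate_methylation(ann, rdesign, seed = seed + 43,
                                   reuse_ledger = ledger)
      rqc <- filter_probes(rsim$beta, ann,
                           drop_sex_chroms = cfg$qc$drop_sex_chroms,
                           drop_flagged = cfg$qc$drop_flagged)
      rbeta <- normalize_betas(rqc$beta, ann, "type_aware_quantile")
      rm_ <- beta_to_m(rbeta$values)
      if (length(unique(rdesign$batch)) > 1)
        rm_ <- combat(rm_, rdesign$batch,
                      covariates = rdesign[, c("group", "age", "sex")])
      rdmp <- fit_dmp(rm_, rdesign, beta = rbeta$values,
                      covariates = cfg$dmp$covariates,
                      delta_beta = cfg$dmp$delta_beta, fdr = cfg$dmp$fdr)
      repl <- replicate_dmps(dmp, rdmp,
                             sign_only = isTRUE(cfg$integrate$sign_only))
      dmegs <- derive_dmegs(repl, dmp, de$deg, ann)
      list(replication_dmp = rdmp, replicated = repl, dmegs = dmegs)
    })
    bundle$replicated <- intg$replicated
    bundle$dmegs <- intg$dmegs
    bundle$replication_dmp <- intg$replication_dmp
  }

  ## ---- subtype --------------------------------------------------------
  if (isTRUE(cfg$stages$subtype) && length(ledger$svm_probes) == 5) {
    sub <- stage("subtype", TRUE, function() {
      centres <- c("n-CLL" = 0.15, "i-CLL" = 0.5, "m-CLL" = 0.85)
      set.seed(seed + 53)
      ref_lab <- rep(names(centres), each = 12)
      ref <- matrix(stats::rnorm(length(ref_lab) * 5, 0, 0.05),
                    length(ref_lab), 5) + centres[ref_lab]
      colnames(ref) <- ledger$svm_probes
      rownames(ref) <- sprintf("REF%02d", seq_along(ref_lab))
      model <- train_subtype_model(ref, ref_lab, cfg$svm$C, cfg$svm$gamma)
      cll_ids <- sheet$sample_id[sheet$group == "CLL"]
      calls <- classify_subtypes(model, subset_beta(sim$data$beta,
                                                    samples = cll_ids))
      sd_ <- subtype_dmps(m[, cll_ids, drop = FALSE], calls, sheet,
                          beta = beta$values[, cll_ids, drop = FALSE],
                          covariates = cfg$dmp$covariates,
                          reference_dmps = dmp$probe_id[dmp$is_dmp])
      list(model = model, calls = calls, dmps = sd_)
    })
    bundle$subtype <- sub
  }

  ## ---- bcell filter ---------------------------------------------------
  if (isTRUE(cfg$stages$bcell) && !is.null(dmp)) {
    bc <- stage("bcell", TRUE, function() {
      sc <- cfg$simulate
      groups <- c(rep("mixture", sc$n_mixture),
                  rep(c("NBC", "CD5+NBC", "csMBC", "ncsMBC"),
                      each = sc$n_per_bcell_subtype))
      bdesign <- generate_sample_design(groups = groups, seed = seed + 61)
      bsim <- generate_methylation(
        ann, bdesign, seed = seed + 67,
        effects = list(
          affected_fraction = 0, dmeg = list(n83 = 0, n9 = 0),
          subtype = list(n_probes = 0), svm_markers = FALSE,
          bcell = list(pool = dmp$probe_id[dmp$is_dmp])))
      bqc <- filter_probes(bsim$beta, ann,
                           drop_sex_chroms = cfg$qc$drop_sex_chroms,
                           drop_flagged = cfg$qc$drop_flagged)
      bm <- beta_to_m(normalize_betas(bqc$beta, ann,
                                      "type_aware_quantile")$values)
      bdmps <- bcell_differentiation_dmps(bm, bdesign,
                                          beta = bqc$beta$values)
      # restrict the B-cell set to the case-control QC universe
      bset <- intersect(bdmps$union, rownames(m))
      rescr <- subtract_and_rescreen(m, sheet, ann, bset,
                                     beta = beta$values,
                                     deg_table = bundle$deg,
                                     covariates = cfg$dmp$covariates,
                                     delta_beta = cfg$dmp$delta_beta,
                                     fdr = cfg$dmp$fdr)
      list(bcell = bdmps, bcell_set = bset, rescreen = rescr)
    })
    bundle$bcell <- bc
  }

  ## ---- ora ------------------------------------------------------------
  if (isTRUE(cfg$stages$ora) && !is.null(cfg$gmt) &&
      !is.null(bundle$dmegs) && nrow(bundle$dmegs)) {
    bundle$ora <- stage("ora", TRUE, function() {
      sets <- read_gmt(cfg$gmt)
      ora(bundle$dmegs$gene, sets, unique(ann$gene[ann$gene != ""]),
          fdr = cfg$ora$fdr)
    })
  }

  bundle$manifest <- manifest

  ## ---- write bundle ---------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- cfg$out_dir
    cm <- sprintf("seed=%d", seed)
    write_table_tsv(ann, file.path(od, "annotation.tsv"), cm)
    write_table_tsv(design, file.path(od, "samples.tsv"), cm)
    write_ledger_json(ledger, file.path(od, "ledger.json"))
    if (!is.null(bundle$dmp))
      write_table_tsv(bundle$dmp, file.path(od, "dmp.tsv"), cm)
    if (!is.null(bundle$dmr) && nrow(bundle$dmr)) {
      write_table_tsv(bundle$dmr, file.path(od, "dmr.tsv"), cm)
      write_bed(bundle$dmr, file.path(od, "dmr.bed"))
    }
    if (!is.null(bundle$cna) && nrow(bundle$cna$segments)) {
      write_table_tsv(bundle$cna$segments, file.path(od, "cna.tsv"), cm)
      write_bed(bundle$cna$segments, file.path(od, "cna.bed"))
    }
    if (!is.null(bundle$deg))
      write_table_tsv(bundle$deg, file.path(od, "deg.tsv"), cm)
    if (!is.null(bundle$dmegs))
      write_table_tsv(bundle$dmegs, file.path(od, "dmeg.tsv"), cm)
    if (!is.null(bundle$subtype)) {
      write_subtype_model(bundle$subtype$model,
                          file.path(od, "subtype_model.json"))
      write_table_tsv(data.frame(sample_id = names(bundle$subtype$calls),
                                 subtype = bundle$subtype$calls),
                      file.path(od, "subtype_calls.tsv"), cm)
    }
    if (!is.null(bundle$ora))
      write_table_tsv(bundle$ora, file.path(od, "ora.tsv"), cm)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}
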