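# Synthetic 450K-like data with a ground-truth ledger.
#
# The generator emits annotated beta matrices, intensity pairs, RNA counts
# and sample sheets whose statistical structure matches what the downstream
# stages assume: bimodal beta distributions, case hypomethylation
# concentrated in gene bodies / open sea, promoter-inverse expression
# coupling, additive M-scale batch shifts, an X-linked sex effect,
# B-cell-subtype shifts, MBL intermediacy and intensity-encoded CNAs.

GENOMIC_FEATURES <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                      "3'UTR", "IGR")
CGI_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
PROMOTER_FEATURES <- c("TSS1500", "TSS200", "1stExon")

# canonical 5'->3' ordering of features inside a gene
.feature_order <- c("TSS1500" = 1, "TSS200" = 2, "5'UTR" = 3, "1stExon" = 4,
                    "Body" = 5, "3'UTR" = 6)

#' Default genomic-feature mixture for synthetic annotation
#' @return named probability vector over the seven genomic features.
#' @export
default_feature_mix <- function() {
  c("TSS1500" = 0.11, "TSS200" = 0.07, "5'UTR" = 0.09, "1stExon" = 0.05,
    "Body" = 0.34, "3'UTR" = 0.04, "IGR" = 0.30)
}

#' Default CpG-island-relation mixture for synthetic annotation
#' @return named probability vector over Island/Shore/Shelf/OpenSea.
#' @export
default_cgi_mix <- function() {
  c("Island" = 0.31, "Shore" = 0.23, "Shelf" = 0.10, "OpenSea" = 0.36)
}

.check_mix <- function(mix, expected, what) {
  if (!setequal(names(mix), expected))
    stop(sprintf("invalid-config: %s must be named over {%s}", what,
                 paste(expected, collapse = ", ")), call. = FALSE)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
    stop(sprintf("invalid-config: %s must be a probability vector summing to 1",
                 what), call. = FALSE)
  mix[expected]
}

#' Generate a 450K-manifest-like probe annotation
#'
#' Probes receive unique ids, per-chromosome sorted 1-based positions, gene
#' assignments forming contiguous runs that span promoter and body features
#' in genomic order, a CGI relation, SNP/cross-reactive flags and a probe
#' design type.
#'
#' @param n_probes number of probes (>= 1).
#' @param chromosomes chromosomes to use; X/Y probes are included only when
#'   listed here.
#' @param feature_mix probability vector over the seven genomic features.
#' @param cgi_mix probability vector over the four CGI relations.
#' @param flagged_fraction per-flag probability that a probe is marked
#'   SNP-overlapping (and, independently, cross-reactive).
#' @param seed RNG seed for this call.
#' @return data.frame of class `ProbeAnnotation` with columns `probe_id`,
#'   `chrom`, `pos`, `strand`, `gene`, `feature`, `cgi`, `snp_flag`,
#'   `crossreactive_flag`, `design_type`.
#' @export
generate_annotation <- function(n_probes,
                                chromosomes = c(as.character(1:22), "X", "Y"),
                                feature_mix = default_feature_mix(),
                                cgi_mix = default_cgi_mix(),
                                flagged_fraction = 0.02,
                                seed = 1) {
  if (length(n_probes) != 1 || n_probes < 1)
    stop("invalid-config: n_probes must be >= 1", call. = FALSE)
  feature_mix <- .check_mix(feature_mix, GENOMIC_FEATURES, "feature_mix")
  cgi_mix <- .check_mix(cgi_mix, CGI_RELATIONS, "cgi_mix")
  bad <- setdiff(chromosomes, c(as.character(1:22), "X", "Y"))
  if (length(bad))
    stop("invalid-config: unknown chromosomes: ", paste(bad, collapse = ","),
         call. = FALSE)
  set.seed(seed)

  # chromosome weights: autosomes uniform; X small, Y tiny (manifest-like)
  w <- ifelse(chromosomes == "X", 0.05, ifelse(chromosomes == "Y", 0.01, 1))
  chrom <- sample(chromosomes, n_probes, replace = TRUE, prob = w / sum(w))
  # order probes by chromosome then emit sorted positions per chromosome
  chrom <- chrom[order(match(chrom, chromosomes))]
  pos <- integer(n_probes)
  feature <- sample(GENOMIC_FEATURES, n_probes, replace = TRUE,
                    prob = feature_mix)
  cgi <- sample(CGI_RELATIONS, n_probes, replace = TRUE, prob = cgi_mix)
  # inter-probe spacing tracks CGI context: islands are probe-dense,
  # open sea sparse (this is what makes region calling meaningful)
  gap_lo <- c(Island = 30, Shore = 100, Shelf = 300, OpenSea = 500)
  gap_hi <- c(Island = 300, Shore = 800, Shelf = 1500, OpenSea = 4000)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- round(stats::runif(length(idx), gap_lo[cgi[idx]],
                               gap_hi[cgi[idx]]))
    pos[idx] <- cumsum(gaps)
  }

  # genes: runs of consecutive non-IGR probes on a chromosome are chopped
  # into gene-sized chunks; within a chunk features are re-ordered 5'->3'
  gene <- character(n_probes)
  gene_counter <- 0L
  is_genic <- feature != "IGR"
  run_id <- cumsum(c(TRUE, diff(as.integer(is_genic)) != 0 |
                       chrom[-1] != chrom[-n_probes]))
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (!is_genic[idx[1]]) next
    while (length(idx)) {
      take <- min(length(idx), sample(4:15, 1))
      chunk <- idx[seq_len(take)]
      idx <- idx[-seq_len(take)]
      gene_counter <- gene_counter + 1L
      gene[chunk] <- sprintf("GENE%05d", gene_counter)
      feature[chunk] <- feature[chunk][order(.feature_order[feature[chunk]])]
    }
  }

  ann <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = chrom,
    pos = pos,
    strand = sample(c("+", "-"), n_probes, replace = TRUE),
    gene = gene,
    feature = feature,
    cgi = cgi,
    snp_flag = stats::runif(n_probes) < flagged_fraction,
    crossreactive_flag = stats::runif(n_probes) < flagged_fraction,
    design_type = sample(c("I", "II"), n_probes, replace = TRUE,
                         prob = c(0.28, 0.72)),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("ProbeAnnotation", "data.frame")
  ann
}

#' Generate a sample design (sample sheet)
#'
#' Cohort structure mirrors a CLL case-control study: cases are older with
#' strongly elevated white-blood-cell and absolute-lymphocyte counts, sex is
#' roughly balanced, samples are spread over processing batches, and cases
#' carry a Rai stage.
#'
#' @param n_cll,n_control,n_mbl group sizes (defaults 48/28/2).
#' @param n_batches number of processing batches.
#' @param groups optional explicit group vector overriding the three sizes
#'   (e.g. B-cell subtype designs); one sample per element.
#' @param seed RNG seed.
#' @return data.frame with columns `sample_id`, `group`, `sex`, `age`,
#'   `batch`, `WBC`, `ALC`, `rai_stage`.
#' @export
generate_sample_design <- function(n_cll = 48, n_control = 28, n_mbl = 2,
                                   n_batches = 2, groups = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(groups))
    groups <- c(rep("CLL", n_cll), rep("control", n_control),
                rep("MBL", n_mbl))
  n <- length(groups)
  is_case <- groups %in% c("CLL", "MBL")
  sex <- ifelse(stats::runif(n) < ifelse(is_case, 0.60, 0.68), "F", "M")
  age <- round(ifelse(is_case, stats::rnorm(n, 62, 9), stats::rnorm(n, 55, 12)))
  age <- pmax(age, 25)
  wbc <- round(exp(ifelse(is_case, stats::rnorm(n, log(30), 0.5),
                          stats::rnorm(n, log(7.4), 0.2))), 1)
  alc <- round(exp(ifelse(is_case, stats::rnorm(n, log(21), 0.6),
                          stats::rnorm(n, log(2), 0.2))), 1)
  rai <- ifelse(groups == "CLL",
                sample(c("0", "I/II", "III/IV"), n, replace = TRUE,
                       prob = c(0.46, 0.48, 0.06)), NA)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    sex = sex,
    age = age,
    batch = sprintf("B%d", 1 + (seq_len(n) - 1) %% n_batches),
    WBC = wbc,
    ALC = alc,
    rai_stage = rai,
    stringsAsFactors = FALSE
  )
}

#' Default effect configuration for [generate_methylation()]
#'
#' @return named list of generator knobs; see the methods vignette for the
#'   rationale behind each default.
#' @export
default_methylation_effects <- function() {
  list(
    affected_fraction = 0.05,   # fraction of clean autosomal probes with a case effect
    hypo_share = 0.9,           # most case DMPs are hypomethylated
    delta_hypo = -0.3,
    delta_hyper = 0.3,
    sigma_m = 0.5,              # per-call noise sd on the M scale
    intermediate_weight = 0.25, # mass of the intermediate-methylation mode
    sex_x_delta = 0.25,         # female - male mean beta on X probes
    mbl_attenuation = 0.8,      # MBL gets this fraction of the CLL effect
    batch_shifts = NULL,        # named M-scale offsets; default (i-1)*0.5
    dmr_regions = list(n = 10, min_probes = 10),  # clustered DMP runs
    detection_fail_rate = 1e-4,
    detection_fail_samples = character(), # samples with elevated failure
    detection_fail_sample_frac = 0.02,
    detection_fail_probes = character(),  # probes with elevated failure
    detection_fail_probe_frac = 0.02,
    low_bead_probes = character(),        # probes with low beads in many samples
    low_bead_frac = 0.06,
    bead_low_rate = 1e-4,
    cna = list(),               # list of list(chrom,start,end,dosage,samples)
    dmeg = list(n83 = 15, n9 = 9, delta = 0.3),
    subtype = list(n_probes = 200, delta = 0.3),
    subtype_probs = c("n-CLL" = 0.5, "i-CLL" = 1 / 6, "m-CLL" = 1 / 3),
    svm_markers = TRUE,
    bcell = list(n_probes_per_subtype = 300, delta = 0.5,
                 pool = character(), pool_frac = 0.92),
    exclude_probes = character(),  # never inject case effects here
    intensity_meanlog = log(4000),
    intensity_sdlog = 0.25
  )
}

.merge_effects <- function(effects) {
  def <- default_methylation_effects()
  for (nm in names(effects)) {
    if (!nm %in% names(def))
      stop("invalid-config: unknown effect '", nm, "'", call. = FALSE)
    if (is.list(def[[nm]]) && is.list(effects[[nm]]) && nm != "cna") {
      def[[nm]][names(effects[[nm]])] <- effects[[nm]]
    } else {
      def[[nm]] <- effects[[nm]]
    }
  }
  for (d in c(def$delta_hypo, def$delta_hyper, def$dmeg$delta,
              def$subtype$delta, def$bcell$delta))
    if (abs(d) >= 1)
      stop("invalid-config: effect magnitudes must lie in (-1, 1)",
           call. = FALSE)
  def
}

# empty ground-truth ledger
.new_ledger <- function() {
  structure(list(
    dmp_probes = numeric(),      # named signed delta-beta by probe id
    deg_genes = numeric(),       # named log2 fold change by gene
    dmeg_classes = character(),  # named class by gene
    cna_segments = list(),
    dmr_regions = list(),
    batch_shifts = numeric(),
    subtype_labels = character(),
    subtype_probes = character(),
    svm_probes = character(),
    bcell_probes = character(),
    bcell_by_subtype = list(),
    low_depth_samples = character()
  ), class = "GroundTruthLedger")
}

#' Generate a synthetic methylation dataset
#'
#' Baseline probe means are drawn from a two-component Beta mixture (low
#' mode ~0.1, high mode ~0.9) with the low-mode weight set by CGI context
#' (islands mostly unmethylated, open sea mostly methylated), giving the
#' bimodal genome-wide beta density seen on real arrays. Per-call noise is
#' added on the M scale together with batch offsets; case effects, the
#' X-linked sex effect and subtype/B-cell shifts are then added on the beta
#' scale and clipped to \[0, 1\], so the injected delta-beta is exactly the
#' expected group mean difference away from the clip boundaries.
#'
#' @param annotation a `ProbeAnnotation`.
#' @param sample_design data.frame with at least `sample_id`, `group`,
#'   `sex`, `batch` (see [generate_sample_design()]).
#' @param effects named list overriding [default_methylation_effects()].
#' @param seed RNG seed for this call; sub-streams decouple the matrices.
#' @param reuse_ledger optional `GroundTruthLedger` from a previous call on
#'   the same annotation: the injected probe effects, direction classes and
#'   marker/subtype/B-cell probe sets are reused (with fresh noise and
#'   baselines given headroom for the reused effects), emulating an
#'   independent replication cohort carrying the same biology.
#' @return list with elements `beta` (a [beta_matrix()] with detection-p and
#'   bead-count companions), `meth`, `unmeth` (intensity matrices),
#'   `ledger` (a `GroundTruthLedger`).
#' @export
generate_methylation <- function(annotation, sample_design, effects = list(),
                                 seed = 1, reuse_ledger = NULL) {
  eff <- .merge_effects(effects)
  ann <- annotation
  des <- sample_design
  P <- nrow(ann); S <- nrow(des)
  stopifnot(all(c("sample_id", "group", "sex", "batch") %in% names(des)))
  ledger <- .new_ledger()
  set.seed(seed)

  ## baseline probe means: three-component Beta mixture. Low/high modes by
  ## CGI context (islands mostly unmethylated, open sea methylated) plus an
  ## intermediate component so the density valley between the modes is
  ## populated, as on real arrays (partially methylated / heterogeneous
  ## CpGs)
  w_low <- c(Island = 0.85, Shore = 0.60, Shelf = 0.35, OpenSea = 0.15)
  w_mid <- eff$intermediate_weight
  u <- stats::runif(P)
  lowq <- u < (1 - w_mid) * w_low[ann$cgi]
  midq <- !lowq & u < (1 - w_mid) * w_low[ann$cgi] + w_mid
  mu_p <- ifelse(lowq, stats::rbeta(P, 2, 18),
                 ifelse(midq, stats::rbeta(P, 4, 4), stats::rbeta(P, 18, 2)))
  # the +100 intensity offset keeps real array betas off the boundaries;
  # bounding baselines likewise avoids degenerate logit values
  mu_p <- pmin(pmax(mu_p, 0.01), 0.99)

  clean_auto <- !(ann$chrom %in% c("X", "Y")) & !ann$snp_flag &
    !ann$crossreactive_flag & !(ann$probe_id %in% eff$exclude_probes)

  delta <- numeric(P)  # signed injected case effect per probe
  svm_reuse <- NULL
  if (!is.null(reuse_ledger)) {
    ## replication mode: reuse injected structure, fresh noise
    stopifnot(inherits(reuse_ledger, "GroundTruthLedger"))
    ix <- match(names(reuse_ledger$dmp_probes), ann$probe_id)
    if (anyNA(ix))
      stop("reuse_ledger probes missing from annotation", call. = FALSE)
    delta[ix] <- reuse_ledger$dmp_probes
    neg <- ix[reuse_ledger$dmp_probes < 0]
    posv <- ix[reuse_ledger$dmp_probes > 0]
    mu_p[neg] <- stats::runif(length(neg), 0.55, 0.9)
    mu_p[posv] <- stats::runif(length(posv), 0.1, 0.35)
    ledger$dmp_probes <- reuse_ledger$dmp_probes
    ledger$dmeg_classes <- reuse_ledger$dmeg_classes
    ledger$dmr_regions <- reuse_ledger$dmr_regions
    ledger$subtype_probes <- reuse_ledger$subtype_probes
    ledger$bcell_by_subtype <- reuse_ledger$bcell_by_subtype
    ledger$bcell_probes <- reuse_ledger$bcell_probes
    svm_reuse <- reuse_ledger$svm_probes
  }

  ## DMEG-coordinated probes: force headroom by overriding baselines
  if (is.null(reuse_ledger)) {
  genic <- split(seq_len(P)[clean_auto & ann$gene != ""],
                 ann$gene[clean_auto & ann$gene != ""])
  has_both <- vapply(genic, function(ix)
    any(ann$feature[ix] %in% PROMOTER_FEATURES) &&
      any(ann$feature[ix] == "Body"), logical(1))
  pool_genes <- names(genic)[has_both]
  n_need <- eff$dmeg$n83 + eff$dmeg$n9
  if (n_need > length(pool_genes))
    stop("invalid-config: not enough promoter+body genes for requested DMEGs",
         call. = FALSE)
  dmeg_genes <- sample(pool_genes, n_need)
  g83 <- dmeg_genes[seq_len(eff$dmeg$n83)]
  g9 <- setdiff(dmeg_genes, g83)
  d <- eff$dmeg$delta
  for (g in dmeg_genes) {
    ix <- genic[[g]]
    prom <- ix[ann$feature[ix] %in% PROMOTER_FEATURES]
    body <- ix[ann$feature[ix] == "Body"]
    if (g %in% g83) {
      # expression up, promoter hypo, body hypo
      mu_p[c(prom, body)] <- stats::runif(length(c(prom, body)), 0.55, 0.9)
      delta[c(prom, body)] <- -d
    } else {
      # expression down, promoter hyper, body hypo
      mu_p[prom] <- stats::runif(length(prom), 0.1, 0.35)
      delta[prom] <- d
      mu_p[body] <- stats::runif(length(body), 0.55, 0.9)
      delta[body] <- -d
    }
  }
  ledger$dmeg_classes <- stats::setNames(
    c(rep("83-type", length(g83)), rep("9-type", length(g9))), c(g83, g9))

  ## generic case-effect probes (context-directed hypo/hyper)
  n_affected <- round(eff$affected_fraction * sum(clean_auto))
  free <- clean_auto & delta == 0
  # hypo effects on well-methylated probes, hyper on unmethylated ones:
  # the canonical tumour patterns, and both keep the injected shift clear
  # of the [0,1] boundaries even under per-call noise
  hypo_cand <- which(free & (ann$feature == "Body" | ann$cgi == "OpenSea") &
                       mu_p >= max(abs(eff$delta_hypo) + 0.1, 0.55) &
                       mu_p <= 0.97)
  hyper_cand <- which(free & (ann$cgi == "Island" |
                                ann$feature %in% PROMOTER_FEATURES) &
                        mu_p >= 0.03 & mu_p <= 0.35)
  n_hypo <- min(round(eff$hypo_share * n_affected), length(hypo_cand))
  n_hyper <- min(n_affected - n_hypo, length(hyper_cand))
  hypo_idx <- if (n_hypo) sample(hypo_cand, n_hypo) else integer()
  hyper_idx <- if (n_hyper) sample(hyper_cand, n_hyper) else integer()
  delta[hypo_idx] <- eff$delta_hypo
  delta[hyper_idx] <- eff$delta_hyper

  ## clustered DMP runs so the region caller has true regions to find:
  ## runs of adjacent clean probes with inter-probe gaps under 1 kb get a
  ## shared effect (hyper on island-dominated runs, hypo elsewhere)
  if (eff$dmr_regions$n > 0) {
    minp <- eff$dmr_regions$min_probes
    runs <- list()
    ok <- which(clean_auto & delta == 0)
    for (ch in unique(ann$chrom[ok])) {
      ix <- ok[ann$chrom[ok] == ch]
      if (length(ix) < minp) next
      contig <- diff(ix) == 1 & diff(ann$pos[ix]) < 1000
      grp <- cumsum(c(1L, as.integer(!contig)))
      for (g2 in split(seq_along(ix), grp))
        if (length(g2) >= minp)
          runs[[length(runs) + 1]] <- ix[g2[seq_len(minp)]]
    }
    if (length(runs)) {
      take <- runs[sample(length(runs),
                          min(eff$dmr_regions$n, length(runs)))]
      for (run in take) {
        hyper_run <- mean(ann$cgi[run] == "Island") > 0.5
        dlt <- if (hyper_run) eff$delta_hyper else eff$delta_hypo
        mu_p[run] <- if (hyper_run) stats::runif(length(run), 0.1, 0.35)
                     else stats::runif(length(run), 0.55, 0.9)
        delta[run] <- dlt
        ledger$dmr_regions[[length(ledger$dmr_regions) + 1]] <- list(
          chrom = ann$chrom[run[1]], start = ann$pos[run[1]],
          end = ann$pos[run[length(run)]],
          probes = ann$probe_id[run], delta = dlt)
      }
    }
  }

  ledger$dmp_probes <- stats::setNames(delta[delta != 0],
                                       ann$probe_id[delta != 0])
  }  # end fresh-selection path

  ## subtype labels and subtype-differential probes (CLL only)
  cll <- which(des$group == "CLL")
  sub_lab <- character(S)
  if (length(cll)) {
    sub_lab[cll] <- sample(names(eff$subtype_probs), length(cll),
                           replace = TRUE, prob = eff$subtype_probs)
    ledger$subtype_labels <- stats::setNames(sub_lab[cll],
                                             des$sample_id[cll])
  }
  sub_idx <- integer()
  if (!is.null(reuse_ledger)) {
    sub_idx <- match(ledger$subtype_probes, ann$probe_id)
  } else if (length(cll) && eff$subtype$n_probes > 0) {
    cand <- which(clean_auto & delta == 0 & mu_p >= 0.05 &
                    mu_p <= 0.92 - eff$subtype$delta)
    sub_idx <- sample(cand, min(eff$subtype$n_probes, length(cand)))
    ledger$subtype_probes <- ann$probe_id[sub_idx]
  }

  ## B-cell subtype probes (active when the design carries those groups)
  bc_groups <- c("NBC", "CD5+NBC", "csMBC", "ncsMBC")
  present_bc <- intersect(bc_groups, des$group)
  bc_sets <- list()
  if (!is.null(reuse_ledger) && length(ledger$bcell_by_subtype)) {
    bc_sets <- lapply(ledger$bcell_by_subtype,
                      function(p) match(p, ann$probe_id))
  } else if (length(present_bc) && eff$bcell$n_probes_per_subtype > 0) {
    used <- delta != 0 | seq_len(P) %in% sub_idx
    pool_ids <- intersect(eff$bcell$pool, ann$probe_id)
    for (bg in present_bc) {
      npb <- eff$bcell$n_probes_per_subtype
      n_pool <- min(round(eff$bcell$pool_frac * npb), length(pool_ids))
      from_pool <- if (n_pool) sample(match(pool_ids, ann$probe_id), n_pool)
                   else integer()
      cand <- which(clean_auto & !used & mu_p >= 0.05 &
                      mu_p <= 0.92 - eff$bcell$delta)
      cand <- setdiff(cand, from_pool)
      extra <- sample(cand, min(npb - length(from_pool), length(cand)))
      bc_sets[[bg]] <- sort(c(from_pool, extra))
    }
    ledger$bcell_by_subtype <- lapply(bc_sets, function(ix) ann$probe_id[ix])
    ledger$bcell_probes <- ann$probe_id[sort(unique(unlist(bc_sets)))]
  }

  ## batch shifts on the M scale
  batches <- sort(unique(des$batch))
  if (is.null(eff$batch_shifts)) {
    shifts <- stats::setNames((seq_along(batches) - 1) * 0.5, batches)
  } else {
    shifts <- eff$batch_shifts
    if (!all(batches %in% names(shifts)))
      stop("invalid-config: batch_shifts must cover all batches", call. = FALSE)
  }
  ledger$batch_shifts <- shifts
  ledger$cna_segments <- eff$cna

  ## assemble beta matrix: M-scale baseline + noise, beta-scale effects
  set.seed(seed + 1L)
  M0 <- matrix(beta_to_m(mu_p), P, S) +
    matrix(shifts[des$batch], P, S, byrow = TRUE) +
    matrix(stats::rnorm(P * S, 0, eff$sigma_m), P, S)
  beta0 <- m_to_beta(M0)

  E <- matrix(0, P, S)
  is_cll <- des$group == "CLL"
  is_mbl <- des$group == "MBL"
  if (any(delta != 0)) {
    E[, is_cll] <- E[, is_cll] + delta
    E[, is_mbl] <- E[, is_mbl] + delta * eff$mbl_attenuation
  }
  x_probes <- ann$chrom == "X"
  if (any(x_probes) && any(des$sex == "F"))
    E[x_probes, des$sex == "F"] <- E[x_probes, des$sex == "F"] +
      eff$sex_x_delta
  if (length(sub_idx)) {
    step <- c("m-CLL" = 0, "i-CLL" = eff$subtype$delta / 2,
              "n-CLL" = eff$subtype$delta)
    for (s in cll)
      E[sub_idx, s] <- E[sub_idx, s] + step[sub_lab[s]]
  }
  if (length(bc_sets)) {
    for (bg in names(bc_sets)) {
      cols <- which(des$group == bg)
      rows <- bc_sets[[bg]]
      # shift away from the nearer beta boundary so the effect is not clipped
      bdlt <- ifelse(mu_p[rows] > 0.5, -eff$bcell$delta, eff$bcell$delta)
      E[rows, cols] <- E[rows, cols] + bdlt
    }
  }
  beta <- pmin(pmax(beta0 + E, 0), 1)

  ## 5-CpG subtype marker probes: overridden, not added
  if ((isTRUE(eff$svm_markers) || !is.null(svm_reuse)) && length(cll)) {
    if (!is.null(svm_reuse) && length(svm_reuse) == 5) {
      svm_idx <- match(svm_reuse, ann$probe_id)
    } else {
      cand <- which(clean_auto & delta == 0 & !(seq_len(P) %in% sub_idx))
      svm_idx <- sample(cand, 5)
    }
    ledger$svm_probes <- ann$probe_id[svm_idx]
    centre <- c("n-CLL" = 0.15, "i-CLL" = 0.5, "m-CLL" = 0.85)
    mk <- matrix(stats::rnorm(5 * S, 0, 0.05), 5, S) + 0.5
    for (s in cll) mk[, s] <- centre[sub_lab[s]] +
        stats::rnorm(5, 0, 0.05)
    beta[svm_idx, ] <- pmin(pmax(mk, 0), 1)
  }

  dimnames(beta) <- list(ann$probe_id, des$sample_id)

  ## detection p and bead counts
  set.seed(seed + 2L)
  det <- matrix(stats::runif(P * S, 0, 0.01), P, S, dimnames = dimnames(beta))
  fail <- matrix(stats::runif(P * S) < eff$detection_fail_rate, P, S)
  if (length(eff$detection_fail_samples)) {
    cols <- match(eff$detection_fail_samples, des$sample_id)
    fail[, cols] <- matrix(stats::runif(P * length(cols)) <
                             eff$detection_fail_sample_frac, P)
  }
  if (length(eff$detection_fail_probes)) {
    rows <- match(eff$detection_fail_probes, ann$probe_id)
    fail[rows, ] <- matrix(stats::runif(length(rows) * S) <
                             eff$detection_fail_probe_frac, length(rows))
  }
  det[fail] <- stats::runif(sum(fail), 0.051, 0.5)

  beads <- matrix(stats::rpois(P * S, 14) + 3L, P, S,
                  dimnames = dimnames(beta))
  lowb <- matrix(stats::runif(P * S) < eff$bead_low_rate, P, S)
  if (length(eff$low_bead_probes)) {
    rows <- match(eff$low_bead_probes, ann$probe_id)
    lowb[rows, ] <- matrix(stats::runif(length(rows) * S) <
                             eff$low_bead_frac, length(rows))
  }
  beads[lowb] <- 2L

  ## intensities: lognormal total, split by beta, scaled by CNA dosage
  set.seed(seed + 3L)
  tot <- matrix(stats::rlnorm(P * S, eff$intensity_meanlog,
                              eff$intensity_sdlog), P, S)
  dosage <- matrix(1, P, S)
  for (seg in eff$cna) {
    rows <- which(ann$chrom == seg$chrom & ann$pos >= seg$start &
                    ann$pos <= seg$end)
    cols <- if (is.null(seg$samples)) which(is_cll)
            else match(seg$samples, des$sample_id)
    dosage[rows, cols] <- seg$dosage
  }
  tot <- tot * dosage
  meth <- beta * tot
  unmeth <- (1 - beta) * tot
  dimnames(meth) <- dimnames(unmeth) <- dimnames(beta)

  list(beta = beta_matrix(beta, detection_p = det, bead_count = beads),
       meth = meth, unmeth = unmeth, ledger = ledger)
}

#' Generate a synthetic RNA-seq count matrix coupled to the methylation ledger
#'
#' Counts follow a negative-binomial model with lognormal per-gene baselines
#' and per-sample library-size factors. Genes recorded in the ledger's
#' direction classes get the matching expression sign: "83-type" genes are
#' up-regulated in cases, "9-type" genes down-regulated.
#'
#' @param genes character vector of gene ids (rows of the matrix).
#' @param sample_design data.frame with `sample_id` and `group`; any group
#'   other than "control" is treated as a case.
#' @param deg_spec optional data.frame with columns `gene`, `log2fc` and
#'   optionally `dispersion` fixing per-gene parameters.
#' @param coupling optional `GroundTruthLedger` whose `dmeg_classes` drive
#'   the coupled genes' log2 fold changes.
#' @param deg_fraction fraction of remaining genes given a +/-`lfc_default`
#'   effect.
#' @param lfc_default magnitude of uncoupled DEG effects (log2 scale).
#' @param lfc_coupled magnitude of ledger-coupled DEG effects.
#' @param dispersion NB dispersion (1/size); must be positive.
#' @param base_meanlog,base_sdlog lognormal baseline mean parameters.
#' @param low_depth_samples sample ids forced to a total count of 99,999
#'   (below the default depth filter) and flagged in the ledger.
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples integer matrix) and `ledger`
#'   (input ledger updated with `deg_genes` and `low_depth_samples`).
#' @export
generate_counts <- function(genes, sample_design, deg_spec = NULL,
                            coupling = NULL, deg_fraction = 0.1,
                            lfc_default = 2, lfc_coupled = 2.5,
                            dispersion = 0.1,
                            base_meanlog = log(200), base_sdlog = 1,
                            low_depth_samples = character(), seed = 1) {
  if (any(dispersion <= 0))
    stop("invalid-config: dispersion must be positive", call. = FALSE)
  set.seed(seed + 7L)
  G <- length(genes); S <- nrow(sample_design)
  lfc <- stats::setNames(numeric(G), genes)
  disp <- stats::setNames(rep(dispersion, G), genes)
  if (!is.null(coupling)) {
    cls <- coupling$dmeg_classes
    cls <- cls[names(cls) %in% genes]
    lfc[names(cls)] <- ifelse(cls == "83-type", lfc_coupled, -lfc_coupled)
  }
  if (!is.null(deg_spec)) {
    stopifnot(all(c("gene", "log2fc") %in% names(deg_spec)))
    lfc[deg_spec$gene] <- deg_spec$log2fc
    if ("dispersion" %in% names(deg_spec)) {
      if (any(deg_spec$dispersion <= 0))
        stop("invalid-config: dispersion must be positive", call. = FALSE)
      disp[deg_spec$gene] <- deg_spec$dispersion
    }
  }
  free <- names(lfc)[lfc == 0]
  n_extra <- round(deg_fraction * length(free))
  if (n_extra > 0) {
    extra <- sample(free, n_extra)
    lfc[extra] <- sample(c(-1, 1), n_extra, replace = TRUE) * lfc_default
  }

  base <- stats::rlnorm(G, base_meanlog, base_sdlog)
  sf <- stats::rlnorm(S, 0, 0.15)
  is_case <- sample_design$group != "control"
  mu <- base * 2^(outer(lfc, as.numeric(is_case))) *
    matrix(sf, G, S, byrow = TRUE)
  counts <- matrix(stats::rnbinom(G * S, mu = mu,
                                  size = 1 / rep(disp, S)), G, S)
  dimnames(counts) <- list(genes, sample_design$sample_id)
  for (sid in low_depth_samples) {
    j <- match(sid, colnames(counts))
    counts[, j] <- stats::rmultinom(1, 99999L, prob = counts[, j] + 0.5)[, 1]
  }
  ledger <- if (is.null(coupling)) .new_ledger() else coupling
  ledger$deg_genes <- lfc[lfc != 0]
  ledger$low_depth_samples <- low_depth_samples
  list(counts = counts, ledger = ledger)
}

#' Validate a ground-truth ledger against emitted data
#'
#' Checks referential integrity (every ledger probe/gene id exists in the
#' emitted annotation or matrices) and the consistency of direction classes
#' with the injected methylation and expression signs.
#'
#' @param ledger a `GroundTruthLedger`.
#' @param annotation the `ProbeAnnotation` the data were generated from.
#' @param counts optional counts matrix to check `deg_genes` against.
#' @return invisible TRUE; stops on violation.
#' @export
validate_ledger <- function(ledger, annotation, counts = NULL) {
  stopifnot(inherits(ledger, "GroundTruthLedger"))
  probes <- c(names(ledger$dmp_probes), ledger$subtype_probes,
              ledger$svm_probes, ledger$bcell_probes)
  if (!all(probes %in% annotation$probe_id))
    stop("ledger probe ids missing from annotation", call. = FALSE)
  if (!is.null(counts) && length(ledger$deg_genes) &&
      !all(names(ledger$deg_genes) %in% rownames(counts)))
    stop("ledger genes missing from counts", call. = FALSE)
  if (length(ledger$dmeg_classes)) {
    for (g in names(ledger$dmeg_classes)) {
      cls <- ledger$dmeg_classes[[g]]
      pr <- annotation$probe_id[annotation$gene == g]
      dd <- ledger$dmp_probes[names(ledger$dmp_probes) %in% pr]
      if (cls == "83-type" && any(dd > 0))
        stop("83-type gene ", g, " has hypermethylated probes", call. = FALSE)
      if (length(ledger$deg_genes)) {
        lf <- ledger$deg_genes[[g]]
        if (!is.null(lf) && !is.na(lf)) {
          if (cls == "83-type" && lf <= 0)
            stop("83-type gene ", g, " has non-positive log2FC", call. = FALSE)
          if (cls == "9-type" && lf >= 0)
            stop("9-type gene ", g, " has non-negative log2FC", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Write a ground-truth ledger as JSON
#' @param ledger a `GroundTruthLedger`.
#' @param path output path.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits the TSV/JSON artefacts of a generated dataset: beta, detection-p,
#' bead-count, methylated/unmethylated intensity and count matrices, the
#' annotation, the sample sheet and the ledger.
#'
#' @param sim result of [generate_methylation()].
#' @param annotation the `ProbeAnnotation` used.
#' @param sample_design the sample sheet used.
#' @param dir output directory (created if needed).
#' @param counts optional counts matrix.
#' @param seed seed recorded in file headers.
#' @return invisible vector of written paths.
#' @export
write_dataset <- function(sim, annotation, sample_design, dir,
                          counts = NULL, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- if (is.na(seed)) character() else sprintf("seed=%d", seed)
  paths <- c(
    write_matrix_tsv(sim$beta$values, file.path(dir, "beta.tsv"),
                     "probe_id", cm),
    write_matrix_tsv(sim$beta$detection_p, file.path(dir, "detection_p.tsv"),
                     "probe_id", cm),
    write_matrix_tsv(sim$beta$bead_count, file.path(dir, "bead_count.tsv"),
                     "probe_id", cm),
    write_matrix_tsv(sim$meth, file.path(dir, "meth.tsv"), "probe_id", cm),
    write_matrix_tsv(sim$unmeth, file.path(dir, "unmeth.tsv"), "probe_id", cm),
    write_table_tsv(annotation, file.path(dir, "annotation.tsv"), cm),
    write_table_tsv(sample_design, file.path(dir, "samples.tsv"), cm),
    write_ledger_json(sim$ledger, file.path(dir, "ledger.json"))
  )
  if (!is.null(counts))
    paths <- c(paths, write_matrix_tsv(counts, file.path(dir, "counts.tsv"),
                                       "gene", cm))
  invisible(paths)
}
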