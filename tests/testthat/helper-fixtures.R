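# Shared fixtures: everything is generated in code at test time.

# effect list that switches off every injected signal (pure null world)
null_effects <- function(...) {
  utils::modifyList(
    list(affected_fraction = 0,
         dmeg = list(n83 = 0, n9 = 0),
         subtype = list(n_probes = 0),
         svm_markers = FALSE,
         dmr_regions = list(n = 0),
         sex_x_delta = 0,
         batch_shifts = NULL),
    list(...))
}

small_annotation <- function(n = 2000, seed = 7,
                             chromosomes = as.character(1:6), ...) {
  generate_annotation(n, chromosomes = chromosomes, seed = seed, ...)
}

small_design <- function(n_cll = 12, n_control = 12, n_mbl = 0,
                         n_batches = 1, seed = 3, ...) {
  generate_sample_design(n_cll, n_control, n_mbl, n_batches, seed = seed,
                         ...)
}

# hand-rolled annotation for targeted probe-level scenarios
manual_annotation <- function(probe_id, chrom = "1",
                              pos = seq_along(probe_id) * 100L,
                              gene = "", feature = "Body",
                              cgi = "OpenSea") {
  n <- length(probe_id)
  ann <- data.frame(probe_id = probe_id,
                    chrom = rep_len(chrom, n), pos = pos,
                    strand = "+", gene = rep_len(gene, n),
                    feature = rep_len(feature, n),
                    cgi = rep_len(cgi, n),
                    snp_flag = FALSE, crossreactive_flag = FALSE,
                    design_type = "II", stringsAsFactors = FALSE)
  class(ann) <- c("ProbeAnnotation", "data.frame")
  ann
}

# minimal DMP table for the region caller / integration fixtures
manual_dmp_table <- function(probe_id, delta_beta, q = 0.001,
                             is_dmp = TRUE) {
  n <- length(probe_id)
  out <- data.frame(probe_id = probe_id, delta_beta = delta_beta,
                    coef_m = delta_beta, p = rep_len(q, n),
                    q = rep_len(q, n),
                    direction = ifelse(delta_beta >= 0, "hyper", "hypo"),
                    is_dmp = rep_len(is_dmp, n), stringsAsFactors = FALSE)
  class(out) <- c("DMPTable", "data.frame")
  out
}

# independent brute-force DMR oracle: enumerate all maximal chains by
# checking every consecutive probe pair, then filter on the stated criteria
oracle_dmrs <- function(dmp_table, annotation, min_dmps = 8, min_len = 51,
                        merge_gap = 1000) {
  dmps <- dmp_table[dmp_table$is_dmp, , drop = FALSE]
  if (!nrow(dmps)) return(character())
  idx <- match(dmps$probe_id, annotation$probe_id)
  d <- data.frame(chrom = annotation$chrom[idx], pos = annotation$pos[idx])
  d <- d[order(d$chrom, d$pos), ]
  keys <- character()
  for (ch in unique(d$chrom)) {
    p <- sort(d$pos[d$chrom == ch])
    n <- length(p)
    for (i in seq_len(n)) {
      for (j in i:n) {
        ok <- j == i || all(diff(p[i:j]) < merge_gap)
        if (!ok) break
        maximal_left <- i == 1 || (p[i] - p[i - 1]) >= merge_gap
        maximal_right <- j == n || (p[j + 1] - p[j]) >= merge_gap
        if (maximal_left && maximal_right &&
            (j - i + 1) >= min_dmps && (p[j] - p[i]) > (min_len - 1))
          keys <- c(keys, sprintf("%s:%d-%d", ch, p[i], p[j]))
      }
    }
  }
  sort(keys)
}
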