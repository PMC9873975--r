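# DMR calling from DMP coordinates and CNA profiling from total intensity.

#' Call differentially methylated regions by fixed-gap chaining
#'
#' Per chromosome, consecutive DMPs whose inter-probe gap is below
#' `merge_gap` are chained greedily; chains with at least `min_dmps`
#' members and a span strictly greater than `min_len - 1` bases become
#' DMRs. With the defaults this implements the criteria: more than seven
#' DMPs (>= 8), length over 50 bp (span > 50), and at least 1,000 bp
#' between adjacent DMRs.
#'
#' @param dmp_table a `DMPTable` (only rows with `is_dmp` are used).
#' @param annotation `ProbeAnnotation` giving probe coordinates and genes.
#' @param min_dmps minimum DMPs per region (default 8).
#' @param min_len minimum length in bp; span must be > `min_len - 1`
#'   (default 51, i.e. span > 50).
#' @param merge_gap chain-breaking gap in bp (default 1000).
#' @return data.frame with one row per DMR: `chrom`, `start`, `end`
#'   (1-based inclusive, first/last member DMP), `n_dmps`, `probes`
#'   (comma-separated), `genes`, `mean_delta_beta`.
#' @export
call_dmrs <- function(dmp_table, annotation, min_dmps = 8, min_len = 51,
                      merge_gap = 1000) {
  dmps <- dmp_table[dmp_table$is_dmp, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dmps = integer(),
                      probes = character(), genes = character(),
                      mean_delta_beta = numeric(), stringsAsFactors = FALSE)
  if (nrow(dmps) == 0) return(empty)
  idx <- match(dmps$probe_id, annotation$probe_id)
  if (anyNA(idx)) stop("DMPs not mappable to annotation", call. = FALSE)
  d <- data.frame(probe_id = dmps$probe_id,
                  chrom = annotation$chrom[idx],
                  pos = annotation$pos[idx],
                  gene = annotation$gene[idx],
                  delta_beta = dmps$delta_beta,
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), ]
  out <- list()
  for (ch in unique(d$chrom)) {
    dc <- d[d$chrom == ch, , drop = FALSE]
    gaps <- diff(dc$pos)
    chain <- cumsum(c(1L, as.integer(gaps >= merge_gap)))
    for (cid in unique(chain)) {
      cc <- dc[chain == cid, , drop = FALSE]
      span <- max(cc$pos) - min(cc$pos)
      if (nrow(cc) >= min_dmps && span > (min_len - 1)) {
        genes <- sort(unique(cc$gene[cc$gene != ""]))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = min(cc$pos), end = max(cc$pos),
          n_dmps = nrow(cc),
          probes = paste(cc$probe_id, collapse = ","),
          genes = paste(genes, collapse = ","),
          mean_delta_beta = mean(cc$delta_beta),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

#' Per-chromosome DMR counts
#' @param dmrs result of [call_dmrs()].
#' @return data.frame `chrom`, `n_dmrs` sorted by count.
#' @export
dmr_summary <- function(dmrs) {
  tab <- table(dmrs$chrom)
  data.frame(chrom = names(tab), n_dmrs = as.integer(tab),
             stringsAsFactors = FALSE)[order(-as.integer(tab)), ]
}

#' Copy-number profiling from total probe intensity
#'
#' Per probe and case sample, log2 of total intensity (methylated +
#' unmethylated) over the per-probe median of the control samples;
#' running-median smoothing over `window` probes ordered by position;
#' maximal same-sign runs with |smoothed ratio| >= `threshold` become
#' segments, bridging sub-threshold gaps of up to `bridge` probes.
#'
#' @param meth,unmeth probes x samples intensity matrices.
#' @param sample_sheet data.frame with `sample_id` and `group`;
#'   "control" samples form the reference, all others are profiled.
#' @param annotation `ProbeAnnotation` for coordinates.
#' @param window running-median window in probes (default 50; forced odd).
#' @param threshold |log2 ratio| call threshold (default 0.2).
#' @param bridge maximum sub-threshold probes bridged inside a run
#'   (default 2).
#' @param min_probes minimum probes per emitted segment (default 10);
#'   suppresses smoothing edge artifacts at chromosome ends.
#' @return list with `segments` (per-case calls: `sample_id`, `chrom`,
#'   `start`, `end`, `n_probes`, `mean_log2_ratio`, `call`) and
#'   `recurrence` (per distinct segment footprint, the fraction of cases
#'   carrying a call of that sign overlapping it).
#' @export
profile_cna <- function(meth, unmeth, sample_sheet, annotation,
                        window = 50, threshold = 0.2, bridge = 2,
                        min_probes = 10) {
  if (is.null(meth) || is.null(unmeth))
    stop(paste("CNA profiling needs methylated and unmethylated",
               "intensities; beta-only mode is unsupported"), call. = FALSE)
  sheet <- sample_sheet[match(colnames(meth), sample_sheet$sample_id), ]
  ctrl <- sheet$sample_id[sheet$group == "control"]
  cases <- sheet$sample_id[sheet$group != "control"]
  if (length(ctrl) < 3)
    stop("CNA profiling needs at least three control samples", call. = FALSE)
  tot <- meth + unmeth
  ref <- apply(tot[, ctrl, drop = FALSE], 1, stats::median)
  k <- if (window %% 2 == 1) window else window + 1

  idx <- match(rownames(tot), annotation$probe_id)
  ord <- order(annotation$chrom[idx], annotation$pos[idx])
  chrom <- annotation$chrom[idx][ord]
  pos <- annotation$pos[idx][ord]

  seg_rows <- list()
  for (sid in cases) {
    lr <- log2(tot[, sid] / ref)[ord]
    # per-sample median centering: calls depend on ratios only, so a
    # global rescaling of one sample's intensities cannot shift them
    lr <- lr - stats::median(lr)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      x <- lr[sel]
      sm <- if (length(x) >= k) stats::runmed(x, k, endrule = "median")
            else rep(stats::median(x), length(x))
      state <- ifelse(sm >= threshold, 1L, ifelse(sm <= -threshold, -1L, 0L))
      # bridge short sub-threshold gaps flanked by the same sign
      r <- rle(state)
      if (length(r$lengths) > 2) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (j in 2:(length(r$lengths) - 1)) {
          if (r$values[j] == 0L && r$lengths[j] <= bridge &&
              r$values[j - 1] != 0L && r$values[j - 1] == r$values[j + 1])
            state[starts[j]:ends[j]] <- r$values[j - 1]
        }
      }
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$lengths)) {
        if (r$values[j] == 0L || r$lengths[j] < min_probes) next
        run <- starts[j]:ends[j]
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          sample_id = sid, chrom = ch,
          start = pos[sel[run][1]], end = pos[sel[run][length(run)]],
          n_probes = length(run),
          mean_log2_ratio = mean(sm[run]),
          call = if (r$values[j] > 0) "gain" else "loss",
          stringsAsFactors = FALSE)
      }
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), n_probes = integer(),
               mean_log2_ratio = numeric(), call = character(),
               stringsAsFactors = FALSE)

  # recurrence: distinct footprints, fraction of cases with an overlapping
  # same-sign call
  recurrence <- NULL
  if (nrow(segments)) {
    foot <- unique(segments[, c("chrom", "start", "end", "call")])
    frac <- vapply(seq_len(nrow(foot)), function(i) {
      f <- foot[i, ]
      hit <- segments$chrom == f$chrom & segments$call == f$call &
        segments$start <= f$end & segments$end >= f$start
      length(unique(segments$sample_id[hit])) / length(cases)
    }, numeric(1))
    recurrence <- cbind(foot, fraction_cases = frac)
    rownames(recurrence) <- NULL
  }
  list(segments = segments, recurrence = recurrence)
}
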