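# Cross-cohort DMP replication, promoter/body region labels, DMEG direction
# classes, and hypergeometric over-representation analysis.

#' Direction-consistent DMP replication between two cohorts
#'
#' A probe is replicated when it is a DMP in both tables and its delta-beta
#' carries the same sign in both. With `sign_only = TRUE`, DMP status is
#' required only in the discovery table and the replication cohort
#' contributes its sign alone.
#'
#' @param dmp_a discovery `DMPTable`.
#' @param dmp_b replication `DMPTable`.
#' @param sign_only relax the replication-cohort DMP requirement.
#' @return character vector of replicated probe ids.
#' @export
replicate_dmps <- function(dmp_a, dmp_b, sign_only = FALSE) {
  a <- dmp_a[dmp_a$is_dmp, c("probe_id", "delta_beta")]
  b <- if (sign_only) dmp_b[, c("probe_id", "delta_beta", "is_dmp")]
       else dmp_b[dmp_b$is_dmp, c("probe_id", "delta_beta")]
  m <- merge(a, b, by = "probe_id", suffixes = c("_a", "_b"))
  m$probe_id[sign(m$delta_beta_a) == sign(m$delta_beta_b)]
}

#' Promoter/body region label per probe-gene pair
#'
#' Promoter = TSS1500, TSS200 or 1stExon; body = Body; everything else
#' (5'UTR, 3'UTR, IGR) = other. A probe annotated to several genes may be
#' promoter for one and body for another; the annotation's per-row
#' (probe, gene, feature) triplets drive the labels.
#'
#' @param annotation `ProbeAnnotation`.
#' @return data.frame `probe_id`, `gene`, `region` for genic probes.
#' @export
define_promoter_body <- function(annotation) {
  genic <- annotation[annotation$gene != "", c("probe_id", "gene", "feature")]
  genic$region <- ifelse(genic$feature %in% PROMOTER_FEATURES, "promoter",
                         ifelse(genic$feature == "Body", "body", "other"))
  genic[, c("probe_id", "gene", "region")]
}

#' Derive differentially methylated and expressed genes (DMEGs)
#'
#' A DMEG is a differentially expressed gene covered by at least one
#' replicated DMP. Each DMEG gets a direction class from the sign pattern
#' of its promoter/body DMPs and its expression direction:
#' \itemize{
#'   \item "83-type": expression up, >=1 promoter and >=1 body DMP, all
#'     hypomethylated in both regions;
#'   \item "9-type": expression down, all promoter DMPs hypermethylated,
#'     all body DMPs hypomethylated, >=1 of each;
#'   \item "promoter_discordant": >=1 promoter DMP, all promoter signs equal
#'     and opposite to the expression direction;
#'   \item "body_concordant": >=1 body DMP, all body signs equal;
#'   \item otherwise "unclassified" (including mixed signs within a region).
#' }
#' The two headline classes are checked first and are mutually exclusive
#' (opposite expression directions).
#'
#' @param replicated character vector of replicated probe ids.
#' @param dmp_table discovery `DMPTable` (supplies DMP directions).
#' @param deg_table `DEGTable`.
#' @param annotation `ProbeAnnotation`.
#' @return data.frame of class `DMEGTable`: `gene`, `expression_direction`,
#'   `n_promoter_dmps`, `n_body_dmps`, `promoter_directions`,
#'   `body_directions`, `class`, `probes`.
#' @export
derive_dmegs <- function(replicated, dmp_table, deg_table, annotation) {
  degs <- deg_table[deg_table$is_deg, , drop = FALSE]
  regions <- define_promoter_body(annotation)
  rep_regions <- regions[regions$probe_id %in% replicated, , drop = FALSE]
  dir_map <- stats::setNames(dmp_table$direction, dmp_table$probe_id)

  known <- unique(annotation$gene)
  missing <- setdiff(degs$gene, known)
  if (length(missing))
    warning("DEG genes missing from annotation, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...")

  rows <- list()
  for (i in seq_len(nrow(degs))) {
    g <- degs$gene[i]
    if (g %in% missing) next
    pr <- rep_regions[rep_regions$gene == g, , drop = FALSE]
    if (nrow(pr) == 0) next    # DEG without replicated DMP: not a DMEG
    expr_dir <- if (degs$log2fc[i] > 0) "up" else "down"
    pdir <- dir_map[pr$probe_id[pr$region == "promoter"]]
    bdir <- dir_map[pr$probe_id[pr$region == "body"]]
    all_eq <- function(x, v) length(x) > 0 && all(x == v)
    uni <- function(x) length(x) > 0 && length(unique(x)) == 1

    cls <- "unclassified"
    if (expr_dir == "up" && all_eq(pdir, "hypo") && all_eq(bdir, "hypo")) {
      cls <- "83-type"
    } else if (expr_dir == "down" && all_eq(pdir, "hyper") &&
               all_eq(bdir, "hypo")) {
      cls <- "9-type"
    } else if (uni(pdir) &&
               ((expr_dir == "up" && pdir[1] == "hypo") ||
                (expr_dir == "down" && pdir[1] == "hyper"))) {
      cls <- "promoter_discordant"
    } else if (uni(bdir)) {
      cls <- "body_concordant"
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene = g,
      expression_direction = expr_dir,
      n_promoter_dmps = length(pdir),
      n_body_dmps = length(bdir),
      promoter_directions = paste(pdir, collapse = ","),
      body_directions = paste(bdir, collapse = ","),
      class = cls,
      probes = paste(pr$probe_id, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), expression_direction = character(),
               n_promoter_dmps = integer(), n_body_dmps = integer(),
               promoter_directions = character(),
               body_directions = character(), class = character(),
               probes = character(), stringsAsFactors = FALSE)
  class(out) <- c("DMEGTable", "data.frame")
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set: overlap k of the query list (size n) with the set
#' restricted to the universe (size K out of N); upper-tail hypergeometric
#' p = P(X >= k); BH adjustment across sets; significant when q < `fdr`.
#'
#' @param gene_list character vector of query genes (subset of universe;
#'   genes outside the universe are dropped).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe character vector of background genes.
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame: `set`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
ora <- function(gene_list, gene_sets, universe, fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_list <- intersect(unique(gene_list), universe)
  n <- length(gene_list)
  N <- length(universe)
  res <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    K <- length(set)
    k <- length(intersect(gene_list, set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr
  out[order(out$p), ]
}
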