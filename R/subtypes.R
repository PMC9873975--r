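# Methylation-based CLL subgrouping (5-CpG RBF-SVM) and quantification of
# B-cell-differentiation confounding via CpG subtraction.
#
# No SVM library is assumed: a compact deterministic SMO solver for the
# binary soft-margin dual is included, composed one-vs-one for multiclass.

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# deterministic sequential-minimal-optimization for the binary C-SVM dual.
# Second index chosen by maximal |E_i - E_j| (no randomization), so training
# is reproducible. Suited to the small reference panels used here.
.smo_train <- function(K, y, C, tol = 1e-4, max_passes = 50) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fx <- function() drop(K %*% (alpha * y)) + b
  passes <- 0
  while (passes < max_passes) {
    changed <- 0L
    E <- fx() - y
    for (i in seq_len(n)) {
      Ei <- E[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - Ei))
        if (j == i) next
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        E <- fx() - y
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1 else 0
  }
  list(alpha = alpha, b = b)
}

#' Train the 5-CpG RBF-SVM subtype model
#'
#' Multiclass soft-margin classifier with an RBF kernel and one-vs-one
#' decomposition, default hyperparameters C = 10 and gamma = 0.01. The
#' reference panel is any labelled matrix over exactly five feature probes
#' (the published model's five CpGs, or stand-ins for synthetic data).
#'
#' @param reference samples x 5 matrix of beta (or M) values, columns named
#'   by feature probe id, rows by sample.
#' @param labels per-sample subtype labels (>= 2 classes, e.g. n-CLL,
#'   i-CLL, m-CLL).
#' @param C soft-margin cost (default 10).
#' @param gamma RBF width (default 0.01).
#' @return an object of class `SubtypeModel`.
#' @export
train_subtype_model <- function(reference, labels, C = 10, gamma = 0.01) {
  reference <- as.matrix(reference)
  if (ncol(reference) != 5)
    stop("the subtype model uses exactly 5 feature probes", call. = FALSE)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("labels must cover at least two classes", call. = FALSE)
  if (nrow(reference) != length(labels))
    stop("labels must match reference rows", call. = FALSE)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    X <- reference[sel, , drop = FALSE]
    y <- ifelse(labels[sel] == pr[1], 1, -1)
    K <- .rbf_kernel(X, X, gamma)
    fit <- .smo_train(K, y, C)
    list(classes = pr, X = X, y = y, alpha = fit$alpha, b = fit$b)
  })
  structure(list(machines = machines, classes = classes,
                 features = colnames(reference), C = C, gamma = gamma),
            class = "SubtypeModel")
}

#' Classify samples with a trained subtype model
#'
#' One-vs-one voting; ties broken toward the class with the largest total
#' decision margin. Samples with a missing (NaN/NA) feature are skipped
#' with a warning.
#'
#' @param model a `SubtypeModel`.
#' @param beta a [beta_matrix()] or a probes x samples matrix carrying all
#'   five feature probes in its rows.
#' @return named character vector of subtype calls (NA for skipped
#'   samples).
#' @export
classify_subtypes <- function(model, beta) {
  vals <- if (inherits(beta, "BetaMatrix")) beta$values else beta
  missing <- setdiff(model$features, rownames(vals))
  if (length(missing))
    stop("feature probes absent from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- t(vals[model$features, , drop = FALSE])
  bad <- apply(X, 1, function(r) any(!is.finite(r)))
  if (any(bad))
    warning("samples with missing features skipped: ",
            paste(rownames(X)[bad], collapse = ", "))
  calls <- rep(NA_character_, nrow(X))
  names(calls) <- rownames(X)
  if (all(bad)) return(calls)
  Xok <- X[!bad, , drop = FALSE]
  votes <- matrix(0, nrow(Xok), length(model$classes),
                  dimnames = list(rownames(Xok), model$classes))
  margin <- votes
  for (mch in model$machines) {
    K <- .rbf_kernel(Xok, mch$X, model$gamma)
    f <- drop(K %*% (mch$alpha * mch$y)) + mch$b
    win <- ifelse(f >= 0, mch$classes[1], mch$classes[2])
    for (k in seq_along(win)) {
      votes[k, win[k]] <- votes[k, win[k]] + 1
      margin[k, mch$classes[1]] <- margin[k, mch$classes[1]] + f[k]
      margin[k, mch$classes[2]] <- margin[k, mch$classes[2]] - f[k]
    }
  }
  calls[!bad] <- vapply(seq_len(nrow(Xok)), function(k) {
    v <- votes[k, ]
    top <- names(v)[v == max(v)]
    if (length(top) > 1) top <- top[which.max(margin[k, top])]
    top
  }, character(1))
  calls
}

#' Serialize a subtype model as JSON
#' @param model a `SubtypeModel`.
#' @param path output path.
#' @export
write_subtype_model <- function(model, path) {
  obj <- list(classes = model$classes, features = model$features,
              C = model$C, gamma = model$gamma,
              machines = lapply(model$machines, function(m)
                list(classes = m$classes, X = m$X, y = m$y,
                     alpha = m$alpha, b = m$b)))
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a subtype model from JSON
#' @param path JSON path written by [write_subtype_model()].
#' @return a `SubtypeModel`.
#' @export
read_subtype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  machines <- lapply(obj$machines, function(m) {
    X <- do.call(rbind, lapply(m$X, num))
    list(classes = unlist(m$classes), X = X, y = num(m$y),
         alpha = num(m$alpha), b = as.numeric(m$b[[1]]))
  })
  structure(list(machines = machines,
                 classes = unlist(obj$classes),
                 features = unlist(obj$features),
                 C = as.numeric(obj$C[[1]]),
                 gamma = as.numeric(obj$gamma[[1]])),
            class = "SubtypeModel")
}

#' DMPs between two methylation subtypes
#'
#' Runs [fit_dmp()] on the n-CLL vs m-CLL samples (i-CLL excluded), with
#' the same criteria as the case-control analysis, and reports the overlap
#' with a reference DMP set.
#'
#' @param m M-value matrix (CLL samples in columns, or a superset).
#' @param subtype_calls named subtype per sample (as from
#'   [classify_subtypes()]).
#' @param sample_sheet sample sheet for covariates.
#' @param beta optional beta matrix for delta-beta.
#' @param compare the two subtype labels to contrast.
#' @param covariates covariate columns (default age and sex).
#' @param reference_dmps optional probe ids (e.g. the case-control DMPs) to
#'   compute an overlap percentage against.
#' @param ... further arguments to [fit_dmp()].
#' @return list with `dmp_table` and, when reference given,
#'   `overlap_pct` = 100 * |subtype DMPs intersect reference| / |subtype DMPs|
#'   and `reference_overlap_pct` (same numerator over the reference size).
#' @export
subtype_dmps <- function(m, subtype_calls, sample_sheet, beta = NULL,
                         compare = c("n-CLL", "m-CLL"),
                         covariates = c("age", "sex"),
                         reference_dmps = NULL, ...) {
  keep <- names(subtype_calls)[subtype_calls %in% compare]
  sheet <- sample_sheet[match(keep, sample_sheet$sample_id), , drop = FALSE]
  sheet$group <- subtype_calls[keep]
  tab <- fit_dmp(m[, keep, drop = FALSE], sheet,
                 beta = if (is.null(beta)) NULL else
                   beta[, keep, drop = FALSE],
                 groups = compare, covariates = covariates, ...)
  out <- list(dmp_table = tab)
  if (!is.null(reference_dmps)) {
    sub <- tab$probe_id[tab$is_dmp]
    inter <- length(intersect(sub, reference_dmps))
    out$overlap_pct <- if (length(sub)) 100 * inter / length(sub) else 0
    out$reference_overlap_pct <- if (length(reference_dmps))
      100 * inter / length(reference_dmps) else 0
  }
  out
}

#' B-cell-differentiation DMPs (subtype vs mixture union)
#'
#' Four pairwise analyses — each sorted B-cell subtype against the CD19+
#' mixture — with the standard DMP criteria and, by default, no covariates
#' (tiny per-subtype n makes adjustment rank-fragile). The union of the
#' four DMP sets is returned with per-comparison provenance.
#'
#' @param m M-value matrix over mixture + subtype samples.
#' @param sample_sheet sheet whose `group` holds "mixture" and subtype
#'   labels.
#' @param beta optional beta matrix.
#' @param mixture_group label of the mixture group (default "mixture").
#' @param subtype_groups subtype labels to compare (default the four
#'   standard B-cell subtypes).
#' @param covariates covariates (default none).
#' @param ... further arguments to [fit_dmp()].
#' @return list with `union` (probe ids), `by_subtype` (named list of probe
#'   id vectors) and `tables` (the per-comparison `DMPTable`s).
#' @export
bcell_differentiation_dmps <- function(m, sample_sheet, beta = NULL,
                                       mixture_group = "mixture",
                                       subtype_groups = c("NBC", "CD5+NBC",
                                                          "csMBC", "ncsMBC"),
                                       covariates = character(), ...) {
  sheet <- sample_sheet
  if (!any(sheet$group == mixture_group))
    stop("mixture group absent from sample sheet", call. = FALSE)
  by_subtype <- list()
  tables <- list()
  for (sg in intersect(subtype_groups, unique(sheet$group))) {
    n_sg <- sum(sheet$group == sg)
    if (n_sg < 2) {
      warning("subtype ", sg, " has fewer than two samples; skipped")
      next
    }
    keep <- sheet$sample_id[sheet$group %in% c(sg, mixture_group)]
    tab <- fit_dmp(m[, keep, drop = FALSE],
                   sheet[sheet$sample_id %in% keep, , drop = FALSE],
                   beta = if (is.null(beta)) NULL else
                     beta[, keep, drop = FALSE],
                   groups = c(sg, mixture_group),
                   covariates = covariates, ...)
    by_subtype[[sg]] <- tab$probe_id[tab$is_dmp]
    tables[[sg]] <- tab
  }
  list(union = sort(unique(unlist(by_subtype))), by_subtype = by_subtype,
       tables = tables)
}

#' Subtract B-cell-differentiation CpGs and re-screen
#'
#' Removes the B-cell set from the background probe universe, re-runs the
#' case-control DMP analysis on the surviving probes, and (when a DEG table
#' is supplied) re-derives DMEGs restricted to them. Also reports the
#' fraction of the original case-control DMPs that fall in the B-cell set.
#'
#' @param m M-value matrix over the case-control samples (full background).
#' @param sample_sheet case-control sample sheet.
#' @param annotation `ProbeAnnotation`.
#' @param bcell_set probe ids to subtract (must be within the annotated
#'   universe).
#' @param beta optional beta matrix.
#' @param deg_table optional `DEGTable` for the DMEG re-derivation.
#' @param ... further arguments to [fit_dmp()].
#' @return list with `dmp_table` (residual-background run), `specific_dmps`
#'   (probe ids), `bcell_overlap_fraction` (share of original DMPs in the
#'   B-cell set) and, if `deg_table` given, `dmegs`.
#' @export
subtract_and_rescreen <- function(m, sample_sheet, annotation, bcell_set,
                                  beta = NULL, deg_table = NULL, ...) {
  background <- rownames(m)
  if (!all(bcell_set %in% annotation$probe_id))
    stop("bcell set contains probes outside the annotated universe",
         call. = FALSE)
  residual <- setdiff(background, bcell_set)
  if (!length(residual)) stop("empty residual background", call. = FALSE)

  full <- fit_dmp(m, sample_sheet, beta = beta, ...)
  orig_dmps <- full$probe_id[full$is_dmp]
  overlap <- if (length(orig_dmps))
    length(intersect(orig_dmps, bcell_set)) / length(orig_dmps) else 0

  tab <- fit_dmp(m[residual, , drop = FALSE], sample_sheet,
                 beta = if (is.null(beta)) NULL else
                   beta[residual, , drop = FALSE], ...)
  out <- list(dmp_table = tab,
              specific_dmps = tab$probe_id[tab$is_dmp],
              bcell_overlap_fraction = overlap)
  if (!is.null(deg_table))
    out$dmegs <- derive_dmegs(out$specific_dmps, tab, deg_table, annotation)
  out
}
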