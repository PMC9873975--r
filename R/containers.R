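#' Beta-value matrix container
#'
#' Bundles a probes x samples matrix of beta values in \[0, 1\] with optional
#' companion matrices of detection p-values and bead counts sharing the same
#' axes. Row names are probe ids, column names are sample ids; both must be
#' unique.
#'
#' @param values numeric matrix, probes in rows, samples in columns, entries
#'   in \[0, 1\]. Must carry unique row and column names.
#' @param detection_p optional numeric matrix of per-call detection p-values,
#'   same shape and dimnames as `values`.
#' @param bead_count optional integer matrix of per-call bead counts, same
#'   shape and dimnames as `values`.
#' @return an object of class `BetaMatrix` (a list with elements `values`,
#'   `detection_p`, `bead_count`).
#' @export
beta_matrix <- function(values, detection_p = NULL, bead_count = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in beta matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in beta matrix", call. = FALSE)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)
  for (nm in c("detection_p", "bead_count")) {
    comp <- get(nm)
    if (!is.null(comp)) {
      if (!identical(dim(comp), dim(values)))
        stop(sprintf("`%s` must share the shape of `values`", nm), call. = FALSE)
      if (!identical(dimnames(comp), dimnames(values)))
        stop(sprintf("`%s` must share the dimnames of `values`", nm), call. = FALSE)
    }
  }
  structure(list(values = values, detection_p = detection_p,
                 bead_count = bead_count),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  companions: detection_p=%s bead_count=%s\n",
              !is.null(x$detection_p), !is.null(x$bead_count)))
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$values)

# subset a BetaMatrix (and companions) by probe/sample ids or indices
subset_beta <- function(x, probes = NULL, samples = NULL) {
  pick <- function(mat) {
    if (is.null(mat)) return(NULL)
    if (!is.null(probes))  mat <- mat[probes, , drop = FALSE]
    if (!is.null(samples)) mat <- mat[, samples, drop = FALSE]
    mat
  }
  beta_matrix(pick(x$values), pick(x$detection_p), pick(x$bead_count))
}

#' Quality-control report
#'
#' Records which samples and probes were excluded, with a reason code per
#' exclusion. An axis element matching several rules is counted once per
#' matched reason but excluded only once.
#'
#' @param excluded_samples data.frame with columns `sample_id`, `reason`.
#' @param excluded_probes data.frame with columns `probe_id`, `reason`.
#' @param notes optional character vector of free-form notes.
#' @return an object of class `QCReport`.
#' @export
qc_report <- function(excluded_samples = NULL, excluded_probes = NULL,
                      notes = character()) {
  empty_s <- data.frame(sample_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  empty_p <- data.frame(probe_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (is.null(excluded_samples)) excluded_samples <- empty_s
  if (is.null(excluded_probes))  excluded_probes  <- empty_p
  structure(list(excluded_samples = excluded_samples,
                 excluded_probes = excluded_probes,
                 notes = notes),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QCReport\n")
  cat(sprintf("  samples excluded: %d\n",
              length(unique(x$excluded_samples$sample_id))))
  if (nrow(x$excluded_samples))
    print(table(x$excluded_samples$reason))
  cat(sprintf("  probes excluded: %d\n",
              length(unique(x$excluded_probes$probe_id))))
  if (nrow(x$excluded_probes))
    print(table(x$excluded_probes$reason))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Counts of exclusions per reason
#'
#' @param report a `QCReport`.
#' @return named integer vector of per-reason counts (samples and probes
#'   pooled; names are reason codes).
#' @export
qc_counts <- function(report) {
  stopifnot(inherits(report, "QCReport"))
  c(table(c(report$excluded_samples$reason, report$excluded_probes$reason)))
}

merge_qc <- function(a, b) {
  qc_report(rbind(a$excluded_samples, b$excluded_samples),
            rbind(a$excluded_probes, b$excluded_probes),
            c(a$notes, b$notes))
}
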