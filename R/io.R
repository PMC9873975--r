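#' Read a TSV matrix (probes or genes in rows, samples in columns)
#'
#' The dialect is tab-separated UTF-8 with an id column first and one column
#' per sample; lines starting with `#` are treated as comments and skipped.
#'
#' @param path file path.
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write a matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_col name for the id column (default "id").
#' @param comments optional character vector written as leading `#` lines
#'   (e.g. `"seed=7"`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", comments = character()) {
  writeLines(c(if (length(comments)) paste0("# ", comments),
               paste(c(id_col, colnames(m)), collapse = "\t")), path)
  dt <- data.table::data.table(id = rownames(m), m)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a TSV table (annotation, sample sheet, result tables)
#'
#' @param path file path; `#`-prefixed lines are skipped.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = lines, sep = "\t", header = TRUE,
                    data.table = FALSE)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @param comments optional `#` comment lines.
#' @export
write_table_tsv <- function(df, path, comments = character()) {
  writeLines(c(if (length(comments)) paste0("# ", comments),
               paste(names(df), collapse = "\t")), path)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write regions as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; BED output converts with
#' `start - 1`, `end`.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
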