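# Spectral-count matrix container: protein groups x samples, with group
# labels, per-sample raw totals and the scaling state.

#' Construct a spectral-count matrix
#'
#' @param values Non-negative protein-group x sample matrix (raw integer
#'   counts, or reals after scaling).
#' @param sample_groups Optional factor (or vector) of length `ncol(values)`
#'   assigning each sample to one of two groups (tissue vs reference).
#' @param scaled Whether columns have been scaled to the average total.
#' @param library_sizes Per-sample raw totals; defaults to column sums.
#' @return An `spc_matrix` object.
#' @export
spc_matrix <- function(values, sample_groups = NULL, scaled = FALSE,
                       library_sizes = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("spectral counts must be non-negative")
  if (!is.null(sample_groups)) {
    if (length(sample_groups) != ncol(values))
      stop("'sample_groups' must label every sample column")
    sample_groups <- as.factor(sample_groups)
    names(sample_groups) <- colnames(values)
  }
  if (is.null(library_sizes)) library_sizes <- colSums(values)
  structure(list(values = values, sample_groups = sample_groups,
                 scaled = scaled, library_sizes = library_sizes),
            class = "spc_matrix")
}

#' @export
dim.spc_matrix <- function(x) dim(x$values)

#' @export
print.spc_matrix <- function(x, ...) {
  cat(sprintf("spc_matrix: %d protein groups x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "scaled" else "raw"))
  if (!is.null(x$sample_groups))
    cat("groups:", paste(sprintf("%s=%d", levels(x$sample_groups),
                                 tabulate(x$sample_groups)),
                         collapse = ", "), "\n")
  invisible(x)
}

# Accept either a bare matrix or an spc_matrix in the statistics layer.
count_values <- function(x) {
  if (inherits(x, "spc_matrix")) x$values else as.matrix(x)
}

count_groups <- function(x, groups = NULL) {
  if (is.null(groups) && inherits(x, "spc_matrix")) groups <- x$sample_groups
  if (is.null(groups)) stop("sample groups are required")
  as.factor(groups)
}

#' Write a count matrix as TSV (first column the group id)
#'
#' @param x An `spc_matrix` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  v <- count_values(x)
  df <- data.frame(group_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV path.
#' @param sample_groups Optional group labels for the sample columns.
#' @param scaled Scaling state of the stored values.
#' @return An `spc_matrix`.
#' @export
read_count_matrix <- function(path, sample_groups = NULL, scaled = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  spc_matrix(v, sample_groups = sample_groups, scaled = scaled)
}
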