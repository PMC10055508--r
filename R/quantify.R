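# Spectral-count quantification: per-group tallies under the razor policy,
# scaling to the average total count per sample, and the abundance filter.

#' Tally spectral counts per protein group per sample
#'
#' Each accepted PSM contributes one count to the group its peptide is
#' razor-assigned to.  PSMs whose peptide maps to no surviving group are
#' dropped with a message.  Decoy and contaminant groups are excluded by
#' default so the quantitative matrix holds biological entries only.
#'
#' @param accepted_psms Filtered PSM table.
#' @param groups A `protein_groups` object.
#' @param sample_groups Optional group labels for the sample columns.
#' @param include_decoys,include_contaminants Keep decoy / contaminant
#'   group rows.
#' @return A raw [spc_matrix()].
#' @export
tally_spc <- function(accepted_psms, groups, sample_groups = NULL,
                      include_decoys = FALSE, include_contaminants = FALSE) {
  razor <- attr(groups, "razor")
  keys <- peptide_key(accepted_psms$peptide, accepted_psms$mod_state)
  gid <- razor[keys]
  dropped <- sum(is.na(gid))
  if (dropped > 0)
    message(dropped, " PSM(s) on peptides outside surviving groups ",
            "were not counted")

  samples <- attr(groups, "samples")
  if (is.null(samples)) samples <- sort(unique(accepted_psms$sample_id))
  ids <- names(groups)
  tab <- table(factor(gid, levels = ids),
               factor(accepted_psms$sample_id, levels = samples))
  vals <- matrix(as.integer(tab), nrow = length(ids),
                 dimnames = list(ids, samples))

  keep <- rep(TRUE, length(ids))
  if (!include_decoys)
    keep <- keep & !vapply(groups, `[[`, TRUE, "is_decoy")
  if (!include_contaminants)
    keep <- keep & !vapply(groups, `[[`, TRUE, "is_contaminant")
  spc_matrix(vals[keep, , drop = FALSE], sample_groups = sample_groups)
}

#' Scale each sample to the average total spectral count
#'
#' Every column is multiplied by (grand mean of column totals) / (its own
#' total), so all scaled column totals equal the average raw total.
#' Applying the operation to an already scaled matrix is a no-op (the
#' totals are already equal).
#'
#' @param x A raw `spc_matrix`.
#' @return The scaled `spc_matrix` (values become reals).
#' @export
scale_to_average_total <- function(x) {
  stopifnot(inherits(x, "spc_matrix"))
  if (x$scaled) return(x)
  totals <- colSums(x$values)
  if (any(totals == 0))
    stop("cannot scale: sample(s) with zero total counts: ",
         paste(colnames(x$values)[totals == 0], collapse = ", "))
  target <- mean(totals)
  out <- x
  out$values <- sweep(x$values, 2, target / totals, `*`)
  out$scaled <- TRUE
  out$library_sizes <- totals
  out
}

#' Filter protein groups by mean scaled abundance
#'
#' Retains rows whose mean across all samples (both groups pooled) is
#' strictly greater than `min_avg` spectral counts.
#'
#' @param x A scaled `spc_matrix`.
#' @param min_avg Minimum average spectral count (exclusive).
#' @return The retained subset of `x`.
#' @export
abundance_filter <- function(x, min_avg = 2.5) {
  stopifnot(inherits(x, "spc_matrix"))
  keep <- rowMeans(x$values) > min_avg
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}
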