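# PSM error control: discriminant scoring, conditional target/decoy score
# histograms, and per-subclass threshold search for an experiment-wide FDR.

subclass_key <- function(charge, mod_state, delta_mass_bin) {
  paste(charge, mod_state, delta_mass_bin, sep = "/")
}

#' Compute a discriminant score as a weighted combination of raw scores
#'
#' The combination is a configurable linear form over (optionally
#' log-transformed) search-engine scores; the conventional default for
#' Comet-style output is `ln(xcorr) + 4 * deltacn`.  Synthetic tables
#' carry a single ready-made `disc` column, which the default selects
#' unchanged.
#'
#' @param psms PSM data frame.
#' @param weights Named numeric vector; names must be score columns.
#' @param log_transform Score names to natural-log before weighting.
#' @return Numeric vector, one discriminant per PSM.
#' @export
discriminant_score <- function(psms, weights = c(disc = 1),
                               log_transform = character(0)) {
  missing <- setdiff(names(weights), names(psms))
  if (length(missing))
    stop("missing score column(s): ", paste(missing, collapse = ", "))
  out <- numeric(nrow(psms))
  for (nm in names(weights)) {
    v <- psms[[nm]]
    if (nm %in% log_transform) v <- log(v)
    out <- out + weights[[nm]] * v
  }
  out
}

#' Add the discriminant column to a PSM table
#'
#' @inheritParams discriminant_score
#' @return The PSM table with a `discriminant` column.
#' @export
add_discriminant <- function(psms, weights = c(disc = 1),
                             log_transform = character(0)) {
  psms$discriminant <- discriminant_score(psms, weights, log_transform)
  psms
}

#' Target/decoy FDR of the set accepted at a score threshold
#'
#' Estimated as (decoys at or above `t`) / (targets at or above `t`),
#' capped at 1.  With no targets above `t` the estimate is undefined and
#' a classed error (`spcenrich_undefined_fdr`) is signaled.
#'
#' @param psms PSM data frame with `discriminant` and `is_decoy` columns.
#' @param t Score threshold.
#' @return Estimated FDR in \[0, 1\].
#' @export
fdr_at_threshold <- function(psms, t) {
  if (is.null(psms$discriminant))
    stop("PSM table lacks a 'discriminant' column; see add_discriminant()")
  above <- psms$discriminant >= t
  n_target <- sum(above & !psms$is_decoy)
  n_decoy <- sum(above & psms$is_decoy)
  if (n_target == 0L)
    stop(errorCondition(
      "no target PSMs at or above threshold; FDR undefined",
      class = "spcenrich_undefined_fdr"))
  min(1, n_decoy / n_target)
}

#' Build conditional target/decoy score histograms
#'
#' PSMs are grouped into (charge, modification state, delta-mass window)
#' subclasses and binned on the discriminant with a common bin grid.
#' Subclasses with fewer than `min_decoys` decoy PSMs are flagged to fall
#' back to the pooled histogram during threshold search, because their
#' conditional FDR estimates are unstable.
#'
#' @param psms PSM table with `discriminant`, `is_decoy`, `charge`,
#'   `mod_state`, `delta_mass_bin`.
#' @param bin_width Histogram bin width in discriminant units.
#' @param min_decoys Minimum decoy count for a subclass to stand alone.
#' @return A `score_histograms` object.
#' @export
build_score_histograms <- function(psms, bin_width = 0.1, min_decoys = 50L) {
  if (is.null(psms$discriminant))
    stop("PSM table lacks a 'discriminant' column; see add_discriminant()")
  if (nrow(psms) == 0L) stop("empty PSM table")
  d <- psms$discriminant
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= max(d)) hi <- hi + bin_width
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L

  bin_of <- function(x) pmin(pmax(findInterval(x, edges), 1L), nb)
  tab <- function(rows) {
    tgt <- tabulate(bin_of(d[rows & !psms$is_decoy]), nbins = nb)
    dec <- tabulate(bin_of(d[rows & psms$is_decoy]), nbins = nb)
    list(target_counts = tgt, decoy_counts = dec)
  }

  key <- subclass_key(psms$charge, psms$mod_state, psms$delta_mass_bin)
  keys <- sort(unique(key))
  subclasses <- lapply(keys, function(k) {
    h <- tab(key == k)
    c(list(subclass = k, bin_edges = edges), h,
      list(fallback = sum(h$decoy_counts) < min_decoys))
  })
  names(subclasses) <- keys
  pooled <- c(list(subclass = "pooled", bin_edges = edges),
              tab(rep(TRUE, nrow(psms))), list(fallback = FALSE))
  structure(list(subclasses = subclasses, pooled = pooled,
                 bin_edges = edges, bin_width = bin_width,
                 min_decoys = min_decoys),
            class = "score_histograms")
}

# Counts at or above each bin's lower edge (accepting discriminant >= edge).
cum_from_top <- function(counts) rev(cumsum(rev(counts)))

#' FDR as a function of threshold for one histogram pair
#'
#' Raw estimates (decoy/target at or above each bin edge, capped at 1)
#' are monotonized q-value style: the reported `fdr` at threshold t is
#' the smallest raw estimate achieved at any threshold <= t, so it is
#' non-increasing as t increases.
#'
#' @param hist One histogram pair from [build_score_histograms()] (an
#'   element of `$subclasses`, or `$pooled`).
#' @return Data frame with `threshold`, `fdr_raw`, `fdr`.
#' @export
fdr_curve <- function(hist) {
  t_cum <- cum_from_top(hist$target_counts)
  d_cum <- cum_from_top(hist$decoy_counts)
  raw <- ifelse(t_cum > 0, pmin(1, d_cum / t_cum), 1)
  data.frame(threshold = hist$bin_edges[-length(hist$bin_edges)],
             fdr_raw = raw, fdr = cummin(raw))
}

#' Search per-subclass score thresholds for an experiment-wide FDR
#'
#' Each subclass is first set to the smallest threshold whose
#' (monotonized) conditional FDR is at or below `target_fdr`; subclasses
#' flagged as decoy-sparse take their initial threshold from the pooled
#' curve.  Because every subclass then satisfies the bound, so does the
#' pooled accepted set.  A greedy relaxation follows: thresholds are
#' lowered one bin at a time, always taking the move that adds the most
#' target PSMs while keeping the pooled estimated FDR at or below
#' `target_fdr` (ties resolved toward the first subclass in sorted key
#' order), until no move qualifies.
#'
#' @param histograms A `score_histograms` object.
#' @param target_fdr Experiment-wide FDR target in (0, 1).
#' @return Named numeric vector of per-subclass thresholds (`Inf` means
#'   the subclass accepts nothing), with a `pooled` entry for unseen
#'   subclasses and attributes `pooled_fdr`, `accepted_targets`,
#'   `accepted_decoys`.
#' @export
threshold_search <- function(histograms, target_fdr = 0.01) {
  if (target_fdr <= 0 || target_fdr >= 1)
    stop("'target_fdr' must lie in (0, 1)")
  subs <- histograms$subclasses
  keys <- names(subs)
  edges <- histograms$bin_edges
  m <- length(edges) - 1L

  t_cum <- lapply(subs, function(h) c(cum_from_top(h$target_counts), 0))
  d_cum <- lapply(subs, function(h) c(cum_from_top(h$decoy_counts), 0))

  # Most permissive qualifying threshold: maximize accepted targets; on
  # ties (edges adding only decoys) take the highest edge.
  init_index <- function(curve_hist) {
    cv <- fdr_curve(curve_hist)
    tc <- cum_from_top(curve_hist$target_counts)
    ok <- which(cv$fdr <= target_fdr & tc > 0)
    if (!length(ok)) return(m + 1L)
    max(ok[tc[ok] == max(tc[ok])])
  }
  idx <- vapply(keys, function(k) {
    h <- subs[[k]]
    if (h$fallback) init_index(histograms$pooled) else init_index(h)
  }, integer(1))

  pooled_t <- sum(vapply(keys, function(k) t_cum[[k]][idx[k]], 0))
  pooled_d <- sum(vapply(keys, function(k) d_cum[[k]][idx[k]], 0))

  repeat {
    best <- NULL
    best_gain <- 0
    for (k in keys) {
      i <- idx[k]
      if (i <= 1L) next
      gain_t <- t_cum[[k]][i - 1L] - t_cum[[k]][i]
      gain_d <- d_cum[[k]][i - 1L] - d_cum[[k]][i]
      new_t <- pooled_t + gain_t
      new_d <- pooled_d + gain_d
      if (new_t > 0 && new_d / new_t <= target_fdr && gain_t > best_gain) {
        best <- k
        best_gain <- gain_t
      }
    }
    if (is.null(best)) break
    idx[best] <- idx[best] - 1L
    pooled_t <- sum(vapply(keys, function(k) t_cum[[k]][idx[k]], 0))
    pooled_d <- sum(vapply(keys, function(k) d_cum[[k]][idx[k]], 0))
  }

  thr <- vapply(keys, function(k)
    if (idx[k] > m) Inf else edges[idx[k]], 0)
  pooled_idx <- init_index(histograms$pooled)
  thr <- c(thr, pooled = if (pooled_idx > m) Inf else edges[pooled_idx])
  attr(thr, "pooled_fdr") <- if (pooled_t > 0) pooled_d / pooled_t else 0
  attr(thr, "accepted_targets") <- pooled_t
  attr(thr, "accepted_decoys") <- pooled_d
  attr(thr, "fallback") <- vapply(subs, `[[`, TRUE, "fallback")
  thr
}

#' Filter PSMs by per-subclass thresholds and minimum peptide length
#'
#' Accepts PSMs whose discriminant reaches their subclass threshold and
#' whose peptide is at least `min_length` residues.  Decoy PSMs passing
#' the thresholds are retained so that downstream protein-level FDR can
#' be estimated.
#'
#' @param psms PSM table with a `discriminant` column.
#' @param thresholds Named vector from [threshold_search()].
#' @param min_length Minimum peptide length (residues).
#' @return The accepted subset of `psms`.
#' @export
filter_psms <- function(psms, thresholds, min_length = 7L) {
  if (nrow(psms) == 0L) return(psms)
  if (is.null(psms$discriminant))
    stop("PSM table lacks a 'discriminant' column; see add_discriminant()")
  key <- subclass_key(psms$charge, psms$mod_state, psms$delta_mass_bin)
  thr <- thresholds[key]
  unseen <- is.na(thr)
  if (any(unseen)) {
    if (!"pooled" %in% names(thresholds))
      stop("thresholds do not cover all subclasses present")
    thr[unseen] <- thresholds[["pooled"]]
  }
  keep <- psms$discriminant >= thr & nchar(psms$peptide) >= min_length
  psms[keep, , drop = FALSE]
}

#' One-call PSM filtering to a target experiment-wide FDR
#'
#' Adds the discriminant, builds conditional histograms, searches
#' per-subclass thresholds and filters, returning the accepted set plus
#' the thresholds used.
#'
#' @inheritParams discriminant_score
#' @inheritParams build_score_histograms
#' @inheritParams threshold_search
#' @inheritParams filter_psms
#' @return List with `accepted` (PSM table), `thresholds`, `histograms`.
#' @export
filter_psms_fdr <- function(psms, target_fdr = 0.01, min_length = 7L,
                            weights = c(disc = 1),
                            log_transform = character(0),
                            bin_width = 0.1, min_decoys = 50L) {
  psms <- add_discriminant(psms, weights, log_transform)
  hists <- build_score_histograms(psms, bin_width, min_decoys)
  thr <- threshold_search(hists, target_fdr)
  list(accepted = filter_psms(psms, thr, min_length),
       thresholds = thr, histograms = hists)
}

#' Write / read the tab-delimited PSM table
#'
#' Header columns: `sample_id`, `scan_id`, `charge`, `peptide`,
#' `mod_state`, `delta_mass_bin`, raw score columns (e.g. `disc`),
#' `is_decoy`, `accessions` (semicolon-joined), and optionally
#' `discriminant`.
#'
#' @param psms PSM data frame.
#' @param path File path.
#' @return `path` (write) or the PSM data frame (read).
#' @export
write_psm_table <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write the per-subclass threshold report
#'
#' @param thresholds Vector from [threshold_search()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  fb <- attr(thresholds, "fallback")
  df <- data.frame(subclass = names(thresholds),
                   threshold = as.numeric(thresholds),
                   pooled_fallback = as.logical(fb[names(thresholds)]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
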