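# Differential enrichment statistics: TMM normalization, qCML common
# dispersion, the conditional negative-binomial exact test, BH adjustment,
# fold changes and the enrichment call with confidence bands.

#' TMM normalization factors
#'
#' Per-sample scaling factors from a doubly trimmed, precision-weighted
#' mean of library-size-adjusted log2 count ratios (M values) against a
#' reference sample, using only rows positive in both samples.  The top
#' and bottom `trim_m` of M values and `trim_a` of A values are trimmed;
#' the weighted mean uses inverse asymptotic (delta-method) variances.
#' Factors are renormalized to geometric mean 1.  The automatic reference
#' is the sample whose upper-quartile-normalized value is closest to the
#' mean across samples.
#'
#' @param counts An `spc_matrix` or count matrix (raw scale).
#' @param trim_m Fraction of M values trimmed from each tail.
#' @param trim_a Fraction of A values trimmed from each tail.
#' @param ref Reference sample (column name or index); `NULL` for
#'   automatic selection.
#' @return A `norm_factors` object: `factors` (geometric mean 1), `ref`,
#'   `lib_sizes`, `effective_lib_sizes` (= library size x factor).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  y <- count_values(counts)
  lib <- colSums(y)
  if (any(lib <= 0)) stop("library sizes must be positive")
  nsamp <- ncol(y)

  f75 <- vapply(seq_len(nsamp), function(j)
    quantile(y[, j], 0.75, names = FALSE) / lib[j], 0)
  if (is.null(ref)) {
    ref_j <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_j <- if (is.character(ref)) match(ref, colnames(y)) else as.integer(ref)
    if (is.na(ref_j) || ref_j < 1 || ref_j > nsamp)
      stop("unknown reference sample")
  }

  fac <- vapply(seq_len(nsamp), function(j) {
    if (j == ref_j) return(1)
    one_tmm_factor(y[, j], y[, ref_j], lib[j], lib[ref_j], trim_m, trim_a,
                   colnames(y)[j])
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(y)
  structure(list(factors = fac,
                 ref = if (!is.null(colnames(y))) colnames(y)[ref_j] else ref_j,
                 lib_sizes = lib,
                 effective_lib_sizes = lib * fac),
            class = "norm_factors")
}

one_tmm_factor <- function(obs, refv, n_o, n_r, trim_m, trim_a, label) {
  pos <- obs > 0 & refv > 0
  if (!any(pos)) {
    warning("sample ", label, " shares no positive rows with the ",
            "reference; factor set to 1")
    return(1)
  }
  o <- obs[pos] / n_o
  r <- refv[pos] / n_r
  m <- log2(o / r)
  a <- (log2(o) + log2(r)) / 2
  v <- (n_o - obs[pos]) / (n_o * obs[pos]) +
    (n_r - refv[pos]) / (n_r * refv[pos])
  if (max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_l <- floor(n * trim_m) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(m) >= lo_l & rank(m) <= hi_l &
    rank(a) >= lo_s & rank(a) <= hi_s
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

# Pseudo-counts at equal effective library sizes: a mean-preserving linear
# rescaling of each column to the geometric-mean effective library size.
pseudo_counts <- function(y, norm) {
  eff <- colSums(y) * norm$factors
  geo <- exp(mean(log(eff)))
  sweep(y, 2, geo / eff, `*`)
}

# Conditional NB log-likelihood given per-group totals (qCML), summed
# over genes and groups.  n = 1 groups contribute exactly zero.
cond_loglik <- function(y, groups, phi) {
  r <- 1 / phi
  total <- 0
  for (lev in levels(groups)) {
    sub <- y[, groups == lev, drop = FALSE]
    n <- ncol(sub)
    if (n < 2L) next
    z <- rowSums(sub)
    ll <- rowSums(lgamma(sub + r)) - n * lgamma(r) -
      rowSums(lgamma(sub + 1)) +
      lgamma(n * r) + lgamma(z + 1) - lgamma(z + n * r)
    total <- total + sum(ll)
  }
  total
}

#' qCML common dispersion estimate
#'
#' Maximizes the negative-binomial log-likelihood conditional on
#' per-group totals, computed on pseudo-counts rescaled to equal
#' effective library sizes, by bounded one-dimensional search on the log
#' scale.  Returns 0 when the likelihood is maximized at the Poisson
#' boundary.
#'
#' @param counts An `spc_matrix` or count matrix.
#' @param groups Sample group factor (defaults to the matrix's labels).
#' @param norm Optional `norm_factors`; computed by [tmm_factors()] when
#'   absent.
#' @return A `dispersion_estimate`: `common` (phi >= 0) and the maximized
#'   log-likelihood.
#' @export
common_dispersion <- function(counts, groups = NULL, norm = NULL) {
  y <- count_values(counts)
  groups <- count_groups(counts, groups)
  if (all(y == 0)) stop("all-zero count matrix")
  if (max(tabulate(groups)) < 2L)
    stop("at least one group needs two or more samples")
  if (is.null(norm)) norm <- tmm_factors(counts)
  pseudo <- pseudo_counts(y, norm)
  pseudo <- pseudo[rowSums(pseudo) > 0, , drop = FALSE]

  negll <- function(logphi) -cond_loglik(pseudo, groups, exp(logphi))
  lo <- log(1e-8)
  opt <- optimize(negll, interval = c(lo, log(5)), tol = 1e-5)
  phi <- exp(opt$minimum)
  if (negll(lo) <= opt$objective + 1e-8) phi <- 0
  structure(list(common = phi, logLik = -opt$objective),
            class = "dispersion_estimate")
}

# Two-sided conditional NB exact p for one gene: group sums a, b from
# nA and nB samples at common dispersion phi (phi = 0: binomial).
exact_nb_p <- function(a, b, n_a, n_b, phi,
                       rejection = c("smallp", "doubletail")) {
  rejection <- match.arg(rejection)
  total <- a + b
  if (total == 0) return(1)
  x <- 0:total
  if (phi == 0) {
    pr <- dbinom(x, total, n_a / (n_a + n_b))
  } else {
    s_a <- n_a / phi
    s_b <- n_b / phi
    lp <- lgamma(x + s_a) - lgamma(x + 1) +
      lgamma(total - x + s_b) - lgamma(total - x + 1)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
  }
  p_obs <- pr[a + 1]
  p <- switch(rejection,
    smallp = sum(pr[pr <= p_obs * (1 + 1e-10)]),
    doubletail = 2 * min(sum(pr[x <= a]), sum(pr[x >= a])))
  min(1, p)
}

#' Conditional negative-binomial exact test
#'
#' For each protein, group sums of (rounded) pseudo-counts at equal
#' effective library sizes are compared under the NB model with common
#' dispersion `phi`, conditional on the two-group total.  The default
#' two-sided p sums the probabilities of all outcomes no more probable
#' than the observed one; the tail-doubling variant is available as a
#' flag.  `phi = 0` reduces to the binomial exact test.
#'
#' @param counts An `spc_matrix` or count matrix.
#' @param groups Sample group factor with exactly two levels.
#' @param dispersion Common NB dispersion phi (>= 0), or a
#'   `dispersion_estimate`.
#' @param norm Optional `norm_factors` (computed when absent).
#' @param rejection Two-sided rule: `"smallp"` (default) or
#'   `"doubletail"`.
#' @return Numeric vector of p-values, one per protein row.
#' @export
exact_test <- function(counts, groups = NULL, dispersion = 0.1, norm = NULL,
                       rejection = c("smallp", "doubletail")) {
  rejection <- match.arg(rejection)
  y <- count_values(counts)
  groups <- count_groups(counts, groups)
  if (nlevels(groups) != 2L)
    stop("exactly two sample groups are required")
  if (inherits(dispersion, "dispersion_estimate"))
    dispersion <- dispersion$common
  if (dispersion < 0) stop("'dispersion' must be non-negative")
  if (is.null(norm)) norm <- tmm_factors(counts)

  pseudo <- pseudo_counts(y, norm)
  in_a <- groups == levels(groups)[1]
  a <- round(rowSums(pseudo[, in_a, drop = FALSE]))
  b <- round(rowSums(pseudo[, !in_a, drop = FALSE]))
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  p <- vapply(seq_along(a), function(i)
    exact_nb_p(a[i], b[i], n_a, n_b, dispersion, rejection), 0)
  names(p) <- rownames(y)
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with cumulative-minimum
#' monotonization, capped at 1 (via [stats::p.adjust()]).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted FDR values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Log2 fold change and average log expression (MA coordinates)
#'
#' Group means are computed on pseudo-counts at equal effective library
#' sizes and augmented with a small prior count, so zero rows stay
#' finite.  M = log2(mean A / mean B); A = mean of the two log2 group
#' means.
#'
#' @param counts An `spc_matrix` or count matrix (scaled or raw).
#' @param groups Two-level sample group factor.
#' @param norm Optional `norm_factors` (computed when absent).
#' @param prior Prior count added to each group mean.
#' @return Data frame: `mean_A`, `mean_B`, `log2fc`, `avg_log_expr`.
#' @export
log_fold_change <- function(counts, groups = NULL, norm = NULL,
                            prior = 0.125) {
  y <- count_values(counts)
  groups <- count_groups(counts, groups)
  if (nlevels(groups) != 2L)
    stop("exactly two sample groups are required")
  if (is.null(norm)) norm <- tmm_factors(counts)
  pseudo <- pseudo_counts(y, norm)
  in_a <- groups == levels(groups)[1]
  m_a <- rowMeans(pseudo[, in_a, drop = FALSE])
  m_b <- rowMeans(pseudo[, !in_a, drop = FALSE])
  data.frame(mean_A = m_a, mean_B = m_b,
             log2fc = log2((m_a + prior) / (m_b + prior)),
             avg_log_expr = (log2(m_a + prior) + log2(m_b + prior)) / 2,
             row.names = rownames(y))
}

#' Assign FDR confidence bands and the enrichment call
#'
#' Bands follow the MA-plot classification: `high` (FDR below the first
#' cut, default 0.01), `medium`, `low`, `none`.  A protein is called
#' enriched when its band is `high` and its fold change toward group A
#' is at least `fc_min` (log2fc >= log2(fc_min)).
#'
#' @param records Data frame with `fdr` and `log2fc` columns.
#' @param fc_min Minimum fold change for the enriched call.
#' @param bands Named increasing FDR cutpoints for high/medium/low.
#' @return `records` with `band` (ordered factor) and `enriched` added.
#' @export
call_enrichment <- function(records, fc_min = 2,
                            bands = c(high = 0.01, medium = 0.05,
                                      low = 0.1)) {
  stopifnot(all(c("fdr", "log2fc") %in% names(records)))
  band <- cut(records$fdr, breaks = c(-Inf, bands, Inf),
              labels = c(names(bands), "none"), right = FALSE)
  records$band <- factor(band, levels = c(names(bands), "none"),
                         ordered = TRUE)
  records$enriched <- records$band == "high" &
    records$log2fc >= log2(fc_min)
  records
}

#' Full enrichment test on a filtered count matrix
#'
#' Runs TMM normalization, common-dispersion estimation (unless a value
#' is supplied), the exact test, BH adjustment, fold-change computation
#' and the enrichment call, returning one record per protein group.
#'
#' @param counts A (scaled, abundance-filtered) `spc_matrix` or matrix.
#' @param groups Two-level sample group factor.
#' @param dispersion Common dispersion; `NULL` to estimate.
#' @param fc_min,bands Passed to [call_enrichment()].
#' @param prior Passed to [log_fold_change()].
#' @param rejection Passed to [exact_test()].
#' @return An `enrichment_result` data frame: `group_id`, group means,
#'   `avg_spc`, `log2fc`, `avg_log_expr`, `p`, `fdr`, `band`,
#'   `enriched`; the normalization factors and dispersion are attached
#'   as attributes `norm` and `dispersion`.
#' @export
wb_enrich <- function(counts, groups = NULL, dispersion = NULL, fc_min = 2,
                      bands = c(high = 0.01, medium = 0.05, low = 0.1),
                      prior = 0.125, rejection = "smallp") {
  y <- count_values(counts)
  groups <- count_groups(counts, groups)
  norm <- tmm_factors(counts)
  if (is.null(dispersion))
    dispersion <- common_dispersion(counts, groups, norm)
  phi <- if (inherits(dispersion, "dispersion_estimate"))
    dispersion$common else dispersion

  p <- exact_test(counts, groups, phi, norm, rejection)
  fc <- log_fold_change(counts, groups, norm, prior)
  records <- data.frame(
    group_id = rownames(y), fc,
    avg_spc = rowMeans(pseudo_counts(y, norm)),
    p = unname(p), fdr = unname(bh_adjust(p)),
    stringsAsFactors = FALSE, row.names = NULL)
  records <- call_enrichment(records, fc_min, bands)
  attr(records, "norm") <- norm
  attr(records, "dispersion") <- phi
  class(records) <- c("enrichment_result", "data.frame")
  records
}

#' In silico reference-subtraction pipeline on a raw count matrix
#'
#' Applies the quantitative workflow to a raw spectral-count matrix:
#' scaling to the average total count per sample, the mean-abundance
#' filter, and the full enrichment test.
#'
#' @param counts A raw `spc_matrix` with `sample_groups` set.
#' @param min_avg Mean scaled-count filter (exclusive).
#' @param ... Passed to [wb_enrich()].
#' @return List: `records` (the `enrichment_result`), `counts_filtered`
#'   (the scaled filtered matrix).
#' @export
run_wb_subtraction <- function(counts, min_avg = 2.5, ...) {
  scaled <- scale_to_average_total(counts)
  filtered <- abundance_filter(scaled, min_avg)
  records <- wb_enrich(filtered, ...)
  list(records = records, counts_filtered = filtered)
}

#' Write the enrichment results table as TSV
#'
#' @param records An `enrichment_result` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
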