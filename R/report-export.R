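# QC summaries, ranked candidate tables, MA-plot data, and UCSC-style
# custom heat-map track export.

#' Quality-control summary of a normalized count matrix
#'
#' Computes per-sample totals, five-number summaries of the log2
#' normalized counts (boxplot statistics), the pairwise Pearson
#' correlation matrix of the logged matrix, and 2-D classical
#' multidimensional scaling of leading-log-fold-change distances (the
#' root-mean-square of the `top` largest absolute log2 ratios between
#' each sample pair).
#'
#' @param counts An `spc_matrix` or count matrix with >= 2 samples.
#' @param norm Optional `norm_factors` (computed when absent).
#' @param prior Prior count added before logging.
#' @param top Number of top rows entering each pairwise distance.
#' @return A `qc_summary` list: `totals`, `box_stats` (5 x samples),
#'   `cor`, `mds` (samples x 2).
#' @export
qc_summary <- function(counts, norm = NULL, prior = 0.125, top = 500L) {
  y <- count_values(counts)
  if (ncol(y) < 2L) stop("at least two samples are required")
  if (is.null(norm)) norm <- tmm_factors(counts)
  logmat <- log2(pseudo_counts(y, norm) + prior)

  nsamp <- ncol(y)
  dd <- matrix(0, nsamp, nsamp, dimnames = list(colnames(y), colnames(y)))
  topn <- min(top, nrow(y))
  for (i in seq_len(nsamp - 1)) for (j in (i + 1):nsamp) {
    sq <- sort((logmat[, i] - logmat[, j])^2, decreasing = TRUE)[seq_len(topn)]
    dd[i, j] <- dd[j, i] <- sqrt(mean(sq))
  }
  k <- min(2L, nsamp - 1L)
  mds <- cmdscale(dd, k = k)
  if (k < 2L) mds <- cbind(mds, 0)
  colnames(mds) <- c("dim1", "dim2")

  structure(list(totals = colSums(y),
                 box_stats = apply(logmat, 2, fivenum),
                 cor = cor(logmat),
                 mds = mds),
            class = "qc_summary")
}

#' Rank candidates by expression or by enrichment
#'
#' `mode = "expressed"` sorts all records by descending average
#' normalized spectral count (absolute abundance).  `mode = "enriched"`
#' keeps records flagged enriched and sorts by descending log2 fold
#' change, ties broken by ascending FDR -- the ordering under which the
#' strongest reference-subtraction candidates top the table.
#'
#' @param records An `enrichment_result` data frame.
#' @param mode `"enriched"` or `"expressed"`.
#' @param top_n Rows returned.
#' @return The ranked head of the table with a `rank` column.
#' @export
rank_table <- function(records, mode = c("enriched", "expressed"),
                       top_n = 30L) {
  mode <- match.arg(mode)
  out <- if (mode == "expressed") {
    records[order(-records$avg_spc, records$group_id), , drop = FALSE]
  } else {
    sub <- records[records$enriched, , drop = FALSE]
    sub[order(-sub$log2fc, sub$fdr, sub$group_id), , drop = FALSE]
  }
  out <- head(out, top_n)
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' MA-plot coordinates with confidence bands
#'
#' @param records An `enrichment_result` data frame.
#' @return Data frame: `group_id`, `A` (average log expression), `M`
#'   (log2 fold change), `band`.
#' @export
ma_data <- function(records) {
  data.frame(group_id = records$group_id,
             A = records$avg_log_expr,
             M = records$log2fc,
             band = records$band,
             stringsAsFactors = FALSE)
}

#' Read a BED file (3-9 columns)
#'
#' Minimal validating reader: track/browser/comment lines are skipped,
#' every data line must have at least chrom/start/end with numeric
#' 0-based half-open coordinates, and a malformed line is rejected with
#' its line number.
#'
#' @param path BED file path.
#' @return Data frame: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `thick_start`, `thick_end`, `item_rgb` (missing columns
#'   are `NA`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("line ", i, ": expected at least 3 tab-separated fields")
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end))
      stop("line ", i, ": non-numeric start/end")
    if (start >= end)
      stop("line ", i, ": start must be < end (0-based half-open)")
    k <- k + 1L
    out[[k]] <- data.frame(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5]))
              else NA_real_,
      strand = if (length(f) >= 6) f[6] else NA_character_,
      thick_start = if (length(f) >= 7) suppressWarnings(as.numeric(f[7]))
                    else NA_real_,
      thick_end = if (length(f) >= 8) suppressWarnings(as.numeric(f[8]))
                  else NA_real_,
      item_rgb = if (length(f) >= 9) f[9] else NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out[seq_len(k)])
}

# Ordered heat-map palette, low to high, as itemRgb strings.
default_track_palette <- function(bins) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  rgb <- round(ramp(seq(0, 1, length.out = bins)))
  apply(rgb, 1, paste, collapse = ",")
}

#' Export a UCSC custom heat-map track (BED9 with itemRgb)
#'
#' Each record with gene coordinates becomes one BED9 line; the item
#' color encodes the quantile bin of the chosen score (average
#' normalized spectral count for `"expression"`, log2 fold change for
#' `"enrichment"`) among the exported records, using an ordered palette.
#' Records without coordinates are skipped with a message.
#'
#' @param records An `enrichment_result` data frame.
#' @param gene_coords BED data frame from [read_bed()] (or a path);
#'   `name` must carry the group id.
#' @param path Output file path.
#' @param score `"expression"` or `"enrichment"`.
#' @param bins Number of quantile color classes.
#' @param palette Optional vector of `bins` itemRgb strings, low to high.
#' @param track_name Track name in the definition line.
#' @return The exported data frame (one row per written record),
#'   invisibly.
#' @export
export_tracks <- function(records, gene_coords, path,
                          score = c("expression", "enrichment"),
                          bins = 8L, palette = NULL,
                          track_name = NULL) {
  score <- match.arg(score)
  if (is.character(gene_coords) && length(gene_coords) == 1L)
    gene_coords <- read_bed(gene_coords)
  if (is.null(palette)) palette <- default_track_palette(bins)
  if (length(palette) != bins)
    stop("'palette' must supply one color per bin")
  if (is.null(track_name))
    track_name <- paste0("proteome_", score)

  hit <- match(records$group_id, gene_coords$name)
  skipped <- sum(is.na(hit))
  if (skipped > 0)
    message(skipped, " record(s) without gene coordinates were skipped")
  rec <- records[!is.na(hit), , drop = FALSE]
  coords <- gene_coords[hit[!is.na(hit)], , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records with gene coordinates to export")

  s <- if (score == "expression") rec$avg_spc else rec$log2fc
  qs <- quantile(s, probs = seq(0, 1, length.out = bins + 1), names = FALSE)
  breaks <- unique(qs)
  if (length(breaks) < 2L) {
    cls <- rep(1L, length(s))                 # degenerate: one color class
  } else {
    cls <- as.integer(cut(s, breaks = breaks, include.lowest = TRUE))
    nb <- length(breaks) - 1L
    if (nb < bins && nb > 1L)                 # ties collapsed some bins:
      cls <- as.integer(round((cls - 1L) / (nb - 1L) * (bins - 1L))) + 1L
  }

  bed_score <- if (diff(range(s)) == 0) rep(0L, length(s)) else
    as.integer(round(1000 * (s - min(s)) / diff(range(s))))
  body <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%d\t%d\t%s",
                  coords$chrom, as.integer(coords$start),
                  as.integer(coords$end), rec$group_id, bed_score,
                  as.integer(coords$start), as.integer(coords$end),
                  palette[cls])
  header <- sprintf('track name="%s" description="%s" itemRgb="On"',
                    track_name,
                    if (score == "expression")
                      "protein expression (avg normalized SpC)"
                    else "protein enriched-expression (log2 fold change)")
  writeLines(c(header, body), path)

  invisible(data.frame(chrom = coords$chrom, start = coords$start,
                       end = coords$end, group_id = rec$group_id,
                       score = s, color_class = cls,
                       item_rgb = palette[cls], stringsAsFactors = FALSE))
}
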