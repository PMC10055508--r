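# Synthetic databases, PSM tables and spectral-count matrices with known
# ground truth, so each downstream stage can be validated without raw MS data.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DECOY_PREFIX <- "REV_"
CONTAMINANT_PREFIX <- "CON"

random_sequences <- function(n, length_range) {
  if (n == 0L) return(character(0))
  lens <- sample(seq.int(length_range[1], length_range[2]), n, replace = TRUE)
  chars <- sample(AMINO_ACIDS, sum(lens), replace = TRUE)
  idx <- factor(rep.int(seq_len(n), lens), levels = seq_len(n))
  vapply(split(chars, idx), paste0, collapse = "", FUN.VALUE = character(1),
         USE.NAMES = FALSE)
}

reverse_sequences <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverse(Biostrings::AAStringSet(x)))
}

#' Build a concatenated target + contaminant + reversed-decoy database
#'
#' Generates random amino-acid sequences for targets and contaminants and
#' appends one whole-sequence-reversed decoy per forward entry, so the
#' final database holds exactly twice as many entries as the forward set.
#' Decoy accessions carry the reserved `REV_` prefix.
#'
#' @param n_targets Number of target protein sequences.
#' @param n_contaminants Number of common-contaminant sequences.
#' @param length_range Integer interval of sequence lengths to draw from.
#' @param seed Optional integer seed; fixes the output completely.
#' @return A `sequence_db` data frame with columns `accession`,
#'   `sequence`, `category` (one of target/contaminant/decoy).
#' @examples
#' db <- make_database(5, 1, length_range = c(30, 60), seed = 1)
#' nrow(db)  # 12: every forward entry has a reversed decoy
#' @export
make_database <- function(n_targets, n_contaminants = 0L,
                          length_range = c(60L, 600L), seed = NULL) {
  if (n_targets < 0 || n_contaminants < 0)
    stop("'n_targets' and 'n_contaminants' must be non-negative")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 1)
    stop("'length_range' must be an increasing positive integer interval")
  if (!is.null(seed)) set.seed(seed)

  n_fwd <- n_targets + n_contaminants
  acc <- c(if (n_targets > 0) sprintf("TGT%05d", seq_len(n_targets)),
           if (n_contaminants > 0)
             sprintf("%s%04d", CONTAMINANT_PREFIX, seq_len(n_contaminants)))
  seqs <- random_sequences(n_fwd, length_range)
  db <- data.frame(
    accession = c(acc, if (n_fwd > 0) paste0(DECOY_PREFIX, acc)),
    sequence = c(seqs, reverse_sequences(seqs)),
    category = c(rep("target", n_targets),
                 rep("contaminant", n_contaminants),
                 rep("decoy", n_fwd)),
    stringsAsFactors = FALSE
  )
  class(db) <- c("sequence_db", "data.frame")
  db
}

#' Write a sequence database as wrapped FASTA
#'
#' @param db A `sequence_db` data frame (see [make_database()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  x <- Biostrings::AAStringSet(setNames(db$sequence, db$accession))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTA database written by [write_fasta()]
#'
#' Categories are recovered from the reserved accession prefixes
#' (`REV_` for decoys, `CON` for contaminants).
#'
#' @param path FASTA file path.
#' @return A `sequence_db` data frame.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  acc <- names(x)
  category <- ifelse(startsWith(acc, DECOY_PREFIX), "decoy",
                     ifelse(startsWith(acc, CONTAMINANT_PREFIX),
                            "contaminant", "target"))
  db <- data.frame(accession = acc, sequence = as.character(x),
                   category = category, stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("sequence_db", "data.frame")
  db
}

random_peptides <- function(n, p_short = 0) {
  if (n == 0L) return(character(0))
  short <- runif(n) < p_short
  lens <- integer(n)
  lens[short] <- sample(5:6, sum(short), replace = TRUE)
  lens[!short] <- sample(7:25, sum(!short), replace = TRUE)
  chars <- sample(AMINO_ACIDS, sum(lens), replace = TRUE)
  idx <- factor(rep.int(seq_len(n), lens), levels = seq_len(n))
  vapply(split(chars, idx), paste0, collapse = "", FUN.VALUE = character(1),
         USE.NAMES = FALSE)
}

# Assign peptide sets to target proteins, planting shared-peptide structure:
# identical-set pairs, strict-subset pairs, and homolog families sharing a
# stated fraction of their peptides.
build_peptide_incidence <- function(targets, peptides_per_protein,
                                    identical_pairs, subset_pairs,
                                    homolog_families, homolog_share,
                                    p_short) {
  npro <- length(targets)
  k <- peptides_per_protein
  need <- 2L * (identical_pairs + subset_pairs + homolog_families)
  if (npro < need)
    stop("database has too few target proteins for the requested families")

  pep_sets <- vector("list", npro)
  i <- 1L
  for (f in seq_len(identical_pairs)) {
    a <- random_peptides(k, p_short)
    pep_sets[[i]] <- a; pep_sets[[i + 1L]] <- a
    i <- i + 2L
  }
  for (f in seq_len(subset_pairs)) {
    a <- random_peptides(k, p_short)
    pep_sets[[i]] <- a
    pep_sets[[i + 1L]] <- a[seq_len(max(1L, k %/% 2L))]
    i <- i + 2L
  }
  for (f in seq_len(homolog_families)) {
    nshared <- max(1L, round(homolog_share * k))
    shared <- random_peptides(nshared, p_short)
    pep_sets[[i]] <- c(shared, random_peptides(k - nshared, p_short))
    pep_sets[[i + 1L]] <- c(shared, random_peptides(k - nshared, p_short))
    i <- i + 2L
  }
  while (i <= npro) {
    pep_sets[[i]] <- random_peptides(k, p_short)
    i <- i + 1L
  }
  pairs <- data.frame(
    peptide = unlist(pep_sets),
    accession = rep(targets, lengths(pep_sets)),
    stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)
  split(pairs$accession, pairs$peptide)
}

#' Simulate a peptide-spectrum-match table with known truth flags
#'
#' Emulates the score stream a database search produces: each spectrum is
#' either a correct match to a database peptide (discriminant drawn from a
#' shifted Gaussian) or an incorrect match landing on a random target or
#' decoy entry (both drawn from the same null Gaussian, the premise of
#' target/decoy FDR estimation).  Subclass structure (charge 2-4,
#' unmodified/oxidized, 0/1-Da delta-mass windows) is generated so that
#' conditional score histograms are exercised, and the target-protein
#' peptide map contains configurable shared-peptide families.
#'
#' @param db A `sequence_db` (see [make_database()]).
#' @param n_spectra Number of spectra (PSMs) to simulate.
#' @param p_correct Fraction of spectra that are correct identifications.
#' @param score_params List with `mu_correct`, `sd_correct`, `mu_null`,
#'   `sd_null` and a named `charge_shift` vector added to both
#'   distributions within a charge subclass.
#' @param samples Sample identifiers spectra are spread across.
#' @param peptides_per_protein Peptides assigned to each target protein.
#' @param identical_pairs,subset_pairs,homolog_families Numbers of planted
#'   shared-peptide protein families.
#' @param homolog_share Fraction of a homolog's peptides shared with its
#'   family partner.
#' @param p_short Fraction of generated peptides shorter than 7 residues
#'   (exercises the minimum-length rule).
#' @param seed Optional integer seed.
#' @return A `psm_simulation` list: `psms` (the PSM table, one row per
#'   spectrum), `truth` (per-PSM correct/incorrect flags and the seed),
#'   and `incidence` (the peptide-to-protein map used).
#' @export
simulate_psms <- function(db, n_spectra, p_correct = 0.9,
                          score_params = list(
                            mu_correct = 3, sd_correct = 1,
                            mu_null = 0, sd_null = 1,
                            charge_shift = c(`2` = 0, `3` = 0.3, `4` = 0.5)),
                          samples = paste0("S", 1:5),
                          peptides_per_protein = 10L,
                          identical_pairs = 2L, subset_pairs = 2L,
                          homolog_families = 2L, homolog_share = 0.9,
                          p_short = 0.03, seed = NULL) {
  if (p_correct < 0 || p_correct > 1)
    stop("'p_correct' must lie in [0, 1]")
  targets <- db$accession[db$category != "decoy"]
  decoys <- db$accession[db$category == "decoy"]
  if (n_spectra > 0 && (length(targets) == 0L || length(decoys) == 0L))
    stop("database must contain target and decoy entries")
  if (!is.null(seed)) set.seed(seed)

  incidence <- build_peptide_incidence(
    targets, peptides_per_protein, identical_pairs, subset_pairs,
    homolog_families, homolog_share, p_short)
  target_peps <- names(incidence)

  n <- n_spectra
  correct <- runif(n) < p_correct
  charge <- sample(c(2L, 3L, 4L), n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  mod_state <- sample(c("unmodified", "oxidized"), n, replace = TRUE,
                      prob = c(0.8, 0.2))
  dmass <- integer(n)
  dmass[correct] <- sample(c(0L, 1L), sum(correct), replace = TRUE,
                           prob = c(0.9, 0.1))
  dmass[!correct] <- sample(c(0L, 1L), sum(!correct), replace = TRUE)

  peptide <- character(n)
  accessions <- character(n)
  is_decoy <- logical(n)

  ci <- which(correct)
  if (length(ci)) {
    peptide[ci] <- sample(target_peps, length(ci), replace = TRUE)
    accessions[ci] <- vapply(incidence[peptide[ci]], paste, collapse = ";",
                             FUN.VALUE = character(1))
  }
  wi <- which(!correct)
  if (length(wi)) {
    p_dec <- length(decoys) / (length(decoys) + length(targets))
    hit_decoy <- runif(length(wi)) < p_dec
    peptide[wi] <- random_peptides(length(wi), p_short)
    accessions[wi] <- ifelse(hit_decoy,
                             sample(decoys, length(wi), replace = TRUE),
                             sample(targets, length(wi), replace = TRUE))
    is_decoy[wi] <- hit_decoy
  }

  shift <- score_params$charge_shift[as.character(charge)]
  shift[is.na(shift)] <- 0
  mu <- ifelse(correct, score_params$mu_correct, score_params$mu_null) + shift
  sdv <- ifelse(correct, score_params$sd_correct, score_params$sd_null)
  disc <- rnorm(n, mean = mu, sd = sdv)

  psms <- data.frame(
    sample_id = if (n) sample(samples, n, replace = TRUE) else character(0),
    scan_id = sprintf("sc%06d", seq_len(n)),
    charge = charge,
    peptide = peptide,
    mod_state = mod_state,
    delta_mass_bin = dmass,
    disc = disc,
    is_decoy = is_decoy,
    accessions = accessions,
    stringsAsFactors = FALSE
  )
  structure(list(psms = psms,
                 truth = list(psm_truth = data.frame(
                   scan_id = psms$scan_id, correct = correct,
                   stringsAsFactors = FALSE), seed = seed),
                 incidence = incidence),
            class = "psm_simulation")
}

#' Simulate a spectral-count matrix with a planted enriched subset
#'
#' Per-protein baseline means are drawn from a right-skewed lognormal
#' (defaults reproduce roughly 35K total counts per sample in the
#' reference group across ~2,700 quantifiable proteins, the scale of a
#' deep embryonic-tissue run).  Counts are negative-binomial with shared
#' dispersion `phi` (var = mu + phi * mu^2; `phi = 0` gives Poisson).
#' Planted proteins keep their baseline mean in group B (the reference
#' body) and are elevated in group A: group-A mean = 2^log2fc x group-B
#' mean, the tissue-enrichment structure the pipeline is meant to
#' recover.
#'
#' @param n_proteins Number of protein rows.
#' @param n_per_group Biological replicates per group (two groups).
#' @param n_enriched Number of planted enriched proteins.
#' @param log2fc True log2 fold change of planted proteins (group A over
#'   group B).
#' @param dispersion NB dispersion phi (>= 0).
#' @param libsizes Relative per-sample depth multipliers (length 1 or
#'   `2 * n_per_group`).
#' @param base_meanlog,base_sdlog Lognormal parameters of baseline means.
#' @param base_min Lower truncation of baseline means (draws below it are
#'   resampled).  The default matches the quantitative workflow's
#'   abundance filter: the simulated rows stand for the proteins that
#'   entered the differential analysis, all of which passed that filter.
#'   Set to 0 for an untruncated abundance distribution.
#' @param group_labels Labels for group A (tissue) and group B (reference).
#' @param seed Optional integer seed.
#' @return A list: `counts` (an [spc_matrix()] with `sample_groups` set),
#'   `truth` (per-protein enriched flag and true log2 fold change), and
#'   the seed.
#' @export
simulate_counts <- function(n_proteins, n_per_group = 5L, n_enriched = 0L,
                            log2fc = 1.5, dispersion = 0.05, libsizes = 1,
                            base_meanlog = log(8), base_sdlog = 1,
                            base_min = 2.5,
                            group_labels = c("tissue", "reference"),
                            seed = NULL) {
  if (n_enriched > n_proteins)
    stop("'n_enriched' must not exceed 'n_proteins'")
  if (dispersion < 0)
    stop("'dispersion' must be non-negative")
  if (any(libsizes <= 0))
    stop("'libsizes' must be positive")
  if (!is.null(seed)) set.seed(seed)

  n_samp <- 2L * n_per_group
  lib <- rep_len(libsizes, n_samp)
  base <- rlnorm(n_proteins, base_meanlog, base_sdlog)
  while (any(low <- base < base_min))
    base[low] <- rlnorm(sum(low), base_meanlog, base_sdlog)
  enriched_idx <- sort(sample.int(n_proteins, n_enriched))
  mu_a <- base
  mu_b <- base
  mu_a[enriched_idx] <- base[enriched_idx] * 2^log2fc

  mu <- cbind(matrix(mu_a, n_proteins, n_per_group),
              matrix(mu_b, n_proteins, n_per_group))
  mu <- sweep(mu, 2, lib, `*`)
  vals <- if (dispersion == 0) {
    matrix(rpois(length(mu), lambda = mu), n_proteins, n_samp)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_proteins, n_samp)
  }
  rownames(vals) <- sprintf("P%05d", seq_len(n_proteins))
  colnames(vals) <- paste(rep(group_labels, each = n_per_group),
                          rep(seq_len(n_per_group), 2L), sep = "_")
  groups <- factor(rep(group_labels, each = n_per_group),
                   levels = group_labels)
  names(groups) <- colnames(vals)

  truth <- data.frame(
    protein = rownames(vals),
    enriched = seq_len(n_proteins) %in% enriched_idx,
    true_log2fc = ifelse(seq_len(n_proteins) %in% enriched_idx, log2fc, 0),
    stringsAsFactors = FALSE
  )
  list(counts = spc_matrix(vals, sample_groups = groups, scaled = FALSE),
       truth = truth, seed = seed)
}
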