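# Shared fixture builders and independent oracles.

# A minimal PSM table with full control over the filtering-relevant fields.
toy_psms <- function(disc, is_decoy = rep(FALSE, length(disc)),
                     peptide = NULL, charge = 2L,
                     mod_state = "unmodified", delta_mass_bin = 0L,
                     sample_id = "S1", accessions = "TGT00001") {
  n <- length(disc)
  if (is.null(peptide))
    peptide <- sprintf("PEPTIDEK%03d", seq_len(n))
  data.frame(sample_id = rep_len(sample_id, n),
             scan_id = sprintf("sc%04d", seq_len(n)),
             charge = rep_len(charge, n),
             peptide = rep_len(peptide, n),
             mod_state = rep_len(mod_state, n),
             delta_mass_bin = rep_len(delta_mass_bin, n),
             disc = disc,
             discriminant = disc,
             is_decoy = rep_len(is_decoy, n),
             accessions = rep_len(accessions, n),
             stringsAsFactors = FALSE)
}

# An accepted-PSM table realizing a given peptide -> accessions incidence,
# with `spc` PSMs per peptide per sample.
psms_from_incidence <- function(incidence, samples = "S1", spc = 1L) {
  rows <- list()
  for (pep in names(incidence)) for (s in samples) for (r in seq_len(spc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, scan_id = "",
      charge = 2L, peptide = pep, mod_state = "unmodified",
      delta_mass_bin = 0L, disc = 5, discriminant = 5,
      is_decoy = all(startsWith(incidence[[pep]], "REV_")),
      accessions = paste(incidence[[pep]], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$scan_id <- sprintf("sc%05d", seq_len(nrow(out)))
  out
}

# A sequence_db covering the accessions an incidence refers to.
db_for <- function(incidence) {
  acc <- sort(unique(unlist(incidence)))
  data.frame(accession = acc,
             sequence = strrep("ACDEFGHIK", 5),
             category = ifelse(startsWith(acc, "REV_"), "decoy",
                               ifelse(startsWith(acc, "CON"),
                                      "contaminant", "target")),
             stringsAsFactors = FALSE)
}

# Exhaustive minimum set cover cardinality over the distinct peptide sets.
min_cover_oracle <- function(sets) {
  sets <- unique(lapply(sets, function(s) sort(unique(s))))
  universe <- sort(unique(unlist(sets)))
  n <- length(sets)
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      if (setequal(unlist(sets[combs[, j]]), universe)) return(k)
    }
  }
  stop("no cover found")
}

# Conditional two-sided exact-test p by direct enumeration of the joint
# NB (or Poisson) law of the two group sums given their total.
exact_p_oracle <- function(a, b, n_a, n_b, phi, mu = 3) {
  total <- a + b
  if (total == 0) return(1)
  x <- 0:total
  if (phi == 0) {
    joint <- dpois(x, n_a * mu) * dpois(total - x, n_b * mu)
  } else {
    joint <- dnbinom(x, size = n_a / phi, mu = n_a * mu) *
      dnbinom(total - x, size = n_b / phi, mu = n_b * mu)
  }
  pr <- joint / sum(joint)
  p_obs <- pr[a + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# Reference BH step-up computation, written out longhand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
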