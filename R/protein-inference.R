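# Parsimony protein inference: peptide-protein incidence, minimal-cover
# group selection, extended grouping of insufficiently distinguished
# homologs, the two-distinct-peptide rule, and decoy-based protein FDR.

peptide_key <- function(peptide, mod_state) paste(peptide, mod_state, sep = "|")

#' Build the peptide-protein incidence map from accepted PSMs
#'
#' A distinct peptide is a unique (sequence, modification state) pair.
#' The map records which accessions each distinct peptide matches and the
#' per-sample PSM counts per peptide.
#'
#' @param accepted_psms Filtered PSM table (see [filter_psms()]).
#' @param db The `sequence_db` searched; every PSM accession must exist.
#' @return A `peptide_protein_map`: `incidence` (peptide key ->
#'   accession vector), `peptide_spc` (peptide x sample PSM counts),
#'   `categories` (accession -> target/contaminant/decoy).
#' @export
build_map <- function(accepted_psms, db) {
  acc_lists <- strsplit(accepted_psms$accessions, ";", fixed = TRUE)
  all_acc <- unique(unlist(acc_lists))
  unknown <- setdiff(all_acc, db$accession)
  if (length(unknown))
    stop("unknown accession(s): ", paste(head(unknown, 5), collapse = ", "))

  keys <- peptide_key(accepted_psms$peptide, accepted_psms$mod_state)
  if (nrow(accepted_psms) == 0L) {
    return(structure(list(
      incidence = list(),
      peptide_spc = matrix(0L, 0, 0),
      categories = setNames(db$category, db$accession)),
      class = "peptide_protein_map"))
  }
  pairs <- unique(data.frame(
    peptide = rep(keys, lengths(acc_lists)),
    accession = unlist(acc_lists),
    stringsAsFactors = FALSE))
  incidence <- split(pairs$accession, pairs$peptide)

  samples <- sort(unique(accepted_psms$sample_id))
  spc <- table(factor(keys, levels = names(incidence)),
               factor(accepted_psms$sample_id, levels = samples))
  spc <- matrix(as.integer(spc), nrow = length(incidence),
                dimnames = list(names(incidence), samples))

  structure(list(incidence = incidence, peptide_spc = spc,
                 categories = setNames(db$category, db$accession)),
            class = "peptide_protein_map")
}

# --- internal: deterministic minimal set cover ------------------------------

# Union-find over n items.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# Greedy cover over candidate peptide sets (list of integer vectors),
# candidates pre-sorted; returns indices of selected candidates.
greedy_cover <- function(pep_sets, n_pep) {
  uncovered <- rep(TRUE, n_pep)
  chosen <- integer(0)
  while (any(uncovered)) {
    gains <- vapply(pep_sets, function(p) sum(uncovered[p]), 0L)
    best <- which.max(gains)           # first max: pre-sorted tie order
    if (gains[best] == 0L) break       # unreachable if map is consistent
    chosen <- c(chosen, best)
    uncovered[pep_sets[[best]]] <- FALSE
  }
  sort(chosen)
}

# Exact minimum cover by size-ordered enumeration, bounded by the greedy
# solution; falls back to greedy when enumeration would be too large.
min_cover <- function(pep_sets, n_pep, max_groups = 20L, max_enum = 5e4) {
  g <- greedy_cover(pep_sets, n_pep)
  n <- length(pep_sets)
  if (n > max_groups) return(g)
  for (k in seq_len(length(g) - 1L)) {
    if (choose(n, k) > max_enum) return(g)
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      if (length(unique(unlist(pep_sets[sel]))) == n_pep)
        return(sort(sel))
    }
  }
  g
}

# Connected components of the group-peptide bipartite graph, via
# union-find over groups joined through shared peptides.
components_of <- function(pep_sets, n_pep) {
  parent <- uf_new(length(pep_sets))
  owner <- integer(n_pep)              # first group seen per peptide
  for (i in seq_along(pep_sets)) {
    for (p in pep_sets[[i]]) {
      if (owner[p] == 0L) owner[p] <- i
      else parent <- uf_union(parent, owner[p], i)
    }
  }
  roots <- vapply(seq_along(pep_sets), function(i) uf_find(parent, i), 0L)
  split(seq_along(pep_sets), roots)
}

# Recompute per-group derived fields (flags, uniqueness, razor assignment,
# per-sample distinct-peptide tallies) from the member/peptide sets.
finalize_groups <- function(members_list, pep_idx_list, pep_keys,
                            presence, categories) {
  ord <- order(-lengths(pep_idx_list),
               vapply(members_list, function(m) sort(m)[1], ""))
  members_list <- members_list[ord]
  pep_idx_list <- pep_idx_list[ord]
  n <- length(members_list)
  ids <- sprintf("G%05d", seq_len(n))

  pep_count <- integer(length(pep_keys))
  for (p in pep_idx_list) pep_count[p] <- pep_count[p] + 1L
  n_unique <- vapply(pep_idx_list, function(p) sum(pep_count[p] == 1L), 0L)

  first_acc <- vapply(members_list, function(m) sort(m)[1], "")
  razor <- rep(NA_character_, length(pep_keys))
  holders <- vector("list", length(pep_keys))
  for (i in seq_len(n)) for (p in pep_idx_list[[i]])
    holders[[p]] <- c(holders[[p]], i)
  for (p in which(lengths(holders) > 0)) {
    h <- holders[[p]]
    best <- h[order(-n_unique[h], first_acc[h])][1]
    razor[p] <- ids[best]
  }
  names(razor) <- pep_keys

  groups <- lapply(seq_len(n), function(i) {
    m <- sort(members_list[[i]])
    cats <- categories[m]
    dps <- if (ncol(presence)) colSums(presence[pep_idx_list[[i]], ,
                                                drop = FALSE] > 0)
           else integer(0)
    list(id = ids[i], members = m,
         peptides = sort(pep_keys[pep_idx_list[[i]]]),
         peptide_idx = pep_idx_list[[i]],
         n_unique = n_unique[i],
         distinct_per_sample = dps,
         is_decoy = all(cats == "decoy"),
         is_contaminant = any(cats == "contaminant") &&
           !any(cats == "target"))
  })
  names(groups) <- ids
  structure(groups, class = "protein_groups",
            samples = colnames(presence), peptide_keys = pep_keys,
            presence = presence, categories = categories,
            razor = razor[!is.na(razor)])
}

#' Infer protein groups by parsimony
#'
#' Accessions with identical peptide sets are merged into one group of
#' indistinguishable proteins; a minimum set of groups explaining every
#' peptide is then selected.  The incidence graph is split into connected
#' components and each small component is solved exactly for the minimum
#' cover (size-ordered enumeration bounded by the greedy solution), with
#' greedy selection as the fallback for large components -- so reported
#' group counts match exhaustive set-cover search wherever that search is
#' feasible.  Peptides shared between surviving groups are razor-assigned
#' to the group with more unique distinct peptides (ties broken
#' lexicographically by first accession).
#'
#' @param map A `peptide_protein_map` from [build_map()].
#' @param exact_max_groups Largest component (in candidate groups) still
#'   solved by exact enumeration.
#' @return A `protein_groups` object (list of groups with members,
#'   peptide sets, per-sample distinct-peptide tallies, decoy and
#'   contaminant flags, and a razor assignment attribute).
#' @export
parsimony_infer <- function(map, exact_max_groups = 20L) {
  if (length(map$incidence) == 0L) stop("empty peptide-protein map")
  pep_keys <- names(map$incidence)
  pep_index <- setNames(seq_along(pep_keys), pep_keys)

  prot_peps <- split(
    rep(unname(pep_index), lengths(map$incidence)),
    unlist(map$incidence))
  prot_peps <- lapply(prot_peps, function(p) sort(unique(p)))

  sig <- vapply(prot_peps, paste, collapse = ",", FUN.VALUE = "")
  merged <- split(names(prot_peps), sig)
  members_list <- lapply(merged, sort)
  pep_idx_list <- lapply(merged, function(m) prot_peps[[m[1]]])

  ord <- order(-lengths(pep_idx_list),
               vapply(members_list, function(m) sort(m)[1], ""))
  members_list <- members_list[ord]
  pep_idx_list <- pep_idx_list[ord]

  comps <- components_of(pep_idx_list, length(pep_keys))
  selected <- integer(0)
  for (comp in comps) {
    local_peps <- sort(unique(unlist(pep_idx_list[comp])))
    remap <- setNames(seq_along(local_peps), local_peps)
    local_sets <- lapply(pep_idx_list[comp],
                         function(p) unname(remap[as.character(p)]))
    sel <- min_cover(local_sets, length(local_peps),
                     max_groups = exact_max_groups)
    selected <- c(selected, comp[sel])
  }
  selected <- sort(selected)

  finalize_groups(members_list[selected], pep_idx_list[selected],
                  pep_keys, map$peptide_spc, map$categories)
}

#' @export
`[.protein_groups` <- function(x, i) {
  out <- unclass(x)[i]
  for (a in c("samples", "peptide_keys", "presence", "categories", "razor"))
    attr(out, a) <- attr(x, a)
  class(out) <- "protein_groups"
  out
}

#' Merge insufficiently distinguished homologous groups
#'
#' Two groups are merged when each shares at least `share_min` of its own
#' peptide set with the other and each has at most `unique_max` peptides
#' the other lacks; merging is applied transitively (families close under
#' the pairwise rule).
#'
#' @param groups A `protein_groups` object from [parsimony_infer()].
#' @param share_min Minimum shared fraction of each group's peptide set.
#' @param unique_max Maximum peptides a group may hold that its partner
#'   lacks.
#' @return A `protein_groups` object with families merged.
#' @export
extended_group <- function(groups, share_min = 0.9, unique_max = 1L) {
  n <- length(groups)
  if (n <= 1L) return(groups)
  pep_idx <- lapply(groups, `[[`, "peptide_idx")

  holders <- list()
  for (i in seq_len(n)) for (p in pep_idx[[i]]) {
    key <- as.character(p)
    holders[[key]] <- c(holders[[key]], i)
  }
  cand <- unique(do.call(rbind, c(list(matrix(0L, 0, 2)), lapply(
    holders[lengths(holders) > 1],
    function(h) t(utils::combn(sort(h), 2L))))))

  parent <- uf_new(n)
  if (nrow(cand)) for (r in seq_len(nrow(cand))) {
    a <- pep_idx[[cand[r, 1]]]
    b <- pep_idx[[cand[r, 2]]]
    shared <- length(intersect(a, b))
    if (shared / length(a) >= share_min &&
        shared / length(b) >= share_min &&
        length(setdiff(a, b)) <= unique_max &&
        length(setdiff(b, a)) <= unique_max)
      parent <- uf_union(parent, cand[r, 1], cand[r, 2])
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  fams <- split(seq_len(n), roots)

  members_list <- lapply(fams, function(f)
    sort(unique(unlist(lapply(groups[f], `[[`, "members")))))
  pep_idx_list <- lapply(fams, function(f)
    sort(unique(unlist(pep_idx[f]))))
  finalize_groups(members_list, pep_idx_list,
                  attr(groups, "peptide_keys"), attr(groups, "presence"),
                  attr(groups, "categories"))
}

#' Keep groups with two distinct peptides in at least one sample
#'
#' @param groups A `protein_groups` object.
#' @return The retained subset, with razor assignments recomputed.
#' @export
two_peptide_filter <- function(groups) {
  keep <- vapply(groups, function(g)
    length(g$distinct_per_sample) > 0 && max(g$distinct_per_sample) >= 2L,
    TRUE)
  finalize_groups(lapply(groups[keep], `[[`, "members"),
                  lapply(groups[keep], `[[`, "peptide_idx"),
                  attr(groups, "peptide_keys"), attr(groups, "presence"),
                  attr(groups, "categories"))
}

#' Decoy-based protein FDR (percent)
#'
#' Returns 100 x (decoy groups) / (non-decoy groups), contaminant groups
#' excluded.  Groups mixing decoy and target members count as target
#' (conservative).  With zero non-decoy groups the estimate is undefined
#' and a classed error (`spcenrich_undefined_fdr`) is signaled.
#'
#' @param groups A `protein_groups` object (or any list of groups with
#'   `is_decoy` / `is_contaminant` flags).
#' @return Percent FDR.
#' @export
protein_fdr_percent <- function(groups) {
  is_con <- vapply(groups, `[[`, TRUE, "is_contaminant")
  is_dec <- vapply(groups, `[[`, TRUE, "is_decoy")
  n_dec <- sum(is_dec & !is_con)
  n_tgt <- sum(!is_dec & !is_con)
  if (n_tgt == 0L)
    stop(errorCondition("no non-decoy protein groups; FDR undefined",
                        class = "spcenrich_undefined_fdr"))
  100 * n_dec / n_tgt
}

#' Summarize protein groups as a data frame
#'
#' @param groups A `protein_groups` object.
#' @return Data frame: id, members, peptide count, unique-peptide count,
#'   per-sample distinct peptides, decoy/contaminant flags.
#' @export
protein_group_table <- function(groups) {
  samples <- attr(groups, "samples")
  base <- data.frame(
    group_id = vapply(groups, `[[`, "", "id"),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"), ""),
    n_peptides = vapply(groups, function(g) length(g$peptides), 0L),
    n_unique_peptides = vapply(groups, `[[`, 0L, "n_unique"),
    is_decoy = vapply(groups, `[[`, TRUE, "is_decoy"),
    is_contaminant = vapply(groups, `[[`, TRUE, "is_contaminant"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (length(samples) && length(groups)) {
    dps <- do.call(rbind, lapply(groups, function(g)
      as.numeric(g$distinct_per_sample)))
    colnames(dps) <- paste0("distinct_", samples)
    base <- cbind(base, dps)
  }
  base
}

#' Write the protein-group report as TSV
#'
#' @param groups A `protein_groups` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_report <- function(groups, path) {
  write.table(protein_group_table(groups), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
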