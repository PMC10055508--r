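test_that("incidence map counts distinct (sequence, modification) peptides", {
  inc <- list(AAAAAAAK = "TGT00001")
  ps <- psms_from_incidence(inc)
  map <- build_map(ps, db_for(inc))
  expect_equal(length(map$incidence), 1)
  expect_equal(map$incidence[["AAAAAAAK|unmodified"]], "TGT00001")

  # same sequence, two modification states -> two distinct peptides
  ps2 <- rbind(ps, transform(ps, mod_state = "oxidized"))
  map2 <- build_map(ps2, db_for(inc))
  expect_equal(length(map2$incidence), 2)

  empty <- build_map(ps[0, ], db_for(inc))
  expect_equal(length(empty$incidence), 0)

  bad <- transform(ps, accessions = "NOPE1")
  expect_error(build_map(bad, db_for(inc)), "unknown accession")
})

test_that("parsimony merges indistinguishable proteins and absorbs subsets", {
  inc <- list(
    PEPTIDEA = c("TGT00001", "TGT00002", "TGT00003"),
    PEPTIDEB = c("TGT00001", "TGT00002"),
    PEPTIDEC = c("TGT00001", "TGT00002"))
  map <- build_map(psms_from_incidence(inc), db_for(inc))
  grp <- parsimony_infer(map)
  # TGT00001/2 identical -> one group; TGT00003 subset -> absorbed
  expect_equal(length(grp), 1)
  expect_equal(grp[[1]]$members, c("TGT00001", "TGT00002"))
  expect_equal(length(grp[[1]]$peptides), 3)
})

test_that("razor peptides follow the unique-evidence winner deterministically", {
  inc <- list(
    U1AAAAAK = "TGT00001", U2AAAAAK = "TGT00001", U3AAAAAK = "TGT00001",
    U4AAAAAK = "TGT00002",
    SHAREDK1 = c("TGT00001", "TGT00002"))
  map <- build_map(psms_from_incidence(inc), db_for(inc))
  grp <- parsimony_infer(map)
  expect_equal(length(grp), 2)
  razor <- attr(grp, "razor")
  g1 <- grp[[which(vapply(grp, function(g) "TGT00001" %in% g$members, TRUE))]]
  expect_equal(unname(razor[["SHAREDK1|unmodified"]]), g1$id)

  # tie in unique evidence -> lexicographically first accession wins
  inc2 <- list(U1AAAAAK = "TGT00001", U2AAAAAK = "TGT00002",
               SHAREDK1 = c("TGT00001", "TGT00002"))
  grp2 <- parsimony_infer(build_map(psms_from_incidence(inc2), db_for(inc2)))
  razor2 <- attr(grp2, "razor")
  winner <- grp2[[unname(razor2[["SHAREDK1|unmodified"]])]]
  expect_true("TGT00001" %in% winner$members)
})

test_that("group count equals exhaustive minimal set cover on random instances", {
  set.seed(41)
  for (rep in seq_len(60)) {
    n_prot <- sample(2:8, 1)
    n_pep <- sample(3:12, 1)
    peps <- sprintf("PEPAAAK%02d", seq_len(n_pep))
    prots <- sprintf("TGT%05d", seq_len(n_prot))
    inc <- lapply(peps, function(p)
      sort(sample(prots, sample(seq_len(min(3, n_prot)), 1))))
    names(inc) <- peps
    map <- build_map(psms_from_incidence(inc), db_for(inc))
    grp <- parsimony_infer(map)

    prot_sets <- split(rep(names(inc), lengths(inc)), unlist(inc))
    expect_equal(length(grp), min_cover_oracle(prot_sets),
                 info = paste("instance", rep))

    # peptide coverage conservation
    expect_setequal(unlist(lapply(grp, `[[`, "peptides")),
                    paste0(names(inc), "|unmodified"))
    # subset-freeness among surviving groups
    sets <- lapply(grp, `[[`, "peptides")
    if (length(sets) > 1) {
      for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (i != j)
          expect_false(all(sets[[i]] %in% sets[[j]]) &&
                         length(sets[[i]]) < length(sets[[j]]))
      }
    }
  }
})

test_that("extended grouping merges homologs with insufficient unique evidence", {
  # two homologs sharing 9 of their 10 peptides, one unique each
  shared <- sprintf("SHRPEPK%02d", 1:9)
  inc <- c(setNames(lapply(seq_len(9), function(i) c("TGT00001", "TGT00002")),
                    shared),
           list(UNIQA01K = "TGT00001", UNIQB01K = "TGT00002"))
  grp <- parsimony_infer(build_map(psms_from_incidence(inc), db_for(inc)))
  expect_equal(length(grp), 2)
  fam <- extended_group(grp, share_min = 0.9, unique_max = 1)
  expect_equal(length(fam), 1)
  expect_equal(fam[[1]]$members, c("TGT00001", "TGT00002"))

  # disjoint peptide sets never merge, whatever the parameters
  inc2 <- list(AAPEPAAK = "TGT00001", CCPEPCCK = "TGT00002")
  grp2 <- parsimony_infer(build_map(psms_from_incidence(inc2), db_for(inc2)))
  expect_equal(length(extended_group(grp2, share_min = 0, unique_max = 99)),
               2)

  # share_min = 1 leaves parsimony output unchanged
  expect_equal(length(extended_group(grp, share_min = 1)), length(grp))
})

test_that("two-peptide rule keeps groups with two distinct peptides in one sample", {
  inc <- list(ONEPEPAK = "TGT00001",
              TWOPEPAK = "TGT00002", TWOPEPBK = "TGT00002")
  ps <- rbind(
    psms_from_incidence(inc["ONEPEPAK"], samples = c("S1", "S2")),
    psms_from_incidence(inc[c("TWOPEPAK", "TWOPEPBK")], samples = "S2"))
  grp <- parsimony_infer(build_map(ps, db_for(inc)))
  expect_equal(length(grp), 2)
  kept <- two_peptide_filter(grp)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$members, "TGT00002")
  expect_equal(length(two_peptide_filter(kept[0])), 0)
})

test_that("protein FDR percent follows the decoy/target group ratio", {
  mk <- function(n, decoy = FALSE, contam = FALSE)
    replicate(n, list(is_decoy = decoy, is_contaminant = contam),
              simplify = FALSE)
  # the published-scale arithmetic: 37 decoys among 3,963 detected groups
  grp <- c(mk(3963), mk(37, decoy = TRUE))
  expect_equal(round(protein_fdr_percent(grp), 1), 0.9)
  expect_equal(protein_fdr_percent(grp), 100 * 37 / 3963)

  expect_equal(protein_fdr_percent(mk(10)), 0)
  expect_equal(protein_fdr_percent(c(mk(5), mk(5, decoy = TRUE))), 100)
  # contaminants excluded from both numerator and denominator
  expect_equal(protein_fdr_percent(c(mk(10), mk(4, contam = TRUE))), 0)
  expect_error(protein_fdr_percent(mk(3, decoy = TRUE)),
               class = "spcenrich_undefined_fdr")
})

test_that("decoy-only groups are flagged and the report round-trips", {
  inc <- list(AADECPK1 = "REV_TGT00001", AATGTPK1 = "TGT00001",
              AATGTPK2 = "TGT00001", AACONPK1 = "CON0001")
  ps <- psms_from_incidence(inc)
  grp <- parsimony_infer(build_map(ps, db_for(inc)))
  tab <- protein_group_table(grp)
  expect_equal(sum(tab$is_decoy), 1)
  expect_equal(sum(tab$is_contaminant), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_report(grp, path)
  back <- read.delim(path)
  expect_equal(back$group_id, tab$group_id)
  expect_equal(back$n_peptides, tab$n_peptides)
})
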