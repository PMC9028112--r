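test_that("protein validation counts distinct observed peptides dataset-wide", {
  # P1 has two peptides observed in different samples; P3 only one
  ev <- make_evidence(list(a = "P1", b = "P1", c = "P3"),
                      matrix(c(1L, 0L,
                               0L, 2L,
                               1L, 1L), 3, 2, byrow = TRUE))
  v <- validate_proteins(ev, min_peptides = 2L)
  expect_equal(v$retained, "P1")
  expect_equal(v$discarded, c(P3 = "too_few_peptides"))
  v1 <- validate_proteins(ev, min_peptides = 1L)
  expect_setequal(v1$retained, c("P1", "P3"))
  expect_length(v1$discarded, 0L)
})

test_that("indistinguishable proteins merge and subsets are subsumed", {
  # P1{a,b}, P2{a,b}, P3{a}: one subgroup {P1,P2}; P3 subsumed
  ev <- make_evidence(list(a = c("P1", "P2", "P3"), b = c("P1", "P2")))
  inf <- infer_subgroups(ev, c("P1", "P2", "P3"))
  expect_length(inf$subgroups, 1L)
  expect_equal(inf$subgroups[[1]]$members, c("P1", "P2"))
  expect_setequal(inf$subgroups[[1]]$specific_peptides, c("a", "b"))
  expect_equal(inf$discarded, c(P3 = "subsumed"))
  expect_identical(inferred_families(inf),
                   oracle_families(evidence_acc_sets(ev)))
})

test_that("overlapping but non-nested subgroups share a group id", {
  # P1{a,b}, P2{b,c}: two subgroups, specific {a} and {c}, one group
  ev <- make_evidence(list(a = "P1", b = c("P1", "P2"), c = "P2"))
  inf <- infer_subgroups(ev, c("P1", "P2"))
  expect_length(inf$subgroups, 2L)
  gids <- vapply(inf$subgroups, `[[`, "", "group_id")
  expect_equal(gids[1], gids[2])
  specs <- lapply(inf$subgroups, `[[`, "specific_peptides")
  expect_setequal(unlist(specs), c("a", "c"))
  expect_true(all(lengths(specs) == 1L))
  expect_identical(inferred_families(inf),
                   oracle_families(evidence_acc_sets(ev)))
})

test_that("a lone protein keeps all its peptides as specific", {
  ev <- make_evidence(list(a = "P1", b = "P1"))
  inf <- infer_subgroups(ev, "P1")
  expect_length(inf$subgroups, 1L)
  expect_setequal(inf$subgroups[[1]]$specific_peptides, c("a", "b"))
})

test_that("subgroups without specific peptides are dropped and ledgered", {
  # a triangle of pairwise-shared peptides: no subgroup has a specific
  # peptide; P4 has its own
  ev <- make_evidence(list(a = c("P1", "P2"), b = c("P1", "P3"),
                           c = c("P2", "P3"), d = "P4"))
  inf <- infer_subgroups(ev, c("P1", "P2", "P3", "P4"))
  ids <- unlist(lapply(inf$subgroups, `[[`, "members"))
  expect_equal(ids, "P4")
  expect_equal(sort(names(inf$discarded)), c("P1", "P2", "P3"))
  expect_true(all(inf$discarded == "no_specific_peptide"))
})

test_that("ids are ordered by size then accession and are stable", {
  # two disconnected groups: sizes 3 and 1 peptides
  ev <- make_evidence(list(a = "PB", b = "PB", c = "PB", d = "PA"))
  inf <- infer_subgroups(ev, c("PA", "PB"))
  tab <- subgroups_table(inf)
  expect_equal(tab$subgroup_id, c("g0001.s01", "g0002.s01"))
  expect_equal(tab$members, c("PB", "PA"))
  # tie on size: lexicographically smaller accession first
  ev2 <- make_evidence(list(a = "PZ", b = "PZ", c = "PA", d = "PA"))
  inf2 <- infer_subgroups(ev2, c("PA", "PZ"))
  expect_equal(subgroups_table(inf2)$members, c("PA", "PZ"))
  # determinism across reruns
  rerun <- infer_subgroups(ev2, c("PA", "PZ"))
  expect_identical(subgroups_table(rerun), subgroups_table(inf2))
})

test_that("inference matches the brute-force oracle on random instances", {
  for (seed in 1:40) {
    ev <- random_bipartite_evidence(seed)
    inf <- infer_subgroups(ev, validate_proteins(ev, 1L),
                           drop_passes = 0L)
    expect_identical(inferred_families(inf),
                     oracle_families(evidence_acc_sets(ev)),
                     info = paste("seed", seed))
  }
})

test_that("specificity uniqueness and conservation hold on random instances", {
  for (seed in 41:70) {
    ev <- random_bipartite_evidence(seed)
    v <- validate_proteins(ev, 1L)
    inf <- infer_subgroups(ev, v)
    spec <- unlist(lapply(inf$subgroups, `[[`, "specific_peptides"))
    expect_false(anyDuplicated(spec) > 0, info = paste("seed", seed))
    accounted <- c(unlist(lapply(inf$subgroups, `[[`, "members")),
                   names(inf$discarded))
    expect_setequal(accounted, unique(unlist(ev$accessions)))
    expect_false(anyDuplicated(accounted) > 0)
  }
})

test_that("raising the validation threshold never adds parsimony subgroups", {
  # monotonicity is a property of the merge-and-subsumption core; the
  # later no-specific-peptide drop can resurrect a subgroup when its
  # peptide-sharing competitor is discarded by the higher threshold
  for (seed in 71:90) {
    ev <- random_bipartite_evidence(seed)
    n <- vapply(1:3, function(k)
      length(infer_subgroups(ev, validate_proteins(ev, k),
                             drop_passes = 0L)$subgroups),
      integer(1))
    expect_true(all(diff(n) <= 0L), info = paste("seed", seed))
  }
})

test_that("subsumption removal is independent of input row order", {
  for (seed in 91:100) {
    ev <- random_bipartite_evidence(seed)
    set.seed(seed + 1000)
    perm <- sample(length(ev$peptide))
    ev2 <- evidence_table(ev$peptide[perm], ev$accessions[perm],
                          ev$counts[perm, , drop = FALSE])
    f1 <- inferred_families(infer_subgroups(ev, validate_proteins(ev, 1L)))
    f2 <- inferred_families(infer_subgroups(ev2, validate_proteins(ev2, 1L)))
    expect_identical(f1, f2, info = paste("seed", seed))
  }
})
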