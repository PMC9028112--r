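quant_fixture <- function() {
  # two subgroups sharing peptide "b"; "a","c","d" specific
  ev <- make_evidence(
    list(a = "P1", b = c("P1", "P2"), c = "P2", d = "P2"),
    matrix(c(3L, 2L,
             9L, 9L,
             2L, 0L,
             0L, 4L), 4, 2, byrow = TRUE))
  list(ev = ev, inf = infer_subgroups(ev, c("P1", "P2")))
}

test_that("abundance sums specific counts only; shared peptides never count", {
  fx <- quant_fixture()
  ab <- subgroup_abundance(fx$ev, fx$inf)
  # P2's subgroup: specific c + d -> (2, 4); P1's: only a -> (3, 2)
  tab <- subgroups_table(fx$inf)
  p1 <- tab$subgroup_id[tab$members == "P1"]
  p2 <- tab$subgroup_id[tab$members == "P2"]
  expect_equal(unname(ab[p1, ]), c(3L, 2L))
  expect_equal(unname(ab[p2, ]), c(2L, 4L))
  # removing the shared peptide leaves the matrix unchanged
  keep <- fx$ev$peptide != "b"
  ev2 <- evidence_table(fx$ev$peptide[keep], fx$ev$accessions[keep],
                        fx$ev$counts[keep, , drop = FALSE])
  inf2 <- infer_subgroups(ev2, c("P1", "P2"))
  ab2 <- subgroup_abundance(ev2, inf2)
  expect_equal(unname(sort(ab2[, 1])), unname(sort(ab[, 1])))
  expect_equal(unname(sort(ab2[, 2])), unname(sort(ab[, 2])))
  # zero cells are kept as matrix cells
  expect_equal(ab[p2, "s1"], 2L)
})

test_that("group normalization divides pooled sums by group size", {
  m <- matrix(c(4L, 0L, 6L, 1L, 5L, 0L, 0L, 0L, 0L, 0L),
              2, 5, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              c("CTRL_S01_F", "CTRL_S01_C", "CDC_S03_F",
                                "CDIC_S04_F", "UC_S05_F")))
  sh <- mini_sheet()
  gm <- normalize_by_group_size(m, sh)
  expect_equal(gm["g1", "CTRL"], 2)      # (4 + 0) / 2
  expect_equal(gm["g1", "CDC"], 6)       # one-sample group: identity
  expect_equal(unname(gm["g2", ]), c(0, 0, 0, 0))
  # linearity: scaling counts scales every group value
  expect_equal(normalize_by_group_size(m * 3L, sh), gm * 3)
  expect_error(normalize_by_group_size(
    matrix(1, 1, 1, dimnames = list("g1", "zzz")), sh), "zzz")
})

test_that("taxon aggregation conserves column totals at every rank", {
  cfg <- small_sim_config(seed = 11L)
  catalogue <- generate_catalogue(cfg)
  sim <- generate_evidence(cfg, catalogue)
  inf <- infer_subgroups(sim$evidence)
  ann <- annotate_subgroups(
    inf, resolve_annotations(sim$evidence, catalogue$annotations))
  ab <- subgroup_abundance(sim$evidence, inf)
  for (rank in c("phylum", "genus", "species")) {
    agg <- aggregate_by_taxon(ab, ann, rank)
    expect_equal(colSums(agg), colSums(ab))
  }
  # normalization and taxon summation commute
  sh <- sim$sheet
  a1 <- aggregate_by_taxon(normalize_by_group_size(ab, sh), ann, "phylum")
  a2 <- normalize_by_group_size(aggregate_by_taxon(ab, ann, "phylum"), sh)
  expect_equal(a1, a2)
})

test_that("taxon aggregation bins shallow-consensus subgroups as unclassified", {
  ann <- tiny_annotations()
  ev <- make_evidence(list(a = c("P1", "P2"), b = c("P1", "P2"),
                           e = "P3", f = "P3", g = "P4", h = "P4"))
  inf <- infer_subgroups(ev)
  sub_ann <- annotate_subgroups(inf, ann)
  ab <- subgroup_abundance(ev, inf)
  genus <- aggregate_by_taxon(ab, sub_ann, "genus")
  expect_true("unclassified" %in% rownames(genus))  # P4: superkingdom only
  expect_equal(unname(genus["Coprococcus", ]), unname(colSums(ab) -
                                                        genus["unclassified", ]))
  # two species of one genus sum into the genus row
  species <- aggregate_by_taxon(ab, sub_ann, "species")
  expect_equal(unname(genus["Coprococcus", ]),
               unname(species["Coprococcus comes", ] +
                        species["Coprococcus eutactus", ]))
})

test_that("KO aggregation multi-counts subgroups across their KOs", {
  ann <- tiny_annotations()
  ev <- make_evidence(list(a = c("P1", "P2"), b = c("P1", "P2")),
                      matrix(c(5L, 0L, 0L, 5L), 2, 2))
  inf <- infer_subgroups(ev)
  ab <- subgroup_abundance(ev, inf)
  sub_ann <- annotate_subgroups(inf, ann)
  byko <- aggregate_by_ko(ab, sub_ann)
  expect_setequal(rownames(byko), c("K00001", "K02112"))
  # the single subgroup contributes its full abundance to both KO rows
  expect_equal(unname(byko["K00001", ]), unname(ab[1, ]))
  expect_equal(unname(byko["K02112", ]), unname(ab[1, ]))
  ko_map <- data.frame(ko = c("K00001", "K02112", "K02112"),
                       pathway = c("map00010", "map00010", "map00190"))
  bypath <- aggregate_by_pathway(ab, sub_ann, ko_map)
  expect_setequal(rownames(bypath), c("map00010", "map00190"))
  expect_equal(unname(bypath["map00010", ]), unname(ab[1, ]))
})

test_that("diversity summary counts presence per sample with set semantics", {
  ann <- tiny_annotations()
  # three subgroups: species-consensus microbial (with KOs), human,
  # and one annotated at superkingdom only (P4)
  ev <- make_evidence(
    list(a = c("P1", "P2"), b = c("P1", "P2"),
         c = "H1", d = "H1",
         e = "P4", f = "P4"),
    matrix(c(1L, 0L,
             2L, 1L,
             1L, 1L,
             0L, 3L,
             0L, 2L,
             0L, 1L), 6, 2, byrow = TRUE))
  inf <- infer_subgroups(ev)
  ab <- subgroup_abundance(ev, inf)
  sub_ann <- annotate_subgroups(inf, ann)
  div <- diversity_summary(ab, sub_ann)
  s1 <- div[div$sample == "s1", ]
  expect_equal(s1$n_subgroups_total, 2L)
  expect_equal(s1$n_bacterial, 1L)
  expect_equal(s1$n_human, 1L)
  expect_equal(s1$n_bacterial + s1$n_human + s1$n_other,
               s1$n_subgroups_total)
  s2 <- div[div$sample == "s2", ]
  expect_equal(s2$n_subgroups_total, 3L)
  expect_equal(s2$n_annotated_species, 2L)  # P4: superkingdom only
  expect_equal(s2$n_taxa_genus, 2L)         # Coprococcus + Homo
  # KO identities shared between subgroups count once
  expect_equal(s2$n_ko, length(unique(unlist(sub_ann$kos))))
})

test_that("per-sample abundance never exceeds total evidence counts", {
  fx <- quant_fixture()
  ab <- subgroup_abundance(fx$ev, fx$inf)
  expect_true(all(colSums(ab) <= colSums(fx$ev$counts)))
})
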