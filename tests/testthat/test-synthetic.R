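test_that("tryptic digestion follows the K/R rule with the proline exception", {
  expect_equal(tryptic_digest("AAAGGKGGGGRCCCCC", missed_cleavages = 1,
                              min_length = 4),
               c("AAAGGK", "GGGGR", "CCCCC",
                 "AAAGGKGGGGR", "GGGGRCCCCC"))
  # no cleavage after K when P follows
  expect_equal(tryptic_digest("AAAKPGGGR"), "AAAKPGGGR")
  # no cleavage sites at all: the whole sequence (if long enough)
  expect_equal(tryptic_digest("AAAAAAAA"), "AAAAAAAA")
  expect_equal(tryptic_digest("AAA"), character(0))
  # short products are filtered out
  expect_equal(tryptic_digest("AAAGGKGGGGRCCCCC", missed_cleavages = 0,
                              min_length = 6), "AAAGGK")
  expect_error(tryptic_digest("AAAXAA"), "X")
})

test_that("catalogue generation is deterministic and collision-free", {
  cfg <- small_sim_config(seed = 3L, homology_rate = 0)
  c1 <- generate_catalogue(cfg)
  c2 <- generate_catalogue(cfg)
  expect_identical(c1$sequences, c2$sequences)
  expect_identical(c1$annotations$kos, c2$annotations$kos)
  # homology 0: no peptide maps to two proteins
  peps <- unlist(c1$families$peptides)
  expect_false(anyDuplicated(peps) > 0)
  # FASTA written from the same seed is byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "catalogue.fasta"))),
                   unname(tools::md5sum(file.path(d2, "catalogue.fasta"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "evidence.tsv"))),
                   unname(tools::md5sum(file.path(d2, "evidence.tsv"))))
})

test_that("full within-species homology collapses into one subgroup", {
  tax <- default_sim_config()$taxonomy[1, , drop = FALSE]
  cfg <- default_sim_config(seed = 9L, taxonomy = tax,
                            proteins_per_species = 1L,
                            n_human = 0L, n_contaminant = 0L,
                            homology_rate = 1,
                            effects = list(), biomarkers = list())
  sim <- generate_evidence(cfg, generate_catalogue(cfg))
  inf <- infer_subgroups(sim$evidence)
  expect_length(inf$subgroups, 1L)
  expect_length(inf$subgroups[[1]]$members, 2L)
})

test_that("planted biomarkers separate with the configured margin", {
  cfg <- small_sim_config(seed = 23L, marker_margin = 5L)
  sim <- generate_evidence(cfg, generate_catalogue(cfg))
  led <- sim$ledger
  sheet <- sim$sheet
  sets <- list(
    ibd_vs_ctrl = list(a = sheet$sample[sheet$group != "CTRL"],
                       b = sheet$sample[sheet$group == "CTRL"]),
    cdic_vs_other_ibd = list(
      a = sheet$sample[sheet$group == "CDIC"],
      b = sheet$sample[sheet$group %in% c("CDC", "UC")]),
    cdc_vs_uc = list(a = sheet$sample[sheet$group == "CDC"],
                     b = sheet$sample[sheet$group == "UC"]))
  for (k in seq_len(nrow(led$biomarkers))) {
    bm <- led$biomarkers[k, ]
    ab <- led$abundance[bm$family_id, ]
    s <- sets[[bm$stage]]
    gap <- if (bm$direction == "over_in_A") {
      min(ab[s$a]) - max(ab[s$b])
    } else {
      min(ab[s$b]) - max(ab[s$a])
    }
    expect_gte(gap, 5)
  }
})

test_that("generated artifacts pass every loader validation", {
  cfg <- small_sim_config(seed = 31L)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, dir)
  ev <- read_evidence(file.path(dir, "evidence.tsv"))
  sh <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(sort(colnames(ev$counts)), sort(sh$sample))
  full <- resolve_annotations(ev, ann)
  expect_length(attr(full, "unannotated"), 0L)
  expect_identical(ev$counts[ev$peptide, ],
                   sim$evidence$counts[sim$evidence$peptide, ])
})

test_that("inference and quantification recover the generator's ledger", {
  cfg <- small_sim_config(seed = 47L, homology_rate = 0.25)
  sim <- generate_evidence(cfg, generate_catalogue(cfg))
  inf <- infer_subgroups(sim$evidence)
  led <- sim$ledger
  # subgroup composition: exactly the retained families
  got <- lapply(inf$subgroups, `[[`, "members")
  want <- led$members[led$retained]
  key <- function(x) sort(vapply(x, function(m)
    paste(sort(m), collapse = ";"), ""))
  expect_identical(key(got), key(want))
  # specific peptides are exactly the observed family peptides
  ids <- ledger_subgroup_ids(inf, led, led$family_id[led$retained])
  ord <- match(ids, vapply(inf$subgroups, `[[`, "", "subgroup_id"))
  for (k in seq_along(ord)) {
    expect_setequal(inf$subgroups[[ord[k]]]$specific_peptides,
                    led$observed_peptides[led$retained][[k]])
  }
  # abundances equal the planted specific-count totals exactly
  ab <- subgroup_abundance(sim$evidence, inf)
  expect_equal(unname(ab[ids, ]),
               unname(led$abundance[led$family_id[led$retained], ]))
  # and the screen recovers exactly the planted biomarker set
  hits <- iterative_screen(ab, sim$sheet)
  planted <- paste(led$biomarkers$stage,
                   ledger_subgroup_ids(inf, led, led$biomarkers$family_id),
                   led$biomarkers$direction)
  found <- paste(hits$stage, hits$subgroup_id, hits$direction)
  expect_setequal(found, planted)
})

test_that("the noise-free limit makes paired samples nearly identical", {
  cfg <- small_sim_config(seed = 53L, subject_sdlog = 0.3,
                          prep_sdlog = 0, depth_sdlog = 0,
                          nb_size = Inf, effects = list(),
                          biomarkers = list())
  sim <- generate_evidence(cfg, generate_catalogue(cfg))
  inf <- infer_subgroups(sim$evidence)
  ab <- subgroup_abundance(sim$evidence, inf)
  pairs <- flag_discordant_pairs(pearson_matrix(ab), sim$sheet)
  expect_true(all(pairs$r > 1 - 1e-9))
})
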