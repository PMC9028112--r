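# Shared fixtures and independent brute-force oracles.

make_evidence <- function(sets, counts = NULL, samples = NULL) {
  # sets: named list peptide -> accession vector
  peps <- names(sets)
  if (is.null(counts)) {
    counts <- matrix(1L, length(peps), 2L)
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- if (is.null(samples)) {
      paste0("s", seq_len(ncol(counts)))
    } else samples
  }
  evidence_table(peps, unname(sets), counts)
}

# brute-force parsimony oracle: enumerate identical-set merges, then
# repeatedly remove any peptide set that is a strict subset of another
oracle_families <- function(acc_sets) {
  sets <- lapply(acc_sets, function(s) sort(unique(s)))
  keys <- vapply(sets, paste, character(1), collapse = "|")
  fam <- split(names(sets), keys)
  fam_sets <- lapply(names(fam), function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  repeat {
    drop <- rep(FALSE, length(fam_sets))
    for (i in seq_along(fam_sets)) {
      for (j in seq_along(fam_sets)) {
        if (i != j && !drop[i] &&
            length(fam_sets[[i]]) < length(fam_sets[[j]]) &&
            all(fam_sets[[i]] %in% fam_sets[[j]])) {
          drop[i] <- TRUE
        }
      }
    }
    if (!any(drop)) break
    fam_sets <- fam_sets[!drop]
    fam <- fam[!drop]
  }
  # return sorted family of sorted peptide sets
  out <- lapply(fam_sets, sort)
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

random_bipartite_evidence <- function(seed, max_prot = 10L, max_pep = 15L) {
  set.seed(seed)
  n_prot <- sample(2:max_prot, 1L)
  n_pep <- sample(2:max_pep, 1L)
  prots <- sprintf("P%02d", seq_len(n_prot))
  peps <- sprintf("pep%02d", seq_len(n_pep))
  sets <- lapply(peps, function(p)
    sample(prots, sample(1:min(3L, n_prot), 1L)))
  names(sets) <- peps
  counts <- matrix(rpois(n_pep * 3L, 2L) + 1L, n_pep, 3L,
                   dimnames = list(NULL, c("a1", "a2", "a3")))
  make_evidence(sets, counts)
}

evidence_acc_sets <- function(ev) {
  # accession -> observed peptide set, as the oracle sees the instance
  obs <- rowSums(ev$counts) > 0
  pairs_acc <- unlist(ev$accessions[obs])
  pairs_pep <- rep(ev$peptide[obs], lengths(ev$accessions[obs]))
  lapply(split(pairs_pep, pairs_acc), function(p) sort(unique(p)))
}

inferred_families <- function(inf) {
  out <- lapply(inf$subgroups, function(s) sort(s$peptides))
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

# all-pairs brute-force dominance oracle
oracle_strict_contrast <- function(m, a, b) {
  hits <- list()
  for (i in seq_len(nrow(m))) {
    va <- m[i, a]
    vb <- m[i, b]
    over <- all(outer(va, vb, `>`))
    under <- all(outer(va, vb, `<`))
    if (over || under) {
      hits[[length(hits) + 1L]] <- data.frame(
        subgroup_id = rownames(m)[i],
        direction = if (over) "over_in_A" else "under_in_A",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(subgroup_id = character(0),
                      direction = character(0))
  }
  out[order(out$subgroup_id), , drop = FALSE]
}

tiny_annotations <- function() {
  lin <- function(...) {
    v <- c(...)
    c(v, rep(NA_character_, 7 - length(v)))
  }
  ranks <- rbind(
    P1 = lin("Bacteria", "Firmicutes", "Clostridia", "Eubacteriales",
             "Lachnospiraceae", "Coprococcus", "Coprococcus comes"),
    P2 = lin("Bacteria", "Firmicutes", "Clostridia", "Eubacteriales",
             "Lachnospiraceae", "Coprococcus", "Coprococcus comes"),
    P3 = lin("Bacteria", "Firmicutes", "Clostridia", "Eubacteriales",
             "Lachnospiraceae", "Coprococcus", "Coprococcus eutactus"),
    P4 = lin("Bacteria"),
    H1 = lin("Eukaryota", "Chordata", "Mammalia", "Primates",
             "Hominidae", "Homo", "Homo sapiens"))
  df <- as.data.frame(ranks, stringsAsFactors = FALSE)
  protein_annotations(
    accession = rownames(ranks),
    source = c("microbial", "microbial", "microbial", "microbial",
               "human"),
    lineage = df,
    kos = list("K02112", c("K02112", "K00001"), "K00002",
               character(0), "K09999"))
}

small_sim_config <- function(seed = 101L, ...) {
  default_sim_config(
    seed = seed,
    proteins_per_species = 4L,
    n_human = 12L,
    n_contaminant = 3L,
    protein_length_mean = 120,
    protein_length_sd = 15,
    protein_length_min = 60,
    ...)
}

mini_sheet <- function() {
  sample_sheet(
    sample = c("CTRL_S01_F", "CTRL_S01_C", "CTRL_S02_F", "CTRL_S02_C",
               "CDC_S03_F", "CDC_S03_C", "CDIC_S04_F", "CDIC_S04_C",
               "UC_S05_F", "UC_S05_C"),
    subject = rep(sprintf("S%02d", 1:5), each = 2),
    group = rep(c("CTRL", "CTRL", "CDC", "CDIC", "UC"), each = 2),
    preparation = rep(c("fresh", "frozen"), 5))
}

ledger_subgroup_ids <- function(inference, ledger, family_ids) {
  mem_key <- vapply(inference$subgroups,
                    function(s) paste(s$members, collapse = ";"), "")
  ids <- vapply(inference$subgroups, `[[`, "", "subgroup_id")
  led_key <- vapply(ledger$members[match(family_ids, ledger$family_id)],
                    function(m) paste(sort(m), collapse = ";"), "")
  ids[match(led_key, mem_key)]
}
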