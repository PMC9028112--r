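# Ground-truthed synthetic data: a protein catalogue over a realistic
# gut taxonomy, in silico tryptic digestion, and negative-binomial
# spectral counts with planted group effects and strictly separating
# biomarkers.  The generator's ledger records the expected downstream
# result of every pipeline stage so tests can compare against it.

#' In silico tryptic digestion
#'
#' Cleaves after every K or R not followed by P and emits all products
#' carrying up to `missed_cleavages` internal missed cleavage sites,
#' keeping peptides of at least `min_length` residues.
#'
#' @param sequence protein sequence over the 20-letter amino-acid
#'   alphabet.
#' @param missed_cleavages maximum internal missed cleavages (default
#'   1, the usual search-engine setting).
#' @param min_length minimum peptide length to report (default 6).
#' @return character vector of unique peptides, fully cleaved products
#'   first, then missed-cleavage products, each in sequence order.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 1L,
                           min_length = 6L) {
  stopifnot(length(sequence) == 1L, missed_cleavages >= 0L)
  bad <- setdiff(strsplit(sequence, "")[[1L]], AA_ALPHABET)
  if (length(bad)) {
    stop("non-amino-acid character(s) in sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  n <- nchar(sequence)
  if (n == 0L) return(character(0))
  chars <- strsplit(sequence, "")[[1L]]
  cut <- if (n > 1L) {
    which(chars[-n] %in% c("K", "R") & chars[-1L] != "P")
  } else integer(0)
  bounds <- c(0L, cut, n)
  nf <- length(bounds) - 1L
  out <- character(0)
  for (mc in 0:missed_cleavages) {
    if (nf <= mc) break
    i <- seq_len(nf - mc)
    peps <- substring(sequence, bounds[i] + 1L, bounds[i + mc + 1L])
    out <- c(out, peps[nchar(peps) >= min_length])
  }
  unique(out)
}

default_taxonomy <- function() {
  row <- function(phylum, class, order, family, genus, species) {
    data.frame(superkingdom = "Bacteria", phylum = phylum, class = class,
               order = order, family = family, genus = genus,
               species = species, stringsAsFactors = FALSE)
  }
  fir <- function(family, genus, sp)
    row("Firmicutes", "Clostridia", "Eubacteriales", family, genus,
        paste(genus, sp))
  bac <- function(family, genus, sp)
    row("Bacteroidetes", "Bacteroidia", "Bacteroidales", family, genus,
        paste(genus, sp))
  rbind(
    fir("Lachnospiraceae", "Blautia", "obeum"),
    fir("Lachnospiraceae", "Blautia", "wexlerae"),
    fir("Lachnospiraceae", "Blautia", "hansenii"),
    fir("Lachnospiraceae", "Coprococcus", "comes"),
    fir("Lachnospiraceae", "Coprococcus", "eutactus"),
    fir("Lachnospiraceae", "Anaerostipes", "hadrus"),
    fir("Lachnospiraceae", "Fusicatenibacter", "saccharivorans"),
    fir("Lachnospiraceae", "Roseburia", "intestinalis"),
    fir("Lachnospiraceae", "Roseburia", "hominis"),
    fir("Lachnospiraceae", "Clostridium", "clostridioforme"),
    fir("Lachnospiraceae", "Clostridium", "bolteae"),
    fir("Ruminococcaceae", "Faecalibacterium", "prausnitzii"),
    fir("Ruminococcaceae", "Faecalibacterium", "duncaniae"),
    fir("Ruminococcaceae", "Ruminococcus", "bromii"),
    fir("Ruminococcaceae", "Ruminococcus", "bicirculans"),
    bac("Bacteroidaceae", "Bacteroides", "uniformis"),
    bac("Bacteroidaceae", "Bacteroides", "vulgatus"),
    bac("Bacteroidaceae", "Bacteroides", "dorei"),
    bac("Bacteroidaceae", "Bacteroides", "thetaiotaomicron"),
    bac("Prevotellaceae", "Prevotella", "copri"),
    bac("Prevotellaceae", "Prevotella", "stercorea"),
    bac("Rikenellaceae", "Alistipes", "putredinis"),
    bac("Rikenellaceae", "Alistipes", "finegoldii"),
    row("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Escherichia", "Escherichia coli"),
    row("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Escherichia", "Escherichia fergusonii"),
    row("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Klebsiella", "Klebsiella pneumoniae"),
    row("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Enterobacter", "Enterobacter cloacae"),
    row("Actinobacteria", "Actinomycetia", "Bifidobacteriales",
        "Bifidobacteriaceae", "Bifidobacterium", "Bifidobacterium bifidum"),
    row("Actinobacteria", "Actinomycetia", "Bifidobacteriales",
        "Bifidobacteriaceae", "Bifidobacterium", "Bifidobacterium longum"),
    row("Actinobacteria", "Coriobacteriia", "Coriobacteriales",
        "Coriobacteriaceae", "Collinsella", "Collinsella aerofaciens"),
    row("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales",
        "Akkermansiaceae", "Akkermansia", "Akkermansia muciniphila"))
}

human_lineage <- function() {
  data.frame(superkingdom = "Eukaryota", phylum = "Chordata",
             class = "Mammalia", order = "Primates",
             family = "Hominidae", genus = "Homo",
             species = "Homo sapiens", stringsAsFactors = FALSE)
}

#' Default simulation configuration
#'
#' Encodes the study design the synthetic data emulate: 8 CTRL, 3 CDC,
#' 2 CDIC and 7 UC subjects, each contributing a fresh and a frozen
#' sample (40 samples); a five-phylum gut taxonomy of 32 species;
#' within-genus homology creating indistinguishable protein pairs;
#' log-normal subgroup baselines with negative-binomial spectral
#' counts; planted group-level effects (a proteobacterial bloom in
#' CDIC, elevated human proteins and depleted Firmicutes in patients);
#' and planted strictly separating biomarkers for every screening
#' stage, realized by rejection sampling so the separation holds in
#' the drawn counts, not just in expectation.
#'
#' @param seed integer seed driving both catalogue and count
#'   generation (default 17).
#' @param ... overrides for any configuration field (see the returned
#'   list for names and defaults).
#' @return a `sim_config` list.
#' @export
default_sim_config <- function(seed = 17L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    subjects = c(CTRL = 8L, CDC = 3L, CDIC = 2L, UC = 7L),
    taxonomy = default_taxonomy(),
    proteins_per_species = 60L,
    n_human = 150L,
    n_contaminant = 15L,
    protein_length_mean = 210,
    protein_length_sd = 40,
    protein_length_min = 80,
    homology_rate = 0.15,
    missed_cleavages = 1L,
    min_peptide_length = 6L,
    n_ko = 250L,
    n_pathway = 25L,
    baseline_meanlog = log(12),
    baseline_sdlog = 1.2,
    subject_sdlog = 0.3,
    prep_sdlog = 0.05,
    depth_sdlog = 0.15,
    nb_size = 15,
    effects = list(
      list(rank = "phylum", taxon = "Proteobacteria",
           groups = "CDIC", fold = 2.5),
      list(rank = "source", taxon = "human",
           groups = c("CDC", "CDIC", "UC"), fold = 2),
      list(rank = "phylum", taxon = "Firmicutes",
           groups = c("CDC", "CDIC", "UC"), fold = 0.6)),
    biomarkers = list(
      list(stage = "ibd_vs_ctrl", direction = "over_in_A", n = 2L),
      list(stage = "ibd_vs_ctrl", direction = "under_in_A", n = 1L),
      list(stage = "cdic_vs_other_ibd", direction = "over_in_A", n = 2L),
      list(stage = "cdc_vs_uc", direction = "over_in_A", n = 2L)),
    marker_base = 10,
    marker_fold = 5,
    marker_margin = 2L,
    marker_max_tries = 1000L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  stopifnot(all(cfg$subjects > 0L), cfg$marker_margin >= 1L,
            cfg$homology_rate >= 0, cfg$homology_rate <= 1)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Any field of [default_sim_config()] may be overridden; omitted
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @param seed optional seed overriding both default and file value.
#' @return a `sim_config` list.
#' @export
read_sim_config <- function(path, seed = NULL) {
  over <- yaml::read_yaml(path)
  if (!is.null(seed)) over$seed <- as.integer(seed)
  if (!is.null(over$subjects)) over$subjects <- unlist(over$subjects)
  do.call(default_sim_config,
          c(list(seed = if (is.null(over$seed)) 17L else over$seed),
            over[setdiff(names(over), "seed")]))
}

random_sequences <- function(n, cfg) {
  p <- rep((1 - 0.048 * 2 - 0.045) / 17, 20)
  names(p) <- AA_ALPHABET
  p[c("K", "R")] <- 0.048
  p["P"] <- 0.045
  len <- pmax(cfg$protein_length_min,
              round(stats::rnorm(n, cfg$protein_length_mean,
                                 cfg$protein_length_sd)))
  vapply(len, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = p),
          collapse = ""), character(1))
}

#' Generate a synthetic protein catalogue
#'
#' Random tryptic-friendly protein sequences for every species of the
#' configured taxonomy plus a human and a contaminant set, with
#' per-accession annotations and a KO-to-pathway map.  A configurable
#' fraction of microbial proteins is duplicated under a new accession
#' (species drawn from the same genus), creating proteins that share
#' their entire peptide set -- the within-genus homology that drives
#' indistinguishability downstream.  Digestion products are collision
#' checked: at homology rate 0 no peptide maps to two proteins.
#'
#' @param config a `sim_config` from [default_sim_config()].
#' @return a `sim_catalogue` list: `sequences` (named character),
#'   `annotations` (`protein_annotations`), `families` (one per
#'   original protein: id, member accessions, peptide set, expected
#'   consensus rank), `ko_map`, and the config.
#' @export
generate_catalogue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tax <- config$taxonomy
  n_mic <- nrow(tax) * config$proteins_per_species
  acc_mic <- sprintf("MP%05d", seq_len(n_mic))
  sp_idx <- rep(seq_len(nrow(tax)), each = config$proteins_per_species)
  acc_hum <- sprintf("HP%04d", seq_len(config$n_human))
  acc_con <- sprintf("CT%03d", seq_len(config$n_contaminant))
  accs <- c(acc_mic, acc_hum, acc_con)
  seqs <- stats::setNames(random_sequences(length(accs), config), accs)

  digest_all <- function(seqs) {
    lapply(seqs, tryptic_digest,
           missed_cleavages = config$missed_cleavages,
           min_length = config$min_peptide_length)
  }
  peps <- digest_all(seqs)
  for (round in 1:25) {
    tab <- table(unlist(peps))
    shared <- names(tab)[tab > 1L]
    if (!length(shared)) break
    offenders <- which(vapply(peps, function(p) any(p %in% shared),
                              logical(1)))
    if (round == 25L) {
      stop("could not generate a collision-free catalogue", call. = FALSE)
    }
    seqs[offenders] <- random_sequences(length(offenders), config)
    peps[offenders] <- digest_all(seqs[offenders])
  }

  # within-genus homology: exact duplicates under a new accession
  n_dup <- round(config$homology_rate * n_mic)
  dup_of <- if (n_dup > 0) sort(sample(seq_len(n_mic), n_dup)) else integer(0)
  acc_dup <- sprintf("%sB", acc_mic[dup_of])
  dup_sp <- vapply(dup_of, function(i) {
    genus <- tax$genus[sp_idx[i]]
    cand <- which(tax$genus == genus)
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  seqs <- c(seqs, stats::setNames(seqs[acc_mic[dup_of]], acc_dup))
  peps <- c(peps, stats::setNames(peps[acc_mic[dup_of]], acc_dup))

  # annotations
  empty_lin <- as.data.frame(matrix(NA_character_, 1L,
                                    length(TAXONOMIC_RANKS)))
  names(empty_lin) <- TAXONOMIC_RANKS
  lin <- rbind(tax[sp_idx, TAXONOMIC_RANKS],
               human_lineage()[rep(1L, config$n_human), ],
               empty_lin[rep(1L, config$n_contaminant), ],
               tax[dup_sp, TAXONOMIC_RANKS])
  source <- c(rep("microbial", n_mic), rep("human", config$n_human),
              rep("contaminant", config$n_contaminant),
              rep("microbial", n_dup))
  ko_pool <- sprintf("K%05d", sort(sample.int(20000L, config$n_ko)))
  n_ko_prot <- sample(0:2, n_mic, replace = TRUE,
                      prob = c(0.15, 0.70, 0.15))
  kos <- lapply(n_ko_prot, function(k) sample(ko_pool, k))
  kos_hum <- lapply(stats::rbinom(config$n_human, 1L, 0.4),
                    function(k) sample(ko_pool, k))
  kos <- c(kos, kos_hum, rep(list(character(0)), config$n_contaminant),
           kos[dup_of])
  ann <- protein_annotations(c(accs, acc_dup), source, lin, kos)

  pathways <- sprintf("map%05d", sort(sample.int(1100L, config$n_pathway)))
  npath <- sample(1:3, config$n_ko, replace = TRUE)
  ko_map <- data.frame(
    ko = rep(ko_pool, npath),
    pathway = unlist(lapply(npath, function(k) sample(pathways, k))),
    stringsAsFactors = FALSE)
  ko_map <- unique(ko_map[order(ko_map$ko, ko_map$pathway), ])
  rownames(ko_map) <- NULL

  # one family per original protein; duplicates join their original
  fam_members <- c(lapply(seq_len(n_mic), function(i) acc_mic[i]),
                   as.list(acc_hum), as.list(acc_con))
  for (k in seq_along(dup_of)) {
    fam_members[[dup_of[k]]] <- c(fam_members[[dup_of[k]]], acc_dup[k])
  }
  orig_acc <- c(acc_mic, acc_hum, acc_con)
  consensus <- c(
    ifelse(seq_len(n_mic) %in% dup_of[sp_idx[dup_of] != dup_sp],
           "genus", "species"),
    rep("species", config$n_human),
    rep("none", config$n_contaminant))
  families <- list(
    family_id = sprintf("F%04d", seq_along(orig_acc)),
    members = fam_members,
    peptides = unname(peps[orig_acc]),
    source = c(rep("microbial", n_mic), rep("human", config$n_human),
               rep("contaminant", config$n_contaminant)),
    phylum = c(tax$phylum[sp_idx], rep("Chordata", config$n_human),
               rep(NA_character_, config$n_contaminant)),
    genus = c(tax$genus[sp_idx], rep("Homo", config$n_human),
              rep(NA_character_, config$n_contaminant)),
    species = c(tax$species[sp_idx],
                rep("Homo sapiens", config$n_human),
                rep(NA_character_, config$n_contaminant)),
    expected_consensus = consensus)
  structure(list(sequences = seqs, annotations = ann, ko_map = ko_map,
                 families = families, config = config),
            class = "sim_catalogue")
}

#' Sample sheet implied by a simulation configuration
#' @param config a `sim_config`.
#' @return a `sample_sheet`: one fresh and one frozen sample per
#'   subject, subjects numbered S01... across groups in the order
#'   CTRL, CDC, CDIC, UC.
#' @export
sim_sample_sheet <- function(config) {
  groups <- rep(names(config$subjects), config$subjects)
  subjects <- sprintf("S%02d", seq_along(groups))
  sample_sheet(
    sample = paste0(rep(groups, each = 2L), "_",
                    rep(subjects, each = 2L), "_",
                    rep(c("F", "C"), length(subjects))),
    subject = rep(subjects, each = 2L),
    group = rep(groups, each = 2L),
    preparation = rep(c("fresh", "frozen"), length(subjects)))
}

marker_profile <- function(stage, direction, groups, base, fold) {
  side_a <- switch(stage,
                   ibd_vs_ctrl = c("CDC", "CDIC", "UC"),
                   cdic_vs_other_ibd = "CDIC",
                   cdc_vs_uc = "CDC")
  mu <- stats::setNames(rep(base, length(groups)), groups)
  if (direction == "over_in_A") {
    mu[side_a] <- base * fold
  } else {
    mu[side_a] <- 0
  }
  mu
}

marker_sides <- function(stage, sheet) {
  switch(stage,
         ibd_vs_ctrl = list(a = samples_of(sheet, c("CDC", "CDIC", "UC")),
                            b = samples_of(sheet, "CTRL")),
         cdic_vs_other_ibd = list(a = samples_of(sheet, "CDIC"),
                                  b = samples_of(sheet, c("CDC", "UC"))),
         cdc_vs_uc = list(a = samples_of(sheet, "CDC"),
                          b = samples_of(sheet, "UC")))
}

#' Generate synthetic peptide evidence with ground truth
#'
#' Draws per-sample spectral counts for every catalogue peptide:
#' log-normal family baselines, multiplicative group effects, a
#' subject-level latent abundance shared by the fresh and frozen
#' samples of a subject (with small preparation noise, so paired
#' profiles correlate strongly), per-sample depth variation, and
#' negative-binomial counting noise.  Planted biomarker families are
#' redrawn (rejection sampling) until their realized subgroup
#' abundances satisfy strict dominance with the configured margin.
#'
#' @param config a `sim_config`.
#' @param catalogue matching `sim_catalogue`; regenerated from the
#'   config when omitted.
#' @param seed seed for count generation (defaults to `config$seed`).
#' @return list with `evidence` ([evidence_table()]), `sheet`
#'   (`sample_sheet`) and `ledger` (ground truth: per-family observed
#'   peptides, retention, realized abundances, planted biomarkers and
#'   expected stage counts).
#' @export
generate_evidence <- function(config, catalogue = NULL,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(catalogue)) catalogue <- generate_catalogue(config)
  set.seed(seed)
  sheet <- sim_sample_sheet(config)
  nsamp <- nrow(sheet)
  fam <- catalogue$families
  nfam <- length(fam$family_id)
  groups <- names(config$subjects)
  grp_of <- sheet$group
  subj_of <- match(sheet$subject, unique(sheet$subject))
  nsubj <- max(subj_of)

  pep <- unlist(fam$peptides, use.names = FALSE)
  fam_of_pep <- rep.int(seq_len(nfam), lengths(fam$peptides))
  npep <- length(pep)

  # multiplicative pieces of the expected count
  baseline <- stats::rlnorm(nfam, config$baseline_meanlog,
                            config$baseline_sdlog)
  fold <- matrix(1, nfam, length(groups),
                 dimnames = list(NULL, groups))
  for (e in config$effects) {
    target <- if (identical(e$rank, "source")) {
      fam$source == e$taxon
    } else {
      !is.na(fam[[e$rank]]) & fam[[e$rank]] == e$taxon
    }
    fold[target, e$groups] <- fold[target, e$groups, drop = FALSE] * e$fold
  }

  # plant biomarkers on unaffected microbial families with enough
  # peptides, then neutralize their baseline/effects
  eligible <- which(fam$source == "microbial" &
                      rowSums(fold != 1) == 0 &
                      lengths(fam$peptides) >= 4L)
  n_markers <- sum(vapply(config$biomarkers, function(b)
    as.integer(b$n), integer(1)))
  if (n_markers > length(eligible)) {
    stop("not enough eligible families to plant biomarkers", call. = FALSE)
  }
  if (n_markers > 0L) {
    chosen <- sample(eligible, n_markers)
    marker_tab <- do.call(rbind, lapply(config$biomarkers, function(b)
      data.frame(stage = b$stage, direction = b$direction,
                 n = b$n, stringsAsFactors = FALSE)))
    markers <- data.frame(
      family = chosen,
      family_id = fam$family_id[chosen],
      stage = rep(marker_tab$stage, marker_tab$n),
      direction = rep(marker_tab$direction, marker_tab$n),
      stringsAsFactors = FALSE)
  } else {
    markers <- data.frame(family = integer(0), family_id = character(0),
                          stage = character(0), direction = character(0),
                          stringsAsFactors = FALSE)
  }

  subj_fx <- matrix(stats::rlnorm(nfam * nsubj, 0, config$subject_sdlog),
                    nfam, nsubj)
  depth <- stats::rlnorm(nsamp, 0, config$depth_sdlog)
  prep_fx <- matrix(stats::rlnorm(nfam * nsamp, 0, config$prep_sdlog),
                    nfam, nsamp)
  mu_fam <- baseline * fold[, grp_of, drop = FALSE]
  for (k in seq_len(nrow(markers))) {
    prof <- marker_profile(markers$stage[k], markers$direction[k],
                           groups, config$marker_base, config$marker_fold)
    mu_fam[markers$family[k], ] <- prof[grp_of]
  }
  mu_fam <- mu_fam * subj_fx[, subj_of, drop = FALSE] * prep_fx
  mu_fam <- sweep(mu_fam, 2L, depth, `*`)

  w <- stats::rgamma(npep, shape = 2)
  fam_factor <- factor(fam_of_pep, levels = seq_len(nfam))
  wsum <- vapply(split(w, fam_factor), sum, numeric(1))
  w <- w / wsum[fam_of_pep]
  mu_pep <- mu_fam[fam_of_pep, , drop = FALSE] * w
  # infinite dispersion switches counting noise off entirely
  # (counts equal their rounded expectations)
  rnb <- function(n, mu) {
    if (is.infinite(config$nb_size)) round(mu)
    else stats::rnbinom(n, mu = mu, size = config$nb_size)
  }
  counts <- matrix(rnb(npep * nsamp, mu_pep),
                   npep, nsamp, dimnames = list(NULL, sheet$sample))

  # Rejection sampling makes planted separation exact in the realized
  # counts: each planted family is redrawn until it strictly separates
  # with the configured margin in its own stage and in no other stage;
  # every other family is redrawn (subject effects included, so the
  # redraw actually changes its expectation) until it strictly
  # separates in no stage at all.  The ledger's planted set is thereby
  # exactly the set of strict-dominance hits.
  all_stages <- c("ibd_vs_ctrl", "cdic_vs_other_ibd", "cdc_vs_uc")
  sides_of <- lapply(stats::setNames(nm = all_stages), marker_sides,
                     sheet = sheet)
  # stages lacking samples on either side cannot be screened; skip them
  sides_of <- Filter(function(s) length(s$a) && length(s$b), sides_of)
  all_stages <- names(sides_of)
  bad_stage <- setdiff(markers$stage, all_stages)
  if (length(bad_stage)) {
    stop("cannot plant biomarkers for stage(s) without samples: ",
         paste(unique(bad_stage), collapse = ", "), call. = FALSE)
  }
  stage_gap <- function(ab, sides, direction) {
    if (direction == "over_in_A") {
      min(ab[sides$a]) - max(ab[sides$b])
    } else {
      min(ab[sides$b]) - max(ab[sides$a])
    }
  }
  separates_in <- function(ab, stage) {
    stage_gap(ab, sides_of[[stage]], "over_in_A") >= 1 ||
      stage_gap(ab, sides_of[[stage]], "under_in_A") >= 1
  }
  marker_stage <- stats::setNames(markers$stage, markers$family)
  family_ok <- function(i, ab) {
    own <- marker_stage[as.character(i)]
    if (!is.na(own)) {
      k <- match(i, markers$family)
      gap <- stage_gap(ab, sides_of[[own]], markers$direction[k])
      if (gap < config$marker_margin) return(FALSE)
    }
    for (s in setdiff(all_stages, own)) {
      if (separates_in(ab, s)) return(FALSE)
    }
    TRUE
  }
  redraw_family <- function(i, rows) {
    subj_fx[i, ] <<- stats::rlnorm(nsubj, 0, config$subject_sdlog)
    prep_fx[i, ] <<- stats::rlnorm(nsamp, 0, config$prep_sdlog)
    base_mu <- if (i %in% markers$family) {
      k <- match(i, markers$family)
      prof <- marker_profile(markers$stage[k], markers$direction[k],
                             groups, config$marker_base,
                             config$marker_fold)
      prof[grp_of]
    } else {
      baseline[i] * fold[i, grp_of]
    }
    mu_row <- base_mu * subj_fx[i, subj_of] * prep_fx[i, ] * depth
    mu_pep[rows, ] <<- outer(w[rows], mu_row)
    counts[rows, ] <<- rnb(length(rows) * nsamp,
                           mu_pep[rows, , drop = FALSE])
  }
  rows_of_fam <- split(seq_len(npep), fam_factor)
  for (i in seq_len(nfam)) {
    rows <- rows_of_fam[[i]]
    if (!length(rows)) next
    planted <- i %in% markers$family
    ok <- FALSE
    for (try in seq_len(config$marker_max_tries)) {
      ab <- colSums(counts[rows, , drop = FALSE])
      enough <- !planted ||
        sum(rowSums(counts[rows, , drop = FALSE]) > 0) >= 2L
      if (enough && family_ok(i, ab)) {
        ok <- TRUE
        break
      }
      redraw_family(i, rows)
    }
    if (!ok) {
      stop("rejection sampling failed for family ", fam$family_id[i],
           if (planted) " (planted biomarker)", " after ",
           config$marker_max_tries,
           " tries; adjust marker_fold/marker_margin or effect sizes",
           call. = FALSE)
    }
  }

  observed <- rowSums(counts) > 0L
  evidence <- evidence_table(pep[observed],
                             fam$members[fam_of_pep[observed]],
                             counts[observed, , drop = FALSE])

  n_obs_pep <- tabulate(fam_of_pep[observed], nbins = nfam)
  retained <- n_obs_pep >= 2L
  fam_ab <- matrix(0L, nfam, nsamp,
                   dimnames = list(fam$family_id, sheet$sample))
  rs <- rowsum(counts, fam_of_pep)
  fam_ab[as.integer(rownames(rs)), ] <- rs
  stage_counts <- table(factor(markers$stage,
                               c("ibd_vs_ctrl", "cdic_vs_other_ibd",
                                 "cdc_vs_uc")))
  ledger <- list(
    family_id = fam$family_id,
    members = fam$members,
    source = fam$source,
    species = fam$species,
    expected_consensus = fam$expected_consensus,
    n_observed_peptides = n_obs_pep,
    retained = retained,
    observed_peptides = unname(split(pep[observed],
                                     fam_factor[observed])),
    abundance = fam_ab[retained, , drop = FALSE],
    biomarkers = markers[c("family_id", "stage", "direction")],
    expected_stage_hits = stats::setNames(as.integer(stage_counts),
                                          names(stage_counts)),
    n_evidence_peptides = sum(observed),
    n_retained_families = sum(retained))
  list(evidence = evidence, sheet = sheet, ledger = ledger)
}

#' Generate a complete synthetic dataset, optionally writing it out
#'
#' Convenience wrapper: catalogue plus evidence.  With `out_dir` set,
#' writes `catalogue.fasta`, `annotations.tsv`, `ko_map.tsv`,
#' `evidence.tsv`, `sample_sheet.tsv` and `ledger.json`.
#'
#' @param config a `sim_config`.
#' @param out_dir optional output directory (created if needed).
#' @return (invisibly) list with `catalogue`, `evidence`, `sheet`,
#'   `ledger` and, when written, `files`.
#' @export
simulate_dataset <- function(config = default_sim_config(),
                             out_dir = NULL) {
  catalogue <- generate_catalogue(config)
  sim <- generate_evidence(config, catalogue)
  out <- list(catalogue = catalogue, evidence = sim$evidence,
              sheet = sim$sheet, ledger = sim$ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir,
                       c("catalogue.fasta", "annotations.tsv",
                         "ko_map.tsv", "evidence.tsv",
                         "sample_sheet.tsv", "ledger.json"))
    names(paths) <- c("fasta", "annotations", "ko_map", "evidence",
                      "sheet", "ledger")
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(catalogue$sequences), paths["fasta"])
    write_annotations(catalogue$annotations, paths["annotations"])
    write_table_plain(catalogue$ko_map, paths["ko_map"])
    write_evidence(sim$evidence, paths["evidence"])
    write_sample_sheet(sim$sheet, paths["sheet"])
    led <- sim$ledger
    led$abundance <- NULL  # kept in memory; matrices go to TSV
    write_matrix(sim$ledger$abundance,
                 file.path(out_dir, "ledger_abundance.tsv"))
    jsonlite::write_json(led, paths["ledger"], auto_unbox = TRUE,
                         digits = NA)
    out$files <- c(paths, abundance = file.path(out_dir,
                                                "ledger_abundance.tsv"))
  }
  invisible(out)
}
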