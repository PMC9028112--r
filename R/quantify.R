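# Specific spectral-count quantification and descriptive aggregation.

#' Subgroup abundance matrix from specific spectral counts
#'
#' The abundance of a subgroup in a sample is the sum of the spectral
#' counts of its specific peptides in that sample; shared peptides
#' never contribute.  A subgroup is "present" in a sample when its
#' abundance there is positive.
#'
#' @param evidence an [evidence_table()].
#' @param inference an `inference_result` with specific peptides
#'   assigned; a subgroup without any specific peptide is a contract
#'   violation and raises an error.
#' @return integer matrix, rows = subgroup ids, columns = sample ids.
#' @export
subgroup_abundance <- function(evidence, inference) {
  stopifnot(inherits(evidence, "evidence_table"),
            inherits(inference, "inference_result"))
  subs <- inference$subgroups
  if (!length(subs)) {
    return(matrix(0L, 0L, ncol(evidence$counts),
                  dimnames = list(NULL, colnames(evidence$counts))))
  }
  nspec <- vapply(subs, function(s) length(s$specific_peptides), integer(1))
  if (any(nspec == 0L)) {
    stop("subgroup(s) without specific peptides reached quantification: ",
         paste(vapply(subs[nspec == 0L], `[[`, character(1), "subgroup_id"),
               collapse = ", "), call. = FALSE)
  }
  ids <- vapply(subs, `[[`, character(1), "subgroup_id")
  pep <- unlist(lapply(subs, `[[`, "specific_peptides"), use.names = FALSE)
  owner <- rep.int(ids, nspec)
  idx <- match(pep, evidence$peptide)
  if (anyNA(idx)) {
    stop("specific peptide(s) absent from evidence: ",
         paste(pep[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  m <- rowsum(evidence$counts[idx, , drop = FALSE], group = owner,
              reorder = FALSE)
  m <- m[ids, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Average abundance per clinical group
#'
#' Divides the per-group summed counts by the number of samples in the
#' group (fresh and frozen samples pooled), i.e. the per-sample mean.
#' Used for group-level descriptive aggregation only; the strict
#' contrast screen works on raw per-sample counts.
#'
#' @param m abundance matrix (columns = sample ids).
#' @param sheet a `sample_sheet` covering every column.
#' @return real matrix, one column per clinical group present.
#' @export
normalize_by_group_size <- function(m, sheet) {
  grp <- sheet$group[match(colnames(m), sheet$sample)]
  if (anyNA(grp)) {
    stop("matrix columns absent from sample sheet: ",
         paste(colnames(m)[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  groups <- CLINICAL_GROUPS[CLINICAL_GROUPS %in% grp]
  if (!length(groups)) stop("no non-empty clinical group", call. = FALSE)
  out <- vapply(groups, function(g) {
    cols <- which(grp == g)
    rowSums(m[, cols, drop = FALSE]) / length(cols)
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), groups))
  out
}

subgroup_taxon_label <- function(ann, rank) {
  depth <- rank_depth(rank)
  ok <- rank_depth(ann$consensus_rank) >= depth
  lab <- rep("unclassified", nrow(ann))
  lab[ok] <- as.data.frame(ann)[ok, rank]
  lab
}

#' Aggregate abundances by taxon
#'
#' Sums subgroup abundances within each taxon at the requested rank.
#' Subgroups whose consensus is shallower than the rank are binned as
#' `"unclassified"`, so column sums are conserved.
#'
#' @param m abundance matrix (rows = subgroup ids).
#' @param ann `subgroup_annotations` covering the rows.
#' @param rank one of the seven taxonomic ranks.
#' @return numeric matrix, rows = taxa (plus `"unclassified"`).
#' @export
aggregate_by_taxon <- function(m, ann, rank = "phylum") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  idx <- match(rownames(m), ann$subgroup_id)
  if (anyNA(idx)) {
    stop("subgroup(s) missing from annotations: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lab <- subgroup_taxon_label(ann[idx, , drop = FALSE], rank)
  out <- rowsum(m, group = lab)
  out[order(rownames(out) == "unclassified", rownames(out)), ,
      drop = FALSE]
}

#' Aggregate abundances by KEGG Orthology entry
#'
#' A subgroup annotated with k KOs contributes its full abundance to
#' each of the k KO rows, so KO totals are deliberately not conserved
#' (multi-annotation rule).  Subgroups without KOs are omitted.
#'
#' @inheritParams aggregate_by_taxon
#' @return numeric matrix, rows = KO ids.
#' @export
aggregate_by_ko <- function(m, ann) {
  idx <- match(rownames(m), ann$subgroup_id)
  if (anyNA(idx)) {
    stop("subgroup(s) missing from annotations: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  kos <- ann$kos[idx]
  n <- lengths(kos)
  if (!sum(n)) {
    return(matrix(0, 0L, ncol(m), dimnames = list(NULL, colnames(m))))
  }
  rows <- rep.int(seq_len(nrow(m)), n)
  rowsum(m[rows, , drop = FALSE], group = unlist(kos))
}

#' Aggregate abundances by KEGG pathway map
#'
#' @inheritParams aggregate_by_ko
#' @param ko_map data.frame with columns `ko` and `pathway` mapping KO
#'   entries to pathway maps (a KO may occur in several pathways).
#' @return numeric matrix, rows = pathway ids.
#' @export
aggregate_by_pathway <- function(m, ann, ko_map) {
  stopifnot(all(c("ko", "pathway") %in% names(ko_map)))
  idx <- match(rownames(m), ann$subgroup_id)
  paths <- lapply(ann$kos[idx], function(k)
    sort(unique(ko_map$pathway[ko_map$ko %in% k])))
  n <- lengths(paths)
  if (!sum(n)) {
    return(matrix(0, 0L, ncol(m), dimnames = list(NULL, colnames(m))))
  }
  rows <- rep.int(seq_len(nrow(m)), n)
  rowsum(m[rows, , drop = FALSE], group = unlist(paths))
}

#' Per-sample diversity summary
#'
#' Presence-based counts per sample (a subgroup counts when its
#' abundance there is positive): total subgroups, bacterial/human/other
#' splits, subgroups annotated at each rank, distinct taxa at each
#' rank, subgroups carrying a KO, and distinct KO entries.  Only
#' consensus annotations (concordant within a subgroup) contribute.
#'
#' @param m abundance matrix (rows = subgroup ids, columns = samples).
#' @param ann `subgroup_annotations` covering the rows.
#' @return data.frame, one row per sample.
#' @export
diversity_summary <- function(m, ann) {
  idx <- match(rownames(m), ann$subgroup_id)
  if (anyNA(idx)) {
    stop("subgroup(s) missing from annotations: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ann <- ann[idx, , drop = FALSE]
  depth <- rank_depth(ann$consensus_rank)
  lin <- as.matrix(as.data.frame(ann)[TAXONOMIC_RANKS])
  has_ko <- lengths(ann$kos) > 0L
  present <- m > 0
  rows <- lapply(colnames(m), function(j) {
    p <- present[, j]
    row <- list(sample = j,
                n_subgroups_total = sum(p),
                n_bacterial = sum(p & ann$category == "microbial"),
                n_human = sum(p & ann$category == "human"),
                n_other = sum(p & !ann$category %in% c("microbial", "human")))
    for (r in seq_along(TAXONOMIC_RANKS)) {
      ok <- p & depth >= r
      row[[paste0("n_annotated_", TAXONOMIC_RANKS[r])]] <- sum(ok)
      row[[paste0("n_taxa_", TAXONOMIC_RANKS[r])]] <-
        length(unique(lin[ok, r]))
    }
    row$n_with_ko <- sum(p & has_ko)
    row$n_ko <- length(unique(unlist(ann$kos[p])))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
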