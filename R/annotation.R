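# Consensus taxonomic and functional annotation of protein subgroups.
# The per-protein annotations (best-hit taxonomy, KO assignments) are
# an upstream input; here they are combined per subgroup: the consensus
# lineage is the deepest rank at which every member agrees, and KO
# annotation is only granted to subgroups whose members reach a full
# species-level consensus (the functional gate).

lineage_matrix <- function(members, annotations) {
  idx <- match(members, annotations$accession)
  if (anyNA(idx)) {
    stop("no annotation for accession(s): ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(annotations)[idx, TAXONOMIC_RANKS,
                                            drop = FALSE])
  rownames(m) <- members
  m
}

#' Consensus lineage of a protein subgroup
#'
#' The consensus rank is the deepest taxonomic rank at which every
#' member's annotation is present and identical (string comparison
#' after whitespace trimming, case-sensitive).  If members disagree at
#' superkingdom, or any member is unannotated there, the consensus rank
#' is `"none"`.
#'
#' @param members character vector of member accessions.
#' @param annotations a `protein_annotations` table covering them.
#' @return list with `consensus_rank` (`"none"` or a rank name) and
#'   `lineage` (named character vector over the seven ranks, `NA` below
#'   the consensus rank).
#' @export
consensus_lineage <- function(members, annotations) {
  m <- lineage_matrix(members, annotations)
  lineage <- stats::setNames(rep(NA_character_, length(TAXONOMIC_RANKS)),
                             TAXONOMIC_RANKS)
  rank <- "none"
  for (r in TAXONOMIC_RANKS) {
    vals <- m[, r]
    if (anyNA(vals) || length(unique(vals)) != 1L) break
    lineage[r] <- vals[1L]
    rank <- r
  }
  list(consensus_rank = rank, lineage = lineage)
}

#' KO union of a protein subgroup
#'
#' Returns all KEGG Orthology entries assigned to any member protein
#' (when a protein carries several functions, all are kept).  Under the
#' functional gate (the default) the union is only returned when the
#' subgroup reaches a species-level taxonomic consensus; otherwise the
#' empty set.
#'
#' @param members member accessions.
#' @param annotations a `protein_annotations` table.
#' @param gate apply the species-consensus gate (default TRUE).
#' @return character vector of KO identifiers (possibly empty).
#' @export
ko_union <- function(members, annotations, gate = TRUE) {
  if (gate &&
      consensus_lineage(members, annotations)$consensus_rank != "species") {
    return(character(0))
  }
  idx <- match(members, annotations$accession)
  if (anyNA(idx)) {
    stop("no annotation for accession(s): ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sort(unique(unlist(annotations$kos[idx])))
}

#' Annotate every subgroup of an inference result
#'
#' @param inference an `inference_result`.
#' @param annotations a `protein_annotations` table covering every
#'   member accession (see [resolve_annotations()]).
#' @return a data.frame of class `subgroup_annotations`: one row per
#'   subgroup with `subgroup_id`, `consensus_rank`, the seven rank
#'   columns (filled down to the consensus rank), `category`
#'   (`"human"` when all members are human, `"microbial"` when all are
#'   microbial, `"other"` otherwise), `is_human`, `n_members` and a
#'   `kos` list column (empty unless the species gate passes).
#' @export
annotate_subgroups <- function(inference, annotations) {
  stopifnot(inherits(inference, "inference_result"))
  subs <- inference$subgroups
  rows <- lapply(subs, function(s) {
    cons <- consensus_lineage(s$members, annotations)
    idx <- match(s$members, annotations$accession)
    src <- annotations$source[idx]
    category <- if (all(src == "human")) "human"
                else if (all(src == "microbial")) "microbial"
                else "other"
    kos <- if (cons$consensus_rank == "species") {
      sort(unique(unlist(annotations$kos[idx])))
    } else character(0)
    c(list(subgroup_id = s$subgroup_id,
           consensus_rank = cons$consensus_rank,
           category = category,
           is_human = category == "human",
           n_members = length(s$members)),
      as.list(cons$lineage),
      list(kos = list(kos)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[setdiff(names(r), "kos")], stringsAsFactors = FALSE)))
  if (is.null(out)) {
    out <- data.frame(subgroup_id = character(0))
  }
  out$kos <- lapply(rows, function(r) r$kos[[1L]])
  class(out) <- c("subgroup_annotations", "data.frame")
  out
}

#' Depth of a rank in the lineage (superkingdom = 1 ... species = 7;
#' "none" = 0).
#' @param rank character vector of rank names.
#' @return integer vector.
#' @export
rank_depth <- function(rank) {
  d <- match(rank, TAXONOMIC_RANKS)
  d[is.na(d) & rank == "none"] <- 0L
  if (anyNA(d)) {
    stop("unknown rank name(s): ",
         paste(unique(rank[is.na(d)]), collapse = ", "), call. = FALSE)
  }
  d
}

#' Write a subgroup annotation table
#' @param x a `subgroup_annotations` data.frame.
#' @param path output path.
#' @export
write_subgroup_annotations <- function(x, path) {
  df <- as.data.frame(x)
  df$kos <- join_list_field(x$kos)
  df[is.na(df)] <- ""
  write_table_plain(df, path)
}
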