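# Parsimony protein inference: collapse accessions with identical
# observed-peptide sets into subgroups ("metaproteins"), remove
# subgroups whose evidence is a strict subset of another's, and assign
# specific peptides.

#' Validate proteins by distinct-peptide support
#'
#' A protein accession is retained when at least `min_peptides`
#' distinct peptides matching it carry a non-zero spectral count
#' somewhere in the dataset (support is pooled across all samples).
#'
#' @param evidence an [evidence_table()].
#' @param min_peptides minimum number of distinct observed peptides
#'   required to validate a protein (default 2).
#' @return a list with `retained` (character vector of accessions) and
#'   `discarded` (named character vector accession -> reason).
#' @export
validate_proteins <- function(evidence, min_peptides = 2L) {
  stopifnot(inherits(evidence, "evidence_table"), min_peptides >= 1L)
  obs <- rowSums(evidence$counts) > 0L
  if (!any(obs)) {
    warning("no observed peptides in evidence; nothing to validate")
    return(list(retained = character(0), discarded = character(0)))
  }
  accs <- evidence$accessions[obs]
  support <- table(unlist(lapply(accs, unique)))
  retained <- sort(names(support)[support >= min_peptides])
  dropped <- sort(names(support)[support < min_peptides])
  discarded <- rep("too_few_peptides", length(dropped))
  names(discarded) <- dropped
  list(retained = retained, discarded = discarded)
}

#' Infer protein subgroups by parsimony
#'
#' Accessions identified by the same set of observed peptides are
#' indistinguishable and merged into one subgroup.  A subgroup whose
#' peptide set is a strict subset of another subgroup's is subsumed
#' (principle of parsimony) and removed.  Peptides occurring in exactly
#' one surviving subgroup are that subgroup's specific peptides;
#' subgroups left without any specific peptide are removed and
#' specificity is recomputed over the survivors (`drop_passes` controls
#' how many removal passes run; one by default).
#'
#' @param evidence an [evidence_table()].
#' @param validation result of [validate_proteins()], or a character
#'   vector of retained accessions.
#' @param drop_passes number of no-specific-peptide removal passes.
#' @return an `inference_result`: list with `subgroups` (each a list
#'   with `subgroup_id`, `group_id`, `members`, `peptides`,
#'   `specific_peptides`) and `discarded` (named character vector
#'   accession -> reason).  Ids are assigned by [assign_ids()], which
#'   is called automatically.
#' @export
infer_subgroups <- function(evidence, validation = validate_proteins(evidence),
                            drop_passes = 1L) {
  stopifnot(inherits(evidence, "evidence_table"))
  if (is.character(validation)) {
    validation <- list(retained = validation, discarded = character(0))
  }
  retained <- validation$retained
  discarded <- validation$discarded
  if (!length(retained)) {
    res <- structure(list(subgroups = list(), discarded = discarded),
                     class = "inference_result")
    return(assign_ids(res))
  }

  obs <- rowSums(evidence$counts) > 0L
  pep <- evidence$peptide[obs]
  accs <- evidence$accessions[obs]
  pairs_acc <- unlist(accs, use.names = FALSE)
  pairs_pep <- rep.int(pep, lengths(accs))
  keep <- pairs_acc %in% retained
  pairs_acc <- pairs_acc[keep]
  pairs_pep <- pairs_pep[keep]

  pep_levels <- sort(unique(pairs_pep))
  pep_idx <- match(pairs_pep, pep_levels)
  acc_sets <- split(pep_idx, pairs_acc)
  acc_sets <- lapply(acc_sets, function(v) sort(unique(v)))

  # 1. merge accessions with identical observed-peptide sets
  key <- vapply(acc_sets, paste, character(1), collapse = ",")
  members <- split(names(acc_sets), key)
  sets <- lapply(acc_sets[vapply(members, `[`, character(1), 1L)],
                 identity)
  names(sets) <- NULL
  members <- unname(members)

  # 2. strict-subset subsumption: because equal sets are already
  # merged, a single pass removing every subgroup that is a strict
  # subset of any other reaches the fixpoint (subset is transitive).
  sizes <- lengths(sets)
  n_sub <- length(sets)
  inc <- Matrix::sparseMatrix(i = unlist(sets),
                              j = rep.int(seq_len(n_sub), sizes),
                              x = 1,
                              dims = c(length(pep_levels), n_sub))
  shared <- as(as(Matrix::crossprod(inc), "generalMatrix"), "TsparseMatrix")
  tri <- data.frame(i = shared@i + 1L, j = shared@j + 1L, x = shared@x)
  tri <- tri[tri$i != tri$j, , drop = FALSE]
  subset_of <- tri$x == sizes[tri$i] & sizes[tri$i] < sizes[tri$j]
  subsumed <- unique(tri$i[subset_of])
  if (length(subsumed)) {
    for (k in subsumed) {
      d <- rep("subsumed", length(members[[k]]))
      names(d) <- members[[k]]
      discarded <- c(discarded, d)
    }
    keep_idx <- setdiff(seq_len(n_sub), subsumed)
    sets <- sets[keep_idx]
    members <- members[keep_idx]
  }

  # 3-5. specific peptides; drop subgroups without any, then recompute
  specific_of <- function(sets) {
    if (!length(sets)) return(list())
    deg <- tabulate(unlist(sets), nbins = length(pep_levels))
    lapply(sets, function(s) s[deg[s] == 1L])
  }
  spec <- specific_of(sets)
  passes <- 0L
  while (passes < drop_passes) {
    empty <- which(lengths(spec) == 0L)
    if (!length(empty)) break
    for (k in empty) {
      d <- rep("no_specific_peptide", length(members[[k]]))
      names(d) <- members[[k]]
      discarded <- c(discarded, d)
    }
    keep_idx <- setdiff(seq_along(sets), empty)
    sets <- sets[keep_idx]
    members <- members[keep_idx]
    spec <- specific_of(sets)
    passes <- passes + 1L
  }

  # connected components of the surviving subgroup-peptide graph
  comp <- rep(1L, length(sets))
  if (length(sets) > 1L) {
    sizes <- lengths(sets)
    inc <- Matrix::sparseMatrix(i = unlist(sets),
                                j = rep.int(seq_along(sets), sizes),
                                x = 1,
                                dims = c(length(pep_levels), length(sets)))
    adj <- Matrix::crossprod(inc)
    g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
  }

  subgroups <- lapply(seq_along(sets), function(k) {
    list(subgroup_id = NA_character_,
         group_id = NA_character_,
         component = as.integer(comp[k]),
         members = sort(members[[k]]),
         peptides = pep_levels[sets[[k]]],
         specific_peptides = pep_levels[spec[[k]]])
  })
  res <- structure(list(subgroups = subgroups, discarded = discarded),
                   class = "inference_result")
  assign_ids(res)
}

#' Assign deterministic subgroup and group identifiers
#'
#' Groups (connected components of the subgroup-peptide graph) are
#' sorted by descending number of distinct peptides, ties broken by the
#' lexicographically smallest member accession, and named `g0001`,
#' `g0002`, ...  Subgroups within a group are sorted the same way and
#' named `g0001.s01`, ...  The assignment is a pure function of the
#' inference result, hence stable across reruns on identical input.
#'
#' @param result an `inference_result`.
#' @return the result with `group_id`/`subgroup_id` filled in and
#'   subgroups ordered by id.
#' @export
assign_ids <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  subs <- result$subgroups
  if (!length(subs)) return(result)
  comp <- vapply(subs, `[[`, integer(1), "component")
  npep_grp <- tapply(subs, comp, function(ss)
    length(unique(unlist(lapply(ss, `[[`, "peptides")))))
  minacc_grp <- tapply(subs, comp, function(ss)
    min(unlist(lapply(ss, `[[`, "members"))))
  comp_levels <- as.integer(names(npep_grp))
  ord <- order(-unlist(npep_grp), unlist(minacc_grp))
  grp_rank <- integer(max(comp_levels))
  grp_rank[comp_levels[ord]] <- seq_along(ord)
  gw <- max(4L, nchar(length(comp_levels)))
  sw <- max(2L, nchar(max(tabulate(comp))))
  npep <- vapply(subs, function(s) length(s$peptides), integer(1))
  minacc <- vapply(subs, function(s) min(s$members), character(1))
  sub_order <- order(grp_rank[comp], -npep, minacc)
  counter <- integer(length(comp_levels))
  subs <- subs[sub_order]
  for (k in seq_along(subs)) {
    g <- grp_rank[subs[[k]]$component]
    counter[g] <- counter[g] + 1L
    subs[[k]]$group_id <- sprintf("g%0*d", gw, g)
    subs[[k]]$subgroup_id <- sprintf("g%0*d.s%0*d", gw, g, sw, counter[g])
  }
  result$subgroups <- subs
  result
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("inference_result: %d subgroups, %d discarded accessions\n",
              length(x$subgroups), length(x$discarded)))
  invisible(x)
}

#' Tabulate an inference result
#'
#' @param result an `inference_result`.
#' @return data.frame with one row per subgroup (members, peptides and
#'   specific peptides semicolon-joined).
#' @export
subgroups_table <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  subs <- result$subgroups
  data.frame(
    subgroup_id = vapply(subs, `[[`, character(1), "subgroup_id"),
    group_id = vapply(subs, `[[`, character(1), "group_id"),
    members = vapply(subs, function(s) paste(s$members, collapse = ";"),
                     character(1)),
    n_peptides = vapply(subs, function(s) length(s$peptides), integer(1)),
    peptides = vapply(subs, function(s) paste(sort(s$peptides),
                                              collapse = ";"), character(1)),
    specific_peptides = vapply(subs, function(s)
      paste(sort(s$specific_peptides), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Tabulate the discard ledger of an inference result
#' @param result an `inference_result`.
#' @return data.frame with columns `accession` and `reason`.
#' @export
discarded_table <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  d <- result$discarded
  data.frame(accession = names(d), reason = unname(d),
             stringsAsFactors = FALSE)[order(names(d)), , drop = FALSE]
}
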