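# Strict all-samples dominance screen between clinical groups -- the
# biomarker discovery engine.  A subgroup is a hit for contrast (A, B)
# when every sample of A strictly exceeds (or strictly falls below)
# every sample of B; ties never qualify, so a subgroup absent from
# both sides can never be a hit.

#' Define a two-sided sample contrast
#'
#' @param name contrast name.
#' @param side_a,side_b disjoint, non-empty sets of sample ids.  Fresh
#'   and frozen samples of a subject enter as ordinary members of the
#'   side they belong to (pooled preparations).
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(name, side_a, side_b) {
  side_a <- unique(as.character(side_a))
  side_b <- unique(as.character(side_b))
  if (!length(side_a) || !length(side_b)) {
    stop("contrast '", name, "': both sides must be non-empty",
         call. = FALSE)
  }
  if (length(intersect(side_a, side_b))) {
    stop("contrast '", name, "': sides overlap: ",
         paste(intersect(side_a, side_b), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, side_a = side_a, side_b = side_b),
            class = "contrast_spec")
}

#' Strict dominance screen for one contrast
#'
#' @param m abundance matrix (rows = subgroup ids, columns = samples);
#'   raw per-sample specific spectral counts.
#' @param spec a [contrast_spec()] whose samples are all columns of `m`.
#' @return data.frame of hits: `subgroup_id`, `contrast`, `direction`
#'   (`over_in_A` when min over A strictly exceeds max over B,
#'   `under_in_A` when max over A is strictly below min over B),
#'   `min_a`, `max_a`, `min_b`, `max_b`.
#' @export
strict_contrast <- function(m, spec) {
  stopifnot(inherits(spec, "contrast_spec"))
  missing <- setdiff(c(spec$side_a, spec$side_b), colnames(m))
  if (length(missing)) {
    stop("contrast '", spec$name, "': samples absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  A <- m[, spec$side_a, drop = FALSE]
  B <- m[, spec$side_b, drop = FALSE]
  min_a <- apply(A, 1L, min); max_a <- apply(A, 1L, max)
  min_b <- apply(B, 1L, min); max_b <- apply(B, 1L, max)
  over <- min_a > max_b
  under <- max_a < min_b
  hit <- over | under
  out <- data.frame(
    subgroup_id = rownames(m)[hit],
    contrast = rep(spec$name, sum(hit)),
    direction = c("under_in_A", "over_in_A")[over[hit] + 1L],
    min_a = min_a[hit], max_a = max_a[hit],
    min_b = min_b[hit], max_b = max_b[hit],
    stringsAsFactors = FALSE)
  out <- out[order(out$direction, out$subgroup_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

samples_of <- function(sheet, groups) {
  sheet$sample[sheet$group %in% groups]
}

#' Iterative biomarker screen across clinical groups
#'
#' Runs the staged screening strategy on the full subgroup set (stages
#' are independent screens, not residual filters):
#' \describe{
#'   \item{ibd_vs_ctrl}{all IBD samples (CDC + CDIC + UC) versus all
#'     controls.}
#'   \item{cdic_vs_other_ibd}{CDIC versus the pooled other IBD
#'     phenotypes (CDC + UC); each hit is additionally annotated with
#'     whether it also dominates CDIC versus everything else including
#'     the controls (`also_vs_ctrl`).}
#'   \item{cdc_vs_uc}{CDC versus UC.}
#' }
#'
#' @param m abundance matrix of raw per-sample specific spectral
#'   counts.
#' @param sheet a `sample_sheet`; stages whose groups are absent are
#'   skipped with a warning.
#' @param stages subset of the stage names above, in screening order.
#' @return data.frame of hits with columns `stage`, those of
#'   [strict_contrast()], and `also_vs_ctrl` (logical, `NA` outside
#'   the CDIC stage).
#' @export
iterative_screen <- function(m, sheet,
                             stages = c("ibd_vs_ctrl", "cdic_vs_other_ibd",
                                        "cdc_vs_uc")) {
  stages <- match.arg(stages, several.ok = TRUE)
  sheet <- sheet[sheet$sample %in% colnames(m), , drop = FALSE]
  have <- function(g) any(sheet$group %in% g)
  need <- list(ibd_vs_ctrl = c("CDC", "CDIC", "UC", "CTRL"),
               cdic_vs_other_ibd = c("CDIC", "CDC", "UC"),
               cdc_vs_uc = c("CDC", "UC"))
  out <- list()
  for (stage in stages) {
    absent <- need[[stage]][!vapply(need[[stage]], have, logical(1))]
    if (length(absent)) {
      warning("stage ", stage, " skipped; group(s) absent: ",
              paste(absent, collapse = ", "))
      next
    }
    spec <- switch(stage,
      ibd_vs_ctrl = contrast_spec(stage,
        samples_of(sheet, c("CDC", "CDIC", "UC")),
        samples_of(sheet, "CTRL")),
      cdic_vs_other_ibd = contrast_spec(stage,
        samples_of(sheet, "CDIC"),
        samples_of(sheet, c("CDC", "UC"))),
      cdc_vs_uc = contrast_spec(stage,
        samples_of(sheet, "CDC"),
        samples_of(sheet, "UC")))
    hits <- strict_contrast(m, spec)
    hits$stage <- rep(stage, nrow(hits))
    hits$also_vs_ctrl <- rep(NA, nrow(hits))
    if (stage == "cdic_vs_other_ibd" && nrow(hits) &&
        have("CTRL")) {
      wide <- strict_contrast(m, contrast_spec(
        "cdic_vs_all_others",
        samples_of(sheet, "CDIC"),
        samples_of(sheet, c("CDC", "UC", "CTRL"))))
      key <- paste(wide$subgroup_id, wide$direction)
      hits$also_vs_ctrl <- paste(hits$subgroup_id, hits$direction) %in% key
    }
    out[[stage]] <- hits
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(subgroup_id = character(0), contrast = character(0),
                      direction = character(0), min_a = numeric(0),
                      max_a = numeric(0), min_b = numeric(0),
                      max_b = numeric(0), stage = character(0),
                      also_vs_ctrl = logical(0))
  }
  res <- res[c("stage", setdiff(names(res), "stage"))]
  rownames(res) <- NULL
  res
}

#' Heatmap-ready export of hit abundances
#'
#' Log-transforms (natural log after adding a pseudocount) and
#' zero-centres every row by subtracting its mean, the standard
#' visual normalization for spectral-count heatmaps.
#'
#' @param m abundance matrix.
#' @param hits optional hit table from [iterative_screen()] or
#'   [strict_contrast()]; when given, rows are restricted to the hits
#'   and ordered by stage, then direction, then subgroup id (row names
#'   become `stage|subgroup_id` when a stage column is present).
#' @param pseudocount added before the log (default 1).
#' @return real matrix of row-centred log counts.
#' @export
heatmap_export <- function(m, hits = NULL, pseudocount = 1) {
  if (!is.null(hits)) {
    if (!nrow(hits)) stop("empty hit list", call. = FALSE)
    if ("stage" %in% names(hits)) {
      ord <- order(hits$stage, hits$direction, hits$subgroup_id)
      hits <- hits[ord, , drop = FALSE]
      m <- m[hits$subgroup_id, , drop = FALSE]
      rownames(m) <- paste(hits$stage, hits$subgroup_id, sep = "|")
    } else {
      ord <- order(hits$direction, hits$subgroup_id)
      m <- m[hits$subgroup_id[ord], , drop = FALSE]
    }
  }
  x <- log(m + pseudocount)
  x - rowMeans(x)
}

#' Proteotypic biomarker report
#'
#' One row per hit: its specific (proteotypic) peptides ranked by
#' total spectral count (descending, lexicographic tie-break), the
#' consensus annotation when available, and per-group mean abundances
#' -- the payload of a diagnostic decision tree.
#'
#' @param hits hit table from [iterative_screen()]/[strict_contrast()].
#' @param inference the `inference_result` that produced the hits.
#' @param evidence the [evidence_table()] behind the counts.
#' @param ann optional `subgroup_annotations`.
#' @param sheet optional `sample_sheet`; adds `mean_<group>` columns.
#' @return data.frame with exactly `nrow(hits)` rows.
#' @export
proteotypic_report <- function(hits, inference, evidence, ann = NULL,
                               sheet = NULL) {
  ids <- vapply(inference$subgroups, `[[`, character(1), "subgroup_id")
  idx <- match(hits$subgroup_id, ids)
  if (anyNA(idx)) {
    stop("hit subgroup(s) missing from inference: ",
         paste(hits$subgroup_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  totals <- rowSums(evidence$counts)
  ranked <- vapply(idx, function(k) {
    p <- inference$subgroups[[k]]$specific_peptides
    t <- totals[match(p, evidence$peptide)]
    paste(p[order(-t, p)], collapse = ";")
  }, character(1))
  out <- hits
  out$members <- vapply(idx, function(k)
    paste(inference$subgroups[[k]]$members, collapse = ";"), character(1))
  out$n_specific_peptides <- vapply(idx, function(k)
    length(inference$subgroups[[k]]$specific_peptides), integer(1))
  out$proteotypic_peptides <- ranked
  if (!is.null(ann)) {
    aidx <- match(hits$subgroup_id, ann$subgroup_id)
    out$consensus_rank <- ann$consensus_rank[aidx]
    out$taxon <- vapply(aidx, function(a) {
      if (is.na(a) || ann$consensus_rank[a] == "none") return("")
      as.character(as.data.frame(ann)[a, ann$consensus_rank[a]])
    }, character(1))
    out$kos <- join_list_field(ann$kos[aidx])
  }
  if (!is.null(sheet)) {
    ab <- subgroup_abundance(evidence, inference)
    gm <- normalize_by_group_size(ab[hits$subgroup_id, , drop = FALSE],
                                  sheet)
    colnames(gm) <- paste0("mean_", colnames(gm))
    out <- cbind(out, as.data.frame(gm, row.names = NULL))
  }
  rownames(out) <- NULL
  out
}
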