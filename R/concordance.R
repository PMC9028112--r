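# Fresh/frozen concordance QC and group-comparison statistics.

#' Pearson correlation matrix between sample profiles
#'
#' Correlates the full subgroup-abundance vectors of every pair of
#' samples.  Computed on raw counts by default; `log1p` transforms the
#' matrix first.  Zero-variance samples have undefined correlations:
#' their off-diagonal entries are `NA` and they are listed in the
#' `zero_variance` attribute.
#'
#' @param m abundance matrix (columns = samples, at least two).
#' @param log1p apply `log(1 + x)` before correlating (default FALSE).
#' @return square symmetric matrix of Pearson r with unit diagonal and
#'   attribute `zero_variance`.
#' @export
pearson_matrix <- function(m, log1p = FALSE) {
  if (ncol(m) < 2L) stop("need at least two samples", call. = FALSE)
  x <- if (log1p) log1p(m) else m
  sds <- apply(x, 2L, stats::sd)
  zv <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  attr(r, "zero_variance") <- zv
  r
}

#' Flag discordant fresh/frozen pairs
#'
#' Looks up, for every subject with both preparations among the
#' correlated samples, the Pearson r between its fresh and frozen
#' profiles, and flags pairs at or below the threshold (the study's
#' working definition of concordance is r > 0.9).
#'
#' @param corr correlation matrix from [pearson_matrix()].
#' @param sheet a `sample_sheet`.
#' @param threshold flag pairs with r <= threshold (default 0.9).
#' @return data.frame with one row per paired subject: `subject`,
#'   `sample_fresh`, `sample_frozen`, `r`, `flagged`.  Subjects without
#'   both preparations are skipped with a warning.
#' @export
flag_discordant_pairs <- function(corr, sheet, threshold = 0.9) {
  sheet <- sheet[sheet$sample %in% colnames(corr), , drop = FALSE]
  subjects <- sort(unique(sheet$subject))
  rows <- list()
  unpaired <- character(0)
  for (s in subjects) {
    sf <- sheet$sample[sheet$subject == s & sheet$preparation == "fresh"]
    sc <- sheet$sample[sheet$subject == s & sheet$preparation == "frozen"]
    if (length(sf) != 1L || length(sc) != 1L) {
      unpaired <- c(unpaired, s)
      next
    }
    r <- corr[sf, sc]
    rows[[s]] <- data.frame(subject = s, sample_fresh = sf,
                            sample_frozen = sc, r = r,
                            flagged = !is.na(r) && r <= threshold,
                            stringsAsFactors = FALSE)
  }
  if (length(unpaired)) {
    warning("subject(s) without a fresh/frozen pair skipped: ",
            paste(unpaired, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject = character(0), sample_fresh = character(0),
                      sample_frozen = character(0), r = numeric(0),
                      flagged = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Agglomerative clustering of samples from their correlations
#'
#' Average-linkage clustering on the distance d = 1 - r.  Samples are
#' ordered by id before clustering so the merge tree does not depend
#' on input column order.
#'
#' @param corr complete correlation matrix (no missing values).
#' @return list with `hclust` (the merge tree) and `newick` (the same
#'   tree as a Newick string, branch lengths from merge heights).
#' @export
cluster_samples <- function(corr) {
  if (anyNA(corr)) stop("missing correlations; cannot cluster",
                        call. = FALSE)
  ord <- order(colnames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = "average")
  nw <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nw)
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' For every metric column, runs a two-sided Wilcoxon rank-sum test for
#' every pair of clinical groups, then applies the Benjamini-Hochberg
#' step-up adjustment within that metric's family of pairwise
#' comparisons.  The exact null distribution is used when both arms
#' have at most `exact_max_n` observations and the data are tie-free;
#' otherwise the normal approximation with tie correction and without
#' continuity correction.
#'
#' @param metrics data.frame of per-sample metrics; sample ids either
#'   in a `sample` column or as row names, all other columns numeric.
#' @param sheet a `sample_sheet` mapping samples to clinical groups.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param exact_max_n largest per-arm n for the exact test (default 25).
#' @return data.frame with one row per (metric, group pair): `metric`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `statistic` (rank-sum W of
#'   the first group), `p_value`, `p_adjusted`, `significant`.
#' @export
wilcoxon_bh <- function(metrics, sheet, alpha = 0.05, exact_max_n = 25L) {
  metrics <- as.data.frame(metrics)
  if ("sample" %in% names(metrics)) {
    ids <- as.character(metrics$sample)
    metrics <- metrics[setdiff(names(metrics), "sample")]
  } else {
    ids <- rownames(metrics)
  }
  grp <- sheet$group[match(ids, sheet$sample)]
  if (anyNA(grp)) {
    stop("metric sample(s) absent from sample sheet: ",
         paste(ids[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  groups <- CLINICAL_GROUPS[CLINICAL_GROUPS %in% grp]
  if (length(groups) < 2L) stop("need at least two clinical groups",
                                call. = FALSE)
  pairs <- utils::combn(groups, 2L)
  out <- list()
  for (metric in names(metrics)) {
    v <- as.numeric(metrics[[metric]])
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      x <- v[grp == a & !is.na(v)]
      y <- v[grp == b & !is.na(v)]
      if (!length(x) || !length(y)) {
        return(data.frame(metric = metric, group_a = a, group_b = b,
                          n_a = length(x), n_b = length(y),
                          statistic = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE))
      }
      exact <- max(length(x), length(y)) <= exact_max_n
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = FALSE))
      data.frame(metric = metric, group_a = a, group_b = b,
                 n_a = length(x), n_b = length(y),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_adjusted <- stats::p.adjust(fam$p_value, method = "BH")
    fam$significant <- !is.na(fam$p_adjusted) & fam$p_adjusted < alpha
    out[[metric]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
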