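# Reading/writing the pipeline's tabular artifacts.  All files are
# UTF-8, tab-separated, '#' starts a comment line, ';' separates list
# values (accessions, KO identifiers).

read_table_raw <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_table_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

split_list_field <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    unique(v[nzchar(v)])
  })
}

join_list_field <- function(x) {
  vapply(x, function(v) paste(sort(v), collapse = ";"), character(1))
}

#' Construct a peptide-evidence table
#'
#' The evidence table is the pipeline's raw input: one row per observed
#' peptide, the set of protein accessions the peptide matches, and its
#' spectral count in every sample.
#'
#' @param peptide character vector of peptide sequences (unique).
#' @param accessions list of character vectors, one non-empty set of
#'   matched protein accessions per peptide.
#' @param counts integer matrix of spectral counts, one row per peptide
#'   and one column per sample; column names are sample ids.
#' @return an object of class `evidence_table` with elements `peptide`,
#'   `accessions` and `counts` (rows named by peptide).
#' @export
evidence_table <- function(peptide, accessions, counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop("count matrix must have sample-id column names", call. = FALSE)
  }
  peptide <- as.character(peptide)
  if (length(peptide) != nrow(counts) || length(accessions) != nrow(counts)) {
    stop("peptide, accessions and counts disagree in length", call. = FALSE)
  }
  if (anyDuplicated(peptide)) {
    stop("duplicate peptide sequences: ",
         paste(unique(peptide[duplicated(peptide)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0)
  if (length(bad)) {
    stop("negative or missing spectral counts in rows: ",
         paste(unique(((bad - 1L) %% nrow(counts)) + 1L), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  empty <- which(lengths(accessions) == 0L)
  if (length(empty)) {
    stop("empty accession set in rows: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  allzero <- which(rowSums(counts) == 0L)
  if (length(allzero)) {
    stop("rows with zero counts in every sample: ",
         paste(allzero, collapse = ", "), call. = FALSE)
  }
  rownames(counts) <- peptide
  structure(list(peptide = peptide,
                 accessions = lapply(accessions, as.character),
                 counts = counts),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("evidence_table: %d peptides x %d samples, %d accessions\n",
              length(x$peptide), ncol(x$counts),
              length(unique(unlist(x$accessions)))))
  invisible(x)
}

#' Read a peptide-evidence table
#'
#' Expects tab-separated text with a header line naming the columns
#' `peptide`, `accessions` (semicolon-joined) and then one column per
#' sample.  Duplicate peptide rows are merged by summing their counts
#' and taking the union of their accession sets.
#'
#' @param path path to the evidence TSV.
#' @return an [evidence_table()].
#' @export
read_evidence <- function(path) {
  df <- read_table_raw(path)
  need <- c("peptide", "accessions")
  if (!all(need %in% names(df))) {
    stop("evidence file ", path, " misses required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(df), need)
  if (!length(samples)) {
    stop("evidence file ", path, " has no sample columns", call. = FALSE)
  }
  counts <- as.matrix(df[samples])
  if (!is.numeric(counts)) {
    stop("non-numeric spectral counts in ", path, call. = FALSE)
  }
  bad <- which(rowSums(!is.finite(counts) | counts < 0) > 0)
  if (length(bad)) {
    stop("negative or missing counts in ", path, ", rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  accessions <- split_list_field(df$accessions)
  empty <- which(lengths(accessions) == 0L)
  if (length(empty)) {
    stop("empty accession field in ", path, ", rows: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  peptide <- as.character(df$peptide)
  if (anyDuplicated(peptide)) {
    counts <- rowsum(counts, group = peptide, reorder = FALSE)
    accs <- tapply(accessions, peptide, function(a) unique(unlist(a)),
                   simplify = FALSE)
    peptide <- rownames(counts)
    accessions <- unname(accs[peptide])
  }
  keep <- rowSums(counts) > 0
  evidence_table(peptide[keep], accessions[keep],
                 counts[keep, , drop = FALSE])
}

#' Write a peptide-evidence table
#'
#' @param x an [evidence_table()].
#' @param path output path; same dialect as [read_evidence()].
#' @export
write_evidence <- function(x, path) {
  stopifnot(inherits(x, "evidence_table"))
  df <- data.frame(peptide = x$peptide,
                   accessions = join_list_field(x$accessions),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_plain(df, path)
}

#' Read per-protein annotations
#'
#' One row per accession: `accession`, `source` (microbial, human or
#' contaminant), the seven taxonomic ranks from superkingdom to species
#' (empty cells for unassigned ranks) and a semicolon-joined `kos`
#' column of KEGG Orthology identifiers.  Lineages must be filled
#' prefix-wise: a rank may only be present if every shallower rank is.
#'
#' @param path path to the annotation TSV.
#' @return a data.frame of class `protein_annotations` with one row per
#'   accession; the `kos` column is a list of character vectors.
#' @export
read_annotations <- function(path) {
  df <- read_table_raw(path)
  need <- c("accession", "source", TAXONOMIC_RANKS, "kos")
  if (!all(need %in% names(df))) {
    stop("annotation file ", path, " misses required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  protein_annotations(df$accession, df$source,
                      df[TAXONOMIC_RANKS], split_list_field(df$kos))
}

#' Construct a per-protein annotation table
#'
#' @param accession character vector of accessions (unique).
#' @param source one of `r toString(PROTEIN_SOURCES)` per accession.
#' @param lineage data.frame with the seven rank columns (strings; ""
#'   or NA for unassigned).
#' @param kos list of character vectors of KO identifiers.
#' @return a `protein_annotations` data.frame.
#' @export
protein_annotations <- function(accession, source, lineage, kos = NULL) {
  accession <- as.character(accession)
  if (anyDuplicated(accession)) {
    stop("duplicate accessions in annotation table", call. = FALSE)
  }
  source <- as.character(source)
  bad <- which(!source %in% PROTEIN_SOURCES)
  if (length(bad)) {
    stop("unknown source label(s) ",
         paste(unique(source[bad]), collapse = ", "),
         "; allowed: ", paste(PROTEIN_SOURCES, collapse = ", "),
         call. = FALSE)
  }
  lin <- as.data.frame(lineage, stringsAsFactors = FALSE)
  names(lin) <- TAXONOMIC_RANKS
  for (r in TAXONOMIC_RANKS) {
    lin[[r]] <- trimws(as.character(lin[[r]]))
    lin[[r]][!nzchar(lin[[r]]) | is.na(lin[[r]])] <- NA_character_
  }
  filled <- !is.na(as.matrix(lin))
  # prefix-wise: no rank present after a gap
  gap <- apply(filled, 1L, function(f) any(diff(as.integer(f)) > 0L))
  if (any(gap)) {
    stop("lineage gap (deep rank present with a shallower rank absent) ",
         "for accession(s): ",
         paste(accession[gap], collapse = ", "), call. = FALSE)
  }
  if (is.null(kos)) kos <- rep(list(character(0)), length(accession))
  kos <- lapply(kos, function(k) sort(unique(as.character(k))))
  out <- data.frame(accession = accession, source = source, lin,
                    stringsAsFactors = FALSE)
  out$kos <- kos
  class(out) <- c("protein_annotations", "data.frame")
  out
}

#' Write a per-protein annotation table
#' @param x a `protein_annotations` data.frame.
#' @param path output path.
#' @export
write_annotations <- function(x, path) {
  df <- as.data.frame(x)
  df$kos <- join_list_field(x$kos)
  df[is.na(df)] <- ""
  write_table_plain(df, path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample`, `subject`, `group` (one of
#' `r toString(CLINICAL_GROUPS)`) and `preparation` (fresh or frozen).
#' A subject may contribute at most one sample per preparation and must
#' belong to a single clinical group.
#'
#' @param path path to the sample sheet TSV.
#' @return a validated `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_table_raw(path)
  need <- c("sample", "subject", "group", "preparation")
  if (!all(need %in% names(df))) {
    stop("sample sheet ", path, " misses required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  sample_sheet(df$sample, df$subject, df$group, df$preparation)
}

#' Construct and validate a sample sheet
#'
#' @param sample,subject,group,preparation character vectors of equal
#'   length describing one sample per element.
#' @return a `sample_sheet` data.frame.
#' @export
sample_sheet <- function(sample, subject, group, preparation) {
  df <- data.frame(sample = as.character(sample),
                   subject = as.character(subject),
                   group = as.character(group),
                   preparation = as.character(preparation),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  bad <- setdiff(df$group, CLINICAL_GROUPS)
  if (length(bad)) {
    stop("unknown clinical group label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CLINICAL_GROUPS, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(df$preparation, PREPARATIONS)
  if (length(bad)) {
    stop("unknown preparation label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(PREPARATIONS, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$subject, df$preparation, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$subject[duplicated(key)]
    stop("duplicate (subject, preparation) pair(s) for subject(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  ngrp <- tapply(df$group, df$subject, function(g) length(unique(g)))
  if (any(ngrp > 1L)) {
    stop("clinical group differs within subject(s): ",
         paste(names(ngrp)[ngrp > 1L], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @export
#' @rdname read_sample_sheet
#' @param x a `sample_sheet`.
write_sample_sheet <- function(x, path) {
  write_table_plain(as.data.frame(x), path)
}

#' Write / read a numeric matrix with row and column headers
#'
#' Round-trips bit-exactly for integer matrices and to at least 12
#' significant digits for real-valued ones.  Column names are sample
#' (or group) ids; row names identify subgroups, taxa, KOs, etc.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param sheet optional `sample_sheet`; when given, matrix column ids
#'   must all appear in the sheet.
#' @return `read_matrix` returns the matrix; `write_matrix` the path,
#'   invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  vals <- if (is.integer(m) || all(m == round(m))) {
    format(m, trim = TRUE, scientific = FALSE)
  } else {
    format(m, trim = TRUE, digits = 15)
  }
  df <- data.frame(id = rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(m))
  write_table_plain(df, path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, sheet = NULL) {
  df <- read_table_raw(path)
  if (names(df)[1] != "id") {
    stop("matrix file ", path, " must have leading 'id' column",
         call. = FALSE)
  }
  m <- as.matrix(df[-1])
  rownames(m) <- df$id
  if (!is.numeric(m)) stop("non-numeric matrix values in ", path,
                           call. = FALSE)
  if (!is.null(sheet)) {
    unknown <- setdiff(colnames(m), sheet$sample)
    if (length(unknown)) {
      stop("matrix columns absent from sample sheet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  m
}

#' Close evidence/annotation referential integrity
#'
#' Every accession occurring in the evidence must have an annotation
#' row.  Accessions without one are never dropped: they are added with
#' `source = "microbial"` and an empty lineage (so they can never reach
#' a taxonomic consensus) and listed in the `unannotated` attribute.
#'
#' @param evidence an [evidence_table()].
#' @param annotations a `protein_annotations` table.
#' @return the completed annotation table, with attribute
#'   `unannotated` holding the accessions that were filled in.
#' @export
resolve_annotations <- function(evidence, annotations) {
  accs <- sort(unique(unlist(evidence$accessions)))
  missing <- setdiff(accs, annotations$accession)
  if (length(missing)) {
    empty <- as.data.frame(matrix(NA_character_, length(missing),
                                  length(TAXONOMIC_RANKS)))
    names(empty) <- TAXONOMIC_RANKS
    extra <- protein_annotations(missing, rep("microbial", length(missing)),
                                 empty)
    out <- rbind(as.data.frame(annotations), as.data.frame(extra))
    out$kos <- c(annotations$kos, extra$kos)
    class(out) <- class(annotations)
  } else {
    out <- annotations
  }
  attr(out, "unannotated") <- missing
  out
}
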