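# PPR arrays and the amino-acid -> nucleotide recognition-code table.
#
# Each PPR motif contacts one RNA base; the identity of the amino acids at
# motif position 5 and at the motif's last position determines which base is
# preferred. The code table stores, per (aa5, aa_last) combination, a
# log-likelihood ratio for each of the four RNA bases. Combinations absent
# from the table (including the unknown amino acid 'X') score
# `default_score`, 0 by default -- the neutral log-likelihood for
# non-canonical combinations whose selectivity is not characterized.

#' Construct a PPR array
#'
#' A PPR editing factor is represented as an ordered list of motifs
#' (N-terminal to C-terminal), each carrying its class label and the amino
#' acids at positions 5 and last that determine base recognition.
#'
#' @param protein_id character scalar identifying the factor.
#' @param motifs data.frame with columns `motif_class`, `aa5`, `aa_last`
#'   (one-letter amino-acid codes, `X` for unknown) and optionally `index`
#'   (1-based N-to-C ordinal; defaults to row order).
#' @param scored logical vector, one element per motif, marking the motifs
#'   that contribute to alignment scores. `NULL` (default) means "every
#'   motif with an entry in the code table", resolved at scoring time.
#'
#' @return An object of class `ppr_array`.
#' @export
#' @examples
#' ppr_array("toy", data.frame(motif_class = c("P1", "S1"),
#'                             aa5 = c("T", "S"), aa_last = c("D", "N")))
ppr_array <- function(protein_id, motifs, scored = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  motifs <- as.data.frame(motifs)
  if (nrow(motifs) == 0L) stop("a PPR array needs at least one motif")
  req <- c("motif_class", "aa5", "aa_last")
  if (!all(req %in% names(motifs))) {
    stop("`motifs` must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(motifs$index)) motifs$index <- seq_len(nrow(motifs))
  if (any(motifs$index < 1L)) stop("motif index must be >= 1")
  motifs$aa5 <- toupper(motifs$aa5)
  motifs$aa_last <- toupper(motifs$aa_last)
  bad <- !(motifs$aa5 %in% AA_ALPHABET) | !(motifs$aa_last %in% AA_ALPHABET)
  if (any(bad)) {
    stop("invalid amino-acid code(s) in motifs: ",
         paste(unique(c(motifs$aa5[bad], motifs$aa_last[bad])), collapse = ", "))
  }
  if (!is.null(scored)) {
    scored <- as.logical(scored)
    if (length(scored) != nrow(motifs)) {
      stop("`scored` must have one element per motif")
    }
    if (!any(scored)) stop("at least one motif must be scored")
  }
  motifs <- motifs[order(motifs$index),
                   c("index", "motif_class", "aa5", "aa_last")]
  rownames(motifs) <- NULL
  structure(list(protein_id = protein_id, motifs = motifs, scored = scored),
            class = "ppr_array")
}

#' @export
print.ppr_array <- function(x, ...) {
  cat("PPR array ", x$protein_id, ": ", nrow(x$motifs), " motifs (",
      paste(x$motifs$motif_class, collapse = "-"), ")\n", sep = "")
  invisible(x)
}

#' Construct a recognition-code table
#'
#' @param entries data.frame with columns `aa5`, `aa_last`, `A`, `C`, `G`,
#'   `U` (log-likelihood ratios). May have zero rows.
#' @param default_score score returned for (aa5, aa_last) combinations absent
#'   from the table; default 0 (neutral log-likelihood).
#' @param metadata free-text source descriptor.
#'
#' @return An object of class `code_table`.
#' @export
code_table <- function(entries, default_score = 0, metadata = "") {
  entries <- as.data.frame(entries)
  req <- c("aa5", "aa_last", "A", "C", "G", "U")
  if (!all(req %in% names(entries))) {
    stop("code table needs columns: ", paste(req, collapse = ", "))
  }
  key <- paste(toupper(entries$aa5), toupper(entries$aa_last), sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (aa5, aa_last) entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  m <- as.matrix(entries[, RNA_BASES, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) > 0L && any(!is.finite(m))) stop("code-table scores must be finite")
  rownames(m) <- key
  structure(list(scores = m, default_score = as.numeric(default_score),
                 metadata = metadata),
            class = "code_table")
}

#' @export
print.code_table <- function(x, ...) {
  cat("PPR recognition-code table: ", nrow(x$scores), " (aa5, aa_last) entries, ",
      "default score ", x$default_score, "\n", sep = "")
  if (nzchar(x$metadata)) cat("  source: ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' Read a recognition-code table from TSV
#'
#' Expects a tab-separated file with header columns `aa5`, `aa_last`, `A`,
#' `C`, `G`, `U`; lines starting with `#` are ignored. Duplicate
#' (aa5, aa_last) keys are an error.
#'
#' @param path file path.
#' @param default_score,metadata passed to [code_table()].
#' @return A `code_table`.
#' @export
read_code_table <- function(path, default_score = 0, metadata = path) {
  if (!file.exists(path)) stop("code-table file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  req <- c("aa5", "aa_last", "A", "C", "G", "U")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("code-table file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("code-table file has no data rows: ", path)
    return(code_table(df, default_score, metadata))
  }
  for (b in RNA_BASES) {
    v <- suppressWarnings(as.numeric(df[[b]]))
    if (anyNA(v)) {
      stop("non-numeric score in column ", b, " at data row ",
           which(is.na(v))[1L], " of ", path)
    }
    df[[b]] <- v
  }
  code_table(df, default_score, metadata)
}

#' Write a recognition-code table to TSV
#'
#' Scores are written with enough digits to round-trip exactly through
#' [read_code_table()].
#'
#' @param table a `code_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(table, path) {
  stopifnot(inherits(table, "code_table"))
  key <- rownames(table$scores)
  df <- data.frame(
    aa5 = sub("\\|.*$", "", key),
    aa_last = sub("^.*\\|", "", key),
    stringsAsFactors = FALSE
  )
  if (nrow(table$scores) == 0L) df <- data.frame(aa5 = character(), aa_last = character())
  for (b in RNA_BASES) df[[b]] <- sprintf("%.17g", table$scores[, b])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Score matrix lookup for a set of (aa5, aa_last) pairs: returns an
# n x 4 matrix over A,C,G,U using default_score for absent keys and 'X'.
#' @noRd
.code_rows <- function(table, aa5, aa_last) {
  key <- paste(aa5, aa_last, sep = "|")
  out <- matrix(table$default_score, nrow = length(key), ncol = 4L,
                dimnames = list(NULL, RNA_BASES))
  hit <- key %in% rownames(table$scores) & aa5 != "X" & aa_last != "X"
  if (any(hit)) out[hit, ] <- table$scores[key[hit], , drop = FALSE]
  out
}

#' Score one motif against one base
#'
#' Returns the log-likelihood ratio the code table assigns to the pairing of
#' a motif's (aa5, aa_last) combination with an RNA base. `T` is accepted
#' and treated as `U`. Combinations absent from the table, or involving the
#' unknown amino acid `X`, score `table$default_score`.
#'
#' @param motif a one-row data.frame (or list) with `aa5` and `aa_last`.
#' @param base a single nucleotide in `A`, `C`, `G`, `U` (or `T`).
#' @param table a `code_table`.
#' @return A numeric scalar.
#' @export
motif_base_score <- function(motif, base, table) {
  stopifnot(inherits(table, "code_table"))
  b <- .check_base(base)
  if (length(b) != 1L) stop("`base` must be a single nucleotide")
  row <- .code_rows(table, toupper(motif$aa5), toupper(motif$aa_last))
  unname(row[1L, b])
}

# Resolve the scored-motif mask: explicit mask if the array carries one,
# otherwise every motif whose (aa5, aa_last) combination is in the table.
#' @noRd
.scored_mask <- function(array, table) {
  if (!is.null(array$scored)) return(array$scored)
  key <- paste(array$motifs$aa5, array$motifs$aa_last, sep = "|")
  mask <- key %in% rownames(table$scores) &
    array$motifs$aa5 != "X" & array$motifs$aa_last != "X"
  if (!any(mask)) mask[] <- TRUE  # degenerate table: score all at default
  mask
}

# Per-motif score matrix for the scored motifs (rows, N->C) over A,C,G,U.
#' @noRd
.array_score_matrix <- function(array, table) {
  m <- array$motifs[.scored_mask(array, table), , drop = FALSE]
  .code_rows(table, m$aa5, m$aa_last)
}

#' Most-preferred binding window of a PPR array
#'
#' For each scored motif (N- to C-terminal) returns the nucleotide with the
#' maximal code-table score; ties are broken alphabetically (A < C < G < U).
#' This is the inverse of alignment scoring and is used to plant synthetic
#' targets that are guaranteed to be the factor's best possible match.
#'
#' @param array a `ppr_array`.
#' @param table a `code_table`.
#' @return An RNA string (5' to 3') whose length equals the number of scored
#'   motifs.
#' @export
preferred_window <- function(array, table) {
  stopifnot(inherits(array, "ppr_array"), inherits(table, "code_table"))
  sm <- .array_score_matrix(array, table)
  paste(RNA_BASES[apply(sm, 1L, which.max)], collapse = "")
}

#' Read PPR arrays from TSV
#'
#' Expects columns `protein_id`, `index`, `motif_class`, `aa5`, `aa_last`
#' and optionally `scored` (0/1); `#` comment lines are ignored.
#'
#' @param path file path.
#' @return A named list of `ppr_array` objects.
#' @export
read_ppr_arrays <- function(path) {
  if (!file.exists(path)) stop("PPR-array file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("protein_id", "index", "motif_class", "aa5", "aa_last")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("PPR-array file missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$index), ]
    scored <- if ("scored" %in% names(d)) as.logical(d$scored) else NULL
    ppr_array(d$protein_id[1L],
              d[, c("index", "motif_class", "aa5", "aa_last")], scored)
  })
  out[unique(df$protein_id)]
}

#' Write PPR arrays to TSV
#'
#' @param arrays a `ppr_array` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppr_arrays <- function(arrays, path) {
  if (inherits(arrays, "ppr_array")) arrays <- list(arrays)
  rows <- do.call(rbind, lapply(arrays, function(a) {
    d <- a$motifs
    d$protein_id <- a$protein_id
    d$scored <- as.integer(if (is.null(a$scored)) rep(TRUE, nrow(d)) else a$scored)
    d[, c("protein_id", "index", "motif_class", "aa5", "aa_last", "scored")]
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
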