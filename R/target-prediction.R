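# Genome-wide candidate-site enumeration, alignment scoring and z-score
# ranking.
#
# Candidate editing sites are YC dinucleotides: a cytidine preceded
# (immediately 5') by a pyrimidine, on either strand. Each candidate
# carries the upstream window that the PPR array is aligned to; by the
# canonical PPR-code register the C-terminal-most scored motif sits at
# position -4 relative to the edited C (offset = 4), configurable.
# z-scores are computed per factor against the full population of candidate
# alignments (divide-by-n standard deviation), so a factor's z-scores over
# all its candidates have mean 0 and population SD 1 by construction.

# Window of `window_len` bases ending `offset` bases 5' of position `p` on
# the given strand, as characters of the transcript strand (5'->3', DNA
# alphabet, 'N' for positions beyond the sequence end unless `circular`).
#' @noRd
.window_at <- function(bases, p, strand, window_len, offset, circular = FALSE) {
  n <- length(bases)
  if (strand == "+") {
    idx <- (p - offset - window_len + 1L):(p - offset)
  } else {
    idx <- (p + offset + window_len - 1L):(p + offset)
  }
  if (circular) {
    w <- bases[((idx - 1L) %% n) + 1L]
  } else {
    w <- rep("N", length(idx))
    ok <- idx >= 1L & idx <= n
    w[ok] <- bases[idx[ok]]
  }
  if (strand == "-") w <- .comp_base(w)
  paste(w, collapse = "")
}

#' Enumerate candidate (YC) editing sites in a genome
#'
#' A candidate site is a C immediately preceded (5') by a pyrimidine on the
#' examined strand; both strands of every record are scanned. Reverse-strand
#' sites report the forward-strand coordinate of the edited C and strand
#' `-`. Each site carries the upstream window of `window_len` bases ending
#' `offset` bases 5' of the C; windows running past a sequence end are
#' left-padded with `N` (which scores the table's default) unless
#' `pad_edges = FALSE`, in which case such sites are dropped.
#'
#' @param genome `DNAStringSet` or named character vector of sequences.
#' @param window_len window length (number of scored motifs of the factor
#'   that will be aligned).
#' @param offset bases between the 3' end of the window and the edited C
#'   (default 4: the C-terminal-most scored motif aligns to position -4).
#' @param pad_edges keep edge sites with `N`-padded windows (default TRUE).
#' @param circular treat each record as circular (windows wrap).
#' @return data.frame with columns `seq_id`, `position` (1-based, forward
#'   strand), `strand`, `window` (DNA, 5'->3' on the examined strand) and
#'   `context_5prime` (`C` or `U`).
#' @export
enumerate_candidate_sites <- function(genome, window_len, offset = 4L,
                                      pad_edges = TRUE, circular = FALSE) {
  seqs <- .as_seq_char(genome)
  if (length(seqs) == 0L || all(!nzchar(seqs))) stop("empty genome")
  stopifnot(window_len >= 1L, offset >= 0L)
  res <- lapply(names(seqs), function(sid) {
    b <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
    n <- length(b)
    if (n == 0L) return(NULL)
    prev <- if (circular) c(b[n], b[-n]) else c(NA, b[-n])
    nxt <- if (circular) c(b[-1L], b[1L]) else c(b[-1L], NA)
    fwd <- which(b == "C" & prev %in% c("C", "T"))
    rev <- which(b == "G" & nxt %in% c("A", "G"))
    one <- function(pos, strand, ctx) {
      if (!length(pos)) return(NULL)
      win <- vapply(pos, .window_at, character(1L), bases = b, strand = strand,
                    window_len = window_len, offset = offset, circular = circular)
      data.frame(seq_id = sid, position = pos, strand = strand, window = win,
                 context_5prime = ctx, stringsAsFactors = FALSE)
    }
    rbind(
      one(fwd, "+", .to_rna(prev[fwd])),
      one(rev, "-", .to_rna(.comp_base(nxt[rev])))
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), position = integer(),
                      strand = character(), window = character(),
                      context_5prime = character(), stringsAsFactors = FALSE)
  }
  if (!pad_edges && nrow(out)) out <- out[!grepl("N", out$window, fixed = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Score a PPR array against one window
#'
#' Sum of the per-position log-likelihood ratios: the scored motifs, N- to
#' C-terminal, are aligned to the window 5' to 3' and each motif contributes
#' [motif_base_score()] for its aligned base. `N` in the window contributes
#' the table's default score.
#'
#' @param array a `ppr_array`.
#' @param window nucleotide string (DNA or RNA) whose length equals the
#'   number of scored motifs.
#' @param table a `code_table`.
#' @return Numeric raw alignment score.
#' @export
score_alignment <- function(array, window, table) {
  stopifnot(inherits(array, "ppr_array"), inherits(table, "code_table"))
  sm <- .array_score_matrix(array, table)
  w <- strsplit(.to_rna(window), "", fixed = TRUE)[[1]]
  if (length(w) != nrow(sm)) {
    stop("window length (", length(w), ") must equal the number of scored motifs (",
         nrow(sm), ")")
  }
  bad <- !(w %in% c(RNA_BASES, "N"))
  if (any(bad)) stop("window contains non-nucleotide character(s): ",
                     paste(unique(w[bad]), collapse = ", "))
  s <- ifelse(w == "N", table$default_score, sm[cbind(seq_along(w), match(w, RNA_BASES))])
  sum(s)
}

#' Scan a genome with one PPR factor
#'
#' Enumerates every candidate (YC) site, scores each alignment, and
#' normalizes scores to z-scores against the full candidate population:
#' z = (s - mean) / sd with the population (divide-by-n) standard deviation.
#'
#' @inheritParams enumerate_candidate_sites
#' @param array a `ppr_array`.
#' @param table a `code_table`.
#' @param top_n number of top hits retained in `top_hits` (all hits are
#'   available in `alignments`).
#' @return An object of class `scan_summary`: a list with `factor_id`,
#'   `n_sites`, `mean_score`, `sd_score`, `alignments` (data.frame of every
#'   candidate with `raw_score` and `z_score`, sorted by z descending, ties
#'   broken by seq_id, position, strand) and `top_hits` (head of that).
#' @export
scan_factor <- function(array, genome, table, offset = 4L, top_n = 10L,
                        pad_edges = TRUE, circular = FALSE) {
  stopifnot(inherits(array, "ppr_array"), inherits(table, "code_table"))
  sm <- .array_score_matrix(array, table)
  wl <- nrow(sm)
  sites <- enumerate_candidate_sites(genome, wl, offset, pad_edges, circular)
  if (nrow(sites) == 0L) stop("no candidate sites in genome for factor ", array$protein_id)
  # vectorized: window char matrix indexed into the per-motif score matrix
  wchar <- matrix(unlist(strsplit(sites$window, "", fixed = TRUE), use.names = FALSE),
                  nrow = nrow(sites), ncol = wl, byrow = TRUE)
  wchar <- chartr("T", "U", wchar)
  col <- match(wchar, RNA_BASES)            # NA for 'N'
  smx <- cbind(sm, N = table$default_score) # 5th column for padding
  col[is.na(col)] <- 5L
  scores <- matrix(smx[cbind(rep(seq_len(wl), each = nrow(sites)), as.vector(col))],
                   nrow = nrow(sites))
  sites$raw_score <- rowSums(scores)
  mu <- mean(sites$raw_score)
  sigma <- .pop_sd(sites$raw_score)
  if (sigma == 0) {
    stop("degenerate score spread (all alignments identical) for factor ",
         array$protein_id)
  }
  sites$factor_id <- array$protein_id
  sites$z_score <- (sites$raw_score - mu) / sigma
  ord <- order(-sites$z_score, sites$seq_id, sites$position, sites$strand)
  sites <- sites[ord, c("factor_id", "seq_id", "position", "strand", "window",
                        "context_5prime", "raw_score", "z_score")]
  rownames(sites) <- NULL
  structure(list(factor_id = array$protein_id, n_sites = nrow(sites),
                 mean_score = mu, sd_score = sigma,
                 alignments = sites,
                 top_hits = utils::head(sites, top_n)),
            class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("Genome scan for factor ", x$factor_id, "\n",
      "  candidate YC sites: ", x$n_sites, "\n",
      "  score mean ", signif(x$mean_score, 5), ", population SD ",
      signif(x$sd_score, 5), "\n  top hits:\n", sep = "")
  print(utils::head(x$top_hits, 5L))
  invisible(x)
}

#' Rank PPR factors against one editing site
#'
#' For each factor, scans the whole genome to obtain its score mean and
#' population SD, scores the given site, and reports the site's z-score;
#' factors are returned in decreasing z order. Factors with a degenerate
#' (zero) score spread are reported with `NA` z and a warning rather than
#' dropped.
#'
#' @param arrays list of `ppr_array` objects.
#' @param seq_id,position,strand the site (1-based forward-strand coordinate
#'   of the edited C). The site must be a YC candidate: its 5'-adjacent base
#'   on the examined strand must be a pyrimidine.
#' @param genome,table,offset as in [scan_factor()].
#' @return data.frame with columns `factor_id`, `raw_score`, `z_score`,
#'   sorted by z descending (`NA` last).
#' @export
rank_factors_for_site <- function(arrays, seq_id, position, strand, genome,
                                  table, offset = 4L) {
  if (inherits(arrays, "ppr_array")) arrays <- list(arrays)
  seqs <- .as_seq_char(genome)
  if (!seq_id %in% names(seqs)) stop("seq_id not in genome: ", seq_id)
  b <- strsplit(seqs[[seq_id]], "", fixed = TRUE)[[1]]
  if (position < 1L || position > length(b)) {
    stop("position ", position, " outside sequence ", seq_id)
  }
  ctx_idx <- if (strand == "+") position - 1L else position + 1L
  if (ctx_idx < 1L || ctx_idx > length(b)) {
    stop("site ", seq_id, ":", position, strand,
         " has no 5'-adjacent base on the examined strand")
  }
  base_here <- if (strand == "+") b[position] else .comp_base(b[position])
  if (is.na(base_here) || base_here != "C") {
    stop("site ", seq_id, ":", position, strand, " is not a C on the examined strand")
  }
  ctx <- if (strand == "+") b[ctx_idx] else .comp_base(b[ctx_idx])
  if (is.na(ctx) || !(ctx %in% c("C", "T"))) {
    stop("site ", seq_id, ":", position, strand,
         " is not a YC candidate (5'-adjacent base is not a pyrimidine)")
  }
  rows <- lapply(arrays, function(a) {
    wl <- nrow(.array_score_matrix(a, table))
    win <- .window_at(b, position, strand, wl, offset)
    s <- score_alignment(a, win, table)
    z <- tryCatch({
      sc <- scan_factor(a, genome, table, offset = offset, top_n = 0L)
      (s - sc$mean_score) / sc$sd_score
    }, error = function(e) {
      warning("factor ", a$protein_id, ": ", conditionMessage(e),
              "; reporting NA z-score", call. = FALSE)
      NA_real_
    })
    data.frame(factor_id = a$protein_id, raw_score = s, z_score = z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$z_score, out$factor_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Histogram-ready binning of a factor's alignment scores
#'
#' Emits bin edges and counts of the raw scores of a [scan_factor()] result,
#' for plotting score distributions across the genome.
#'
#' @param scan a `scan_summary`.
#' @param bins number of equal-width bins.
#' @return data.frame with `bin_lower`, `bin_upper`, `count`.
#' @export
score_histogram <- function(scan, bins = 50L) {
  stopifnot(inherits(scan, "scan_summary"))
  h <- graphics::hist(scan$alignments$raw_score, breaks = bins, plot = FALSE)
  data.frame(bin_lower = utils::head(h$breaks, -1L),
             bin_upper = utils::tail(h$breaks, -1L),
             count = h$counts)
}
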