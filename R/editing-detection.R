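# C-to-U editing quantification from strand-aware base-count pileups.
#
# A pileup row gives, for one sample at one position on one transcript
# strand, the number of reads supporting each base on that strand. Editing
# at a genomically encoded C shows up as T-supporting reads; the editing
# extent is 100 * T / (T + C) percent. Candidate events must clear a strict
# edited-read count filter (> 10 reads by default) and a strict fraction
# filter (> 1% by default). Events induced by over-expression of a factor
# must additionally be detected in every over-expressor replicate, fall
# outside homopolymer contexts that attract mis-alignment, and follow the
# genotype pattern low-expressor <= control < over-expressor.

#' Filter configuration for editing detection
#'
#' @param min_edited_reads a site needs strictly more than this many
#'   edited (T) reads; default 10.
#' @param min_fraction_percent the edited fraction must strictly exceed this
#'   percentage; default 1.
#' @param homopolymer_min_run minimum flanking homopolymer run length (per
#'   flank) for [flag_homopolymer_context()]; default 2.
#' @param pattern_tolerance additive tolerance (percentage points) in the
#'   genotype-pattern comparison of [call_induced_events()]; default 0.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_edited_reads = 10, min_fraction_percent = 1,
                          homopolymer_min_run = 2, pattern_tolerance = 0) {
  stopifnot(min_edited_reads >= 0, min_fraction_percent >= 0,
            homopolymer_min_run >= 1, pattern_tolerance >= 0)
  structure(list(min_edited_reads = min_edited_reads,
                 min_fraction_percent = min_fraction_percent,
                 homopolymer_min_run = homopolymer_min_run,
                 pattern_tolerance = pattern_tolerance),
            class = "filter_config")
}

#' Edited-read fraction in percent
#'
#' `100 * n_T / (n_T + n_C)`, the editing extent at a site. Vectorized.
#'
#' @param n_T edited-read count(s).
#' @param n_C unedited-read count(s).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
#' @examples
#' editing_fraction(30, 70)  # 30
editing_fraction <- function(n_T, n_C) {
  stopifnot(all(n_T >= 0), all(n_C >= 0))
  tot <- n_T + n_C
  if (any(tot == 0)) stop("no coverage: n_T + n_C is zero")
  100 * n_T / tot
}

#' Read a pileup TSV
#'
#' Columns: `sample_id`, `seq_id`, `position`, `strand`, `ref_base`,
#' `nA`, `nC`, `nG`, `nT` (counts on the examined transcript strand).
#'
#' @param path file path.
#' @return data.frame of pileup columns.
#' @export
read_pileups <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "seq_id", "position", "strand", "ref_base",
           "nA", "nC", "nG", "nT")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pileup file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a pileup TSV
#' @param pileups data.frame in the [read_pileups()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileups <- function(pileups, path) {
  write.table(pileups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Verify pileup ref_base agrees with the genome on the examined strand.
#' @noRd
.check_pileup_ref <- function(pileups, genome) {
  seqs <- .as_seq_char(genome)
  for (sid in unique(pileups$seq_id)) {
    if (!sid %in% names(seqs)) stop("pileup seq_id not in genome: ", sid)
    b <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
    rows <- pileups$seq_id == sid
    pos <- pileups$position[rows]
    if (any(pos < 1L | pos > length(b))) {
      stop("pileup position outside ", sid, ": ",
           pos[which(pos < 1L | pos > length(b))[1L]])
    }
    gb <- b[pos]
    minus <- pileups$strand[rows] == "-"
    gb[minus] <- .comp_base(gb[minus])
    bad <- gb != pileups$ref_base[rows]
    if (any(bad)) {
      stop("pileup ref_base disagrees with genome at ", sid, ":",
           pos[which(bad)[1L]])
    }
  }
  invisible(TRUE)
}

#' Detect candidate editing events in one or more samples
#'
#' Applies the site-level filter: the position is genomically encoded as C
#' on the examined strand, the edited-read count `nT` strictly exceeds
#' `cfg$min_edited_reads`, and the edited fraction strictly exceeds
#' `cfg$min_fraction_percent`.
#'
#' @param pileups data.frame in the [read_pileups()] layout (any number of
#'   samples).
#' @param genome the genome the pileups were produced against; used to check
#'   `ref_base` consistency.
#' @param cfg a [filter_config()].
#' @return data.frame of `EditingMeasurement` rows: `sample_id`, `seq_id`,
#'   `position`, `strand`, `n_T`, `n_C`, `fraction_percent`.
#' @export
detect_candidate_events <- function(pileups, genome, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  .check_pileup_ref(pileups, genome)
  p <- pileups[pileups$ref_base == "C", , drop = FALSE]
  n_T <- p$nT
  n_C <- p$nC
  tot <- n_T + n_C
  frac <- ifelse(tot > 0, 100 * n_T / tot, 0)
  keep <- tot > 0 & n_T > cfg$min_edited_reads & frac > cfg$min_fraction_percent
  out <- data.frame(sample_id = p$sample_id, seq_id = p$seq_id,
                    position = p$position, strand = p$strand,
                    n_T = n_T, n_C = n_C, fraction_percent = frac,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag a site in a mis-alignment-prone homopolymer context
#'
#' Edited reads at a C inside a poly-T run (forward strand) or at the
#' corresponding G inside a poly-A run (reverse-strand site read on the
#' forward strand) are often mis-aligned rather than edited. A site is
#' flagged when, on the forward strand, the context is `(T)nC(T)n` for a
#' forward-strand site or `(A)nG(A)n` for a reverse-strand site, with both
#' flanking runs at least `min_run` long. Flanks truncated by a sequence
#' boundary are measured on the available bases.
#'
#' @param genome genome sequences.
#' @param seq_id,position,strand the site (forward-strand coordinate).
#' @param min_run minimum run length per flank.
#' @return Logical scalar.
#' @export
flag_homopolymer_context <- function(genome, seq_id, position, strand,
                                     min_run = 2L) {
  stopifnot(min_run >= 1L)
  seqs <- .as_seq_char(genome)
  if (!seq_id %in% names(seqs)) stop("seq_id not in genome: ", seq_id)
  b <- strsplit(seqs[[seq_id]], "", fixed = TRUE)[[1]]
  if (position < 1L || position > length(b)) {
    stop("position outside sequence: ", position)
  }
  run_base <- if (strand == "+") "T" else "A"
  run_len <- function(idx_seq) {
    r <- 0L
    for (i in idx_seq) {
      if (i < 1L || i > length(b) || b[i] != run_base) break
      r <- r + 1L
    }
    r
  }
  left <- run_len(seq(position - 1L, by = -1L, length.out = min_run))
  right <- run_len(seq(position + 1L, by = 1L, length.out = min_run))
  left >= min_run && right >= min_run
}

#' Call editing events induced across a genotype series
#'
#' Implements the three-rule caller over a low-expressor / control /
#' over-expressor series: a site is called induced iff
#' (1) it passes [detect_candidate_events()] in every over-expressor
#' replicate; (2) it is not in a mis-alignment-prone homopolymer context
#' ([flag_homopolymer_context()]); and (3) replicate-mean edited fractions
#' follow low <= control + tol and control + tol < over-expressor, with
#' `tol = cfg$pattern_tolerance` (default 0).
#'
#' @param pileups data.frame covering all samples ([read_pileups()] layout).
#' @param genotype_map data.frame with columns `sample_id` and `genotype`
#'   (values among `low_expr`, `control`, `over_expr`).
#' @param genome genome sequences.
#' @param cfg a [filter_config()].
#' @param require_over_replicates expected number of over-expressor
#'   replicates (default 3); a different count is an error unless `NULL`.
#' @return A list with `calls` (data.frame of induced sites: position,
#'   per-genotype mean fractions) and `flagged` (sites that passed rules 1
#'   and 3 but sit in a homopolymer context, reported for manual review).
#' @export
call_induced_events <- function(pileups, genotype_map, genome,
                                cfg = filter_config(),
                                require_over_replicates = 3L) {
  stopifnot(inherits(cfg, "filter_config"))
  gmap <- as.data.frame(genotype_map)
  need <- c("low_expr", "control", "over_expr")
  for (g in need) {
    if (!any(gmap$genotype == g)) stop("genotype with zero replicates: ", g)
  }
  over_samples <- gmap$sample_id[gmap$genotype == "over_expr"]
  if (!is.null(require_over_replicates) &&
      length(over_samples) != require_over_replicates) {
    stop("expected ", require_over_replicates, " over-expressor replicates, got ",
         length(over_samples))
  }
  det <- detect_candidate_events(
    pileups[pileups$sample_id %in% over_samples, , drop = FALSE], genome, cfg)
  if (nrow(det) == 0L) {
    empty <- data.frame(seq_id = character(), position = integer(),
                        strand = character(), mean_low = numeric(),
                        mean_control = numeric(), mean_over = numeric())
    return(list(calls = empty, flagged = empty))
  }
  # rule 1: detected in every over-expressor replicate
  key <- paste(det$seq_id, det$position, det$strand, sep = "\r")
  n_det <- table(key)
  cand_keys <- names(n_det)[n_det == length(over_samples)]
  if (!length(cand_keys)) {
    empty <- data.frame(seq_id = character(), position = integer(),
                        strand = character(), mean_low = numeric(),
                        mean_control = numeric(), mean_over = numeric())
    return(list(calls = empty, flagged = empty))
  }
  cand <- unique(det[key %in% cand_keys, c("seq_id", "position", "strand")])
  pk <- paste(pileups$seq_id, pileups$position, pileups$strand, sep = "\r")
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ck <- paste(cand$seq_id[i], cand$position[i], cand$strand[i], sep = "\r")
    sub <- pileups[pk == ck & pileups$ref_base == "C", , drop = FALSE]
    sub$genotype <- gmap$genotype[match(sub$sample_id, gmap$sample_id)]
    tot <- sub$nT + sub$nC
    frac <- ifelse(tot > 0, 100 * sub$nT / tot, NA_real_)
    gm <- vapply(need, function(g) mean(frac[sub$genotype == g], na.rm = TRUE),
                 numeric(1L))
    tol <- cfg$pattern_tolerance
    pattern_ok <- !anyNA(gm) &&
      gm["low_expr"] <= gm["control"] + tol &&
      gm["control"] + tol < gm["over_expr"]
    hp <- flag_homopolymer_context(genome, cand$seq_id[i], cand$position[i],
                                   cand$strand[i], cfg$homopolymer_min_run)
    data.frame(seq_id = cand$seq_id[i], position = cand$position[i],
               strand = cand$strand[i],
               mean_low = unname(gm["low_expr"]),
               mean_control = unname(gm["control"]),
               mean_over = unname(gm["over_expr"]),
               pattern_ok = pattern_ok, homopolymer = hp,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  calls <- tab[tab$pattern_ok & !tab$homopolymer, , drop = FALSE]
  flagged <- tab[tab$homopolymer, , drop = FALSE]
  cols <- c("seq_id", "position", "strand", "mean_low", "mean_control", "mean_over")
  calls <- calls[order(calls$seq_id, calls$position), cols, drop = FALSE]
  flagged <- flagged[order(flagged$seq_id, flagged$position), cols, drop = FALSE]
  rownames(calls) <- rownames(flagged) <- NULL
  list(calls = calls, flagged = flagged)
}

#' Quantify editing at a list of known sites
#'
#' For each listed site and each sample, reports the edited fraction
#' (percent); sites with no coverage in a sample are reported as missing
#' (`NA`), not zero. Per genotype (or over all samples if no map is given),
#' reports the replicate mean and standard error (sample SD / sqrt(n); `NA`
#' for a single replicate).
#'
#' @param pileups data.frame in the [read_pileups()] layout.
#' @param sites data.frame with columns `name`, `seq_id`, `position`,
#'   `strand`.
#' @param genotype_map optional data.frame with `sample_id`, `genotype`.
#' @return A list with `per_sample` (site x sample fractions, long format)
#'   and `summary` (per site and genotype: `n`, `mean`, `se`).
#' @export
quantify_known_sites <- function(pileups, sites, genotype_map = NULL) {
  sites <- as.data.frame(sites)
  pk <- paste(pileups$seq_id, pileups$position, pileups$strand, sep = "\r")
  samples <- unique(pileups$sample_id)
  per <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    ck <- paste(sites$seq_id[i], sites$position[i], sites$strand[i], sep = "\r")
    f <- vapply(samples, function(sm) {
      sub <- pileups[pk == ck & pileups$sample_id == sm, , drop = FALSE]
      if (nrow(sub) == 0L) return(NA_real_)
      tot <- sum(sub$nT) + sum(sub$nC)
      if (tot == 0L) return(NA_real_)
      100 * sum(sub$nT) / tot
    }, numeric(1L))
    data.frame(name = sites$name[i], seq_id = sites$seq_id[i],
               position = sites$position[i], strand = sites$strand[i],
               sample_id = samples, fraction_percent = unname(f),
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(per$fraction_percent))) {
    warning("none of the listed sites is covered in any sample")
  }
  if (is.null(genotype_map)) {
    per$genotype <- "all"
  } else {
    per$genotype <- genotype_map$genotype[match(per$sample_id,
                                                genotype_map$sample_id)]
  }
  sl <- split(per, list(per$name, per$genotype), drop = TRUE)
  summ <- do.call(rbind, lapply(sl, function(d) {
    v <- d$fraction_percent[!is.na(d$fraction_percent)]
    data.frame(name = d$name[1L], genotype = d$genotype[1L],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               se = .se(v), stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$name, summ$genotype), ]
  rownames(summ) <- rownames(per) <- NULL
  list(per_sample = per, summary = summ)
}
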