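# Fixture builders and independent oracles used across test files.

# A small fixed code table covering a handful of (aa5, aa_last) pairs.
toy_table <- function(default_score = 0) {
  code_table(data.frame(
    aa5     = c("T",  "S",  "N",  "G"),
    aa_last = c("D",  "N",  "D",  "D"),
    A = c(1.2, -0.2, -0.9, 0.2),
    C = c(-0.5, 0.1,  0.1, 0.3),
    G = c(-1.0, -0.9, -0.6, -0.5),
    U = c(-0.8, 1.1,  1.2,  0.1)),
    default_score = default_score)
}

# A random code table over random amino-acid pairs (keys distinct).
random_table <- function(n_entries = 12L, default_score = 0) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pairs <- unique(data.frame(aa5 = sample(aa, 3L * n_entries, replace = TRUE),
                             aa_last = sample(aa, 3L * n_entries, replace = TRUE)))
  pairs <- pairs[seq_len(min(n_entries, nrow(pairs))), ]
  for (b in c("A", "C", "G", "U")) pairs[[b]] <- round(rnorm(nrow(pairs)), 3)
  code_table(pairs, default_score = default_score)
}

# A random PPR array whose (aa5, aa_last) pairs are drawn from the table's
# entries, so every motif is scored.
random_array <- function(table, n_motifs = 6L, id = "factorX") {
  key <- rownames(table$scores)
  pick <- sample(key, n_motifs, replace = TRUE)
  ppr_array(id, data.frame(
    motif_class = rep_len(c("P1", "L1", "S1"), n_motifs),
    aa5 = sub("\\|.*", "", pick),
    aa_last = sub(".*\\|", "", pick)))
}

# Independent per-position scoring oracle: a plain double loop over motifs
# with direct named lookups, no shared code with score_alignment().
oracle_score <- function(array, window, table) {
  w <- chartr("T", "U", toupper(strsplit(window, "")[[1]]))
  motifs <- array$motifs
  if (!is.null(array$scored)) motifs <- motifs[array$scored, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(motifs))) {
    key <- paste0(motifs$aa5[i], "|", motifs$aa_last[i])
    s <- table$default_score
    if (w[i] != "N" && key %in% rownames(table$scores) &&
        motifs$aa5[i] != "X" && motifs$aa_last[i] != "X") {
      s <- table$scores[key, w[i]]
    }
    total <- total + s
  }
  total
}

# Independent brute-force enumeration of YC sites (both strands) by direct
# string inspection; returns forward-strand positions and strands.
oracle_yc_sites <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  fwd <- integer(0); rev <- integer(0)
  for (i in 2:n) if (b[i] == "C" && b[i - 1] %in% c("C", "T")) fwd <- c(fwd, i)
  for (i in 1:(n - 1)) if (b[i] == "G" && b[i + 1] %in% c("A", "G")) rev <- c(rev, i)
  data.frame(position = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

# Minimal plastid-like annotation as a GRanges.
toy_annotation <- function() {
  GenomicRanges::GRanges(
    seqnames = "ChrC",
    ranges = IRanges::IRanges(
      start = c(100, 1200, 2500, 3200, 4100, 5000, 5400, 6000, 43700, 43752, 44467),
      end   = c(900, 2000, 3100, 3900, 4800, 5300, 5900, 6200, 45000, 44465, 45000)),
    strand = "+",
    type   = c(rep("gene", 9), "intron", "exon"),
    gene_id = c("psbA", "rbcL", "rps14", "rrn16", "trnE", "ndhB_ir", "rps12",
                "matK", "ycf3", "ycf3", "ycf3"),
    biotype = c("mRNA", "mRNA", "mRNA", "rRNA", "tRNA", "mRNA", "mRNA",
                "mRNA", "mRNA", "mRNA", "mRNA"))
}
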