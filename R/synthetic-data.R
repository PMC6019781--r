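# Seeded generators for every input the pipeline consumes: random genomes,
# planted PPR targets, binomial editing pileups across a three-genotype
# expression series, decoy sites in mis-alignment-prone homopolymer
# contexts, multinomial gene counts with known RPKM, qPCR tables with a
# known expression ratio, and Mendelian seed segregation from a selfed
# heterozygote carrying a recessive embryo-lethal allele.
#
# Defaults mirror the study design the pipeline targets: three genotypes
# (low-expressor / control / over-expressor) x three replicates, fixed
# per-site depth, uniform sequencing error 0.001 spread equally over the
# three alternative bases.

GENOTYPES <- c("low_expr", "control", "over_expr")

#' Simulate a random genome
#'
#' I.i.d. bases at a stated GC fraction, reproducible under `seed`.
#'
#' @param length sequence length (>= 50 nt).
#' @param gc GC fraction in `[0, 1]` (C and G equiprobable, likewise A/T).
#' @param seq_id record name.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A named `DNAStringSet` of one record.
#' @export
sim_genome <- function(length, gc = 0.36, seq_id = "chrSim", seed = NULL) {
  if (length < 50L) stop("genome length must be at least 50 nt")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  .seed_if(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  out <- Biostrings::DNAStringSet(s)
  names(out) <- seq_id
  out
}

#' Plant a PPR factor's preferred target into a genome
#'
#' Overwrites the upstream window at the given register with
#' [preferred_window()] of the factor, sets the edited position to C (on
#' the requested strand) and forces the 5'-adjacent base to a pyrimidine,
#' so the planted site is a YC candidate whose raw score is the factor's
#' maximum achievable score. A manifest of occupied intervals is threaded
#' through successive calls; planting over a previously planted interval is
#' a collision error.
#'
#' @param genome `DNAStringSet` or character.
#' @param array,table factor and code table ([ppr_array()], [code_table()]).
#' @param position forward-strand coordinate of the edited C.
#' @param strand `"+"` or `"-"`.
#' @param offset alignment register as in [enumerate_candidate_sites()].
#' @param manifest manifest from a previous `plant_target()` call, or
#'   `NULL`.
#' @return A list with `genome` (modified `DNAStringSet`) and `manifest`
#'   (data.frame of planted sites: `seq_id`, `position`, `strand`,
#'   `window`, `start`, `end`).
#' @export
plant_target <- function(genome, array, table, position, strand = "+",
                         offset = 4L, manifest = NULL) {
  seqs <- .as_seq_char(genome)
  sid <- names(seqs)[1L]
  b <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
  n <- length(b)
  pw_rna <- preferred_window(array, table)
  pw <- strsplit(.to_dna(pw_rna), "", fixed = TRUE)[[1]]
  wl <- length(pw)
  if (strand == "+") {
    widx <- (position - offset - wl + 1L):(position - offset)
    ctx_idx <- position - 1L
  } else {
    widx <- (position + offset):(position + offset + wl - 1L)
    ctx_idx <- position + 1L
  }
  span <- range(c(widx, position, ctx_idx))
  if (span[1L] < 1L || span[2L] > n) {
    stop("planted window extends beyond the sequence (", span[1L], "..",
         span[2L], " on ", n, " nt)")
  }
  if (!is.null(manifest) && nrow(manifest)) {
    prev <- manifest[manifest$seq_id == sid, , drop = FALSE]
    if (any(prev$start <= span[2L] & prev$end >= span[1L])) {
      stop("collision with a previously planted site at ", sid, ":",
           span[1L], "-", span[2L])
    }
  }
  if (strand == "+") {
    b[widx] <- pw
    b[position] <- "C"
    if (!(b[ctx_idx] %in% c("C", "T"))) b[ctx_idx] <- "T"
  } else {
    b[widx] <- rev(.comp_base(pw))
    b[position] <- "G"
    if (!(b[ctx_idx] %in% c("A", "G"))) b[ctx_idx] <- "A"
  }
  seqs[[sid]] <- paste(b, collapse = "")
  entry <- data.frame(seq_id = sid, position = position, strand = strand,
                      factor_id = array$protein_id, window = pw_rna,
                      start = span[1L], end = span[2L],
                      stringsAsFactors = FALSE)
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(seqs)
  list(genome = out, manifest = rbind(manifest, entry))
}

#' Plant homopolymer-context decoy sites
#'
#' Writes `(T)runC(T)run` motifs (forward strand) at well-separated
#' positions: apparent editing planted there mimics mis-aligned reads and
#' should be flagged by [flag_homopolymer_context()] and excluded by
#' [call_induced_events()].
#'
#' @param genome `DNAStringSet` or character.
#' @param n number of decoys.
#' @param run flanking run length (default 3).
#' @param manifest planting manifest to respect / extend (see
#'   [plant_target()]).
#' @param seed integer seed or `NULL`.
#' @return A list with `genome`, `positions` (of the decoy Cs) and
#'   `manifest`.
#' @export
plant_decoys <- function(genome, n, run = 3L, manifest = NULL, seed = NULL) {
  .seed_if(seed)
  seqs <- .as_seq_char(genome)
  sid <- names(seqs)[1L]
  b <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
  len <- length(b)
  positions <- integer(0)
  guard <- 0L
  while (length(positions) < n && guard < 1000L * n) {
    guard <- guard + 1L
    p <- sample.int(len - 2L * (run + 1L), 1L) + run + 1L
    span <- c(p - run - 1L, p + run)
    clash <- FALSE
    if (!is.null(manifest) && nrow(manifest)) {
      prev <- manifest[manifest$seq_id == sid, , drop = FALSE]
      clash <- any(prev$start <= span[2L] & prev$end >= span[1L])
    }
    if (!clash) {
      # extra leading T makes the 5' context a pyrimidine (a YC site)
      b[(p - run - 1L):(p + run)] <- c(rep("T", run + 1L), "C", rep("T", run))
      positions <- c(positions, p)
      manifest <- rbind(manifest,
                        data.frame(seq_id = sid, position = p, strand = "+",
                                   factor_id = "decoy", window = "",
                                   start = span[1L], end = span[2L],
                                   stringsAsFactors = FALSE))
    }
  }
  if (length(positions) < n) stop("could not place ", n, " decoys without collisions")
  seqs[[sid]] <- paste(b, collapse = "")
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(seqs)
  list(genome = out, positions = positions, manifest = manifest)
}

#' Simulate per-sample editing pileups
#'
#' For every genomically encoded C on either strand, draws base counts at
#' fixed depth for each genotype x replicate sample. At planted sites the
#' edited-read count is Binomial(depth, f(1-e) + (1-f)e/3) for the
#' genotype's true fraction f and sequencing error rate e; at background
#' positions edited reads arise only from sequencing error. Remaining
#' error reads are split between the two other alternative bases.
#'
#' @param genome `DNAStringSet` or character.
#' @param planted data.frame with `position`, `strand` and per-genotype
#'   true fractions `low_expr`, `control`, `over_expr` (0-1). May be empty.
#' @param depth reads per site (fixed).
#' @param error_rate per-base miscall rate e in `[0, 0.01]`.
#' @param replicates replicates per genotype (default 3).
#' @param seed integer seed or `NULL`.
#' @return A list with `pileups` (data.frame, [read_pileups()] layout) and
#'   `genotype_map` (`sample_id`, `genotype`).
#' @export
simulate_pileups <- function(genome, planted = NULL, depth = 1000L,
                             error_rate = 0.001, replicates = 3L,
                             seed = NULL) {
  if (depth <= 0L) stop("depth must be positive")
  if (error_rate < 0 || error_rate > 0.01) stop("error_rate must be in [0, 0.01]")
  .seed_if(seed)
  seqs <- .as_seq_char(genome)
  sid <- names(seqs)[1L]
  b <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
  fwd <- which(b == "C")
  rev <- which(b == "G")
  pos <- c(fwd, rev)
  strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
  key <- paste(pos, strand)
  truef <- matrix(0, nrow = length(pos), ncol = 3L,
                  dimnames = list(NULL, GENOTYPES))
  if (!is.null(planted) && nrow(planted)) {
    hit <- match(paste(planted$position, planted$strand), key)
    if (anyNA(hit)) {
      stop("planted site is not a C on its strand: position ",
           planted$position[which(is.na(hit))[1L]])
    }
    truef[hit, ] <- as.matrix(planted[, GENOTYPES])
  }
  samples <- paste(rep(GENOTYPES, each = replicates),
                   rep(seq_len(replicates), times = 3L), sep = "_rep")
  gmap <- data.frame(sample_id = samples,
                     genotype = rep(GENOTYPES, each = replicates),
                     stringsAsFactors = FALSE)
  e <- error_rate
  res <- lapply(seq_len(nrow(gmap)), function(i) {
    f <- truef[, gmap$genotype[i]]
    p_t <- f * (1 - e) + (1 - f) * e / 3
    nT <- rbinom(length(pos), depth, p_t)
    rest <- depth - nT
    nerr <- rbinom(length(pos), rest, 2 * e / 3)
    nA <- rbinom(length(pos), nerr, 0.5)
    nG <- nerr - nA
    nC <- rest - nerr
    data.frame(sample_id = gmap$sample_id[i], seq_id = sid, position = pos,
               strand = strand, ref_base = "C",
               nA = nA, nC = nC, nG = nG, nT = nT, stringsAsFactors = FALSE)
  })
  list(pileups = do.call(rbind, res), genotype_map = gmap)
}

#' Simulate a gene count table with known RPKM
#'
#' Multinomial read allocation with per-gene probability proportional to
#' `true_rpkm * length`, so [rpkm()] applied to the draw recovers
#' `true_rpkm` up to multinomial noise (after a common rescaling by the
#' total probability mass).
#'
#' @param lengths named vector of gene lengths (nt).
#' @param true_rpkm named vector of target RPKM values (same genes).
#' @param total_reads total reads to allocate.
#' @param sample_id sample label.
#' @param seed integer seed or `NULL`.
#' @return data.frame with `gene_id`, `sample_id`, `reads`.
#' @export
simulate_counts <- function(lengths, true_rpkm, total_reads,
                            sample_id = "sim", seed = NULL) {
  stopifnot(total_reads > 0, all(true_rpkm >= 0),
            identical(names(lengths), names(true_rpkm)))
  if (all(true_rpkm == 0)) stop("all-zero true RPKM")
  .seed_if(seed)
  p <- true_rpkm * lengths
  counts <- as.vector(rmultinom(1L, total_reads, p / sum(p)))
  data.frame(gene_id = names(lengths), sample_id = sample_id,
             reads = counts, stringsAsFactors = FALSE)
}

#' Simulate a qPCR table with a known expression ratio
#'
#' Draws Cq pairs whose noiseless transform under
#' [qpcr_normalized_expression()] equals `true_ratio`, then adds Gaussian
#' noise to each Cq.
#'
#' @param true_ratio target normalized expression ratio (> 0).
#' @param e_target,e_ref amplification efficiencies (> -1; `e_target` must
#'   be non-zero unless `true_ratio` is 1).
#' @param cq_noise_sd Gaussian SD added to each Cq (cycles).
#' @param n number of replicate measurements.
#' @param cq_ref_center reference-gene Cq about which draws are centred.
#' @param max_cycles cycle ceiling (default 35).
#' @param seed integer seed or `NULL`.
#' @return data.frame with `sample_id`, `cq_target`, `e_target`, `cq_ref`,
#'   `e_ref`.
#' @export
simulate_qpcr <- function(true_ratio, e_target = 1, e_ref = 1,
                          cq_noise_sd = 0.1, n = 3L, cq_ref_center = 25,
                          max_cycles = 35, seed = NULL) {
  if (true_ratio <= 0) stop("true_ratio must be positive")
  if (e_target <= -1 || e_ref <= -1) stop("amplification efficiency must exceed -1")
  if (e_target == 0 && true_ratio != 1) {
    stop("a zero target efficiency cannot encode a ratio other than 1")
  }
  .seed_if(seed)
  cq_ref <- rep(cq_ref_center, n)
  cq_target <- if (e_target == 0) cq_ref else {
    max_cycles - (log(true_ratio) + (max_cycles - cq_ref) * log1p(e_ref)) / log1p(e_target)
  }
  data.frame(sample_id = paste0("rep", seq_len(n)),
             cq_target = cq_target + rnorm(n, 0, cq_noise_sd),
             e_target = e_target,
             cq_ref = cq_ref + rnorm(n, 0, cq_noise_sd),
             e_ref = e_ref, stringsAsFactors = FALSE)
}

#' Simulate seed segregation from a selfed heterozygote
#'
#' Each seed of a selfed heterozygote carrying a recessive embryo-lethal
#' allele is independently homozygous mutant (white) with probability 1/4
#' and green otherwise: the Mendelian 3:1 ratio.
#'
#' @param n_seeds number of seeds (>= 0).
#' @param seed integer RNG seed or `NULL`.
#' @return A list with `n_seeds`, `n_green`, `n_white`.
#' @export
simulate_seed_segregation <- function(n_seeds, seed = NULL) {
  if (n_seeds < 0) stop("n_seeds must be non-negative")
  .seed_if(seed)
  n_white <- if (n_seeds == 0L) 0L else rbinom(1L, n_seeds, 0.25)
  list(n_seeds = as.integer(n_seeds), n_green = as.integer(n_seeds - n_white),
       n_white = as.integer(n_white))
}

#' One-call synthetic study: genome, planted target, decoys, pileups
#'
#' Convenience wrapper reproducing the study design end to end: a random
#' genome, one planted preferred-window target for the given factor whose
#' editing follows a low/control/over fraction pattern, homopolymer decoys
#' following the same pattern, and binomial pileups for three genotypes x
#' `replicates`.
#'
#' @param array,table factor and code table.
#' @param genome_length genome size (default 3000 nt).
#' @param gc GC fraction.
#' @param fractions named numeric vector of true edited fractions per
#'   genotype; default `c(low_expr = 0.02, control = 0.5, over_expr = 0.95)`.
#' @param n_decoys number of homopolymer decoys (default 3).
#' @param depth,error_rate,replicates as in [simulate_pileups()].
#' @param offset alignment register.
#' @param seed integer seed (drives every stage).
#' @return A list with `genome`, `site` (position/strand of the planted
#'   target), `decoys`, `pileups`, `genotype_map`, `manifest`.
#' @export
simulate_study <- function(array, table, genome_length = 3000L, gc = 0.36,
                           fractions = c(low_expr = 0.02, control = 0.5,
                                         over_expr = 0.95),
                           n_decoys = 3L, depth = 1000L, error_rate = 0.001,
                           replicates = 3L, offset = 4L, seed = 1L) {
  .seed_if(seed)
  g <- sim_genome(genome_length, gc = gc)
  position <- as.integer(genome_length / 2)
  pt <- plant_target(g, array, table, position, "+", offset = offset)
  # the genuine target is constructed outside homopolymer decoy contexts:
  # break any chance (T)nC(T)n flanks so only the planted decoys carry them
  seqs <- .as_seq_char(pt$genome)
  b <- strsplit(seqs[[1L]], "", fixed = TRUE)[[1]]
  if (b[position + 1L] == "T") b[position + 1L] <- "A"
  if (b[position - 1L] == "T" && b[position - 2L] == "T") b[position - 1L] <- "C"
  seqs[[1L]] <- paste(b, collapse = "")
  clean <- Biostrings::DNAStringSet(unlist(seqs))
  names(clean) <- names(seqs)
  pt$genome <- clean
  pt$manifest$end[1L] <- pt$manifest$end[1L] + 1L  # protect the 3' flank
  dc <- plant_decoys(pt$genome, n_decoys, run = 3L, manifest = pt$manifest)
  planted <- data.frame(position = c(position, dc$positions),
                        strand = "+",
                        low_expr = fractions[["low_expr"]],
                        control = fractions[["control"]],
                        over_expr = fractions[["over_expr"]])
  sim <- simulate_pileups(dc$genome, planted, depth = depth,
                          error_rate = error_rate, replicates = replicates)
  list(genome = dc$genome, site = list(seq_id = names(.as_seq_char(g))[1L],
                                       position = position, strand = "+"),
       decoys = dc$positions, pileups = sim$pileups,
       genotype_map = sim$genotype_map, manifest = dc$manifest)
}
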