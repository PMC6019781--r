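# Expression quantification: RPKM over a curated plastid gene set,
# efficiency-corrected qPCR normalization, and pairing of editing with
# expression per transgenic line.
#
# The plastid annotation is first modified so that reads spanning the
# trans-spliced rps12 junctions can be counted on a concatenated construct
# appended to the end of the plastid record; rRNA genes, tRNA genes, the
# original rps12 exons and one copy of the inverted repeat are excluded
# from the counted gene set before RPKM is computed.

# Canonical register of the appended concatenated-rps12 construct:
# total length and the two intron intervals, 1-based relative to the
# construct start. With a plastid record of 154,478 bp these place the
# construct at 154479-156997 and its introns at 154653-156142 and
# 156375-156911.
RPS12_CONSTRUCT_LENGTH <- 2519L
RPS12_INTRON1_REL <- c(175L, 1664L)
RPS12_INTRON2_REL <- c(1897L, 2433L)

#' Append the concatenated rps12 construct and adjust the annotation
#'
#' Extends the plastid record with the concatenated rps12 construct
#' (rps12 exons joined in cis with 60 bp of flank at each end), adds the
#' construct and its two intron features at the stated relative
#' coordinates, and shifts the ycf3 first intron one nucleotide downstream.
#' All coordinates are 1-based inclusive.
#'
#' @param genome `DNAStringSet` (or named character vector); the plastid
#'   record is extended in place.
#' @param annotation `GRanges` with metadata columns `type` (e.g. `gene`,
#'   `exon`, `intron`), `gene_id` and `biotype`.
#' @param construct character or `DNAString`: the concatenated rps12
#'   sequence to append. Its length must accommodate both intron intervals.
#' @param plastid_seqid name of the plastid record; default the first.
#' @param intron1_rel,intron2_rel 1-based (start, end) of the two
#'   concatenated-construct introns relative to the construct start;
#'   defaults are the canonical register (175-1664 and 1897-2433).
#' @param ycf3_gene_id gene_id of ycf3 in `annotation`; its first intron
#'   (lowest start) is shifted +1. Skipped with a message if absent.
#' @return A list with `genome` (`DNAStringSet`) and `annotation`
#'   (`GRanges` including the new features, the construct gene carrying
#'   `gene_id = "rps12_concat"`, `biotype = "mRNA"`).
#' @export
build_modified_annotation <- function(genome, annotation, construct,
                                      plastid_seqid = NULL,
                                      intron1_rel = RPS12_INTRON1_REL,
                                      intron2_rel = RPS12_INTRON2_REL,
                                      ycf3_gene_id = "ycf3") {
  seqs <- .as_seq_char(genome)
  if (is.null(plastid_seqid)) plastid_seqid <- names(seqs)[1L]
  if (!plastid_seqid %in% names(seqs)) {
    stop("plastid record not found in genome: ", plastid_seqid)
  }
  construct <- .to_dna(as.character(construct))
  clen <- nchar(construct)
  for (iv in list(intron1_rel, intron2_rel)) {
    if (length(iv) != 2L || iv[1L] > iv[2L] || iv[1L] < 1L || iv[2L] > clen) {
      stop("intron coordinates inconsistent with construct length (", clen, " nt)")
    }
  }
  L0 <- nchar(seqs[[plastid_seqid]])
  seqs[[plastid_seqid]] <- paste0(seqs[[plastid_seqid]], construct)

  new_feats <- GenomicRanges::GRanges(
    seqnames = plastid_seqid,
    ranges = IRanges::IRanges(
      start = L0 + c(1L, intron1_rel[1L], intron2_rel[1L]),
      end = L0 + c(clen, intron1_rel[2L], intron2_rel[2L])),
    strand = "+",
    type = c("gene", "intron", "intron"),
    gene_id = "rps12_concat",
    biotype = "mRNA")

  ann <- annotation
  ycf3_introns <- which(ann$gene_id == ycf3_gene_id & ann$type == "intron")
  if (length(ycf3_introns)) {
    first <- ycf3_introns[which.min(GenomicRanges::start(ann)[ycf3_introns])]
    ann[first] <- GenomicRanges::shift(ann[first], 1L)
  } else {
    message("no ycf3 intron in annotation; coordinate shift skipped")
  }
  common <- intersect(names(S4Vectors::mcols(ann)), names(S4Vectors::mcols(new_feats)))
  S4Vectors::mcols(new_feats) <- S4Vectors::mcols(new_feats)[, common, drop = FALSE]
  ann2 <- ann
  S4Vectors::mcols(ann2) <- S4Vectors::mcols(ann2)[, common, drop = FALSE]
  out_ann <- suppressWarnings(c(ann2, new_feats))
  list(genome = Biostrings::DNAStringSet(seqs), annotation = out_ann)
}

#' Select the counted gene set
#'
#' Applies the expression-analysis exclusions: rRNA and tRNA genes, the
#' original (non-concatenated) rps12 features, and genes lying wholly
#' inside one designated inverted-repeat copy are removed.
#'
#' @param annotation `GRanges` with `type`, `gene_id`, `biotype`; only
#'   `type == "gene"` features are considered.
#' @param exclude_biotypes biotypes removed; default `c("rRNA", "tRNA")`.
#' @param ir_exclude `GRanges` spanning the inverted-repeat copy to exclude,
#'   or `NULL` (no IR filtering, with a warning). Supplying more than one
#'   range is a configuration error (both copies must not be removed).
#' @param rps12_gene_id the original rps12 gene_id to drop; the
#'   concatenated construct (`rps12_concat`) is retained.
#' @return `GRanges` of retained genes.
#' @export
select_gene_set <- function(annotation, exclude_biotypes = c("rRNA", "tRNA"),
                            ir_exclude = NULL, rps12_gene_id = "rps12") {
  g <- annotation[annotation$type == "gene"]
  keep <- !(g$biotype %in% exclude_biotypes) & g$gene_id != rps12_gene_id
  g <- g[keep]
  if (is.null(ir_exclude)) {
    warning("no inverted-repeat span designated; IR filtering skipped")
  } else {
    if (length(ir_exclude) > 1L) {
      stop("only one inverted-repeat copy may be designated for exclusion")
    }
    inside <- IRanges::overlapsAny(g, ir_exclude, type = "within")
    g <- g[!inside]
  }
  g
}

#' Gene lengths for RPKM
#'
#' Exon-union length per gene when exon features are present (the sum of
#' the per-gene reduced exon widths); otherwise, or with
#' `method = "locus_span"`, the genomic span end - start + 1.
#'
#' @param annotation `GRanges` with `type`, `gene_id`.
#' @param genes character vector of gene_ids (default: all genes).
#' @param method `"exon_union"` (default) or `"locus_span"`.
#' @return Named integer vector of lengths (nt).
#' @export
gene_lengths <- function(annotation, genes = NULL,
                         method = c("exon_union", "locus_span")) {
  method <- match.arg(method)
  g <- annotation[annotation$type == "gene"]
  if (is.null(genes)) genes <- unique(g$gene_id)
  ex <- annotation[annotation$type == "exon"]
  vapply(genes, function(id) {
    if (method == "exon_union" && any(ex$gene_id == id)) {
      sum(GenomicRanges::width(GenomicRanges::reduce(ex[ex$gene_id == id])))
    } else {
      gi <- g[g$gene_id == id]
      if (length(gi) == 0L) stop("gene not in annotation: ", id)
      sum(GenomicRanges::width(GenomicRanges::reduce(gi)))
    }
  }, integer(1L))
}

#' RPKM
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `1e9 * Ri / (Ti * L)`, where `Ri` is the read count of the gene, `Ti`
#' the total reads mapped to the counted gene set in the sample, and `L`
#' the gene length in nucleotides. Vectorized over `Ri` and `L`.
#'
#' @param Ri gene read count(s).
#' @param Ti total mapped reads over the counted gene set.
#' @param L gene length(s), nt.
#' @return Numeric RPKM value(s).
#' @export
#' @examples
#' rpkm(100, 1e6, 1000)  # 100
rpkm <- function(Ri, Ti, L) {
  if (any(Ti == 0)) stop("Ti must be positive")
  if (any(L == 0)) stop("gene length must be positive")
  stopifnot(all(Ri >= 0))
  1e9 * Ri / (Ti * L)
}

#' RPKM table over a counted gene set
#'
#' Computes `Ti` per sample as the total reads over the gene set and
#' applies [rpkm()] per gene.
#'
#' @param counts data.frame with `gene_id`, `sample_id`, `reads`.
#' @param lengths named vector of gene lengths (nt); genes absent from it
#'   are dropped from the counted set.
#' @return data.frame with `gene_id`, `sample_id`, `reads`, `Ti`, `rpkm`.
#' @export
rpkm_table <- function(counts, lengths) {
  counts <- counts[counts$gene_id %in% names(lengths), , drop = FALSE]
  if (nrow(counts) == 0L) stop("no counted genes overlap the gene set")
  ti <- tapply(counts$reads, counts$sample_id, sum)
  counts$Ti <- as.numeric(ti[counts$sample_id])
  counts$rpkm <- rpkm(counts$reads, counts$Ti,
                      as.numeric(lengths[counts$gene_id]))
  rownames(counts) <- NULL
  counts
}

#' Efficiency-corrected qPCR expression ratio
#'
#' Target expression normalized to a reference gene:
#' `(1 + E_target)^(max_cycles - Cq_target) /
#'  (1 + E_ref)^(max_cycles - Cq_ref)`.
#'
#' @param cq_target,cq_ref quantification cycles.
#' @param e_target,e_ref amplification efficiencies (1 = perfect doubling);
#'   must exceed -1.
#' @param max_cycles cycle ceiling of the run; default 35.
#' @return Numeric ratio(s). Vectorized.
#' @export
#' @examples
#' qpcr_normalized_expression(30, 32, 1, 1)  # 2^5 / 2^3 = 4
qpcr_normalized_expression <- function(cq_target, cq_ref, e_target, e_ref,
                                       max_cycles = 35) {
  if (any(e_target <= -1) || any(e_ref <= -1)) {
    stop("amplification efficiency must be greater than -1")
  }
  if (any(cq_target > max_cycles) || any(cq_ref > max_cycles)) {
    warning("Cq above max_cycles (", max_cycles, ")")
  }
  (1 + e_target)^(max_cycles - cq_target) / (1 + e_ref)^(max_cycles - cq_ref)
}

#' Read a qPCR table
#'
#' Columns: `sample_id`, `cq_target`, `e_target`, `cq_ref`, `e_ref`.
#' @param path file path.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("qPCR file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "cq_target", "e_target", "cq_ref", "e_ref")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("qPCR file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Pair per-line editing with expression
#'
#' Joins replicate editing fractions and replicate normalized-expression
#' values by transgenic line and reports per-line means and standard errors
#' on both axes (sample SD / sqrt(n); `NA` with a single replicate). Lines
#' present in only one input are dropped with a warning.
#'
#' @param editing data.frame with `line_id` and `editing_percent`
#'   (replicate rows).
#' @param expression data.frame with `line_id` and `expression`
#'   (replicate rows).
#' @return data.frame with one row per line: `line_id`, `n_editing`,
#'   `mean_editing`, `se_editing`, `n_expression`, `mean_expression`,
#'   `se_expression`.
#' @export
pair_editing_expression <- function(editing, expression) {
  le <- unique(editing$line_id)
  lx <- unique(expression$line_id)
  common <- intersect(le, lx)
  if (length(common) == 0L) stop("no overlapping line_id between inputs")
  unmatched <- setdiff(union(le, lx), common)
  if (length(unmatched)) {
    warning("line(s) present in only one input dropped: ",
            paste(unmatched, collapse = ", "))
  }
  out <- do.call(rbind, lapply(common, function(ln) {
    ev <- editing$editing_percent[editing$line_id == ln]
    xv <- expression$expression[expression$line_id == ln]
    data.frame(line_id = ln,
               n_editing = length(ev), mean_editing = mean(ev),
               se_editing = .se(ev),
               n_expression = length(xv), mean_expression = mean(xv),
               se_expression = .se(xv), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write GFF3 annotation
#'
#' Thin wrappers around rtracklayer for the GFF3 annotations used by
#' [build_modified_annotation()] and [select_gene_set()].
#'
#' @param path file path.
#' @return `read_annotation`: a `GRanges`; `write_annotation`: `path`,
#'   invisibly.
#' @export
read_annotation <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' @rdname read_annotation
#' @param annotation `GRanges` to write.
#' @export
write_annotation <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gff3")
  invisible(path)
}
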