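# Cis-element co-evolution profiling.
#
# Orthologous windows around an editing site are partitioned by the
# genomic state at the edited position: species whose genome carries a C
# still require editing; species carrying a T have lost the editing event
# (the genome already encodes the edited state). Per-position symbol
# frequencies are then compared between the two groups; a position is
# highlighted when either group contains a nucleotide absent from the
# other ("new nucleotides introduced"), and faded otherwise.

#' Build a set of species cis-elements
#'
#' @param species character vector of species names.
#' @param window character vector of equal-length, gap-free nucleotide
#'   windows covering positions `span[1]..span[2]` relative to the edited
#'   position (position 0 = the edited / genomically substituted base).
#' @param frame_offset codon phase of position 0 (0-2), recycled.
#' @param span integer pair, relative coordinates of the first and last
#'   window position; default `c(-20, 4)` covers the PPR footprint and the
#'   edited codon.
#' @return data.frame of class `cis_elements` with `species`, `window`
#'   (RNA alphabet), `frame_offset`, `genomic_state` and a `span`
#'   attribute.
#' @export
cis_elements <- function(species, window, frame_offset = 0L, span = c(-20L, 4L)) {
  stopifnot(length(species) == length(window))
  window <- .to_rna(window)
  wl <- unique(nchar(window))
  if (length(wl) > 1L) stop("windows must all have the same length")
  if (length(window) && wl != span[2L] - span[1L] + 1L) {
    stop("window length (", wl, ") does not match span ",
         span[1L], "..", span[2L])
  }
  chars <- unique(unlist(strsplit(window, "", fixed = TRUE)))
  bad <- setdiff(chars, RNA_BASES)
  if (length(bad)) stop("non-nucleotide character(s) in windows: ",
                        paste(bad, collapse = ", "))
  pos0 <- 1L - span[1L]
  b0 <- substr(window, pos0, pos0)
  state <- ifelse(b0 == "C", "C_requires_editing",
                  ifelse(b0 == "U", "T_editing_lost", "other"))
  out <- data.frame(species = species, window = window,
                    frame_offset = as.integer(frame_offset),
                    genomic_state = state, stringsAsFactors = FALSE)
  attr(out, "span") <- as.integer(span)
  class(out) <- c("cis_elements", "data.frame")
  out
}

#' Partition cis-elements by the genomic state at the edited position
#'
#' @param elements a [cis_elements()] data.frame (or any data.frame with
#'   `window` and a `span` attribute).
#' @return A list with `requires_editing` (genomic C at position 0),
#'   `editing_lost` (genomic T) and `other` (any other base; reported with
#'   a warning when non-empty).
#' @export
partition_by_genomic_state <- function(elements) {
  if (nrow(elements) == 0L) stop("no cis-elements to partition")
  st <- elements$genomic_state
  out <- list(requires_editing = elements[st == "C_requires_editing", , drop = FALSE],
              editing_lost = elements[st == "T_editing_lost", , drop = FALSE],
              other = elements[st == "other", , drop = FALSE])
  if (nrow(out$other) > 0L) {
    warning(nrow(out$other), " element(s) with a non-C/T base at the edited ",
            "position routed to `other`")
  }
  if (nrow(out$requires_editing) == 0L || nrow(out$editing_lost) == 0L) {
    warning("one genomic-state group is empty")
  }
  out
}

#' Per-position divergence profile of two cis-element groups
#'
#' Computes, per alignment position, each group's nucleotide frequency
#' vector and flags the position `highlighted` when the two groups'
#' observed symbol sets differ (a nucleotide present in one group is
#' absent from the other); positions with identical symbol sets are faded.
#' With `within_group = TRUE` the comparison is instead against each
#' group's own consensus: a position is highlighted when either group
#' contains a symbol different from that group's majority base.
#'
#' @param group_a,group_b data.frames with a `window` column (equal window
#'   lengths across both groups).
#' @param span integer pair of relative coordinates; default taken from
#'   `group_a`'s `span` attribute, else `c(-20, 4)`.
#' @param within_group alternative consensus-based fading rule (default
#'   FALSE, across-group symbol-set comparison).
#' @return A list with `frequencies` (long data.frame: `position`, `base`,
#'   `freq_a`, `freq_b`) and `positions` (data.frame: `position`,
#'   `highlighted`).
#' @export
position_profile <- function(group_a, group_b, span = NULL,
                             within_group = FALSE) {
  wa <- .to_rna(group_a$window)
  wb <- .to_rna(group_b$window)
  if (length(wa) == 0L || length(wb) == 0L) stop("both groups must be non-empty")
  wl <- unique(nchar(c(wa, wb)))
  if (length(wl) > 1L) stop("all windows must have the same length")
  if (is.null(span)) span <- attr(group_a, "span") %||% c(-20L, 4L)
  ma <- matrix(unlist(strsplit(wa, "", fixed = TRUE)), ncol = wl, byrow = TRUE)
  mb <- matrix(unlist(strsplit(wb, "", fixed = TRUE)), ncol = wl, byrow = TRUE)
  pos <- seq(span[1L], span[2L])
  freq <- function(col) {
    t <- table(factor(col, levels = RNA_BASES))
    as.numeric(t) / length(col)
  }
  rows <- lapply(seq_len(wl), function(j) {
    fa <- freq(ma[, j])
    fb <- freq(mb[, j])
    hl <- if (within_group) {
      length(unique(ma[, j])) > 1L || length(unique(mb[, j])) > 1L
    } else {
      !setequal(unique(ma[, j]), unique(mb[, j]))
    }
    list(freq = data.frame(position = pos[j], base = RNA_BASES,
                           freq_a = fa, freq_b = fb,
                           stringsAsFactors = FALSE),
         hl = data.frame(position = pos[j], highlighted = hl))
  })
  list(frequencies = do.call(rbind, lapply(rows, `[[`, "freq")),
       positions = do.call(rbind, lapply(rows, `[[`, "hl")))
}

#' Translate a cis-element window
#'
#' Drops `frame_offset` leading bases so that translation starts at a codon
#' boundary, drops any trailing partial codon, and translates with the
#' standard genetic code. `T` and `U` are equivalent.
#'
#' @param window nucleotide string.
#' @param frame_offset codon phase of the window's first base (0-2).
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_window("CCA")   # "P"
#' translate_window("CTA")   # "L"
translate_window <- function(window, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  w <- .to_dna(window)
  chars <- unique(strsplit(w, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, DNA_BASES)
  if (length(bad)) stop("non-nucleotide character(s) in window: ",
                        paste(bad, collapse = ", "))
  w <- substr(w, frame_offset + 1L, nchar(w))
  n_codon <- nchar(w) %/% 3L
  if (n_codon == 0L) stop("window too short to contain a full codon")
  w <- substr(w, 1L, 3L * n_codon)
  as.character(Biostrings::translate(Biostrings::DNAString(w)))
}

#' Translate all windows of a cis-element group
#'
#' @param elements a [cis_elements()] data.frame.
#' @return The input with an added `peptide` column.
#' @export
translate_elements <- function(elements) {
  elements$peptide <- vapply(seq_len(nrow(elements)), function(i) {
    translate_window(elements$window[i], elements$frame_offset[i])
  }, character(1L))
  elements
}
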