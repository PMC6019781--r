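# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize a genome argument (Biostrings::DNAStringSet, DNAString, or a
# character vector of sequences) to an uppercase named character vector.
#' @noRd
.as_seq_char <- function(genome) {
  if (methods::is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else if (is.character(genome)) {
    if (length(genome) == 0L) stop("empty genome")
    out <- toupper(genome)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    stop("`genome` must be a DNAStringSet or a character vector of sequences")
  }
  nm <- names(out)
  nm[nm == ""] <- paste0("seq", which(nm == ""))
  names(out) <- nm
  out
}

#' @noRd
.comp_base <- function(b) {
  m <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
  unname(m[b])
}

# Canonical RNA form: uppercase, T -> U.
#' @noRd
.to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Canonical DNA form: uppercase, U -> T.
#' @noRd
.to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @noRd
.check_base <- function(base) {
  b <- .to_rna(base)
  bad <- !(b %in% RNA_BASES)
  if (any(bad)) {
    stop("base(s) outside the nucleotide alphabet {A, C, G, U/T}: ",
         paste(unique(base[bad]), collapse = ", "))
  }
  b
}

# Population (divide-by-n) standard deviation.
#' @noRd
.pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

# Sample standard error of the mean; NA for a single value.
#' @noRd
.se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' @noRd
.seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
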