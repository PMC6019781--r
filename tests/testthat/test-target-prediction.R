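# Candidate-site enumeration, alignment scoring and z-score ranking.

test_that("YC enumeration matches hand-derived cases on both strands", {
  s <- enumerate_candidate_sites(c(chr = "TCA"), window_len = 2)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 2L)
  expect_equal(s$strand, "+")
  expect_equal(s$context_5prime, "U")

  expect_equal(nrow(enumerate_candidate_sites(c(chr = "AAA"), 2)), 0L)

  s <- enumerate_candidate_sites(c(chr = "GCC"), 2)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 3L)
  expect_equal(s$context_5prime, "C")

  # a reverse-strand site: forward GA = C preceded by U on the minus strand
  s <- enumerate_candidate_sites(c(chr = "TTGAT"), 2)
  rev <- s[s$strand == "-", ]
  expect_equal(rev$position, 3L)
  expect_equal(rev$context_5prime, "U")

  expect_error(enumerate_candidate_sites(character(0), 2), "empty genome")
})

test_that("enumeration agrees with a brute-force oracle on random sequences", {
  for (s in 1:5) {
    set.seed(200 + s)
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- enumerate_candidate_sites(c(chr = seq), window_len = 6)
    want <- oracle_yc_sites(seq)
    expect_setequal(paste(got$position, got$strand),
                    paste(want$position, want$strand))
  }
})

test_that("enumeration is strand-symmetric under reverse complement", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  a <- enumerate_candidate_sites(c(chr = seq), 5)
  b <- enumerate_candidate_sites(c(chr = rc), 5)
  # site (p, +) on seq maps to (n - p + 1, -) on the reverse complement
  mapped <- paste(n - a$position + 1, ifelse(a$strand == "+", "-", "+"))
  expect_setequal(mapped, paste(b$position, b$strand))
  # windows travel with the site
  key_a <- setNames(a$window, mapped)
  key_b <- setNames(b$window, paste(b$position, b$strand))
  expect_identical(key_a[order(names(key_a))], key_b[order(names(key_b))])
})

test_that("edge windows are N-padded by default and droppable by flag", {
  # window (-1..1) relative to the C at 2: two positions off the 5' end
  s <- enumerate_candidate_sites(c(chr = "TCA"), window_len = 3, offset = 1)
  expect_equal(s$window, "NNT")
  s2 <- enumerate_candidate_sites(c(chr = "TCA"), 3, offset = 1,
                                  pad_edges = FALSE)
  expect_equal(nrow(s2), 0L)
})

test_that("alignment scoring sums per-position lookups and handles N", {
  tab <- toy_table()
  arr <- ppr_array("f", data.frame(motif_class = c("P1", "S1"),
                                   aa5 = c("T", "S"), aa_last = c("D", "N")))
  expect_equal(score_alignment(arr, "AG", tab), 1.2 + (-0.9))
  expect_equal(score_alignment(arr, "NN", tab), 0)
  expect_error(score_alignment(arr, "AGG", tab), "length")

  unknown <- ppr_array("g", data.frame(motif_class = rep("P1", 2),
                                       aa5 = "Q", aa_last = "Q"))
  expect_equal(score_alignment(unknown, "AU", tab), 0)
})

test_that("alignment scoring equals the independent oracle on random instances", {
  for (s in 1:20) {
    set.seed(300 + s)
    tab <- random_table(12)
    arr <- random_array(tab, n_motifs = 6L)
    w <- paste(sample(c("A", "C", "G", "U", "N"), 6, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.08)), collapse = "")
    expect_equal(score_alignment(arr, w, tab), oracle_score(arr, w, tab))
  }
})

test_that("z-scores use the population SD: engineered two-site genome", {
  # one motif; table scores U=10 for (T,D), others 0; windows 'T' vs 'A'
  tab <- code_table(data.frame(aa5 = "T", aa_last = "D",
                               A = 0, C = 0, G = 0, U = 10))
  arr <- ppr_array("f", data.frame(motif_class = "P1", aa5 = "T", aa_last = "D"))
  # exactly two YC sites: C4 (window base b[1] = T -> 10) and C9 (b[6] = A -> 0)
  g <- c(chr = "TTTCAAACCAAAA")
  sc <- scan_factor(arr, g, tab, offset = 3)
  # verify the engineered spread
  expect_setequal(sc$alignments$raw_score, c(0, 10))
  expect_equal(sc$mean_score, 5)
  expect_equal(sc$sd_score, 5)          # divide-by-n, not n-1
  expect_setequal(sc$alignments$z_score, c(-1, 1))
})

test_that("scan z-scores have mean 0 and population SD 1", {
  set.seed(77)
  tab <- random_table(10)
  arr <- random_array(tab, 8)
  g <- sim_genome(2000, seed = 78)
  sc <- scan_factor(arr, g, tab)
  z <- sc$alignments$z_score
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
})

test_that("degenerate score spread raises an error naming the factor", {
  tab <- code_table(data.frame(aa5 = "T", aa_last = "D",
                               A = 1, C = 1, G = 1, U = 1))
  arr <- ppr_array("flatfac", data.frame(motif_class = "P1",
                                         aa5 = "T", aa_last = "D"))
  expect_error(scan_factor(arr, c(chr = "AATCAAACCAAA"), tab, offset = 2),
               "flatfac")
})

test_that("scan top hit equals exhaustive double-loop search on small genomes", {
  for (s in 1:5) {
    set.seed(400 + s)
    tab <- random_table(12)
    arr <- random_array(tab, 5)
    g <- sim_genome(300, seed = 400 + s)
    sc <- scan_factor(arr, g, tab)
    # independent exhaustive search over candidate sites
    seqc <- as.character(g)[[1]]
    sites <- oracle_yc_sites(seqc)
    b <- strsplit(seqc, "")[[1]]
    best <- -Inf
    for (i in seq_len(nrow(sites))) {
      p <- sites$position[i]; st <- sites$strand[i]
      idx <- if (st == "+") (p - 4 - 5 + 1):(p - 4) else (p + 4 + 5 - 1):(p + 4)
      w <- ifelse(idx >= 1 & idx <= length(b), b[idx], "N")
      if (st == "-") w <- chartr("ACGTN", "TGCAN", w)
      sc_i <- oracle_score(arr, paste(w, collapse = ""), tab)
      if (sc_i > best) best <- sc_i
    }
    expect_equal(sc$top_hits$raw_score[1], best)
  }
})

test_that("raw score never decreases as windows match more motif preferences", {
  set.seed(55)
  tab <- random_table(12)
  arr <- random_array(tab, 8)
  pw <- strsplit(preferred_window(arr, tab), "")[[1]]
  w <- rep("A", 8)
  prev <- score_alignment(arr, paste(w, collapse = ""), tab)
  for (i in seq_along(pw)) {
    w[i] <- pw[i]
    cur <- score_alignment(arr, paste(w, collapse = ""), tab)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("planted preferred-window sites rank first both ways", {
  set.seed(66)
  tab <- random_table(14)
  planted_fac <- random_array(tab, 10, "planted")
  scrambled <- random_array(tab, 10, "scrambled")
  g <- sim_genome(5000, seed = 67)
  pt <- plant_target(g, planted_fac, tab, 2500, "+")
  sc <- scan_factor(planted_fac, pt$genome, tab)
  expect_equal(sc$top_hits$position[1], 2500)
  expect_equal(sc$top_hits$strand[1], "+")

  rk <- rank_factors_for_site(list(planted_fac, scrambled), "chrSim", 2500,
                              "+", pt$genome, tab)
  expect_equal(rk$factor_id[1], "planted")
})

test_that("ranking a non-YC site is rejected", {
  tab <- toy_table()
  arr <- ppr_array("f", data.frame(motif_class = "P1", aa5 = "T", aa_last = "D"))
  # C at position 3 preceded by A (a purine) on the forward strand
  expect_error(rank_factors_for_site(list(arr), "chr", 3, "+",
                                     c(chr = "TACAAAA"), tab),
               "pyrimidine")
  # and a position that is not even a C
  expect_error(rank_factors_for_site(list(arr), "chr", 2, "+",
                                     c(chr = "TACAAAA"), tab),
               "not a C")
})

test_that("a single-factor ranking returns a singleton", {
  tab <- toy_table()
  arr <- ppr_array("only", data.frame(motif_class = c("P1", "S1"),
                                      aa5 = c("T", "S"), aa_last = c("D", "N")))
  g <- sim_genome(500, seed = 9)
  sites <- enumerate_candidate_sites(g, 2)
  s1 <- sites[sites$position > 20 & sites$position < 480, ][1, ]
  rk <- rank_factors_for_site(list(arr), s1$seq_id, s1$position, s1$strand, g, tab)
  expect_equal(nrow(rk), 1L)
  expect_equal(rk$factor_id, "only")
})
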