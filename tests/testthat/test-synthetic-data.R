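# Seeded generators: reproducibility, statistical calibration, planting.

test_that("genome simulation is reproducible and respects the GC dial", {
  g1 <- sim_genome(500, seed = 1)
  g2 <- sim_genome(500, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(sim_genome(500, seed = 2)),
                         as.character(g1)))

  at_only <- as.character(sim_genome(200, gc = 0, seed = 3))[[1]]
  expect_true(grepl("^[AT]+$", at_only))

  # GC recovery within 3 binomial SEs at length 1e5
  g <- as.character(sim_genome(1e5, gc = 0.36, seed = 4))[[1]]
  obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.36), 3 * sqrt(0.36 * 0.64 / 1e5))

  expect_error(sim_genome(10), "at least 50")
  expect_error(sim_genome(100, gc = 1.2), "gc")
})

test_that("planted targets score the factor's maximum and rank first", {
  for (s in 1:3) {
    set.seed(500 + s)
    tab <- random_table(14)
    arr <- random_array(tab, 10)
    g <- sim_genome(5000, seed = 500 + s)
    pt <- plant_target(g, arr, tab, 2500, "+")
    sc <- scan_factor(arr, pt$genome, tab)
    top <- sc$top_hits[1, ]
    expect_equal(top$position, 2500)
    # the planted window scores the maximum achievable raw score
    expect_equal(top$raw_score,
                 score_alignment(arr, preferred_window(arr, tab), tab))
  }
})

test_that("minus-strand planting mirrors plus-strand planting", {
  set.seed(61)
  tab <- random_table(12)
  arr <- random_array(tab, 8)
  g <- sim_genome(500, seed = 61)
  n <- 500
  pt_minus <- plant_target(g, arr, tab, 250, "-")
  rc <- Biostrings::reverseComplement(pt_minus$genome)
  names(rc) <- names(pt_minus$genome)
  pt_plus <- plant_target(g, arr, tab, n - 250 + 1, "+")
  # reverse complement of the minus-strand construction contains the same
  # planted site as the direct plus-strand construction at the mapped position
  sc1 <- scan_factor(arr, rc, tab)
  expect_equal(sc1$top_hits$position[1], n - 250 + 1)
  expect_equal(sc1$top_hits$raw_score[1],
               scan_factor(arr, pt_plus$genome, tab)$top_hits$raw_score[1])
})

test_that("planting collisions and out-of-bounds windows are rejected", {
  set.seed(62)
  tab <- random_table(12)
  arr <- random_array(tab, 8)
  g <- sim_genome(200, seed = 62)
  pt <- plant_target(g, arr, tab, 100, "+")
  expect_error(plant_target(pt$genome, arr, tab, 102, "+",
                            manifest = pt$manifest), "collision")
  expect_error(plant_target(g, arr, tab, 5, "+"), "beyond the sequence")
})

test_that("pileup simulation is calibrated to the binomial model", {
  g <- sim_genome(200, seed = 71)
  b <- strsplit(as.character(g)[[1]], "")[[1]]
  cpos <- which(b == "C")[1]

  # degenerate: error 0, fraction 1 -> all reads edited
  sim <- simulate_pileups(g, data.frame(position = cpos, strand = "+",
                                        low_expr = 1, control = 1, over_expr = 1),
                          depth = 100, error_rate = 0, replicates = 1, seed = 72)
  row <- sim$pileups[sim$pileups$position == cpos &
                       sim$pileups$strand == "+", ][1, ]
  expect_equal(row$nT, 100)
  expect_equal(row$nC, 0)

  # fraction recovery: mean of 500 replicate draws near 0.5 at depth 1000
  set.seed(73)
  draws <- replicate(500, {
    s <- simulate_pileups(g, data.frame(position = cpos, strand = "+",
                                        low_expr = 0.5, control = 0.5,
                                        over_expr = 0.5),
                          depth = 1000, error_rate = 0, replicates = 1)
    r <- s$pileups[s$pileups$position == cpos & s$pileups$strand == "+", ][1, ]
    r$nT / 1000
  })
  se <- sqrt(0.25 / 1000) / sqrt(500)
  expect_lt(abs(mean(draws) - 0.5), 4 * se)

  expect_error(simulate_pileups(g, depth = 0), "depth")
})

test_that("decoy sites are homopolymer-flagged and excluded by the caller", {
  set.seed(81)
  tab <- random_table(12)
  arr <- random_array(tab, 10)
  st <- simulate_study(arr, tab, genome_length = 2000, seed = 81)
  for (p in st$decoys) {
    expect_true(flag_homopolymer_context(st$genome, "chrSim", p, "+", 2))
  }
  res <- call_induced_events(st$pileups, st$genotype_map, st$genome)
  expect_false(any(st$decoys %in% res$calls$position))
  expect_setequal(res$flagged$position, st$decoys)
})

test_that("count simulation recovers true RPKM up to multinomial noise", {
  lengths <- setNames(c(500, 1000, 2000, 800), paste0("g", 1:4))
  true_rpkm <- setNames(c(50, 50, 10, 200), paste0("g", 1:4))
  cts <- simulate_counts(lengths, true_rpkm, total_reads = 1e6, seed = 91)
  # single gene gets everything
  one <- simulate_counts(c(g1 = 500), c(g1 = 3), 1000, seed = 92)
  expect_equal(one$reads, 1000)
  # equal rpkm, double length -> expected 1:2 count ratio
  two <- simulate_counts(c(a = 1000, b = 2000), c(a = 5, b = 5), 1e6, seed = 93)
  expect_lt(abs(two$reads[2] / two$reads[1] - 2), 0.05)
  # recovery through rpkm_table: estimated/true constant across genes,
  # each within 3 relative SEs of the shared rescaling
  tab <- rpkm_table(cts, lengths)
  est <- tab$rpkm[match(names(true_rpkm), tab$gene_id)]
  ratio <- est / true_rpkm
  p <- true_rpkm * lengths / sum(true_rpkm * lengths)
  rel_se <- sqrt((1 - p) / (1e6 * p))
  expect_true(all(abs(ratio / mean(ratio) - 1) < 3 * rel_se + 1e-3))
  expect_error(simulate_counts(lengths, true_rpkm * 0, 100), "all-zero")
})

test_that("qPCR simulation encodes the requested ratio", {
  q0 <- simulate_qpcr(4, cq_noise_sd = 0, n = 2, seed = 95)
  r0 <- qpcr_normalized_expression(q0$cq_target, q0$cq_ref, q0$e_target, q0$e_ref)
  expect_equal(r0, c(4, 4))
  # geometric mean of noisy recoveries near truth
  q <- simulate_qpcr(4, cq_noise_sd = 0.1, n = 1000, seed = 96)
  r <- qpcr_normalized_expression(q$cq_target, q$cq_ref, q$e_target, q$e_ref)
  # log2 ratio is Gaussian with SD sqrt(2)*0.1 cycles
  se <- sqrt(2) * 0.1 / sqrt(1000)
  expect_lt(abs(mean(log2(r)) - 2), 4 * se)
  expect_error(simulate_qpcr(4, e_ref = -1), "efficiency")
})

test_that("seed segregation follows the 3:1 Mendelian model", {
  d <- simulate_seed_segregation(10000, seed = 101)
  expect_equal(d$n_green + d$n_white, 10000L)
  expect_lt(abs(d$n_white / 10000 - 0.25), 3 * sqrt(0.1875 / 10000))
  expect_equal(simulate_seed_segregation(0), list(n_seeds = 0L, n_green = 0L,
                                                  n_white = 0L))
  expect_error(simulate_seed_segregation(-1), "non-negative")
})

test_that("the full synthetic pipeline is reproducible under one seed", {
  set.seed(111)
  tab <- random_table(12)
  arr <- random_array(tab, 10)
  s1 <- simulate_study(arr, tab, genome_length = 1500, seed = 7)
  s2 <- simulate_study(arr, tab, genome_length = 1500, seed = 7)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$decoys, s2$decoys)
})
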