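test_that("haplotype distance sums squared size differences with exclusions", {
  panel <- toy_panel(3)
  mk <- function(tokens) {
    calls <- lapply(tokens, parse_allele)
    names(calls) <- panel$loci
    haplotype("x", calls)
  }
  h1 <- mk(c("10", "15", "null"))
  h2 <- mk(c("12", "15", "17"))
  d <- haplotype_distance(h1, h2, panel)
  expect_equal(d$value, 4)                       # (10-12)^2, null skipped
  expect_identical(d$included_loci, c("L1", "L2"))
  expect_equal(haplotype_distance(h1, h1, panel)$value, 0)
  # single locus 10 vs 14
  p1 <- toy_panel(1)
  a <- pop_from_matrix("a", matrix(c(10, 14), 2, 1), p1)
  expect_equal(haplotype_distance(a$haplotypes[[1]], a$haplotypes[[2]],
                                  p1)$value, 16)
  # intermediate alleles use the decimal size
  hi <- mk(c("10.1", "15", "12"))
  hj <- mk(c("10", "15", "12"))
  expect_equal(haplotype_distance(hi, hj, panel)$value, 0.1^2,
               tolerance = 1e-9)
  # duplications are excluded pairwise; all-anomalous comparison errors
  hd <- mk(c("10,11", "null", "null"))
  expect_error(haplotype_distance(hd, mk(c("10", "null", "null")), panel),
               "no loci remain")
})

test_that("two-level AMOVA matches a brute-force oracle", {
  p1 <- toy_panel(1)
  # hand example: pop1 {10,10,11}, pop2 {13,14,14}
  m1 <- matrix(c(10, 10, 11), 3, 1)
  m2 <- matrix(c(13, 14, 14), 3, 1)
  res <- amova_two_level(list(pop_from_matrix("a", m1, p1),
                              pop_from_matrix("b", m2, p1)))
  orc <- amova_oracle(list(m1, m2))
  expect_equal(res$phi, orc$phi, tolerance = 1e-12)
  expect_equal(res$sigma2_among, orc$sigma2_among, tolerance = 1e-12)
  expect_equal(res$sigma2_within, orc$sigma2_within, tolerance = 1e-12)
  expect_equal(res$df_among, 1L)
  expect_equal(res$df_within, 4L)
  # random multi-locus instances with up to 10 individuals, 2-3 pops
  set.seed(23)
  for (rep in 1:20) {
    P <- sample(2:3, 1)
    sizes <- sample(2:4, P, replace = TRUE)
    L <- sample(1:4, 1)
    mats <- lapply(sizes, function(n) {
      matrix(sample(8:16, n * L, replace = TRUE), n, L)
    })
    panel <- toy_panel(L)
    pops <- lapply(seq_len(P), function(i) {
      pop_from_matrix(paste0("p", i), mats[[i]], panel)
    })
    res <- amova_two_level(pops)
    orc <- amova_oracle(mats)
    expect_equal(res$phi, orc$phi, tolerance = 1e-9)
    expect_equal(res$sigma2_among, orc$sigma2_among, tolerance = 1e-9)
    expect_equal(res$sigma2_within, orc$sigma2_within, tolerance = 1e-9)
    # additivity of the decomposition
    expect_equal(res$ssd_total, res$ssd_among + res$ssd_within,
                 tolerance = 1e-9)
  }
})

test_that("AMOVA degenerate and separated cases behave as specified", {
  p1 <- toy_panel(1)
  # identical fixed populations: phi defined as 0
  same <- lapply(c("a", "b"), function(l) {
    pop_from_matrix(l, matrix(12, 4, 1), p1)
  })
  expect_equal(amova_two_level(same)$phi, 0)
  # complete separation: phi = 1
  sep <- list(pop_from_matrix("a", matrix(10, 5, 1), p1),
              pop_from_matrix("b", matrix(14, 5, 1), p1))
  res <- amova_two_level(sep)
  expect_equal(res$sigma2_within, 0)
  expect_equal(res$phi, 1)
  # N <= P errors
  tiny <- list(pop_from_matrix("a", matrix(10, 1, 1), p1),
               pop_from_matrix("b", matrix(11, 1, 1), p1))
  expect_error(amova_two_level(tiny), "more individuals")
})

test_that("phi is invariant to size shifts and scale", {
  set.seed(31)
  p2 <- toy_panel(2)
  m1 <- matrix(sample(10:14, 10, replace = TRUE), 5, 2)
  m2 <- matrix(sample(12:16, 10, replace = TRUE), 5, 2)
  base <- amova_two_level(list(pop_from_matrix("a", m1, p2),
                               pop_from_matrix("b", m2, p2)))$phi
  shifted <- amova_two_level(list(pop_from_matrix("a", m1 + 7, p2),
                                  pop_from_matrix("b", m2 + 7, p2)))$phi
  scaled <- amova_two_level(list(pop_from_matrix("a", m1 * 3, p2),
                                 pop_from_matrix("b", m2 * 3, p2)))$phi
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("pairwise R_ST matrices are symmetric with near-zero self pairs", {
  set.seed(47)
  cfg <- sim_config(pop_sizes = c(A = 20, B = 20, C = 20), seed = 53)
  pops <- simulate_smm(cfg)
  M <- pairwise_rst(unname(pops))
  expect_equal(M, t(M))
  expect_equal(diag(M), c(A = 0, B = 0, C = 0))
  # a population against a relabeled copy of itself: no real structure
  copy <- pops$A
  copy$population <- "A2"
  # an exact copy gives a small deterministic negative (about -1/(n-1))
  phi_self <- amova_two_level(list(pops$A, copy))$phi
  expect_lt(abs(phi_self), 0.06)
})

test_that("permutation p-values are reproducible, exact under separation", {
  p1 <- toy_panel(1)
  sep <- list(pop_from_matrix("a", matrix(10, 5, 1), p1),
              pop_from_matrix("b", matrix(14, 5, 1), p1))
  # complete separation: observed phi = 1 is the maximum, so only the
  # ~2/choose(10,5) of permutations that recreate the exact split tie it;
  # p is near (1 + 999*2/252)/1000, bounded well below any alpha in use
  p_sep <- permutation_p(sep, n_perm = 999, seed = 2)
  expect_gte(p_sep, 1 / 1000)
  expect_lt(p_sep, 0.025)
  set.seed(61)
  cfg <- sim_config(pop_sizes = c(A = 12, B = 12), divergence = 100,
                    seed = 67)
  pops <- unname(simulate_smm(cfg))
  p_a <- permutation_p(pops, n_perm = 199, seed = 5)
  p_b <- permutation_p(pops, n_perm = 199, seed = 5)
  expect_identical(p_a, p_b)
  expect_true(p_a > 0 && p_a <= 1)
})

test_that("grouped AMOVA is structurally consistent", {
  set.seed(71)
  p2 <- toy_panel(2)
  mats <- lapply(1:4, function(i) {
    matrix(sample(8:18, 8, replace = TRUE), 4, 2) + 2 * (i > 2)
  })
  pops <- lapply(1:4, function(i) {
    pop_from_matrix(paste0("p", i), mats[[i]], p2)
  })
  g2 <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  res <- amova_grouped(pops, g2)
  # SSD additivity across the three levels
  expect_equal(res$ssd_total,
               res$ssd_among_groups + res$ssd_among_pops +
                 res$ssd_within_pops, tolerance = 1e-9)
  # every population its own group: among-pops-within-groups term vanishes
  gown <- stats::setNames(paste0("g", 1:4), paste0("p", 1:4))
  own <- amova_grouped(pops, gown)
  expect_equal(own$ssd_among_pops, 0)
  expect_equal(own$sigma2_among_pops, 0)
  # single group falls back to the two-level analysis
  gone <- stats::setNames(rep("g", 4), paste0("p", 1:4))
  expect_warning(flat <- amova_grouped(pops, gone), "two_level")
  two <- amova_two_level(pops)
  expect_equal(flat$phi, two$phi, tolerance = 1e-12)
  expect_equal(flat$sigma2_among, two$sigma2_among, tolerance = 1e-12)
})

test_that("distance matrices round-trip through the text format", {
  M <- matrix(c(0, 0.1, -0.02, 0.1, 0, 0.3, -0.02, 0.3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  f <- file.path(tempdir(), "rst.tsv")
  write_dist_matrix(M, f)
  expect_equal(read_dist_matrix(f), M)
})
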