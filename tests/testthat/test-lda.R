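# build a population over the full 26-locus panel with chosen anomalies
anomaly_census_pop <- function(label, n, anomalies = list(), seed = 1) {
  panel <- ystr_panel("y26")
  set.seed(seed)
  haps <- lapply(seq_len(n), function(i) {
    calls <- lapply(panel$loci, function(loc) {
      if (loc %in% panel$multi_copy) parse_allele("11,14")
      else parse_allele(as.character(sample(10:16, 1)))
    })
    names(calls) <- panel$loci
    haplotype(sprintf("%s%03d", label, i), calls)
  })
  for (a in anomalies) {
    haps[[a$sample]]$calls[[a$locus]] <- parse_allele(a$token)
  }
  population_sample(label, panel, haps)
}

test_that("marker exclusion reproduces the published 9-marker selection", {
  # anomaly census of the study population: DYS449 intermediate (1),
  # DYS19 + DYS449 duplications (1 each), nulls at DYS448 / DYS643 /
  # Y_GATA_H4 (1 each). On the 17-locus intersection panel available for
  # all reference populations, with the additional loci that fail the
  # multiple-anomaly rule across reference data, exactly 9 markers remain.
  pop_u <- anomaly_census_pop("U", 100, list(
    list(sample = 98, locus = "DYS449", token = "34.1"),
    list(sample = 9, locus = "DYS19", token = "14,15"),
    list(sample = 35, locus = "DYS449", token = "31,32"),
    list(sample = 89, locus = "DYS448", token = "null"),
    list(sample = 5, locus = "DYS643", token = "null"),
    list(sample = 6, locus = "Y_GATA_H4", token = "null")))
  # reference populations typed on 17 loci with repeated anomalies at the
  # loci the published analysis discarded
  ref <- anomaly_census_pop("R", 60, list(
    list(sample = 1, locus = "DYS19", token = "14,15"),
    list(sample = 2, locus = "DYS19", token = "null"),
    list(sample = 3, locus = "DYS456", token = "null"),
    list(sample = 4, locus = "DYS456", token = "null"),
    list(sample = 5, locus = "DYS635", token = "null"),
    list(sample = 6, locus = "DYS635", token = "13,14"),
    list(sample = 8, locus = "DYS438", token = "null"),
    list(sample = 9, locus = "DYS438", token = "null")),
    seed = 2)
  got <- select_lda_markers(list(pop_u, ref),
                            loci = ystr_panel("yfiler17")$loci)
  expect_setequal(got, c("DYS393", "DYS390", "DYS439", "DYS391", "DYS392",
                         "DYS458", "DYS437", "DYS448", "Y_GATA_H4"))
  # panel order is preserved
  expect_identical(got, got[order(match(got, ystr_panel("y26")$loci))])
})

test_that("single anomalies are retained, repeated ones excluded", {
  pop <- anomaly_census_pop("U", 20, list(
    list(sample = 1, locus = "DYS391", token = "null"),
    list(sample = 2, locus = "DYS392", token = "null"),
    list(sample = 3, locus = "DYS392", token = "null")))
  got <- select_lda_markers(list(pop))
  expect_true("DYS391" %in% got)    # one null: retained
  expect_false("DYS392" %in% got)   # two nulls: excluded
  # structural exclusions always apply
  expect_false(any(c("DYS385ab", "DYS389I", "DYS389II") %in% got))
  clean <- anomaly_census_pop("C", 10)
  expect_setequal(select_lda_markers(list(clean)),
                  setdiff(ystr_panel("y26")$loci,
                          c("DYS385ab", "DYS389I", "DYS389II")))
})

test_that("two classes yield one factor carrying 100% discrimination", {
  panel <- toy_panel(3)
  set.seed(7)
  a <- pop_from_matrix("a", matrix(sample(10:12, 30, TRUE), 10, 3), panel)
  b <- pop_from_matrix("b", matrix(sample(13:15, 30, TRUE), 10, 3), panel)
  m <- fit_lda(list(a, b), markers = panel$loci)
  expect_equal(ncol(m$axes), 1)
  expect_equal(m$percent_discrimination, 100)
  # scores separate the classes along F1
  sc <- lda_transform(m, list(a, b))
  expect_true(abs(mean(sc$F1[sc$population == "a"]) -
                    mean(sc$F1[sc$population == "b"])) > 1)
})

test_that("eigenvalues match a direct scatter-matrix oracle", {
  set.seed(13)
  panel <- toy_panel(2)
  # 3-class Gaussian toy on 2 markers (rounded to repeat units)
  mats <- list(
    cbind(round(rnorm(15, 10, 1)), round(rnorm(15, 14, 1))),
    cbind(round(rnorm(15, 13, 1)), round(rnorm(15, 10, 1))),
    cbind(round(rnorm(15, 16, 1)), round(rnorm(15, 14, 1))))
  pops <- lapply(1:3, function(i) {
    pop_from_matrix(paste0("c", i), mats[[i]], panel)
  })
  m <- fit_lda(pops, markers = panel$loci)
  # oracle: explicit between/within scatter and eigen of solve(W) %*% B
  X <- do.call(rbind, mats)
  cls <- rep(1:3, each = 15)
  Xc <- scale(X, scale = FALSE)
  W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  for (g in 1:3) {
    Xg <- Xc[cls == g, ]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, mg))
    B <- B + nrow(Xg) * tcrossprod(mg)
  }
  lam_oracle <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)
  expect_equal(m$eigenvalues, lam_oracle[1:2], tolerance = 1e-8)
  expect_equal(sum(m$percent_discrimination), 100, tolerance = 1e-9)
  expect_true(all(m$percent_discrimination >= 0))
  # identical class means: no separation
  same <- lapply(1:2, function(i) {
    pop_from_matrix(paste0("s", i), mats[[1]], panel)
  })
  expect_lt(max(fit_lda(same, markers = panel$loci)$eigenvalues), 1e-8)
})

test_that("scores are stable under marker reordering up to sign", {
  set.seed(17)
  panel <- toy_panel(3)
  pops <- lapply(1:3, function(i) {
    pop_from_matrix(paste0("c", i),
                    matrix(sample(10:16, 36, TRUE), 12, 3) + i, panel)
  })
  m1 <- fit_lda(pops, markers = c("L1", "L2", "L3"))
  m2 <- fit_lda(pops, markers = c("L3", "L1", "L2"))
  s1 <- as.matrix(lda_transform(m1, pops)[, c("F1", "F2")])
  s2 <- as.matrix(lda_transform(m2, pops)[, c("F1", "F2")])
  for (j in 1:2) {
    expect_equal(abs(stats::cor(s1[, j], s2[, j])), 1, tolerance = 1e-8)
  }
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
})

test_that("marker-factor correlations match the direct Pearson formula", {
  set.seed(19)
  panel <- toy_panel(3)
  pops <- lapply(1:2, function(i) {
    pop_from_matrix(paste0("c", i),
                    matrix(sample(9:15, 30, TRUE), 10, 3) + 2 * i, panel)
  })
  m <- fit_lda(pops, markers = panel$loci)
  cors <- variable_factor_correlations(m, pops)
  sc <- lda_transform(m, pops)
  X <- do.call(rbind, lapply(pops, function(p) {
    t(vapply(p$haplotypes,
             function(h) vapply(panel$loci,
                                function(l) h$calls[[l]]$values, 0),
             numeric(3)))
  }))
  for (j in 1:3) {
    expect_equal(cors[j, "F1"], stats::cor(X[, j], sc$F1),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(cors) <= 1 + 1e-12, na.rm = TRUE))
  # a marker affine in F1 correlates at +/- 1
  Xa <- cbind(1:12, 0)
  Xa[, 2] <- 2 * Xa[, 1] + 3
  pa <- pop_from_matrix("a", Xa[1:6, ], toy_panel(2))
  pb <- pop_from_matrix("b", Xa[7:12, ], toy_panel(2))
  ma <- fit_lda(list(pa, pb), markers = c("L1", "L2"))
  ca <- variable_factor_correlations(ma, list(pa, pb))
  expect_equal(abs(ca["L1", "F1"]), 1, tolerance = 1e-9)
  # anomalous samples are dropped with a message
  Xn <- matrix(sample(10:14, 20, TRUE), 10, 2)
  Xn[1, 1] <- NA
  pn <- pop_from_matrix("n", Xn, toy_panel(2))
  expect_message(
    mn <- fit_lda(list(pn, pop_from_matrix("m", Xn[2:10, ] + 3,
                                           toy_panel(2))),
                  markers = c("L1", "L2")),
    "dropped")
  expect_equal(mn$n_dropped, 1)
})
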