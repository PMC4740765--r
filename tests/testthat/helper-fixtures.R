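# Fixtures and independent oracles shared across the test files.

# simple all-single-copy panel with k loci
toy_panel <- function(k = 3, name = "toy") {
  new_panel <- getFromNamespace("new_panel", "ystrkit")
  loci <- if (k > 0) paste0("L", seq_len(k)) else character()
  new_panel(name, loci)
}

# population from a numeric matrix (rows = males, cols = panel loci);
# NA -> null call, list entries of length 2 -> duplication
pop_from_matrix <- function(label, X, panel) {
  haps <- lapply(seq_len(nrow(X)), function(i) {
    calls <- lapply(seq_along(panel$loci), function(j) {
      v <- X[i, j]
      if (is.na(v)) return(parse_allele("null"))
      parse_allele(format(v))
    })
    names(calls) <- panel$loci
    haplotype(sprintf("%s_%02d", label, i), calls)
  })
  population_sample(label, panel, haps)
}

# Brute-force two-level AMOVA oracle: explicit loops over all pairs and a
# direct solve of the moment equations. Takes a list of numeric matrices
# (one per population, rows = individuals, cols = loci).
amova_oracle <- function(mats) {
  X <- do.call(rbind, mats)
  sizes <- vapply(mats, nrow, 0L)
  N <- nrow(X)
  P <- length(mats)
  grp <- rep(seq_len(P), sizes)
  d2 <- function(a, b) sum((X[a, ] - X[b, ])^2)
  ssd_tot <- 0
  for (a in seq_len(N - 1)) for (b in seq(a + 1, N)) {
    ssd_tot <- ssd_tot + d2(a, b)
  }
  ssd_tot <- ssd_tot / N
  ssd_win <- 0
  for (g in seq_len(P)) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      acc <- 0
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in seq(a + 1, length(idx))) {
          acc <- acc + d2(idx[a], idx[b])
        }
      }
      ssd_win <- ssd_win + acc / length(idx)
    }
  }
  msd_a <- (ssd_tot - ssd_win) / (P - 1)
  msd_w <- ssd_win / (N - P)
  n_bar <- (N - sum(sizes^2) / N) / (P - 1)
  s2a <- (msd_a - msd_w) / n_bar
  s2w <- msd_w
  list(sigma2_among = s2a, sigma2_within = s2w,
       phi = if (s2a + s2w == 0) 0 else s2a / (s2a + s2w))
}

# fixed 5-taxon unrooted tree and its additive distance matrix
additive_fixture <- function() {
  # unrooted topology ((A,B),(C,D),E) with internal node X = parent of
  # A,B; Y = parent of C,D; Z = center joining X, Y, E
  bl <- c(A = 2, B = 3, C = 1.5, D = 4, E = 6, X = 1, Y = 2.5)
  paths <- list(
    c("A", "B", "A.B"), c("A", "C", "A.X.Y.C"), c("A", "D", "A.X.Y.D"),
    c("A", "E", "A.X.E"), c("B", "C", "B.X.Y.C"), c("B", "D", "B.X.Y.D"),
    c("B", "E", "B.X.E"), c("C", "D", "C.D"), c("C", "E", "C.Y.E"),
    c("D", "E", "D.Y.E")
  )
  labs <- c("A", "B", "C", "D", "E")
  M <- matrix(0, 5, 5, dimnames = list(labs, labs))
  for (p in paths) {
    edges <- strsplit(p[3], ".", fixed = TRUE)[[1]]
    M[p[1], p[2]] <- M[p[2], p[1]] <- sum(bl[edges])
  }
  list(D = M, branch = bl,
       newick = "((A:2,B:3):1,(C:1.5,D:4):2.5,E:6);")
}

# deterministic random haplotype over a panel (integer alleles 8..20,
# occasional anomalies)
random_haplotype <- function(panel, id, anomalies = FALSE) {
  calls <- lapply(panel$loci, function(loc) {
    if (anomalies && stats::runif(1) < 0.1) {
      return(parse_allele(sample(c("null", "12,13", "14.1"), 1)))
    }
    parse_allele(as.character(sample(8:20, 1)))
  })
  names(calls) <- panel$loci
  haplotype(id, calls)
}

# enumerate partitions of `total` into exactly `parts` integer parts, each
# >= min_part, non-increasing order (oracle for forced count structures)
enumerate_partitions <- function(total, parts, min_part = 2) {
  if (parts == 1) {
    if (total >= min_part) return(list(total))
    return(list())
  }
  out <- list()
  for (first in seq(min_part, total - min_part * (parts - 1))) {
    for (rest in enumerate_partitions(total - first, parts - 1, min_part)) {
      if (first >= rest[1]) out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}
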