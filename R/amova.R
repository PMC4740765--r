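#' Squared repeat-size distance between two haplotypes
#'
#' The molecular distance underlying R_ST: the sum over included loci of
#' the squared difference in repeat size, the natural metric under the
#' stepwise mutation model. Intermediate alleles use their decimal size.
#' Loci where either call is null or duplicated are excluded pairwise (no
#' renormalization), and multi-copy loci are excluded by default because
#' their two values have no unambiguous pairing; `multi_copy = "sorted_pair"`
#' instead pairs sorted values and sums both squared differences.
#'
#' @param h1,h2 `ystr_haplotype` objects conforming to `panel`.
#' @param panel a `ystr_panel`.
#' @param multi_copy `"exclude"` (default) or `"sorted_pair"`.
#' @return list with `value` (the distance) and `included_loci`.
#' @export
haplotype_distance <- function(h1, h2, panel, multi_copy = "exclude") {
  stopifnot(inherits(panel, "ystr_panel"))
  multi_copy <- match.arg(multi_copy, c("exclude", "sorted_pair"))
  total <- 0
  included <- character()
  for (loc in panel$loci) {
    c1 <- h1$calls[[loc]]
    c2 <- h2$calls[[loc]]
    if (loc %in% panel$multi_copy) {
      if (multi_copy == "exclude") next
      if (c1$state == "null" || c2$state == "null") next
      v1 <- sort(c1$values); v2 <- sort(c2$values)
      if (length(v1) != length(v2)) next
      total <- total + sum((v1 - v2)^2)
      included <- c(included, loc)
    } else {
      if (is_anomalous(c1) || is_anomalous(c2)) next
      total <- total + (c1$values - c2$values)^2
      included <- c(included, loc)
    }
  }
  if (!length(included)) {
    stop("no loci remain after anomaly exclusion for samples ",
         h1$sample_id, " and ", h2$sample_id, call. = FALSE)
  }
  list(value = total, included_loci = included)
}

# N x N squared-size distance matrix with pairwise locus deletion,
# vectorized per locus over the size matrix (NA = excluded call)
squared_distance_matrix <- function(pops, multi_copy = "exclude") {
  if (inherits(pops, "ystr_population")) pops <- list(pops)
  m <- size_matrix(pops)
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    dj <- outer(x, x, "-")^2
    dj[is.na(dj)] <- 0  # pairwise deletion, no renormalization
    D <- D + dj
  }
  if (multi_copy == "sorted_pair") {
    panel <- pops[[1]]$panel
    for (loc in panel$multi_copy) {
      vals <- list()
      i <- 0L
      for (s in pops) for (h in s$haplotypes) {
        i <- i + 1L
        call <- h$calls[[loc]]
        vals[[i]] <- if (call$state == "null") NULL else sort(call$values)
      }
      for (a in seq_len(n)) for (b in seq_len(n)) {
        va <- vals[[a]]; vb <- vals[[b]]
        if (a < b && !is.null(va) && !is.null(vb) &&
            length(va) == length(vb)) {
          d <- sum((va - vb)^2)
          D[a, b] <- D[a, b] + d
          D[b, a] <- D[b, a] + d
        }
      }
    }
  }
  attr(D, "population") <- attr(m, "population")
  D
}

# core two-level variance-component decomposition from a precomputed
# squared-distance matrix and a grouping factor
.amova2_core <- function(D, grp) {
  grp <- as.factor(grp)
  N <- nrow(D)
  P <- nlevels(grp)
  if (N <= P) stop("need more individuals than populations", call. = FALSE)
  ssd_total <- sum(D[upper.tri(D)]) / N
  sizes <- tabulate(grp)
  ssd_within <- 0
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      Dg <- D[idx, idx, drop = FALSE]
      ssd_within <- ssd_within + sum(Dg[upper.tri(Dg)]) / length(idx)
    }
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1L
  df_within <- N - P
  msd_among <- ssd_among / df_among
  msd_within <- ssd_within / df_within
  n_bar <- (N - sum(sizes^2) / N) / (P - 1)
  sigma2_within <- msd_within
  sigma2_among <- (msd_among - msd_within) / n_bar
  tot <- sigma2_among + sigma2_within
  phi <- if (tot == 0) 0 else sigma2_among / tot
  list(ssd_total = ssd_total, ssd_among = ssd_among,
       ssd_within = ssd_within, df_among = df_among, df_within = df_within,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       phi = phi)
}

#' Two-level AMOVA and R_ST
#'
#' Decomposes the total sum of squared molecular distances into among- and
#' within-population components (sum of squared deviations of a group =
#' sum of its pairwise squared distances divided by group size) and solves
#' the moment equations for the variance components. The Phi-statistic on
#' squared repeat-size distances is R_ST. Negative estimates are retained.
#'
#' @param pops list of `ystr_population` (>= 2) on a shared panel.
#' @param multi_copy policy for multi-copy loci, see
#'   [haplotype_distance()].
#' @param n_perm if > 0, a permutation p-value for Phi is computed by
#'   randomly reassigning individuals to populations (sizes preserved),
#'   with the add-one estimator `p = (1 + #{perm >= obs})/(n_perm + 1)`.
#' @param seed integer seed for the permutations.
#' @return an object of class `amova_result` with variance components,
#'   degrees of freedom, `phi`, and optionally `p_value`.
#' @export
amova_two_level <- function(pops, multi_copy = "exclude", n_perm = 0,
                            seed = NULL) {
  stopifnot(is.list(pops), length(pops) >= 2)
  D <- squared_distance_matrix(pops, multi_copy)
  grp <- attr(D, "population")
  res <- .amova2_core(D, grp)
  if (n_perm > 0) {
    res$p_value <- .perm_p(D, grp, res$phi, n_perm, seed)
    res$n_perm <- n_perm
  }
  structure(res, class = "amova_result")
}

.perm_p <- function(D, grp, phi_obs, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(grp)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    phi_b <- .amova2_core(D, grp[perm])$phi
    if (phi_b >= phi_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' @rdname amova_two_level
#' @export
permutation_p <- function(pops, n_perm = 10000, seed = NULL,
                          multi_copy = "exclude") {
  stopifnot(n_perm >= 1)
  amova_two_level(pops, multi_copy, n_perm = n_perm, seed = seed)$p_value
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA on squared repeat-size distances\n")
  cat(sprintf("  among pops : df=%d  sigma2=%.6g\n", x$df_among,
              x$sigma2_among))
  cat(sprintf("  within pops: df=%d  sigma2=%.6g\n", x$df_within,
              x$sigma2_within))
  cat(sprintf("  Phi (R_ST) = %.4f\n", x$phi))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p_value,
                x$n_perm))
  }
  invisible(x)
}

#' Pairwise R_ST matrix
#'
#' Runs a two-level AMOVA for every pair of populations and assembles the
#' symmetric matrix of Phi-statistics (zero diagonal, negatives retained).
#'
#' @inheritParams amova_two_level
#' @return a labeled symmetric matrix of class `matrix`.
#' @export
pairwise_rst <- function(pops, multi_copy = "exclude") {
  stopifnot(is.list(pops), length(pops) >= 2)
  labels <- vapply(pops, function(s) s$population, "")
  P <- length(pops)
  M <- matrix(0, P, P, dimnames = list(labels, labels))
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      phi <- amova_two_level(pops[c(i, j)], multi_copy)$phi
      M[i, j] <- M[j, i] <- phi
    }
  }
  M
}

#' Three-level (grouped) AMOVA
#'
#' Decomposes variance among groups of populations, among populations
#' within groups, and within populations, with the standard moment
#' estimators and Phi-statistics (Phi_CT among groups, Phi_SC among
#' populations within groups, Phi_ST overall). A single group delegates to
#' [amova_two_level()] with a warning.
#'
#' @inheritParams amova_two_level
#' @param grouping named character vector mapping population label to
#'   group label.
#' @param n_perm if > 0, permutation p-value for Phi_CT obtained by
#'   permuting whole populations among groups.
#' @return object of class `amova_grouped_result` (or `amova_result` for a
#'   single group).
#' @export
amova_grouped <- function(pops, grouping, multi_copy = "exclude",
                          n_perm = 0, seed = NULL) {
  stopifnot(is.list(pops), length(pops) >= 2)
  labels <- vapply(pops, function(s) s$population, "")
  if (!all(labels %in% names(grouping))) {
    stop("grouping lacks entries for: ",
         paste(setdiff(labels, names(grouping)), collapse = ", "),
         call. = FALSE)
  }
  gof <- as.character(grouping[labels])
  if (length(unique(gof)) == 1L) {
    warning("only one group; falling back to amova_two_level()")
    return(amova_two_level(pops, multi_copy))
  }
  D <- squared_distance_matrix(pops, multi_copy)
  pop <- attr(D, "population")
  grp <- gof[match(pop, labels)]
  res <- .amova3_core(D, pop, grp)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gperm <- sample(gof)
      grpb <- gperm[match(pop, labels)]
      phib <- .amova3_core(D, pop, grpb)$phi_ct
      if (phib >= res$phi_ct - 1e-12) hits <- hits + 1L
    }
    res$p_value <- (1 + hits) / (n_perm + 1)
    res$n_perm <- n_perm
  }
  structure(res, class = "amova_grouped_result")
}

.amova3_core <- function(D, pop, grp) {
  pop <- as.factor(pop)
  N <- nrow(D)
  P <- nlevels(pop)
  groups <- unique(grp)
  G <- length(groups)
  ssd_of <- function(idx) {
    if (length(idx) < 2) return(0)
    Di <- D[idx, idx, drop = FALSE]
    sum(Di[upper.tri(Di)]) / length(idx)
  }
  ssd_total <- ssd_of(seq_len(N))
  ssd_wp <- sum(vapply(levels(pop), function(p) ssd_of(which(pop == p)), 0))
  ssd_wg <- sum(vapply(groups, function(g) ssd_of(which(grp == g)), 0))
  ssd_ap <- ssd_wg - ssd_wp   # among pops within groups
  ssd_ag <- ssd_total - ssd_wg
  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P
  n_p <- tabulate(pop)
  N_g <- vapply(groups, function(g) sum(grp == g), 0)
  sum_np2_by_g <- vapply(groups, function(g) {
    idx <- which(grp == g)
    sum(tabulate(droplevels(pop[idx]))^2) / length(idx)
  }, 0)
  n1 <- if (df_ap > 0) (N - sum(sum_np2_by_g)) / df_ap else NA_real_
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sigma2_c <- ssd_wp / df_wp
  sigma2_b <- if (df_ap > 0) (ssd_ap / df_ap - sigma2_c) / n1 else 0
  sigma2_a <- (ssd_ag / df_ag - sigma2_c - n2 * sigma2_b) / n3
  tot <- sigma2_a + sigma2_b + sigma2_c
  list(ssd_total = ssd_total, ssd_among_groups = ssd_ag,
       ssd_among_pops = ssd_ap, ssd_within_pops = ssd_wp,
       df_among_groups = df_ag, df_among_pops = df_ap,
       df_within_pops = df_wp,
       sigma2_among_groups = sigma2_a, sigma2_among_pops = sigma2_b,
       sigma2_within_pops = sigma2_c,
       phi_ct = if (tot == 0) 0 else sigma2_a / tot,
       phi_sc = if (sigma2_b + sigma2_c == 0) 0
                else sigma2_b / (sigma2_b + sigma2_c),
       phi_st = if (tot == 0) 0 else (sigma2_a + sigma2_b) / tot)
}

#' @export
print.amova_grouped_result <- function(x, ...) {
  cat("Three-level AMOVA on squared repeat-size distances\n")
  cat(sprintf("  among groups      : df=%d  sigma2=%.6g\n",
              x$df_among_groups, x$sigma2_among_groups))
  cat(sprintf("  among pops/groups : df=%d  sigma2=%.6g\n",
              x$df_among_pops, x$sigma2_among_pops))
  cat(sprintf("  within pops       : df=%d  sigma2=%.6g\n",
              x$df_within_pops, x$sigma2_within_pops))
  cat(sprintf("  Phi_CT=%.4f  Phi_SC=%.4f  Phi_ST=%.4f\n", x$phi_ct,
              x$phi_sc, x$phi_st))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p (Phi_CT) = %.4g\n", x$p_value))
  }
  invisible(x)
}

#' Read and write labeled distance matrices
#'
#' Square delimited-text format: header row of labels, one row per label
#' with the label in the first column. Tab-separated.
#'
#' @param M symmetric labeled matrix.
#' @param path file path.
#' @export
write_dist_matrix <- function(M, path) {
  df <- data.frame(label = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  M
}
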