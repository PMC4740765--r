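#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centers the squared dissimilarity matrix, `B = -1/2 J D^2 J`,
#' and embeds on the top-k eigenvectors scaled by the square roots of the
#' (non-negative) eigenvalues. Dimensions with negative eigenvalues
#' contribute zero coordinates; all eigenvalues are reported. Negative
#' entries of the input (as arise in R_ST matrices) are clamped to zero
#' before squaring.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal (labeled).
#' @param k number of output dimensions (default 2).
#' @return object of class `mds_solution` with `coordinates`
#'   (labels x k, column-centered), `eigenvalues`, and
#'   `proportion_explained` (eigenvalue / sum of positive eigenvalues).
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) ||
      !isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("input must be a symmetric square matrix", call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-12)) {
    stop("input must have a zero diagonal", call. = FALSE)
  }
  stopifnot(k >= 1)
  D <- pmax(D, 0)
  n <- nrow(D)
  D2 <- D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  coords <- matrix(0, n, k, dimnames = list(rownames(D),
                                            paste0("dim", seq_len(k))))
  for (j in seq_len(min(k, n))) {
    if (ev[j] > 1e-12) coords[, j] <- e$vectors[, j] * sqrt(ev[j])
  }
  pos <- sum(ev[ev > 0])
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained =
                   if (pos > 0) ev / pos else rep(0, n)),
            class = "mds_solution")
}

#' @export
print.mds_solution <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("Classical MDS solution, k =", k, "\n")
  cat("  proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained[seq_len(k)]),
            collapse = " "), "\n")
  print(round(x$coordinates, 4))
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q_ij = (m-2) d_ij - r_i - r_j` is joined with the standard
#' branch-length formulas. Ties in Q are broken deterministically by the
#' lexicographically smallest pair of cluster representative labels.
#' Negative branch lengths are kept by default; with `clamp = TRUE` a
#' negative length is set to zero and transferred to the sister branch so
#' path lengths through the new node are preserved.
#'
#' @param D symmetric labeled distance matrix (>= 3 taxa). Small negative
#'   entries are tolerated.
#' @param clamp clamp negative branch lengths (default FALSE).
#' @return an unrooted `phylo` tree (package \pkg{ape}).
#' @export
neighbor_joining <- function(D, clamp = FALSE) {
  D <- as.matrix(D)
  labels <- rownames(D)
  m <- nrow(D)
  if (m < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(labels)) labels <- paste0("t", seq_len(m))
  # each active cluster: newick fragment + representative (min leaf label)
  frag <- labels
  rep_lab <- labels
  act <- seq_len(m)
  d <- D
  fmt <- function(x) sprintf("%.15g", x)
  while (length(act) > 3) {
    mm <- length(act)
    r <- rowSums(d[act, act])
    best <- NULL
    best_q <- Inf
    for (ii in seq_len(mm - 1)) for (jj in seq(ii + 1, mm)) {
      i <- act[ii]; j <- act[jj]
      q <- (mm - 2) * d[i, j] - r[ii] - r[jj]
      pair <- sort(c(rep_lab[i], rep_lab[j]))
      if (q < best_q - 1e-12 ||
          (abs(q - best_q) <= 1e-12 && !is.null(best) &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best_q <- q
        best <- list(i = i, j = j, ri = r[ii], rj = r[jj], pair = pair)
      }
    }
    i <- best$i; j <- best$j
    bi <- d[i, j] / 2 + (best$ri - best$rj) / (2 * (mm - 2))
    bj <- d[i, j] - bi
    if (clamp) {
      if (bi < 0) { bj <- bj + bi; bi <- 0 }
      if (bj < 0) { bi <- bi + bj; bj <- 0 }
    }
    new_frag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":",
                       fmt(bj), ")")
    # distances to the new node
    rest <- setdiff(act, c(i, j))
    dnew <- (d[i, rest] + d[j, rest] - d[i, j]) / 2
    d <- rbind(cbind(d, 0), 0)
    u <- nrow(d)
    d[u, rest] <- dnew
    d[rest, u] <- dnew
    frag <- c(frag, new_frag)
    rep_lab <- c(rep_lab, min(best$pair))
    act <- c(rest, u)
  }
  a <- act[order(rep_lab[act])]
  d12 <- d[a[1], a[2]]; d13 <- d[a[1], a[3]]; d23 <- d[a[2], a[3]]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  if (clamp) { b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0) }
  nwk <- paste0("(", frag[a[1]], ":", fmt(b1), ",", frag[a[2]], ":",
                fmt(b2), ",", frag[a[3]], ":", fmt(b3), ");")
  read_newick(nwk)
}

#' Newick input and output
#'
#' Thin wrappers around \pkg{ape}'s reader and writer that guarantee a
#' terminating semicolon and raise a parse error on malformed input.
#'
#' @param tree a `phylo` object.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return `write_newick()` the Newick string (invisibly if written to
#'   file); `read_newick()` a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text a Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) && is.null(path)) {
    stop("provide a Newick string or a file path", call. = FALSE)
  }
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) {
    stop("malformed Newick: ", n_open, " '(' vs ", n_close,
         " ')' (first imbalance near character ",
         newick_imbalance_pos(text), ")", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string", call. = FALSE)
  }
  tr
}

newick_imbalance_pos <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  length(chars)
}
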