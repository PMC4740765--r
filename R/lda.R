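#' Marker selection for discriminant analysis
#'
#' Applies the exclusion rule used when comparing populations typed with
#' different kits: the multi-copy markers (DYS385ab and the DYS389 pair,
#' whose second fragment contains the first) are excluded structurally, and
#' any locus carrying null or duplicated calls in more than one sample
#' across all populations is excluded; a single anomalous sample does not
#' disqualify a locus.
#'
#' @param pops list of `ystr_population` on a shared panel.
#' @param loci candidate loci; defaults to the shared panel's loci.
#' @return character vector of retained loci in panel order.
#' @export
select_lda_markers <- function(pops, loci = NULL) {
  if (inherits(pops, "ystr_population")) pops <- list(pops)
  panel <- pops[[1]]$panel
  loci <- loci %||% panel$loci
  structural <- c(panel$multi_copy, "DYS389I", "DYS389II")
  keep <- setdiff(loci, structural)
  anom <- stats::setNames(integer(length(keep)), keep)
  for (s in pops) {
    for (h in s$haplotypes) {
      for (loc in keep) {
        if (is_anomalous(h$calls[[loc]])) anom[loc] <- anom[loc] + 1L
      }
    }
  }
  keep <- keep[anom[keep] <= 1L]
  if (length(keep) < 2) {
    stop("fewer than 2 markers survive the exclusion rule", call. = FALSE)
  }
  panel$loci[panel$loci %in% keep]
}

#' Multi-class linear discriminant analysis of allele sizes
#'
#' Solves the generalized eigenproblem of the between-class scatter against
#' the pooled within-class scatter of allele repeat sizes (intermediate
#' alleles enter as decimals). Samples with null or duplicated calls at a
#' retained marker are dropped listwise with a message. Axes are ordered by
#' eigenvalue; `percent_discrimination` is each eigenvalue as a percentage
#' of their sum. The sign of each axis is fixed so the loading of the first
#' marker (panel order) is non-negative. A singular within-class scatter is
#' ridge-regularized (`lambda = 1e-8 * trace/dim`) with a warning.
#'
#' @param pops list of `ystr_population`; the population label is the
#'   class.
#' @param markers markers to use; defaults to [select_lda_markers()].
#' @param standardize scale each marker to unit variance before fitting
#'   (default FALSE, raw repeat sizes).
#' @return object of class `ystr_lda` with `markers`, `class_labels`,
#'   `axes` (markers x factors), `eigenvalues`, `percent_discrimination`,
#'   `class_means`, `center`, `scale`, `n_dropped`.
#' @export
fit_lda <- function(pops, markers = NULL, standardize = FALSE) {
  stopifnot(is.list(pops), length(pops) >= 2)
  markers <- markers %||% select_lda_markers(pops)
  m <- size_matrix(pops, loci = markers)
  cls <- attr(m, "population")
  ok <- stats::complete.cases(m)
  if (any(!ok)) {
    message(sum(!ok), " sample(s) dropped for anomalous calls at ",
            "retained markers")
  }
  m <- m[ok, , drop = FALSE]
  cls <- factor(cls[ok])
  if (nlevels(cls) < 2) stop("need >= 2 classes with usable samples",
                             call. = FALSE)
  center <- colMeans(m)
  scl <- if (standardize) apply(m, 2, stats::sd) else rep(1, ncol(m))
  if (any(scl == 0)) stop("zero-variance marker; cannot standardize",
                          call. = FALSE)
  X <- sweep(sweep(m, 2, center), 2, scl, "/")
  p <- ncol(X)
  W <- matrix(0, p, p)
  mu <- matrix(0, nlevels(cls), p,
               dimnames = list(levels(cls), markers))
  B <- matrix(0, p, p)
  for (g in levels(cls)) {
    Xg <- X[cls == g, , drop = FALSE]
    mg <- colMeans(Xg)
    mu[g, ] <- mg
    Xc <- sweep(Xg, 2, mg)
    W <- W + crossprod(Xc)
    B <- B + nrow(Xg) * tcrossprod(mg)
  }
  L <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(L)) {
    warning("singular within-class scatter; applying ridge regularization")
    W <- W + diag(1e-8 * sum(diag(W)) / p, p)
    L <- chol(W)
  }
  # eigen of W^-1 B via symmetric whitening: W = L'L (chol gives upper L)
  Linv <- backsolve(L, diag(p))
  Msym <- t(Linv) %*% B %*% Linv
  e <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  r <- min(p, nlevels(cls) - 1L)
  lam <- pmax(e$values[seq_len(r)], 0)
  axes <- Linv %*% e$vectors[, seq_len(r), drop = FALSE]
  # sign convention: first marker's loading non-negative per factor
  for (j in seq_len(r)) if (axes[1, j] < 0) axes[, j] <- -axes[, j]
  dimnames(axes) <- list(markers, paste0("F", seq_len(r)))
  structure(list(markers = markers, class_labels = levels(cls),
                 axes = axes, eigenvalues = lam,
                 percent_discrimination = 100 * lam / sum(lam),
                 class_means = mu, center = center, scale = scl,
                 n_dropped = sum(!ok)),
            class = "ystr_lda")
}

#' @export
print.ystr_lda <- function(x, ...) {
  cat("Linear discriminant analysis on", length(x$markers), "markers,",
      length(x$class_labels), "classes\n")
  cat("  factors:",
      paste(sprintf("%s %.3f%%", colnames(x$axes),
                    x$percent_discrimination), collapse = ", "), "\n")
  invisible(x)
}

#' Factor scores and marker-factor correlations
#'
#' `lda_transform()` projects samples onto the discriminant axes (centered
#' with the training means). `variable_factor_correlations()` returns the
#' Pearson correlation of each marker's allele sizes with each factor's
#' scores; markers with zero variance among the scored samples yield `NA`.
#'
#' @param model a `ystr_lda`.
#' @param pops list of `ystr_population` (or a single one) to score.
#' @return `lda_transform()`: a data.frame with columns sample_id,
#'   population and one column per factor. `variable_factor_correlations()`:
#'   a markers x factors matrix.
#' @export
lda_transform <- function(model, pops) {
  stopifnot(inherits(model, "ystr_lda"))
  if (inherits(pops, "ystr_population")) pops <- list(pops)
  m <- size_matrix(pops, loci = model$markers)
  cls <- attr(m, "population")
  ids <- unlist(lapply(pops, function(s) {
    vapply(s$haplotypes, function(h) h$sample_id, "")
  }))
  ok <- stats::complete.cases(m)
  X <- sweep(sweep(m[ok, , drop = FALSE], 2, model$center), 2,
             model$scale, "/")
  sc <- X %*% model$axes
  data.frame(sample_id = ids[ok], population = cls[ok], sc,
             check.names = FALSE)
}

#' @rdname lda_transform
#' @export
variable_factor_correlations <- function(model, pops) {
  stopifnot(inherits(model, "ystr_lda"))
  if (inherits(pops, "ystr_population")) pops <- list(pops)
  m <- size_matrix(pops, loci = model$markers)
  ok <- stats::complete.cases(m)
  m <- m[ok, , drop = FALSE]
  sc <- lda_transform(model, pops)
  fac <- as.matrix(sc[, colnames(model$axes), drop = FALSE])
  out <- matrix(NA_real_, ncol(m), ncol(fac),
                dimnames = list(model$markers, colnames(fac)))
  for (j in seq_len(ncol(m))) {
    if (stats::sd(m[, j]) > 0) {
      out[j, ] <- apply(fac, 2, function(f) {
        if (stats::sd(f) == 0) NA_real_ else stats::cor(m[, j], f)
      })
    }
  }
  out
}
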