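#' Allele frequency tables
#'
#' Frequencies are obtained by direct counting over all allele copies
#' observed at a locus: each numeric or intermediate call contributes one
#' copy, a duplicated call contributes one copy per value (so the number of
#' copies can exceed the number of males), and a null call contributes one
#' copy to the distinct class `"null"`. `n_obs` is the number of allele
#' copies; `n_samples` the number of males. The two differ only when
#' duplications or multi-copy loci are involved, and the distinction
#' matters for gene diversity (see [gene_diversity()]).
#'
#' @param sample a `ystr_population`.
#' @param locus locus name present in the sample panel.
#' @return an object of class `freq_table` with fields `locus`, `alleles`,
#'   `counts`, `n_obs`, `n_samples`, `freqs`.
#' @export
allele_frequencies <- function(sample, locus) {
  stopifnot(inherits(sample, "ystr_population"))
  if (!locus %in% sample$panel$loci) {
    stop("locus '", locus, "' is not in panel '", sample$panel$name, "'",
         call. = FALSE)
  }
  keys <- character()
  for (h in sample$haplotypes) {
    call <- h$calls[[locus]]
    if (call$state == "null") keys <- c(keys, "null")
    else keys <- c(keys, vapply(call$values, format_size, ""))
  }
  tab <- table(keys)
  frequency_table(locus, stats::setNames(as.integer(tab), names(tab)),
                  n_samples = sample$n)
}

#' @rdname allele_frequencies
#' @param counts named integer vector of allele-class counts; names are
#'   allele keys (`"15"`, `"34.1"`, `"null"`, ...).
#' @param n_samples number of males the counts came from; defaults to
#'   `sum(counts)`.
#' @export
frequency_table <- function(locus, counts, n_samples = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  counts <- counts[counts > 0]
  n_obs <- sum(counts)
  ord <- order(suppressWarnings(as.numeric(names(counts))),
               na.last = TRUE)  # numeric order, "null" last
  counts <- counts[ord]
  structure(list(locus = locus, alleles = names(counts),
                 counts = as.integer(counts), n_obs = as.integer(n_obs),
                 n_samples = as.integer(n_samples %||% n_obs),
                 freqs = as.numeric(counts) / n_obs),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("<freq_table ", x$locus, ": ", length(x$alleles), " classes, n_obs=",
      x$n_obs, ", n=", x$n_samples, ">\n", sep = "")
  print(stats::setNames(x$freqs, x$alleles))
  invisible(x)
}

#' Gene diversity (Nei's unbiased heterozygosity analogue)
#'
#' \eqn{GD = n(1 - \sum_i P_i^2)/(n - 1)} where \eqn{P_i} is the relative
#' frequency of the i-th allele class (over all allele copies, including
#' `"null"` and intermediate classes) and n is the number of sampled males.
#' When a duplication inflates the copy count, frequencies are computed
#' over all copies (`n_obs`) but the n in the unbiasedness factor remains
#' the sample size: this is the convention that reproduces published
#' per-locus values at loci with duplications and at the multi-copy locus
#' DYS385ab.
#'
#' @param ft a `freq_table`.
#' @param n override for the sample size n in the formula; defaults to
#'   `ft$n_samples`.
#' @return gene diversity in \[0, 1\].
#' @export
gene_diversity <- function(ft, n = NULL) {
  stopifnot(inherits(ft, "freq_table"))
  n <- n %||% ft$n_samples
  if (n < 2) stop("gene diversity is undefined for n < 2", call. = FALSE)
  sum_p2 <- sum((ft$counts / ft$n_obs)^2)
  n * (1 - sum_p2) / (n - 1)
}

#' Haplotype spectrum
#'
#' The multiset of haplotype counts over canonical keys after projecting to
#' `panel`: n males, k distinct haplotypes, u singletons.
#'
#' @param sample a `ystr_population`.
#' @param panel target panel (subset of the sample panel); defaults to the
#'   sample's own panel.
#' @return an object of class `hap_spectrum` with fields `panel`, `counts`
#'   (named by canonical key), `n`, `k`, `u`.
#' @export
haplotype_spectrum <- function(sample, panel = NULL) {
  stopifnot(inherits(sample, "ystr_population"))
  panel <- panel %||% sample$panel
  proj <- if (identical(panel$loci, sample$panel$loci)) sample
          else project_panel(sample, panel)
  keys <- vapply(proj$haplotypes, canonical_key, "", panel = panel)
  tab <- table(keys)
  spectrum_from_counts(stats::setNames(as.integer(tab), names(tab)),
                       panel = panel$name)
}

#' @rdname haplotype_spectrum
#' @param counts integer vector of haplotype counts (optionally named by
#'   canonical key).
#' @export
spectrum_from_counts <- function(counts, panel = "custom") {
  counts <- as.integer(counts)
  if (length(counts) == 0L || any(counts < 1L)) {
    stop("haplotype counts must be positive integers", call. = FALSE)
  }
  structure(list(panel = panel, counts = counts, n = sum(counts),
                 k = length(counts), u = sum(counts == 1L)),
            class = "hap_spectrum")
}

#' Haplotype-level forensic parameters
#'
#' `haplotype_diversity()` applies the gene-diversity estimator to
#' haplotype frequencies, `HD = n(1 - sum p_i^2)/(n-1)`;
#' `match_probability()` is `MP = sum p_i^2`, the chance two random males
#' share a haplotype; `discrimination_capacity()` is `DC = k/n`;
#' `proportion_unique()` is `PUH = u/n`. `hd_standard_error()` is the
#' square root of Nei's (1987) sampling variance of the diversity
#' estimator.
#'
#' @param s a `hap_spectrum`.
#' @return a single numeric value.
#' @export
haplotype_diversity <- function(s) {
  stopifnot(inherits(s, "hap_spectrum"))
  if (s$n < 2) stop("haplotype diversity is undefined for n < 2",
                    call. = FALSE)
  s$n * (1 - sum((s$counts / s$n)^2)) / (s$n - 1)
}

#' @rdname haplotype_diversity
#' @export
match_probability <- function(s) {
  stopifnot(inherits(s, "hap_spectrum"))
  sum((s$counts / s$n)^2)
}

#' @rdname haplotype_diversity
#' @export
discrimination_capacity <- function(s) {
  stopifnot(inherits(s, "hap_spectrum"))
  s$k / s$n
}

#' @rdname haplotype_diversity
#' @export
proportion_unique <- function(s) {
  stopifnot(inherits(s, "hap_spectrum"))
  s$u / s$n
}

#' @rdname haplotype_diversity
#' @export
hd_standard_error <- function(s) {
  stopifnot(inherits(s, "hap_spectrum"))
  n <- s$n
  p <- s$counts / n
  j2 <- sum(p^2)
  j3 <- sum(p^3)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (j3 - j2^2) + j2 - j2^2)
  sqrt(max(v, 0))
}

#' Multi-panel forensic report
#'
#' One row per panel with sample size n, distinct haplotypes k, singletons
#' u, PUH, MP, DC, HD and its standard error, after projecting the sample
#' onto each panel. Values are rounded half-up to 4 decimals for display
#' parity with published tables; set `digits = NULL` for full precision.
#'
#' @param sample a `ystr_population`.
#' @param panels list of `ystr_panel` (or names of built-ins); defaults to
#'   the five built-in nested panels.
#' @param digits decimals for half-up rounding of the ratio columns, or
#'   `NULL` to disable.
#' @return a `data.frame` with columns panel, n, k, u, PUH, MP, DC, HD, SE.
#' @export
forensic_report <- function(sample, panels = names(builtin_panels()),
                            digits = 4) {
  panels <- lapply(panels, function(p) {
    if (inherits(p, "ystr_panel")) p else ystr_panel(p)
  })
  rows <- lapply(panels, function(p) {
    s <- haplotype_spectrum(sample, p)
    data.frame(panel = p$name, n = s$n, k = s$k, u = s$u,
               PUH = proportion_unique(s), MP = match_probability(s),
               DC = discrimination_capacity(s),
               HD = haplotype_diversity(s), SE = hd_standard_error(s))
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    for (col in c("PUH", "MP", "DC", "HD", "SE")) {
      out[[col]] <- round_half_up(out[[col]], digits)
    }
  }
  out
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() is half-to-even)
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
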