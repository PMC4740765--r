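#' Haplotypes and population samples
#'
#' A haplotype is one male's joint allele profile over a panel; a population
#' sample is a named collection of haplotypes sharing a panel.
#'
#' @param sample_id sample identifier.
#' @param calls named list of `allele_call`, one per panel locus.
#' @return `haplotype()` returns an object of class `ystr_haplotype`;
#'   `population_sample()` an object of class `ystr_population` with fields
#'   `population`, `panel`, `haplotypes`, `n`.
#' @export
haplotype <- function(sample_id, calls) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  structure(list(sample_id = as.character(sample_id), calls = calls),
            class = "ystr_haplotype")
}

#' @rdname haplotype
#' @param population population label.
#' @param panel a `ystr_panel`.
#' @param haplotypes list of `ystr_haplotype` conforming to `panel`.
#' @export
population_sample <- function(population, panel, haplotypes) {
  stopifnot(inherits(panel, "ystr_panel"), is.list(haplotypes))
  for (h in haplotypes) validate_haplotype(h, panel)
  ids <- vapply(haplotypes, function(h) h$sample_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs within population '", population, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(population = as.character(population), panel = panel,
                 haplotypes = haplotypes, n = length(haplotypes)),
            class = "ystr_population")
}

validate_haplotype <- function(h, panel) {
  miss <- setdiff(panel$loci, names(h$calls))
  if (length(miss)) {
    stop("sample ", h$sample_id, " lacks calls at: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (loc in panel$loci) {
    call <- h$calls[[loc]]
    if (!inherits(call, "allele_call")) {
      stop("call at ", loc, " for sample ", h$sample_id,
           " is not an allele_call", call. = FALSE)
    }
  }
  invisible(h)
}

#' @export
print.ystr_population <- function(x, ...) {
  cat("<Y-STR population '", x$population, "': n = ", x$n, ", panel ",
      x$panel$name, " (", panel_size(x$panel), " markers)>\n", sep = "")
  invisible(x)
}

#' Read and write haplotype tables
#'
#' The on-disk format is delimited text (comma or tab, auto-detected on
#' read) with header `SampleID`, `Population`, then one column per panel
#' locus. Allele tokens follow [parse_allele()] syntax; duplications are
#' written `"a,b"` ascending, null as `"null"`.
#'
#' @param path file path.
#' @param panel `ystr_panel` the table must conform to.
#' @return list of `ystr_population`, one per distinct population label in
#'   order of first appearance.
#' @export
read_haplotype_table <- function(path, panel) {
  stopifnot(inherits(panel, "ystr_panel"))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          encoding = "UTF-8")
  need <- c("SampleID", "Population", panel$loci)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("haplotype table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pops <- unique(df$Population)
  out <- lapply(pops, function(p) {
    rows <- which(df$Population == p)
    haps <- lapply(rows, function(i) {
      calls <- lapply(panel$loci, function(loc) {
        parse_allele(df[[loc]][i], locus = loc)
      })
      names(calls) <- panel$loci
      haplotype(df$SampleID[i], calls)
    })
    population_sample(p, panel, haps)
  })
  stats::setNames(out, pops)
}

#' @rdname read_haplotype_table
#' @param samples a `ystr_population` or list of them (shared panel).
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_haplotype_table <- function(samples, path, sep = ",") {
  if (inherits(samples, "ystr_population")) samples <- list(samples)
  panel <- samples[[1]]$panel
  rows <- list(paste(c("SampleID", "Population", panel$loci),
                     collapse = sep))
  for (s in samples) {
    for (h in s$haplotypes) {
      toks <- vapply(panel$loci, function(loc) format_allele(h$calls[[loc]]),
                     "")
      # duplication tokens contain commas: quote them in CSV output
      toks <- ifelse(grepl(sep, toks, fixed = TRUE),
                     paste0('"', toks, '"'), toks)
      rows[[length(rows) + 1L]] <-
        paste(c(h$sample_id, s$population, toks), collapse = sep)
    }
  }
  writeLines(unlist(rows), path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a population sample to a nested panel
#'
#' Drops all calls at loci outside `target`. The number of distinct
#' haplotypes is non-increasing under projection (profiles can only merge).
#'
#' @param sample a `ystr_population`.
#' @param target a `ystr_panel` whose loci are a subset of the sample panel.
#' @return a `ystr_population` on the target panel, same n.
#' @export
project_panel <- function(sample, target) {
  stopifnot(inherits(sample, "ystr_population"), inherits(target, "ystr_panel"))
  extra <- setdiff(target$loci, sample$panel$loci)
  if (length(extra)) {
    stop("target panel has loci absent from the sample panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  haps <- lapply(sample$haplotypes, function(h) {
    haplotype(h$sample_id, h$calls[target$loci])
  })
  population_sample(sample$population, target, haps)
}

#' Canonical haplotype key
#'
#' Deterministic serialization used to define haplotype identity: two
#' haplotypes share a key iff every call is equal (duplications and
#' multi-copy pairs compared as sorted multisets, null matching only null).
#'
#' @param h a `ystr_haplotype`.
#' @param panel the panel fixing locus order.
#' @return a single string.
#' @export
canonical_key <- function(h, panel) {
  toks <- vapply(panel$loci, function(loc) format_allele(h$calls[[loc]]), "")
  paste(toks, collapse = "|")
}

# pool several populations into one relabeled sample
pool_populations <- function(pops, label = "pooled") {
  haps <- list()
  for (s in pops) {
    for (h in s$haplotypes) {
      h$sample_id <- paste0(s$population, ":", h$sample_id)
      haps[[length(haps) + 1L]] <- h
    }
  }
  population_sample(label, pops[[1]]$panel, haps)
}

# numeric allele-size matrix (samples x single-copy loci); null/duplicated
# calls become NA. Used by the distance and LDA machinery.
size_matrix <- function(pops, loci = NULL) {
  if (inherits(pops, "ystr_population")) pops <- list(pops)
  panel <- pops[[1]]$panel
  if (is.null(loci)) loci <- setdiff(panel$loci, panel$multi_copy)
  n <- sum(vapply(pops, function(s) s$n, 0L))
  m <- matrix(NA_real_, n, length(loci), dimnames = list(NULL, loci))
  grp <- character(n)
  i <- 0L
  for (s in pops) {
    for (h in s$haplotypes) {
      i <- i + 1L
      grp[i] <- s$population
      for (j in seq_along(loci)) {
        call <- h$calls[[loci[j]]]
        if (!is_anomalous(call) && length(call$values) == 1L) {
          m[i, j] <- call$values
        }
      }
    }
  }
  attr(m, "population") <- grp
  m
}
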