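#' Simulation configuration for the stepwise-mutation forward simulator
#'
#' The simulator evolves founder haplotypes along a population tree and
#' then independent within-population lineages, under the symmetric
#' single-step stepwise mutation model (SMM): per generation each locus
#' mutates with the per-locus rate, gaining or losing one repeat with equal
#' probability, with a reflecting floor at one repeat. Multi-copy loci
#' carry two values mutating independently.
#'
#' Defaults state a realistic forensic scenario: the average Y-STR
#' mutation rate is about 2e-3 per locus per generation, two populations
#' separated for 300 generations (roughly 7500-9000 years) develop clear
#' structure, and 100 generations of within-population depth provide
#' standing diversity.
#'
#' @param panel a `ystr_panel` (default the 17-locus panel).
#' @param pop_sizes named integer vector: haplotypes per population.
#' @param mut_rate per-locus per-generation mutation probability.
#' @param tree list of edges `list(parent, child, generations)` describing
#'   founder divergence; populations without an edge descend directly from
#'   the root. `NULL` gives every population an independent branch of
#'   `divergence` generations from the root.
#' @param divergence branch length (generations) used when `tree` is NULL.
#' @param within generations of independent within-population evolution
#'   applied to every sampled lineage.
#' @param ancestral named numeric vector of root repeat sizes; defaults to
#'   a plausible modal haplotype (14 repeats at every locus, pairs 11/14 at
#'   multi-copy loci).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(panel = ystr_panel("yfiler17"),
                       pop_sizes = c(popA = 50, popB = 50),
                       mut_rate = 0.002, tree = NULL, divergence = 300,
                       within = 100, ancestral = NULL, seed = NULL) {
  stopifnot(inherits(panel, "ystr_panel"), all(pop_sizes >= 0),
            mut_rate >= 0, mut_rate <= 1, divergence >= 0, within >= 0)
  if (is.null(ancestral)) {
    ancestral <- stats::setNames(rep(14, length(panel$loci)), panel$loci)
  }
  structure(list(panel = panel, pop_sizes = pop_sizes,
                 mut_rate = mut_rate, tree = tree, divergence = divergence,
                 within = within, ancestral = ancestral, seed = seed),
            class = "sim_config")
}

# mutate a vector of repeat sizes for g generations under symmetric SMM
smm_mutate <- function(sizes, rate, generations) {
  if (generations == 0 || rate == 0) return(sizes)
  n_mut <- stats::rbinom(length(sizes), generations, rate)
  steps <- vapply(n_mut, function(k) {
    if (k == 0) 0 else sum(sample(c(-1, 1), k, replace = TRUE))
  }, 0)
  pmax(sizes + steps, 1)  # reflecting floor at one repeat
}

#' Simulate population samples under the stepwise mutation model
#'
#' @param config a [sim_config()].
#' @return named list of `ystr_population`, one per entry of
#'   `config$pop_sizes`.
#' @export
simulate_smm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  if (!length(panel$loci)) stop("panel has no loci", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  # expand ancestral haplotype to one size per allele copy
  copies <- unlist(lapply(panel$loci, function(loc) {
    k <- if (loc %in% panel$multi_copy) 2L else 1L
    v <- config$ancestral[[loc]]
    v <- if (k == 2L) c(max(v - 3, 1), v) else v
    stats::setNames(v, rep(loc, k))
  }))
  pops <- names(config$pop_sizes)
  founders <- list()
  if (is.null(config$tree)) {
    for (p in pops) {
      founders[[p]] <- smm_mutate(copies, config$mut_rate,
                                  config$divergence)
    }
  } else {
    node <- list(root = copies)
    for (edge in config$tree) {
      parent <- node[[edge[[1]]]]
      if (is.null(parent)) {
        stop("tree edge references unknown parent '", edge[[1]], "'",
             call. = FALSE)
      }
      node[[edge[[2]]]] <- smm_mutate(parent, config$mut_rate,
                                      as.numeric(edge[[3]]))
    }
    for (p in pops) founders[[p]] <- node[[p]] %||% node$root
  }
  out <- lapply(pops, function(p) {
    haps <- lapply(seq_len(config$pop_sizes[[p]]), function(i) {
      sizes <- smm_mutate(founders[[p]], config$mut_rate, config$within)
      calls <- lapply(panel$loci, function(loc) {
        v <- unname(sizes[names(sizes) == loc])
        if (length(v) == 2L) new_allele("duplicated", sort(v))
        else new_allele("numeric", v)
      })
      names(calls) <- panel$loci
      # multi-copy pairs are regular two-value calls, not anomalies:
      # recode their state
      for (loc in panel$multi_copy) {
        calls[[loc]]$state <- "duplicated"
      }
      haplotype(sprintf("%s_%03d", p, i), calls)
    })
    population_sample(p, panel, haps)
  })
  stats::setNames(out, pops)
}

#' Admix two populations
#'
#' Each of `n` haplotypes is copied from a uniformly chosen member of
#' `popA` with probability `alpha`, otherwise from `popB` — the simplest
#' model of a hybrid gene pool with contribution `alpha` from side A.
#'
#' @param popA,popB `ystr_population` on a shared panel.
#' @param alpha probability of drawing from `popA`.
#' @param n number of haplotypes to generate.
#' @param seed integer seed.
#' @param label population label of the result.
#' @return a `ystr_population`.
#' @export
admix <- function(popA, popB, alpha = 0.5, n = popA$n, seed = NULL,
                  label = "admixed") {
  stopifnot(inherits(popA, "ystr_population"),
            inherits(popB, "ystr_population"),
            alpha >= 0, alpha <= 1, n >= 0)
  if (!identical(popA$panel$loci, popB$panel$loci)) {
    stop("source populations must share a panel", call. = FALSE)
  }
  if (n > 0 && ((alpha > 0 && popA$n == 0) || (alpha < 1 && popB$n == 0))) {
    stop("cannot sample from an empty source population", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  haps <- lapply(seq_len(n), function(i) {
    src <- if (stats::runif(1) < alpha) popA else popB
    h <- src$haplotypes[[sample.int(src$n, 1)]]
    haplotype(sprintf("%s_%03d", label, i), h$calls)
  })
  population_sample(label, popA$panel, haps)
}

#' Inject typing anomalies
#'
#' Independently for each (sample, locus) pair, converts the call to null,
#' to a duplication (adds a second value one repeat away from the
#' original), or to an intermediate allele (adds a 0.1 partial repeat),
#' with the stated probabilities. The expected anomaly count is
#' `n * n_loci * rate` per type. Multi-copy loci are skipped for
#' duplication injection (they already carry two values).
#'
#' @param sample a `ystr_population`.
#' @param rates named numeric vector with entries `null`, `duplication`,
#'   `intermediate` (missing entries are 0).
#' @param seed integer seed.
#' @return a `ystr_population` with anomalies applied.
#' @export
inject_anomalies <- function(sample, rates = c(null = 0, duplication = 0,
                                               intermediate = 0),
                             seed = NULL) {
  stopifnot(inherits(sample, "ystr_population"))
  r_dup <- if ("duplication" %in% names(rates)) rates[["duplication"]] else 0
  r_int <- if ("intermediate" %in% names(rates)) rates[["intermediate"]] else 0
  r_null <- if ("null" %in% names(rates)) rates[["null"]] else 0
  stopifnot(r_null >= 0, r_dup >= 0, r_int >= 0,
            r_null + r_dup + r_int <= 1)
  if (!is.null(seed)) set.seed(seed)
  panel <- sample$panel
  haps <- lapply(sample$haplotypes, function(h) {
    for (loc in panel$loci) {
      u <- stats::runif(1)
      call <- h$calls[[loc]]
      if (u < r_null) {
        h$calls[[loc]] <- new_allele("null", numeric())
      } else if (u < r_null + r_dup) {
        if (!loc %in% panel$multi_copy && call$state == "numeric") {
          extra <- call$values + sample(c(-1, 1), 1)
          h$calls[[loc]] <- new_allele("duplicated",
                                       sort(c(call$values, max(extra, 1))))
        }
      } else if (u < r_null + r_dup + r_int) {
        if (call$state == "numeric") {
          h$calls[[loc]] <- new_allele("intermediate", call$values + 0.1)
        }
      }
    }
    h
  })
  population_sample(sample$population, panel, haps)
}

#' Resample pseudo-haplotypes from marginal allele frequencies
#'
#' Draws each locus independently from its marginal allele distribution.
#' This destroys haplotype linkage by construction: per-locus statistics
#' (allele frequencies, gene diversity) converge to the inputs, but
#' haplotype-level parameters (HD, MP, DC) of a resample must not be
#' compared with values from real linked data. Multi-copy loci draw two
#' copies per male; the `"null"` class yields a null call; intermediate
#' allele keys yield intermediate calls.
#'
#' @param freq_tables list of `freq_table`, one per panel locus (names
#'   must cover the panel).
#' @param n number of pseudo-haplotypes.
#' @param panel a `ystr_panel`; defaults to a panel built from the table
#'   loci (all single-copy).
#' @param seed integer seed.
#' @param label population label.
#' @return a `ystr_population`.
#' @export
resample_from_marginals <- function(freq_tables, n, panel = NULL,
                                    seed = NULL, label = "resample") {
  loci <- vapply(freq_tables, function(ft) ft$locus, "")
  names(freq_tables) <- loci
  if (is.null(panel)) panel <- new_panel("marginals", loci)
  miss <- setdiff(panel$loci, loci)
  if (length(miss)) {
    stop("no frequency table for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (ft in freq_tables) {
    if (abs(sum(ft$freqs) - 1) > 1e-6) {
      stop("frequencies at ", ft$locus, " do not sum to 1", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(ft, k) sample(ft$alleles, k, replace = TRUE,
                                 prob = ft$freqs)
  haps <- lapply(seq_len(n), function(i) {
    calls <- lapply(panel$loci, function(loc) {
      ft <- freq_tables[[loc]]
      if (loc %in% panel$multi_copy) {
        keys <- draw(ft, 2)
        if (any(keys == "null")) return(new_allele("null", numeric()))
        new_allele("duplicated", sort(as.numeric(keys)))
      } else {
        key <- draw(ft, 1)
        if (key == "null") return(new_allele("null", numeric()))
        v <- as.numeric(key)
        new_allele(if (is_whole(v)) "numeric" else "intermediate", v)
      }
    })
    names(calls) <- panel$loci
    haplotype(sprintf("%s_%05d", label, i), calls)
  })
  population_sample(label, panel, haps)
}
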