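#' Y-STR marker panel definitions
#'
#' A panel is a named, ordered list of Y-STR loci plus the subset of loci
#' that are multi-copy (amplified from two paralogous sites, e.g. DYS385ab,
#' which yields an unordered allele pair). The five built-in panels follow
#' the standard forensic kit definitions and are strictly nested:
#' minimal9 < ppy12 < yfiler17 < ppy23 < y26.
#'
#' @param name panel name (for built-ins one of `"minimal9"`, `"ppy12"`,
#'   `"yfiler17"`, `"ppy23"`, `"y26"`; case-insensitive, `"26Y"` accepted).
#' @param loci character vector of locus names, unique, in reporting order.
#' @param multi_copy character vector, subset of `loci`, loci expected to
#'   carry two values per male.
#' @return An object of class `ystr_panel`.
#' @examples
#' p <- ystr_panel("ppy23")
#' panel_size(p)  # 23: DYS385ab counts as two loci
#' @export
ystr_panel <- function(name, loci = NULL, multi_copy = character()) {
  if (is.null(loci)) {
    key <- tolower(gsub("[-_ ]", "", name))
    key <- switch(key, "26y" = "y26", "minimal" = "minimal9", key)
    builtin <- builtin_panels()
    if (!key %in% names(builtin)) {
      stop("unknown built-in panel '", name, "'; available: ",
           paste(names(builtin), collapse = ", "), call. = FALSE)
    }
    return(builtin[[key]])
  }
  new_panel(name, loci, multi_copy)
}

new_panel <- function(name, loci, multi_copy = character()) {
  stopifnot(is.character(name), length(name) == 1L, is.character(loci))
  if (anyDuplicated(loci)) stop("panel loci must be unique", call. = FALSE)
  if (!all(multi_copy %in% loci)) {
    stop("multi_copy loci must be a subset of panel loci", call. = FALSE)
  }
  structure(list(name = name, loci = loci, multi_copy = multi_copy),
            class = "ystr_panel")
}

# 26-locus reporting order of the Goldeneye 26Y system; nested kit panels
# are subsets of this order.
.LOCI_26 <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
              "DYS393", "DYS385ab", "DYS437", "DYS438", "DYS439", "DYS448",
              "DYS456", "DYS458", "DYS635", "Y_GATA_H4", "DYS576", "DYS570",
              "DYS481", "DYS533", "DYS549", "DYS643", "DYS460", "DYS449",
              "DYS388")

#' @rdname ystr_panel
#' @export
builtin_panels <- function() {
  min9 <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
            "DYS393", "DYS385ab")
  ppy12 <- c(min9, "DYS437", "DYS438", "DYS439")
  yf17 <- c(ppy12, "DYS448", "DYS456", "DYS458", "DYS635", "Y_GATA_H4")
  ppy23 <- c(yf17, "DYS576", "DYS570", "DYS481", "DYS533", "DYS549",
             "DYS643")
  ord <- function(x) .LOCI_26[.LOCI_26 %in% x]
  list(
    minimal9 = new_panel("minimal9", ord(min9), "DYS385ab"),
    ppy12    = new_panel("ppy12", ord(ppy12), "DYS385ab"),
    yfiler17 = new_panel("yfiler17", ord(yf17), "DYS385ab"),
    ppy23    = new_panel("ppy23", ord(ppy23), "DYS385ab"),
    y26      = new_panel("y26", .LOCI_26, "DYS385ab")
  )
}

#' @rdname ystr_panel
#' @param panel a `ystr_panel`.
#' @details `panel_size()` counts each multi-copy locus twice, matching the
#'   conventional kit marker counts (9, 12, 17, 23, 26).
#' @export
panel_size <- function(panel) {
  stopifnot(inherits(panel, "ystr_panel"))
  length(panel$loci) + length(panel$multi_copy)
}

#' Read panel definitions from a JSON config
#'
#' The config maps panel name to either a locus vector or a list with
#' elements `loci` and optional `multi_copy`.
#'
#' @param path path to a JSON file.
#' @return named list of `ystr_panel` objects.
#' @export
read_panel_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(cfg), function(nm) {
    x <- cfg[[nm]]
    if (is.character(x)) new_panel(nm, x)
    else new_panel(nm, as.character(x$loci),
                   as.character(x$multi_copy %||% character()))
  })
  stats::setNames(out, names(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ystr_panel <- function(x, ...) {
  cat("Y-STR panel '", x$name, "': ", panel_size(x), " markers (",
      length(x$loci), " named loci)\n", sep = "")
  cat("  ", paste(x$loci, collapse = ", "), "\n", sep = "")
  if (length(x$multi_copy)) {
    cat("  multi-copy: ", paste(x$multi_copy, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
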