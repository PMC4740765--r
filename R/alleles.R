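#' Allele calls
#'
#' A single typing result at one locus. Four states occur in Y-STR casework:
#' \describe{
#'   \item{numeric}{one integer repeat count, e.g. `15`;}
#'   \item{intermediate}{one non-integer repeat size with a partial repeat,
#'     e.g. `34.1` (34 full repeats plus one partial), ordered between 34
#'     and 35;}
#'   \item{null}{no amplification product (token `"null"`);}
#'   \item{duplicated}{two or more values at a normally single-copy locus,
#'     e.g. `"13,14"`.}
#' }
#' Repeat sizes are held in tenths of a repeat internally, so intermediate
#' alleles are exact and sort correctly.
#'
#' @param token allele token as text, e.g. `"15"`, `"34.1"`, `"null"`,
#'   `"13,14"` (hyphen also accepted as duplication separator on read).
#' @param locus optional locus name used in error messages.
#' @return an object of class `allele_call` with fields `state` and
#'   `values` (numeric, sorted ascending; empty for null).
#' @examples
#' parse_allele("34.1")$state   # "intermediate"
#' parse_allele("13,14")$values # c(13, 14)
#' @export
parse_allele <- function(token, locus = NULL) {
  tok <- trimws(as.character(token))
  where <- if (is.null(locus)) "" else paste0(" at locus ", locus)
  if (length(tok) != 1L || is.na(tok) || !nzchar(tok)) {
    stop("empty allele token", where, call. = FALSE)
  }
  if (tolower(tok) == "null") return(new_allele("null", numeric()))
  # duplication: comma- or hyphen-separated values
  if (grepl("[,-]", tok)) {
    parts <- trimws(strsplit(tok, "[,-]")[[1]])
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || anyNA(vals) || any(vals <= 0)) {
      stop("unparseable allele token '", tok, "'", where, call. = FALSE)
    }
    return(new_allele("duplicated", sort(vals)))
  }
  val <- suppressWarnings(as.numeric(tok))
  if (is.na(val) || val <= 0) {
    stop("unparseable allele token '", tok, "'", where, call. = FALSE)
  }
  if (is_whole(val)) new_allele("numeric", val)
  else new_allele("intermediate", val)
}

# store repeat sizes as exact tenths
new_allele <- function(state, values) {
  structure(list(state = state, values = round(values * 10) / 10),
            class = "allele_call")
}

is_whole <- function(x) abs(x - round(x)) < 1e-9

#' @rdname parse_allele
#' @param call an `allele_call`.
#' @export
format_allele <- function(call) {
  stopifnot(inherits(call, "allele_call"))
  if (call$state == "null") return("null")
  paste(vapply(call$values, format_size, ""), collapse = ",")
}

format_size <- function(v) {
  if (is_whole(v)) sprintf("%d", as.integer(round(v)))
  else sprintf("%.1f", v)
}

#' @export
print.allele_call <- function(x, ...) {
  cat("<allele ", x$state, ": ", format_allele(x), ">\n", sep = "")
  invisible(x)
}

is_anomalous <- function(call) call$state %in% c("null", "duplicated")
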