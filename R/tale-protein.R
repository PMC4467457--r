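#' @import methods
NULL

#' Supported repeat variable diresidues and the canonical TALE code
#'
#' The four RVDs handled by the trained model, mapped to the base each one
#' targets under the canonical one-to-one TALE recognition code
#' (NI to A, HD to C, NN to G, NG to T).
#'
#' @format Named character vector of length 4.
#' @export
RVD_CODE <- c(NI = "A", HD = "C", NN = "G", NG = "T")

#' TALEProtein: an ordered TALE repeat (RVD) array
#'
#' Represents a TALE DNA-binding domain as the ordered sequence of its
#' repeat variable diresidues.  The final element is the C-terminal
#' half-repeat; it contacts a base like any full repeat but counts as 0.5
#' towards the protein's nominal length, following the x.5 repeat-counting
#' convention.  The N-terminal region (NTR), which contacts the obligatory
#' 5' T of the target site, is implicit: it is position 0 of every energy
#' matrix derived for the protein.
#'
#' @slot id single character label.
#' @slot rvds character vector of RVD codes, each one of
#'   \code{names(RVD_CODE)}; the last element is the half-repeat.
#' @export
setClass("TALEProtein",
  representation(id = "character", rvds = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@id) != 1L || is.na(object@id))
      msg <- c(msg, "'id' must be a single string")
    if (length(object@rvds) < 2L)
      msg <- c(msg, "a TALE needs at least 2 repeat elements")
    bad <- which(!object@rvds %in% names(RVD_CODE))
    if (length(bad))
      msg <- c(msg, sprintf("unsupported RVD code '%s' at index %d",
                            object@rvds[bad[1L]], bad[1L]))
    if (length(msg)) msg else TRUE
  })

#' Construct a TALEProtein
#'
#' @param rvds character vector of RVD codes (last element = half-repeat).
#' @param id protein label.
#' @return A \linkS4class{TALEProtein}.
#' @examples
#' TALEProtein(c("NI", "HD", "NN", "NG"))
#' @export
TALEProtein <- function(rvds, id = "TALE") {
  new("TALEProtein", id = id, rvds = as.character(rvds))
}

#' Parse a delimiter-separated RVD string
#'
#' Accepts "-" or whitespace as delimiters, e.g. \code{"NI-HD-NN-NG"} or
#' \code{"NI HD NN NG"}.  Unknown codes are rejected with the offending
#' token and its (1-based) index.
#'
#' @param text RVD string.
#' @param id protein label.
#' @return A \linkS4class{TALEProtein}; the final token is the half-repeat.
#' @examples
#' parseRVD("NI-HD-NN-NG")
#' @export
parseRVD <- function(text, id = "TALE") {
  chkString(text, "'text'")
  toks <- strsplit(trimws(text), "[-[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2L)
    stop("RVD string must contain at least 2 repeat elements, got ",
         length(toks), call. = FALSE)
  bad <- which(!toks %in% names(RVD_CODE))
  if (length(bad))
    stop(sprintf("unknown RVD token '%s' at index %d", toks[bad[1L]], bad[1L]),
         call. = FALSE)
  TALEProtein(toks, id = id)
}

#' @describeIn TALEProtein-class the RVD codes of a protein
#' @param x,object a \code{TALEProtein}
#' @export
setGeneric("rvds", function(x) standardGeneric("rvds"))

#' @rdname TALEProtein-class
#' @export
setMethod("rvds", "TALEProtein", function(x) x@rvds)

#' @rdname TALEProtein-class
#' @export
setMethod("length", "TALEProtein", function(x) length(x@rvds))

#' Nominal repeat count (the x.5 convention)
#'
#' Number of repeat elements minus 0.5: the C-terminal half-repeat counts
#' as half a repeat, so a protein of 10 elements has nominal length 9.5.
#'
#' @param x a \linkS4class{TALEProtein}.
#' @return numeric scalar.
#' @export
setGeneric("nominalLength", function(x) standardGeneric("nominalLength"))

#' @rdname nominalLength
#' @export
setMethod("nominalLength", "TALEProtein",
          function(x) length(x@rvds) - 0.5)

#' Canonical target site of a TALE under the one-to-one code
#'
#' The 5' T contacted by the NTR followed by one base per repeat element
#' under NI to A, HD to C, NN to G, NG to T.  The site length is therefore
#' the number of repeat elements plus one.
#'
#' @param x a \linkS4class{TALEProtein}.
#' @return character DNA string.
#' @examples
#' canonicalTargetSite(parseRVD("NI-HD-NN-NG"))  # "TACGT"
#' @export
setGeneric("canonicalTargetSite", function(x)
  standardGeneric("canonicalTargetSite"))

#' @rdname canonicalTargetSite
#' @export
setMethod("canonicalTargetSite", "TALEProtein", function(x) {
  paste0("T", paste(RVD_CODE[x@rvds], collapse = ""))
})

#' Format a TALEProtein back to its canonical "-"-delimited RVD string
#'
#' @param x a \linkS4class{TALEProtein}.
#' @param ... unused.
#' @return character scalar such as \code{"NI-HD-NN-NG"}.
#' @export
setMethod("as.character", "TALEProtein", function(x, ...) {
  paste(x@rvds, collapse = "-")
})

setMethod("show", "TALEProtein", function(object) {
  cat("TALEProtein", object@id, "\n")
  cat("  ", as.character(object), "\n", sep = "")
  cat(sprintf("  %.1f nominal repeats; target site %s (%d bp)\n",
              nominalLength(object), canonicalTargetSite(object),
              length(object@rvds) + 1L))
})

## Build the TALE that targets `site` (which must start with T) under the
## inverse canonical code.  Used by the design pipeline.
proteinForSite <- function(site, id = paste0("TALE_", site)) {
  bases <- strsplit(site, "")[[1L]]
  if (bases[1L] != "T")
    stop("a canonical TALE target site must start with T", call. = FALSE)
  inv <- setNames(names(RVD_CODE), RVD_CODE)
  TALEProtein(unname(inv[bases[-1L]]), id = id)
}
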