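#' EnergyMatrix: per-position, per-base binding free-energy changes
#'
#' A 4 x L matrix of ddG values in RT units.  Row names are the bases
#' A, C, G, T; column j describes position j-1 of the binding site, with
#' position 0 the 5' T contacted by the N-terminal region.  Each column
#' carries an anchor base (the canonical-code base for that position);
#' after \code{normalizeEM} the anchor entry is exactly 0 and every other
#' entry is the free-energy penalty (possibly negative) of that base
#' relative to the anchor.
#'
#' @slot mat numeric 4 x L matrix, rownames A,C,G,T.
#' @slot anchors character vector of per-column anchor bases.
#' @export
setClass("EnergyMatrix",
  representation(mat = "matrix", anchors = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(rownames(object@mat), DNA_BASES))
      msg <- c(msg, "rows must be named A, C, G, T in that order")
    if (!all(is.finite(object@mat)))
      msg <- c(msg, "all ddG values must be finite")
    if (length(object@anchors) != ncol(object@mat))
      msg <- c(msg, "need one anchor base per column")
    if (!all(object@anchors %in% DNA_BASES))
      msg <- c(msg, "anchor bases must be in A, C, G, T")
    if (length(msg)) msg else TRUE
  })

#' Construct an EnergyMatrix
#'
#' @param mat numeric 4 x L matrix (rows A, C, G, T) of ddG values in RT
#'   units.
#' @param anchors character vector of anchor bases, one per column.
#' @return An \linkS4class{EnergyMatrix}.
#' @export
EnergyMatrix <- function(mat, anchors) {
  mat <- as.matrix(mat)
  rownames(mat) <- DNA_BASES
  if (is.null(colnames(mat))) colnames(mat) <- as.character(seq_len(ncol(mat)) - 1L)
  new("EnergyMatrix", mat = mat, anchors = unname(anchors))
}

#' @rdname EnergyMatrix
#' @param x an \code{EnergyMatrix}.
#' @export
setMethod("as.matrix", "EnergyMatrix", function(x) x@mat)

#' Anchor bases of an EnergyMatrix
#' @param x an \linkS4class{EnergyMatrix}.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname anchors
#' @export
setMethod("anchors", "EnergyMatrix", function(x) x@anchors)

#' @rdname EnergyMatrix
#' @export
setMethod("ncol", "EnergyMatrix", function(x) ncol(x@mat))

setMethod("show", "EnergyMatrix", function(object) {
  cat(sprintf("EnergyMatrix: %d positions (RT units)%s\n", ncol(object@mat),
              if (isAnchored(object)) ", anchored" else ""))
  cat("  anchors:", paste(object@anchors, collapse = ""), "\n")
  print(round(object@mat, 3))
})

#' Is every anchor entry exactly zero?
#'
#' @param em an \linkS4class{EnergyMatrix}.
#' @return logical scalar.
#' @export
isAnchored <- function(em) {
  all(em@mat[cbind(match(em@anchors, DNA_BASES),
             seq_len(ncol(em@mat)))] == 0)
}

#' Anchor an energy matrix so the preferred-base entry is exactly zero
#'
#' Shifts each column by a constant so the anchor base's ddG is exactly 0.
#' A per-column constant shift is a gauge transformation: the Boltzmann
#' PWM derived before and after anchoring is identical.  Fitted entries
#' for other bases may be negative (an NN repeat can genuinely prefer A);
#' they are preserved as data.
#'
#' @param em an \linkS4class{EnergyMatrix}.
#' @param anchors optional replacement anchor bases (defaults to the ones
#'   stored in \code{em}).
#' @return An anchored \linkS4class{EnergyMatrix}.
#' @export
normalizeEM <- function(em, anchors = NULL) {
  if (is.null(anchors)) anchors <- em@anchors
  if (length(anchors) != ncol(em@mat))
    stop("need one anchor per column", call. = FALSE)
  if (!all(anchors %in% DNA_BASES))
    stop("invalid anchor base: ",
         paste(setdiff(anchors, DNA_BASES), collapse = ", "), call. = FALSE)
  shift <- em@mat[cbind(match(anchors, DNA_BASES),
                        seq_len(ncol(em@mat)))]
  EnergyMatrix(sweep(em@mat, 2L, shift, "-"), anchors)
}

#' PWM: per-position base probabilities
#'
#' The Boltzmann-probability counterpart of an energy matrix.  Columns sum
#' to one; entries are never clamped to zero.
#'
#' @slot mat numeric 4 x L matrix of probabilities, rownames A,C,G,T.
#' @export
setClass("PWM",
  representation(mat = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(rownames(object@mat), DNA_BASES))
      msg <- c(msg, "rows must be named A, C, G, T in that order")
    if (any(object@mat <= 0) || any(object@mat > 1))
      msg <- c(msg, "probabilities must lie in (0, 1]")
    if (any(abs(colSums(object@mat) - 1) > 1e-9))
      msg <- c(msg, "columns must sum to 1 (tolerance 1e-9)")
    if (length(msg)) msg else TRUE
  })

#' @rdname PWM-class
#' @param x a \code{PWM}.
#' @export
setMethod("as.matrix", "PWM", function(x) x@mat)

#' @rdname PWM-class
#' @export
setMethod("ncol", "PWM", function(x) ncol(x@mat))

setMethod("show", "PWM", function(object) {
  cat(sprintf("PWM: %d positions\n", ncol(object@mat)))
  print(round(object@mat, 4))
})

#' Convert an energy matrix to a Boltzmann PWM
#'
#' Per column, \eqn{p(b) = e^{-\Delta\Delta G_b} / \sum_{b'}
#' e^{-\Delta\Delta G_{b'}}}.  The map is invariant to per-column constant
#' shifts of the energies, so anchored and unanchored versions of the same
#' matrix give the same PWM.
#'
#' @param em an \linkS4class{EnergyMatrix}.
#' @return A \linkS4class{PWM}.
#' @export
emToPWM <- function(em) {
  m <- em@mat
  m <- sweep(m, 2L, apply(m, 2L, min), "-")  # numeric safety, gauge-neutral
  w <- exp(-m)
  new("PWM", mat = sweep(w, 2L, colSums(w), "/"))
}

#' Total ddG of a binding site under an energy matrix
#'
#' Sum over positions of the per-base ddG entries.  On an anchored matrix
#' the canonical site scores exactly 0.
#'
#' @param em an \linkS4class{EnergyMatrix}.
#' @param site DNA string of the same length as the matrix.
#' @return numeric ddG in RT units.
#' @export
siteDdg <- function(em, site) {
  bases <- strsplit(toupper(site), "")[[1L]]
  if (length(bases) != ncol(em@mat))
    stop(sprintf("site length %d does not match matrix width %d",
                 length(bases), ncol(em@mat)), call. = FALSE)
  if (!all(bases %in% DNA_BASES))
    stop("site contains non-ACGT characters", call. = FALSE)
  sum(em@mat[cbind(match(bases, DNA_BASES), seq_along(bases))])
}

#' Relative dissociation constant from a ddG
#'
#' With energies in RT units the relative Kd of a site (taking the optimal
#' site's Kd as 1) is the bare exponential \eqn{e^{\Delta\Delta G}}.
#'
#' @param ddg numeric ddG in RT units.
#' @return numeric relative Kd; 0 maps to 1.
#' @export
relativeKd <- function(ddg) {
  stopifnot(all(is.finite(ddg)))
  exp(ddg)
}

#' Write / read the tab-separated energy-matrix text format
#'
#' One row per base (A, C, G, T), one column per 0-based position, a
#' header row of position indices, and a leading comment line recording
#' the units and per-column anchors.
#'
#' @param em an \linkS4class{EnergyMatrix}.
#' @param file path.
#' @return \code{readEnergyMatrix} returns an \linkS4class{EnergyMatrix};
#'   \code{writeEnergyMatrix} returns \code{file} invisibly.
#' @export
writeEnergyMatrix <- function(em, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# units=RT anchors=%s",
                     paste(em@anchors, collapse = ",")), con)
  writeLines(paste(c("base", colnames(em@mat)), collapse = "\t"), con)
  for (b in DNA_BASES)
    writeLines(paste(c(b, format(em@mat[b, ], digits = 10)),
                     collapse = "\t"), con)
  invisible(file)
}

#' @rdname writeEnergyMatrix
#' @export
readEnergyMatrix <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  anch <- sub(".*anchors=", "", hdr[1L])
  anchors <- strsplit(anch, ",")[[1L]]
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", row.names = 1L, check.names = FALSE)
  EnergyMatrix(as.matrix(tab)[DNA_BASES, , drop = FALSE], anchors)
}

#' Write a PWM in MEME minimal motif format
#'
#' For use with downstream logo and motif tools.
#'
#' @param pwm a \linkS4class{PWM}.
#' @param file path.
#' @param name motif name.
#' @return \code{file}, invisibly.
#' @export
writeMEME <- function(pwm, file, name = "motif") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(pwm@mat))), con)
  for (j in seq_len(ncol(pwm@mat)))
    writeLines(paste(format(pwm@mat[, j], digits = 6), collapse = " "), con)
  invisible(file)
}
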