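#' ProbeSet: variant target sites destined for a custom PBM
#'
#' Each entry is one unique site variant, labelled by its class
#' (\code{reference}, \code{single}, \code{dinuc}, \code{nonadjacent_k},
#' \code{cluster5}, \code{cluster3}) and by the 0-based site positions at
#' which it differs from the reference.  After \code{embedInFlanks} every
#' entry also carries the full probe sequence, with identical flanks and
#' site offset across the set.
#'
#' @slot site the reference target site.
#' @slot entries data.frame with columns \code{probe_id}, \code{class},
#'   \code{mutated_positions} (comma list, 0-based), \code{site_sequence}
#'   and, once embedded, \code{probe_sequence}.
#' @slot flank5,flank3 constant flanking DNA (empty until embedding).
#' @slot replicate_count replicate spots per probe on the array.
#' @export
setClass("ProbeSet",
  representation(site = "character", entries = "data.frame",
                 flank5 = "character", flank3 = "character",
                 replicate_count = "integer"),
  prototype(flank5 = "", flank3 = "", replicate_count = 8L),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@entries$site_sequence))
      msg <- c(msg, "site sequences must be unique")
    if (object@replicate_count < 8L)
      msg <- c(msg, "PBM designs use at least 8 replicate spots per probe")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ProbeSet", function(object) {
  cat(sprintf("ProbeSet for site %s: %d variants (%d replicates each)\n",
              object@site, nrow(object@entries), object@replicate_count))
  print(table(object@entries$class))
})

#' @rdname ProbeSet-class
#' @param x a \code{ProbeSet}.
#' @export
setMethod("nrow", "ProbeSet", function(x) nrow(x@entries))

#' Probe entries as a data.frame
#' @param x a \linkS4class{ProbeSet}.
#' @export
setGeneric("probeEntries", function(x) standardGeneric("probeEntries"))

#' @rdname probeEntries
#' @export
setMethod("probeEntries", "ProbeSet", function(x) x@entries)

siteChars <- function(site) {
  bases <- strsplit(toupper(site), "")[[1L]]
  if (!all(bases %in% DNA_BASES))
    stop("site contains non-ACGT characters", call. = FALSE)
  bases
}

newEntry <- function(bases, positions, class) {
  data.frame(class = class,
             mutated_positions = paste(positions, collapse = ","),
             site_sequence = paste(bases, collapse = ""),
             stringsAsFactors = FALSE)
}

makeProbeSet <- function(site, entries, replicate_count = 8L) {
  entries <- entries[!duplicated(entries$site_sequence), , drop = FALSE]
  entries$probe_id <- sprintf("p%04d", seq_len(nrow(entries)))
  rownames(entries) <- NULL
  new("ProbeSet", site = site,
      entries = entries[, c("probe_id", "class", "mutated_positions",
                            "site_sequence")],
      replicate_count = as.integer(replicate_count))
}

#' All single and adjacent-dinucleotide substitution variants of a site
#'
#' The reference site, every single-base substitution (3n variants) and
#' every substitution of an adjacent position pair in which both bases
#' differ from the reference (9(n-1) variants): 12n - 8 unique sequences
#' for sites of length n >= 3.  This is the minimal design from which all
#' mononucleotide and adjacent-dinucleotide energy terms are identifiable.
#'
#' @param site reference target-site DNA string (length >= 2).
#' @param replicate_count replicate spots per probe.
#' @return A \linkS4class{ProbeSet}.
#' @examples
#' nrow(dinucSubstitutionProbes("TACGT"))  # 52
#' @export
dinucSubstitutionProbes <- function(site, replicate_count = 8L) {
  ref <- siteChars(site)
  n <- length(ref)
  if (n < 2L) stop("site must have length >= 2", call. = FALSE)
  out <- list(newEntry(ref, integer(0), "reference"))
  for (j in seq_len(n)) {
    for (b in setdiff(DNA_BASES, ref[j])) {
      v <- ref; v[j] <- b
      out[[length(out) + 1L]] <- newEntry(v, j - 1L, "single")
    }
  }
  for (j in seq_len(n - 1L)) {
    for (b1 in setdiff(DNA_BASES, ref[j])) {
      for (b2 in setdiff(DNA_BASES, ref[j + 1L])) {
        v <- ref; v[j] <- b1; v[j + 1L] <- b2
        out[[length(out) + 1L]] <- newEntry(v, c(j - 1L, j), "dinuc")
      }
    }
  }
  makeProbeSet(site, do.call(rbind, out), replicate_count)
}

## largest number of pairwise-nonadjacent positions in 1..n
maxNonadjacent <- function(n) (n + 1L) %/% 2L

sampleNonadjacentPositions <- function(n, k) {
  ## sample uniformly via the bijection with unrestricted k-subsets of
  ## 1..(n-k+1): add 0..(k-1) to the sorted subset
  base <- sort(sample.int(n - k + 1L, k))
  base + seq_len(k) - 1L
}

#' Variants with k pairwise-nonadjacent mismatches
#'
#' For each k = 2..\code{max_mm}, draws \code{per_level} variants whose
#' substituted positions form an independent set on the site's path graph
#' (no two mismatches adjacent), sampled reproducibly from \code{seed}.
#' Used to test that mononucleotide additivity extends beyond adjacent
#' double substitutions.
#'
#' @param site reference target-site DNA string.
#' @param max_mm maximum number of mismatches (default 5); must satisfy
#'   \code{max_mm <= (n+1) \%/\% 2}.
#' @param per_level variants per mismatch count.
#' @param seed integer seed.
#' @param replicate_count replicate spots per probe.
#' @return A \linkS4class{ProbeSet}.
#' @export
nonadjacentMismatchProbes <- function(site, max_mm = 5L, per_level = 20L,
                                      seed = 1L, replicate_count = 8L) {
  ref <- siteChars(site)
  n <- length(ref)
  if (per_level < 1L) stop("per_level must be >= 1", call. = FALSE)
  if (max_mm > maxNonadjacent(n))
    stop(sprintf("no %d pairwise-nonadjacent positions exist in a site of length %d",
                 max_mm, n), call. = FALSE)
  if (max_mm < 2L) stop("max_mm must be >= 2", call. = FALSE)
  withSeed(seed, {
    out <- list()
    for (k in 2:max_mm) {
      seen <- character(0)
      tries <- 0L
      while (length(seen) < per_level && tries < 50L * per_level) {
        tries <- tries + 1L
        pos <- sampleNonadjacentPositions(n, k)
        v <- ref
        for (j in pos) v[j] <- sample(setdiff(DNA_BASES, ref[j]), 1L)
        sq <- paste(v, collapse = "")
        if (!sq %in% seen) {
          seen <- c(seen, sq)
          out[[length(out) + 1L]] <-
            newEntry(v, pos - 1L, sprintf("nonadjacent_%d", k))
        }
      }
    }
    makeProbeSet(site, do.call(rbind, out), replicate_count)
  })
}

#' Variants with a cluster of three substitutions at either site end
#'
#' All 27 combinations of non-reference bases in the three 5'-most
#' positions, and all 27 in the three 3'-most positions.  Designed to
#' contrast the binding cost of 5'-end versus 3'-end damage.
#'
#' @param site reference target-site DNA string (length >= 6).
#' @param replicate_count replicate spots per probe.
#' @return A \linkS4class{ProbeSet} with classes \code{cluster5} and
#'   \code{cluster3}.
#' @export
terminalClusterProbes <- function(site, replicate_count = 8L) {
  ref <- siteChars(site)
  n <- length(ref)
  if (n < 6L) stop("site must have length >= 6", call. = FALSE)
  out <- list()
  for (end in c("cluster5", "cluster3")) {
    win <- if (end == "cluster5") 1:3 else (n - 2L):n
    alts <- lapply(win, function(j) setdiff(DNA_BASES, ref[j]))
    for (b1 in alts[[1L]]) for (b2 in alts[[2L]]) for (b3 in alts[[3L]]) {
      v <- ref; v[win] <- c(b1, b2, b3)
      out[[length(out) + 1L]] <- newEntry(v, win - 1L, end)
    }
  }
  makeProbeSet(site, do.call(rbind, out), replicate_count)
}

#' Embed a probe set's site variants in constant flanks
#'
#' Every output probe has identical flanking DNA and site offset, so
#' replicate spots differ only in the variant site.  Warns when a flank
#' contains the canonical reference site (array flanks are chosen not to
#' carry binding sites).
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @param flank5,flank3 constant DNA placed 5' and 3' of the site.
#' @param probe_length required total probe length (default 60).
#' @return The \linkS4class{ProbeSet} with a \code{probe_sequence} column.
#' @export
embedInFlanks <- function(probes, flank5, flank3, probe_length = 60L) {
  n <- nchar(probes@site)
  if (nchar(flank5) + n + nchar(flank3) != probe_length)
    stop(sprintf("flank5 (%d) + site (%d) + flank3 (%d) must equal probe_length %d",
                 nchar(flank5), n, nchar(flank3), probe_length), call. = FALSE)
  if (grepl(probes@site, paste0(flank5, flank3), fixed = TRUE))
    warning("flank sequence contains the reference binding site",
            call. = FALSE)
  probes@entries$probe_sequence <-
    paste0(flank5, probes@entries$site_sequence, flank3)
  probes@flank5 <- flank5
  probes@flank3 <- flank3
  validObject(probes)
  probes
}

#' Combine probe sets over the same reference site
#'
#' Deduplicates on site sequence, keeping the first class label.
#'
#' @param ... \linkS4class{ProbeSet} objects sharing a reference site.
#' @return A merged \linkS4class{ProbeSet}.
#' @export
combineProbeSets <- function(...) {
  sets <- list(...)
  site <- sets[[1L]]@site
  if (!all(vapply(sets, function(s) s@site, "") == site))
    stop("probe sets target different reference sites", call. = FALSE)
  ent <- do.call(rbind, lapply(sets, function(s)
    s@entries[, c("class", "mutated_positions", "site_sequence")]))
  makeProbeSet(site, ent, max(vapply(sets, function(s) s@replicate_count, 1L)))
}

#' Write a probe set as TSV or FASTA
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @param file path.
#' @return \code{file}, invisibly.
#' @export
writeProbeSetTSV <- function(probes, file) {
  utils::write.table(probes@entries, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeProbeSetTSV
#' @export
writeProbeSetFASTA <- function(probes, file) {
  seqs <- if ("probe_sequence" %in% names(probes@entries))
    probes@entries$probe_sequence else probes@entries$site_sequence
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, probes@entries$probe_id)), file)
  invisible(file)
}
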