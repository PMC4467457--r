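## PBM quantification: raw replicate background-subtracted intensities
## (BSI) -> robust, Cy3-normalized per-probe z-scores.
##
## The long-format probe table has one row per (probe, channel, replicate):
## columns probe_id, sequence, channel ("alexa"|"cy3"), replicate, bsi,
## and optionally role ("foreground"|"background").

#' Read / write the long-format PBM probe table
#'
#' @param file path to a tab-separated table with columns \code{probe_id},
#'   \code{sequence}, \code{channel}, \code{replicate}, \code{bsi} and
#'   optionally \code{role}.
#' @return A data.frame.
#' @export
readProbeTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("probe_id", "sequence", "channel", "replicate", "bsi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("probe table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname readProbeTable
#' @param records probe-table data.frame.
#' @export
writeProbeTable <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Shift intensities so every BSI is positive
#'
#' Background subtraction can leave negative intensities when the region
#' around a spot is brighter than the spot.  If any BSI in a channel is
#' negative, one constant is added to every BSI of that channel (the whole
#' experiment, never per probe) so the minimum becomes +1; otherwise the
#' data are returned unchanged.  A monotone shift preserves probe ordering
#' and is absorbed by the downstream scaling parameters.
#'
#' @param records probe-table data.frame.
#' @return The data.frame with adjusted \code{bsi}.
#' @export
applyPseudocount <- function(records) {
  for (ch in unique(records$channel)) {
    i <- records$channel == ch
    lo <- min(records$bsi[i])
    if (lo < 0) records$bsi[i] <- records$bsi[i] - lo + 1
  }
  records
}

triNucCounts <- function(seqs) {
  tri <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(seqs))
  storage.mode(tri) <- "double"
  tri
}

#' Cy3-based normalization for double-stranded DNA content
#'
#' The Cy3 channel reports the amount of double-stranded DNA per spot, but
#' Cy3-dUTP incorporation depends on local sequence, so the expected Cy3
#' signal is modelled by ordinary least squares on the counts of the 64
#' trinucleotides in each probe sequence.  Each probe's Alexa BSIs are
#' multiplied by the expected/observed Cy3 ratio; probes corrected by more
#' than twofold in either direction, or whose adjustment would leave a
#' non-positive BSI, are removed and reported.
#'
#' @param records probe-table data.frame containing both \code{alexa} and
#'   \code{cy3} channels.
#' @return A list with \code{records} (normalized, offending probes
#'   dropped) and \code{removed} (data.frame of probe_id, factor, reason).
#' @export
cy3Normalize <- function(records) {
  cy3 <- records[records$channel == "cy3", , drop = FALSE]
  if (!nrow(cy3)) stop("no cy3 channel rows present", call. = FALSE)
  obs <- tapply(cy3$bsi, cy3$probe_id, stats::median)
  seqs <- cy3$sequence[!duplicated(cy3$probe_id)]
  names(seqs) <- cy3$probe_id[!duplicated(cy3$probe_id)]
  seqs <- seqs[names(obs)]
  if (length(obs) < 64L)
    stop("cy3 trinucleotide regression needs >= 64 probes; got ",
         length(obs), " - use a larger probe set", call. = FALSE)
  X <- triNucCounts(unname(seqs))
  fit <- stats::lm.fit(X, as.numeric(obs))
  if (all(is.na(fit$coefficients)))
    stop("singular trinucleotide design; use a larger, more diverse probe set",
         call. = FALSE)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  expected <- as.numeric(X %*% beta)
  f <- expected / as.numeric(obs)
  bad <- !is.finite(f) | f > 2 | f < 0.5
  removed <- data.frame(probe_id = names(obs)[bad],
                        factor = f[bad],
                        reason = ifelse(is.finite(f[bad]) & f[bad] > 2,
                                        "corrected_gt_twofold",
                                 ifelse(is.finite(f[bad]) & f[bad] >= 0,
                                        "corrected_lt_halffold",
                                        "negative_adjusted_bsi")),
                        stringsAsFactors = FALSE)
  keep_f <- setNames(f[!bad], names(obs)[!bad])
  out <- records[records$probe_id %in% names(keep_f), , drop = FALSE]
  ia <- out$channel == "alexa"
  out$bsi[ia] <- out$bsi[ia] * keep_f[out$probe_id[ia]]
  ## adjustment itself may push an alexa BSI negative
  neg <- unique(out$probe_id[ia][out$bsi[ia] < 0])
  if (length(neg)) {
    removed <- rbind(removed,
                     data.frame(probe_id = neg, factor = keep_f[neg],
                                reason = "negative_adjusted_bsi",
                                stringsAsFactors = FALSE))
    out <- out[!out$probe_id %in% neg, , drop = FALSE]
  }
  rownames(removed) <- NULL
  list(records = out, removed = removed)
}

#' Robust replicate aggregation with outlier filtering
#'
#' Computes the median and MAD of a probe's replicate intensities, the
#' robust standard deviation 1.4826 x MAD, drops replicates more than
#' 3 robust s.d. from the median in a single pass, and reports the
#' median over the survivors.  The filter is deliberately single-pass:
#' re-estimating the band from the survivors and trimming again can
#' cascade (each trim shrinks the MAD) and destroys clean replicates.
#' When the MAD is zero the band is degenerate; a replicate that
#' differs from the median is then dropped when it exceeds three times
#' the plain standard deviation of the remaining replicates
#' (leave-one-out), which removes gross outliers while keeping ties.
#'
#' @param values numeric replicate intensities (>= 1).
#' @param n_sd band half-width in robust s.d. units (default 3).
#' @param use_robust use 1.4826 x MAD (default) rather than the plain
#'   standard deviation for the band.
#' @return A list with \code{median_bsi}, \code{mad}, \code{robust_sd},
#'   \code{n_used} and \code{kept} (logical per replicate).
#' @examples
#' aggregateReplicates(c(1, 2, 3, 4, 5))$robust_sd  # 1.4826
#' @export
aggregateReplicates <- function(values, n_sd = 3, use_robust = TRUE) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  med <- stats::median(values)
  madv <- stats::median(abs(values - med))
  rsd <- 1.4826 * madv
  band_sd <- if (use_robust) rsd else stats::sd(values)
  if (is.na(band_sd)) band_sd <- 0
  if (band_sd > 0) {
    kept <- abs(values - med) <= n_sd * band_sd
  } else {
    kept <- vapply(seq_along(values), function(i) {
      if (values[i] == med) return(TRUE)
      s <- stats::sd(values[-i])
      if (is.na(s)) s <- 0
      abs(values[i] - med) <= n_sd * s
    }, logical(1L))
  }
  list(median_bsi = if (any(kept)) stats::median(values[kept]) else NA_real_,
       mad = madv, robust_sd = rsd,
       n_used = sum(kept), kept = kept)
}

#' Aggregate every probe's replicates into a quantified table
#'
#' @param records probe-table data.frame (alexa channel used).
#' @param n_sd,use_robust passed to \code{\link{aggregateReplicates}}.
#' @return data.frame with one row per probe: \code{probe_id},
#'   \code{sequence}, \code{median_bsi}, \code{mad}, \code{robust_sd},
#'   \code{n_used}, \code{flagged} (all replicates dropped) and
#'   \code{role} when present in the input.
#' @export
quantifyReplicates <- function(records, n_sd = 3, use_robust = TRUE) {
  al <- records[records$channel == "alexa", , drop = FALSE]
  if (!nrow(al)) stop("no alexa channel rows present", call. = FALSE)
  ids <- unique(al$probe_id)
  rows <- lapply(ids, function(id) {
    sub <- al[al$probe_id == id, , drop = FALSE]
    agg <- aggregateReplicates(sub$bsi, n_sd = n_sd, use_robust = use_robust)
    data.frame(probe_id = id, sequence = sub$sequence[1L],
               median_bsi = agg$median_bsi, mad = agg$mad,
               robust_sd = agg$robust_sd, n_used = agg$n_used,
               flagged = agg$n_used == 0L,
               role = if ("role" %in% names(sub)) sub$role[1L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Background-referenced robust z-scores
#'
#' Centres every probe's median BSI on the median of the background probe
#' set and scales by 1.4826 x MAD of the background medians.  This is a
#' linear transformation of the medians: downstream model fitting carries
#' its own scale parameters, so the z-scores exist for interpretability,
#' and any positive affine rescaling of the raw intensities leaves them
#' unchanged.
#'
#' @param quantified output of \code{\link{quantifyReplicates}}.
#' @param background_ids probe_ids of the background set (>= 20), e.g. the
#'   probes designed for other proteins on the same array.
#' @return \code{quantified} with a \code{zscore} column.
#' @export
backgroundZscores <- function(quantified, background_ids) {
  bg <- quantified$median_bsi[quantified$probe_id %in% background_ids &
                              !quantified$flagged]
  if (length(bg) < 20L)
    stop("need >= 20 usable background probes, got ", length(bg),
         call. = FALSE)
  m <- stats::median(bg)
  s <- 1.4826 * stats::median(abs(bg - m))
  if (s == 0) stop("background probes have zero spread", call. = FALSE)
  quantified$zscore <- (quantified$median_bsi - m) / s
  quantified
}

#' Full quantification pipeline: raw probe table to z-scores
#'
#' Pseudocount, Cy3 trinucleotide normalization, robust replicate
#' aggregation and background z-scoring, in that order.
#'
#' @param records probe-table data.frame.
#' @param background_ids probe_ids of the background set.
#' @param cy3 run the Cy3 normalization step (skipped automatically when
#'   the table has no cy3 channel).
#' @param n_sd,use_robust replicate-filter settings.
#' @return A list with \code{quantified} (per-probe table incl.
#'   \code{zscore}) and \code{removed} (Cy3 removals).
#' @export
quantifyPBM <- function(records, background_ids, cy3 = TRUE,
                        n_sd = 3, use_robust = TRUE) {
  records <- applyPseudocount(records)
  removed <- data.frame(probe_id = character(0), factor = numeric(0),
                        reason = character(0))
  if (cy3 && any(records$channel == "cy3")) {
    nrm <- cy3Normalize(records)
    records <- nrm$records
    removed <- nrm$removed
  }
  q <- quantifyReplicates(records, n_sd = n_sd, use_robust = use_robust)
  q <- backgroundZscores(q, background_ids)
  list(quantified = q, removed = removed)
}
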