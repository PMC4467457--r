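## Off-target pipeline: enumerate every sequence within a relative-Kd
## bound of a TALE's optimal site, locate all exact genomic occurrences
## on both strands, and summarize each candidate protein's off-target
## burden.

#' Enumerate all binding sites under a relative-Kd threshold
#'
#' Depth-first search over site positions with branch-and-bound pruning:
#' a partial prefix is abandoned as soon as its accumulated ddG plus the
#' sum of the remaining column minima exceeds ln(threshold).  Returns
#' exactly the set \{s : siteDdg(s) <= ln(threshold)\}; sites whose
#' relative Kd equals the threshold are included.
#'
#' @param em anchored \linkS4class{EnergyMatrix}.
#' @param kd_threshold relative-Kd bound (default 10, >= 1).
#' @return data.frame with \code{sequence}, \code{ddg}, \code{rel_kd},
#'   sorted by ddg.
#' @export
enumerateSites <- function(em, kd_threshold = 10) {
  if (!isAnchored(em))
    stop("energy matrix must be anchored (normalizeEM) before enumeration",
         call. = FALSE)
  if (kd_threshold < 1) stop("kd_threshold must be >= 1", call. = FALSE)
  m <- em@mat
  L <- ncol(m)
  budget <- log(kd_threshold)
  colmin <- apply(m, 2L, min)
  suffix <- rev(cumsum(rev(colmin)))  # best achievable from position j on
  suffix <- c(suffix[-1L], 0)
  seqs <- character(0)
  ddgs <- numeric(0)
  ## iterative DFS; tolerance guards the <=-boundary against float drift
  eps <- 1e-9
  recurse <- function(j, acc, prefix) {
    if (j > L) {
      seqs[length(seqs) + 1L] <<- paste(prefix, collapse = "")
      ddgs[length(ddgs) + 1L] <<- acc
      return(invisible(NULL))
    }
    for (b in DNA_BASES) {
      acc2 <- acc + m[b, j]
      if (acc2 + suffix[j] <= budget + eps)
        recurse(j + 1L, acc2, c(prefix, b))
    }
  }
  recurse(1L, 0, character(0))
  out <- data.frame(sequence = seqs, ddg = ddgs, rel_kd = exp(ddgs),
                    stringsAsFactors = FALSE)
  out[order(out$ddg), , drop = FALSE]
}

asGenome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or a FASTA path", call. = FALSE)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  names(genome) <- sub("\\s.*", "", names(genome))
  genome
}

#' Find every genomic occurrence of a set of binding sites
#'
#' Exact multi-pattern matching on both strands using Aho-Corasick-style
#' preprocessed dictionaries (\code{\link[Biostrings]{PDict}}).  Hits are
#' reported in 0-based half-open coordinates via a \code{GRanges} (which
#' prints 1-based); the \code{site} metadata column always carries the
#' site sequence as bound by the protein, i.e. the reverse complement of
#' the genomic plus-strand substring for minus-strand hits.  Ambiguity
#' characters in the genome never match.
#'
#' @param sites character vector of equal-length site sequences, or the
#'   data.frame from \code{\link{enumerateSites}}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @return \code{GRanges} with metadata columns \code{site} and, when the
#'   input carried them, \code{rel_kd}.
#' @export
scanGenome <- function(sites, genome) {
  kd <- NULL
  if (is.data.frame(sites)) {
    kd <- setNames(sites$rel_kd, sites$sequence)
    sites <- sites$sequence
  }
  if (!length(sites)) stop("empty site set", call. = FALSE)
  if (length(unique(nchar(sites))) != 1L)
    stop("all site sequences must have equal length", call. = FALSE)
  genome <- asGenome(genome)
  fwd <- Biostrings::DNAStringSet(sites)
  rev <- Biostrings::reverseComplement(fwd)
  pd_f <- Biostrings::PDict(fwd)
  pd_r <- Biostrings::PDict(rev)
  sinfo <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                  seqlengths = Biostrings::width(genome))
  hits <- list()
  for (ch in names(genome)) {
    subj <- genome[[ch]]
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_f else pd_r
      ml <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(ml)
      if (!sum(cnt)) next
      ir <- unlist(IRanges::IRangesList(ml), use.names = FALSE)
      hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
        seqnames = ch, ranges = ir, strand = strand,
        site = rep(sites, cnt), seqinfo = sinfo)
    }
  }
  if (!length(hits)) {
    gr <- GenomicRanges::GRanges(site = character(0))
    return(gr)
  }
  gr <- sort(do.call(c, hits), ignore.strand = TRUE)
  if (!is.null(kd)) gr$rel_kd <- unname(kd[gr$site])
  gr
}

## reference oracle: naive sliding-window scan (both strands); every
## window of the genome is extracted and compared against the site set
naiveScanGenome <- function(sites, genome) {
  genome <- asGenome(genome)
  L <- unique(nchar(sites))
  stopifnot(length(L) == 1L)
  sset <- unique(sites)
  rcmap <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sset))), sset)
  res <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    n <- nchar(s)
    if (n < L) next
    wins <- substring(s, seq_len(n - L + 1L), L:n)
    ip <- which(wins %in% sset)
    if (length(ip))
      res[[length(res) + 1L]] <- data.frame(chrom = ch, start = ip - 1L,
                                            strand = "+", site = wins[ip],
                                            stringsAsFactors = FALSE)
    im <- which(wins %in% unname(rcmap))
    if (length(im)) {
      inv <- setNames(names(rcmap), rcmap)
      res[[length(res) + 1L]] <- data.frame(chrom = ch, start = im - 1L,
                                            strand = "-",
                                            site = unname(inv[wins[im]]),
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), site = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Off-target summary score
#'
#' Sum over off-target hits of 1 / relative Kd.  Each term lies in (0, 1]
#' and is proportional to the relative occupancy of that locus at fixed
#' chemical potential, so the score captures both the number and the
#' strength of genomic off-target sequences; lower is better.  The
#' intended target locus must already have been excluded.
#'
#' @param rel_kd numeric vector of off-target relative Kd values (or a
#'   \code{GRanges} from \code{\link{scanGenome}} carrying a
#'   \code{rel_kd} column).
#' @param exponent optional exponent on 1/rel_kd (default 1).
#' @param cap optional per-hit cap.
#' @return numeric score, 0 for no hits.
#' @export
summaryScore <- function(rel_kd, exponent = 1, cap = Inf) {
  if (is(rel_kd, "GRanges")) rel_kd <- rel_kd$rel_kd
  if (!length(rel_kd)) return(0)
  stopifnot(all(rel_kd > 0))
  sum(pmin((1 / rel_kd)^exponent, cap))
}

#' Write genomic hits as BED6
#'
#' 0-based half-open intervals; score = min(1000, round(1000 / rel_kd));
#' name = site sequence.
#'
#' @param hits \code{GRanges} from \code{\link{scanGenome}}.
#' @param file path.
#' @return \code{file}, invisibly.
#' @export
writeHitsBED <- function(hits, file) {
  score <- if (!is.null(hits$rel_kd))
    pmin(1000, round(1000 / hits$rel_kd)) else 0L
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(hits)),
                   start = GenomicRanges::start(hits) - 1L,
                   end = GenomicRanges::end(hits),
                   name = hits$site, score = score,
                   strand = as.character(GenomicRanges::strand(hits)))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Rank candidate TALEs for a target region by off-target burden
#'
#' Implements the design pipeline: every window of length
#' \code{repeat_count + 1} beginning with T, on either strand of the
#' region, is a candidate site; the TALE targeting it follows from the
#' canonical code; its energy matrix is predicted from the context model;
#' all binding sites within the relative-Kd bound are enumerated and
#' located in the genome; and candidates are ranked by ascending summary
#' score with the intended locus excluded by coordinate (not sequence)
#' identity.
#'
#' @param region DNA string, \code{DNAStringSet} of length 1, or FASTA
#'   path: the sub-sequence of the genome to target.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param model trained \linkS4class{ContextModel}.
#' @param repeat_count number of repeat elements (site length - 1).
#' @param kd_threshold relative-Kd bound for enumeration.
#' @param region_origin list(chrom, start) giving the region's 0-based
#'   location in the genome; when NULL the first exact occurrence of the
#'   region in the genome is used.
#' @param max_candidates optionally limit the number of windows scored.
#' @return list with \code{report} (one row per candidate, ascending
#'   summary score) and \code{hits} (per-candidate \code{GRanges} of
#'   off-target loci).
#' @export
designPipeline <- function(region, genome, model, repeat_count,
                           kd_threshold = 10, region_origin = NULL,
                           max_candidates = Inf) {
  genome <- asGenome(genome)
  if (is.character(region) && file.exists(region))
    region <- Biostrings::readDNAStringSet(region)
  if (is(region, "DNAStringSet")) region <- as.character(region[[1L]])
  region <- toupper(region)
  L <- repeat_count + 1L
  if (nchar(region) < L) stop("region shorter than the target site",
                              call. = FALSE)
  if (is.null(region_origin)) {
    loc <- Biostrings::matchPattern(region, genome[[1L]])
    if (length(loc)) {
      region_origin <- list(chrom = names(genome)[1L],
                            start = Biostrings::start(loc)[1L] - 1L)
    }
  }
  rc_region <- revComp(region)
  cands <- list()
  collect <- function(seqstr, strand) {
    n <- nchar(seqstr)
    for (i in seq_len(n - L + 1L)) {
      win <- substr(seqstr, i, i + L - 1L)
      if (substr(win, 1L, 1L) == "T" &&
          !grepl("[^ACGT]", win))
        cands[[length(cands) + 1L]] <<-
          data.frame(site = win, strand = strand, offset = i - 1L,
                     stringsAsFactors = FALSE)
    }
  }
  collect(region, "+")
  collect(rc_region, "-")
  if (!length(cands)) {
    message("no candidate sites (no T-initiated window on either strand)")
    return(list(report = data.frame(), hits = list()))
  }
  cand <- do.call(rbind, cands)
  cand <- cand[!duplicated(paste(cand$site, cand$strand, cand$offset)), ]
  if (nrow(cand) > max_candidates) cand <- cand[seq_len(max_candidates), ]

  reports <- vector("list", nrow(cand))
  hits_out <- vector("list", nrow(cand))
  rlen <- nchar(region)
  for (i in seq_len(nrow(cand))) {
    protein <- proteinForSite(cand$site[i])
    em <- predictEM(protein, model)$em
    sites <- enumerateSites(em, kd_threshold)
    hits <- scanGenome(sites, genome)
    ## genomic footprint of the intended site (0-based half-open)
    if (!is.null(region_origin)) {
      if (cand$strand[i] == "+") {
        s0 <- region_origin$start + cand$offset[i]
      } else {
        s0 <- region_origin$start + rlen - cand$offset[i] - L
      }
      keep <- !(as.character(GenomicRanges::seqnames(hits)) ==
                  region_origin$chrom &
                GenomicRanges::start(hits) - 1L == s0 &
                as.character(GenomicRanges::strand(hits)) == cand$strand[i])
      hits <- hits[keep]
    }
    reports[[i]] <- data.frame(
      candidate_id = sprintf("cand%03d", i),
      site = cand$site[i], strand = cand$strand[i],
      offset = cand$offset[i], rvd = as.character(protein),
      n_offtargets = length(hits),
      summary_score = summaryScore(hits),
      stringsAsFactors = FALSE)
    hits_out[[i]] <- hits
  }
  report <- do.call(rbind, reports)
  ord <- order(report$summary_score)
  names(hits_out) <- report$candidate_id
  list(report = report[ord, , drop = FALSE], hits = hits_out[ord])
}

pwmNegLogScore <- function(pwm, site) {
  bases <- strsplit(site, "")[[1L]]
  if (length(bases) != ncol(pwm@mat))
    stop("site length does not match PWM width", call. = FALSE)
  p <- pwm@mat[cbind(match(bases, DNA_BASES), seq_along(bases))]
  if (any(p <= 0)) stop("zero-probability base in site", call. = FALSE)
  sum(-log(p))
}

pwmArgmaxSite <- function(pwm) {
  paste(DNA_BASES[apply(pwm@mat, 2L, which.max)], collapse = "")
}

#' TALEN pair score from the two monomer PWMs
#'
#' For each monomer, S(site) is the summed negative natural log of the
#' PWM probabilities along the site; the partial score is
#' (S(optimal)/S(site))^0.6 with the optimal site the PWM's
#' maximum-probability sequence (or the canonical-code site, see
#' \code{optimal}); the pair score is the sum of the two partials.  The
#' optimal-vs-optimal pair scores exactly 2.
#'
#' @param pwm_left,pwm_right monomer \linkS4class{PWM}s.
#' @param site_left,site_right bound site sequences.
#' @param exponent ratio exponent (default 0.6).
#' @param optimal "argmax" (PWM maximum-probability site, default) or
#'   "canonical" with explicit sites supplied via \code{opt_left},
#'   \code{opt_right}.
#' @param opt_left,opt_right optional explicit optimal sites.
#' @return list with \code{left}, \code{right} partial scores and
#'   \code{total}.
#' @export
talenPairScore <- function(pwm_left, pwm_right, site_left, site_right,
                           exponent = 0.6,
                           optimal = c("argmax", "explicit"),
                           opt_left = NULL, opt_right = NULL) {
  optimal <- match.arg(optimal)
  part <- function(pwm, site, opt) {
    if (is.null(opt)) opt <- pwmArgmaxSite(pwm)
    (pwmNegLogScore(pwm, opt) / pwmNegLogScore(pwm, site))^exponent
  }
  l <- part(pwm_left, site_left,
            if (optimal == "explicit") opt_left else NULL)
  r <- part(pwm_right, site_right,
            if (optimal == "explicit") opt_right else NULL)
  list(left = l, right = r, total = l + r)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sensitivity and specificity at every distinct score threshold (higher
#' scores predict the positive class); tied scores are grouped at one
#' threshold; AUC by the trapezoid rule, which equals the concordant-pair
#' (Mann-Whitney) fraction with ties counted half.
#'
#' @param scores numeric predictions.
#' @param labels logical (or 0/1) true classes; both classes must be
#'   present.
#' @return list with \code{points} (threshold, sensitivity, specificity)
#'   and \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1L))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1L))
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(threshold = thr, sensitivity = sens,
                           specificity = spec),
       auc = auc)
}

#' Correlation between predicted and observed affinities
#'
#' \code{mode = "log_pearson"}: Pearson correlation of the natural logs
#' (Kd values span orders of magnitude, so the log prevents extreme
#' values from dominating); requires positive values.
#' \code{mode = "spearman"}: rank correlation with average ranks on ties
#' (for monotone-but-nonlinear readouts such as expression).
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @param mode "log_pearson" or "spearman".
#' @return numeric correlation.
#' @export
correlationMetrics <- function(predicted, observed,
                               mode = c("log_pearson", "spearman")) {
  mode <- match.arg(mode)
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3L)
  if (mode == "log_pearson") {
    if (any(predicted <= 0) || any(observed <= 0))
      stop("log mode requires positive values", call. = FALSE)
    stats::cor(log(predicted), log(observed))
  } else {
    stats::cor(predicted, observed, method = "spearman")
  }
}
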