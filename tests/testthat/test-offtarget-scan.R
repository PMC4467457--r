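test_that("enumeration boundary cases behave as specified", {
  em <- randomAnchoredEM(5L, 51L)
  ## threshold 1 with unique minima keeps exactly the canonical site
  e1 <- enumerateSites(em, 1)
  expect_identical(e1$sequence, paste(anchors(em), collapse = ""))
  expect_equal(e1$rel_kd, 1)
  ## an all-zero matrix is unconstrained
  em0 <- EnergyMatrix(matrix(0, 4L, 3L,
                             dimnames = list(c("A", "C", "G", "T"), NULL)),
                      rep("A", 3L))
  expect_equal(nrow(enumerateSites(em0, 1)), 64L)
  ## unanchored matrices are rejected
  emu <- EnergyMatrix(as.matrix(em) + 1, anchors(em))
  expect_error(enumerateSites(emu, 10), "anchored")
  expect_error(enumerateSites(em, 0.5), ">= 1")
})

test_that("bounded search equals brute force over random matrices", {
  for (seed in 1:10) {
    L <- sample(4:7, 1L)
    em <- randomAnchoredEM(L, seed * 13L)
    bf <- bruteForceSiteEnergies(em)
    for (thr in c(1, 2, 10)) {
      want <- bf$sequence[bf$ddg <= log(thr) + 1e-9]
      got <- enumerateSites(em, thr)
      expect_setequal(got$sequence, want)
      expect_equal(got$rel_kd, exp(got$ddg))
      expect_true(all(got$rel_kd <= thr * (1 + 1e-9)))
    }
  }
})

test_that("genome scanning reports exact coordinates on both strands", {
  site <- "TACGGTAC"
  g <- simulateGenome(c(chr1 = 4000L),
                      planted = data.frame(chrom = "chr1",
                                           start = c(100L, 900L),
                                           strand = c("+", "-"),
                                           seq = site),
                      seed = 61L)
  hits <- scanGenome(site, g)
  plus <- hits[as.character(GenomicRanges::strand(hits)) == "+"]
  minus <- hits[as.character(GenomicRanges::strand(hits)) == "-"]
  expect_true(100L %in% (GenomicRanges::start(plus) - 1L))
  expect_true(900L %in% (GenomicRanges::start(minus) - 1L))
  expect_true(all(GenomicRanges::width(hits) == nchar(site)))
  ## the minus-strand genomic substring is the reverse complement
  sub <- as.character(Biostrings::subseq(g[["chr1"]], 901L, 908L))
  expect_identical(sub, sifted:::revComp(site))
})

test_that("multi-pattern scan equals the naive sliding-window oracle", {
  em <- randomAnchoredEM(6L, 71L, hi = 2)
  sites <- enumerateSites(em, 10)
  g <- simulateGenome(c(chr1 = 8000L, chr2 = 4000L), gc = 0.45, seed = 72L)
  hits <- scanGenome(sites, g)
  nv <- sifted:::naiveScanGenome(sites$sequence, g)
  got <- data.frame(chrom = as.character(GenomicRanges::seqnames(hits)),
                    start = GenomicRanges::start(hits) - 1L,
                    strand = as.character(GenomicRanges::strand(hits)),
                    site = hits$site, stringsAsFactors = FALSE)
  got <- got[order(got$chrom, got$start, got$strand), ]
  rownames(got) <- rownames(nv) <- NULL
  expect_equal(got, nv)
})

test_that("scanning commutes with reverse-complementing the genome", {
  sites <- c("TACGTT", "TTGCAA")
  g <- simulateGenome(c(chr1 = 3000L), seed = 81L)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  h1 <- scanGenome(sites, g)
  h2 <- scanGenome(sites, grc)
  n <- length(g[["chr1"]])
  ## a + hit at [s, e] maps to a - hit at [n - e + 1, n - s + 1]
  m1 <- sort(paste(n - GenomicRanges::end(h1) + 1L,
                   c("+" = "-", "-" = "+")[
                     as.character(GenomicRanges::strand(h1))]))
  m2 <- sort(paste(GenomicRanges::start(h2),
                   as.character(GenomicRanges::strand(h2))))
  expect_identical(m1, m2)
})

test_that("summary score is the occupancy-weighted hit count", {
  expect_equal(summaryScore(numeric(0)), 0)
  expect_equal(summaryScore(1), 1)
  expect_equal(summaryScore(c(2, 4)), 0.75)
  set.seed(5)
  kd <- runif(20L, 1, 10)
  expect_equal(summaryScore(kd), summaryScore(sample(kd)))
  ## strictly monotone in added hits
  expect_gt(summaryScore(c(kd, 9.9)), summaryScore(kd))
})

test_that("BED export uses 0-based half-open coordinates and capped scores", {
  g <- simulateGenome(c(chr1 = 2000L),
                      planted = data.frame(chrom = "chr1", start = 50L,
                                           strand = "+", seq = "TACGTT"),
                      seed = 91L)
  hits <- scanGenome(data.frame(sequence = "TACGTT", ddg = log(2),
                                rel_kd = 2), g)
  f <- tempfile(fileext = ".bed")
  writeHitsBED(hits, f)
  bed <- utils::read.delim(f, header = FALSE)
  i <- which(bed$V2 == 50L & bed$V6 == "+")
  expect_length(i, 1L)
  expect_equal(bed$V3[i], 56L)
  expect_equal(bed$V5[i], 500L)
  expect_equal(bed$V4[i], "TACGTT")
})

test_that("the design pipeline finds, scores and ranks candidates", {
  cm <- rawContextModel(c("ind|NI|C" = 4, "ind|NI|G" = 4, "ind|NI|T" = 4,
                          "ind|HD|A" = 4, "ind|HD|G" = 4, "ind|HD|T" = 4,
                          "ind|NN|A" = 4, "ind|NN|C" = 4, "ind|NN|T" = 4,
                          "ind|NG|A" = 4, "ind|NG|C" = 4, "ind|NG|G" = 4,
                          "ind|NTR|A" = 4, "ind|NTR|C" = 4,
                          "ind|NTR|G" = 4))
  ## a region of C has no T on either strand (reverse strand is all G)
  g0 <- simulateGenome(c(chr1 = 500L), seed = 101L)
  expect_message(
    out0 <- designPipeline(strrep("C", 40L), g0, cm, repeat_count = 4L),
    "no candidate")
  expect_equal(nrow(out0$report), 0L)

  ## region TACGT... yields the offset-0 candidate under the code
  region <- paste0("TACGT", strrep("C", 20L))
  g <- simulateGenome(c(chr1 = 3000L),
                      planted = data.frame(chrom = "chr1", start = 1000L,
                                           strand = "+", seq = region),
                      seed = 103L)
  out <- designPipeline(region, g, cm, repeat_count = 4L)
  expect_true(any(out$report$site == "TACGT" & out$report$offset == 0L &
                    out$report$strand == "+"))
  expect_identical(out$report$rvd[out$report$site == "TACGT"][1L],
                   "NI-HD-NN-NG")
  ## scores come back sorted ascending (best candidate first)
  expect_true(!is.unsorted(out$report$summary_score))

  ## planting an exact duplicate of one candidate's site elsewhere makes
  ## it rank below an otherwise-identical candidate without a duplicate
  region2 <- paste0("TACGT", "TAGGT", strrep("C", 15L))
  g2 <- simulateGenome(c(chr1 = 5000L),
                       planted = data.frame(chrom = "chr1",
                                            start = c(2000L, 3000L),
                                            strand = "+",
                                            seq = c(region2, "TACGT")),
                       seed = 105L)
  out2 <- designPipeline(region2, g2, cm, repeat_count = 4L,
                         region_origin = list(chrom = "chr1",
                                              start = 2000L))
  r <- out2$report
  sc_dup <- r$summary_score[r$site == "TACGT" & r$strand == "+"][1L]
  sc_clean <- r$summary_score[r$site == "TAGGT" & r$strand == "+"][1L]
  expect_gte(sc_dup, 1)
  expect_gt(sc_dup, sc_clean)
})

test_that("TALEN pair scores follow the PROGNOS-style combination rule", {
  mk <- function(cols) {
    m <- do.call(cbind, cols)
    rownames(m) <- c("A", "C", "G", "T")
    new("PWM", mat = sweep(m, 2L, colSums(m), "/"))
  }
  pwm <- mk(list(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
                 c(0.1, 0.1, 0.7, 0.1)))
  opt <- "ACG"
  ps <- talenPairScore(pwm, pwm, opt, opt)
  expect_equal(ps$total, 2)
  expect_equal(ps$left, 1)
  ## one mismatch, verified by independent arithmetic
  s_opt <- -sum(log(c(0.7, 0.7, 0.7)))
  s_mm <- -sum(log(c(0.7, 0.1, 0.7)))
  want <- (s_opt / s_mm)^0.6
  ps2 <- talenPairScore(pwm, pwm, "ATG", opt)
  expect_equal(ps2$left, want, tolerance = 1e-12)
  expect_equal(ps2$total, want + 1)
  expect_lt(ps2$left, 1)
  expect_gt(ps2$left, 0)
  ## monotone degradation with each added mismatch
  ps3 <- talenPairScore(pwm, pwm, "TTT", opt)
  expect_lt(ps3$left, ps2$left)
})

test_that("ROC handles separation, ties, and matches pair counting", {
  perfect <- rocCurve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  ties <- rocCurve(rep(5, 6L), c(0, 0, 0, 1, 1, 1))
  expect_equal(ties$auc, 0.5)
  ## Mann-Whitney equivalence on a toy set with ties
  set.seed(7)
  sc <- c(3, 5, 5, 2, 8, 7, 1, 5, 9, 4)
  lab <- c(0, 1, 0, 0, 1, 1, 0, 1, 1, 0)
  pos <- sc[lab == 1]; neg <- sc[lab == 0]
  conc <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(rocCurve(sc, lab)$auc, conc)
  ## independent cross-check against pROC
  expect_equal(rocCurve(sc, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))))
  expect_error(rocCurve(sc, rep(1, 10L)), "both classes")
})

test_that("correlation metrics match their definitions", {
  x <- c(1, 2, 5, 9, 20)
  expect_equal(correlationMetrics(x, x, "log_pearson"), 1)
  expect_equal(correlationMetrics(x, x, "spearman"), 1)
  ## power law is linear in log space
  expect_equal(correlationMetrics(x, 3 * x^1.7, "log_pearson"), 1)
  ## rank arithmetic oracle with ties
  a <- c(1, 4, 4, 2, 7); b <- c(2, 9, 8, 1, 12)
  expect_equal(correlationMetrics(a, b, "spearman"),
               cor(rank(a), rank(b)))
  expect_error(correlationMetrics(c(-1, 2, 3), c(1, 2, 3), "log_pearson"),
               "positive")
})
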