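## shared fixtures, all generated in code

## random anchored energy matrix with entries in [0, hi]
randomAnchoredEM <- function(L, seed, hi = 3) {
  set.seed(seed)
  m <- matrix(runif(4L * L, 0, hi), 4L, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- sweep(m, 2L, apply(m, 2L, min))
  anchors <- rownames(m)[apply(m, 2L, which.min)]
  EnergyMatrix(m, anchors)
}

## all 4^L sequences and their total ddG under an energy matrix,
## computed by accumulation over positions (independent of siteDdg)
bruteForceSiteEnergies <- function(em) {
  m <- as.matrix(em)
  L <- ncol(m)
  seqs <- ""
  e <- 0
  for (j in seq_len(L)) {
    seqs <- as.vector(outer(seqs, rownames(m), paste0))
    e <- as.vector(outer(e, m[, j], `+`))
  }
  data.frame(sequence = seqs, ddg = e, stringsAsFactors = FALSE)
}

## hand-built ContextModel with raw coefficients and identity scaling
rawContextModel <- function(coefs, intercept = 0, rvd_only = FALSE) {
  universe <- sifted:::featureUniverse(rvd_only)
  beta <- setNames(numeric(length(universe)), universe)
  beta[names(coefs)] <- coefs
  new("ContextModel",
      coefficients = c("(Intercept)" = intercept, beta),
      alpha = 0.95, lambda = 0,
      center = setNames(numeric(length(universe)), universe),
      scale = setNames(rep(1, length(universe)), universe),
      features = universe, rvd_only = rvd_only, version = "test")
}

## simulated quantified probe z-scores for one protein, via the full
## quantification pipeline
simulatedProbeZ <- function(protein, em, config) {
  tbl <- simulatePBM(protein, em, config)
  bg <- unique(tbl$probe_id[tbl$role == "background"])
  q <- quantifyPBM(tbl, bg)$quantified
  pr <- probeEntries(attr(tbl, "probes"))
  fg <- q[q$probe_id %in% pr$probe_id, , drop = FALSE]
  data.frame(site_sequence = pr$site_sequence[match(fg$probe_id,
                                                    pr$probe_id)],
             zscore = fg$zscore, stringsAsFactors = FALSE)
}
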