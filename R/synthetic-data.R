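## Synthetic-data generators.  They emit the same objects and text
## formats the real pipeline consumes, with the statistical structure the
## inference assumes: a ground-truth context model in the exact feature
## recipe of the regression, PBM probe tables with replicate noise,
## outlier spikes, a Cy3 channel generated from a known trinucleotide
## model and a background probe block, and genomes with planted sites.

#' Simulation configuration for PBM probe tables
#'
#' Defaults describe a strong, well-saturated PBM experiment: chemical
#' potential mu = 1 (protein concentration ~3x the optimal-site Kd, so
#' the optimal probe is near saturation), background-referenced z-scores
#' spanning 0 to ~100 (foreground/background contrasts of this size are
#' what lets the assay resolve ddG differences out to ~6 RT), unit
#' replicate noise in background robust-s.d. units, and 8 replicate
#' spots per probe.
#'
#' @param mu chemical potential of the simulated experiment.
#' @param a,b lower/upper z-score scaling terms.
#' @param z_noise_sd replicate noise s.d. in z-score units.
#' @param replicates replicate spots per probe (>= 1; arrays use 8).
#' @param outlier_rate per-replicate probability of an outlier spike.
#' @param outlier_size spike magnitude in replicate-noise robust-s.d.
#'   units.
#' @param n_background background probes (sites of unrelated proteins).
#' @param bg_median,bg_scale affine map from z-scores to raw BSI units.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
simulationConfig <- function(mu = 1, a = 0, b = 100, z_noise_sd = 1,
                             replicates = 8L, outlier_rate = 0.02,
                             outlier_size = 10, n_background = 40L,
                             bg_median = 1000, bg_scale = 150,
                             seed = 1L) {
  stopifnot(replicates >= 1L, z_noise_sd >= 0, b > a, n_background >= 20L)
  structure(list(mu = mu, a = a, b = b, z_noise_sd = z_noise_sd,
                 replicates = as.integer(replicates),
                 outlier_rate = outlier_rate, outlier_size = outlier_size,
                 n_background = as.integer(n_background),
                 bg_median = bg_median, bg_scale = bg_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth context model for simulation
#'
#' Coefficients live on the raw (unstandardized) feature recipe of the
#' regression, so a truth energy matrix is literally what a noiseless
#' regression would predict.  The default effect directions follow the
#' qualitative biology: NN is the least specific repeat and tolerates A;
#' HD strongly disfavours G; specificity decays towards the 3' end of the
#' site and with total protein length, more strongly for NN and NG than
#' for NI and HD; NI neighbours sharpen NI and NN repeats; an NN
#' half-repeat (CTR as C-terminal neighbour) loses specificity for G; an
#' NG N-terminal neighbour loosens NI.
#'
#' @param position_scale,length_scale,neighbour_scale multipliers on the
#'   default context-effect magnitudes (0 switches a family off).
#' @param noise_sd s.d. (RT) of per-entry deviations from the linear
#'   model.
#' @param floor smallest generated non-anchored ddG (RT).
#' @return list of class \code{truth_context_model} with elements
#'   \code{coefficients} (named raw-feature vector), \code{noise_sd},
#'   \code{floor} and \code{planted} (data.frame of the planted context
#'   effects and their signs, for recovery checks).
#' @export
truthContextModel <- function(position_scale = 1, length_scale = 1,
                              neighbour_scale = 1, noise_sd = 0.15,
                              floor = 0.2) {
  universe <- featureUniverse(FALSE)
  beta <- setNames(numeric(length(universe)), universe)
  ## baselines are the ddG at the high-specificity reference context
  ## (repeat position 2, site length 9); position and length effects are
  ## negative, so the baseline is also the ceiling - keeping every
  ## generated entry inside the ~0.2-4.5 RT window a strong PBM
  ## experiment can actually resolve
  baseline <- list(
    NTR = c(A = 2.8, C = 2.8, G = 2.8),
    NI  = c(C = 3.2, G = 3.6, T = 3.2),
    HD  = c(A = 3.2, G = 4.2, T = 3.4),
    NN  = c(A = 1.2, C = 3.4, T = 3.6),
    NG  = c(A = 3.0, C = 3.0, G = 3.4))
  pos_eff <- c(NI = -0.25, HD = -0.25, NN = -0.55, NG = -0.45) *
    position_scale
  len_eff <- c(NI = -0.70, HD = -0.70, NN = -1.20, NG = -1.00) *
    length_scale
  ref_p <- log(2); ref_L <- log(9)
  for (t in names(baseline)) {
    for (b in names(baseline[[t]])) {
      off <- if (t == "NTR") 0
             else pos_eff[[t]] * ref_p + len_eff[[t]] * ref_L
      beta[paste("ind", t, b, sep = "|")] <- baseline[[t]][[b]] - off
    }
  }
  for (t in names(pos_eff)) {
    for (b in setdiff(DNA_BASES, elementAnchor(t))) {
      beta[paste("lpos", t, b, sep = "|")] <- pos_eff[[t]]
      beta[paste("llen", t, b, sep = "|")] <- len_eff[[t]]
    }
  }
  nbr <- data.frame(
    type = c("NI", "NI", "NN", "NN", "NN", "NI"),
    nbr  = c("NI", "NI", "NI", "NI", "CTR", "NG"),
    side = c("N",  "C",  "N",  "C",  "C",   "N"),
    effect = c(0.6, 0.6, 0.7, 0.7, -1.2, -0.6) * neighbour_scale,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(nbr))) {
    pre <- if (nbr$side[i] == "N") "nN" else "nC"
    for (b in setdiff(DNA_BASES, elementAnchor(nbr$type[i])))
      beta[paste(pre, nbr$type[i], b, nbr$nbr[i], sep = "|")] <-
        nbr$effect[i]
  }
  planted <- rbind(
    data.frame(family = "position", type = names(pos_eff), nbr = NA,
               side = NA, effect = unname(pos_eff)),
    data.frame(family = "length", type = names(len_eff), nbr = NA,
               side = NA, effect = unname(len_eff)),
    data.frame(family = "neighbour", type = nbr$type, nbr = nbr$nbr,
               side = nbr$side, effect = nbr$effect))
  planted <- planted[planted$effect != 0, , drop = FALSE]
  structure(list(coefficients = beta, noise_sd = noise_sd, floor = floor,
                 planted = planted),
            class = "truth_context_model")
}

#' Simulate a designed panel of TALE proteins
#'
#' RVD arrays emulating a deliberately designed specificity panel:
#' nominal lengths are spread evenly over the requested range, the final
#' (half-)repeat cycles through the four RVD types so C-terminal-region
#' context is observed for every type, and with \code{pair_coverage} the
#' panel is adjusted (deterministically from the seed) until the union
#' of adjacent ordered RVD pairs covers all 16 - a requirement for
#' identifying neighbour effects, mirroring how experimental panels are
#' chosen.
#'
#' @param n_proteins panel size (>= 2).
#' @param length_range nominal-length range, x.5 convention (default
#'   8.5-18.5).
#' @param pair_coverage require all 16 ordered adjacent RVD pairs.
#' @param seed integer seed.
#' @return list of \linkS4class{TALEProtein}.
#' @export
simulatePanel <- function(n_proteins, length_range = c(8.5, 18.5),
                          pair_coverage = TRUE, seed = 1L) {
  stopifnot(n_proteins >= 2L)
  kmin <- as.integer(length_range[1L] + 0.5)
  kmax <- as.integer(length_range[2L] + 0.5)
  stopifnot(kmin >= 2L, kmax >= kmin)
  if (pair_coverage && n_proteins * (kmax - 1L) < 16L)
    stop("pair coverage infeasible: need at least ",
         ceiling(16 / (kmax - 1L)), " proteins of ", kmax, " elements",
         call. = FALSE)
  allPairs <- function(panel) {
    unique(unlist(lapply(panel, function(p) {
      rv <- rvds(p)
      paste(rv[-length(rv)], rv[-1L], sep = ">")
    })))
  }
  withSeed(seed, {
    ## even length spread and balanced final repeats: a designed panel
    ks <- sample(round(seq(kmin, kmax, length.out = n_proteins)))
    finals <- sample(rep_len(names(RVD_CODE), n_proteins))
    panel <- lapply(seq_len(n_proteins), function(i)
      TALEProtein(c(sample(names(RVD_CODE), ks[i] - 1L, replace = TRUE),
                    finals[i]),
                  id = sprintf("SIM%02d", i)))
    if (pair_coverage) {
      for (iter in seq_len(500L)) {
        missing <- setdiff(as.vector(outer(names(RVD_CODE),
                                           names(RVD_CODE),
                                           paste, sep = ">")),
                           allPairs(panel))
        if (!length(missing)) break
        pr <- strsplit(missing[1L], ">")[[1L]]
        i <- sample.int(n_proteins, 1L)
        rv <- rvds(panel[[i]])
        ## keep the balanced final repeat intact where possible
        pos <- if (length(rv) > 2L) sample.int(length(rv) - 2L, 1L)
               else 1L
        rv[pos] <- pr[1L]; rv[pos + 1L] <- pr[2L]
        panel[[i]] <- TALEProtein(rv, id = panel[[i]]@id)
      }
      if (length(setdiff(as.vector(outer(names(RVD_CODE),
                                         names(RVD_CODE), paste,
                                         sep = ">")), allPairs(panel))))
        stop("could not achieve all-pairs coverage; increase panel size",
             call. = FALSE)
    }
    panel
  })
}

#' Ground-truth energy matrix for a protein
#'
#' Assembles the anchored energy matrix the truth context model implies
#' for the protein - the feature rows of the regression recipe dotted
#' with the truth coefficients - plus seeded Gaussian deviations, clamped
#' below at the configured floor.
#'
#' @param protein a \linkS4class{TALEProtein}.
#' @param truth a \code{\link{truthContextModel}}.
#' @param seed integer seed (NULL for the noiseless matrix).
#' @return anchored \linkS4class{EnergyMatrix}.
#' @export
truthEM <- function(protein, truth, seed = NULL) {
  fr <- featureRowsForProtein(protein, rvd_only = FALSE)
  ddg <- as.numeric(fr$X[, names(truth$coefficients), drop = FALSE] %*%
                      truth$coefficients)
  if (truth$noise_sd > 0 && !is.null(seed))
    ddg <- ddg + withSeed(seed, stats::rnorm(length(ddg), 0,
                                             truth$noise_sd))
  ddg <- pmax(ddg, truth$floor)
  anchor_bases <- strsplit(canonicalTargetSite(protein), "")[[1L]]
  L <- length(anchor_bases)
  m <- matrix(0, 4L, L, dimnames = list(DNA_BASES,
                                        as.character(seq_len(L) - 1L)))
  m[cbind(match(fr$meta$base, DNA_BASES),
          fr$meta$element_index + 1L)] <- ddg
  EnergyMatrix(m, anchor_bases)
}

randomDNA <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a PBM probe table for one protein
#'
#' Builds the dinucleotide-substitution probe set for the protein's
#' canonical site, embeds it in constant flanks at a fixed offset of a
#' 60-mer, and emits the long-format probe table the quantification
#' pipeline consumes: replicate Alexa BSIs obtained by mapping the
#' occupancy-model z-scores through an affine transform to intensity
#' units, with Gaussian replicate noise and optional labelled outlier
#' spikes; a Cy3 channel generated exactly from a known trinucleotide
#' linear model; and a block of background probes whose z-scores have
#' median 0 and robust s.d. 1 by construction, so quantification maps
#' BSIs back onto the simulated z-scale.
#'
#' @param protein a \linkS4class{TALEProtein}.
#' @param em anchored \linkS4class{EnergyMatrix} (the protein's truth).
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame probe table (columns probe_id, sequence, channel,
#'   replicate, bsi, role, site_sequence, is_outlier) with attributes
#'   \code{z_true} (named by probe_id) and \code{probes} (the
#'   \linkS4class{ProbeSet}).
#' @export
simulatePBM <- function(protein, em, config = simulationConfig()) {
  site <- canonicalTargetSite(protein)
  n <- nchar(site)
  stopifnot(n <= 40L)
  withSeed(config$seed, {
    f5len <- (60L - n) %/% 2L
    repeat {
      flank5 <- randomDNA(f5len)
      flank3 <- randomDNA(60L - n - f5len)
      if (!grepl(site, paste0(flank5, flank3), fixed = TRUE)) break
    }
    probes <- dinucSubstitutionProbes(site, config$replicates)
    probes <- embedInFlanks(probes, flank5, flank3)
    ent <- probeEntries(probes)
    E <- vapply(ent$site_sequence, function(s) siteDdg(em, s), numeric(1L))
    occ <- 1 / (1 + exp(E - config$mu))
    z_true <- config$a + (config$b - config$a) * occ
    names(z_true) <- ent$probe_id

    ## background block: fixed symmetric z grid, median 0, robust sd 1
    u <- seq(-1, 1, length.out = config$n_background)
    z_bg <- u / (1.4826 * stats::median(abs(u)))
    bg_seq <- vapply(seq_len(config$n_background), function(i) {
      repeat {
        s <- randomDNA(60L)
        if (!grepl(site, s, fixed = TRUE)) return(s)
      }
    }, character(1L))
    bg_id <- sprintf("bg%03d", seq_len(config$n_background))

    emitAlexa <- function(ids, seqs, z0, role, sites) {
      out <- list()
      for (i in seq_along(ids)) {
        noise <- stats::rnorm(config$replicates, 0, config$z_noise_sd)
        spike <- stats::runif(config$replicates) < config$outlier_rate
        noise[spike] <- noise[spike] +
          sample(c(-1, 1), sum(spike), replace = TRUE) *
            config$outlier_size * max(config$z_noise_sd, 1e-12)
        z <- z0[i] + noise
        out[[i]] <- data.frame(
          probe_id = ids[i], sequence = seqs[i], channel = "alexa",
          replicate = seq_len(config$replicates),
          bsi = config$bg_median + config$bg_scale * z,
          role = role, site_sequence = sites[i],
          is_outlier = spike, stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    alexa <- rbind(
      emitAlexa(ent$probe_id, ent$probe_sequence, unname(z_true),
                "foreground", ent$site_sequence),
      emitAlexa(bg_id, bg_seq, z_bg, "background",
                rep(NA_character_, config$n_background)))

    ## Cy3 channel generated exactly from a trinucleotide linear model
    tri_coef <- 10 + stats::runif(64L, 0, 5)
    all_ids <- c(ent$probe_id, bg_id)
    all_seqs <- c(ent$probe_sequence, bg_seq)
    cy3val <- as.numeric(triNucCounts(all_seqs) %*% tri_coef)
    cy3 <- data.frame(
      probe_id = rep(all_ids, each = config$replicates),
      sequence = rep(all_seqs, each = config$replicates),
      channel = "cy3",
      replicate = rep(seq_len(config$replicates), length(all_ids)),
      bsi = rep(cy3val, each = config$replicates),
      role = rep(c(rep("foreground", nrow(ent)),
                   rep("background", config$n_background)),
                 each = config$replicates),
      site_sequence = rep(c(ent$site_sequence,
                            rep(NA_character_, config$n_background)),
                          each = config$replicates),
      is_outlier = FALSE, stringsAsFactors = FALSE)
    tbl <- rbind(alexa, cy3)
    rownames(tbl) <- NULL
    attr(tbl, "z_true") <- z_true
    attr(tbl, "probes") <- probes
    tbl
  })
}

#' Simulate a genome with planted sites
#'
#' I.i.d. background at the requested GC content, with the given
#' sequences written at stated loci and strands (minus-strand plants are
#' reverse-complemented into the forward strand).
#'
#' @param lengths named integer vector of chromosome lengths.
#' @param gc GC fraction in (0, 1).
#' @param planted optional data.frame with columns \code{chrom},
#'   \code{start} (0-based), \code{strand}, \code{seq}; plants must fit
#'   and must not overlap one another.
#' @param seed integer seed.
#' @return \code{DNAStringSet}.
#' @export
simulateGenome <- function(lengths, gc = 0.41, planted = NULL, seed = 1L) {
  stopifnot(gc > 0, gc < 1)
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  withSeed(seed, {
    chroms <- lapply(lengths, function(n) {
      strsplit(randomDNA(n, gc), "")[[1L]]
    })
    if (!is.null(planted) && nrow(planted)) {
      iv <- data.frame(chrom = planted$chrom, s = planted$start,
                       e = planted$start + nchar(planted$seq))
      for (ch in unique(iv$chrom)) {
        sub <- iv[iv$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$s), , drop = FALSE]
        if (nrow(sub) > 1L && any(sub$s[-1L] < sub$e[-nrow(sub)]))
          stop("planted sites overlap on ", ch, call. = FALSE)
        if (any(sub$e > lengths[[ch]]))
          stop("planted site extends past the end of ", ch, call. = FALSE)
      }
      for (i in seq_len(nrow(planted))) {
        s <- planted$seq[i]
        if (identical(planted$strand[i], "-")) s <- revComp(s)
        pos <- planted$start[i] + seq_len(nchar(s))
        chroms[[planted$chrom[i]]][pos] <- strsplit(s, "")[[1L]]
      }
    }
    Biostrings::DNAStringSet(
      setNames(vapply(chroms, paste, character(1L), collapse = ""),
               names(lengths)))
  })
}
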