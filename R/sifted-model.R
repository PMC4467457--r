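## The SIFTED context model: each non-anchored (element, base) ddG of
## every panel protein is one observation; features encode the element
## type, its position and the target-site length (linear and log), and
## the identities of the N- and C-terminal neighbouring repeats, all
## interacted with the (element type, base) indicator so each repeat type
## is influenced differently by its context.  A weighted Elastic Net
## (95% L1 / 5% L2) with nested protein-grouped cross-validation and the
## one-standard-error rule controls complexity.

ELEMENT_TYPES <- c("NTR", "NI", "HD", "NN", "NG")
NBR_N_TYPES <- c("NTR", "NI", "HD", "NN", "NG")
NBR_C_TYPES <- c("NI", "HD", "NN", "NG", "CTR")

elementAnchor <- function(type) {
  ifelse(type == "NTR", "T", RVD_CODE[type])
}

## deterministic universe of raw feature names
featureUniverse <- function(rvd_only = FALSE) {
  out <- character(0)
  for (t in ELEMENT_TYPES) {
    for (b in setdiff(DNA_BASES, elementAnchor(t))) {
      out <- c(out, paste("ind", t, b, sep = "|"))
      if (rvd_only) next
      if (t != "NTR")
        out <- c(out, paste(c("pos", "lpos", "len", "llen"), t, b, sep = "|"))
      if (t != "NTR")
        out <- c(out, paste("nN", t, b, NBR_N_TYPES, sep = "|"))
      out <- c(out, paste("nC", t, b, NBR_C_TYPES, sep = "|"))
    }
  }
  out
}

## raw feature vector for a single (element, base) observation
featureVector <- function(type, base, position, site_length, nbrN, nbrC,
                          universe) {
  v <- setNames(numeric(length(universe)), universe)
  setf <- function(nm, val) {
    if (nm %in% universe) v[nm] <<- val
    invisible(NULL)
  }
  setf(paste("ind", type, base, sep = "|"), 1)
  if (type != "NTR") {
    setf(paste("pos", type, base, sep = "|"), position)
    setf(paste("lpos", type, base, sep = "|"), log(position))
    setf(paste("len", type, base, sep = "|"), site_length)
    setf(paste("llen", type, base, sep = "|"), log(site_length))
    if (!is.na(nbrN)) setf(paste("nN", type, base, nbrN, sep = "|"), 1)
  }
  if (!is.na(nbrC)) setf(paste("nC", type, base, nbrC, sep = "|"), 1)
  v
}

#' Per-observation feature rows for one protein
#'
#' One row per element (NTR = index 0, repeats 1..k) and non-anchored
#' base.  The NTR is treated like a repeat except that it carries no
#' position or length features and no N-terminal neighbour; the final
#' repeat's C-terminal neighbour is the C-terminal region (CTR).
#'
#' @param protein a \linkS4class{TALEProtein}.
#' @param rvd_only restrict features to the (element type, base)
#'   indicators (the context-free, canonical-code model).
#' @return list with \code{meta} (protein_id, element_index, type, base)
#'   and \code{X} (raw feature matrix).
#' @export
featureRowsForProtein <- function(protein, rvd_only = FALSE) {
  universe <- featureUniverse(rvd_only)
  rv <- rvds(protein)
  k <- length(rv)
  L <- k + 1L  # target-site length in bases
  meta <- list()
  rowsX <- list()
  for (e in 0:k) {
    type <- if (e == 0L) "NTR" else rv[e]
    nbrN <- if (e == 0L) NA_character_
            else if (e == 1L) "NTR" else rv[e - 1L]
    nbrC <- if (e == k) "CTR" else rv[e + 1L]
    for (b in setdiff(DNA_BASES, elementAnchor(type))) {
      meta[[length(meta) + 1L]] <-
        data.frame(protein_id = protein@id, element_index = e,
                   type = type, base = b, stringsAsFactors = FALSE)
      rowsX[[length(rowsX) + 1L]] <-
        featureVector(type, b, e, L, nbrN, nbrC, universe)
    }
  }
  list(meta = do.call(rbind, meta),
       X = do.call(rbind, rowsX))
}

#' Assemble the panel-wide feature matrix, response and weights
#'
#' Stacks the non-anchored ddG observations of every (protein, energy
#' matrix) pair.  Matrices are anchored first; the zero-valued anchor
#' entries are excluded.  Observation weight = 1 / (number of panel
#' proteins sharing the protein's nominal length), which stops abundant
#' lengths from dominating the regression.
#'
#' @param proteins list of \linkS4class{TALEProtein}.
#' @param ems list of matching \linkS4class{EnergyMatrix} (one column per
#'   element, NTR first).
#' @param rvd_only drop all context features.
#' @return list with raw \code{X}, response \code{y} (RT), \code{weights},
#'   and \code{meta}.
#' @export
buildFeatureMatrix <- function(proteins, ems, rvd_only = FALSE) {
  stopifnot(length(proteins) == length(ems))
  lens <- vapply(proteins, nominalLength, numeric(1L))
  wt_by_len <- 1 / table(lens)
  parts <- lapply(seq_along(proteins), function(i) {
    p <- proteins[[i]]
    em <- normalizeEM(ems[[i]])
    if (ncol(em@mat) != length(rvds(p)) + 1L)
      stop("energy matrix of '", p@id,
           "' does not match its element count", call. = FALSE)
    fr <- featureRowsForProtein(p, rvd_only)
    y <- em@mat[cbind(match(fr$meta$base, DNA_BASES),
                      fr$meta$element_index + 1L)]
    w <- rep(as.numeric(wt_by_len[as.character(nominalLength(p))]),
             nrow(fr$meta))
    list(X = fr$X, y = y, w = w, meta = fr$meta)
  })
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y")),
       weights = unlist(lapply(parts, `[[`, "w")),
       meta = do.call(rbind, lapply(parts, `[[`, "meta")))
}

## standardize to mean 0 / variance 1, dropping constant columns
standardizeColumns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  keep <- which(scl > 1e-12)
  if (length(keep) < ncol(X))
    message(ncol(X) - length(keep), " constant feature columns dropped")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep], "-"),
              2L, scl[keep], "/")
  list(X = Xs, center = ctr[keep], scale = scl[keep],
       dropped = colnames(X)[-keep])
}

## lambda_max (all coefficients zero) for the weighted elastic net,
## then a log-spaced path over `decades` decades below it
lambdaPath <- function(X, y, weights, alpha = 0.95, n_lambda = 100L,
                      decades = 4) {
  w <- weights / mean(weights)
  ybar <- sum(w * y) / sum(w)
  lmax <- max(abs(crossprod(X, w * (y - ybar)))) / (nrow(X) * max(alpha, 1e-3))
  10^seq(log10(lmax), log10(lmax) - decades, length.out = n_lambda)
}

#' Weighted Elastic Net coefficient path
#'
#' Thin wrapper over \code{\link[glmnet]{glmnet}} minimizing
#' \eqn{(1/2N) \sum_i w_i (y_i - \beta_0 - x_i^T\beta)^2 +
#' \lambda(\alpha \|\beta\|_1 + ((1-\alpha)/2)\|\beta\|_2^2)} along a
#' log-spaced path from \eqn{\lambda_{max}} (all coefficients zero)
#' downwards.  Columns are expected pre-standardized.
#'
#' @param X standardized feature matrix.
#' @param y response (ddG, RT).
#' @param weights observation weights.
#' @param alpha L1 fraction (default 0.95).
#' @param n_lambda path length (default 100).
#' @param lambda optional explicit path.
#' @return list with the \code{glmnet} fit and the \code{lambda} path.
#' @export
elasticNetPath <- function(X, y, weights = rep(1, length(y)), alpha = 0.95,
                           n_lambda = 100L, lambda = NULL) {
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)
  if (is.null(lambda))
    lambda <- lambdaPath(X, y, weights, alpha, n_lambda)
  fit <- glmnet::glmnet(X, y, weights = weights, alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE)
  list(fit = fit, lambda = lambda)
}

#' ContextModel: a trained SIFTED predictor
#'
#' @slot coefficients named vector of raw-feature coefficients, first
#'   element the intercept.
#' @slot alpha L1 fraction of the Elastic Net penalty.
#' @slot lambda penalty at which the model was fit.
#' @slot center,scale per-feature standardization statistics.
#' @slot features feature names (post constant-column drop).
#' @slot rvd_only TRUE for the context-free reduced model.
#' @slot version feature-recipe version tag.
#' @export
setClass("ContextModel",
  representation(coefficients = "numeric", alpha = "numeric",
                 lambda = "numeric", center = "numeric", scale = "numeric",
                 features = "character", rvd_only = "logical",
                 version = "character"))

setMethod("show", "ContextModel", function(object) {
  nz <- sum(object@coefficients[-1L] != 0)
  cat(sprintf("ContextModel (%s, recipe %s)\n",
              if (object@rvd_only) "RVD-only" else "full context",
              object@version))
  cat(sprintf("  alpha = %.2f, lambda = %.4g, %d/%d nonzero coefficients\n",
              object@alpha, object@lambda, nz, length(object@features)))
})

FEATURE_RECIPE_VERSION <- "1.0"

fitContextModel <- function(X, y, weights, lambda, alpha, std, rvd_only) {
  fit <- glmnet::glmnet(std$X, y, weights = weights, alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE)
  beta <- as.numeric(stats::coef(fit, s = lambda[1L]))
  names(beta) <- c("(Intercept)", colnames(std$X))
  new("ContextModel", coefficients = beta, alpha = alpha,
      lambda = lambda[1L], center = std$center, scale = std$scale,
      features = colnames(std$X), rvd_only = rvd_only,
      version = FEATURE_RECIPE_VERSION)
}

#' Train the context model with nested, protein-grouped cross-validation
#'
#' Outer loop: leave one protein out.  Inner loop: the remaining proteins
#' are split into \code{n_folds} protein-grouped folds (no protein's rows
#' ever straddle train and test) and the weighted Elastic Net is fit along
#' one shared lambda path.  Held-out squared errors are pooled over all
#' inner folds of all outer iterations; a seeded bootstrap over them gives
#' the standard error of the MSE at each lambda, and the chosen lambda is
#' the largest (most penalized) one whose mean MSE is within one standard
#' error of the minimum.  That single lambda is used to refit each outer
#' training set for the held-out predictions and to refit the full panel
#' for the deliverable model.
#'
#' @param proteins list of \linkS4class{TALEProtein} (>= 6).
#' @param ems matching list of \linkS4class{EnergyMatrix}.
#' @param alpha L1 fraction (default 0.95).
#' @param n_folds inner folds (default 5).
#' @param n_lambda lambda path length (default 100).
#' @param n_boot bootstrap resamples for the MSE standard error.
#' @param seed integer seed (fold assignment and bootstrap).
#' @param rvd_only train the context-free reduced model.
#' @return list with \code{model} (\linkS4class{ContextModel}) and
#'   \code{report}: lambda path, mean MSE and bootstrap s.e. per lambda,
#'   \code{lambda_min}, \code{lambda_1se}, and \code{heldout} (per-row
#'   leave-one-protein-out predictions).
#' @export
nestedCV <- function(proteins, ems, alpha = 0.95, n_folds = 5L,
                     n_lambda = 100L, n_boot = 1000L, seed = 1L,
                     rvd_only = FALSE) {
  nP <- length(proteins)
  if (nP < n_folds + 1L)
    stop("need more proteins (", nP, ") than inner folds (", n_folds, ") + 1",
         call. = FALSE)
  fm <- buildFeatureMatrix(proteins, ems, rvd_only)
  std <- standardizeColumns(fm$X)
  X <- std$X; y <- fm$y; w <- fm$weights
  pid <- fm$meta$protein_id
  ids <- vapply(proteins, function(p) p@id, "")
  lambda <- lambdaPath(X, y, w, alpha, n_lambda)

  ## pooled held-out squared errors: rows x lambda
  err <- matrix(NA_real_, length(y), n_lambda)
  withSeed(childSeed(seed, 1L), {
    for (o in seq_len(nP)) {
      rest <- setdiff(ids, ids[o])
      folds <- sample(rep_len(seq_len(n_folds), length(rest)))
      for (f in seq_len(n_folds)) {
        te_ids <- rest[folds == f]
        tr <- which(!pid %in% c(ids[o], te_ids))
        te <- which(pid %in% te_ids)
        fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                              weights = w[tr], alpha = alpha,
                              lambda = lambda, standardize = FALSE,
                              intercept = TRUE)
        pr <- stats::predict(fit, X[te, , drop = FALSE], s = lambda)
        e2 <- (pr - y[te])^2
        ## average over the outer iterations in which a row is tested
        err[te, ] <- ifelse(is.na(err[te, ]), 0, err[te, ]) + e2 / (nP - 1L)
      }
    }
  })
  mse <- colMeans(err)
  boot_se <- withSeed(childSeed(seed, 2L), {
    n <- nrow(err)
    bm <- vapply(seq_len(n_boot), function(b) {
      colMeans(err[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(n_lambda))
    apply(bm, 1L, stats::sd)
  })
  i_min <- which.min(mse)
  i_1se <- min(which(mse <= mse[i_min] + boot_se[i_min]))
  lambda_1se <- lambda[i_1se]

  ## held-out predictions at the single shared lambda
  heldout <- fm$meta
  heldout$observed <- y
  heldout$predicted <- NA_real_
  for (o in seq_len(nP)) {
    tr <- which(pid != ids[o])
    te <- which(pid == ids[o])
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], weights = w[tr],
                          alpha = alpha, lambda = lambda,
                          standardize = FALSE, intercept = TRUE)
    heldout$predicted[te] <-
      as.numeric(stats::predict(fit, X[te, , drop = FALSE], s = lambda_1se))
  }

  model <- fitContextModel(fm$X, y, w, c(lambda_1se, lambda_1se * 0.999),
                           alpha, std, rvd_only)
  model@lambda <- lambda_1se
  list(model = model,
       report = list(lambda = lambda, mse = mse, se = boot_se,
                     lambda_min = lambda[i_min], lambda_1se = lambda_1se,
                     heldout = heldout))
}

#' Train on the full panel at a fixed penalty
#'
#' @inheritParams nestedCV
#' @param lambda penalty value.
#' @return A \linkS4class{ContextModel}.
#' @export
trainContextModel <- function(proteins, ems, lambda, alpha = 0.95,
                              rvd_only = FALSE) {
  fm <- buildFeatureMatrix(proteins, ems, rvd_only)
  std <- standardizeColumns(fm$X)
  fitContextModel(fm$X, fm$y, fm$weights, c(lambda, lambda * 0.999),
                  alpha, std, rvd_only)
}

predictRows <- function(model, Xraw) {
  Xs <- sweep(sweep(Xraw[, model@features, drop = FALSE], 2L,
                    model@center, "-"), 2L, model@scale, "/")
  as.numeric(model@coefficients[1L] +
               Xs %*% model@coefficients[model@features])
}

#' Predict the energy matrix and PWM of an arbitrary TALE
#'
#' Builds the feature rows for the protein, applies the trained model
#' (re-standardizing with the training statistics), sets the anchored
#' (canonical) base of every column to 0 and returns the anchored energy
#' matrix; the PWM follows by the Boltzmann transform.
#'
#' @param protein a \linkS4class{TALEProtein}.
#' @param model a trained \linkS4class{ContextModel}.
#' @return list with \code{em} (\linkS4class{EnergyMatrix}) and \code{pwm}
#'   (\linkS4class{PWM}).
#' @export
predictEM <- function(protein, model) {
  fr <- featureRowsForProtein(protein, model@rvd_only)
  pred <- predictRows(model, fr$X)
  anchor_bases <- strsplit(canonicalTargetSite(protein), "")[[1L]]
  L <- length(anchor_bases)
  m <- matrix(0, 4L, L, dimnames = list(DNA_BASES,
                                        as.character(seq_len(L) - 1L)))
  m[cbind(match(fr$meta$base, DNA_BASES),
          fr$meta$element_index + 1L)] <- pred
  em <- EnergyMatrix(m, anchor_bases)
  list(em = em, pwm = emToPWM(em))
}

#' Log2 effect of a neighbouring repeat on a predicted base frequency
#'
#' Builds two contexts for an element of the given type that differ only
#' in the presence of the named neighbour indicator, predicts the
#' element's full ddG column under both, converts to Boltzmann
#' frequencies and returns log2(f_with / f_without) for the requested
#' base.
#'
#' @param model trained \linkS4class{ContextModel}.
#' @param type element type ("NTR", "NI", "HD", "NN", "NG").
#' @param base base whose frequency is compared.
#' @param neighbour neighbour type; "CTR" only as C-terminal neighbour,
#'   "NTR" only as N-terminal neighbour.
#' @param side "N" or "C".
#' @param position,site_length context for the position/length features
#'   (ignored for the NTR).
#' @return numeric log2 ratio.
#' @export
neighborEffectLog2Ratio <- function(model, type, base, neighbour,
                                    side = c("N", "C"),
                                    position = 5, site_length = 11) {
  side <- match.arg(side)
  type <- match.arg(type, ELEMENT_TYPES)
  base <- match.arg(base, DNA_BASES)
  if (side == "N") {
    if (type == "NTR")
      stop("the NTR has no N-terminal neighbour", call. = FALSE)
    if (!neighbour %in% NBR_N_TYPES)
      stop("invalid N-terminal neighbour '", neighbour, "'", call. = FALSE)
  } else if (!neighbour %in% NBR_C_TYPES) {
    stop("invalid C-terminal neighbour '", neighbour, "'", call. = FALSE)
  }
  universe <- featureUniverse(model@rvd_only)
  anchor <- elementAnchor(type)
  colDdg <- function(with_nbr) {
    vapply(setdiff(DNA_BASES, anchor), function(b) {
      x <- featureVector(type, b, position, site_length,
                         nbrN = if (side == "N" && with_nbr) neighbour
                                else NA_character_,
                         nbrC = if (side == "C" && with_nbr) neighbour
                                else NA_character_,
                         universe)
      predictRows(model, rbind(x))
    }, numeric(1L))
  }
  freq <- function(dd) {
    w <- exp(-c(setNames(0, anchor), dd))
    (w / sum(w))[[base]]
  }
  log2(freq(colDdg(TRUE)) / freq(colDdg(FALSE)))
}

#' Context-effect contrast of a trained model
#'
#' The direction and magnitude a trained model assigns to a context
#' effect, averaged over the element type's non-anchored bases, in RT
#' units of ddG.  For \code{family = "position"} (or \code{"length"}) it
#' is the predicted ddG difference between the high and low position (or
#' site length), the other context held fixed.  For
#' \code{family = "neighbour"} it is the predicted ddG with the named
#' neighbour minus the average over the other possible neighbours on
#' that side - within a (type, base) group the neighbour indicators sum
#' to one, so only such relative contrasts are identified.  Positive
#' values mean the context makes the element more specific (larger
#' mismatch penalty).
#'
#' @param model trained \linkS4class{ContextModel}.
#' @param type element type.
#' @param family "position", "length" or "neighbour".
#' @param nbr,side neighbour type and side ("N"/"C") for
#'   \code{family = "neighbour"}.
#' @param positions low/high positions contrasted (default 2 and 8).
#' @param lengths low/high site lengths contrasted (default 8 and 14).
#' @param at_position,at_length fixed context for the non-contrasted
#'   variable.
#' @return numeric contrast (RT).
#' @export
contextEffectContrast <- function(model, type,
                                  family = c("position", "length",
                                             "neighbour"),
                                  nbr = NULL, side = NULL,
                                  positions = c(2, 8), lengths = c(8, 14),
                                  at_position = 5, at_length = 11) {
  family <- match.arg(family)
  type <- match.arg(type, ELEMENT_TYPES)
  universe <- featureUniverse(model@rvd_only)
  bases <- setdiff(DNA_BASES, elementAnchor(type))
  pv <- function(b, p, L, nN, nC)
    predictRows(model, rbind(featureVector(type, b, p, L, nN, nC,
                                           universe)))
  mean(vapply(bases, function(b) {
    switch(family,
      position = pv(b, positions[2L], at_length, NA, NA) -
                 pv(b, positions[1L], at_length, NA, NA),
      length = pv(b, at_position, lengths[2L], NA, NA) -
               pv(b, at_position, lengths[1L], NA, NA),
      neighbour = {
        if (is.null(nbr) || is.null(side))
          stop("neighbour contrasts need 'nbr' and 'side'", call. = FALSE)
        pool <- if (side == "N") NBR_N_TYPES else NBR_C_TYPES
        if (!nbr %in% pool)
          stop("invalid ", side, "-side neighbour '", nbr, "'",
               call. = FALSE)
        others <- setdiff(pool, nbr)
        w <- if (side == "N") pv(b, at_position, at_length, nbr, NA)
             else pv(b, at_position, at_length, NA, nbr)
        o <- mean(vapply(others, function(nn) {
          if (side == "N") pv(b, at_position, at_length, nn, NA)
          else pv(b, at_position, at_length, NA, nn)
        }, numeric(1L)))
        w - o
      })
  }, numeric(1L)))
}

#' Serialize / load a trained context model as a TSV coefficient table
#'
#' Human-readable and sufficient for prediction without the training
#' data: coefficients plus the standardization sidecar columns.
#'
#' @param model a \linkS4class{ContextModel}.
#' @param file path.
#' @return \code{readContextModel} returns a
#'   \linkS4class{ContextModel}; \code{writeContextModel} returns
#'   \code{file} invisibly.
#' @export
writeContextModel <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# sifted context model recipe=%s alpha=%.6g lambda=%.10g rvd_only=%s",
                     model@version, model@alpha, model@lambda,
                     model@rvd_only), con)
  df <- data.frame(feature = c("(Intercept)", model@features),
                   coefficient = model@coefficients,
                   center = c(NA, model@center),
                   scale = c(NA, model@scale))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeContextModel
#' @export
readContextModel <- function(file) {
  lines <- readLines(file)
  hdr <- lines[1L]
  getv <- function(key) sub(paste0(".*", key, "="), "", hdr)
  alpha <- as.numeric(sub(" .*", "", getv("alpha")))
  lambda <- as.numeric(sub(" .*", "", getv("lambda")))
  rvd_only <- as.logical(sub(" .*", "", getv("rvd_only")))
  version <- sub(" .*", "", getv("recipe"))
  df <- utils::read.delim(text = lines[-1L], stringsAsFactors = FALSE)
  feats <- df$feature[-1L]
  new("ContextModel",
      coefficients = setNames(df$coefficient, df$feature),
      alpha = alpha, lambda = lambda,
      center = setNames(df$center[-1L], feats),
      scale = setNames(df$scale[-1L], feats),
      features = feats, rvd_only = rvd_only, version = version)
}
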