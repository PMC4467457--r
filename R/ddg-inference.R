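## Occupancy-model inference of ddG energy matrices from probe z-scores.
##
## Observation model: for a probe whose embedded site has total energy
## E = siteDdg(em, site) (RT units), occupancy = 1 / (1 + exp(E - mu))
## with mu the chemical potential log([TF]/Kd of the optimal site), and
## the predicted z-score is the linear scaling a + (b - a) * occupancy.
## z_obs ~ Normal(z_pred, sigma).  Priors: shifted exponential on each
## non-anchored ddG (decreasing from a small negative floor, so a repeat
## that genuinely prefers a non-canonical base stays representable),
## half-Cauchy(5) on sigma, flat priors on mu, a, b with b > a enforced
## through the parameterization b = a + exp(gap).

#' Scaling parameters of the occupancy-to-z-score model
#'
#' @slot mu chemical potential, log([TF]/Kd) of the optimal site.
#' @slot a lower scaling term (z-score at zero occupancy).
#' @slot b upper scaling term (z-score at full occupancy).
#' @export
setClass("BindingModelParams",
  representation(mu = "numeric", a = "numeric", b = "numeric"),
  validity = function(object) {
    if (!all(is.finite(c(object@mu, object@a, object@b))))
      "mu, a, b must be finite" else TRUE
  })

#' @rdname BindingModelParams-class
#' @param mu,a,b numeric scalars.
#' @export
BindingModelParams <- function(mu, a, b) {
  new("BindingModelParams", mu = mu, a = a, b = b)
}

setMethod("show", "BindingModelParams", function(object) {
  cat(sprintf("BindingModelParams: mu = %.4g, a = %.4g, b = %.4g\n",
              object@mu, object@a, object@b))
})

#' Predicted fractional occupancy of a site
#'
#' \eqn{occ = 1 / (1 + e^{E - \mu})} with \eqn{E} the site's total ddG on
#' an anchored energy matrix.
#'
#' @param em anchored \linkS4class{EnergyMatrix}.
#' @param mu chemical potential.
#' @param site DNA string matching the matrix width.
#' @return numeric in [0, 1].
#' @export
predictOccupancy <- function(em, mu, site) {
  E <- siteDdg(em, site)
  1 / (1 + exp(E - mu))
}

#' Predicted z-scores for a set of sites
#'
#' Linear scaling of occupancy: \eqn{z = a + (b - a) \cdot occ}.
#'
#' @param em anchored \linkS4class{EnergyMatrix}.
#' @param params \linkS4class{BindingModelParams}.
#' @param sites character vector of site sequences.
#' @return numeric vector of predicted z-scores.
#' @export
predictZscores <- function(em, params, sites) {
  E <- vapply(sites, function(s) siteDdg(em, s), numeric(1L))
  unname(params@a + (params@b - params@a) / (1 + exp(E - params@mu)))
}

## Indicator design matrix over the non-anchored (position, base) energy
## parameters for a set of site variants.  Parameter k corresponds to
## name "<pos0>:<base>"; X[i, k] = 1 iff variant i carries that base.
siteDesignMatrix <- function(sites, anchor_bases) {
  L <- length(anchor_bases)
  pnames <- unlist(lapply(seq_len(L), function(j)
    paste0(j - 1L, ":", setdiff(DNA_BASES, anchor_bases[j]))))
  X <- matrix(0, length(sites), length(pnames),
              dimnames = list(NULL, pnames))
  for (i in seq_along(sites)) {
    bases <- strsplit(sites[i], "")[[1L]]
    if (length(bases) != L)
      stop("site length mismatch at variant ", i, call. = FALSE)
    for (j in seq_len(L)) {
      if (bases[j] != anchor_bases[j])
        X[i, paste0(j - 1L, ":", bases[j])] <- 1
    }
  }
  X
}

#' Configuration for the posterior fit
#'
#' @param n_chains independent sampler runs used for convergence checking.
#' @param burn_in discarded ensemble sweeps per run.
#' @param samples retained ensemble sweeps per run.
#' @param prior_mean mean (RT) of the exponential prior on non-anchored
#'   ddG values.
#' @param init_nonpref initial ddG (RT) for non-preferred bases.
#' @param rhat_threshold split-Rhat above which the fit is flagged.
#' @param floor lower support bound (RT) of the shifted-exponential ddG
#'   prior; slightly negative so sub-anchor preferences (NN repeats can
#'   prefer A) stay representable.
#' @param n_walkers ensemble walkers (default max(80, 2 x parameters + 2)).
#' @param thin keep every thin-th sweep.
#' @param seed integer seed.
#' @return A list of class \code{ddg_fit_config}.
#' @export
ddgFitConfig <- function(n_chains = 4L, burn_in = 1500L, samples = 1500L,
                         prior_mean = 10, init_nonpref = 3,
                         rhat_threshold = 1.05, floor = -2,
                         n_walkers = NULL, thin = 5L, seed = 1L) {
  stopifnot(n_chains >= 2L, burn_in > 0L, samples > 0L, prior_mean > 0,
            thin >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 samples = as.integer(samples),
                 prior_mean = prior_mean, init_nonpref = init_nonpref,
                 rhat_threshold = rhat_threshold, floor = floor,
                 n_walkers = n_walkers, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "ddg_fit_config")
}

## log posterior in the working parameterization
## p = (theta[K], mu, a, gap = log(b - a), log sigma)
ddgLogPosterior <- function(p, X, z, floor, prior_mean) {
  K <- ncol(X)
  th <- p[seq_len(K)]
  if (any(th < floor)) return(-Inf)
  a <- p[K + 2L]; b <- a + exp(p[K + 3L]); s <- exp(p[K + 4L])
  zp <- a + (b - a) / (1 + exp(as.vector(X %*% th) - p[K + 1L]))
  sum(stats::dnorm(z, zp, s, log = TRUE)) -
    sum(th - floor) / prior_mean +
    stats::dcauchy(s, 0, 5, log = TRUE) + p[K + 4L]
}

## Multi-start MAP in the working parameterization; returns optim result.
ddgMAP <- function(X, z, floor, prior_mean, init_nonpref = 3) {
  K <- ncol(X)
  nlp <- function(p) {
    v <- ddgLogPosterior(p, X, z, floor, prior_mean)
    if (!is.finite(v)) 1e10 else -v
  }
  a0 <- min(z); b0 <- max(z); gap0 <- log(max(b0 - a0, 1e-3))
  ## crude data-driven start from the single-substitution probes
  singles <- which(rowSums(X) == 1)
  refi <- which(rowSums(X) == 0)
  zref <- if (length(refi)) z[refi[1L]] else b0
  occ0 <- min(max((zref - a0) / (b0 - a0), 0.05), 0.95)
  mu0 <- log(occ0 / (1 - occ0))
  th0 <- rep(init_nonpref, K)
  for (i in singles) {
    k <- which(X[i, ] == 1)
    oc <- min(max((z[i] - a0) / (b0 - a0), 1e-3), 0.999)
    th0[k] <- min(max(mu0 - log(oc / (1 - oc)), floor + 0.05), 15)
  }
  starts <- list(c(rep(init_nonpref, K), -1, a0, gap0, 0),
                 c(th0, mu0, a0, gap0, 0),
                 c(rep(init_nonpref, K), 1, a0, gap0, 0))
  lower <- c(rep(floor + 0.01, K), -30, -1e4, -10, -10)
  upper <- c(rep(30, K), 30, 1e4, 14, 10)
  fits <- lapply(starts, function(p0) tryCatch(
    stats::optim(p0, nlp, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 5000L), hessian = TRUE),
    error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("MAP optimization failed", call. = FALSE)
  fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
}

## Batched log posterior: one row of P per walker.  A single matrix
## multiply evaluates every walker's site energies at once.
ddgLogPosteriorBatch <- function(P, X, z, floor, prior_mean) {
  K <- ncol(X)
  N <- length(z)
  m <- nrow(P)
  th <- P[, seq_len(K), drop = FALSE]
  bad <- apply(th < floor, 1L, any)
  a <- P[, K + 2L]
  b <- a + exp(P[, K + 3L])
  s <- exp(P[, K + 4L])
  EE <- tcrossprod(th, X)                       # m x N site energies
  ZP <- a + (b - a) / (1 + exp(EE - P[, K + 1L]))
  SSE <- rowSums((ZP - rep(z, each = m))^2)
  ll <- -SSE / (2 * s^2) - N * log(s) - N * log(2 * pi) / 2
  lp <- ll - rowSums(th - floor) / prior_mean +
    stats::dcauchy(s, 0, 5, log = TRUE) + P[, K + 4L]
  lp[bad] <- -Inf
  lp
}

## One affine-invariant stretch-move ensemble (Goodman & Weare).  Returns
## a (kept sweeps x walkers) x d matrix of draws.
runEnsemble <- function(batch_logpost, center, spread, floor, K,
                        n_walkers, n_iter, burn, thin, seed) {
  d <- length(center)
  withSeed(seed, {
    W <- matrix(rep(center, n_walkers), nrow = n_walkers, byrow = TRUE) +
      matrix(stats::rnorm(n_walkers * d), n_walkers) *
        rep(pmin(spread, 1), each = n_walkers) * 2
    W[, seq_len(K)] <- pmax(W[, seq_len(K)], floor + 0.02)
    lp <- batch_logpost(W)
    keep <- vector("list", (n_iter - burn) %/% thin)
    ki <- 0L
    half <- n_walkers %/% 2L
    for (it in seq_len(n_iter)) {
      for (grp in 0:1) {
        idx <- if (grp == 0) seq_len(half) else (half + 1L):n_walkers
        oth <- if (grp == 0) (half + 1L):n_walkers else seq_len(half)
        zz <- (stats::runif(length(idx)) * (sqrt(2) - sqrt(0.5)) +
                 sqrt(0.5))^2
        js <- sample(oth, length(idx), replace = TRUE)
        prop <- W[js, , drop = FALSE] +
          zz * (W[idx, , drop = FALSE] - W[js, , drop = FALSE])
        lpp <- batch_logpost(prop)
        acc <- log(stats::runif(length(idx))) < (d - 1) * log(zz) + lpp - lp[idx]
        acc[!is.finite(lpp)] <- FALSE
        W[idx[acc], ] <- prop[acc, , drop = FALSE]
        lp[idx[acc]] <- lpp[acc]
      }
      if (it > burn && (it - burn) %% thin == 0L) {
        ki <- ki + 1L
        keep[[ki]] <- W
      }
    }
    do.call(rbind, keep[seq_len(ki)])
  })
}

#' Split-Rhat convergence diagnostic
#'
#' The Gelman-Rubin potential scale reduction factor computed after
#' splitting each chain in half, per scalar parameter.  A parameter that
#' is constant across all chains has no defined Rhat and is reported as
#' \code{NA} rather than propagating \code{NaN}.
#'
#' @param chains list (>= 2) of equal-width numeric matrices, one row per
#'   draw, one column per parameter.
#' @return Named numeric vector of Rhat values.
#' @export
checkConvergence <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need >= 2 chains", call. = FALSE)
  d <- ncol(chains[[1L]])
  if (!all(vapply(chains, ncol, 1L) == d))
    stop("chains must have identical parameter sets", call. = FALSE)
  n2 <- min(vapply(chains, nrow, 1L)) %/% 2L
  if (n2 < 2L) stop("chains too short to split", call. = FALSE)
  sub <- do.call(c, lapply(chains, function(m)
    list(m[seq_len(n2), , drop = FALSE],
         m[(n2 + 1L):(2L * n2), , drop = FALSE])))
  r <- vapply(seq_len(d), function(j) {
    ch <- vapply(sub, function(m) m[, j], numeric(n2))
    mns <- colMeans(ch)
    vs <- apply(ch, 2L, stats::var)
    W <- mean(vs)
    if (W == 0) return(if (stats::var(mns) == 0) NA_real_ else Inf)
    B <- n2 * stats::var(mns)
    sqrt(((n2 - 1) / n2 * W + B / n2) / W)
  }, numeric(1L))
  names(r) <- colnames(chains[[1L]])
  r
}

#' Posterior summary of an energy-matrix fit
#'
#' @slot em posterior-mean (or MAP) anchored \linkS4class{EnergyMatrix}.
#' @slot ci_lower,ci_upper 4 x L matrices of 95\% credible bounds (anchor
#'   entries 0).
#' @slot rhat named per-parameter split-Rhat (\code{NA} for the MAP path).
#' @slot params data.frame of posterior summaries for mu, a, b, sigma.
#' @slot converged logical; all Rhat below the configured threshold.
#' @slot method "mcmc" or "map" (Laplace-approximate intervals).
#' @export
setClass("PosteriorEM",
  representation(em = "EnergyMatrix", ci_lower = "matrix",
                 ci_upper = "matrix", rhat = "numeric",
                 params = "data.frame", converged = "logical",
                 method = "character"))

setMethod("show", "PosteriorEM", function(object) {
  cat(sprintf("PosteriorEM (%s): %d positions, %s\n", object@method,
              ncol(object@em@mat),
              if (isTRUE(object@converged)) "converged"
              else "NOT converged"))
  if (length(object@rhat) && any(is.finite(object@rhat)))
    cat(sprintf("  max Rhat %.3f\n", max(object@rhat, na.rm = TRUE)))
  print(object@params)
})

#' @rdname PosteriorEM-class
#' @param x a \code{PosteriorEM}.
#' @export
setGeneric("posteriorMeanEM", function(x) standardGeneric("posteriorMeanEM"))

#' @rdname PosteriorEM-class
#' @export
setMethod("posteriorMeanEM", "PosteriorEM", function(x) x@em)

#' Infer a ddG energy matrix from quantified probe z-scores
#'
#' Fits the occupancy model to per-variant z-scores for one TALE protein.
#' The probe set must cover every single substitution of the canonical
#' site (every non-anchored energy parameter must appear in at least one
#' variant).  Two paths are provided: \code{method = "mcmc"} runs
#' \code{n_chains} independent affine-invariant stretch-move ensembles
#' initialized around the multi-start MAP solution, reports posterior
#' means, central 95\% credible intervals and split-Rhat per parameter;
#' \code{method = "map"} returns the MAP estimate with Laplace-
#' approximate intervals (clearly labelled) in a few seconds.
#'
#' @param protein a \linkS4class{TALEProtein}.
#' @param probes data.frame with columns \code{site_sequence} and
#'   \code{zscore} (one aggregated z-score per variant).
#' @param config a \code{\link{ddgFitConfig}}.
#' @param method "mcmc" (default) or "map".
#' @return A \linkS4class{PosteriorEM}.
#' @export
fitDdgPosterior <- function(protein, probes, config = ddgFitConfig(),
                            method = c("mcmc", "map")) {
  method <- match.arg(method)
  stopifnot(is(protein, "TALEProtein"))
  anchor_bases <- strsplit(canonicalTargetSite(protein), "")[[1L]]
  z <- probes$zscore
  if (!all(is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  X <- siteDesignMatrix(probes$site_sequence, anchor_bases)
  uncovered <- colnames(X)[colSums(X) == 0]
  if (length(uncovered)) {
    pos <- unique(sub(":.*", "", uncovered))
    stop("no variant coverage for position(s) ",
         paste(pos, collapse = ", "), call. = FALSE)
  }
  K <- ncol(X)
  L <- length(anchor_bases)
  map <- ddgMAP(X, z, config$floor, config$prior_mean, config$init_nonpref)
  H <- map$hessian
  Sig <- tryCatch(solve(H), error = function(e)
    solve(H + diag(1e-4, nrow(H))))
  sds <- sqrt(pmax(diag(Sig), 1e-8))

  buildMats <- function(est, lo, hi) {
    toMat <- function(v) {
      m <- matrix(0, 4L, L, dimnames = list(DNA_BASES,
                                            as.character(seq_len(L) - 1L)))
      m[cbind(match(sub(".*:", "", colnames(X)), DNA_BASES),
              as.integer(sub(":.*", "", colnames(X))) + 1L)] <- v
      m
    }
    list(em = EnergyMatrix(toMat(est), anchor_bases),
         lo = toMat(lo), hi = toMat(hi))
  }

  if (method == "map") {
    est <- map$par[seq_len(K)]
    half <- 1.96 * sds[seq_len(K)]
    mats <- buildMats(est, est - half, est + half)
    a <- map$par[K + 2L]; b <- a + exp(map$par[K + 3L])
    pdf <- data.frame(
      parameter = c("mu", "a", "b", "sigma"),
      estimate = c(map$par[K + 1L], a, b, exp(map$par[K + 4L])),
      se = c(sds[K + 1L], sds[K + 2L], NA, NA))
    return(new("PosteriorEM", em = mats$em, ci_lower = mats$lo,
               ci_upper = mats$hi, rhat = setNames(numeric(0), character(0)),
               params = pdf, converged = NA, method = "map"))
  }

  batch <- function(P) ddgLogPosteriorBatch(P, X, z, config$floor,
                                            config$prior_mean)
  d <- K + 4L
  nw <- if (is.null(config$n_walkers)) max(80L, 2L * d + 2L)
        else config$n_walkers
  chains <- lapply(seq_len(config$n_chains), function(c)
    runEnsemble(batch, map$par, sds, config$floor, K, nw,
                config$burn_in + config$samples, config$burn_in,
                config$thin, childSeed(config$seed, c)))
  rh <- checkConvergence(chains)
  names(rh) <- c(colnames(X), "mu", "a", "gap", "log_sigma")
  post <- do.call(rbind, chains)
  pmn <- colMeans(post)
  qs <- apply(post[, seq_len(K), drop = FALSE], 2L, stats::quantile,
              c(0.025, 0.975))
  mats <- buildMats(pmn[seq_len(K)], qs[1L, ], qs[2L, ])
  bdraw <- post[, K + 2L] + exp(post[, K + 3L])
  pdf <- data.frame(
    parameter = c("mu", "a", "b", "sigma"),
    estimate = c(pmn[K + 1L], pmn[K + 2L], mean(bdraw),
                 mean(exp(post[, K + 4L]))),
    se = c(stats::sd(post[, K + 1L]), stats::sd(post[, K + 2L]),
           stats::sd(bdraw), stats::sd(exp(post[, K + 4L]))))
  new("PosteriorEM", em = mats$em, ci_lower = mats$lo, ci_upper = mats$hi,
      rhat = rh, params = pdf,
      converged = all(rh < config$rhat_threshold, na.rm = TRUE),
      method = "mcmc")
}

#' Refit scaling parameters for a fixed energy matrix
#'
#' With the ddG values known, predicting probe intensities only requires
#' the chemical potential mu and the scaling terms a and b.  These are
#' fitted by Levenberg-Marquardt nonlinear least squares, initialized at
#' a = min(z), b = max(z), mu = -1.
#'
#' @param em anchored \linkS4class{EnergyMatrix}.
#' @param sites character vector of variant site sequences.
#' @param z observed z-scores, one per site.
#' @return A list with \code{params} (\linkS4class{BindingModelParams}),
#'   \code{r_squared} (squared Pearson correlation between predicted and
#'   observed z) and \code{predicted}.
#' @export
fitScaling <- function(em, sites, z) {
  stopifnot(length(sites) == length(z), all(is.finite(z)))
  E <- unname(vapply(sites, function(s) siteDdg(em, s), numeric(1L)))
  if (length(unique(round(E, 10))) < 4L)
    stop("need >= 4 probes with distinct site energies", call. = FALSE)
  resid <- function(p) z - (p[2L] + (p[3L] - p[2L]) /
                              (1 + exp(E - p[1L])))
  fit <- minpack.lm::nls.lm(
    par = c(mu = -1, a = min(z), b = max(z)), fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 500L))
  if (fit$info == 0L || fit$info == 9L)
    stop("scaling refit did not converge: ", fit$message, call. = FALSE)
  cf <- fit$par
  pred <- z - fit$fvec
  r2 <- if (stats::sd(pred) == 0 || stats::sd(z) == 0) 0
        else stats::cor(pred, z)^2
  list(params = BindingModelParams(cf[["mu"]], cf[["a"]], cf[["b"]]),
       r_squared = r2, predicted = pred)
}
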