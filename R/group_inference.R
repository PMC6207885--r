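#' Second-level design matrix for the three-group cohort
#'
#' Column 1 is the average effect (all ones); column 2 codes the presence of
#' encephalopathy of any cause (1 for both the NMDAR-antibody encephalitis
#' and other-encephalopathy groups, 0 for neurological controls); column 3
#' codes NMDAR-antibody encephalitis specifically (1 for that group only).
#' Encephalitis subjects are therefore nested inside the encephalopathy
#' indicator.
#'
#' @param groups Per-subject labels in `c("control", "encephalopathy",
#'   "nmdar")`.
#' @return Numeric matrix `n x 3` with columns `mean`, `encephalopathy`,
#'   `nmdar`.
#' @export
build_design <- function(groups) {
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("control", "encephalopathy", "nmdar"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  X <- cbind(mean = 1,
             encephalopathy = as.numeric(groups %in%
                                           c("encephalopathy", "nmdar")),
             nmdar = as.numeric(groups == "nmdar"))
  rownames(X) <- names(groups)
  X
}

#' Canonical variates analysis of parameter sets
#'
#' Finds the mixture of parameters (canonical vector) maximally correlated
#' with a mixture of explanatory variables, after removing confounds
#' (an intercept by default). Canonical correlations are tested with
#' Bartlett's chi-squared approximation; a permutation test of the first
#' canonical correlation is available as a cross-check.
#'
#' @param Y Subjects x parameters matrix.
#' @param X Explanatory variables (subjects x q), e.g. a group indicator.
#' @param subset Optional column indices (e.g. one set from
#'   [count_parameters()]) restricting `Y`.
#' @param confounds Confound matrix regressed out of both sides (default:
#'   intercept).
#' @param n_perm Permutations for the optional exact test (0 to skip).
#' @param seed RNG seed for permutations.
#' @return Object of class `cva_result`: canonical correlations, canonical
#'   `vectors` (parameter weights), `variates` (subject scores), Bartlett
#'   `chi2`, `df`, `p` (and `p_perm` if requested).
#' @export
cva <- function(Y, X, subset = NULL, confounds = NULL, n_perm = 0,
                seed = 1) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (!is.null(subset)) Y <- Y[, subset, drop = FALSE]
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X disagree on the number of subjects")
  if (is.null(confounds)) confounds <- matrix(1, n, 1)
  R <- diag(n) - confounds %*% solve(crossprod(confounds), t(confounds))
  Y0 <- R %*% Y
  X0 <- R %*% X
  sy <- svd(Y0)
  ky <- sum(sy$d > max(sy$d) * 1e-8)
  sx <- svd(X0)
  kx <- sum(sx$d > max(sx$d) * 1e-8)
  if (n <= kx + ky)
    stop("rank deficiency: need more subjects than rank(X) + rank(Y)")
  Uy <- sy$u[, seq_len(ky), drop = FALSE]
  Ux <- sx$u[, seq_len(kx), drop = FALSE]
  cc <- svd(crossprod(Ux, Uy))
  r <- pmin(pmax(cc$d, 0), 1)
  m <- length(r)
  # canonical vectors in original parameter space (unit-variance variates)
  Wy <- sy$v[, seq_len(ky), drop = FALSE] %*%
    diag(1 / sy$d[seq_len(ky)], ky) %*% cc$v
  variates <- Y0 %*% Wy
  dfc <- ncol(confounds)
  neff <- n - dfc
  chi2 <- -(neff - 1 - (ky + kx + 1) / 2) * sum(log(pmax(1 - r^2, 1e-12)))
  df <- ky * kx
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  out <- list(cor = r, vectors = Wy, variates = variates, chi2 = chi2,
              df = df, p = p, rank = c(x = kx, y = ky))
  if (n_perm > 0) {
    set.seed(seed)
    r1 <- replicate(n_perm, {
      Xp <- X0[sample(n), , drop = FALSE]
      sxp <- svd(Xp)
      kxp <- sum(sxp$d > max(sxp$d) * 1e-8)
      max(svd(crossprod(sxp$u[, seq_len(kxp), drop = FALSE], Uy))$d)
    })
    out$p_perm <- (1 + sum(r1 >= r[1])) / (n_perm + 1)
  }
  structure(out, class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat("cva_result: canonical correlations",
      paste(round(x$cor, 3), collapse = ", "),
      "| chi2 =", round(x$chi2, 2), "df =", x$df,
      "p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' Parametric empirical Bayes over subject posteriors
#'
#' Hierarchical Gaussian model: subject parameters are distributed around
#' group-level predictions `X beta` with diagonal between-subject covariance
#' (one variance hyperparameter per receptor class, optimized on the
#' second-level free energy). First-level uncertainty enters through each
#' subject's posterior covariance, so precisely estimated parameters carry
#' more weight. All group effects (`beta`) are estimated jointly with a
#' Gaussian prior and the exact marginal likelihood of this linear-Gaussian
#' model is used as the free energy.
#'
#' @param posteriors List of `cmc_posterior` (or lists with `mean`, `cov`).
#' @param design Design matrix from [build_design()].
#' @param parameters Labels of the parameters entering the hierarchy
#'   (default: the 41 neuronal parameters of the first posterior).
#' @param beta_prior_variance Prior variance of each group effect.
#' @param partition A `param_partition` used to tie between-subject
#'   variances by receptor class.
#' @param optimize_hyper Optimize the class-wise between-subject log
#'   variances (Nelder-Mead on the free energy)?
#' @return Object of class `peb_result` with `beta` (parameters x
#'   covariates), `beta_cov`, `F`, hyperparameters, and the ingredients for
#'   [bmr_search()].
#' @export
peb_fit <- function(posteriors, design,
                    parameters = NULL,
                    beta_prior_variance = 1 / 16,
                    partition = NULL,
                    optimize_hyper = TRUE) {
  X <- as.matrix(design)
  ns <- length(posteriors)
  if (nrow(X) != ns) stop("design rows must match the number of subjects")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  labs0 <- names(posteriors[[1]]$mean)
  if (is.null(parameters))
    parameters <- labs0[!grepl("^noise\\.", labs0)]
  for (po in posteriors)
    if (!all(parameters %in% names(po$mean)))
      stop("posteriors do not share the requested parameter labels")
  p <- length(parameters)
  q <- ncol(X)
  if (is.null(partition)) partition <- count_parameters(parameters)
  cls <- factor(partition$classes, levels = names(partition$sets))
  # prior-corrected first-level likelihood summaries: subtracting the
  # first-level prior precision leaves the information the data actually
  # carry, so directions the spectra do not inform (likelihood ridges)
  # receive ~zero weight instead of being treated as precise estimates
  Lprec <- vector("list", ns)   # likelihood precision, eigenvalue-floored
  Lcov <- vector("list", ns)    # its inverse
  Lmean <- matrix(0, p, ns)     # likelihood summary means
  for (i in seq_len(ns)) {
    po <- posteriors[[i]]
    idx <- match(parameters, names(po$mean))
    Sp <- po$cov[idx, idx, drop = FALSE]
    Pi <- chol2inv(chol((Sp + t(Sp)) / 2))
    if (!is.null(po$priors)) {
      pidx <- match(parameters, names(po$priors$mean))
      C0 <- po$priors$cov[pidx, pidx, drop = FALSE]
      m0 <- as.numeric(po$priors$mean[pidx])
      P0i <- chol2inv(chol((C0 + t(C0)) / 2))
    } else {
      P0i <- matrix(0, p, p)
      m0 <- numeric(p)
    }
    h <- Pi %*% as.numeric(po$mean[idx]) - P0i %*% m0
    Pt <- (Pi + t(Pi)) / 2 - (P0i + t(P0i)) / 2
    eg <- eigen(Pt, symmetric = TRUE)
    # cap the precision spectrum: directions the data determine to better
    # than sd 1e-3 stay "very precise"; directions they leave open are
    # treated as unknown within a unit log-range (variance 1), which also
    # bounds the de-shrunk summary means
    ev <- pmin(pmax(eg$values, 1), 1e6)
    Lprec[[i]] <- eg$vectors %*% (ev * t(eg$vectors))
    Lcov[[i]] <- eg$vectors %*% ((1 / ev) * t(eg$vectors))
    Lmean[, i] <- eg$vectors %*% ((1 / ev) * crossprod(eg$vectors,
                                                       as.numeric(h)))
  }
  vb <- rep(beta_prior_variance, p * q)
  evidence <- function(log_vc) {
    v <- exp(log_vc)[as.integer(cls)]
    # D_i = Lcov_i + Sigma_b handled in precision form
    Di <- vector("list", ns)
    ldD <- 0
    for (i in seq_len(ns)) {
      D <- Lcov[[i]] + diag(v, p)
      cD <- tryCatch(chol((D + t(D)) / 2), error = function(e) NULL)
      if (is.null(cD))
        cD <- chol((D + t(D)) / 2 + diag(1e-8 * max(diag(D)), p))
      Di[[i]] <- chol2inv(cD)
      ldD <- ldD + 2 * sum(log(diag(cD)))
    }
    A <- matrix(0, p * q, p * q)
    b <- numeric(p * q)
    quad0 <- 0
    for (i in seq_len(ns)) {
      A <- A + kronecker(tcrossprod(X[i, ]), Di[[i]])
      b <- b + as.numeric(kronecker(matrix(X[i, ], ncol = 1),
                                    Di[[i]]) %*% Lmean[, i])
      quad0 <- quad0 + sum(Lmean[, i] * (Di[[i]] %*% Lmean[, i]))
    }
    Pb <- diag(1 / vb, p * q) + A
    cP <- chol((Pb + t(Pb)) / 2)
    mb <- backsolve(cP, forwardsolve(t(cP), b))
    ldP <- 2 * sum(log(diag(cP)))
    quad <- quad0 - sum(b * mb)
    Fv <- -0.5 * (quad + ldD + sum(log(vb)) + ldP +
                    ns * p * log(2 * pi))
    list(F = Fv, mb = mb, Pb = Pb, A = A, b = b)
  }
  lv0 <- rep(log(1 / 64), nlevels(cls))
  clamp <- function(lv) pmin(pmax(lv, log(1e-3)), log(1))
  if (optimize_hyper) {
    opt <- stats::optim(lv0, function(lv) -evidence(clamp(lv))$F,
                        method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-6))
    lv <- clamp(opt$par)
  } else lv <- lv0
  ev <- evidence(lv)
  beta <- matrix(ev$mb, p, q,
                 dimnames = list(parameters, colnames(X)))
  beta_sd <- matrix(sqrt(diag(chol2inv(chol((ev$Pb + t(ev$Pb)) / 2)))),
                    p, q, dimnames = dimnames(beta))
  structure(list(beta = beta, beta_sd = beta_sd,
                 beta_mean_vec = ev$mb,
                 beta_post_prec = ev$Pb,
                 beta_prior_var = vb, F = ev$F,
                 hyper = setNames(exp(lv), levels(cls)),
                 parameters = parameters, design = X,
                 partition = partition, n_subjects = ns),
            class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat("peb_result:", length(x$parameters), "parameters x",
      ncol(x$design), "covariates | F =", signif(x$F, 6), "\n")
  invisible(x)
}

# Gaussian Bayesian model reduction: change in log evidence when the prior
# over beta is shrunk from Sigma0 (diagonal v0, zero mean) to vr.
# Works from the full posterior precision Pb and mean mb only.
bmr_delta_f <- function(Pb, mb, v0, vr) {
  b <- Pb %*% mb
  P0 <- diag(1 / v0, length(v0))
  Pr <- diag(1 / vr, length(vr))
  Pt <- Pb + Pr - P0
  cT <- tryCatch(chol((Pt + t(Pt)) / 2), error = function(e) NULL)
  if (is.null(cT)) return(list(dF = -Inf, mt = NULL))
  cB <- chol((Pb + t(Pb)) / 2)
  mt <- backsolve(cT, forwardsolve(t(cT), b))
  dF <- 0.5 * (sum(log(v0)) - sum(log(vr)) +
                 2 * sum(log(diag(cB))) - 2 * sum(log(diag(cT))) +
                 sum(b * mt) - sum(mb * b))
  list(dF = as.numeric(dF), mt = as.numeric(mt))
}

#' Bayesian model reduction search over group effects
#'
#' Scores reduced second-level models in which subsets of group effects are
#' switched off (their prior variance shrunk to near zero), using the
#' analytic reduced-model evidence computed from the full posterior without
#' refitting. A greedy backward search prunes effects while the evidence
#' improves, followed by an exhaustive sweep over the surviving effects
#' (when at most `max_exhaustive` remain). Per-effect posterior
#' probabilities come from Bayesian model averaging over all visited
#' models.
#'
#' @param peb A fitted `peb_result`.
#' @param covariates Indices of design columns whose effects are searched
#'   (default: all but the mean column).
#' @param max_exhaustive Exhaustive-sweep limit on surviving effects.
#' @param off_variance Prior variance representing a switched-off effect.
#' @return Object of class `bmr_result`: data frame `effects` with columns
#'   `parameter`, `covariate`, `Pp` (posterior probability of a nonzero
#'   effect) and `mean` (model-averaged effect size), plus the best reduced
#'   model's `dF`.
#' @export
bmr_search <- function(peb, covariates = NULL, max_exhaustive = 8,
                       off_variance = 1e-8) {
  p <- length(peb$parameters)
  q <- ncol(peb$design)
  if (is.null(covariates)) covariates <- setdiff(seq_len(q), 1L)
  v0 <- peb$beta_prior_var
  Pb <- peb$beta_post_prec
  mb <- peb$beta_mean_vec
  eff_idx <- as.integer(unlist(lapply(covariates, function(j)
    (j - 1L) * p + seq_len(p))))
  ne <- length(eff_idx)
  score <- function(off) {      # off: logical over the ne effects
    vr <- v0
    vr[eff_idx[off]] <- off_variance
    bmr_delta_f(Pb, mb, v0, vr)
  }
  visited_off <- list()
  visited_dF <- numeric(0)
  visited_mt <- list()
  visited_keys <- character(0)
  note <- function(off, sc) {
    key <- paste(which(off), collapse = ",")
    if (key %in% visited_keys) return(invisible())
    visited_keys[length(visited_keys) + 1L] <<- key
    visited_off[[length(visited_off) + 1L]] <<- off
    visited_dF[length(visited_dF) + 1L] <<- sc$dF
    visited_mt[[length(visited_mt) + 1L]] <<- sc$mt
  }
  off <- rep(FALSE, ne)
  cur <- score(off)
  note(off, cur)
  repeat {
    cand_on <- which(!off)
    if (!length(cand_on)) break
    dfs <- vapply(cand_on, function(j) {
      o <- off; o[j] <- TRUE
      sc <- score(o)
      note(o, sc)
      sc$dF
    }, 0)
    best <- which.max(dfs)
    if (dfs[best] <= cur$dF) break
    off[cand_on[best]] <- TRUE
    cur <- score(off)
  }
  surv <- which(!off)
  if (length(surv) > 0 && length(surv) <= max_exhaustive) {
    for (mask in seq_len(2^length(surv)) - 1L) {
      o <- off
      o[surv] <- bitwAnd(mask, 2^(seq_along(surv) - 1L)) > 0
      note(o, score(o))
    }
  }
  w <- exp(visited_dF - max(visited_dF))
  w <- w / sum(w)
  on_mat <- !vapply(visited_off, identity, logical(ne))
  Pp <- as.numeric(on_mat %*% w)
  mt_mat <- vapply(visited_mt, function(m)
    if (is.null(m)) rep(0, p * q) else m, numeric(p * q))
  bma <- as.numeric(mt_mat %*% w)
  effects <- data.frame(
    parameter = rep(peb$parameters, length(covariates)),
    covariate = rep(colnames(peb$design)[covariates], each = p),
    Pp = Pp,
    mean = bma[eff_idx],
    stringsAsFactors = FALSE)
  structure(list(effects = effects,
                 best_dF = max(visited_dF),
                 n_models = length(visited_dF)),
            class = "bmr_result")
}

#' @export
print.bmr_result <- function(x, ...) {
  sig <- x$effects[x$effects$Pp > 0.95, ]
  cat("bmr_result:", nrow(x$effects), "effects searched over",
      x$n_models, "models;", nrow(sig), "with Pp > 0.95\n")
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' Classify subjects along a canonical axis
#'
#' Projects subjects onto a canonical vector and thresholds at the midpoint
#' of the two class means (training-set convention). When an alpha-power
#' covariate is supplied it is regressed out of the scores first, removing
#' the occipital-alpha confound before thresholding.
#'
#' @param Y Subjects x parameters matrix.
#' @param canonical_vector Parameter weights (length = ncol(Y)).
#' @param labels Two-level factor of true class labels.
#' @param alpha_power Optional per-subject covariate to regress out.
#' @return List with `scores`, `threshold`, `predicted`, `accuracy` and the
#'   confusion `table`.
#' @export
classify <- function(Y, canonical_vector, labels, alpha_power = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) != length(canonical_vector))
    stop("canonical vector does not match the parameter dimension")
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("classification requires exactly two classes")
  if (any(table(labels) < 1L) || nrow(Y) < 2L)
    stop("need at least one subject per class and two in total")
  scores <- as.numeric(Y %*% canonical_vector)
  if (!is.null(alpha_power)) {
    if (length(alpha_power) != nrow(Y) || anyNA(alpha_power))
      stop("alpha_power must be complete, one value per subject")
    scores <- residuals(lm(scores ~ alpha_power))
  }
  m <- tapply(scores, labels, mean)
  thr <- mean(m)
  hi <- names(m)[which.max(m)]
  lo <- names(m)[which.min(m)]
  predicted <- factor(ifelse(scores > thr, hi, lo), levels = levels(labels))
  list(scores = scores, threshold = thr, predicted = predicted,
       accuracy = mean(predicted == labels),
       table = table(true = labels, predicted = predicted))
}
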