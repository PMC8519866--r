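#' @title REML engine for IBD-based mixed models
#'
#' @description All six mapping models are linear mixed models
#' `y = X beta + sum_r Z_r u_r + eps` whose marginal covariance is a
#' non-negative combination `V(theta) = sum_i theta_i C_i` of known
#' symmetric matrices: `M M'` for random parental QTL and cofactor effects
#' (M the N x P genetic-predictor matrix), a genomic kinship matrix `K` for
#' the polygenic term, and identity or family-block diagonals for the
#' residual. Variance components are estimated by residual maximum
#' likelihood using average-information (AI) updates with step halving and
#' an L-BFGS-B fallback on log variances; variances are kept non-negative
#' and snapped to exactly 0 at the boundary when the profile likelihood is
#' non-increasing there, which gives the likelihood-ratio statistic its
#' point mass at 0.
#'
#' @name reml-engine
NULL

# ---- component constructors -------------------------------------------------

vc_lowrank <- function(name, Z, residual = FALSE) {
  Z <- as.matrix(Z)
  list(name = name, type = "lowrank", Z = Z, ZZt = tcrossprod(Z),
       residual = residual)
}
vc_dense <- function(name, C, residual = FALSE)
  list(name = name, type = "dense", C = as.matrix(C), residual = residual)
vc_diag <- function(name, d, residual = TRUE)
  list(name = name, type = "diag", d = as.numeric(d), residual = residual)

comp_scale <- function(cmp, n) {
  switch(cmp$type,
         lowrank = sum(cmp$Z^2) / n,
         dense = mean(diag(cmp$C)),
         diag = mean(cmp$d))
}

# ---- likelihood evaluation --------------------------------------------------

# Returns NULL when V is not positive definite.
reml_eval <- function(theta, y, X, comps, want_derivs = TRUE) {
  n <- length(y)
  V <- matrix(0, n, n)
  dg <- numeric(n)
  for (i in seq_along(comps)) {
    cmp <- comps[[i]]
    if (theta[i] == 0) next
    if (cmp$type == "diag") dg <- dg + theta[i] * cmp$d
    else V <- V + theta[i] * if (cmp$type == "lowrank") cmp$ZZt else cmp$C
  }
  diag(V) <- diag(V) + dg
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(NULL)
  logdetX <- 2 * sum(log(diag(cx)))
  XtViX_inv <- chol2inv(cx)
  P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  r <- ncol(X)
  ll <- -0.5 * ((n - r) * log(2 * pi) + logdetV + logdetX + yPy)
  out <- list(ll = ll, Py = Py, P = P, XtViX_inv = XtViX_inv,
              beta = drop(XtViX_inv %*% crossprod(ViX, y)))
  if (want_derivs) out <- reml_derivs(out, comps)
  out
}

# add the REML score and average-information matrix to an evaluated core
reml_derivs <- function(ev, comps) {
  P <- ev$P; Py <- ev$Py
  n <- length(Py)
  p <- length(comps)
  score <- numeric(p)
  U <- matrix(0, n, p)
  dP <- diag(P)
  for (i in seq_len(p)) {
    cmp <- comps[[i]]
    if (cmp$type == "lowrank") {
      PZ <- P %*% cmp$Z
      trPC <- sum(PZ * cmp$Z)
      U[, i] <- cmp$Z %*% crossprod(cmp$Z, Py)
    } else if (cmp$type == "dense") {
      trPC <- sum(P * cmp$C)
      U[, i] <- cmp$C %*% Py
    } else {
      trPC <- sum(dP * cmp$d)
      U[, i] <- cmp$d * Py
    }
    score[i] <- -0.5 * (trPC - sum(Py * U[, i]))
  }
  PU <- P %*% U
  ev$score <- score
  ev$AI <- 0.5 * crossprod(U, PU)
  ev
}

# ---- optimizer --------------------------------------------------------------

reml_engine <- function(y, X, comps, init = NULL,
                        maxit = 60L, tol = 1e-8, starts = 2L,
                        verbose = FALSE) {
  n <- length(y)
  p <- length(comps)
  vy_data <- stats::var(y)                 # may be 0 for constant phenotypes
  vy <- if (is.finite(vy_data) && vy_data > 0) vy_data else max(mean(y^2), 1e-8)
  is_res <- vapply(comps, `[[`, logical(1), "residual")
  if (!any(is_res)) stop("model needs at least one residual component")
  scales <- vapply(comps, comp_scale, numeric(1), n = n)
  floors <- ifelse(is_res, max(1e-8 * vy_data, 1e-12), 0)

  start_list <- list()
  w0 <- ifelse(is_res, 0.5 / sum(is_res), 0.5 / max(1, sum(!is_res)))
  default0 <- pmax(w0 * vy / pmax(scales, 1e-12), floors)
  if (!is.null(init)) {
    init[!is.finite(init)] <- default0[!is.finite(init)]
    start_list[[length(start_list) + 1L]] <- pmax(init, floors)
  }
  start_list[[length(start_list) + 1L]] <- default0
  if (is.null(init) && starts > 1L) {
    w1 <- ifelse(is_res, 0.9 / sum(is_res), 0.1 / max(1, sum(!is_res)))
    start_list[[length(start_list) + 1L]] <- pmax(w1 * vy / pmax(scales, 1e-12), floors)
  }
  start_list <- start_list[seq_len(min(length(start_list), max(1L, starts)))]

  run_ai <- function(theta) {
    ev <- reml_eval(theta, y, X, comps)
    if (is.null(ev)) return(NULL)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      free <- !(theta <= floors & ev$score < 0)
      delta <- numeric(p)
      if (any(free)) {
        A <- ev$AI[free, free, drop = FALSE]
        A <- A + diag(1e-8 * (1 + mean(diag(A))), sum(free))
        delta[free] <- tryCatch(drop(solve(A, ev$score[free])),
                                error = function(e) rep(NA_real_, sum(free)))
        if (anyNA(delta)) delta[free] <- ev$score[free] / pmax(diag(ev$AI)[free], 1e-8)
      }
      step <- 1
      improved <- FALSE
      for (h in 1:30) {
        cand <- pmax(theta + step * delta, floors)
        probe <- reml_eval(cand, y, X, comps, want_derivs = FALSE)
        if (!is.null(probe) && probe$ll >= ev$ll - 1e-12) {
          improved <- probe$ll > ev$ll
          dll <- probe$ll - ev$ll
          theta <- cand
          if (dll < tol * (1 + abs(probe$ll))) converged <- TRUE
          ev <- if (converged) probe else reml_derivs(probe, comps)
          break
        }
        step <- step / 2
      }
      if (verbose) cat(sprintf("  iter %d ll %.6f\n", it, ev$ll))
      if (converged || !improved) { converged <- converged || !improved; break }
    }
    list(theta = theta, ev = ev, iter = it, converged = converged)
  }

  run_bfgs <- function(theta) {
    lb <- log(pmax(floors, 1e-12 * vy))
    fn <- function(lt) {
      ev <- reml_eval(exp(lt), y, X, comps, want_derivs = FALSE)
      if (is.null(ev)) return(1e10)
      -ev$ll
    }
    gr <- function(lt) {
      th <- exp(lt)
      ev <- reml_eval(th, y, X, comps)
      if (is.null(ev)) return(rep(0, p))
      -ev$score * th
    }
    o <- tryCatch(stats::optim(log(pmax(theta, 1e-10 * vy)), fn, gr,
                               method = "L-BFGS-B", lower = lb,
                               control = list(maxit = 200L)),
                  error = function(e) NULL)
    if (is.null(o)) return(NULL)
    th <- pmax(exp(o$par), floors)
    ev <- reml_eval(th, y, X, comps)
    if (is.null(ev)) return(NULL)
    list(theta = th, ev = ev, iter = o$counts[1L], converged = o$convergence == 0)
  }

  best <- NULL
  for (s in start_list) {
    res <- run_ai(s)
    if (is.null(res)) res <- run_bfgs(s)
    if (is.null(res)) next
    if (!res$converged) {
      res2 <- run_bfgs(res$theta)
      if (!is.null(res2) && res2$ev$ll >= res$ev$ll) res <- res2
    }
    if (is.null(best) || res$ev$ll > best$ev$ll) best <- res
  }
  if (is.null(best)) stop("REML failed: covariance matrix not positive definite")

  # snap boundary variances to exactly zero when the profile is non-increasing
  theta <- best$theta
  snap <- which(!is_res & theta <= pmax(1e-7 * vy / pmax(scales, 1e-12), 1e-12))
  for (i in snap) {
    th0 <- theta; th0[i] <- 0
    ev0 <- reml_eval(th0, y, X, comps, want_derivs = FALSE)
    if (!is.null(ev0) && ev0$ll >= best$ev$ll - 1e-9 * (1 + abs(best$ev$ll))) {
      theta <- th0
      best$ev <- reml_eval(theta, y, X, comps)
    }
  }
  best$theta <- theta
  names(best$theta) <- vapply(comps, `[[`, character(1), "name")
  best
}

# ---- user-facing fitting function ------------------------------------------

#' Fit an IBD-based mixed model by REML
#'
#' Fits one of the six mapping models. The fixed part contains family
#' intercepts (a global intercept when there is a single family, as in
#' MAGIC). Random parental QTL and cofactor effects contribute
#' `sigma^2 M M'` with `M` the genetic predictors at the locus; the
#' polygenic term contributes `sigma_g^2 K`; the residual is homogeneous
#' (`_U` models, IBS.Kin) or family-specific (`_F` models). For `IBS.Kin`
#' the tested locus enters the fixed part as an allele-dosage covariate.
#'
#' @param y numeric phenotype vector (BLUEs per individual).
#' @param model one of `"IBD.SQM_U"`, `"IBD.SQM_F"`, `"IBD.MQM_F"`,
#'   `"IBD.Kin_F"`, `"IBD.MQMkin_F"`, `"IBS.Kin"`.
#' @param family factor of family membership (`NULL` for a single family).
#' @param qtl N x P genetic-predictor matrix at the tested locus, or `NULL`
#'   to fit the corresponding null model without a QTL term.
#' @param cofactors named list of N x P predictor matrices for cofactor loci
#'   (only used by `MQM` models).
#' @param kinship N x N kinship matrix (required by `Kin` models; use the
#'   LOCO matrix of the scanned chromosome).
#' @param marker numeric dosage vector at the tested locus (required by
#'   `IBS.Kin` unless fitting its null model).
#' @param init optional named starting values for the variance components.
#' @param starts number of REML starting points (default 2; 1 for speed when
#'   `init` is a good warm start).
#' @param maxit,tol optimizer control.
#' @return Object of class `mpp_fit`: variance components `theta`, fixed
#'   effects `beta` with covariance `vcov_beta`, REML log-likelihood
#'   `loglik`, convergence information and the data needed for BLUPs and
#'   tests.
#' @export
fit_mpp_model <- function(y, model = c("IBD.SQM_U", "IBD.SQM_F", "IBD.MQM_F",
                                       "IBD.Kin_F", "IBD.MQMkin_F", "IBS.Kin"),
                          family = NULL, qtl = NULL, cofactors = list(),
                          kinship = NULL, marker = NULL,
                          init = NULL, starts = 2L, maxit = 60L, tol = 1e-8) {
  model <- match.arg(model)
  n <- length(y)
  if (is.null(family)) family <- factor(rep("pop", n))
  family <- droplevels(as.factor(family))
  if (length(family) != n) stop("family factor does not match phenotype length")
  X <- if (nlevels(family) > 1L)
    stats::model.matrix(~ 0 + family) else matrix(1, n, 1L)
  colnames(X) <- if (nlevels(family) > 1L) levels(family) else "(Intercept)"

  uses_cof <- model %in% c("IBD.MQM_F", "IBD.MQMkin_F")
  uses_kin <- model %in% c("IBD.Kin_F", "IBD.MQMkin_F", "IBS.Kin")
  fam_resid <- model %in% c("IBD.SQM_F", "IBD.MQM_F", "IBD.Kin_F", "IBD.MQMkin_F")

  comps <- list()
  if (model == "IBS.Kin") {
    if (!is.null(marker)) {
      xq <- as.numeric(marker)
      xq[is.na(xq)] <- mean(xq, na.rm = TRUE)
      if (stats::sd(xq) == 0)
        stop("monomorphic marker dosage in IBS.Kin fixed part")
      X <- cbind(X, qtl_dosage = xq)
    }
  } else if (!is.null(qtl)) {
    comps[[length(comps) + 1L]] <- vc_lowrank("qtl", qtl)
  }
  if (uses_cof && length(cofactors)) {
    nm <- names(cofactors)
    if (is.null(nm)) nm <- sprintf("cof%d", seq_along(cofactors))
    for (i in seq_along(cofactors))
      comps[[length(comps) + 1L]] <- vc_lowrank(paste0("cof:", nm[i]),
                                                cofactors[[i]])
  }
  if (uses_kin) {
    if (is.null(kinship)) stop(model, " requires a kinship matrix")
    comps[[length(comps) + 1L]] <- vc_dense("polygenic", kinship)
  }
  if (fam_resid && nlevels(family) > 1L) {
    for (lev in levels(family))
      comps[[length(comps) + 1L]] <- vc_diag(paste0("resid:", lev),
                                             as.numeric(family == lev))
  } else {
    comps[[length(comps) + 1L]] <- vc_diag("resid", rep(1, n))
  }

  init_vec <- NULL
  if (!is.null(init)) {
    nms <- vapply(comps, `[[`, character(1), "name")
    init_vec <- unname(init[nms])  # NAs are filled with defaults downstream
  }
  res <- reml_engine(y, X, comps, init = init_vec, maxit = maxit, tol = tol,
                     starts = starts)
  se <- sqrt(pmax(diag(res$ev$XtViX_inv), 0))
  fit <- list(model = model, theta = res$theta, beta = res$ev$beta,
              se_beta = se, vcov_beta = res$ev$XtViX_inv,
              loglik = res$ev$ll, converged = res$converged,
              iterations = res$iter, n = n, rank_X = ncol(X),
              y = y, X = X, family = family, comps = comps,
              Py = res$ev$Py)
  names(fit$beta) <- colnames(X)
  names(fit$se_beta) <- colnames(X)
  class(fit) <- "mpp_fit"
  fit
}

#' @export
print.mpp_fit <- function(x, ...) {
  cat(sprintf("%s mixed model (REML), n = %d, logLik = %.4f%s\n", x$model,
              x$n, x$loglik, if (x$converged) "" else " [not converged]"))
  cat("variance components:\n")
  print(round(x$theta, 6))
  invisible(x)
}

#' @export
summary.mpp_fit <- function(object, ...) {
  cat(sprintf("REML fit of model %s (n = %d, %d fixed effects)\n",
              object$model, object$n, object$rank_X))
  cat(sprintf("logLik (REML): %.4f  converged: %s  iterations: %d\n",
              object$loglik, object$converged, object$iterations))
  cat("\nVariance components:\n")
  print(data.frame(component = names(object$theta),
                   estimate = unname(object$theta)), row.names = FALSE)
  cat("\nFixed effects:\n")
  print(data.frame(term = names(object$beta), estimate = unname(object$beta),
                   se = unname(object$se_beta)), row.names = FALSE)
  invisible(object)
}

#' @export
coef.mpp_fit <- function(object, ...) object$beta

#' @export
logLik.mpp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta) + object$rank_X,
            nobs = object$n, class = "logLik")
}

#' @export
vcov.mpp_fit <- function(object, ...) object$vcov_beta

#' @export
fitted.mpp_fit <- function(object, ...) drop(object$X %*% object$beta)

#' @export
residuals.mpp_fit <- function(object, ...) object$y - fitted(object)

#' Best linear unbiased predictors of the random effects
#'
#' BLUPs of the random terms: for a QTL or cofactor term with predictor
#' matrix `M`, `u_hat = sigma^2 M' P y`; for the polygenic term,
#' `g_hat = sigma_g^2 K P y`. When a variance component is estimated as 0
#' the corresponding BLUPs are exactly 0.
#'
#' @param object an `mpp_fit`.
#' @param ... unused.
#' @return Named list of BLUP vectors per random term.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.mpp_fit <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$comps)) {
    cmp <- object$comps[[i]]
    if (cmp$residual) next
    th <- object$theta[[cmp$name]]
    out[[cmp$name]] <- switch(cmp$type,
      lowrank = {
        u <- th * drop(crossprod(cmp$Z, object$Py))
        names(u) <- colnames(cmp$Z)
        u
      },
      dense = th * drop(cmp$C %*% object$Py),
      diag = th * cmp$d * object$Py)
  }
  out
}

# ---- tests and criteria -----------------------------------------------------

#' Likelihood-ratio test for a QTL variance component
#'
#' `LRT = max(0, 2 * (logLik_alt - logLik_null))`; because the variance is
#' tested on the boundary of its parameter space, the null distribution is
#' the mixture `0.5 chi2_0 + 0.5 chi2_1`, so `p = 0.5 * Pr(chi2_1 >= LRT)`
#' for positive statistics and `p = 1` at `LRT = 0`.
#'
#' @param fit_null,fit_alt `mpp_fit` objects on the same data with the same
#'   fixed part; the null model omits the QTL variance component.
#' @return List of class `mpp_test`: `stat`, `p`, `mlog10p`, `type`.
#' @export
lrt_variance_component <- function(fit_null, fit_alt) {
  if (fit_null$n != fit_alt$n || !isTRUE(all.equal(fit_null$y, fit_alt$y)))
    stop("null and alternative fits use different data")
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(stat = stat, p = p, mlog10p = -log10(p), type = "LRT"),
            class = "mpp_test")
}

#' Wald test for a fixed marker effect (IBS.Kin)
#'
#' The generalized-least-squares estimate of the allele-dosage effect and
#' its variance come from `(X' V^-1 X)^-1` of the fitted model; the squared
#' ratio is referred to a chi-square with 1 df. With `V = I` this reduces to
#' the ordinary least-squares t-squared statistic.
#'
#' @param fit an `mpp_fit` of model `IBS.Kin` including the marker dosage
#'   in the fixed part (column `qtl_dosage`).
#' @return List of class `mpp_test`: `stat`, `p`, `mlog10p`, `estimate`,
#'   `se`, `type`.
#' @export
wald_test_fixed <- function(fit) {
  j <- match("qtl_dosage", names(fit$beta))
  if (is.na(j)) stop("fit has no marker-dosage fixed effect")
  est <- fit$beta[[j]]
  v <- fit$vcov_beta[j, j]
  stat <- est^2 / v
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(stat = stat, p = p, mlog10p = -log10(p), estimate = est,
                 se = sqrt(v), type = "Wald"), class = "mpp_test")
}

#' @export
print.mpp_test <- function(x, ...) {
  cat(sprintf("%s test: stat = %.4f, p = %.4g (-log10 p = %.3f)\n",
              x$type, x$stat, x$p, x$mlog10p))
  invisible(x)
}

#' Bayesian information criterion for a REML mixed model
#'
#' `BIC = (DF_fixed + DF_var) * ln(n - r + DF_fixed) - 2 * ln(L_max)`, with
#' `n` the number of observations, `r` the rank of the fixed-effects design,
#' `DF_fixed` and `DF_var` the numbers of fixed and variance parameters and
#' `L_max` the maximized residual likelihood. Smaller is better.
#'
#' @param loglik maximized REML log-likelihood (`ln L_max`).
#' @param df_fixed,df_var fixed and variance-parameter counts.
#' @param n number of observations.
#' @param r rank of the fixed-effects design matrix.
#' @return The BIC value.
#' @export
bic_mixed <- function(loglik, df_fixed, df_var, n, r) {
  stopifnot(df_fixed >= 1, df_var >= 0, n > r)
  if (n - r + df_fixed <= 0) stop("n - r + DF_fixed must be positive")
  (df_fixed + df_var) * log(n - r + df_fixed) - 2 * loglik
}

#' @rdname bic_mixed
#' @param object an `mpp_fit`.
#' @param ... unused.
#' @export
BIC.mpp_fit <- function(object, ...) {
  bic_mixed(object$loglik, df_fixed = object$rank_X,
            df_var = length(object$theta), n = object$n, r = object$rank_X)
}

#' Parental effects at the detected QTLs
#'
#' BLUPs of the founder (parental) effects for every QTL and cofactor term
#' in a jointly fitted model, typically the model selected by BIC with all
#' detected QTLs included.
#'
#' @param fit an `mpp_fit` containing one random term per QTL.
#' @return Matrix QTL x founder of BLUPs (rows named by term).
#' @export
estimate_parental_effects <- function(fit) {
  re <- ranef(fit)
  keep <- setdiff(names(re), "polygenic")
  if (!length(keep)) stop("fit has no QTL terms")
  out <- do.call(rbind, re[keep])
  rownames(out) <- sub("^cof:", "", keep)
  out
}
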