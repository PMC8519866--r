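#' Bonferroni threshold on the -log10(p) scale
#'
#' `T = -log10(alpha / n_markers)`. The reference simulation experiments use
#' a fixed override of 4.2 on the 462-marker map; pass `override` to
#' reproduce such a configured threshold.
#'
#' @param alpha genome-wide significance level in (0, 1).
#' @param n_markers number of tested markers.
#' @param override optional explicit threshold bypassing the formula.
#' @return Threshold on the -log10(p) scale.
#' @export
bonferroni_threshold <- function(alpha = 0.01, n_markers, override = NULL) {
  if (!is.null(override)) return(override)
  stopifnot(alpha > 0, alpha < 1, n_markers >= 1)
  -log10(alpha / n_markers)
}

# cofactors in force when testing `marker`: those farther than
# `exclusion_half` cM away on the same chromosome (other chromosomes always
# stay in force)
cofactors_in_force <- function(map, marker, cofactors, exclusion_half) {
  if (!length(cofactors)) return(character(0))
  i <- match(marker, map$marker)
  ic <- match(cofactors, map$marker)
  drop <- !is.na(ic) & map$chrom[ic] == map$chrom[i] &
    abs(map$pos[ic] - map$pos[i]) <= exclusion_half
  cofactors[!drop]
}

#' Genome-wide QTL scan under one mixed model
#'
#' For every retained marker the alternative model (QTL term at the marker
#' plus the background terms) is compared against the matching null model
#' (same terms minus the QTL). IBD-based models are tested by the
#' likelihood-ratio test of the QTL variance component against the
#' `0.5 chi2_0 + 0.5 chi2_1` mixture; `IBS.Kin` uses a Wald test of the
#' fixed dosage effect. Null models are refitted once per chromosome x
#' cofactor configuration, not per marker. When a tested marker lies within
#' the exclusion window of a cofactor, that cofactor is dropped from the
#' model for that test (`window_mode = "drop"`, the composite-interval
#' convention, which yields full profiles); `window_mode = "skip"` instead
#' skips such markers entirely.
#'
#' @param y phenotype vector.
#' @param model model name, see [fit_mpp_model()].
#' @param tensor IBD tensor from [ibd_decode()] (IBD models).
#' @param geno observed dosage matrix (required for `IBS.Kin`).
#' @param map an [mpp_map()]; defaults to the tensor's map.
#' @param family family factor.
#' @param kinships list of LOCO kinship matrices named by chromosome (or a
#'   single matrix used for all chromosomes).
#' @param cofactors character vector of cofactor marker ids.
#' @param exclusion_half half-width in cM of the exclusion window around a
#'   cofactor (default 10, i.e. a 20 cM window).
#' @param window_mode `"drop"` or `"skip"`.
#' @param ibs_exact refit variance components per marker for `IBS.Kin`
#'   (default); `FALSE` reuses the null components per chromosome (fast
#'   approximation).
#' @return Data frame of class `mpp_scan` with per-marker columns `marker`,
#'   `chrom`, `pos`, `model`, `stat`, `p`, `mlog10p`, `tested`,
#'   `cofactors_in_force`; attributes `model`, `cofactors`,
#'   `exclusion_half`.
#' @export
genome_scan <- function(y, model, tensor = NULL, geno = NULL, map = NULL,
                        family = NULL, kinships = NULL,
                        cofactors = character(0), exclusion_half = 10,
                        window_mode = c("drop", "skip"), ibs_exact = TRUE) {
  window_mode <- match.arg(window_mode)
  is_ibs <- model == "IBS.Kin"
  if (is_ibs) {
    if (is.null(geno)) stop("IBS.Kin scan requires the genotype matrix")
    if (is.null(map)) stop("IBS.Kin scan requires a map")
    n_ind <- nrow(geno)
  } else {
    if (is.null(tensor)) stop("IBD models require an IBD tensor")
    if (is.null(map)) map <- attr(tensor, "map")
    n_ind <- dim(tensor)[1L]
  }
  if (length(y) != n_ind)
    stop("phenotype length (", length(y), ") does not match individuals (",
         n_ind, ")")
  map <- as_mpp_map(map)
  retained <- if (is_ibs) intersect(map$marker, colnames(geno))
              else intersect(map$marker, dimnames(tensor)[[2L]])
  map <- map[map$marker %in% retained, , drop = FALSE]
  class(map) <- c("mpp_map", "data.frame")
  uses_kin <- model %in% c("IBD.Kin_F", "IBD.MQMkin_F", "IBS.Kin")
  uses_cof <- model %in% c("IBD.MQM_F", "IBD.MQMkin_F")
  if (!uses_cof) cofactors <- character(0)

  rows <- vector("list", nrow(map))
  null_cache <- new.env(parent = emptyenv())
  prev_alt_theta <- NULL
  for (cc in unique(map$chrom)) {
    K <- NULL
    if (uses_kin) {
      if (is.null(kinships)) stop(model, " requires kinship matrices")
      K <- if (is.list(kinships)) {
        if (!cc %in% names(kinships))
          stop("no LOCO kinship for chromosome ", cc)
        kinships[[cc]]
      } else kinships
    }
    idx <- marker_index(map, cc)
    prev_null_theta <- NULL
    for (i in idx) {
      mk <- map$marker[i]
      cof_now <- cofactors_in_force(map, mk, cofactors, exclusion_half)
      skipped_window <- window_mode == "skip" &&
        length(cof_now) < length(cofactors) && !(mk %in% cofactors)
      row <- data.frame(marker = mk, chrom = cc, pos = map$pos[i],
                        model = model, stat = NA_real_, p = NA_real_,
                        mlog10p = NA_real_, tested = FALSE,
                        cofactors_in_force = paste(cof_now, collapse = ";"),
                        stringsAsFactors = FALSE)
      if (skipped_window) { rows[[i]] <- row; next }
      key <- paste(if (uses_kin) cc else "", # null is chrom-free without LOCO
                   paste(sort(cof_now), collapse = ";"), sep = "|")
      nul <- if (!is.null(null_cache[[key]])) null_cache[[key]] else {
        cofM <- lapply(cof_now, function(m) genetic_predictors(tensor, m))
        names(cofM) <- cof_now
        nf <- fit_mpp_model(y, model, family = family,
                            qtl = NULL, cofactors = if (is_ibs) list() else cofM,
                            kinship = K, marker = NULL,
                            init = prev_null_theta, starts = 1L)
        null_cache[[key]] <- nf
        nf
      }
      prev_null_theta <- nul$theta
      if (is_ibs) {
        xq <- geno[, mk]
        xq <- as.numeric(xq)
        xq[is.na(xq)] <- mean(xq, na.rm = TRUE)
        if (!is.finite(stats::sd(xq)) || stats::sd(xq) == 0) {
          row$p <- 1; row$mlog10p <- 0  # monomorphic: sentinel, not tested
          rows[[i]] <- row; next
        }
        tst <- if (ibs_exact) {
          alt <- fit_mpp_model(y, model, family = family, kinship = K,
                               marker = xq, init = nul$theta, starts = 1L)
          wald_test_fixed(alt)
        } else ibs_wald_fast(nul, xq)
        row$stat <- tst$stat; row$p <- tst$p; row$mlog10p <- tst$mlog10p
        row$tested <- TRUE
      } else {
        Mq <- genetic_predictors(tensor, mk)
        cofM <- lapply(cof_now, function(m) genetic_predictors(tensor, m))
        names(cofM) <- cof_now
        init <- if (!is.null(prev_alt_theta)) prev_alt_theta else nul$theta
        alt <- fit_mpp_model(y, model, family = family, qtl = Mq,
                             cofactors = cofM, kinship = K,
                             init = init, starts = 1L)
        if (alt$loglik < nul$loglik - 1e-6) {
          # warm start trapped below the null: retry from scratch
          alt2 <- fit_mpp_model(y, model, family = family, qtl = Mq,
                                cofactors = cofM, kinship = K, starts = 2L)
          if (alt2$loglik > alt$loglik) alt <- alt2
        }
        prev_alt_theta <- alt$theta
        tst <- lrt_variance_component(nul, alt)
        row$stat <- tst$stat; row$p <- tst$p; row$mlog10p <- tst$mlog10p
        row$tested <- TRUE
      }
      rows[[i]] <- row
    }
  }
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  attr(profile, "model") <- model
  attr(profile, "cofactors") <- cofactors
  attr(profile, "exclusion_half") <- exclusion_half
  class(profile) <- c("mpp_scan", "data.frame")
  profile
}

# Wald test reusing the null model's variance components (fast IBS mode)
ibs_wald_fast <- function(nul, xq) {
  n <- nul$n
  V <- matrix(0, n, n)
  for (i in seq_along(nul$comps)) {
    cmp <- nul$comps[[i]]
    th <- nul$theta[[i]]
    if (th == 0) next
    V <- V + th * switch(cmp$type, lowrank = tcrossprod(cmp$Z),
                         dense = cmp$C, diag = diag(cmp$d, n))
  }
  Xa <- cbind(nul$X, qtl_dosage = xq)
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(Xa, Vi %*% Xa)
  bcov <- chol2inv(chol(XtViX))
  beta <- drop(bcov %*% crossprod(Xa, Vi %*% nul$y))
  j <- ncol(Xa)
  stat <- beta[j]^2 / bcov[j, j]
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  structure(list(stat = stat, p = p, mlog10p = -log10(p),
                 estimate = beta[j], se = sqrt(bcov[j, j]), type = "Wald"),
            class = "mpp_test")
}

#' @export
print.mpp_scan <- function(x, ...) {
  cat(sprintf("Genome scan (%s): %d markers, %d tested, max -log10(p) = %.3f\n",
              attr(x, "model"), nrow(x), sum(x$tested),
              suppressWarnings(max(x$mlog10p, na.rm = TRUE))))
  if (length(attr(x, "cofactors")))
    cat("cofactors:", paste(attr(x, "cofactors"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mpp_scan <- function(x, threshold = NULL, ...) {
  chrs <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chrs, function(cc) max(x$pos[x$chrom == cc]) + 10,
                             numeric(1))))
  names(offs) <- c(chrs, "end")
  gx <- x$pos + offs[x$chrom]
  graphics::plot(gx, x$mlog10p, type = "p", pch = 16, cex = 0.5,
                 col = (match(x$chrom, chrs) %% 2) + 1,
                 xlab = "genome position (cM, chromosomes concatenated)",
                 ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(NULL)
}

#' Greedy selection of cofactor markers from a profile
#'
#' Repeatedly picks the highest -log10(p) marker above the threshold and
#' masks all markers within the exclusion window (20 cM) on the same
#' chromosome, until no super-threshold markers remain. The mask radius is
#' the full window distance: single-QTL likelihood profiles have shoulders
#' wider than the +/-10 cM in-model exclusion half-width, and masking only
#' the half-width would select shoulder markers of an already selected
#' peak as spurious extra cofactors (and make the rescan iteration
#' oscillate).
#'
#' @param profile an [genome_scan()] profile.
#' @param threshold -log10(p) threshold.
#' @param window exclusion-window mask radius in cM (default 20).
#' @return Character vector of cofactor marker ids (possibly empty).
#' @export
select_cofactors <- function(profile, threshold, window = 20) {
  ok <- profile$tested & !is.na(profile$mlog10p) &
    profile$mlog10p > threshold
  cand <- profile[ok, , drop = FALSE]
  sel <- character(0)
  while (nrow(cand)) {
    top <- which.max(cand$mlog10p)
    sel <- c(sel, cand$marker[top])
    keep <- !(cand$chrom == cand$chrom[top] &
                abs(cand$pos - cand$pos[top]) <= window)
    cand <- cand[keep, , drop = FALSE]
  }
  sel
}

#' Iterative multi-QTL genome scan
#'
#' For cofactor models the scan alternates between a genome scan and greedy
#' cofactor selection, rescanning with the selected cofactors in the model,
#' until the cofactor set is unchanged between successive rounds (the
#' profile has stabilized) or `max_rounds` is reached. Models without
#' cofactor support run a single scan. The final QTL calls are the
#' super-threshold peaks of the stabilized profile after greedy window
#' merging.
#'
#' @inheritParams genome_scan
#' @param threshold -log10(p) significance threshold (e.g. 4.2 or
#'   [bonferroni_threshold()]).
#' @param select_window mask radius in cM used by [select_cofactors()] and
#'   for merging the final peaks (default 20).
#' @param max_rounds maximum scan rounds (default 10).
#' @return List of class `qtl_report`: final `profile`, `qtls` (data frame
#'   of called QTLs), `cofactor_history`, `threshold`, `stabilized`,
#'   `rounds`.
#' @export
mqm_iterate <- function(y, model, tensor = NULL, geno = NULL, map = NULL,
                        family = NULL, kinships = NULL, threshold,
                        exclusion_half = 10, select_window = 20,
                        max_rounds = 10L, window_mode = "drop",
                        ibs_exact = TRUE) {
  uses_cof <- model %in% c("IBD.MQM_F", "IBD.MQMkin_F")
  cof <- character(0)
  history <- list()
  stabilized <- FALSE
  round <- 0L
  repeat {
    round <- round + 1L
    profile <- genome_scan(y, model, tensor = tensor, geno = geno, map = map,
                           family = family, kinships = kinships,
                           cofactors = cof, exclusion_half = exclusion_half,
                           window_mode = window_mode, ibs_exact = ibs_exact)
    new_cof <- if (uses_cof)
      select_cofactors(profile, threshold, select_window) else character(0)
    history[[round]] <- new_cof
    if (!uses_cof || setequal(new_cof, cof)) {
      stabilized <- TRUE
      break
    }
    # oscillation guard: a selection seen in an earlier round would replay
    # the cycle; stop on the current profile (its selection is the
    # recurring set) and flag the profile as not stabilized
    cycled <- round > 1L && any(vapply(history[seq_len(round - 1L)],
                                       setequal, logical(1), new_cof))
    if (cycled || round >= max_rounds) break
    cof <- new_cof
  }
  peaks <- select_cofactors(profile, threshold, select_window)
  qtls <- profile[match(peaks, profile$marker), c("marker", "chrom", "pos",
                                                  "mlog10p"), drop = FALSE]
  qtls <- qtls[order(match(qtls$chrom, unique(profile$chrom)), qtls$pos), ,
               drop = FALSE]
  rownames(qtls) <- NULL
  out <- list(profile = profile, qtls = qtls, cofactor_history = history,
              threshold = threshold, stabilized = stabilized, rounds = round,
              model = model)
  class(out) <- "qtl_report"
  out
}

#' @export
print.qtl_report <- function(x, ...) {
  cat(sprintf("QTL report (%s): %d QTL(s) above -log10(p) = %.3g after %d round(s)%s\n",
              x$model, nrow(x$qtls), x$threshold, x$rounds,
              if (x$stabilized) "" else " [profile not stabilized]"))
  if (nrow(x$qtls)) print(x$qtls, row.names = FALSE)
  invisible(x)
}

#' Score detection of the simulated major QTLs
#'
#' A major QTL counts as detected when the peak marker on its chromosome
#' exceeds the threshold and lies within the success window (20 cM) of the
#' true position; the peak distance is recorded for the resolution summary
#' whenever the chromosome has any tested marker.
#'
#' @param profile a final [genome_scan()] profile.
#' @param truth data frame with columns `qtl`, `marker`, `chrom`, `pos` for
#'   the true major QTLs (e.g. `architecture$major`).
#' @param threshold -log10(p) threshold.
#' @param window success window in cM (default 20).
#' @return Data frame per major QTL: `qtl`, `chrom`, `true_pos`,
#'   `peak_marker`, `peak_pos`, `peak_mlog10p`, `distance`, `success`.
#' @export
call_qtls_and_success <- function(profile, truth, threshold, window = 20) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    cc <- as.character(truth$chrom[i])
    sub <- profile[profile$chrom == cc & profile$tested &
                     !is.na(profile$mlog10p), , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(qtl = truth$qtl[i], chrom = cc,
                        true_pos = truth$pos[i], peak_marker = NA_character_,
                        peak_pos = NA_real_, peak_mlog10p = NA_real_,
                        distance = NA_real_, success = FALSE,
                        stringsAsFactors = FALSE))
    top <- which.max(sub$mlog10p)
    dist <- abs(sub$pos[top] - truth$pos[i])
    data.frame(qtl = truth$qtl[i], chrom = cc, true_pos = truth$pos[i],
               peak_marker = sub$marker[top], peak_pos = sub$pos[top],
               peak_mlog10p = sub$mlog10p[top], distance = dist,
               success = sub$mlog10p[top] > threshold && dist <= window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the best model by BIC
#'
#' Each candidate model is refitted jointly with its own final QTL set (all
#' QTLs as random parental-effect terms, plus the model's background
#' terms); the model with the smallest BIC wins, with ties broken toward
#' fewer variance parameters.
#'
#' @param y phenotype vector.
#' @param qtl_sets named list: model name -> character vector of its called
#'   QTL markers.
#' @param tensor IBD tensor.
#' @param geno dosage matrix (for `IBS.Kin` candidates).
#' @param family family factor.
#' @param kinship full-genome kinship matrix used for the joint fits.
#' @return List of class `bic_selection` with `table` (model, df_var,
#'   loglik, bic) and `best`.
#' @export
select_model_by_bic <- function(y, qtl_sets, tensor = NULL, geno = NULL,
                                family = NULL, kinship = NULL) {
  models <- names(qtl_sets)
  fits <- vector("list", length(models))
  tab <- data.frame(model = models, n_qtl = NA_integer_, df_var = NA_integer_,
                    loglik = NA_real_, bic = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(models)) {
    mdl <- models[i]
    qs <- qtl_sets[[i]]
    fit <- if (mdl == "IBS.Kin") {
      xs <- if (length(qs)) {
        xm <- geno[, qs, drop = FALSE]
        storage.mode(xm) <- "double"
        for (j in seq_len(ncol(xm)))
          xm[is.na(xm[, j]), j] <- mean(xm[, j], na.rm = TRUE)
        xm
      } else NULL
      fit_ibs_joint(y, family, xs, kinship)
    } else {
      cofM <- lapply(qs, function(m) genetic_predictors(tensor, m))
      names(cofM) <- qs
      # joint fit keeps the candidate's residual/kinship structure
      mdl_joint <- switch(mdl,
        IBD.SQM_U = "IBD.SQM_U", IBD.SQM_F = "IBD.MQM_F",
        IBD.MQM_F = "IBD.MQM_F", IBD.Kin_F = "IBD.MQMkin_F",
        IBD.MQMkin_F = "IBD.MQMkin_F")
      if (mdl == "IBD.SQM_U" && length(cofM)) {
        # uniform-residual single-QTL model: fit QTLs as joint random terms
        fit_sqmu_joint(y, family, cofM)
      } else {
        fit_mpp_model(y, mdl_joint, family = family, qtl = NULL,
                      cofactors = cofM, kinship = kinship)
      }
    }
    fits[[i]] <- fit
    tab$n_qtl[i] <- length(qs)
    tab$df_var[i] <- length(fit$theta)
    tab$loglik[i] <- fit$loglik
    tab$bic[i] <- BIC.mpp_fit(fit)
  }
  ord <- order(tab$bic, tab$df_var)
  best <- tab$model[ord[1L]]
  out <- list(table = tab, best = best, fits = stats::setNames(fits, models))
  class(out) <- "bic_selection"
  out
}

# joint fit with uniform residual and QTL random terms (IBD.SQM_U candidate)
fit_sqmu_joint <- function(y, family, cofM) {
  n <- length(y)
  if (is.null(family)) family <- factor(rep("pop", n))
  family <- droplevels(as.factor(family))
  X <- if (nlevels(family) > 1L) stats::model.matrix(~ 0 + family)
       else matrix(1, n, 1L)
  comps <- c(lapply(seq_along(cofM), function(i)
    vc_lowrank(paste0("cof:", names(cofM)[i]), cofM[[i]])),
    list(vc_diag("resid", rep(1, n))))
  res <- reml_engine(y, X, comps)
  fit <- list(model = "IBD.SQM_U", theta = res$theta, beta = res$ev$beta,
              se_beta = sqrt(pmax(diag(res$ev$XtViX_inv), 0)),
              vcov_beta = res$ev$XtViX_inv, loglik = res$ev$ll,
              converged = res$converged, iterations = res$iter, n = n,
              rank_X = ncol(X), y = y, X = X, family = family,
              comps = comps, Py = res$ev$Py)
  class(fit) <- "mpp_fit"
  fit
}

# joint IBS.Kin fit: QTL dosages as fixed covariates + polygenic + residual
fit_ibs_joint <- function(y, family, dosages, kinship) {
  n <- length(y)
  if (is.null(family)) family <- factor(rep("pop", n))
  family <- droplevels(as.factor(family))
  X <- if (nlevels(family) > 1L) stats::model.matrix(~ 0 + family)
       else matrix(1, n, 1L)
  if (!is.null(dosages)) X <- cbind(X, dosages)
  comps <- list(vc_dense("polygenic", kinship),
                vc_diag("resid", rep(1, n)))
  res <- reml_engine(y, X, comps)
  fit <- list(model = "IBS.Kin", theta = res$theta, beta = res$ev$beta,
              se_beta = sqrt(pmax(diag(res$ev$XtViX_inv), 0)),
              vcov_beta = res$ev$XtViX_inv, loglik = res$ev$ll,
              converged = res$converged, iterations = res$iter, n = n,
              rank_X = ncol(X), y = y, X = X, family = family,
              comps = comps, Py = res$ev$Py)
  class(fit) <- "mpp_fit"
  fit
}

#' @export
print.bic_selection <- function(x, ...) {
  cat("BIC model selection (smallest BIC wins):\n")
  print(x$table, row.names = FALSE)
  cat("selected:", x$best, "\n")
  invisible(x)
}
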