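#' Replication study of mapping power, resolution and false positives
#'
#' For each replicate a fresh dataset is simulated (new founder genomes,
#' offspring, missingness and phenotypes), IBD probabilities are decoded,
#' LOCO kinship matrices are computed, and every requested model is run
#' through the iterative genome scan. Per replicate and model the three
#' major QTLs are scored for detection success and peak distance, and
#' super-threshold markers on the null chromosome are counted as false
#' positives. Results are deterministic given `seed` (replicate r uses seed
#' `seed + r`).
#'
#' @param design `"diallel"`, `"nam"` or `"magic"`.
#' @param models character vector of model names (see [fit_mpp_model()]).
#' @param n_replicates number of replicates.
#' @param threshold -log10(p) threshold (default 4.2, the configured
#'   Bonferroni threshold of the reference experiment).
#' @param seed base integer seed.
#' @param rho junction density; calibrated once for the design when `NULL`.
#' @param error HMM genotyping error rate.
#' @param sim_args extra arguments passed to [simulate_mpp()] (e.g. a
#'   smaller map for quick experiments).
#' @return List of class `mpp_replication`: `detections` (replicate x model
#'   x QTL rows), `false_positives` (per replicate x model), `design`,
#'   `threshold`, `n_replicates`, `seeds`, `errors` (per-replicate failure
#'   messages, if any).
#' @export
run_replication_study <- function(design, models = c("IBD.SQM_U", "IBD.MQMkin_F"),
                                  n_replicates = 100L, threshold = 4.2,
                                  seed = 1L, rho = NULL, error = 0.005,
                                  sim_args = list()) {
  stopifnot(n_replicates >= 1L)
  det <- list(); fp <- list(); errs <- list()
  seeds <- seed + seq_len(n_replicates)
  if (is.null(rho)) {
    set.seed(seed)
    npf <- if (!is.null(sim_args$n_per_family)) sim_args$n_per_family
           else switch(design, diallel = 50L, nam = 100L, magic = 300L)
    fg <- if (!is.null(sim_args$final_generation)) sim_args$final_generation
          else 6L
    fid <- if (!is.null(sim_args$founder_ids)) sim_args$founder_ids
           else paste0("P", 1:4)
    map0 <- if (!is.null(sim_args$map)) as_mpp_map(sim_args$map) else mpp_sim_map()
    plan0 <- make_crossing_plan(design, fid, npf, fg)
    rho <- calibrate_junction_density(plan0, map0)
  }
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      sim <- do.call(simulate_mpp, c(list(design = design, seed = seeds[r]),
                                     sim_args))
      tensor <- ibd_decode(sim$geno, sim$founders, sim$map, sim$plan,
                           rho = rho, error = error)
      kin <- loco_kinship(sim$geno, sim$map)
      null_chrom <- sim$architecture$null_chrom
      per_model <- lapply(models, function(mdl) {
        rep_ <- mqm_iterate(sim$y, mdl, tensor = tensor, geno = sim$geno,
                            map = sim$map, family = sim$family,
                            kinships = kin, threshold = threshold)
        succ <- call_qtls_and_success(rep_$profile, sim$architecture$major,
                                      threshold)
        succ$model <- mdl
        succ$replicate <- r
        fpc <- false_positive_count(rep_$profile, null_chrom, threshold)
        list(succ = succ, fp = data.frame(replicate = r, model = mdl,
                                          count = fpc))
      })
      list(det = do.call(rbind, lapply(per_model, `[[`, "succ")),
           fp = do.call(rbind, lapply(per_model, `[[`, "fp")))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(replicate = r,
                                              message = conditionMessage(res))
    } else {
      det[[length(det) + 1L]] <- res$det
      fp[[length(fp) + 1L]] <- res$fp
    }
  }
  out <- list(detections = do.call(rbind, det),
              false_positives = do.call(rbind, fp),
              design = design, threshold = threshold,
              n_replicates = n_replicates, seeds = seeds, rho = rho,
              errors = if (length(errs)) do.call(rbind, errs) else NULL)
  class(out) <- "mpp_replication"
  out
}

#' Count false-positive markers on the null chromosome
#'
#' Markers on a chromosome carrying no simulated QTLs whose final profile
#' value exceeds the threshold.
#'
#' @param profile a [genome_scan()] profile.
#' @param null_chrom chromosome id(s) without simulated QTLs.
#' @param threshold -log10(p) threshold.
#' @return Integer count.
#' @export
false_positive_count <- function(profile, null_chrom, threshold) {
  sub <- profile[profile$chrom %in% as.character(null_chrom) & profile$tested &
                   !is.na(profile$mlog10p), , drop = FALSE]
  sum(sub$mlog10p > threshold)
}

#' Summarize a replication study
#'
#' Power is the fraction of replicates in which a major QTL was detected;
#' resolution is the mean distance in cM between the true position and the
#' same-chromosome peak. The headline resolution averages successful
#' replicates only; `resolution_all` averages every replicate with a
#' defined peak. The analytically expected false-positive count is
#' `m_null * R * 10^-T`.
#'
#' @param results an [run_replication_study()] object.
#' @param n_null_markers number of markers on the null chromosome (110 on
#'   the default fixture map).
#' @return List of class `mpp_performance` with `power` (model x QTL data
#'   frame with power, resolution, resolution_all), `false_positives`
#'   (totals per model), `expected_false_positives`.
#' @export
summarize_performance <- function(results, n_null_markers = 110L) {
  det <- results$detections
  if (is.null(det) || !nrow(det)) stop("empty replication results")
  key <- interaction(det$model, det$qtl, drop = TRUE)
  rows <- lapply(split(det, key), function(d) {
    data.frame(model = d$model[1L], qtl = d$qtl[1L],
               n = nrow(d),
               power = mean(d$success),
               resolution = if (any(d$success))
                 mean(d$distance[d$success]) else NA_real_,
               resolution_all = mean(d$distance, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  power <- do.call(rbind, rows)
  power <- power[order(power$model, power$qtl), , drop = FALSE]
  rownames(power) <- NULL
  fp <- results$false_positives
  fp_tot <- if (!is.null(fp) && nrow(fp))
    stats::aggregate(count ~ model, data = fp, FUN = sum) else NULL
  R <- length(unique(det$replicate))
  out <- list(power = power, false_positives = fp_tot,
              expected_false_positives =
                expected_false_positives(n_null_markers, R, results$threshold),
              n_replicates = R, threshold = results$threshold,
              design = results$design)
  class(out) <- "mpp_performance"
  out
}

#' Analytically expected false-positive count
#'
#' Under per-marker tests at -log10(p) threshold T, the expected number of
#' super-threshold null-chromosome markers over R replicates is
#' `m_null * R * 10^-T` (110 x 500 x 10^-4.2 = 3.47 in the reference
#' configuration).
#'
#' @param n_null_markers markers on the null chromosome.
#' @param n_runs number of replicates.
#' @param threshold -log10(p) threshold.
#' @return Expected count.
#' @export
expected_false_positives <- function(n_null_markers, n_runs, threshold) {
  n_null_markers * n_runs * 10^(-threshold)
}

#' @export
print.mpp_performance <- function(x, ...) {
  cat(sprintf("Performance over %d replicates (%s design, T = %.3g):\n",
              x$n_replicates, x$design, x$threshold))
  print(x$power, row.names = FALSE)
  if (!is.null(x$false_positives)) {
    cat("null-chromosome false positives (total):\n")
    print(x$false_positives, row.names = FALSE)
  }
  cat(sprintf("expected false positives: %.3f\n", x$expected_false_positives))
  invisible(x)
}

#' @export
plot.mpp_performance <- function(x, what = c("power", "resolution"), ...) {
  what <- match.arg(what)
  tab <- x$power
  val <- if (what == "power") tab$power else tab$resolution
  m <- tapply(val, list(tab$model, tab$qtl), mean)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = if (what == "power") "mapping power"
                           else "mean peak distance (cM)",
                    main = sprintf("%s design", x$design), ...)
  invisible(NULL)
}
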