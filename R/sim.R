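#' Simulate a complete multiparental population dataset
#'
#' One-stop wrapper around the simulator: builds the crossing plan, draws
#' founder genomes, advances the population to the final generation by
#' single-seed descent, realizes genotypes with missing data, assigns the
#' QTL architecture and simulates the phenotype. Defaults reproduce the
#' reference simulation setting: 4 founders, the 462-marker five-chromosome
#' fixture map, N = 300 F6 offspring (diallel 6 x 50, NAM 3 x 100, MAGIC
#' 1 x 300), 5% missing genotypes, three major QTLs of effect 0.4, 24 minor
#' QTLs of effect 0.1 and N(0, 1) residuals.
#'
#' @param design `"diallel"`, `"nam"` or `"magic"`.
#' @param n_per_family offspring per family; default gives N = 300.
#' @param final_generation filial generation (default 6).
#' @param missing_rate missing-genotype rate (default 0.05).
#' @param a,b major and minor QTL effects.
#' @param residual_sd residual standard deviation.
#' @param map genetic map (default [mpp_sim_map()]).
#' @param majors,chr4_grid major-QTL positions and chromosome-4 minor grid
#'   passed to [qtl_architecture()] (defaults fit the fixture map; override
#'   for custom maps).
#' @param founder_ids founder names.
#' @param seed optional integer seed; when given, `set.seed(seed)` is called
#'   first so the dataset is reproducible.
#' @return List of class `mpp_sim` with components `plan`, `map`,
#'   `founders`, `architecture`, `mosaics`, `geno` (observed, with `NA`),
#'   `geno_true`, `trait`, `y`, `family` (factor) and `seed`.
#' @export
simulate_mpp <- function(design = c("diallel", "nam", "magic"),
                         n_per_family = NULL,
                         final_generation = 6L,
                         missing_rate = 0.05,
                         a = 0.4, b = 0.1, residual_sd = 1,
                         map = mpp_sim_map(),
                         majors = data.frame(chrom = as.character(1:3),
                                             pos = 44),
                         chr4_grid = seq(15, 65, by = 10),
                         founder_ids = paste0("P", 1:4),
                         seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_per_family))
    n_per_family <- switch(design, diallel = 50L, nam = 100L, magic = 300L)
  map <- as_mpp_map(map)
  plan <- make_crossing_plan(design, founder_ids, n_per_family,
                             final_generation)
  major_mk <- vapply(seq_len(nrow(majors)), function(i)
    marker_at(map, majors$chrom[i], majors$pos[i]), character(1))
  carriers <- default_major_carriers(founder_ids)
  names(carriers) <- major_mk  # carrier patterns follow the chosen majors
  founders <- sim_founders(map, founder_ids, major_carriers = carriers)
  architecture <- qtl_architecture(map, founders, majors = majors,
                                   chr4_grid = chr4_grid, a = a, b = b)
  mosaics <- advance_population(plan, map)
  geno <- realize_genotypes(mosaics, founders, map, missing_rate)
  geno_true <- attr(geno, "true")
  attr(geno, "true") <- NULL
  trait <- simulate_phenotype(mosaics, founders, map, architecture,
                              residual_sd)
  out <- list(plan = plan, map = map, founders = founders,
              architecture = architecture, mosaics = mosaics,
              geno = geno, geno_true = geno_true, trait = trait,
              y = trait$y, family = plan_family_factor(plan), seed = seed)
  class(out) <- "mpp_sim"
  out
}

#' @export
print.mpp_sim <- function(x, ...) {
  cat(sprintf("Simulated %s MPP: N = %d (F%d), %d markers, %.1f%% missing\n",
              toupper(x$plan$design), x$plan$N, x$plan$final_generation,
              nrow(x$map), 100 * mean(is.na(x$geno))))
  cat(sprintf("phenotype: mean %.3f, var %.3f; %d major + %d minor QTLs\n",
              mean(x$y), stats::var(x$y), nrow(x$architecture$major),
              nrow(x$architecture$minor)))
  invisible(x)
}
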