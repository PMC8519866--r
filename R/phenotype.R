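#' Simulate phenotypes from the QTL architecture
#'
#' The phenotype of each offspring is the sum of additive contributions of
#' all simulated QTLs plus independent Gaussian noise:
#' `Y = sum(a * z_major) + sum(b * z_minor) + eps`, where the genotype
#' indicator `z` is +1 for the homozygous genotype carrying allele 1 at the
#' QTL marker, -1 for the homozygote carrying allele 2, and 0 for the rare
#' residual heterozygotes at F6; `eps ~ N(0, residual_sd^2)`. Genotypes at
#' QTL markers are read from the true founder mosaics, not from the observed
#' (partially missing) genotype table. Uses R's global random number
#' generator.
#'
#' @param mosaics offspring genomes from [advance_population()].
#' @param founders founder allele matrix.
#' @param map an [mpp_map()].
#' @param architecture a [qtl_architecture()].
#' @param residual_sd residual standard deviation (default 1).
#' @return List of class `simulated_trait` with `y` (named phenotype
#'   vector), `z` (offspring x QTL indicator matrix), `residual_sd`, and the
#'   genetic values `genetic`.
#' @export
simulate_phenotype <- function(mosaics, founders, map, architecture,
                               residual_sd = 1) {
  map <- as_mpp_map(map)
  qtl <- rbind(architecture$major, architecture$minor)
  if (!all(qtl$marker %in% map$marker))
    stop("architecture markers absent from map")
  sub <- map[match(qtl$marker, map$marker), , drop = FALSE]
  geno <- realize_genotypes(mosaics, founders, mpp_map(sub$marker, sub$chrom, sub$pos),
                            missing_rate = 0)
  z <- 1L - geno[, qtl$marker, drop = FALSE]   # dosage 0 (11) -> +1, 2 (22) -> -1
  g <- drop(z %*% qtl$effect)
  eps <- stats::rnorm(length(g), 0, residual_sd)
  y <- g + eps
  names(y) <- names(mosaics)
  out <- list(y = y, z = z, genetic = g, residual_sd = residual_sd,
              qtl = qtl)
  class(out) <- "simulated_trait"
  out
}

#' Expected genetic variance of a simulated QTL
#'
#' In the inbred limit the genotype indicator Z at a QTL takes values -1/+1,
#' so the expected QTL variance is `a^2 * (E[Z^2] - E[Z]^2) = a^2 * (1 -
#' E[Z]^2)` with `E[Z]` implied by the design: in MAGIC the frequency of the
#' allele-1 homozygote equals the fraction of carrier founders; in diallel
#' and NAM designs it averages the within-family frequencies (1, 0 or 1/2
#' when both, neither or one parent carries allele 1) with equal family
#' sizes assumed.
#'
#' @param plan a [make_crossing_plan()] object with equal family sizes.
#' @param architecture a [qtl_architecture()].
#' @param qtl name of the QTL (e.g. `"simQTL1"`) or its marker id.
#' @param var_y optional total phenotypic variance used for the percentage
#'   of explained variance; when `NULL` it is approximated as the sum of all
#'   QTL variances (linkage ignored) plus `residual_var`.
#' @param residual_var residual variance used when `var_y` is `NULL`.
#' @return List with `variance`, `percent_explained`, `freq11` and
#'   `mean_z`.
#' @export
expected_qtl_variance <- function(plan, architecture, qtl, var_y = NULL,
                                  residual_var = 1) {
  all_q <- rbind(architecture$major, architecture$minor)
  i <- match(qtl, all_q$qtl)
  if (is.na(i)) i <- match(qtl, all_q$marker)
  if (is.na(i)) stop("unknown QTL: ", qtl)
  one_var <- function(j) {
    carriers <- architecture$carriers[all_q$marker[j], plan$founders]
    if (plan$design == "magic") {
      p11 <- mean(carriers)
      ez <- 2 * p11 - 1
    } else {
      if (length(unique(plan$families$n)) > 1L)
        warning("unequal family sizes; expected variance assumes balance")
      pk <- vapply(plan$families$parents, function(pp)
        mean(carriers[pp]), numeric(1))  # 1, 0.5 or 0 carriers among the 2
      p11 <- mean(pk)
      ez <- mean(2 * pk - 1)
    }
    c(v = all_q$effect[j]^2 * (1 - ez^2), p11 = p11, ez = ez)
  }
  this <- one_var(i)
  if (is.null(var_y)) {
    tot <- sum(vapply(seq_len(nrow(all_q)), function(j) one_var(j)[["v"]],
                      numeric(1)))
    var_y <- tot + residual_var
  }
  list(variance = unname(this[["v"]]),
       percent_explained = unname(100 * this[["v"]] / var_y),
       freq11 = unname(this[["p11"]]), mean_z = unname(this[["ez"]]))
}
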