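#' @title IBD reconstruction by hidden Markov model decoding
#'
#' @description Founder-origin (IBD) probabilities per offspring per marker
#' are computed by posterior decoding of a hidden Markov chain along each
#' chromosome. Offspring are treated as fully inbred, so the hidden state at
#' a locus is the single founder of origin; the observed heterozygous
#' dosages (rare residual heterozygotes at F6) are treated as missing for
#' decoding. The prior chain is a continuous Markov kernel over map distance
#' d (Morgan): `T(i -> j) = exp(-rho*d) * 1{i=j} + (1 - exp(-rho*d)) *
#' pi_j`, where the junction density `rho` (expected founder-origin
#' junctions per Morgan on an offspring genome) is calibrated per design by
#' simulating the breeding pedigree. Emissions allow a genotyping error rate
#' `e`: an observed homozygous dosage consistent with the founder's allele
#' has probability `1 - e`, an inconsistent one `e`; missing observations
#' are uninformative.
#'
#' @name ibd-hmm
NULL

#' Calibrate the junction density of a design
#'
#' Estimates `rho`, the expected number of founder-origin junctions per
#' Morgan per offspring genome (averaging the two haplotypes), by simulating
#' offspring through the plan's pedigree. For a biparental F6 RIL this is
#' close to the Haldane--Waddington limit of 2 junctions/Morgan; one meiosis
#' (F1 gamete) gives about 1. Uses R's global random number generator.
#'
#' @param plan a [make_crossing_plan()] object.
#' @param map an [mpp_map()].
#' @param n_calibration number of offspring to simulate (>= 100 recommended;
#'   smaller values are accepted but noisy).
#' @return The estimated junction density (junctions per Morgan).
#' @export
calibrate_junction_density <- function(plan, map, n_calibration = 200L) {
  map <- as_mpp_map(map)
  genome_morgan <- sum(chrom_lengths(map)) / 100
  if (genome_morgan <= 0) stop("zero-length genome: cannot calibrate")
  per_fam <- max(1L, ceiling(n_calibration / plan$F))
  small <- make_crossing_plan(plan$design, plan$founders, per_fam,
                              plan$final_generation)
  mos <- advance_population(small, map)
  mean(vapply(mos, junction_count, numeric(1))) / genome_morgan
}

#' Build the origin HMM for one family
#'
#' @param parents founder ids admissible for the family (the family's two
#'   parents, or all founders for MAGIC).
#' @param founders founder allele matrix (founders x markers, 1/2, complete;
#'   markers with any missing founder genotype are excluded).
#' @param map an [mpp_map()] restricted to the markers to decode.
#' @param rho junction density (junctions/Morgan), > 0.
#' @param error genotyping error rate in `[0, 0.5)`.
#' @return List of class `origin_hmm` with the admissible states, uniform
#'   initial distribution, per-state expected homozygous dosages, map and
#'   kernel parameters.
#' @export
build_hmm <- function(parents, founders, map, rho, error = 0.005) {
  map <- as_mpp_map(map)
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0")
  if (error < 0 || error >= 0.5) stop("error rate must be in [0, 0.5)")
  if (!all(parents %in% rownames(founders))) stop("unknown parent id")
  keep <- map$marker[colSums(is.na(founders[, map$marker, drop = FALSE])) == 0L]
  if (length(keep) < nrow(map))
    map <- mpp_map(keep, map$chrom[match(keep, map$marker)],
                   map$pos[match(keep, map$marker)])
  fd <- 2L * (founders[parents, map$marker, drop = FALSE] == 2L)  # S x M dosages
  hmm <- list(states = parents, pi = rep(1 / length(parents), length(parents)),
              rho = rho, error = error, map = map, founder_dosage = fd)
  class(hmm) <- "origin_hmm"
  hmm
}

# transition matrix of the kernel over d Morgan (exposed for tests)
hmm_transition <- function(hmm, d) {
  if (d < 0) stop("non-positive map distance") # d = 0 is allowed (identity)
  S <- length(hmm$states)
  lam <- exp(-hmm$rho * d)
  lam * diag(S) + (1 - lam) * matrix(hmm$pi, S, S, byrow = TRUE)
}

# n x S emission matrix at one marker; het (dosage 1) and NA are uninformative
hmm_emission <- function(hmm, obs, t) {
  S <- length(hmm$states)
  E <- matrix(1, length(obs), S)
  informative <- !is.na(obs) & obs != 1L
  if (any(informative)) {
    fd <- hmm$founder_dosage[, t]
    for (j in seq_len(S)) {
      match_j <- obs[informative] == fd[j]
      E[informative, j] <- ifelse(match_j, 1 - hmm$error, hmm$error)
    }
  }
  E
}

#' Posterior founder-origin probabilities for one family
#'
#' Forward--backward decoding per chromosome, vectorized over offspring.
#' The default scaled recursion normalizes per locus; the log-domain variant
#' (`method = "log"`) is slower but serves as a numerical cross-check --
#' both agree to well below 1e-9.
#'
#' @param hmm an [build_hmm()] object.
#' @param geno offspring x marker dosage matrix over (at least) the HMM's
#'   markers; entries 0/1/2/NA.
#' @param method `"scaled"` or `"log"`.
#' @return Array offspring x markers x states of posterior probabilities;
#'   each (offspring, marker) slice sums to 1.
#' @export
posterior_origins <- function(hmm, geno, method = c("scaled", "log")) {
  method <- match.arg(method)
  map <- hmm$map
  if (!all(map$marker %in% colnames(geno)))
    stop("genotypes lack markers required by the HMM")
  geno <- geno[, map$marker, drop = FALSE]
  n <- nrow(geno); S <- length(hmm$states)
  post <- array(NA_real_, c(n, nrow(map), S),
                dimnames = list(rownames(geno), map$marker, hmm$states))
  for (cc in unique(map$chrom)) {
    idx <- marker_index(map, cc)
    d <- diff(map$pos[idx]) / 100   # Morgan
    Tn <- length(idx)
    E <- lapply(seq_len(Tn), function(t)
      hmm_emission(hmm, geno[, idx[t], drop = TRUE], idx[t]))
    pim <- matrix(hmm$pi, n, S, byrow = TRUE)
    if (method == "scaled") {
      Alist <- vector("list", Tn)
      A <- pim * E[[1L]]
      A <- A / rowSums(A)
      Alist[[1L]] <- A
      if (Tn > 1L) for (t in 2:Tn) {
        lam <- exp(-hmm$rho * d[t - 1L])
        A <- (lam * A + (1 - lam) * pim) * E[[t]]
        A <- A / rowSums(A)
        Alist[[t]] <- A
      }
      B <- matrix(1, n, S)
      post[, idx[Tn], ] <- Alist[[Tn]]
      if (Tn > 1L) for (t in (Tn - 1L):1L) {
        lam <- exp(-hmm$rho * d[t])
        W <- E[[t + 1L]] * B
        B <- lam * W + (1 - lam) * drop(W %*% hmm$pi)
        B <- B / rowSums(B)
        pt <- Alist[[t]] * B
        post[, idx[t], ] <- pt / rowSums(pt)
      }
    } else {
      lpi <- matrix(log(hmm$pi), n, S, byrow = TRUE)
      lse <- function(M) {  # row-wise log-sum-exp
        mx <- apply(M, 1L, max)
        mx + log(rowSums(exp(M - mx)))
      }
      lAlist <- vector("list", Tn)
      lA <- lpi + log(E[[1L]])
      lA <- lA - lse(lA)
      lAlist[[1L]] <- lA
      if (Tn > 1L) for (t in 2:Tn) {
        lam <- exp(-hmm$rho * d[t - 1L])
        # log(lam * exp(lA) + (1 - lam) * pi): exp(lA) rows sum to 1
        lpred <- log(lam * exp(lA) + (1 - lam) * exp(lpi))
        lA <- lpred + log(E[[t]])
        lA <- lA - lse(lA)
        lAlist[[t]] <- lA
      }
      lB <- matrix(0, n, S)
      post[, idx[Tn], ] <- exp(lAlist[[Tn]])
      if (Tn > 1L) for (t in (Tn - 1L):1L) {
        lam <- exp(-hmm$rho * d[t])
        lW <- log(E[[t + 1L]]) + lB
        lB <- log(lam * exp(lW) + (1 - lam) * exp(lse(lW + lpi)))
        lB <- lB - lse(lB)
        lp <- lAlist[[t]] + lB
        lp <- lp - lse(lp)
        post[, idx[t], ] <- exp(lp)
      }
    }
  }
  post
}

#' Decode founder-origin probabilities for a whole population
#'
#' Runs [posterior_origins()] per family: diallel and NAM families are
#' decoded with the prior uniform over their two parents, the MAGIC family
#' with the prior uniform over all founders. Markers with missing founder
#' genotypes are excluded.
#'
#' @param geno offspring x marker dosage matrix (rows named by offspring in
#'   plan order).
#' @param founders founder allele matrix.
#' @param map an [mpp_map()].
#' @param plan the [make_crossing_plan()] that produced the offspring.
#' @param rho junction density; `NULL` calibrates it by simulation via
#'   [calibrate_junction_density()].
#' @param error genotyping error rate (default 0.005).
#' @param method forward--backward flavour, see [posterior_origins()].
#' @return Array of class `ibd_tensor`, offspring x markers x founders;
#'   probabilities are exactly 0 for founders outside an offspring's family.
#'   The junction density used is stored in attribute `"rho"`.
#' @export
ibd_decode <- function(geno, founders, map, plan, rho = NULL, error = 0.005,
                       method = "scaled") {
  map <- as_mpp_map(map)
  if (is.null(rho)) rho <- calibrate_junction_density(plan, map)
  fam <- plan_family_factor(plan)
  if (nrow(geno) != length(fam))
    stop("genotype rows do not match the plan's offspring count")
  P <- length(plan$founders)
  keep <- map$marker[colSums(is.na(founders[, map$marker, drop = FALSE])) == 0L]
  kmap <- mpp_map(keep, map$chrom[match(keep, map$marker)],
                  map$pos[match(keep, map$marker)])
  tensor <- array(0, c(nrow(geno), nrow(kmap), P),
                  dimnames = list(rownames(geno), kmap$marker, plan$founders))
  for (k in seq_len(plan$F)) {
    rows <- which(fam == plan$families$family[k])
    parents <- plan$families$parents[[k]]
    if (plan$design == "magic") parents <- plan$founders
    hmm <- build_hmm(parents, founders, kmap, rho, error)
    post <- posterior_origins(hmm, geno[rows, , drop = FALSE], method)
    tensor[rows, , match(parents, plan$founders)] <- post
  }
  attr(tensor, "rho") <- rho
  attr(tensor, "error") <- error
  attr(tensor, "map") <- kmap
  class(tensor) <- "ibd_tensor"
  tensor
}

#' Genetic predictors at a marker
#'
#' The N x P matrix of expected founder-allele counts: twice the posterior
#' founder-origin probability at the locus. Rows sum to 2.
#'
#' @param tensor an [ibd_decode()] tensor.
#' @param marker marker id.
#' @return N x P numeric matrix.
#' @export
genetic_predictors <- function(tensor, marker) {
  if (!marker %in% dimnames(tensor)[[2L]])
    stop("marker not in IBD tensor: ", marker)
  M <- 2 * tensor[, marker, , drop = TRUE]
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L,
                                   dimnames = list(dimnames(tensor)[[1L]],
                                                   dimnames(tensor)[[3L]]))
  M
}

#' IBD reconstruction quality
#'
#' The per-marker average (over offspring) of the maximum posterior
#' founder-origin probability, and its minimum over markers. Values near 1
#' indicate confidently reconstructed parental origins.
#'
#' @param tensor an [ibd_decode()] tensor.
#' @return Numeric vector per marker with attribute `"min"`.
#' @export
ibd_quality <- function(tensor) {
  if (length(tensor) == 0L) stop("empty IBD tensor")
  mx <- apply(tensor, c(1L, 2L), max)
  q <- colMeans(mx)
  attr(q, "min") <- min(q)
  q
}
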