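#' Genomic kinship (VanRaden) and leave-one-chromosome-out variants
#'
#' `vanraden_kinship()` computes the IBS-based genomic relationship matrix
#' `K = W W' / (2 * sum p_k (1 - p_k))`, where `W` centers the allele
#' dosages by twice the sample allele frequency per marker. Missing dosages
#' are mean-imputed per marker before centering; frequencies are taken from
#' the pooled offspring sample. `loco_kinship()` recomputes K once per
#' chromosome from all markers not on that chromosome, which is the matrix
#' used when scanning markers of that chromosome (avoids proximal
#' contamination).
#'
#' @param geno offspring x marker dosage matrix (0/1/2, `NA` allowed).
#' @param markers optional subset of marker ids to use.
#' @param ridge non-negative diagonal stabilizer added as `ridge * I`
#'   (default 0; a small value such as 1e-6 can stabilize REML when K is
#'   nearly singular).
#' @return Symmetric N x N matrix with offspring ids as dimnames, of class
#'   `kinship_matrix`, with attributes `"markers"` (count used) and
#'   `"loco"` (excluded chromosome or `NA`).
#' @export
vanraden_kinship <- function(geno, markers = NULL, ridge = 0) {
  if (!is.null(markers)) {
    miss <- setdiff(markers, colnames(geno))
    if (length(miss)) stop("markers not in genotypes: ",
                           paste(utils::head(miss), collapse = ", "))
    geno <- geno[, markers, drop = FALSE]
  }
  G <- geno
  storage.mode(G) <- "double"
  cm <- colMeans(G, na.rm = TRUE)
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas)) G[nas] <- cm[nas[, 2L]]
  p <- cm / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers monomorphic: kinship denominator is zero")
  W <- sweep(G, 2L, 2 * p, "-")
  K <- tcrossprod(W) / denom
  if (ridge > 0) K <- K + diag(ridge, nrow(K))
  dimnames(K) <- list(rownames(geno), rownames(geno))
  attr(K, "markers") <- ncol(G)
  attr(K, "loco") <- NA_character_
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' @rdname vanraden_kinship
#' @param map an [mpp_map()] assigning genotype markers to chromosomes.
#' @return For `loco_kinship()`: a named list with one kinship matrix per
#'   chromosome (computed from the complementary marker set).
#' @export
loco_kinship <- function(geno, map, ridge = 0) {
  map <- as_mpp_map(map)
  chrs <- unique(map$chrom)
  if (length(chrs) < 2L)
    stop("LOCO kinship needs at least 2 chromosomes; use vanraden_kinship()")
  out <- vector("list", length(chrs))
  names(out) <- chrs
  for (cc in chrs) {
    use <- intersect(map$marker[map$chrom != cc], colnames(geno))
    K <- vanraden_kinship(geno, use, ridge = ridge)
    attr(K, "loco") <- cc
    out[[cc]] <- K
  }
  out
}
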