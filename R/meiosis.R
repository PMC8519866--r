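#' @title Founder mosaics and meiosis
#'
#' @description Offspring genomes are represented as founder mosaics in a
#' junction representation: each haplotype of each chromosome is a list with
#' `bp`, the ascending right endpoints of founder segments (the last endpoint
#' equals the chromosome length), and `origin`, the founder index carried on
#' each segment. Crossovers per meiosis are Poisson with mean equal to the
#' chromosome length in Morgan and uniformly placed (no interference,
#' Haldane model); a gamete starts from a fair random parental haplotype and
#' alternates at crossovers.
#'
#' @name mosaics
NULL

# single-founder haplotype covering one chromosome
founder_haplotype <- function(founder_index, length_cM) {
  list(bp = as.numeric(length_cM), origin = as.integer(founder_index))
}

# drop breakpoints between adjacent segments with the same origin
compact_haplotype <- function(h) {
  n <- length(h$origin)
  if (n <= 1L) return(h)
  keep <- c(h$origin[-n] != h$origin[-1L], TRUE)
  list(bp = h$bp[keep], origin = h$origin[keep])
}

# index of the segment covering position x (0 <= x <= L); position 0 belongs
# to the first segment, otherwise segments are left-open intervals (b0, b1]
segment_at <- function(h, x) {
  pmax(findInterval(x, h$bp, left.open = TRUE) + 1L, 1L)
}

# splice two haplotypes at crossover positions, starting from `start` (1 or 2)
recombine_haplotypes <- function(h1, h2, xo, start, length_cM) {
  if (length(xo) == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(xo)
  bounds <- c(xo, length_cM)
  src <- rep_len(if (start == 1L) c(1L, 2L) else c(2L, 1L), length(bounds))
  bp <- vector("list", length(bounds))
  or <- vector("list", length(bounds))
  prev <- 0
  for (i in seq_along(bounds)) {
    h <- if (src[i] == 1L) h1 else h2
    b <- bounds[i]
    j0 <- findInterval(prev, h$bp) + 1L          # segment just right of prev
    j0 <- min(j0, length(h$bp))
    j1 <- segment_at(h, b)
    or[[i]] <- h$origin[j0:j1]
    bp[[i]] <- c(if (j1 > j0) h$bp[j0:(j1 - 1L)], b)
    prev <- b
  }
  compact_haplotype(list(bp = unlist(bp, use.names = FALSE),
                         origin = unlist(or, use.names = FALSE)))
}

#' Simulate one meiosis of a diploid genome
#'
#' Draws, per chromosome, a Poisson number of crossovers with mean equal to
#' the chromosome length in Morgan (length in cM / 100), places them
#' uniformly, and recombines the two parental haplotypes starting from a
#' random one. A 0 cM chromosome yields zero crossovers and one parental
#' haplotype unchanged. Uses R's global random number generator.
#'
#' @param genome a diploid genome: named list over chromosomes, each a list
#'   with haplotypes `h1` and `h2` in junction representation.
#' @param lengths named chromosome lengths in cM (see [chrom_lengths()]).
#' @return A gamete: named list over chromosomes of single haplotypes.
#' @export
simulate_meiosis <- function(genome, lengths) {
  out <- vector("list", length(lengths))
  names(out) <- names(lengths)
  for (cc in names(lengths)) {
    L <- lengths[[cc]]
    chrom <- genome[[cc]]
    if (is.null(chrom)) stop("genome lacks chromosome ", cc)
    nco <- if (L > 0) stats::rpois(1L, L / 100) else 0L
    xo <- if (nco > 0L) stats::runif(nco, 0, L) else numeric(0)
    start <- sample.int(2L, 1L)
    out[[cc]] <- recombine_haplotypes(chrom$h1, chrom$h2, xo, start, L)
  }
  out
}

# self one individual: two independent gametes
self_individual <- function(ind, lengths) {
  list_chroms(simulate_meiosis(ind, lengths), simulate_meiosis(ind, lengths))
}

# pair two gametes into a diploid genome
list_chroms <- function(g1, g2) {
  out <- vector("list", length(g1))
  names(out) <- names(g1)
  for (cc in names(g1)) out[[cc]] <- list(h1 = g1[[cc]], h2 = g2[[cc]])
  out
}

# diploid genome of founder f (fully inbred)
founder_genome <- function(f, lengths) {
  out <- vector("list", length(lengths))
  names(out) <- names(lengths)
  for (cc in names(lengths)) {
    h <- founder_haplotype(f, lengths[[cc]])
    out[[cc]] <- list(h1 = h, h2 = h)
  }
  out
}

#' Advance a crossing plan to the final generation
#'
#' Builds the family F1 individuals from the plan's crosses (for MAGIC, the
#' two-way hybrids are intercrossed into the four-way funnel product, which
#' counts as generation 1 of the family), founds `n_k` independent lines per
#' family at the first selfing, and advances each line by single-seed
#' descent (one selfed offspring carried forward) up to the final
#' generation. Uses R's global random number generator.
#'
#' @param plan a [make_crossing_plan()] object.
#' @param map an [mpp_map()]; only chromosome lengths are used.
#' @return List of offspring diploid genomes (founder mosaics) of length
#'   `plan$N`, named by offspring id, with attribute `"founders"` giving the
#'   founder index coding.
#' @export
advance_population <- function(plan, map) {
  map <- as_mpp_map(map)
  lengths <- chrom_lengths(map)
  founders <- plan$founders
  gen1 <- function(parents) {
    idx <- match(parents, founders)
    if (length(idx) == 2L) {
      # biparental F1: deterministic (founders inbred)
      list_chroms(simulate_meiosis(founder_genome(idx[1L], lengths), lengths),
                  simulate_meiosis(founder_genome(idx[2L], lengths), lengths))
    } else if (length(idx) == 4L) {
      ab <- list_chroms(
        simulate_meiosis(founder_genome(idx[1L], lengths), lengths),
        simulate_meiosis(founder_genome(idx[2L], lengths), lengths))
      cd <- list_chroms(
        simulate_meiosis(founder_genome(idx[3L], lengths), lengths),
        simulate_meiosis(founder_genome(idx[4L], lengths), lengths))
      list_chroms(simulate_meiosis(ab, lengths), simulate_meiosis(cd, lengths))
    } else stop("unsupported number of parents in a family: ", length(idx))
  }
  out <- vector("list", plan$N)
  pos <- 0L
  for (k in seq_len(plan$F)) {
    parents <- plan$families$parents[[k]]
    f1 <- gen1(parents)  # shared family F1 (deterministic for 2 parents)
    for (l in seq_len(plan$families$n[k])) {
      ind <- if (length(parents) == 4L && l > 1L) gen1(parents) else f1
      g <- 1L
      while (g < plan$final_generation) {
        ind <- self_individual(ind, lengths)
        g <- g + 1L
      }
      pos <- pos + 1L
      out[[pos]] <- ind
    }
  }
  names(out) <- plan_offspring_ids(plan)
  attr(out, "founders") <- founders
  attr(out, "lengths") <- lengths
  out
}

# founder origin of each haplotype at the map's marker positions:
# list(h1 = N x M integer matrix, h2 = ...)
mosaic_origins <- function(mosaics, map) {
  map <- as_mpp_map(map)
  N <- length(mosaics)
  M <- nrow(map)
  h1 <- matrix(NA_integer_, N, M, dimnames = list(names(mosaics), map$marker))
  h2 <- h1
  for (cc in unique(map$chrom)) {
    idx <- marker_index(map, cc)
    pos <- map$pos[idx]
    for (i in seq_len(N)) {
      chrom <- mosaics[[i]][[cc]]
      h1[i, idx] <- chrom$h1$origin[segment_at(chrom$h1, pos)]
      h2[i, idx] <- chrom$h2$origin[segment_at(chrom$h2, pos)]
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Realize marker genotypes from founder mosaics
#'
#' Reads allele dosages off the founder alleles under each haplotype's
#' origin and masks entries missing completely at random at the given rate.
#' Dosages count copies of allele 2 (0, 1, 2).
#'
#' @param mosaics offspring genomes from [advance_population()].
#' @param founders founder allele matrix (founders x markers, values 1/2).
#' @param map an [mpp_map()].
#' @param missing_rate probability in `[0, 1]` that an entry is masked.
#' @return Integer matrix offspring x markers with `NA` for missing entries;
#'   the unmasked truth is returned as attribute `"true"`.
#' @export
realize_genotypes <- function(mosaics, founders, map, missing_rate = 0.05) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  map <- as_mpp_map(map)
  if (!all(map$marker %in% colnames(founders)))
    stop("founder matrix lacks markers: ",
         paste(utils::head(setdiff(map$marker, colnames(founders))), collapse = ", "))
  founders <- founders[, map$marker, drop = FALSE]
  or <- mosaic_origins(mosaics, map)
  M <- nrow(map); N <- length(mosaics)
  col <- rep(seq_len(M), each = N)
  a1 <- matrix(founders[cbind(as.vector(or$h1), col)], N, M)
  a2 <- matrix(founders[cbind(as.vector(or$h2), col)], N, M)
  geno <- (a1 == 2L) + (a2 == 2L)
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(names(mosaics), map$marker)
  true <- geno
  if (missing_rate > 0) {
    mask <- stats::runif(length(geno)) < missing_rate
    geno[mask] <- NA_integer_
  }
  attr(geno, "true") <- true
  geno
}

# per-individual junction count (average of the two haplotypes)
junction_count <- function(ind) {
  mean(vapply(ind, function(chrom)
    (length(chrom$h1$origin) - 1L + length(chrom$h2$origin) - 1L) / 2,
    numeric(1))) * length(ind)
}

# fraction of markers with discordant haplotype founder origins
origin_heterozygosity <- function(mosaics, map) {
  or <- mosaic_origins(mosaics, map)
  mean(or$h1 != or$h2)
}
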