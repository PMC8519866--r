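#' Genetic map objects
#'
#' An `mpp_map` is a data frame with columns `marker` (unique identifiers),
#' `chrom` (chromosome identifier, treated as an opaque string) and `pos`
#' (genetic position in centimorgan, non-decreasing within a chromosome).
#' It is the coordinate system for founders, offspring genotypes, IBD
#' probabilities and scan profiles.
#'
#' @param marker character vector of unique marker names.
#' @param chrom chromosome identifier per marker.
#' @param pos genetic position in cM (>= 0) per marker.
#' @return A data frame of class `mpp_map`.
#' @export
mpp_map <- function(marker, chrom, pos) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(marker) != length(chrom) || length(marker) != length(pos))
    stop("marker, chrom and pos must have equal length")
  if (anyDuplicated(marker))
    stop("duplicate marker ids: ", paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(!is.finite(pos)) || any(pos < 0))
    stop("positions must be finite and >= 0")
  map <- data.frame(marker = marker, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  # order by chromosome (first appearance) then position, stable for ties
  chr_levels <- unique(chrom)
  ord <- order(match(map$chrom, chr_levels), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  for (cc in chr_levels) {
    p <- map$pos[map$chrom == cc]
    if (is.unsorted(p)) stop("positions not sortable within chromosome ", cc)
  }
  class(map) <- c("mpp_map", "data.frame")
  map
}

#' @export
print.mpp_map <- function(x, ...) {
  cl <- chrom_lengths(x)
  cat(sprintf("Genetic map: %d markers on %d chromosome(s), %.1f cM total\n",
              nrow(x), length(cl), sum(cl)))
  for (cc in names(cl)) {
    n <- sum(x$chrom == cc)
    cat(sprintf("  chr %s: %d markers, %.1f cM\n", cc, n, cl[[cc]]))
  }
  invisible(x)
}

as_mpp_map <- function(x) {
  if (inherits(x, "mpp_map")) return(x)
  stopifnot(is.data.frame(x), all(c("marker", "chrom", "pos") %in% names(x)))
  mpp_map(x$marker, x$chrom, x$pos)
}

#' Chromosome lengths of a genetic map
#'
#' Length of a chromosome is taken as the position of its last marker (maps
#' start at 0 cM by convention).
#'
#' @param map an [mpp_map()].
#' @return Named numeric vector of lengths in cM, in map chromosome order.
#' @export
chrom_lengths <- function(map) {
  map <- as_mpp_map(map)
  chrs <- unique(map$chrom)
  out <- vapply(chrs, function(cc) max(map$pos[map$chrom == cc]), numeric(1))
  names(out) <- chrs
  out
}

#' Simulation fixture map: 462 markers on five chromosomes
#'
#' The default map used by the breeding-design simulator: chromosomes 1 to 4
#' carry 88 markers each at 1 cM spacing (0--87 cM) and chromosome 5 carries
#' 110 markers (0--109 cM), for 462 markers in total. Chromosome 5 is kept
#' free of simulated QTLs and serves as the null chromosome for
#' false-positive accounting.
#'
#' @return An [mpp_map()] with 462 markers.
#' @export
mpp_sim_map <- function() {
  nm <- c(rep(88L, 4), 110L)
  marker <- character(0); chrom <- character(0); pos <- numeric(0)
  for (cc in 1:5) {
    idx <- seq_len(nm[cc])
    marker <- c(marker, sprintf("C%dM%03d", cc, idx))
    chrom <- c(chrom, rep(as.character(cc), nm[cc]))
    pos <- c(pos, idx - 1)
  }
  mpp_map(marker, chrom, pos)
}

# index of markers of one chromosome, in map order
marker_index <- function(map, chr) which(map$chrom == chr)

# marker id at (chrom, pos); error when absent
marker_at <- function(map, chr, position, tol = 1e-9) {
  i <- which(map$chrom == chr & abs(map$pos - position) < tol)
  if (length(i) != 1L)
    stop("no unique marker at chromosome ", chr, " position ", position)
  map$marker[i]
}
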