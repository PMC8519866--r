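#' Simulate founder genomes
#'
#' Founders are fully inbred, so one haplotype per founder suffices. Alleles
#' (coded 1/2) are drawn i.i.d. Bernoulli(0.5) per founder per marker; the
#' designated major-QTL markers are then overwritten with fixed carrier
#' patterns so that the number of founders homozygous for allele 1 at the
#' three major loci is 2, 1 and 3 respectively (the allele labelled 1
#' increases the trait). Uses R's global random number generator.
#'
#' @param map an [mpp_map()].
#' @param founder_ids founder names (default `P1`..`P4`).
#' @param major_carriers named list mapping major-QTL marker ids to the
#'   character vector of founders carrying allele 1 there; `NULL` skips the
#'   overwrite (e.g. for maps without the default majors).
#' @return Integer matrix founders x markers with values 1/2.
#' @export
sim_founders <- function(map, founder_ids = paste0("P", 1:4),
                         major_carriers = default_major_carriers(founder_ids)) {
  map <- as_mpp_map(map)
  P <- length(founder_ids)
  al <- matrix(1L + (stats::runif(P * nrow(map)) < 0.5), P, nrow(map),
               dimnames = list(founder_ids, map$marker))
  storage.mode(al) <- "integer"
  if (!is.null(major_carriers)) {
    for (mk in names(major_carriers)) {
      if (!mk %in% map$marker) stop("major QTL marker not on map: ", mk)
      carriers <- major_carriers[[mk]]
      if (!all(carriers %in% founder_ids))
        stop("unknown carrier founder at ", mk)
      al[, mk] <- 2L
      al[carriers, mk] <- 1L
    }
  }
  al
}

#' Default carrier patterns at the three major simulated QTLs
#'
#' At the three major loci the founders homozygous for the trait-increasing
#' allele 1 number 2, 1 and 3: simQTL1 is carried by P1 and P2 (segregates
#' in 4/6 diallel and 2/3 NAM families, MAGIC frequency 0.5), simQTL2 by the
#' central founder P1 alone (3/6 diallel families, all 3 NAM families) and
#' simQTL3 by P1, P2 and P3 (3/6 diallel families, 1 NAM family).
#'
#' @param founder_ids the four founder names.
#' @return Named list: major marker id -> carriers of allele 1.
#' @export
default_major_carriers <- function(founder_ids = paste0("P", 1:4)) {
  stopifnot(length(founder_ids) == 4L)
  list("C1M045" = founder_ids[c(1L, 2L)],
       "C2M045" = founder_ids[1L],
       "C3M045" = founder_ids[c(1L, 2L, 3L)])
}

#' Assign the simulated QTL architecture
#'
#' Three major QTLs sit at designated markers on chromosomes 1--3. Starting
#' at 20 cM above and below each major position, minor QTLs are placed
#' outward at 10 cM steps and truncated at the chromosome ends; chromosome 4
#' carries only minor QTLs on a 10 cM grid; chromosome 5 carries none (it is
#' the null chromosome). On the default fixture map this yields 6 minors per
#' chromosome on chromosomes 1--3 plus 6 on chromosome 4, 24 in total.
#'
#' @param map an [mpp_map()].
#' @param founders founder allele matrix (used to record per-QTL carrier
#'   configurations).
#' @param majors data frame with columns `chrom` and `pos` for the three
#'   major QTLs (default: position 44 cM on chromosomes 1--3).
#' @param chr4_grid minor positions on chromosome 4.
#' @param a,b additive allele-substitution effects of major and minor QTLs.
#' @return List of class `qtl_architecture` with data frames `major` and
#'   `minor` (columns `qtl`, `marker`, `chrom`, `pos`, `effect`) and the
#'   per-QTL founder carrier matrix `carriers` (TRUE = allele 1).
#' @export
qtl_architecture <- function(map, founders,
                             majors = data.frame(chrom = as.character(1:3),
                                                 pos = 44),
                             chr4_grid = seq(15, 65, by = 10),
                             a = 0.4, b = 0.1) {
  map <- as_mpp_map(map)
  lens <- chrom_lengths(map)
  major <- data.frame(qtl = sprintf("simQTL%d", seq_len(nrow(majors))),
                      marker = vapply(seq_len(nrow(majors)), function(i)
                        marker_at(map, majors$chrom[i], majors$pos[i]),
                        character(1)),
                      chrom = as.character(majors$chrom),
                      pos = as.numeric(majors$pos),
                      effect = a, stringsAsFactors = FALSE)
  minor_pos <- list()
  for (i in seq_len(nrow(major))) {
    cc <- major$chrom[i]; p0 <- major$pos[i]; L <- lens[[cc]]
    lower <- if (p0 - 20 >= 0) seq(p0 - 20, 0, by = -10) else numeric(0)
    upper <- if (p0 + 20 <= L) seq(p0 + 20, L, by = 10) else numeric(0)
    minor_pos[[cc]] <- sort(c(lower, upper))
  }
  if ("4" %in% map$chrom && length(chr4_grid)) minor_pos[["4"]] <- chr4_grid
  minor_pos <- minor_pos[lengths(minor_pos) > 0L]
  minor <- if (length(minor_pos)) {
    mm <- do.call(rbind, lapply(names(minor_pos), function(cc)
      data.frame(chrom = cc, pos = minor_pos[[cc]], stringsAsFactors = FALSE)))
    mm$marker <- vapply(seq_len(nrow(mm)), function(i)
      marker_at(map, mm$chrom[i], mm$pos[i]), character(1))
    mm$qtl <- sprintf("minQTL%d", seq_len(nrow(mm)))
    mm$effect <- b
    mm[, c("qtl", "marker", "chrom", "pos", "effect")]
  } else data.frame(qtl = character(0), marker = character(0),
                    chrom = character(0), pos = numeric(0),
                    effect = numeric(0), stringsAsFactors = FALSE)
  all_mk <- c(major$marker, minor$marker)
  carriers <- t(founders[, all_mk, drop = FALSE] == 1L)
  rownames(carriers) <- all_mk
  out <- list(major = major, minor = minor, carriers = carriers,
              null_chrom = setdiff(unique(map$chrom),
                                   unique(c(major$chrom, minor$chrom))))
  class(out) <- "qtl_architecture"
  out
}

#' @export
print.qtl_architecture <- function(x, ...) {
  cat(sprintf("QTL architecture: %d major (effect %.3g), %d minor (effect %.3g)\n",
              nrow(x$major), x$major$effect[1], nrow(x$minor), x$minor$effect[1]))
  print(x$major, row.names = FALSE)
  cat(sprintf("minor QTLs per chromosome: %s\n",
              paste(sprintf("chr%s:%d", names(table(x$minor$chrom)),
                            as.integer(table(x$minor$chrom))), collapse = ", ")))
  if (length(x$null_chrom))
    cat("null chromosome(s):", paste(x$null_chrom, collapse = ", "), "\n")
  invisible(x)
}
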