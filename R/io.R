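#' @title Readers and writers for the interchange formats
#'
#' @description Comma-delimited text is the canonical interchange format.
#' Every table written by the package starts with `#`-prefixed header
#' comments recording the package version, a configuration hash and the
#' seed when one applies; readers skip such comments. Probabilities are
#' written with enough digits for a lossless round trip (to 1e-12).
#'
#' @name mpp-io
NULL

io_header <- function(meta = list()) {
  meta <- c(list(tool = paste0("ibdqtl ", as.character(
    utils::packageVersion("ibdqtl")))), meta)
  vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15),
                                 collapse = " ")), character(1))
}

write_commented_csv <- function(df, path, meta = list(), digits = 15) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header(meta), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_commented_csv <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read / write a genetic map
#'
#' Delimited table with columns `marker`, `chrom`, `pos` (cM).
#'
#' @param path file path.
#' @param map an [mpp_map()].
#' @param meta named list added to the header comments.
#' @return `read_map()` returns an [mpp_map()].
#' @export
read_map <- function(path) {
  df <- read_commented_csv(path)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("map file must have columns marker, chrom, pos: ", path)
  mpp_map(df$marker, df$chrom, df$pos)
}

#' @rdname read_map
#' @export
write_map <- function(map, path, meta = list()) {
  map <- as_mpp_map(map)
  write_commented_csv(as.data.frame(map), path, meta)
}

#' Read / write genotype tables
#'
#' Rows are individuals (first column `id`), remaining columns are markers
#' with allele-2 dosages 0/1/2 or `NA`. When a map is supplied, marker
#' columns are cross-validated against it and reordered to map order.
#'
#' @param path file path.
#' @param map optional [mpp_map()] for validation.
#' @return Integer matrix individuals x markers.
#' @export
read_genotypes <- function(path, map = NULL) {
  df <- read_commented_csv(path, check.names = FALSE)
  if (names(df)[1L] != "id") stop("first genotype column must be 'id'")
  ids <- as.character(df$id)
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1L])
  G <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(G)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric dosages in column '", names(df)[-1L][bad], "'")
  }
  if (any(!is.na(G) & !(G %in% c(0, 1, 2))))
    stop("dosages must be 0, 1, 2 or NA: ", path)
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  if (!is.null(map)) {
    map <- as_mpp_map(map)
    unknown <- setdiff(colnames(G), map$marker)
    if (length(unknown))
      stop("genotype marker(s) not on map: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    G <- G[, intersect(map$marker, colnames(G)), drop = FALSE]
  }
  G
}

#' @rdname read_genotypes
#' @param geno individuals x markers dosage matrix.
#' @param meta named list added to the header comments.
#' @export
write_genotypes <- function(geno, path, meta = list()) {
  df <- data.frame(id = rownames(geno), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(geno, check.names = FALSE))
  write_commented_csv(df, path, meta)
}

#' Read / write phenotypes
#'
#' Two columns: `id` and `value` (one trait of per-individual BLUEs).
#'
#' @param path file path.
#' @return Named numeric vector.
#' @export
read_phenotypes <- function(path) {
  df <- read_commented_csv(path)
  if (!all(c("id", "value") %in% names(df)))
    stop("phenotype file must have columns id, value")
  if (anyDuplicated(df$id))
    stop("duplicate individual id: ", df$id[duplicated(df$id)][1L])
  if (!is.numeric(df$value)) stop("non-numeric phenotype values")
  stats::setNames(as.numeric(df$value), as.character(df$id))
}

#' @rdname read_phenotypes
#' @param y named numeric vector.
#' @param meta named list added to the header comments.
#' @export
write_phenotypes <- function(y, path, meta = list()) {
  write_commented_csv(data.frame(id = names(y), value = as.numeric(y),
                                 stringsAsFactors = FALSE), path, meta)
}

#' Read / write a crossing plan
#'
#' JSON with fields `design`, `founders`, `final_generation` and `families`
#' (each with `family`, `parents`, `n`). Round trips losslessly.
#'
#' @param path file path.
#' @return A [make_crossing_plan()] object.
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- make_crossing_plan(
    x$design, x$founders,
    family_sizes = as.integer(x$families$n),
    final_generation = x$final_generation,
    central_founder = if (x$design == "nam") x$families$parents[[1L]][1L]
                      else NULL)
  # validate the enumerated families match the file
  got <- lapply(plan$families$parents, sort)
  want <- lapply(x$families$parents, sort)
  if (!identical(got, want))
    stop("family parent sets in ", path,
         " do not match the canonical enumeration for design ", x$design)
  plan
}

#' @rdname read_plan
#' @param plan a [make_crossing_plan()] object.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(design = plan$design, founders = plan$founders,
         final_generation = plan$final_generation,
         families = data.frame(family = plan$families$family,
                               n = plan$families$n,
                               parents = I(plan$families$parents))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write IBD probabilities
#'
#' Long-format delimited table with columns `individual`, `marker`,
#' `founder`, `probability`; zero probabilities (founders outside an
#' offspring's family) are stored too so the round trip is exact in shape.
#'
#' @param path file path.
#' @param map [mpp_map()] giving marker order for the reconstructed tensor.
#' @return An `ibd_tensor` array individuals x markers x founders.
#' @export
read_ibd <- function(path, map = NULL) {
  df <- read_commented_csv(path)
  need <- c("individual", "marker", "founder", "probability")
  if (!all(need %in% names(df))) stop("malformed IBD file: ", path)
  ids <- unique(df$individual); fs <- unique(df$founder)
  mks <- unique(df$marker)
  if (!is.null(map)) {
    map <- as_mpp_map(map)
    unknown <- setdiff(mks, map$marker)
    if (length(unknown)) stop("IBD marker not on map: ", unknown[1L])
    mks <- intersect(map$marker, mks)
  }
  tensor <- array(0, c(length(ids), length(mks), length(fs)),
                  dimnames = list(ids, mks, fs))
  tensor[cbind(match(df$individual, ids), match(df$marker, mks),
               match(df$founder, fs))] <- df$probability
  class(tensor) <- "ibd_tensor"
  tensor
}

#' @rdname read_ibd
#' @param tensor an `ibd_tensor`.
#' @param meta named list added to the header comments.
#' @export
write_ibd <- function(tensor, path, meta = list()) {
  dn <- dimnames(tensor)
  df <- data.frame(
    individual = rep(dn[[1L]], times = length(dn[[2L]]) * length(dn[[3L]])),
    marker = rep(rep(dn[[2L]], each = length(dn[[1L]])), times = length(dn[[3L]])),
    founder = rep(dn[[3L]], each = length(dn[[1L]]) * length(dn[[2L]])),
    probability = as.vector(unclass(tensor)), stringsAsFactors = FALSE)
  write_commented_csv(df, path, meta, digits = 17)
}

#' Read / write scan results
#'
#' The scan profile as a delimited table (one row per marker).
#'
#' @param path file path.
#' @return `read_results()` returns an `mpp_scan` data frame.
#' @export
read_results <- function(path) {
  df <- read_commented_csv(path)
  class(df) <- c("mpp_scan", "data.frame")
  df
}

#' @rdname read_results
#' @param profile an `mpp_scan` data frame.
#' @param meta named list added to the header comments.
#' @export
write_results <- function(profile, path, meta = list()) {
  meta <- c(meta, list(model = attr(profile, "model")))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  write_commented_csv(as.data.frame(profile), path, meta)
}

#' Write founder mosaics (the simulation truth)
#'
#' Long-format junction dump: one row per founder-origin segment with
#' columns `individual`, `chrom`, `haplotype` (1 or 2), `breakpoint` (the
#' segment's right endpoint in cM) and `origin` (founder index).
#'
#' @param mosaics offspring genomes from [advance_population()].
#' @param path file path.
#' @param meta named list added to the header comments.
#' @export
write_mosaics <- function(mosaics, path, meta = list()) {
  rows <- list()
  for (id in names(mosaics)) {
    ind <- mosaics[[id]]
    for (cc in names(ind)) {
      for (h in 1:2) {
        hp <- ind[[cc]][[c("h1", "h2")[h]]]
        rows[[length(rows) + 1L]] <-
          data.frame(individual = id, chrom = cc, haplotype = h,
                     breakpoint = hp$bp, origin = hp$origin,
                     stringsAsFactors = FALSE)
      }
    }
  }
  write_commented_csv(do.call(rbind, rows), path, meta)
}

#' Write a kinship matrix
#'
#' Square delimited matrix with individual ids as header and first column.
#'
#' @param K kinship matrix.
#' @param path file path.
#' @param meta named list added to the header comments.
#' @export
write_kinship <- function(K, path, meta = list()) {
  df <- data.frame(id = rownames(K), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(unclass(K)[, , drop = FALSE],
                                check.names = FALSE))
  write_commented_csv(df, path, meta)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- read_commented_csv(path, check.names = FALSE)
  K <- as.matrix(df[, -1L, drop = FALSE])
  rownames(K) <- df$id
  K
}
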