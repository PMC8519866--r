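#' Crossing plans for multiparental designs
#'
#' Enumerates the families of a diallel, NAM or MAGIC design together with
#' the inbreeding depth of the final generation. Families are listed
#' deterministically: a (half-)diallel over P founders takes all P(P-1)/2
#' unordered founder pairs in lexicographic order; a NAM design crosses one
#' central founder with every other founder; a 4-way MAGIC design has a
#' single family produced through the funnel (P1 x P2) x (P3 x P4) and then
#' selfed.
#'
#' @param design one of `"diallel"`, `"nam"`, `"magic"`.
#' @param founder_ids character vector of founder names (>= 2).
#' @param family_sizes number of offspring per family; either one number
#'   recycled over families or one per family.
#' @param final_generation filial generation of the offspring (6 for F6 RILs;
#'   the funnel product in MAGIC counts as generation 1, after which
#'   single-seed-descent selfing runs up to `final_generation`).
#' @param central_founder for NAM, the shared central founder (default: the
#'   first founder id).
#' @return A list of class `crossing_plan` with elements `design`,
#'   `founders`, `families` (data frame with `family`, `parents` list column,
#'   `n`), `final_generation`, `N` and `F`.
#' @export
make_crossing_plan <- function(design = c("diallel", "nam", "magic"),
                               founder_ids,
                               family_sizes,
                               final_generation = 6L,
                               central_founder = NULL) {
  design <- match.arg(tolower(design), c("diallel", "nam", "magic"))
  founder_ids <- as.character(founder_ids)
  P <- length(founder_ids)
  if (P < 2L) stop("need at least 2 founders")
  if (anyDuplicated(founder_ids)) stop("duplicate founder ids")
  final_generation <- as.integer(final_generation)
  if (final_generation < 1L) stop("final_generation must be >= 1")

  parents <- switch(design,
    diallel = {
      prs <- utils::combn(founder_ids, 2L, simplify = FALSE)
      prs
    },
    nam = {
      if (is.null(central_founder)) central_founder <- founder_ids[1L]
      central_founder <- as.character(central_founder)
      if (!central_founder %in% founder_ids)
        stop("central founder '", central_founder, "' is not among the founders")
      others <- setdiff(founder_ids, central_founder)
      lapply(others, function(p) c(central_founder, p))
    },
    magic = {
      if (P < 4L || bitwAnd(P, P - 1L) != 0L)
        stop("MAGIC requires a founder count that is a power of 2 (>= 4)")
      if (P > 4L)
        stop("only 4-way MAGIC funnels are supported")
      list(founder_ids)
    })

  Fn <- length(parents)
  family_sizes <- as.integer(family_sizes)
  if (length(family_sizes) == 1L) family_sizes <- rep(family_sizes, Fn)
  if (length(family_sizes) != Fn)
    stop("family_sizes must have length 1 or ", Fn)
  if (any(family_sizes < 1L)) stop("family sizes must be positive")

  fam_id <- sprintf("%s%d", switch(design, diallel = "Diallel",
                                   nam = "NAM", magic = "MAGIC"), seq_len(Fn))
  families <- data.frame(family = fam_id, n = family_sizes,
                         stringsAsFactors = FALSE)
  families$parents <- parents

  plan <- list(design = design, founders = founder_ids, families = families,
               final_generation = final_generation,
               N = sum(family_sizes), F = Fn)
  class(plan) <- "crossing_plan"
  plan
}

#' @export
print.crossing_plan <- function(x, ...) {
  cat(sprintf("%s crossing plan: %d founders, %d famil%s, N = %d, F%d offspring\n",
              toupper(x$design), length(x$founders), x$F,
              if (x$F == 1L) "y" else "ies", x$N, x$final_generation))
  for (i in seq_len(x$F))
    cat(sprintf("  %s: %s  (n = %d)\n", x$families$family[i],
                paste(x$families$parents[[i]], collapse = " x "),
                x$families$n[i]))
  invisible(x)
}

# family membership factor for all offspring, in simulation order
plan_family_factor <- function(plan) {
  factor(rep(plan$families$family, plan$families$n),
         levels = plan$families$family)
}

# offspring ids, one per line
plan_offspring_ids <- function(plan) {
  unlist(lapply(seq_len(plan$F), function(i)
    sprintf("%s_%03d", plan$families$family[i],
            seq_len(plan$families$n[i]))), use.names = FALSE)
}
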