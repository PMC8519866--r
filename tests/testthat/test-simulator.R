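test_that("crossing plans enumerate the expected families", {
  p4 <- paste0("P", 1:4)
  di <- make_crossing_plan("diallel", p4, 50, 6)
  expect_equal(di$F, 6L)
  expect_equal(di$N, 300L)
  expect_equal(di$families$parents[[1]], c("P1", "P2"))
  expect_equal(di$families$parents[[6]], c("P3", "P4"))

  nam <- make_crossing_plan("nam", p4, 100, 6, central_founder = "P1")
  expect_equal(nam$F, 3L)
  expect_equal(nam$N, 300L)
  expect_true(all(vapply(nam$families$parents, `[`, character(1), 1) == "P1"))

  mg <- make_crossing_plan("magic", p4, 300, 6)
  expect_equal(mg$F, 1L)
  expect_equal(mg$N, 300L)
  expect_equal(mg$families$parents[[1]], p4)

  # P = 2 degenerates to a single biparental family
  bi <- make_crossing_plan("diallel", c("A", "B"), 50, 6)
  expect_equal(bi$F, 1L)

  expect_error(make_crossing_plan("magic", paste0("P", 1:3), 10, 6),
               "power of 2")
  expect_error(make_crossing_plan("nam", p4, 10, 6, central_founder = "PX"),
               "central founder")
  expect_error(make_crossing_plan("diallel", "P1", 10, 6), "at least 2")
  expect_error(make_crossing_plan("diallel", p4, -5, 6), "positive")
})

test_that("meiosis follows the Poisson crossover model", {
  set.seed(101)
  lens <- c("1" = 100)
  f1 <- ibdqtl:::list_chroms(
    list("1" = ibdqtl:::founder_haplotype(1L, 100)),
    list("1" = ibdqtl:::founder_haplotype(2L, 100)))
  n_gam <- 10000
  counts <- integer(n_gam)
  for (i in seq_len(n_gam)) {
    g <- simulate_meiosis(f1, lens)
    counts[i] <- length(g[["1"]]$origin) - 1L
  }
  # mean junctions = chromosome length in Morgan (1.0), within 3 SE
  expect_lt(abs(mean(counts) - 1), 3 * sd(counts) / sqrt(n_gam))
  # goodness of fit to Poisson(1); junctions = realized crossovers that
  # switch the origin (every crossover does, for fully distinct haplotypes)
  brk <- 0:5
  obs <- c(vapply(brk[-length(brk)], function(k) sum(counts == k), numeric(1)),
           sum(counts >= 5))
  pr <- c(dpois(0:4, 1), ppois(4, 1, lower.tail = FALSE))
  chi <- sum((obs - n_gam * pr)^2 / (n_gam * pr))
  expect_gt(pchisq(chi, df = length(obs) - 1, lower.tail = FALSE), 0.01)

  # 0 cM chromosome: gamete equals a parental haplotype with no junctions
  z <- ibdqtl:::list_chroms(list("1" = ibdqtl:::founder_haplotype(1L, 0)),
                            list("1" = ibdqtl:::founder_haplotype(2L, 0)))
  g0 <- simulate_meiosis(z, c("1" = 0))
  expect_length(g0[["1"]]$origin, 1L)

  # homozygous diploid: gamete identical to the parent haplotype
  hom <- ibdqtl:::founder_genome(3L, c("1" = 100))
  for (i in 1:5) {
    g <- simulate_meiosis(hom, c("1" = 100))
    expect_equal(g[["1"]], ibdqtl:::founder_haplotype(3L, 100))
  }
})

test_that("heterozygosity halves with each selfing generation", {
  set.seed(202)
  map <- tiny_map(n_chr = 2)
  plan_for <- function(g) make_crossing_plan("diallel", c("A", "B"), 300, g)
  for (g in c(2L, 4L, 6L)) {
    mos <- advance_population(plan_for(g), map)
    or <- ibdqtl:::mosaic_origins(mos, map)
    het_i <- rowMeans(or$h1 != or$h2)       # per-individual heterozygosity
    expected <- 0.5^(g - 1)                 # one selfing per generation
    se <- sd(het_i) / sqrt(length(het_i))
    expect_lt(abs(mean(het_i) - expected), 3 * se + 1e-12)
  }
})

test_that("identical founders give genotypically identical offspring", {
  set.seed(7)
  map <- tiny_map(n_chr = 1)
  plan <- make_crossing_plan("diallel", c("A", "B"), 20, 6)
  founders <- rbind(A = rep(1L, nrow(map)), B = rep(1L, nrow(map)))
  colnames(founders) <- map$marker
  mos <- advance_population(plan, map)
  g <- realize_genotypes(mos, founders, map, missing_rate = 0)
  expect_true(all(g == 0L))                 # everyone matches the founder
})

test_that("realized genotypes respect the missing rate", {
  sh <- shared_diallel()
  sim <- sh$sim
  set.seed(11)
  g0 <- realize_genotypes(sim$mosaics, sim$founders, sim$map, 0)
  g0_plain <- g0; attr(g0_plain, "true") <- NULL
  expect_identical(unclass(g0_plain), attr(g0, "true"))
  expect_false(anyNA(g0))

  g1 <- realize_genotypes(sim$mosaics, sim$founders, sim$map, 1)
  expect_true(all(is.na(g1)))

  n_cell <- prod(dim(sim$geno))
  tol <- 3 * sqrt(0.05 * 0.95 / n_cell)
  expect_lt(abs(mean(is.na(sim$geno)) - 0.05), tol)
})

test_that("QTL architecture follows the placement rules", {
  sh <- shared_diallel()
  arch <- sh$sim$architecture
  expect_equal(nrow(arch$major), 3L)
  expect_equal(nrow(arch$minor), 24L)
  expect_equal(arch$null_chrom, "5")
  expect_false(any(arch$minor$chrom == "5"))
  # carrier counts of allele 1 at the majors: 2, 1, 3
  expect_equal(unname(rowSums(arch$carriers[arch$major$marker, ])), c(2, 1, 3))

  # stated rule on a 100 cM chromosome with the major at 50 cM
  mk <- sprintf("X%03d", 0:100)
  m100 <- mpp_map(mk, rep("1", 101), 0:100)
  f <- matrix(1L, 2, 101, dimnames = list(c("A", "B"), mk))
  a1 <- qtl_architecture(m100, f, majors = data.frame(chrom = "1", pos = 50),
                         chr4_grid = numeric(0))
  expect_equal(a1$minor$pos, c(0, 10, 20, 30, 70, 80, 90, 100))

  expect_error(qtl_architecture(m100, f,
                                majors = data.frame(chrom = "1", pos = 50.5)),
               "no unique marker")
})

test_that("phenotypes follow the additive QTL model", {
  sh <- shared_diallel()
  sim <- sh$sim
  qtl <- rbind(sim$architecture$major, sim$architecture$minor)
  # reconstruct: y = z %*% effect + eps, z in {-1, 0, 1}
  expect_true(all(sim$trait$z %in% c(-1L, 0L, 1L)))
  expect_equal(unname(drop(sim$trait$z %*% qtl$effect)),
               unname(sim$trait$genetic))

  # all-homozygous-11 genome scores 3 * 0.4 + 24 * 0.1 = 3.6 (and -3.6 for 22)
  map <- sim$map
  lens <- chrom_lengths(map)
  ind11 <- ibdqtl:::founder_genome(1L, lens)   # P1 carries allele 1 everywhere
  founders_11 <- sim$founders
  founders_11["P1", ] <- 1L
  founders_11["P2", ] <- 2L
  ind22 <- ibdqtl:::founder_genome(2L, lens)
  tr <- simulate_phenotype(list(i11 = ind11, i22 = ind22), founders_11, map,
                           sim$architecture, residual_sd = 0)
  expect_equal(unname(tr$y), c(3.6, -3.6), tolerance = 1e-12)

  # zero effects leave pure N(0,1) noise
  set.seed(33)
  map1 <- tiny_map(n_chr = 1)
  plan <- make_crossing_plan("diallel", c("A", "B"), 4000, 2)
  founders <- rbind(A = rep(1L, nrow(map1)), B = rep(2L, nrow(map1)))
  colnames(founders) <- map1$marker
  mos <- advance_population(plan, map1)
  arch0 <- qtl_architecture(map1, founders,
                            majors = data.frame(chrom = "1", pos = 25),
                            chr4_grid = numeric(0), a = 0, b = 0)
  tr0 <- simulate_phenotype(mos, founders, map1, arch0, residual_sd = 1)
  expect_lt(abs(var(tr0$y) - 1), 0.06)
  # balanced symmetric configuration: mean 0 within 3 SE
  expect_lt(abs(mean(tr0$y)), 3 / sqrt(length(tr0$y)))
})

test_that("expected QTL variance matches design-implied frequencies", {
  sh <- shared_diallel()
  arch <- sh$sim$architecture
  p4 <- paste0("P", 1:4)
  mg <- make_crossing_plan("magic", p4, 300, 6)
  v1 <- expected_qtl_variance(mg, arch, "simQTL1")
  expect_equal(v1$freq11, 0.5)
  expect_equal(v1$variance, 0.16, tolerance = 1e-12)

  # monomorphic locus: zero variance
  arch2 <- arch
  arch2$carriers[arch$major$marker[1], ] <- TRUE
  expect_equal(expected_qtl_variance(mg, arch2, "simQTL1")$variance, 0)

  # single biparental family segregating 0.5/0.5: var = a^2
  bi <- make_crossing_plan("diallel", c("P1", "P2"), 100, 6)
  v_bi <- expected_qtl_variance(bi, arch, "simQTL2")  # carried by P1 only
  expect_equal(v_bi$variance, 0.16, tolerance = 1e-12)
  expect_equal(v_bi$freq11, 0.5)
})

test_that("founder contributions are uniform in MAGIC", {
  set.seed(55)
  map <- tiny_map(n_chr = 2)
  plan <- make_crossing_plan("magic", paste0("P", 1:4), 400, 6)
  mos <- advance_population(plan, map)
  or <- ibdqtl:::mosaic_origins(mos, map)
  share_i <- (rowMeans(or$h1 == 1L) + rowMeans(or$h2 == 1L)) / 2
  se <- sd(share_i) / sqrt(length(share_i))
  expect_lt(abs(mean(share_i) - 0.25), 3 * se)
})

test_that("family structure shows in PCA for diallel but not MAGIC", {
  sh <- shared_diallel()
  sim <- sh$sim
  pcs <- function(geno) {
    G <- geno
    storage.mode(G) <- "double"
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    if (nrow(idx)) G[idx] <- cm[idx[, 2]]
    keep <- apply(G, 2, sd) > 0
    stats::prcomp(G[, keep], scale. = FALSE)$x[, 1:2]
  }
  sil_d <- silhouette_score(pcs(sim$geno_true), sim$family)
  expect_gt(sil_d, 0.3)

  mg <- simulate_mpp("magic", seed = 43)
  # MAGIC has a single family: any balanced pseudo-grouping shows no clusters
  pseudo <- rep(1:6, each = 50)
  sil_m <- silhouette_score(pcs(mg$geno_true), pseudo)
  expect_lt(sil_m, 0.1)
})
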