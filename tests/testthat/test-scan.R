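# small decoded dataset shared by the scan tests: biparental diallel on the
# tiny map (fast fits, clear signal at the chr1 major QTL)
scan_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) {
      args <- tiny_sim_args()
      sim <- do.call(simulate_mpp, c(list(design = "diallel",
                                          n_per_family = 25, a = 1.5, b = 0.1,
                                          seed = 314), args))
      tensor <- ibd_decode(sim$geno, sim$founders, sim$map, sim$plan,
                           rho = 1.9)
      kin <- loco_kinship(sim$geno, sim$map)
      env$fx <- list(sim = sim, tensor = tensor, kin = kin)
    }
    env$fx
  }
})

test_that("Bonferroni thresholds follow the formula and the override", {
  expect_equal(bonferroni_threshold(0.01, 462), 4.6647, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.01, 462, override = 4.2), 4.2)
  expect_equal(bonferroni_threshold(0.05, 1), 1.3010, tolerance = 1e-4)
})

test_that("greedy cofactor selection respects the exclusion window", {
  prof <- data.frame(marker = sprintf("m%d", 1:6), chrom = "1",
                     pos = c(0, 5, 30, 35, 60, 90),
                     mlog10p = c(6, 7, 1, 2, 5, 3), tested = TRUE)
  # two super-threshold markers 5 cM apart: only the higher survives
  expect_equal(select_cofactors(prof, 4.2), c("m2", "m5"))
  # single peak
  expect_equal(select_cofactors(prof, 6.5), "m2")
  # nothing above the threshold
  expect_equal(select_cofactors(prof, 10), character(0))
  # masking uses the full 20 cM window on the same chromosome only
  prof$chrom <- c("1", "2", "1", "1", "1", "1")
  expect_equal(sort(select_cofactors(prof, 4.2)), c("m1", "m2", "m5"))
})

test_that("genome scans localize a strong QTL and keep marker order", {
  fx <- scan_fixture()
  prof <- genome_scan(fx$sim$y, "IBD.SQM_U", tensor = fx$tensor,
                      map = fx$sim$map, family = fx$sim$family)
  expect_equal(nrow(prof), nrow(fx$sim$map))
  expect_equal(prof$marker, fx$sim$map$marker)   # monotone map order
  expect_true(all(prof$tested))
  # the strongest signal sits at (or next to) the simulated a = 1.5 major
  top <- prof$marker[which.max(prof$mlog10p)]
  top_pos <- prof$pos[match(top, prof$marker)]
  expect_equal(prof$chrom[match(top, prof$marker)] %in% as.character(1:3), TRUE)
  tru <- fx$sim$architecture$major
  expect_true(any(tru$chrom == prof$chrom[match(top, prof$marker)] &
                    abs(tru$pos - top_pos) <= 10))
  expect_error(genome_scan(fx$sim$y[-1], "IBD.SQM_U", tensor = fx$tensor,
                           map = fx$sim$map), "does not match")
})

test_that("permuted phenotypes give empty scans at the Bonferroni level", {
  fx <- scan_fixture()
  set.seed(99)
  hits <- 0L
  for (r in 1:3) {
    yp <- sample(fx$sim$y)
    prof <- genome_scan(yp, "IBD.SQM_U", tensor = fx$tensor,
                        map = fx$sim$map, family = fx$sim$family)
    hits <- hits + sum(prof$mlog10p > 4.2, na.rm = TRUE)
  }
  expect_equal(hits, 0L)
})

test_that("cofactors are dropped inside their window, or markers skipped", {
  fx <- scan_fixture()
  cof <- fx$sim$architecture$major$marker[1]   # chr1 at 25 cM
  map1 <- fx$sim$map[fx$sim$map$chrom == "1", ]
  prof <- genome_scan(fx$sim$y, "IBD.MQM_F", tensor = fx$tensor, map = map1,
                      family = fx$sim$family, cofactors = cof)
  inwin <- abs(prof$pos - 25) <= 10
  expect_true(all(prof$cofactors_in_force[inwin] == ""))
  expect_true(all(prof$cofactors_in_force[!inwin] == cof))
  expect_true(all(prof$tested))
  # strict skip mode: in-window markers are not tested (cofactor itself kept)
  prof_s <- genome_scan(fx$sim$y, "IBD.MQM_F", tensor = fx$tensor, map = map1,
                        family = fx$sim$family, cofactors = cof,
                        window_mode = "skip")
  expect_true(all(!prof_s$tested[inwin & prof_s$marker != cof]))
  expect_true(all(prof_s$tested[!inwin]))
})

test_that("the MQM iteration terminates and stabilizes", {
  fx <- scan_fixture()
  # no super-threshold marker in round one: stops after a single round and
  # the profile equals the plain single-QTL scan profile
  set.seed(17)
  yp <- sample(fx$sim$y)
  rep0 <- mqm_iterate(yp, "IBD.MQM_F", tensor = fx$tensor, map = fx$sim$map,
                      family = fx$sim$family, threshold = 4.2)
  expect_equal(rep0$rounds, 1L)
  expect_true(rep0$stabilized)
  sqm <- genome_scan(yp, "IBD.SQM_F", tensor = fx$tensor, map = fx$sim$map,
                     family = fx$sim$family)
  expect_equal(rep0$profile$mlog10p, sqm$mlog10p, tolerance = 1e-6)

  # with signal: terminates, called QTLs pairwise >= 20 cM apart
  rep1 <- mqm_iterate(fx$sim$y, "IBD.MQM_F", tensor = fx$tensor,
                      map = fx$sim$map, family = fx$sim$family,
                      threshold = 4.2)
  expect_true(rep1$rounds <= 10L)
  q <- rep1$qtls
  if (nrow(q) > 1) for (cc in unique(q$chrom)) {
    pp <- sort(q$pos[q$chrom == cc])
    if (length(pp) > 1) expect_true(all(diff(pp) > 20))
  }
  # rescanning the stabilized configuration reproduces the profile
  final_cof <- rep1$cofactor_history[[rep1$rounds]]
  again <- genome_scan(fx$sim$y, "IBD.MQM_F", tensor = fx$tensor,
                       map = fx$sim$map, family = fx$sim$family,
                       cofactors = final_cof)
  expect_equal(again$mlog10p, rep1$profile$mlog10p, tolerance = 1e-6)
})

test_that("QTL success requires threshold and the 20 cM window", {
  prof <- data.frame(marker = c("a", "b", "c"), chrom = "3",
                     pos = c(36, 44, 69), mlog10p = c(2, 6, 3), tested = TRUE)
  truth <- data.frame(qtl = "simQTL3", chrom = "3", pos = 44)
  r1 <- call_qtls_and_success(prof, truth, threshold = 4.2)
  expect_true(r1$success); expect_equal(r1$distance, 0)
  # peak 8 cM away and significant: success at distance 8
  prof$mlog10p <- c(2, 3, 0); prof$pos <- c(52, 44, 69)
  prof$mlog10p[1] <- 6
  r2 <- call_qtls_and_success(prof, truth, threshold = 4.2)
  expect_true(r2$success); expect_equal(r2$distance, 8)
  # peak above threshold but 25 cM away: failure
  prof$pos <- c(69, 44, 90); prof$mlog10p <- c(6, 3, 0)
  r3 <- call_qtls_and_success(prof, truth, threshold = 4.2)
  expect_false(r3$success); expect_equal(r3$distance, 25)
  # nothing above threshold: failure
  prof$mlog10p <- c(1, 2, 1)
  expect_false(call_qtls_and_success(prof, truth, threshold = 4.2)$success)
})

test_that("IBS.Kin scans via the Wald test, exact and fast modes", {
  fx <- scan_fixture()
  map1 <- fx$sim$map[fx$sim$map$chrom == "1", ]
  prof <- genome_scan(fx$sim$y, "IBS.Kin", geno = fx$sim$geno, map = map1,
                      family = fx$sim$family, kinships = fx$kin)
  expect_true(any(prof$tested))
  top <- which.max(prof$mlog10p)
  expect_lt(abs(prof$pos[top] - 25), 10 + 1e-9)
  prof_f <- genome_scan(fx$sim$y, "IBS.Kin", geno = fx$sim$geno, map = map1,
                        family = fx$sim$family, kinships = fx$kin,
                        ibs_exact = FALSE)
  expect_gt(cor(prof$mlog10p, prof_f$mlog10p, use = "complete.obs"), 0.98)
})

test_that("BIC model selection penalizes spurious terms and returns argmin", {
  set.seed(91)
  n <- 80
  M1 <- random_predictors(n, 4)
  M0 <- random_predictors(n, 4)       # unrelated 'spurious cofactor'
  y <- drop(M1 %*% c(1, 1, -1, -1)) + rnorm(n)
  f_good <- ibdqtl:::fit_sqmu_joint(y, NULL, list(q1 = M1))
  f_extra <- ibdqtl:::fit_sqmu_joint(y, NULL, list(q1 = M1, q0 = M0))
  expect_gt(BIC(f_extra), BIC(f_good))

  fx <- scan_fixture()
  K <- vanraden_kinship(fx$sim$geno)
  mk <- fx$sim$architecture$major$marker[1]
  sel <- select_model_by_bic(
    fx$sim$y,
    qtl_sets = list(IBD.SQM_U = mk, IBD.Kin_F = mk),
    tensor = fx$tensor, family = fx$sim$family, kinship = K)
  expect_equal(sel$best, sel$table$model[which.min(sel$table$bic)])
  expect_equal(nrow(sel$table), 2L)
})
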