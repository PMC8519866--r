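# Shared fixtures and independent oracles for the test suite.

# small 5-chromosome map: 11 markers per chromosome at 5 cM spacing (0-50 cM)
tiny_map <- function(n_chr = 5, step = 5, len = 50) {
  marker <- character(0); chrom <- character(0); pos <- numeric(0)
  for (cc in seq_len(n_chr)) {
    p <- seq(0, len, by = step)
    marker <- c(marker, sprintf("T%dM%02d", cc, seq_along(p)))
    chrom <- c(chrom, rep(as.character(cc), length(p)))
    pos <- c(pos, p)
  }
  mpp_map(marker, chrom, pos)
}

tiny_sim_args <- function() {
  list(map = tiny_map(),
       majors = data.frame(chrom = as.character(1:3), pos = 25),
       chr4_grid = c(10, 30, 40))
}

# one moderately sized diallel dataset shared (and decoded) across tests
.shared <- new.env(parent = emptyenv())
shared_diallel <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_mpp("diallel", seed = 42)
    .shared$rho <- 1.9  # biparental F6 junction density (calibrated elsewhere)
    .shared$tensor <- ibd_decode(.shared$sim$geno, .shared$sim$founders,
                                 .shared$sim$map, .shared$sim$plan,
                                 rho = .shared$rho)
  }
  list(sim = .shared$sim, tensor = .shared$tensor, rho = .shared$rho)
}

# brute-force posterior decoding by enumeration over all state paths
enum_posterior <- function(hmm, geno) {
  map <- hmm$map
  S <- length(hmm$states)
  n <- nrow(geno)
  post <- array(NA_real_, c(n, nrow(map), S),
                dimnames = list(rownames(geno), map$marker, hmm$states))
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    Tn <- length(idx)
    d <- diff(map$pos[idx]) / 100
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
    trans <- lapply(d, function(dd) ibdqtl:::hmm_transition(hmm, dd))
    for (i in seq_len(n)) {
      E <- vapply(seq_len(Tn), function(t)
        ibdqtl:::hmm_emission(hmm, geno[i, map$marker[idx[t]]], idx[t])[1L, ],
        numeric(S))                         # S x Tn
      pw <- apply(paths, 1L, function(pth) {
        w <- hmm$pi[pth[1L]] * E[pth[1L], 1L]
        if (Tn > 1L) for (t in 2:Tn)
          w <- w * trans[[t - 1L]][pth[t - 1L], pth[t]] * E[pth[t], t]
        w
      })
      for (t in seq_len(Tn)) {
        marg <- vapply(seq_len(S), function(s) sum(pw[paths[, t] == s]),
                       numeric(1))
        post[i, idx[t], ] <- marg / sum(marg)
      }
    }
  }
  post
}

# mean silhouette width of a labelled 2-D embedding (euclidean distances)
silhouette_score <- function(X, labels) {
  labels <- as.factor(labels)
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(levels(labels)[levels(labels) != labels[i]],
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# build a random biparental-style predictor matrix (2 * origin indicator)
random_predictors <- function(n, P) {
  o <- sample.int(P, n, replace = TRUE)
  M <- matrix(0, n, P, dimnames = list(NULL, paste0("P", seq_len(P))))
  M[cbind(seq_len(n), o)] <- 2
  M
}
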