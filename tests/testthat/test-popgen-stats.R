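test_that("allele frequencies follow the called-chromosome definition", {
  g <- rbind(c(0, NA, 2), c(1, NA, NA), c(2, NA, 2))
  ds <- toy_dataset(g, cluster = rep("C1", 3))
  af <- allele_frequencies(ds)
  expect_equal(af$freq["C1", 1], 0.5)          # (0+1+2)/6
  expect_true(is.na(af$freq["C1", 2]))         # no calls at all
  expect_equal(af$freq["C1", 3], 1.0)
  expect_equal(af$called["C1", ], c(L001 = 6, L002 = 0, L003 = 4))
  ds2 <- ds
  ds2$samples$cluster_id <- NA
  expect_error(allele_frequencies(ds2), "grouping")
})

test_that("diversity statistics match their definitions on toy inputs", {
  ds <- toy_dataset(rbind(0, 2), cluster = c("C", "C"))
  d <- diversity_stats(ds)
  expect_equal(d$h_e, 0.5)
  expect_equal(d$h_o, 0)
  expect_equal(d$maf_mean, 0.5)
  expect_equal(d$n_polymorphic, 1)

  mono <- toy_dataset(rbind(2, 2), cluster = c("C", "C"))
  dm <- diversity_stats(mono)
  expect_equal(dm$h_e, 0)
  expect_equal(dm$h_o, 0)
  expect_equal(dm$n_polymorphic, 0)
})

test_that("diversity statistics equal a naive per-cell oracle on random matrices", {
  oracle <- function(g) {
    L <- ncol(g)
    he <- ho <- maf <- rep(NA_real_, L)
    npoly <- 0
    for (l in seq_len(L)) {
      col <- g[, l]
      called <- col[!is.na(col)]
      if (!length(called)) next
      p <- sum(called) / (2 * length(called))
      if (p > 0 && p < 1) npoly <- npoly + 1
      he[l] <- 2 * p * (1 - p)
      ho[l] <- mean(called == 1)
      maf[l] <- min(p, 1 - p)
    }
    list(n_polymorphic = npoly, h_e = mean(he, na.rm = TRUE),
         h_o = mean(ho, na.rm = TRUE), maf_mean = mean(maf, na.rm = TRUE),
         maf_sd = sd(maf, na.rm = TRUE))
  }
  set.seed(33)
  for (rep_i in 1:10) {
    n <- sample(2:6, 1); L <- sample(2:10, 1)
    g <- matrix(sample(c(0, 1, 2, NA), n * L, replace = TRUE,
                       prob = c(0.3, 0.25, 0.3, 0.15)), n, L)
    g[1, 1] <- 1  # ensure at least one call
    ds <- toy_dataset(g, cluster = rep("C", n))
    d <- diversity_stats(ds)
    o <- oracle(g)
    expect_equal(d$n_polymorphic, o$n_polymorphic)
    expect_equal(d$h_e, o$h_e, tolerance = 1e-9)
    expect_equal(d$h_o, o$h_o, tolerance = 1e-9)
    expect_equal(d$maf_mean, o$maf_mean, tolerance = 1e-9)
    expect_equal(d$maf_sd, o$maf_sd, tolerance = 1e-9)
  }
})

test_that("LD pruning removes one of a perfectly correlated pair and spares orthogonal loci", {
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(0, 2, 0, 2, 1, 1)  # essentially uncorrelated with x
  ds <- toy_dataset(cbind(x, x, y))
  res <- ld_prune(ds)
  # the duplicated pair has equal MAF: the later position goes
  expect_equal(res$removed, "L002")
  expect_setequal_chr(res$dataset$loci$locus_id, c("L001", "L003"))

  ortho <- toy_dataset(cbind(c(0, 2, 0, 2), c(0, 0, 2, 2)))
  expect_length(ld_prune(ortho)$removed, 0)
})

test_that("LD pruning matches an exhaustive greedy oracle and is idempotent", {
  set.seed(44)
  base <- matrix(rbinom(30 * 4, 2, 0.5), 30, 4)
  noisy <- function(v, k) {
    w <- v
    flip <- sample(length(v), k)
    w[flip] <- sample(0:2, k, replace = TRUE)
    w
  }
  g <- cbind(base[, 1], noisy(base[, 1], 3), base[, 2], noisy(base[, 2], 25),
             base[, 3], noisy(base[, 3], 1), base[, 4], noisy(base[, 4], 8),
             rbinom(30, 2, 0.4), rbinom(30, 2, 0.6))
  ds <- toy_dataset(g)
  res <- ld_prune(ds, r2_max = 0.5, window_snps = 10, step_snps = 10)

  # oracle: repeat pair sweeps in position order until stable
  maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  keep <- rep(TRUE, ncol(g))
  repeat {
    changed <- FALSE
    for (a in 1:(ncol(g) - 1)) for (b in (a + 1):ncol(g)) {
      if (!keep[a] || !keep[b]) next
      r2 <- suppressWarnings(cor(g[, a], g[, b], use = "pairwise.complete.obs"))^2
      if (is.na(r2) || r2 <= 0.5) next
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else b
      keep[drop] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  expect_setequal_chr(res$dataset$loci$locus_id, ds$loci$locus_id[keep])

  again <- ld_prune(res$dataset, r2_max = 0.5, window_snps = 10, step_snps = 10)
  expect_length(again$removed, 0)
})

test_that("unsorted loci are rejected with advice to sort", {
  ds <- toy_dataset(matrix(rbinom(40, 2, 0.5), 10, 4),
                    position = c(4000, 1000, 2000, 3000))
  expect_error(ld_prune(ds), "sort")
})

test_that("single-locus theta matches hand-evaluated Weir-Cockerham components", {
  # pop1: 0,1,1,2 (n=4, p=0.5, h=0.5); pop2: 2,2,1,2,2 (n=5, p=0.9, h=0.2)
  g <- matrix(c(0, 1, 1, 2, 2, 2, 1, 2, 2), 9, 1)
  ds <- toy_dataset(g, cluster = c(rep("P1", 4), rep("P2", 5)))
  fst <- pairwise_fst(ds)

  n1 <- 4; n2 <- 5; p1 <- 0.5; p2 <- 0.9; h1 <- 0.5; h2 <- 0.2
  n_bar <- (n1 + n2) / 2
  n_c <- 2 * n_bar - (n1^2 + n2^2) / (2 * n_bar)
  p_bar <- (n1 * p1 + n2 * p2) / (2 * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / n_bar
  h_bar <- (n1 * h1 + n2 * h2) / (2 * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 / 2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 / 2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  expect_equal(fst$values["P1", "P2"], a / (a + b + cc), tolerance = 1e-12)
  expect_equal(fst$values["P1", "P1"], 0)
  expect_equal(fst$values, t(fst$values))
})

test_that("theta is ~0 under the null and 1 at fixed differences", {
  f <- simulate_frequencies(2000, c(X = 0.2), seed = 3)
  anc <- matrix(rep(c(1), 50), 50, 1)
  ds <- simulate_genotypes(f, anc, seed = 4)
  ds$samples$cluster_id <- rep(c("A", "B"), each = 25)
  fst <- pairwise_fst(ds)
  expect_lt(abs(fst$values["A", "B"]), 0.01)

  gfix <- rbind(matrix(0, 25, 50), matrix(2, 25, 50))
  dfix <- toy_dataset(gfix, cluster = rep(c("A", "B"), each = 25))
  expect_equal(pairwise_fst(dfix)$values["A", "B"], 1, tolerance = 1e-3)
})

test_that("theta is invariant under global allele relabeling", {
  sc <- two_pop_dataset(n1 = 15, n2 = 15, L = 300, seed = 12,
                        missing_rate = 0.05)
  ds <- sc$dataset
  flipped <- ds
  flipped$genotypes <- 2 - ds$genotypes
  expect_equal(pairwise_fst(ds)$values, pairwise_fst(flipped)$values,
               tolerance = 1e-12)
})

test_that("rank test reproduces exact enumeration and degenerate cases", {
  fst <- fake_fst(c(1, 2, 3), c(4, 5, 6))
  res <- compare_fst_distributions(fst, c("a1", "a2", "a3"),
                                   c("b1", "b2", "b3"))
  # all 3 group-a values rank below group-b: U = 0; of the choose(6,3) = 20
  # equally likely arrangements only 1 is as extreme each way -> p = 0.1
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_lt(res$statistic, 0)
  expect_equal(res$n_a, 3)
  expect_equal(res$n_b, 3)

  same <- fake_fst(c(1, 2, 3), c(1, 2, 3))
  expect_gt(compare_fst_distributions(same, c("a1", "a2", "a3"),
                                      c("b1", "b2", "b3"))$p_value, 0.9)
  expect_error(compare_fst_distributions(fst, c("a1", "a2"), c("a2", "b1")),
               "overlap")
})

test_that("the rank test detects stochastically larger wild differentiation", {
  set.seed(55)
  reject <- 0
  for (i in 1:200) {
    wild <- rnorm(10, 0.16, 0.03)
    dom <- rnorm(10, 0.10, 0.03)
    fst <- fake_fst(wild, dom)
    res <- compare_fst_distributions(fst, paste0("a", 1:5), paste0("b", 1:5))
    if (res$p_value < 0.05) reject <- reject + 1
  }
  expect_gt(reject / 200, 0.9)
})

test_that("expected exceeds observed heterozygosity under inbreeding but not HWE", {
  f <- simulate_frequencies(1500, c(X = 0.1), seed = 8)
  anc <- matrix(1, 40, 1)
  hwe <- simulate_genotypes(f, anc, seed = 9)
  hwe$samples$cluster_id <- "X"
  d_hwe <- diversity_stats(hwe)
  expect_lt(abs(d_hwe$h_e - d_hwe$h_o), 0.02)

  # inbreeding: replace a third of heterozygotes by homozygotes
  g <- hwe$genotypes
  set.seed(10)
  het <- which(g == 1)
  flip <- sample(het, length(het) / 3)
  g[flip] <- sample(c(0, 2), length(flip), replace = TRUE)
  inb <- toy_dataset(g, cluster = rep("X", nrow(g)))
  d_inb <- diversity_stats(inb)
  expect_gt(d_inb$h_e - d_inb$h_o, 0.02)
})
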