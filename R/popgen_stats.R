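resolve_grouping <- function(dataset, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- stats::setNames(as.character(dataset$samples$cluster_id),
                                dataset$samples$sample_id)
  }
  grouping <- grouping[dataset$samples$sample_id]
  if (!length(grouping) || all(is.na(grouping))) {
    stop("empty grouping: supply a sample -> cluster map or set cluster_id",
         call. = FALSE)
  }
  if (anyNA(grouping)) {
    stop("grouping missing for samples: ",
         paste(utils::head(dataset$samples$sample_id[is.na(grouping)], 5),
               collapse = ", "), call. = FALSE)
  }
  grouping
}

#' Per-cluster allele frequencies
#'
#' B-allele frequency per cluster and locus, computed over called
#' genotypes only, together with the number of called chromosomes.
#' Clusters with no calls at a locus have frequency `NA` there.
#'
#' @param dataset a [genotype_dataset()].
#' @param grouping named character vector mapping `sample_id` to cluster;
#'   defaults to the sample registry's `cluster_id`.
#' @return list with matrices `freq` and `called` (clusters x loci).
#' @export
allele_frequencies <- function(dataset, grouping = NULL) {
  grouping <- resolve_grouping(dataset, grouping)
  clusters <- unique(grouping)
  g <- dataset$genotypes
  freq <- called <- matrix(NA_real_, length(clusters), ncol(g),
                           dimnames = list(clusters, colnames(g)))
  for (cl in clusters) {
    rows <- g[grouping == cl, , drop = FALSE]
    ncall <- colSums(!is.na(rows))
    called[cl, ] <- 2 * ncall
    freq[cl, ] <- ifelse(ncall > 0, colSums(rows, na.rm = TRUE) / (2 * ncall), NA)
  }
  list(freq = freq, called = called)
}

#' Per-cluster diversity statistics
#'
#' For each cluster: number of polymorphic loci, mean expected
#' heterozygosity (per-locus `2p(1-p)`), mean observed heterozygosity
#' (per-locus fraction of heterozygous calls), and the mean and standard
#' deviation of the minor-allele frequency. Means are taken over all loci
#' in the panel, so monomorphic loci contribute 0; loci with no calls in
#' a cluster are excluded from that cluster's means.
#'
#' @inheritParams allele_frequencies
#' @param maf_polymorphic_only average MAF over polymorphic loci only
#'   (default `FALSE`: over the whole panel).
#' @param small_sample_correction multiply per-locus He by `2n/(2n-1)`
#'   (default `FALSE`).
#' @return data frame with one row per cluster: `cluster_id`,
#'   `sample_size`, `n_polymorphic`, `h_e`, `h_o`, `maf_mean`, `maf_sd`.
#' @export
diversity_stats <- function(dataset, grouping = NULL,
                            maf_polymorphic_only = FALSE,
                            small_sample_correction = FALSE) {
  grouping <- resolve_grouping(dataset, grouping)
  af <- allele_frequencies(dataset, grouping)
  clusters <- rownames(af$freq)
  g <- dataset$genotypes
  out <- data.frame(cluster_id = clusters, sample_size = NA_integer_,
                    n_polymorphic = NA_integer_, h_e = NA_real_,
                    h_o = NA_real_, maf_mean = NA_real_, maf_sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    rows <- g[grouping == cl, , drop = FALSE]
    if (all(is.na(rows))) stop("cluster ", cl, " has no called genotypes",
                               call. = FALSE)
    p <- af$freq[cl, ]
    n_chr <- af$called[cl, ]
    he <- 2 * p * (1 - p)
    if (small_sample_correction) {
      he <- ifelse(n_chr > 1, he * n_chr / (n_chr - 1), he)
    }
    ho <- ifelse(colSums(!is.na(rows)) > 0,
                 colMeans(rows == 1, na.rm = TRUE), NA)
    maf <- pmin(p, 1 - p)
    maf_set <- if (maf_polymorphic_only) maf[!is.na(p) & p > 0 & p < 1] else maf
    out$sample_size[i] <- nrow(rows)
    out$n_polymorphic[i] <- sum(p > 0 & p < 1, na.rm = TRUE)
    out$h_e[i] <- mean(he, na.rm = TRUE)
    out$h_o[i] <- mean(ho, na.rm = TRUE)
    out$maf_mean[i] <- mean(maf_set, na.rm = TRUE)
    out$maf_sd[i] <- stats::sd(maf_set, na.rm = TRUE)
  }
  out
}

#' Prune loci in linkage disequilibrium
#'
#' Sliding-window pruning on the squared Pearson correlation of dosage
#' vectors (pairwise-complete samples). Within each window, every pair
#' with `r^2` above `r2_max` is resolved greedily by removing the locus
#' with the smaller minor-allele frequency (ties broken toward the later
#' map position); the window then advances by `step_snps`. Sweeps repeat
#' until no locus is removed, so the operation is idempotent.
#'
#' @param dataset a [genotype_dataset()] with loci sorted by chromosome
#'   and position.
#' @param r2_max maximum tolerated squared correlation (default 0.5;
#'   pairs with `r^2 > r2_max` are pruned).
#' @param window_snps window width in SNPs (default 50).
#' @param step_snps window step in SNPs (default 5).
#' @return list with elements `dataset` (pruned) and `removed`
#'   (character vector of removed locus ids).
#' @export
ld_prune <- function(dataset, r2_max = 0.5, window_snps = 50, step_snps = 5) {
  loci <- dataset$loci
  ord <- order(loci$chromosome, loci$position_bp)
  if (!identical(ord, seq_len(nrow(loci)))) {
    stop("loci must be sorted by chromosome and position; ",
         "sort the dataset before pruning", call. = FALSE)
  }
  g <- dataset$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, ncol(g))

  prune_window <- function(win) {
    cc <- suppressWarnings(stats::cor(g[, win, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    r2 <- cc^2
    for (a in seq_along(win)) {
      for (b in seq_along(win)) {
        if (b <= a) next
        ia <- win[a]; ib <- win[b]
        if (!keep[ia] || !keep[ib]) next
        if (is.na(r2[a, b]) || r2[a, b] <= r2_max) next
        drop <- if (maf[ia] < maf[ib]) ia
                else if (maf[ib] < maf[ia]) ib
                else ib  # equal MAF: drop the later map position
        keep[drop] <<- FALSE
      }
    }
  }

  repeat {
    before <- sum(keep)
    for (chr in unique(loci$chromosome)) {
      repeat_idx <- which(keep & loci$chromosome == chr)
      if (length(repeat_idx) < 2) next
      start <- 1L
      while (start <= length(repeat_idx)) {
        idx <- which(keep & loci$chromosome == chr)
        if (start > length(idx)) break
        win <- idx[start:min(start + window_snps - 1L, length(idx))]
        if (length(win) >= 2) prune_window(win)
        start <- start + step_snps
      }
    }
    if (sum(keep) == before) break
  }
  list(dataset = subset_dataset(dataset, locus_ids = loci$locus_id[keep]),
       removed = loci$locus_id[!keep])
}

# Weir-Cockerham (1984) two-population variance components at one locus.
# n1, n2: called sample sizes; p1, p2: B-allele frequencies;
# h1, h2: observed heterozygote fractions. Returns c(a, b, c).
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  n_bar <- (n1 + n2) / 2
  if (n_bar <= 1) return(c(NA_real_, NA_real_, NA_real_))
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_comp <- h_bar / 2
  c(a, b, c_comp)
}

#' Pairwise Weir-Cockerham F_ST between clusters
#'
#' Multilocus theta for every cluster pair: the ratio of summed
#' among-population variance components to summed total components
#' (`sum(a) / sum(a + b + c)`), over loci polymorphic within the pair.
#' Small negative multilocus values are reported as computed. Pairs
#' sharing no usable loci get `NA`.
#'
#' @inheritParams allele_frequencies
#' @return object of class `fst_matrix`: list with `cluster_ids` and the
#'   symmetric `values` matrix (zero diagonal).
#' @export
pairwise_fst <- function(dataset, grouping = NULL) {
  grouping <- resolve_grouping(dataset, grouping)
  clusters <- unique(grouping)
  sizes <- table(grouping)
  if (any(sizes < 2)) {
    stop("every cluster needs at least 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  g <- dataset$genotypes
  vals <- matrix(0, length(clusters), length(clusters),
                 dimnames = list(clusters, clusters))
  for (i in seq_along(clusters)) {
    gi <- g[grouping == clusters[i], , drop = FALSE]
    ni <- colSums(!is.na(gi))
    pi_ <- ifelse(ni > 0, colSums(gi, na.rm = TRUE) / (2 * ni), NA)
    hi <- ifelse(ni > 0, colMeans(gi == 1, na.rm = TRUE), NA)
    for (j in seq_along(clusters)) {
      if (j <= i) next
      gj <- g[grouping == clusters[j], , drop = FALSE]
      nj <- colSums(!is.na(gj))
      pj <- ifelse(nj > 0, colSums(gj, na.rm = TRUE) / (2 * nj), NA)
      hj <- ifelse(nj > 0, colMeans(gj == 1, na.rm = TRUE), NA)
      p_pool <- (2 * ni * pi_ + 2 * nj * pj) / (2 * ni + 2 * nj)
      use <- which(ni > 0 & nj > 0 & !is.na(p_pool) &
                     p_pool > 0 & p_pool < 1)
      if (!length(use)) {
        vals[i, j] <- vals[j, i] <- NA_real_
        next
      }
      comps <- vapply(use, function(l) {
        wc_components(ni[l], nj[l], pi_[l], pj[l], hi[l], hj[l])
      }, numeric(3))
      num <- sum(comps[1, ], na.rm = TRUE)
      den <- sum(colSums(comps), na.rm = TRUE)
      vals[i, j] <- vals[j, i] <- if (den == 0) NA_real_ else num / den
    }
  }
  structure(list(cluster_ids = clusters, values = vals), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Weir-Cockerham F_ST (", length(x$cluster_ids), " clusters)\n",
      sep = "")
  print(round(x$values, digits))
  invisible(x)
}

upper_values <- function(fst, group) {
  idx <- match(group, fst$cluster_ids)
  if (anyNA(idx)) {
    stop("unknown cluster: ", paste(group[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  sub <- fst$values[idx, idx, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Compare within-group F_ST distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the within-group
#' pairwise F_ST values of two disjoint cluster groups. The p-value is
#' exact for small untied samples and otherwise uses the normal
#' approximation; the reported statistic is the tie-corrected
#' normal-approximation z.
#'
#' @param fst an `fst_matrix` from [pairwise_fst()].
#' @param group_a,group_b disjoint cluster id vectors; each must yield at
#'   least one within-group pair.
#' @return list with `statistic` (z), `p_value`, `n_a`, `n_b`.
#' @export
compare_fst_distributions <- function(fst, group_a, group_b) {
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "), call. = FALSE)
  }
  va <- upper_values(fst, group_a)
  vb <- upper_values(fst, group_b)
  if (!length(va) || !length(vb)) {
    stop("each group needs at least one within-group pair", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
  # tie-corrected normal-approximation z for the U statistic
  na <- length(va); nb <- length(vb)
  u <- unname(wt$statistic)
  ranks <- rank(c(va, vb))
  ties <- table(ranks)
  n <- na + nb
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  list(statistic = z, p_value = unname(wt$p.value), n_a = na, n_b = nb)
}
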