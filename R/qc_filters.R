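new_qc_report <- function(samples_removed_callrate = 0L,
                          loci_removed_missingness = 0L,
                          pairs_flagged_related = 0L,
                          samples_removed_related = 0L,
                          samples_removed_equalization = 0L,
                          seed = NA_integer_) {
  structure(list(samples_removed_callrate = samples_removed_callrate,
                 loci_removed_missingness = loci_removed_missingness,
                 pairs_flagged_related = pairs_flagged_related,
                 samples_removed_related = samples_removed_related,
                 samples_removed_equalization = samples_removed_equalization,
                 seed = seed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat("  samples removed (call rate):   ", x$samples_removed_callrate, "\n")
  cat("  loci removed (missingness):    ", x$loci_removed_missingness, "\n")
  cat("  related pairs flagged:         ", x$pairs_flagged_related, "\n")
  cat("  samples removed (relatedness): ", x$samples_removed_related, "\n")
  cat("  samples removed (equalization):", x$samples_removed_equalization, "\n")
  invisible(x)
}

sample_call_rates <- function(dataset) rowMeans(!is.na(dataset$genotypes))

#' Filter samples and loci on call rate
#'
#' Samples with a call rate at or below `sample_min_call` are removed
#' first; then loci whose missing fraction among the retained samples is
#' at or above `locus_max_missing` are removed. The order is fixed:
#' sample filter, then locus filter.
#'
#' @param dataset a [genotype_dataset()].
#' @param sample_min_call samples are kept when call rate is strictly
#'   greater than this fraction (default 0.9).
#' @param locus_max_missing loci are kept when their missing fraction is
#'   strictly below this (default 0.1).
#' @return list with elements `dataset` and `report` (a QC report).
#' @export
filter_call_rate <- function(dataset, sample_min_call = 0.9,
                             locus_max_missing = 0.1) {
  stopifnot(sample_min_call > 0, sample_min_call <= 1,
            locus_max_missing > 0, locus_max_missing <= 1)
  cr <- sample_call_rates(dataset)
  keep_s <- cr > sample_min_call
  if (!any(keep_s)) stop("empty dataset after QC", call. = FALSE)
  ds <- subset_dataset(dataset, sample_ids = dataset$samples$sample_id[keep_s])
  miss_l <- colMeans(is.na(ds$genotypes))
  keep_l <- miss_l < locus_max_missing
  ds <- subset_dataset(ds, locus_ids = ds$loci$locus_id[keep_l])
  list(dataset = ds,
       report = new_qc_report(samples_removed_callrate = sum(!keep_s),
                              loci_removed_missingness = sum(!keep_l)))
}

#' Estimate pairwise identity-by-descent sharing
#'
#' Method-of-moments PI_HAT from identity-by-state counts and sample
#' allele frequencies: for each pair the observed IBS 0/1/2 counts are
#' compared with their expectations given IBD state, solving sequentially
#' for P(IBD = 0, 1, 2); `pi_hat = P(IBD=1)/2 + P(IBD=2)`, clamped to
#' \[0, 1\]. Loci with minor-allele frequency below `maf_min` (estimated
#' over the whole dataset) are excluded.
#'
#' @param dataset a [genotype_dataset()] with at least two samples.
#' @param maf_min minimum minor-allele frequency of loci entering the
#'   computation (default 0.05).
#' @return data frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `ibs0`, `ibs1`, `ibs2` (proportions), `pi_hat`.
#' @export
estimate_ibd <- function(dataset, maf_min = 0.05) {
  g <- dataset$genotypes
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  use <- !is.na(maf) & maf >= maf_min
  if (sum(use) < 50) {
    warning("fewer than 50 usable loci; IBD estimates are unstable",
            call. = FALSE)
  }
  g <- g[, use, drop = FALSE]
  p <- p[use]
  q <- 1 - p
  # per-locus expected IBS-state probabilities given IBD state
  e00 <- 2 * p^2 * q^2
  e10 <- 4 * p^3 * q + 4 * p * q^3
  e20 <- p^4 + q^4 + 4 * p^2 * q^2
  e11 <- 2 * p * q
  e21 <- p^2 + q^2

  ids <- dataset$samples$sample_id
  pairs <- utils::combn(n, 2)
  out <- data.frame(sample_i = ids[pairs[1, ]], sample_j = ids[pairs[2, ]],
                    ibs0 = NA_real_, ibs1 = NA_real_, ibs2 = NA_real_,
                    pi_hat = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    gi <- g[pairs[1, k], ]
    gj <- g[pairs[2, k], ]
    ok <- !is.na(gi) & !is.na(gj)
    L <- sum(ok)
    if (L == 0) next
    d <- abs(gi[ok] - gj[ok])
    n0 <- sum(d == 2); n1 <- sum(d == 1); n2 <- sum(d == 0)
    E00 <- sum(e00[ok]); E10 <- sum(e10[ok]); E20 <- sum(e20[ok])
    E11 <- sum(e11[ok]); E21 <- sum(e21[ok])
    z0 <- n0 / E00
    z1 <- (n1 - z0 * E10) / E11
    z2 <- (n2 - z0 * E20 - z1 * E21) / L
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    z <- z / sum(z)
    out$ibs0[k] <- n0 / L
    out$ibs1[k] <- n1 / L
    out$ibs2[k] <- n2 / L
    out$pi_hat[k] <- min(max(z[2] / 2 + z[3], 0), 1)
  }
  out
}

#' Remove one member of each closely related pair
#'
#' Greedy removal: while any retained pair exceeds the PI_HAT threshold,
#' the pair with the highest PI_HAT is resolved by removing its member
#' with the lower call rate (ties broken toward the lexicographically
#' larger sample id). When removing the preferred member would empty its
#' population while the alternative would not, the alternative is
#' removed instead.
#'
#' @param dataset a [genotype_dataset()].
#' @param ibd output of [estimate_ibd()] on this dataset.
#' @param pi_hat_threshold pairs at or above this PI_HAT are resolved
#'   (default 0.45, flagging first-order relatives).
#' @return list with elements `dataset` and `report`.
#' @export
remove_related <- function(dataset, ibd, pi_hat_threshold = 0.45) {
  flagged <- ibd[!is.na(ibd$pi_hat) & ibd$pi_hat >= pi_hat_threshold, ,
                 drop = FALSE]
  flagged <- flagged[order(-flagged$pi_hat, flagged$sample_i, flagged$sample_j), ,
                     drop = FALSE]
  cr <- stats::setNames(sample_call_rates(dataset), dataset$samples$sample_id)
  pop <- stats::setNames(as.character(dataset$samples$population_id),
                         dataset$samples$sample_id)
  retained <- dataset$samples$sample_id
  removed <- character(0)

  repeat {
    active <- flagged$sample_i %in% retained & flagged$sample_j %in% retained
    if (!any(active)) break
    pair <- flagged[which(active)[1], ]
    i <- pair$sample_i; j <- pair$sample_j
    drop_id <- if (cr[i] < cr[j]) i
               else if (cr[j] < cr[i]) j
               else max(i, j)
    keep_id <- setdiff(c(i, j), drop_id)
    # avoid emptying a population when the other member's removal would not
    pop_left <- function(id) {
      sum(pop[retained] == pop[id], na.rm = TRUE) - 1L
    }
    if (!is.na(pop[drop_id]) && pop_left(drop_id) == 0 &&
        !is.na(pop[keep_id]) && pop_left(keep_id) > 0) {
      drop_id <- keep_id
    }
    retained <- setdiff(retained, drop_id)
    removed <- c(removed, drop_id)
  }
  ds <- subset_dataset(dataset, sample_ids = retained)
  list(dataset = ds,
       report = new_qc_report(pairs_flagged_related = nrow(flagged),
                              samples_removed_related = length(removed)),
       removed = removed)
}

#' Randomly equalize population sample sizes
#'
#' Populations larger than `max_n` are randomly downsampled to exactly
#' `max_n` with a seeded RNG; smaller populations are untouched. The
#' retained set is deterministic for a fixed seed.
#'
#' @param dataset a [genotype_dataset()] with `population_id` set.
#' @param max_n maximum retained sample size per population (default 25).
#' @param seed integer RNG seed.
#' @return list with elements `dataset` and `report`.
#' @export
equalize_populations <- function(dataset, max_n = 25, seed) {
  pops <- dataset$samples$population_id
  if (anyNA(pops)) stop("population_id must be set for all samples", call. = FALSE)
  ids <- dataset$samples$sample_id
  keep <- withr::with_seed(seed, {
    kept <- character(0)
    for (p in unique(pops)) {
      members <- ids[pops == p]
      if (length(members) > max_n) members <- sample(members, max_n)
      kept <- c(kept, members)
    }
    kept
  })
  retained <- ids[ids %in% keep]  # preserve original order
  ds <- subset_dataset(dataset, sample_ids = retained)
  list(dataset = ds,
       report = new_qc_report(samples_removed_equalization = length(ids) - length(retained),
                              seed = as.integer(seed)))
}

#' Run the full QC chain
#'
#' Call-rate filtering, relatedness removal and population equalization
#' in sequence, returning the filtered dataset and a combined report.
#'
#' @inheritParams filter_call_rate
#' @inheritParams estimate_ibd
#' @inheritParams remove_related
#' @inheritParams equalize_populations
#' @return list with elements `dataset` and `report`.
#' @export
apply_qc <- function(dataset, sample_min_call = 0.9, locus_max_missing = 0.1,
                     maf_min = 0.05, pi_hat_threshold = 0.45, max_n = 25,
                     seed = 1L) {
  step1 <- filter_call_rate(dataset, sample_min_call, locus_max_missing)
  ibd <- estimate_ibd(step1$dataset, maf_min = maf_min)
  step2 <- remove_related(step1$dataset, ibd, pi_hat_threshold)
  step3 <- equalize_populations(step2$dataset, max_n = max_n, seed = seed)
  report <- new_qc_report(
    samples_removed_callrate = step1$report$samples_removed_callrate,
    loci_removed_missingness = step1$report$loci_removed_missingness,
    pairs_flagged_related = step2$report$pairs_flagged_related,
    samples_removed_related = step2$report$samples_removed_related,
    samples_removed_equalization = step3$report$samples_removed_equalization,
    seed = as.integer(seed))
  list(dataset = step3$dataset, report = report)
}
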