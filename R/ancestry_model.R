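EPS_PI <- 1e-9

#' Binomial genotype log-likelihood of an admixture configuration
#'
#' For sample i at called locus l with dosage g, the model is
#' `g ~ Binomial(2, pi_il)` with `pi_il = sum_k Q[i,k] * F[k,l]`. Returns
#' `sum(g * log(pi) + (2 - g) * log(1 - pi))` over called cells, with the
#' constant binomial coefficients omitted and `pi` clamped to
#' `[1e-9, 1 - 1e-9]`.
#'
#' @param dataset a [genotype_dataset()].
#' @param Q samples x K ancestry matrix; rows must sum to 1.
#' @param F_mat K x loci cluster allele-frequency matrix in \[0, 1\].
#' @return log-likelihood (numeric scalar).
#' @export
admixture_loglik <- function(dataset, Q, F_mat) {
  Q <- as.matrix(Q); F_mat <- as.matrix(F_mat)
  g <- dataset$genotypes
  if (nrow(Q) != nrow(g) || ncol(Q) != nrow(F_mat) || ncol(F_mat) != ncol(g)) {
    stop("dimension mismatch between dataset, Q and F", call. = FALSE)
  }
  if (any(abs(rowSums(Q) - 1) > 1e-6)) {
    stop("Q rows must sum to 1", call. = FALSE)
  }
  pi_ <- Q %*% F_mat
  pi_ <- pmin(pmax(pi_, EPS_PI), 1 - EPS_PI)
  ok <- !is.na(g)
  sum(g[ok] * log(pi_[ok]) + (2 - g[ok]) * log(1 - pi_[ok]))
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood ancestry decomposition into K clusters under the
#' binomial genotype likelihood, using alternating multiplicative EM
#' updates on Q (per-sample ancestry fractions) and F (per-cluster
#' allele frequencies). Initialization is a seeded flat-Dirichlet Q and
#' Uniform(0,1) F unless an explicit `init` is supplied. Iteration stops
#' when the log-likelihood gain drops below `tol` or at `max_iter`.
#' Cluster labels are canonicalized by descending total Q mass.
#'
#' @param dataset a [genotype_dataset()].
#' @param K number of ancestry clusters (1 <= K <= samples).
#' @param seed integer RNG seed for the initialization.
#' @param max_iter iteration cap (default 2000).
#' @param tol minimum log-likelihood gain to continue (default 1e-6).
#' @param init optional list with elements `Q` and `F` overriding the
#'   random initialization.
#' @return object of class `ancestry_fit`: `K`, `Q`, `F`,
#'   `loglik_trace` (non-decreasing), `converged`, `seed`.
#' @export
fit_admixture <- function(dataset, K, seed = 1L, max_iter = 2000,
                          tol = 1e-6, init = NULL) {
  g <- dataset$genotypes
  n <- nrow(g); L <- ncol(g)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K cannot exceed the sample count", call. = FALSE)
  M <- !is.na(g)
  if (any(rowSums(M) == 0)) stop("sample with no called genotypes", call. = FALSE)
  G0 <- ifelse(M, g, 0)
  H <- ifelse(M, 2 - g, 0)
  two_Li <- 2 * rowSums(M)

  if (is.null(init)) {
    init <- withr::with_seed(seed, {
      Qr <- matrix(stats::rgamma(n * K, shape = 1), n, K)
      list(Q = Qr / rowSums(Qr),
           F = matrix(stats::runif(K * L), K, L))
    })
  }
  Q <- as.matrix(init$Q)
  F_mat <- pmin(pmax(as.matrix(init$F), 1e-6), 1 - 1e-6)

  trace <- numeric(max_iter)
  converged <- FALSE
  ll_prev <- -Inf
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    pi_c <- pmin(pmax(Q %*% F_mat, EPS_PI), 1 - EPS_PI)
    ll <- sum(G0 * log(pi_c)) + sum(H * log(1 - pi_c))
    n_iter <- iter
    trace[iter] <- ll
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # E/M step in closed matrix form: with U = g/pi and V = (2-g)/(1-pi),
    # rowSums(U * (q_k o f_k)) = q_k * (U f_k) etc., so the per-cluster
    # sums collapse into dense matrix products.
    U <- G0 / pi_c
    V <- H / (1 - pi_c)
    q_num <- Q * (U %*% t(F_mat) + V %*% t(1 - F_mat))
    f_num <- F_mat * t(crossprod(U, Q))
    f_den <- (1 - F_mat) * t(crossprod(V, Q))
    Q <- q_num / two_Li
    Q <- Q / rowSums(Q)  # guard against drift
    tot <- f_num + f_den
    F_new <- ifelse(tot > 0, f_num / tot, F_mat)
    F_mat <- pmin(pmax(F_new, 1e-6), 1 - 1e-6)
  }
  trace <- trace[seq_len(n_iter)]

  ord <- order(-colSums(Q))
  Q <- Q[, ord, drop = FALSE]
  F_mat <- F_mat[ord, , drop = FALSE]
  labels <- paste0("K", seq_len(K))
  dimnames(Q) <- list(dataset$samples$sample_id, labels)
  dimnames(F_mat) <- list(labels, dataset$loci$locus_id)
  structure(list(K = K, Q = Q, F = F_mat, loglik_trace = trace,
                 converged = converged, seed = as.integer(seed)),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry_fit: K =", x$K, "|", nrow(x$Q), "samples |",
      length(x$loglik_trace), "EM iterations |",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  final log-likelihood:", sprintf("%.2f", utils::tail(x$loglik_trace, 1)), "\n")
  invisible(x)
}

#' Masked-genotype cross-validation error for one K
#'
#' Partitions called genotype cells into `folds` random folds; each fold
#' is masked in turn, the model refitted on the remainder, and masked
#' dosages predicted as `2 * pi_hat`. The error is the mean squared
#' deviation `(g - 2 pi_hat)^2` over masked cells, averaged across folds.
#'
#' @inheritParams fit_admixture
#' @param folds number of folds (>= 2; default 10).
#' @param max_iter,tol EM settings for the per-fold fits.
#' @return list with `K`, `folds`, `error`, `seed`.
#' @export
cross_validation_error <- function(dataset, K, folds = 10, seed = 1L,
                                   max_iter = 500, tol = 1e-5) {
  if (folds < 2) stop("folds must be >= 2 (masking nothing is disallowed)",
                      call. = FALSE)
  g <- dataset$genotypes
  cells <- which(!is.na(g))
  if (length(cells) < folds) stop("fewer called cells than folds", call. = FALSE)
  assign <- withr::with_seed(seed, sample(rep(seq_len(folds),
                                              length.out = length(cells))))
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    masked <- cells[assign == f]
    if (!length(masked)) stop("fold ", f, " has zero cells", call. = FALSE)
    ds <- dataset
    ds$genotypes[masked] <- NA
    if (any(rowSums(!is.na(ds$genotypes)) == 0)) {
      stop("masking emptied a sample; use fewer folds or more loci",
           call. = FALSE)
    }
    fit <- fit_admixture(ds, K, seed = seed + f, max_iter = max_iter, tol = tol)
    pred <- 2 * pmin(pmax(fit$Q %*% fit$F, 0), 1)
    errs[f] <- mean((g[masked] - pred[masked])^2)
  }
  list(K = K, folds = folds, error = mean(errs), seed = as.integer(seed))
}

#' Choose K by lowest cross-validation error
#'
#' @param errors list of results from [cross_validation_error()].
#' @return the K with minimal error; ties resolve to the smallest K.
#' @export
select_k <- function(errors) {
  if (!length(errors)) stop("need at least one CV entry", call. = FALSE)
  ks <- vapply(errors, `[[`, numeric(1), "K")
  es <- vapply(errors, `[[`, numeric(1), "error")
  ord <- order(es, ks)
  ks[ord[1]]
}

#' Match inferred cluster labels to a reference ancestry matrix
#'
#' Finds the cluster permutation minimizing the total absolute
#' difference between `Q_hat` (columns permuted) and `Q_ref`, by
#' exhaustive search over K! permutations (K <= 8).
#'
#' @param Q_hat,Q_ref samples x K ancestry matrices on the same samples.
#' @return list with `perm` (column order for `Q_hat`), `Q_matched`, and
#'   `rmse` of the matched matrices.
#' @export
match_cluster_labels <- function(Q_hat, Q_ref) {
  Q_hat <- as.matrix(Q_hat); Q_ref <- as.matrix(Q_ref)
  K <- ncol(Q_hat)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q_hat), K <= 8)
  perms <- permutations_of(K)
  best <- NULL; best_cost <- Inf
  for (i in seq_len(nrow(perms))) {
    cost <- sum(abs(Q_hat[, perms[i, ], drop = FALSE] - Q_ref))
    if (cost < best_cost) {
      best_cost <- cost
      best <- perms[i, ]
    }
  }
  Qm <- Q_hat[, best, drop = FALSE]
  list(perm = best, Q_matched = Qm,
       rmse = sqrt(mean((Qm - Q_ref)^2)))
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  unname(out)
}
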