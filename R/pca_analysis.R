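#' Principal component analysis of a dosage matrix
#'
#' Missing cells are imputed to the locus mean dosage, columns are
#' centered (not variance-scaled), and the centered matrix is decomposed
#' by SVD. Scores are the sample projections and loadings the right
#' singular vectors. Each component is oriented so that its
#' largest-magnitude loading entry is positive.
#'
#' @param dataset a [genotype_dataset()] with at least 2 samples and loci.
#' @param n_components number of components to retain (default: all).
#' @return object of class `pca_result`: `sample_ids`, `scores`
#'   (samples x components), `loadings` (loci x components),
#'   `explained_variance_fraction`.
#' @export
run_pca <- function(dataset, n_components = NULL) {
  g <- dataset$genotypes
  if (nrow(g) < 2 || ncol(g) < 2) {
    stop("need at least 2 samples and 2 loci", call. = FALSE)
  }
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- mu[j]
  }
  x <- sweep(g, 2, colMeans(g))
  if (all(abs(x) < 1e-12)) stop("no variance in genotype matrix", call. = FALSE)
  sv <- svd(x)
  total_var <- sum(sv$d^2)
  kmax <- sum(sv$d > 1e-10)
  k <- if (is.null(n_components)) kmax else min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (c_ in seq_len(k)) {
    peak <- which.max(abs(loadings[, c_]))
    if (loadings[peak, c_] < 0) {
      loadings[, c_] <- -loadings[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  rownames(scores) <- dataset$samples$sample_id
  rownames(loadings) <- dataset$loci$locus_id
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(sample_ids = dataset$samples$sample_id,
                 scores = scores, loadings = loadings,
                 explained_variance_fraction = sv$d[seq_len(k)]^2 / total_var),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", length(x$sample_ids), "samples,",
      nrow(x$loadings), "loci,", ncol(x$scores), "components\n")
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$explained_variance_fraction, 5)),
             collapse = ", "), "\n")
  invisible(x)
}

#' Select the most form-discriminant SNP panel
#'
#' Ranks loci by the absolute loading on the chosen component (by
#' convention the wild/domestic axis) and returns the top `panel_size`,
#' with ties broken by locus id for determinism.
#'
#' @param pca a `pca_result` from [run_pca()].
#' @param dataset the dataset the PCA was computed on.
#' @param panel_size number of loci to retain (default 983).
#' @param axis component index whose loadings rank the loci (default 1).
#' @return object of class `marker_panel`: `locus_ids` (descending score
#'   order) and `ranking_score` (absolute loadings).
#' @export
select_informative_snps <- function(pca, dataset, panel_size = 983, axis = 1) {
  if (axis > ncol(pca$loadings)) {
    stop("axis ", axis, " exceeds available components", call. = FALSE)
  }
  if (panel_size > nrow(pca$loadings)) {
    stop("panel_size (", panel_size, ") exceeds locus count (",
         nrow(pca$loadings), ")", call. = FALSE)
  }
  score <- abs(pca$loadings[, axis])
  ids <- rownames(pca$loadings)
  ord <- order(-score, ids)
  sel <- ord[seq_len(panel_size)]
  structure(list(locus_ids = ids[sel], ranking_score = unname(score[sel])),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", length(x$locus_ids), "loci; top score",
      sprintf("%.4f", x$ranking_score[1]), "\n")
  invisible(x)
}

#' PCA-based candidate hybrid flagging
#'
#' Projects each wild sample's PC1 score onto the axis from the wild
#' reference centroid (t = 0) to the domestic reference centroid (t = 1)
#' and flags candidates with `t >= min_projection`.
#'
#' @param pca a `pca_result`.
#' @param wild_ids,domestic_ids disjoint, non-empty reference sample ids.
#' @param min_projection flagging threshold on t (default 0.10).
#' @return data frame with one row per wild sample: `sample_id`, `t`,
#'   `candidate`.
#' @export
pca_candidate_hybrids <- function(pca, wild_ids, domestic_ids,
                                  min_projection = 0.10) {
  if (!length(wild_ids) || !length(domestic_ids)) {
    stop("both reference lists must be non-empty", call. = FALSE)
  }
  if (length(intersect(wild_ids, domestic_ids))) {
    stop("reference lists overlap", call. = FALSE)
  }
  s <- pca$scores[, 1]
  missing <- setdiff(c(wild_ids, domestic_ids), names(s))
  if (length(missing)) {
    stop("samples not in PCA: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cw <- mean(s[wild_ids])
  cd <- mean(s[domestic_ids])
  span <- cd - cw
  if (abs(span) < 1e-12 * max(1, abs(cw), abs(cd))) {
    stop("wild and domestic centroids coincide on PC1", call. = FALSE)
  }
  t_val <- (s[wild_ids] - cw) / span
  data.frame(sample_id = wild_ids, t = unname(t_val),
             candidate = unname(t_val) >= min_projection,
             stringsAsFactors = FALSE)
}
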