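# Small in-code fixtures shared across the suite.

# Wrap a raw dosage matrix in a dataset with default registries.
toy_dataset <- function(g, form = NULL, population = NULL, country = NULL,
                        cluster = NULL, chromosome = NULL, position = NULL) {
  g <- as.matrix(g)
  n <- nrow(g); L <- ncol(g)
  loci <- data.frame(
    locus_id = sprintf("L%03d", seq_len(L)),
    chromosome = if (is.null(chromosome)) rep("1", L) else chromosome,
    position_bp = if (is.null(position)) seq_len(L) * 1000L else position,
    allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(form)) samples$form <- form
  if (!is.null(population)) samples$population_id <- population
  if (!is.null(country)) samples$country <- country
  if (!is.null(cluster)) samples$cluster_id <- cluster
  genotype_dataset(g, loci, samples)
}

# Two Balding-Nichols clusters plus optional admixed individuals.
two_pop_dataset <- function(n1 = 25, n2 = 25, L = 2000, c1 = 0.1, c2 = 0.1,
                            n_admixed = 0, q_dom = 0.5, missing_rate = 0,
                            seed = 1) {
  f <- simulate_frequencies(L, c(P1 = c1, P2 = c2), seed = seed)
  anc <- rbind(
    matrix(rep(c(1, 0), n1), n1, 2, byrow = TRUE),
    matrix(rep(c(0, 1), n2), n2, 2, byrow = TRUE),
    if (n_admixed > 0) matrix(rep(c(1 - q_dom, q_dom), n_admixed),
                              n_admixed, 2, byrow = TRUE))
  ds <- simulate_genotypes(f, anc, missing_rate = missing_rate,
                           seed = seed + 1000)
  ds$samples$cluster_id <- c(rep("P1", n1), rep("P2", n2),
                             rep("ADM", n_admixed))
  ds$samples$form <- c(rep("wild", n1), rep("domestic", n2),
                       rep("wild", n_admixed))
  ds$samples$population_id <- ds$samples$cluster_id
  list(dataset = ds, ancestry = anc, freqs = f)
}

# Build an fst_matrix whose two within-group upper triangles carry the
# given value vectors (between-group entries are irrelevant filler).
fake_fst <- function(values_a, values_b) {
  k_from_pairs <- function(m) (1 + sqrt(1 + 8 * m)) / 2
  ka <- k_from_pairs(length(values_a))
  kb <- k_from_pairs(length(values_b))
  stopifnot(ka == round(ka), kb == round(kb))
  ids <- c(paste0("a", seq_len(ka)), paste0("b", seq_len(kb)))
  v <- matrix(0, ka + kb, ka + kb, dimnames = list(ids, ids))
  aa <- matrix(0, ka, ka); aa[upper.tri(aa)] <- values_a
  bb <- matrix(0, kb, kb); bb[upper.tri(bb)] <- values_b
  v[seq_len(ka), seq_len(ka)] <- aa + t(aa)
  v[ka + seq_len(kb), ka + seq_len(kb)] <- bb + t(bb)
  structure(list(cluster_ids = ids, values = v), class = "fst_matrix")
}

expect_setequal_chr <- function(x, y) {
  testthat::expect_setequal(as.character(x), as.character(y))
}
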