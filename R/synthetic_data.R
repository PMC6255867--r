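#' Simulate cluster allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are drawn Uniform(0.05, 0.95) (or supplied);
#' each cluster's frequency at a locus with ancestral p and divergence c
#' is Beta(p(1-c)/c, (1-p)(1-c)/c), so the expected pairwise
#' Weir-Cockerham F_ST between clusters of divergence c approximates c.
#'
#' @param n_loci number of loci.
#' @param clusters named numeric vector of divergence values c in (0,1),
#'   one per cluster, or a data frame with columns `name`, `divergence`.
#' @param seed integer RNG seed.
#' @param ancestral optional vector of ancestral frequencies (length
#'   `n_loci`) replacing the uniform draw — used to nest clusters within
#'   a higher-level (e.g. wild vs domestic) divergence.
#' @return clusters x loci frequency matrix with cluster row names, and
#'   the ancestral frequencies as attribute `"ancestral"`.
#' @export
simulate_frequencies <- function(n_loci, clusters, seed, ancestral = NULL) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(clusters$divergence, clusters$name)
  }
  if (any(clusters <= 0 | clusters >= 1)) {
    stop("divergence c must lie in (0, 1)", call. = FALSE)
  }
  withr::with_seed(seed, {
    if (is.null(ancestral)) ancestral <- stats::runif(n_loci, 0.05, 0.95)
    stopifnot(length(ancestral) == n_loci)
    freqs <- matrix(NA_real_, length(clusters), n_loci,
                    dimnames = list(names(clusters), NULL))
    for (i in seq_along(clusters)) {
      c_ <- clusters[i]
      freqs[i, ] <- stats::rbeta(n_loci,
                                 ancestral * (1 - c_) / c_,
                                 (1 - ancestral) * (1 - c_) / c_)
    }
    attr(freqs, "ancestral") <- ancestral
    freqs
  })
}

#' Simulate genotypes from cluster frequencies and ancestry
#'
#' Each dosage is Binomial(2, pi) with `pi = ancestry %*% freqs`, then
#' cells are masked uniformly at `missing_rate`. Genotype column j
#' corresponds to frequency column j.
#'
#' @param freqs clusters x loci frequency matrix.
#' @param ancestry samples x clusters ancestry matrix (rows sum to 1).
#' @param missing_rate fraction of cells set missing (default 0).
#' @param seed integer RNG seed.
#' @param samples optional sample registry data frame (defaults to
#'   generic ids).
#' @return a [genotype_dataset()]; loci are laid out as contiguous
#'   blocks over 18 autosomes with increasing positions and A/G alleles
#'   (G counted).
#' @export
simulate_genotypes <- function(freqs, ancestry, missing_rate = 0, seed,
                               samples = NULL) {
  ancestry <- as.matrix(ancestry)
  stopifnot(ncol(ancestry) == nrow(freqs),
            all(abs(rowSums(ancestry) - 1) < 1e-8))
  n <- nrow(ancestry); L <- ncol(freqs)
  pi_ <- pmin(pmax(ancestry %*% freqs, 0), 1)
  g <- withr::with_seed(seed, {
    m <- matrix(stats::rbinom(n * L, 2, as.vector(pi_)), n, L)
    if (missing_rate > 0) {
      m[matrix(stats::runif(n * L) < missing_rate, n, L)] <- NA
    }
    m
  })
  if (is.null(samples)) {
    samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                          stringsAsFactors = FALSE)
  }
  chr <- rep(seq_len(18), each = ceiling(L / 18), length.out = L)
  pos <- unlist(lapply(unique(chr), function(c_) seq_len(sum(chr == c_)) * 10000L),
                use.names = FALSE)
  loci <- data.frame(locus_id = sprintf("L%05d", seq_len(L)),
                     chromosome = sprintf("%02d", chr),
                     position_bp = pos,
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  genotype_dataset(g, loci, samples)
}

hybrid_class_label <- function(q_dom) {
  if (q_dom == 0) "pure"
  else if (abs(q_dom - 0.5) < 1e-9) "F1"
  else if (abs(q_dom - 0.25) < 1e-9) "BC1"
  else if (abs(q_dom - 0.125) < 1e-9) "BC2"
  else if (q_dom >= 0.75) "feral"
  else "admixed"
}

#' Scenario configuration for the synthetic generator
#'
#' @param n_loci number of loci.
#' @param wild_clusters data frame: `name`, `n`, `divergence`, `country`,
#'   `longitude`, and optionally `area` (geographic analysis area).
#' @param domestic_clusters same columns (area ignored).
#' @param hybrids data frame: `name`, `n`, `q_dom`, `wild_source`,
#'   `domestic_source` (hybrids inherit country/area from their wild
#'   source population and are labeled wild).
#' @param form_divergence divergence of each form's ancestor from the
#'   shared ancestral frequencies (default 0.05).
#' @param missing_rate uniform genotype missingness (default 0.05).
#' @param related_pairs number of parent-offspring pairs to inject
#'   (default 0).
#' @param seed integer RNG seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_loci, wild_clusters, domestic_clusters,
                            hybrids = NULL, form_divergence = 0.05,
                            missing_rate = 0.05, related_pairs = 0,
                            seed = 1L) {
  stopifnot(n_loci > 0, missing_rate >= 0, missing_rate < 1,
            form_divergence > 0, form_divergence < 1,
            all(wild_clusters$divergence > 0 & wild_clusters$divergence < 1),
            all(domestic_clusters$divergence > 0 & domestic_clusters$divergence < 1))
  if (!is.null(hybrids)) {
    stopifnot(all(hybrids$q_dom >= 0 & hybrids$q_dom <= 1))
    bad_w <- setdiff(hybrids$wild_source, wild_clusters$name)
    bad_d <- setdiff(hybrids$domestic_source, domestic_clusters$name)
    if (length(bad_w) || length(bad_d)) {
      stop("unknown hybrid source cluster: ",
           paste(c(bad_w, bad_d), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(wild_clusters$area)) wild_clusters$area <- wild_clusters$name
  structure(list(n_loci = n_loci, wild_clusters = wild_clusters,
                 domestic_clusters = domestic_clusters, hybrids = hybrids,
                 form_divergence = form_divergence,
                 missing_rate = missing_rate,
                 related_pairs = related_pairs, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default scenario: a continent-wide sampling design
#'
#' Eight wild and eight domestic clusters with sample sizes capped at
#' 25, hierarchically diverged (each form drifts from a common ancestor,
#' clusters drift within forms), hybrids spanning domestic fractions
#' 0.05-0.5, two near-pure feral pigs sampled as wild, ~5 percent
#' missingness and two first-order relative pairs.
#'
#' @param seed integer RNG seed.
#' @param n_loci number of loci (default 5000).
#' @return a `scenario_config`.
#' @export
default_scenario_config <- function(seed = 1L, n_loci = 5000) {
  wild <- data.frame(
    name = c("WB-NE", "WB-Bal", "WB-Car", "WB-Ibe", "WB-Ita", "WB-Sar",
             "WB-CW", "WB-CNE"),
    n = c(16, 25, 25, 23, 19, 25, 25, 25),
    divergence = c(0.22, 0.03, 0.03, 0.10, 0.10, 0.14, 0.05, 0.06),
    country = c("Turkey", "Serbia", "Romania", "Spain", "Italy", "Sardinia",
                "Austria", "Estonia"),
    longitude = c(35.0, 21.0, 25.0, -3.7, 12.6, 9.1, 14.6, 25.0),
    area = c("NearEast", "Balkans", "Carpathians", "Iberia", "Italy",
             "Sardinia", "CentralWest", "CentralNorthEast"),
    stringsAsFactors = FALSE)
  dom <- data.frame(
    name = c("DP-Com", "DP-Bal", "DP-Car", "DP-CE", "DP-CN", "DP-CW",
             "DP-Ibe", "DP-Ita"),
    n = c(25, 23, 25, 19, 22, 25, 25, 25),
    divergence = c(0.05, 0.10, 0.07, 0.05, 0.04, 0.04, 0.07, 0.07),
    country = c("Commercial", "Serbia", "Romania", "Hungary", "Denmark",
                "Netherlands", "Spain", "Italy"),
    longitude = c(NA, 21.0, 25.0, 19.5, 9.5, 5.3, -3.7, 12.6),
    stringsAsFactors = FALSE)
  hyb <- data.frame(
    name = c("HYB-low", "HYB-BC2", "HYB-BC1", "HYB-F1", "FERAL"),
    n = c(2, 3, 4, 3, 2),
    q_dom = c(0.05, 0.125, 0.25, 0.5, 0.9),
    wild_source = c("WB-CW", "WB-Bal", "WB-Bal", "WB-Car", "WB-CW"),
    domestic_source = c("DP-CW", "DP-Bal", "DP-Com", "DP-Car", "DP-Com"),
    stringsAsFactors = FALSE)
  scenario_config(n_loci = n_loci, wild_clusters = wild,
                  domestic_clusters = dom, hybrids = hyb,
                  form_divergence = 0.05, missing_rate = 0.05,
                  related_pairs = 2, seed = seed)
}

#' Compact scenario for end-to-end pipeline evaluation
#'
#' Three wild clusters (two in an eastern area, one western) and two
#' domestic clusters, with wild-domestic differentiation in the
#' 0.15-0.25 range, planted hybrids (F1, BC1, BC2, a low-admixture
#' class) and two feral pigs.
#'
#' @param seed integer RNG seed.
#' @param n_loci number of loci (default 5000).
#' @return a `scenario_config`.
#' @export
pipeline_scenario_config <- function(seed = 1L, n_loci = 5000) {
  wild <- data.frame(
    name = c("WB-E1", "WB-E2", "WB-W1"),
    n = c(25, 25, 25),
    divergence = c(0.05, 0.06, 0.08),
    country = c("Serbia", "Romania", "Spain"),
    longitude = c(21.0, 25.0, -3.7),
    area = c("East", "East", "West"),
    stringsAsFactors = FALSE)
  dom <- data.frame(
    name = c("DP-1", "DP-2"),
    n = c(25, 25),
    divergence = c(0.05, 0.06),
    country = c("Commercial", "Hungary"),
    longitude = c(NA, 19.5),
    stringsAsFactors = FALSE)
  hyb <- data.frame(
    name = c("HYB-low", "HYB-BC2", "HYB-BC1", "HYB-F1", "FERAL"),
    n = c(2, 3, 4, 3, 2),
    q_dom = c(0.05, 0.125, 0.25, 0.5, 0.9),
    wild_source = c("WB-E1", "WB-E2", "WB-E1", "WB-E2", "WB-E1"),
    domestic_source = c("DP-1", "DP-1", "DP-2", "DP-1", "DP-1"),
    stringsAsFactors = FALSE)
  scenario_config(n_loci = n_loci, wild_clusters = wild,
                  domestic_clusters = dom, hybrids = hyb,
                  form_divergence = 0.06, missing_rate = 0.02,
                  related_pairs = 0, seed = seed)
}

#' Generate a dataset with known ancestry truth
#'
#' Draws a shared ancestral frequency vector, drifts it once per form
#' (wild, domestic) at `form_divergence`, then once per cluster within
#' its form at the cluster's divergence; pure individuals take unit
#' ancestry rows and hybrids mixture rows `(1 - q_dom, q_dom)` over
#' their two source clusters; genotypes are binomial at the mixed
#' frequencies. Metadata (form, country, population, longitude, area)
#' come from the configuration; hybrids are labeled wild and inherit
#' their wild source's population metadata.
#'
#' @param config a [scenario_config()].
#' @return list with `dataset` (a [genotype_dataset()], with an extra
#'   `area` registry column for wild samples) and `truth` (list:
#'   `ancestry` matrix over generating clusters, `class`, `q_dom`,
#'   `freqs`, `cluster_form`, `related_pairs`).
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  L <- config$n_loci

  anc <- withr::with_seed(seed, stats::runif(L, 0.05, 0.95))
  form_freqs <- simulate_frequencies(
    L, c(wild = config$form_divergence, domestic = config$form_divergence),
    seed = seed + 1L, ancestral = anc)
  wild_freqs <- simulate_frequencies(
    L, stats::setNames(config$wild_clusters$divergence,
                       config$wild_clusters$name),
    seed = seed + 2L, ancestral = form_freqs["wild", ])
  dom_freqs <- simulate_frequencies(
    L, stats::setNames(config$domestic_clusters$divergence,
                       config$domestic_clusters$name),
    seed = seed + 3L, ancestral = form_freqs["domestic", ])
  freqs <- rbind(wild_freqs, dom_freqs)
  cluster_names <- rownames(freqs)

  samples <- data.frame(sample_id = character(0), form = character(0),
                        country = character(0), population_id = character(0),
                        longitude_deg = numeric(0), cluster_id = character(0),
                        area = character(0), stringsAsFactors = FALSE)
  ancestry <- NULL
  classes <- character(0)
  q_dom <- numeric(0)
  unit_row <- function(name) {
    r <- rep(0, length(cluster_names))
    r[match(name, cluster_names)] <- 1
    r
  }
  add_members <- function(n, row, form, country, pop, lon, area, cls, qd) {
    offset <- sum(samples$population_id == pop)
    ids <- sprintf("%s_%02d", pop, seq_len(n) + offset)
    samples <<- rbind(samples, data.frame(
      sample_id = ids, form = form, country = country, population_id = pop,
      longitude_deg = lon, cluster_id = pop, area = area,
      stringsAsFactors = FALSE))
    ancestry <<- rbind(ancestry, matrix(rep(row, n), n, byrow = TRUE))
    classes <<- c(classes, rep(cls, n))
    q_dom <<- c(q_dom, rep(qd, n))
  }
  for (i in seq_len(nrow(config$wild_clusters))) {
    w <- config$wild_clusters[i, ]
    add_members(w$n, unit_row(w$name), "wild", w$country, w$name,
                w$longitude, w$area, "pure", 0)
  }
  for (i in seq_len(nrow(config$domestic_clusters))) {
    d <- config$domestic_clusters[i, ]
    add_members(d$n, unit_row(d$name), "domestic", d$country,
                d$name, d$longitude, NA_character_, "pure", 0)
  }
  if (!is.null(config$hybrids)) {
    for (i in seq_len(nrow(config$hybrids))) {
      h <- config$hybrids[i, ]
      src <- config$wild_clusters[config$wild_clusters$name == h$wild_source, ]
      row <- (1 - h$q_dom) * unit_row(h$wild_source) +
        h$q_dom * unit_row(h$domestic_source)
      add_members(h$n, row, "wild", src$country, src$name,
                  src$longitude, src$area, hybrid_class_label(h$q_dom),
                  h$q_dom)
    }
  }

  ds <- simulate_genotypes(freqs, ancestry, config$missing_rate,
                           seed = seed + 4L, samples = samples)
  truth <- list(
    ancestry = `dimnames<-`(ancestry, list(samples$sample_id, cluster_names)),
    class = stats::setNames(classes, samples$sample_id),
    q_dom = stats::setNames(q_dom, samples$sample_id),
    freqs = freqs,
    cluster_form = stats::setNames(
      c(rep("wild", nrow(wild_freqs)), rep("domestic", nrow(dom_freqs))),
      cluster_names),
    related_pairs = NULL)
  out <- list(dataset = ds, truth = truth)
  if (config$related_pairs > 0) {
    out <- inject_relatives(out$dataset, out$truth, config$related_pairs,
                            seed = seed + 5L)
  }
  out
}

#' Inject first-order relative pairs
#'
#' For each pair, synthesizes an offspring of two same-cluster pure
#' parents by drawing one allele per locus from each parent's genotype
#' (missing parent cells fall back to the cluster frequency). The
#' offspring joins the dataset with its parents' metadata; the truth
#' table gains the parent-child pair list.
#'
#' @param dataset a [genotype_dataset()] from [make_scenario()].
#' @param truth the matching truth list (needs `ancestry`, `class`,
#'   `freqs`).
#' @param n_pairs number of offspring to synthesize.
#' @param seed integer RNG seed.
#' @return list with updated `dataset` and `truth` (pairs appended to
#'   `truth$related_pairs`).
#' @export
inject_relatives <- function(dataset, truth, n_pairs, seed) {
  if (n_pairs == 0) return(list(dataset = dataset, truth = truth))
  pure <- names(truth$class)[truth$class == "pure"]
  pops <- dataset$samples$population_id[match(pure, dataset$samples$sample_id)]
  eligible <- names(which(table(pops) >= 2))
  if (length(eligible) < 1) stop("no cluster large enough for relatives",
                                 call. = FALSE)
  withr::with_seed(seed, {
    g_new <- NULL; meta_new <- NULL
    anc_new <- NULL; cls_new <- character(0); qd_new <- numeric(0)
    pairs <- NULL
    chosen_pops <- sample(rep(eligible, length.out = n_pairs))
    for (k in seq_len(n_pairs)) {
      pop <- chosen_pops[k]
      members <- pure[pops == pop]
      par_ids <- sample(members, 2)
      gi <- dataset$genotypes[par_ids[1], ]
      gj <- dataset$genotypes[par_ids[2], ]
      cl_row <- truth$ancestry[par_ids[1], ]
      f <- as.vector(cl_row %*% truth$freqs)
      p1 <- ifelse(is.na(gi), f, gi / 2)
      p2 <- ifelse(is.na(gj), f, gj / 2)
      child <- stats::rbinom(length(p1), 1, p1) + stats::rbinom(length(p2), 1, p2)
      cid <- sprintf("REL_%s_%02d", pop, k)
      g_new <- rbind(g_new, child)
      src <- dataset$samples[dataset$samples$sample_id == par_ids[1], ,
                             drop = FALSE]
      src$sample_id <- cid
      meta_new <- rbind(meta_new, src)
      anc_new <- rbind(anc_new, cl_row)
      cls_new <- c(cls_new, "offspring")
      qd_new <- c(qd_new, truth$q_dom[par_ids[1]])
      pairs <- rbind(pairs,
                     data.frame(parent = par_ids[1], child = cid,
                                stringsAsFactors = FALSE),
                     data.frame(parent = par_ids[2], child = cid,
                                stringsAsFactors = FALSE))
    }
    rownames(meta_new) <- NULL
    ds <- genotype_dataset(rbind(dataset$genotypes, g_new),
                           dataset$loci,
                           rbind(dataset$samples, meta_new))
    truth$ancestry <- rbind(truth$ancestry,
                            `rownames<-`(anc_new, meta_new$sample_id))
    truth$class <- c(truth$class, stats::setNames(cls_new, meta_new$sample_id))
    truth$q_dom <- c(truth$q_dom, stats::setNames(qd_new, meta_new$sample_id))
    truth$related_pairs <- rbind(truth$related_pairs, pairs)
    list(dataset = ds, truth = truth)
  })
}
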