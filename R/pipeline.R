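#' Multi-analysis hybrid screen
#'
#' Runs the full detection protocol on a labeled dataset and combines
#' the analyses into the weighted consensus:
#'
#' 1. a whole-sample admixture analysis (weight `weight_other`);
#' 2. one focal admixture analysis per geographic area, fitted on the
#'    area's wild samples plus all domestic references (weight
#'    `weight_focal` for the area's own wild samples);
#' 3. an admixture analysis of the most form-discriminant SNP panel
#'    selected from the whole-sample PCA loadings (weight `weight_other`);
#' 4. PCA candidate flagging by centroid-segment projection (weight
#'    `weight_other`).
#'
#' In every admixture analysis, clusters are typed wild/domestic from
#' the form labels and a sample is called when its summed domestic
#' ancestry is strictly above the configured threshold.
#'
#' @param dataset a [genotype_dataset()] whose registry has `form` and,
#'   for wild samples, an area assignment.
#' @param areas named list mapping area name to the wild `population_id`
#'   values it contains; defaults to grouping by the registry's `area`
#'   column.
#' @param K_whole clusters for the whole-sample (and panel) analyses.
#' @param K_area named integer vector of K per area (defaults to
#'   `K_whole`).
#' @param K_panel clusters for the panel analysis (default 2: the
#'   panel targets the wild-domestic axis).
#' @param panel_size loci in the reduced panel (default 983).
#' @param config a [threshold_config()].
#' @param seed integer seed; per-analysis seeds are derived from it.
#' @param max_iter,tol EM settings passed to [fit_admixture()].
#' @return object of class `hybrid_screen`: `runs` (list of
#'   [analysis_run()]), `consensus` (from [consensus_calls()]), `tally`
#'   (from [tally_by_country()]), and `fits`.
#' @export
detect_hybrids <- function(dataset, areas = NULL, K_whole, K_area = NULL,
                           K_panel = 2, panel_size = 983,
                           config = threshold_config(), seed = 1L,
                           max_iter = 400, tol = 1e-4) {
  samples <- dataset$samples
  wild_ids <- samples$sample_id[samples$form == "wild"]
  dom_ids <- samples$sample_id[samples$form == "domestic"]
  if (!length(wild_ids) || !length(dom_ids)) {
    stop("dataset needs both wild and domestic samples", call. = FALSE)
  }
  if (is.null(areas)) {
    if (is.null(samples$area)) {
      stop("supply `areas` or an `area` registry column", call. = FALSE)
    }
    wild_areas <- unique(samples$area[samples$form == "wild"])
    wild_areas <- wild_areas[!is.na(wild_areas)]
    areas <- lapply(wild_areas, function(a) {
      unique(samples$population_id[samples$form == "wild" &
                                     !is.na(samples$area) & samples$area == a])
    })
    names(areas) <- wild_areas
  }
  if (is.null(K_area)) {
    K_area <- stats::setNames(rep(K_whole, length(areas)), names(areas))
  }
  tau <- config$domestic_threshold
  runs <- list()
  fits <- list()

  admix_run <- function(ds, K, run_seed, run_id, scope, covered) {
    fit <- fit_admixture(ds, K, seed = run_seed, max_iter = max_iter, tol = tol)
    types <- classify_clusters(fit, ds$samples)
    calls <- call_hybrids_single(fit, types, tau = tau)
    idx <- match(covered, calls$sample_id)
    fits[[run_id]] <<- fit
    analysis_run(run_id, scope, covered, calls$hybrid[idx],
                 calls$domestic_fraction[idx], config = config)
  }

  # 1. whole-sample analysis
  runs$whole <- admix_run(dataset, K_whole, seed + 101L, "whole",
                          "whole_sample", wild_ids)

  # 2. focal analyses per geographic area
  for (a in names(areas)) {
    area_wild <- samples$sample_id[samples$form == "wild" &
                                     samples$population_id %in% areas[[a]]]
    if (!length(area_wild)) next
    sub <- subset_dataset(dataset, sample_ids = c(area_wild, dom_ids))
    run_id <- paste0("focal_", a)
    runs[[run_id]] <- admix_run(sub, K_area[[a]], seed + 200L + match(a, names(areas)),
                                run_id, "focal_area", area_wild)
  }

  # 3. reduced informative-marker panel analysis
  pca <- run_pca(dataset, n_components = 2)
  panel <- select_informative_snps(pca, dataset, panel_size = panel_size,
                                   axis = 1)
  panel_ds <- subset_dataset(dataset, locus_ids = panel$locus_ids)
  runs$panel <- admix_run(panel_ds, K_panel, seed + 301L, "panel",
                          "whole_sample", wild_ids)

  # 4. PCA centroid-projection candidates
  proj <- pca_candidate_hybrids(pca, wild_ids, dom_ids, min_projection = tau)
  runs$pca <- analysis_run("pca", "whole_sample", proj$sample_id,
                           proj$candidate, pmin(pmax(proj$t, 0), 1),
                           config = config)

  consensus <- consensus_calls(unname(runs), config, sample_ids = wild_ids)
  tally <- tally_by_country(consensus, samples)
  structure(list(runs = runs, consensus = consensus, tally = tally,
                 fits = fits, panel = panel, pca = pca, config = config),
            class = "hybrid_screen")
}

#' @export
print.hybrid_screen <- function(x, ...) {
  n_h <- sum(x$consensus$is_hybrid)
  cat("hybrid_screen:", length(x$runs), "analyses,",
      nrow(x$consensus), "wild samples,", n_h, "consensus hybrids\n")
  print(x$tally, row.names = FALSE)
  invisible(x)
}
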