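#' Threshold configuration for hybrid classification
#'
#' Bundles the operational thresholds of the screen: the per-analysis
#' domestic-ancestry threshold (a sample is called in one analysis when
#' its domestic fraction is strictly above `domestic_threshold`), the
#' weighted consensus fraction (hybrid when the weighted fraction of
#' calling analyses is at least `consensus_fraction`), the analysis
#' weights by scope, and the meridian for the east/west regional split.
#'
#' @param domestic_threshold per-analysis domestic-ancestry cutoff
#'   (default 0.10, strict).
#' @param consensus_fraction weighted consensus cutoff (default 0.30,
#'   inclusive).
#' @param weight_focal weight of analyses focused on the sample's own
#'   geographic area (default 1.0).
#' @param weight_other weight of other-area and whole-sample analyses
#'   (default 0.8).
#' @param meridian_deg longitude separating East from West (default 14).
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(domestic_threshold = 0.10,
                             consensus_fraction = 0.30,
                             weight_focal = 1.0, weight_other = 0.8,
                             meridian_deg = 14.0) {
  stopifnot(domestic_threshold > 0, domestic_threshold < 1,
            consensus_fraction > 0, consensus_fraction < 1,
            is.finite(meridian_deg))
  structure(list(domestic_threshold = domestic_threshold,
                 consensus_fraction = consensus_fraction,
                 weight_focal = weight_focal, weight_other = weight_other,
                 meridian_deg = meridian_deg),
            class = "threshold_config")
}

#' Type ancestry clusters as wild or domestic
#'
#' Cluster k is typed wild when its mean ancestry fraction over
#' wild-labeled reference samples exceeds the mean over domestic-labeled
#' samples, and domestic otherwise.
#'
#' @param fit an `ancestry_fit` from [fit_admixture()].
#' @param samples sample registry rows (with `sample_id` and `form`)
#'   covering the fitted samples.
#' @return named character vector, cluster label -> `"wild"`/`"domestic"`.
#' @export
classify_clusters <- function(fit, samples) {
  idx <- match(rownames(fit$Q), samples$sample_id)
  if (anyNA(idx)) stop("fit contains samples absent from the registry",
                       call. = FALSE)
  form <- samples$form[idx]
  if (!any(form == "wild", na.rm = TRUE) ||
      !any(form == "domestic", na.rm = TRUE)) {
    stop("need reference samples of both forms", call. = FALSE)
  }
  mean_w <- colMeans(fit$Q[form == "wild", , drop = FALSE])
  mean_d <- colMeans(fit$Q[form == "domestic", , drop = FALSE])
  stats::setNames(ifelse(mean_w > mean_d, "wild", "domestic"),
                  colnames(fit$Q))
}

#' Domestic ancestry fraction of one sample
#'
#' The complement of the summed wild-cluster ancestry:
#' `1 - sum(q[wild clusters]) = sum(q[domestic clusters])`.
#'
#' @param q_row normalized ancestry vector (one Q row).
#' @param cluster_types output of [classify_clusters()], aligned with
#'   `q_row`.
#' @return fraction in \[0, 1\].
#' @export
domestic_fraction <- function(q_row, cluster_types) {
  stopifnot(length(q_row) == length(cluster_types))
  sum(q_row[cluster_types == "domestic"])
}

#' Hybrid calls from a single ancestry analysis
#'
#' A sample is called hybrid when its domestic ancestry fraction is
#' strictly greater than `tau` (the "more than 10 percent" rule).
#'
#' @param fit an `ancestry_fit`.
#' @param cluster_types from [classify_clusters()].
#' @param tau domestic-ancestry threshold (default 0.10).
#' @return data frame: `sample_id`, `domestic_fraction`, `hybrid`.
#' @export
call_hybrids_single <- function(fit, cluster_types, tau = 0.10) {
  df <- apply(fit$Q, 1, domestic_fraction, cluster_types = cluster_types)
  data.frame(sample_id = rownames(fit$Q), domestic_fraction = unname(df),
             hybrid = unname(df) > tau, stringsAsFactors = FALSE)
}

#' Record one analysis feeding the consensus
#'
#' @param run_id identifier of the analysis.
#' @param scope one of `"focal_area"`, `"other_area"`, `"whole_sample"`;
#'   focal-area analyses carry weight `weight_focal`, all others
#'   `weight_other`.
#' @param sample_ids samples covered by (i.e. scored in) this analysis.
#' @param hybrid_call logical vector of per-sample calls, aligned with
#'   `sample_ids`.
#' @param domestic_fraction numeric vector of per-sample domestic
#'   fractions, aligned with `sample_ids`.
#' @param config a [threshold_config()].
#' @return list of class `analysis_run`.
#' @export
analysis_run <- function(run_id, scope, sample_ids, hybrid_call,
                         domestic_fraction, config = threshold_config()) {
  scope <- match.arg(scope, c("focal_area", "other_area", "whole_sample"))
  stopifnot(length(sample_ids) == length(hybrid_call),
            length(sample_ids) == length(domestic_fraction))
  weight <- if (scope == "focal_area") config$weight_focal else config$weight_other
  structure(list(run_id = run_id, scope = scope, weight = weight,
                 sample_ids = sample_ids,
                 hybrid_call = stats::setNames(hybrid_call, sample_ids),
                 domestic_fraction = stats::setNames(domestic_fraction, sample_ids)),
            class = "analysis_run")
}

#' Weighted consensus over multiple analyses
#'
#' For each sample, the weighted fraction of covering analyses that call
#' it hybrid: `sum(w_i * call_i) / sum(w_i)`. A sample is a consensus
#' hybrid when this fraction is at least `consensus_fraction`. Samples
#' whose maximum per-analysis domestic fraction reaches 0.75 are
#' additionally flagged as near-pure domestic (feral).
#'
#' @param runs list of [analysis_run()] objects.
#' @param config a [threshold_config()].
#' @param sample_ids optional universe of samples that must each be
#'   covered by at least one run; an uncovered sample is an error.
#' @return data frame: `sample_id`, `weighted_fraction`,
#'   `n_runs_covering`, `is_hybrid`, `max_domestic_fraction`,
#'   `near_pure_domestic`.
#' @export
consensus_calls <- function(runs, config = threshold_config(),
                            sample_ids = NULL) {
  covered <- unique(unlist(lapply(runs, `[[`, "sample_ids")))
  if (is.null(sample_ids)) {
    sample_ids <- covered
  } else {
    uncovered <- setdiff(sample_ids, covered)
    if (length(uncovered)) {
      stop("samples covered by no analysis: ",
           paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
    }
  }
  out <- data.frame(sample_id = sample_ids, weighted_fraction = NA_real_,
                    n_runs_covering = NA_integer_, is_hybrid = NA,
                    max_domestic_fraction = NA_real_,
                    near_pure_domestic = NA, stringsAsFactors = FALSE)
  for (i in seq_along(sample_ids)) {
    id <- sample_ids[i]
    w_sum <- 0; call_sum <- 0; n_cov <- 0L; max_df <- -Inf
    for (r in runs) {
      if (!id %in% r$sample_ids) next
      n_cov <- n_cov + 1L
      w_sum <- w_sum + r$weight
      call_sum <- call_sum + r$weight * as.numeric(r$hybrid_call[[id]])
      max_df <- max(max_df, r$domestic_fraction[[id]])
    }
    wf <- call_sum / w_sum
    out$weighted_fraction[i] <- wf
    out$n_runs_covering[i] <- n_cov
    out$is_hybrid[i] <- wf >= config$consensus_fraction
    out$max_domestic_fraction[i] <- max_df
    out$near_pure_domestic[i] <- max_df >= 0.75
  }
  out
}

#' Tally consensus hybrids by country
#'
#' Counts consensus hybrids among wild-labeled samples per country, with
#' percentages rounded to one decimal, plus a grand-total row
#' (`country = "TOTAL"`). An optional grouping column of the sample
#' registry (e.g. `cluster_id`) adds per-group subtotal rows.
#'
#' @param consensus output of [consensus_calls()].
#' @param samples sample registry with `sample_id`, `form`, `country`.
#' @param group_by optional registry column name for subtotals.
#' @return data frame: `country`, `sample_size`, `n_hybrids`,
#'   `pct_hybrids`.
#' @export
tally_by_country <- function(consensus, samples, group_by = NULL) {
  idx <- match(consensus$sample_id, samples$sample_id)
  if (anyNA(idx)) stop("consensus contains unknown samples", call. = FALSE)
  wild <- samples$form[idx] == "wild"
  cc <- consensus[wild, , drop = FALSE]
  country <- samples$country[idx][wild]
  tally_one <- function(label, flag) {
    data.frame(country = label, sample_size = length(flag),
               n_hybrids = sum(flag),
               pct_hybrids = round(100 * mean(flag), 1),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(unique(country), function(co) {
    tally_one(co, cc$is_hybrid[country == co])
  })
  out <- do.call(rbind, rows)
  if (!is.null(group_by)) {
    grp <- samples[[group_by]][idx][wild]
    g_rows <- lapply(unique(grp), function(gv) {
      tally_one(paste0("[", gv, "]"), cc$is_hybrid[grp == gv])
    })
    out <- rbind(out, do.call(rbind, g_rows))
  }
  rbind(out, tally_one("TOTAL", cc$is_hybrid))
}

#' Aggregate country tallies east and west of a meridian
#'
#' Countries whose representative longitude is at or east of the
#' meridian aggregate to East, the rest to West. Percentages are
#' recomputed from the aggregated counts, not averaged. An empty side is
#' returned with zero counts and `NA` percentage.
#'
#' @param tallies country rows from [tally_by_country()] (the `TOTAL`
#'   and any subtotal rows are ignored).
#' @param country_longitudes named numeric vector, country ->
#'   representative longitude in decimal degrees east.
#' @param meridian longitude of the split (default 14).
#' @return data frame with rows `East` and `West`: `region`,
#'   `sample_size`, `n_hybrids`, `pct_hybrids`.
#' @export
east_west_split <- function(tallies, country_longitudes, meridian = 14.0) {
  rows <- tallies[tallies$country != "TOTAL" &
                    !grepl("^\\[", tallies$country), , drop = FALSE]
  lon <- country_longitudes[rows$country]
  if (anyNA(lon)) {
    stop("missing longitude for: ",
         paste(rows$country[is.na(lon)], collapse = ", "), call. = FALSE)
  }
  east <- lon >= meridian
  agg <- function(region, sel) {
    n <- sum(rows$sample_size[sel])
    h <- sum(rows$n_hybrids[sel])
    data.frame(region = region, sample_size = n, n_hybrids = h,
               pct_hybrids = if (n > 0) round(100 * h / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(agg("East", east), agg("West", !east))
  if (any(out$sample_size == 0)) {
    warning("one side of the meridian contains no samples", call. = FALSE)
  }
  out
}

#' Published per-country hybrid counts for European wild boar
#'
#' The per-country wild boar sample sizes and consensus hybrid counts of
#' a continental SNP survey of pig introgression (shipped as plain text
#' under `inst/extdata`), used to exercise the tally and regional-split
#' arithmetic on real printed numbers.
#'
#' @return data frame: `country`, `abbrev`, `cluster`, `sample_size`,
#'   `n_hybrids`.
#' @export
hybrid_survey_counts <- function() {
  path <- system.file("extdata", "europe_hybrid_survey.csv",
                      package = "boarmix", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Representative country longitudes
#'
#' One representative longitude (decimal degrees east) per surveyed
#' country, used by [east_west_split()].
#'
#' @return named numeric vector.
#' @export
country_longitudes <- function() {
  path <- system.file("extdata", "country_longitudes.csv",
                      package = "boarmix", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$longitude_deg, tab$country)
}

#' Expand per-country counts into per-sample records
#'
#' Turns a counts table (as from [hybrid_survey_counts()]) into a
#' synthetic sample registry and matching consensus table with the
#' stated number of hybrids per country, so the tally arithmetic can be
#' recomputed from per-sample data.
#'
#' @param counts data frame with `country`, `sample_size`, `n_hybrids`
#'   (and optionally `abbrev` used for ids).
#' @return list with `samples` and `consensus` data frames.
#' @export
expand_survey_to_samples <- function(counts) {
  samples <- NULL; consensus <- NULL
  for (i in seq_len(nrow(counts))) {
    n <- counts$sample_size[i]
    h <- counts$n_hybrids[i]
    stub <- if (!is.null(counts$abbrev)) counts$abbrev[i]
            else gsub("[^A-Za-z]", "", counts$country[i])
    ids <- sprintf("%s_%02d", stub, seq_len(n))
    samples <- rbind(samples, data.frame(
      sample_id = ids, form = "wild", country = counts$country[i],
      population_id = stub,
      cluster_id = if (!is.null(counts$cluster)) counts$cluster[i] else NA,
      stringsAsFactors = FALSE))
    consensus <- rbind(consensus, data.frame(
      sample_id = ids, weighted_fraction = NA_real_,
      n_runs_covering = 1L,
      is_hybrid = seq_len(n) <= h,
      max_domestic_fraction = NA_real_, near_pure_domestic = FALSE,
      stringsAsFactors = FALSE))
  }
  list(samples = samples, consensus = consensus)
}
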