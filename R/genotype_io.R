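#' Construct a genotype dataset
#'
#' The shared in-memory container for SNP-array genotypes: a samples x loci
#' matrix of B-allele dosages (0, 1, 2 or `NA` for missing) together with a
#' locus registry and a sample registry.
#'
#' @param genotypes numeric matrix, samples in rows, loci in columns; entries
#'   must be 0, 1, 2 or `NA` (missing).
#' @param loci data frame with columns `locus_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`. `allele_b` is the counted allele;
#'   `"0"` marks an unobserved second allele at a monomorphic locus.
#' @param samples data frame with at least `sample_id`; the columns `form`
#'   (`"wild"` or `"domestic"`), `country`, `population_id`, `longitude_deg`
#'   and `cluster_id` are filled with `NA` when absent.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, loci, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  for (col in c("form", "country", "population_id", "longitude_deg", "cluster_id")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA
  }
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- loci$locus_id
  x <- structure(
    list(genotypes = genotypes, loci = loci, samples = samples),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(x)
  x
}

validate_genotype_dataset <- function(x) {
  g <- x$genotypes
  if (nrow(g) != nrow(x$samples)) {
    stop("genotype rows (", nrow(g), ") do not match sample registry (",
         nrow(x$samples), ")", call. = FALSE)
  }
  if (ncol(g) != nrow(x$loci)) {
    stop("genotype columns (", ncol(g), ") do not match locus registry (",
         nrow(x$loci), ")", call. = FALSE)
  }
  if (anyDuplicated(x$samples$sample_id)) {
    stop("duplicate sample_id in registry", call. = FALSE)
  }
  if (anyDuplicated(x$loci$locus_id)) {
    stop("duplicate locus_id in registry", call. = FALSE)
  }
  bad <- !(g %in% c(0, 1, 2) | is.na(g))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x", nrow(x$loci), "loci\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  if (!all(is.na(x$samples$form))) {
    cat("  forms:", paste(names(table(x$samples$form)),
                          table(x$samples$form), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Number of samples / loci in a dataset
#' @param dataset a [genotype_dataset()].
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$genotypes)

#' @rdname n_samples
#' @export
n_loci <- function(dataset) ncol(dataset$genotypes)

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C", `0` = "0")

#' Read a PLINK text PED/MAP dataset
#'
#' Parses whitespace-delimited PED/MAP files and recodes each locus to
#' B-allele dosage. Within a PED column the two observed alleles are
#' assigned alphabetically: `allele_a` is the smaller code and `allele_b`
#' (the counted allele) the greater. A pair containing `"0"` is missing.
#' Monomorphic columns keep `allele_b = "0"` and read as dosage 0.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (chromosome, locus id, cM, bp).
#' @param metadata_path optional delimited text file with header
#'   `sample_id,form,country,population_id,longitude_deg,cluster_id`,
#'   joined on `sample_id`. Metadata rows without a matching PED sample
#'   raise a warning, not an error.
#' @return a [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path, metadata_path = NULL) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric", "numeric"))
  names(map) <- c("chromosome", "locus_id", "cm", "position_bp")
  n_loc <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_loc
  lens <- lengths(toks)
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    stop("ragged PED row at line ", bad, ": expected ", want,
         " fields, found ", lens[bad], call. = FALSE)
  }
  n_samp <- length(toks)
  ped <- matrix(unlist(toks), nrow = n_samp, byrow = TRUE)
  sample_id <- ped[, 2]
  family_id <- ped[, 1]

  a1 <- ped[, 6L + 2L * seq_len(n_loc) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_loc), drop = FALSE]

  allele_a <- character(n_loc)
  allele_b <- character(n_loc)
  geno <- matrix(NA_real_, n_samp, n_loc)
  for (j in seq_len(n_loc)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2) {
      stop("more than 2 distinct alleles at locus ", map$locus_id[j],
           call. = FALSE)
    }
    allele_a[j] <- if (length(alleles) >= 1) alleles[1] else "0"
    allele_b[j] <- if (length(alleles) == 2) alleles[2] else "0"
    called <- a1[, j] != "0" & a2[, j] != "0"
    geno[called, j] <- (a1[called, j] == allele_b[j]) + (a2[called, j] == allele_b[j])
  }

  loci <- data.frame(locus_id = map$locus_id, chromosome = map$chromosome,
                     position_bp = map$position_bp, allele_a = allele_a,
                     allele_b = allele_b, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, population_id = family_id,
                        stringsAsFactors = FALSE)

  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!"sample_id" %in% names(meta)) {
      stop("metadata file must have a sample_id column", call. = FALSE)
    }
    orphan <- setdiff(meta$sample_id, sample_id)
    if (length(orphan)) {
      warning("metadata rows without a PED sample: ",
              paste(orphan, collapse = ", "), call. = FALSE)
    }
    idx <- match(sample_id, meta$sample_id)
    for (col in setdiff(names(meta), "sample_id")) {
      samples[[col]] <- meta[[col]][idx]
    }
    if (!is.null(samples$longitude_deg)) {
      samples$longitude_deg <- as.numeric(samples$longitude_deg)
    }
  }
  genotype_dataset(geno, loci, samples)
}

#' Write a dataset as a PLINK text PED/MAP pair
#'
#' Dosage 0 is written as two copies of `allele_a`, 1 as a heterozygous
#' pair, 2 as two copies of `allele_b`, and missing cells as `0 0`.
#' Round-trips bit-identically through [read_ped_map()] for datasets whose
#' allele codes follow the alphabetical `allele_a < allele_b` convention.
#'
#' @param dataset a [genotype_dataset()] with at least one locus.
#' @param out_prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(dataset, out_prefix) {
  if (n_loci(dataset) == 0 || n_samples(dataset) == 0) {
    stop("cannot write an empty dataset", call. = FALSE)
  }
  g <- dataset$genotypes
  loci <- dataset$loci
  n_loc <- nrow(loci)
  n_samp <- nrow(g)

  alle <- matrix("0", n_samp, 2L * n_loc)
  for (j in seq_len(n_loc)) {
    a <- loci$allele_a[j]; b <- loci$allele_b[j]
    col <- g[, j]
    first <- ifelse(is.na(col), "0", ifelse(col >= 1, b, a))
    second <- ifelse(is.na(col), "0", ifelse(col == 2, b, a))
    alle[, 2L * j - 1L] <- first
    alle[, 2L * j] <- second
  }
  fam <- dataset$samples$population_id
  fam[is.na(fam) | fam == ""] <- "0"
  lead <- cbind(fam, dataset$samples$sample_id, "0", "0", "0", "-9")
  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  utils::write.table(cbind(lead, alle), ped_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  map <- data.frame(loci$chromosome, loci$locus_id, 0, loci$position_bp)
  utils::write.table(map, map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(c(ped = ped_path, map = map_path))
}

# Harmonize dataset b's coding at one locus against pair (a_a, a_b).
# Returns list(action = "keep" | "swap" | "drop").
harmonize_alleles <- function(a_pair, b_pair) {
  known_a <- a_pair[a_pair != "0"]
  known_b <- b_pair[b_pair != "0"]
  palindromic <- function(p) {
    all(p != "0") && identical(sort(p), sort(unname(COMPLEMENT[p])))
  }
  # fill unknown alleles from the other pair when one side is monomorphic
  if (length(known_b) == 1) {
    if (known_b == a_pair[1]) return(list(action = "keep"))
    if (known_b == a_pair[2]) return(list(action = "swap"))
    if (COMPLEMENT[known_b] == a_pair[1]) return(list(action = "keep"))
    if (COMPLEMENT[known_b] == a_pair[2]) return(list(action = "swap"))
    return(list(action = "drop"))
  }
  if (length(known_a) == 1) {
    if (a_pair[1] %in% b_pair) {
      return(list(action = if (a_pair[1] == b_pair[1]) "keep" else "swap"))
    }
    if (COMPLEMENT[a_pair[1]] %in% b_pair) {
      return(list(action = if (COMPLEMENT[a_pair[1]] == b_pair[1]) "keep" else "swap"))
    }
    return(list(action = "drop"))
  }
  if (identical(b_pair, a_pair)) return(list(action = "keep"))
  if (identical(b_pair, rev(a_pair))) {
    # a swapped palindromic (A/T, C/G) pair cannot be told from a strand flip
    if (palindromic(a_pair)) return(list(action = "drop"))
    return(list(action = "swap"))
  }
  comp_b <- unname(COMPLEMENT[b_pair])
  if (identical(comp_b, a_pair)) return(list(action = "keep"))
  if (identical(comp_b, rev(a_pair))) {
    if (palindromic(a_pair)) return(list(action = "drop"))
    return(list(action = "swap"))
  }
  list(action = "drop")
}

#' Merge two genotype datasets
#'
#' Returns the union of samples restricted to the shared loci (matched on
#' `locus_id`), with `b`'s allele coding harmonized to `a`'s: identical
#' pairs are kept, swapped pairs are recoded `g -> 2 - g`, strand flips
#' (A/G vs T/C) are resolved by complementing, and ambiguous palindromic
#' (A/T, C/G) loci whose coding disagrees are dropped with a reported
#' count (also available as `attr(result, "dropped_loci")`).
#'
#' @param a,b [genotype_dataset()] objects with disjoint sample ids.
#' @return merged [genotype_dataset()].
#' @export
merge_datasets <- function(a, b) {
  dup <- intersect(a$samples$sample_id, b$samples$sample_id)
  if (length(dup)) {
    stop("duplicate sample_id across datasets: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  common <- intersect(a$loci$locus_id, b$loci$locus_id)
  if (!length(common)) stop("no shared loci between datasets", call. = FALSE)

  ia <- match(common, a$loci$locus_id)
  ib <- match(common, b$loci$locus_id)
  keep <- logical(length(common))
  gb <- b$genotypes[, ib, drop = FALSE]
  for (k in seq_along(common)) {
    pa <- c(a$loci$allele_a[ia[k]], a$loci$allele_b[ia[k]])
    pb <- c(b$loci$allele_a[ib[k]], b$loci$allele_b[ib[k]])
    h <- harmonize_alleles(pa, pb)
    if (h$action == "drop") next
    keep[k] <- TRUE
    if (h$action == "swap") gb[, k] <- 2 - gb[, k]
  }
  n_drop <- sum(!keep)
  if (n_drop) {
    message("merge_datasets: dropped ", n_drop,
            " loci with irreconcilable allele coding")
  }
  loci <- a$loci[ia[keep], , drop = FALSE]
  rownames(loci) <- NULL
  geno <- rbind(a$genotypes[, ia[keep], drop = FALSE], gb[, keep, drop = FALSE])
  samples <- rbind_fill(a$samples, b$samples)
  out <- genotype_dataset(geno, loci, samples)
  attr(out, "dropped_loci") <- n_drop
  out
}

rbind_fill <- function(x, y) {
  cols <- union(names(x), names(y))
  for (col in setdiff(cols, names(x))) x[[col]] <- NA
  for (col in setdiff(cols, names(y))) y[[col]] <- NA
  rbind(x[cols], y[cols])
}

#' Subset a dataset by sample and/or locus ids
#'
#' Retained samples and loci follow the order of the request lists.
#'
#' @param dataset a [genotype_dataset()].
#' @param sample_ids character vector of sample ids to keep (default: all).
#' @param locus_ids character vector of locus ids to keep (default: all).
#' @return a [genotype_dataset()].
#' @export
subset_dataset <- function(dataset, sample_ids = NULL, locus_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- dataset$samples$sample_id
  if (is.null(locus_ids)) locus_ids <- dataset$loci$locus_id
  si <- match(sample_ids, dataset$samples$sample_id)
  if (anyNA(si)) {
    stop("unknown sample_id: ", paste(sample_ids[is.na(si)], collapse = ", "),
         call. = FALSE)
  }
  li <- match(locus_ids, dataset$loci$locus_id)
  if (anyNA(li)) {
    stop("unknown locus_id: ", paste(locus_ids[is.na(li)], collapse = ", "),
         call. = FALSE)
  }
  samples <- dataset$samples[si, , drop = FALSE]
  loci <- dataset$loci[li, , drop = FALSE]
  rownames(samples) <- NULL
  rownames(loci) <- NULL
  genotype_dataset(dataset$genotypes[si, li, drop = FALSE], loci, samples)
}
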