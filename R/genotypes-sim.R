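#' Simulate replicate microsatellite genotypes for NGS samples
#'
#' Emulates the laboratory protocol for low-quality non-invasive samples:
#' every sample is amplified three times at each marker, and each replicate
#' call can be corrupted by allelic dropout (a heterozygote losing one allele,
#' scored as a homozygote) or a false allele, or can fail entirely.  True
#' multilocus genotypes are drawn once per individual, so samples from the
#' same individual share a genotype.
#'
#' @param samples Sample table with columns `sample_id` and `individual_id`
#'   (e.g. from [detections_to_samples()]).
#' @param n_loci Number of autosomal microsatellite markers (default 14).  The
#'   sex-determination assay is modelled separately (the `sex` column of the
#'   sample table), not as a scored marker.
#' @param error_rates Named vector `c(dropout = , false_allele = )`, each in
#'   `[0, 0.5)`.
#' @param n_alleles Alleles per locus in the simulated population.
#' @param missing_rate Probability a replicate call fails completely.
#' @param seed Integer seed (required).
#' @return A long tibble with columns `sample_id`, `marker`, `replicate`,
#'   `allele1`, `allele2` (integer allele codes, `NA` for failed calls) and an
#'   attribute `truth` holding the per-individual true genotypes.
#' @export
simulate_replicate_genotypes <- function(samples, n_loci = 14,
                                         error_rates = c(dropout = 0.1,
                                                         false_allele = 0.02),
                                         n_alleles = 8, missing_rate = 0,
                                         seed) {
  seed <- check_seed(seed)
  dropout <- error_rates[["dropout"]]
  false_allele <- error_rates[["false_allele"]]
  if (any(c(dropout, false_allele) < 0) || any(c(dropout, false_allele) >= 0.5)) {
    abort("error rates must be in [0, 0.5)", class = "foxscr_error_domain")
  }
  inds <- unique(samples$individual_id)
  markers <- sprintf("m%02d", seq_len(n_loci))

  withr::with_seed(seed, {
    truth <- tidyr::expand_grid(individual_id = inds, marker = markers)
    a <- matrix(sample.int(n_alleles, 2 * nrow(truth), replace = TRUE), ncol = 2)
    truth$allele1 <- pmin(a[, 1], a[, 2])
    truth$allele2 <- pmax(a[, 1], a[, 2])

    out <- tidyr::expand_grid(
      sample_id = samples$sample_id,
      marker = markers,
      replicate = 1:3
    ) |>
      dplyr::left_join(
        dplyr::select(samples, "sample_id", "individual_id"), by = "sample_id"
      ) |>
      dplyr::left_join(truth, by = c("individual_id", "marker"))

    m <- nrow(out)
    a1 <- out$allele1
    a2 <- out$allele2
    # allelic dropout: heterozygote scored as a homozygote of one allele
    is_het <- a1 != a2
    drop_hit <- is_het & runif(m) < dropout
    keep_first <- runif(m) < 0.5
    a1[drop_hit & !keep_first] <- a2[drop_hit & !keep_first]
    a2[drop_hit & keep_first] <- a1[drop_hit & keep_first]
    # false alleles: each allele independently replaced by a different allele
    for (slot in 1:2) {
      hit <- runif(m) < false_allele
      if (any(hit)) {
        cur <- if (slot == 1) a1[hit] else a2[hit]
        shift <- sample.int(n_alleles - 1, sum(hit), replace = TRUE)
        new <- ((cur - 1 + shift) %% n_alleles) + 1
        if (slot == 1) a1[hit] <- new else a2[hit] <- new
      }
    }
    # whole-call failures
    fail <- runif(m) < missing_rate
    a1[fail] <- NA_integer_
    a2[fail] <- NA_integer_
  })

  out$allele1 <- pmin(a1, a2)
  out$allele2 <- pmax(a1, a2)
  out <- dplyr::select(out, "sample_id", "marker", "replicate",
                       "allele1", "allele2")
  attr(out, "truth") <- truth
  out
}
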