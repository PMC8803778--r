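#' Consensus genotype call from three replicates
#'
#' Applies the replicate-consistency rule used for NGS genotyping: a
#' homozygote is accepted only when all three replicates are identical
#' homozygotes; a heterozygote is accepted when at least two replicates are
#' the same heterozygote; otherwise the marker is scored missing.  Allele
#' pairs are unordered.
#'
#' @param replicates A list of exactly 3 calls, each a length-2 vector of
#'   allele codes (`NA` for a failed call), or a 3 x 2 matrix.
#' @return A length-2 vector (sorted allele pair) or `c(NA, NA)`.
#' @examples
#' consensus_call(list(c(1, 2), c(2, 1), c(1, 1)))  # heterozygote 1/2
#' consensus_call(list(c(1, 1), c(1, 1), c(1, 2)))  # no consensus
#' @export
consensus_call <- function(replicates) {
  if (is.matrix(replicates)) {
    replicates <- lapply(seq_len(nrow(replicates)), function(i) replicates[i, ])
  }
  if (length(replicates) != 3) {
    abort("exactly 3 replicate calls are required", class = "foxscr_error_input")
  }
  keys <- vapply(replicates, call_key, character(1))
  consensus_from_keys(keys[1], keys[2], keys[3])
}

# Canonical unordered representation of one diploid call; NA for missing.
call_key <- function(call) {
  if (length(call) != 2) {
    abort("a diploid call must have exactly 2 alleles",
          class = "foxscr_error_input")
  }
  if (anyNA(call)) return(NA_character_)
  paste(sort(as.character(call)), collapse = "/")
}

# Vectorised consensus rule on canonical keys; returns consensus keys.
consensus_from_keys <- function(k1, k2, k3) {
  is_het <- function(k) !is.na(k) & !vapply(
    strsplit(k, "/", fixed = TRUE),
    function(p) length(p) == 2 && p[1] == p[2], logical(1)
  )
  # unanimous homozygote
  hom_ok <- !is.na(k1) & !is.na(k2) & !is.na(k3) & k1 == k2 & k2 == k3 & !is_het(k1)
  # >= 2 identical heterozygote calls
  cand <- ifelse(!is.na(k1) & ((!is.na(k2) & k1 == k2) | (!is.na(k3) & k1 == k3)),
                 k1,
                 ifelse(!is.na(k2) & !is.na(k3) & k2 == k3, k2, NA_character_))
  het_ok <- !is.na(cand) & is_het(cand)
  out <- rep(NA_character_, length(k1))
  out[het_ok] <- cand[het_ok]
  out[hom_ok] <- k1[hom_ok]
  if (length(out) == 1) {
    if (is.na(out)) return(c(NA_character_, NA_character_))
    return(strsplit(out, "/", fixed = TRUE)[[1]])
  }
  out
}

# Wide per-(sample, marker) replicate keys; shared by the calling functions.
replicate_keys <- function(replicates_tbl) {
  needed <- c("sample_id", "marker", "replicate", "allele1", "allele2")
  if (!all(needed %in% names(replicates_tbl))) {
    abort("replicate table needs columns sample_id, marker, replicate, allele1, allele2",
          class = "foxscr_error_input")
  }
  reps_per <- dplyr::count(replicates_tbl, .data$sample_id, .data$marker)
  if (any(reps_per$n != 3)) {
    abort("exactly 3 replicates per sample and marker are required",
          class = "foxscr_error_input")
  }
  a1c <- as.character(replicates_tbl$allele1)
  a2c <- as.character(replicates_tbl$allele2)
  tb <- replicates_tbl |>
    dplyr::mutate(
      key = ifelse(is.na(a1c) | is.na(a2c), NA_character_,
                   paste(pmin(a1c, a2c), pmax(a1c, a2c), sep = "/"))
    ) |>
    dplyr::group_by(.data$sample_id, .data$marker) |>
    dplyr::mutate(replicate_slot = paste0("r", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "marker", "replicate_slot", "key") |>
    tidyr::pivot_wider(names_from = "replicate_slot", values_from = "key")
  tb$consensus <- consensus_from_keys(tb$r1, tb$r2, tb$r3)
  tb
}

#' Call consensus genotypes for a replicate table
#'
#' @param replicates_tbl Long replicate table with columns `sample_id`,
#'   `marker`, `replicate` (1-3), `allele1`, `allele2`.
#' @return A tibble with one row per sample and marker: `sample_id`, `marker`,
#'   `allele1`, `allele2` (consensus call, `NA` when no consensus).
#' @export
call_consensus <- function(replicates_tbl) {
  keys <- replicate_keys(replicates_tbl)
  parts <- strsplit(ifelse(is.na(keys$consensus), "NA/NA", keys$consensus),
                    "/", fixed = TRUE)
  keys |>
    dplyr::transmute(
      .data$sample_id, .data$marker,
      allele1 = vapply(parts, `[`, character(1), 1),
      allele2 = vapply(parts, `[`, character(1), 2)
    ) |>
    dplyr::mutate(
      allele1 = dplyr::na_if(.data$allele1, "NA"),
      allele2 = dplyr::na_if(.data$allele2, "NA")
    )
}

#' Per-sample genotype quality index
#'
#' The quality index (QI) of a sample is the proportion of replicate calls,
#' across all markers, that agree with that marker's consensus call.  Markers
#' without a consensus contribute all three replicates as inconsistent, as do
#' failed replicate calls.  Samples at or above the threshold are retained.
#'
#' @inheritParams call_consensus
#' @param threshold Retention threshold on QI (default 0.70).
#' @return A tibble `sample_id`, `qi`, `retained`.
#' @export
quality_index <- function(replicates_tbl, threshold = 0.70) {
  if (nrow(replicates_tbl) == 0) {
    abort("at least one marker is required", class = "foxscr_error_domain")
  }
  keys <- replicate_keys(replicates_tbl)
  keys |>
    tidyr::pivot_longer(c("r1", "r2", "r3"), names_to = "replicate",
                        values_to = "key") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      qi = mean(!is.na(.data$consensus) & !is.na(.data$key) &
                  .data$key == .data$consensus),
      .groups = "drop"
    ) |>
    dplyr::mutate(retained = .data$qi >= threshold)
}

#' Cluster retained genotypes into individuals
#'
#' A deliberately simple stand-in for dedicated multilocus-matching software:
#' greedy clustering in ascending `sample_id` order, where a sample joins the
#' first existing cluster whose exemplar disagrees at no more than
#' `max_mismatch` markers among markers scored in both (and shares at least
#' one scored marker); otherwise it founds a new cluster.  Deterministic given
#' the input.
#'
#' @param consensus Consensus genotype table from [call_consensus()].
#' @param quality Optional [quality_index()] table; when supplied, only
#'   retained samples are clustered.
#' @param max_mismatch Maximum number of disagreeing markers for two samples
#'   to share an identity (default 0).
#' @return A tibble `sample_id`, `individual` (cluster labels `ind_001`, ...).
#' @export
match_individuals <- function(consensus, quality = NULL, max_mismatch = 0) {
  if (!is.null(quality)) {
    keep <- quality$sample_id[quality$retained]
    consensus <- consensus[consensus$sample_id %in% keep, ]
  }
  wide <- consensus |>
    dplyr::mutate(key = ifelse(is.na(.data$allele1), NA_character_,
                               paste(.data$allele1, .data$allele2, sep = "/"))) |>
    dplyr::select("sample_id", "marker", "key") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "key") |>
    dplyr::arrange(.data$sample_id)
  ids <- wide$sample_id
  mat <- as.matrix(wide[, -1, drop = FALSE])

  exemplars <- list()
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    gi <- mat[i, ]
    hit <- 0L
    for (k in seq_along(exemplars)) {
      gk <- exemplars[[k]]
      both <- !is.na(gi) & !is.na(gk)
      if (!any(both)) next
      if (sum(gi[both] != gk[both]) <= max_mismatch) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      exemplars[[length(exemplars) + 1L]] <- gi
      hit <- length(exemplars)
    }
    assignment[i] <- hit
  }
  tibble(sample_id = ids, individual = sprintf("ind_%03d", assignment))
}
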