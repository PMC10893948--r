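#' Allele proportion at an inter-homoeologue polymorphism
#'
#' Proportion of the A-diagnostic base signal among the A- and C-diagnostic
#' peak intensities at an IHP position of a co-amplified homoeologue pair.
#' Scale-invariant: only the ratio of the two intensities matters.
#'
#' @param intensity_A,intensity_C Non-negative peak intensities (vectors).
#' @return `p_A = intensity_A / (intensity_A + intensity_C)`; `NA` (no-call)
#'   where both intensities are zero.
#' @export
ihp_proportion <- function(intensity_A, intensity_C) {
  if (any(intensity_A < 0, na.rm = TRUE) ||
      any(intensity_C < 0, na.rm = TRUE)) {
    stop_bad_arg("peak intensities must be >= 0")
  }
  tot <- intensity_A + intensity_C
  ifelse(tot > 0, intensity_A / tot, NA_real_)
}

#' Copy-state hypotheses for IHP classification
#'
#' Each class is an (A copies, C copies) state with expected A-base
#' proportion `a / (a + c)`. The default set spans the A-genome deletion
#' series, homozygous A duplication and homozygous C loss; adjacent
#' expectations are then spaced at least 1/6 apart, so the default margin
#' can never produce an ambiguous call. Two states are deliberately not in
#' the default set: heterozygous C loss (2,1) is exactly confounded with
#' homozygous A duplication (4,2) at p = 2/3, and heterozygous A
#' duplication (3,2), at p = 3/5, sits only 1/15 from (4,2) — too close to
#' resolve at typical chromatogram noise. Both can be requested explicitly.
#'
#' @param a_copies,c_copies Integer copy numbers (a + c > 0 per class);
#'   expected proportions must be pairwise distinct.
#' @return Tibble with `a_copies`, `c_copies`, `label`, `expected_p`.
#' @export
copy_classes <- function(a_copies = c(0, 1, 2, 4, 2),
                         c_copies = c(2, 2, 2, 2, 0)) {
  if (length(a_copies) != length(c_copies) || length(a_copies) == 0) {
    stop_bad_arg("`a_copies` and `c_copies` must be equal-length, non-empty")
  }
  if (any(a_copies + c_copies <= 0)) {
    stop_bad_arg("each class needs a_copies + c_copies > 0")
  }
  tibble::tibble(
    a_copies = as.integer(a_copies), c_copies = as.integer(c_copies),
    label = sprintf("A%dC%d", a_copies, c_copies),
    expected_p = a_copies / (a_copies + c_copies)
  )
}

#' Classify copy state from an IHP allele proportion
#'
#' Nearest-expectation classification with a no-call margin: a proportion
#' further than `margin` from every class expectation, or equidistant
#' between two classes, is returned as no-call (`NA`).
#'
#' @param p_A Observed A-base proportions.
#' @param classes A [copy_classes()] table with distinct expectations.
#' @param margin Maximum allowed |p - expectation| (default 0.08, below
#'   half the 1/6 spacing of adjacent default classes).
#' @return Character vector of class labels (`NA` = no-call).
#' @export
classify_ihp <- function(p_A, classes = copy_classes(), margin = 0.08) {
  if (nrow(classes) == 0) stop_bad_arg("empty class set")
  if (anyDuplicated(round(classes$expected_p, 9))) {
    stop_bad_arg("class expectations must be distinct")
  }
  vapply(p_A, function(p) {
    if (is.na(p)) return(NA_character_)
    d <- abs(p - classes$expected_p)
    o <- order(d)
    if (d[o[1]] > margin) return(NA_character_)
    if (length(o) > 1 && d[o[2]] - d[o[1]] < 1e-6) return(NA_character_)
    classes$label[o[1]]
  }, character(1))
}

#' Consensus genotype across IHP markers
#'
#' Majority vote over per-marker class calls for one sample; no-calls are
#' ignored. Ties (no strict majority among voting markers) give no-call.
#'
#' @param calls Character vector of per-marker class labels (`NA` allowed).
#' @return List with `genotype` (label or `NA`), `agreement` (fraction of
#'   voting markers supporting the consensus) and `n_voting`.
#' @export
ihp_consensus <- function(calls) {
  voting <- calls[!is.na(calls)]
  if (length(voting) == 0) {
    return(list(genotype = NA_character_, agreement = NA_real_,
                n_voting = 0L))
  }
  tab <- sort(table(voting), decreasing = TRUE)
  top <- tab[1]
  tied <- sum(tab == top) > 1
  list(
    genotype = if (tied) NA_character_ else names(tab)[1],
    agreement = if (tied) NA_real_ else unname(top) / length(voting),
    n_voting = length(voting)
  )
}

#' Genotype a table of IHP signals
#'
#' @param signals Tibble with `sample_id`, `marker`, `intensity_A`,
#'   `intensity_C`.
#' @inheritParams classify_ihp
#' @return Tibble per sample: `sample_id`, `genotype`, `agreement`,
#'   `n_voting`, plus the per-marker calls nested in `marker_calls`.
#' @export
genotype_ihp <- function(signals, classes = copy_classes(), margin = 0.08) {
  signals |>
    dplyr::mutate(
      p_A = ihp_proportion(.data$intensity_A, .data$intensity_C),
      call = classify_ihp(.data$p_A, classes, margin)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      marker_calls = list(stats::setNames(.data$call, .data$marker)),
      genotype = ihp_consensus(.data$call)$genotype,
      agreement = ihp_consensus(.data$call)$agreement,
      n_voting = ihp_consensus(.data$call)$n_voting,
      .groups = "drop")
}
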