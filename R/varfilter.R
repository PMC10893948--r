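# record-keeping: filters only touch still-passing rows, append to the
# history, and stamp `filter` with the name of the removing filter, so
# every input record ends up in survivors or rejects exactly once.
mark_filter <- function(records, fail, name) {
  active <- is.na(records$filter)
  records$filter_history <- ifelse(
    active,
    paste0(records$filter_history, name, ":",
           ifelse(fail & active, "fail", "pass"), ";"),
    records$filter_history)
  records$filter[active & fail] <- name
  records
}

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L

#' Surviving variant records
#'
#' @param records Record tibble carrying a `filter` column.
#' @return Records no filter has removed.
#' @export
variant_survivors <- function(records) {
  records[is.na(records$filter), , drop = FALSE]
}

#' Quality and indel-proximity filter
#'
#' Removes records with `QUAL <= qual_min` and SNVs lying within `snp_gap`
#' bases of a retained InDel on the same chromosome (and sample); InDels
#' themselves are never removed by the gap rule.
#'
#' @param records Sample-resolved record tibble sorted by chrom, pos
#'   ([read_vcf()] output layout).
#' @param qual_min QUAL threshold (records at or below are dropped).
#' @param snp_gap Exclusion distance around retained InDels (bases).
#' @return Records with `filter`/`filter_history` updated (`qual`,
#'   `snp_gap`).
#' @export
filter_quality <- function(records, qual_min = 20, snp_gap = 3) {
  if (nrow(records) > 0) {
    o <- order(records$chrom, records$pos)
    if (is.unsorted(o)) {
      stop_bad_arg("records must be sorted by chrom, pos")
    }
  }
  records <- mark_filter(records, records$qual <= qual_min, "qual")
  active <- is.na(records$filter)
  snv <- active & is_snv(records$ref, records$alt)
  near_indel <- rep(FALSE, nrow(records))
  indels <- records[active & !is_snv(records$ref, records$alt), ,
                    drop = FALSE]
  if (nrow(indels) > 0 && any(snv)) {
    has_sample <- "sample" %in% names(records)
    for (i in which(snv)) {
      same <- indels$chrom == records$chrom[i]
      if (has_sample) same <- same & indels$sample == records$sample[i]
      if (any(same) &&
          min(abs(indels$pos[same] - records$pos[i])) <= snp_gap) {
        near_indel[i] <- TRUE
      }
    }
  }
  mark_filter(records, near_indel, "snp_gap")
}

#' Subtract the control master set
#'
#' Any mutant record whose (chrom, pos) appears in the merged control
#' variant set is removed, regardless of allele: pre-existing variation and
#' systematic call artifacts are position-level phenomena.
#'
#' @param records Mutant record tibble (quality-filtered).
#' @param control_records Control record tibble (quality-filtered); all
#'   surviving control positions form the master set.
#' @return Records with the `controls` filter applied.
#' @export
subtract_controls <- function(records, control_records) {
  master <- unique(paste(variant_survivors(control_records)$chrom,
                         variant_survivors(control_records)$pos))
  mark_filter(records, paste(records$chrom, records$pos) %in% master,
              "controls")
}

#' Recurrence (occurrence) filter
#'
#' A variant called in more than `max_occurrence` samples is treated as a
#' systematic artifact and removed from every sample: independent radiation
#' events are line-specific.
#'
#' @param records Sample-resolved records across the panel.
#' @param max_occurrence Largest allowed number of carrier samples
#'   (default 8).
#' @return Records with the `occurrence` filter applied.
#' @export
filter_occurrence <- function(records, max_occurrence = 8) {
  active <- variant_survivors(records)
  occ <- active |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$sample) |>
    dplyr::count(.data$chrom, .data$pos, .data$ref, .data$alt)
  bad <- occ[occ$n > max_occurrence, , drop = FALSE]
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  mark_filter(records, key %in% paste(bad$chrom, bad$pos, bad$ref, bad$alt),
              "occurrence")
}

#' Restrict records to target gene regions
#'
#' @param records Record tibble.
#' @param gene_regions Tibble with `chrom`, `start`, `end` (1-based
#'   inclusive spans).
#' @return Records with the `region` filter applied to records outside all
#'   spans.
#' @export
filter_region <- function(records, gene_regions) {
  inside <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(gene_regions))) {
    inside <- inside | (records$chrom == gene_regions$chrom[i] &
                          records$pos >= gene_regions$start[i] &
                          records$pos <= gene_regions$end[i])
  }
  mark_filter(records, !inside, "region")
}

#' Tier records by variant-allele read depth
#'
#' VAD = 2 calls have a far higher false-positive rate than VAD > 2 calls,
#' so records are tiered `low` (VAD = 2), `standard` (VAD > 2) and
#' `reject` (VAD < 2).
#'
#' @param records Record tibble with a `vad` column.
#' @return Records with a `tier` column added.
#' @export
tier_by_vad <- function(records) {
  records$tier <- dplyr::case_when(
    records$vad < 2 ~ "reject",
    records$vad == 2 ~ "low",
    TRUE ~ "standard")
  records
}

#' Per-tier validation report
#'
#' Counts tested and validated records per VAD tier and renders the
#' validation percentage both to the nearest integer and to one decimal
#' place (both renderings occur in practice: 10/26 prints as 38%, 2/57 as
#' 3.5%). Tiers with nothing tested report `NA`.
#'
#' @param records Tiered records ([tier_by_vad()]).
#' @param validated Logical vector (or column name, default `"is_true"`)
#'   marking validated records.
#' @return Tibble: `tier`, `tested`, `validated`, `pct`, `pct_1dp`.
#' @export
validation_report <- function(records, validated = "is_true") {
  if (is.character(validated) && length(validated) == 1) {
    validated <- records[[validated]]
  }
  records$validated <- validated
  records |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(tested = dplyr::n(),
                     validated = sum(.data$validated), .groups = "drop") |>
    dplyr::mutate(
      pct = ifelse(.data$tested > 0,
                   round_half_up(100 * .data$validated / .data$tested, 0),
                   NA_real_),
      pct_1dp = ifelse(.data$tested > 0,
                       round_half_up(100 * .data$validated / .data$tested, 1),
                       NA_real_))
}

#' Run the full small-variant filter chain
#'
#' Applies the filters in the pipeline order: quality (QUAL, SNV-near-InDel
#' gap) on mutants and controls, control-position subtraction, panel-wide
#' recurrence, optional target-region restriction — then tiers survivors by
#' VAD.
#'
#' @param records Mutant sample records.
#' @param control_records Control sample records.
#' @param gene_regions Optional region table for [filter_region()].
#' @param qual_min,snp_gap,max_occurrence Filter settings.
#' @return List with `records` (all records, histories stamped) and
#'   `survivors`.
#' @export
run_variant_filters <- function(records, control_records,
                                gene_regions = NULL, qual_min = 20,
                                snp_gap = 3, max_occurrence = 8) {
  records <- filter_quality(records, qual_min, snp_gap)
  control_records <- filter_quality(control_records, qual_min, snp_gap)
  records <- subtract_controls(records, control_records)
  records <- filter_occurrence(records, max_occurrence)
  if (!is.null(gene_regions)) records <- filter_region(records, gene_regions)
  records <- tier_by_vad(records)
  list(records = records, survivors = variant_survivors(records))
}
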