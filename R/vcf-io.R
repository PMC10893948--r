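#' Write sample-resolved variant calls as a multi-sample VCF v4.2
#'
#' Sites are the distinct (chrom, pos, ref, alt) tuples; carriers get
#' `GT:AD:DP` genotype fields (AD from a nominal total depth of 12 reads),
#' non-carriers `./.`. Site QUAL is the maximum carrier QUAL.
#'
#' @param variants Long tibble with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `sample`, `gt`, `vad` (e.g. `$variants` of [simulate_variants()]).
#' @param path Output `.vcf` path (plain text).
#' @param contigs Optional contig names for the header.
#' @param total_depth Nominal per-site read depth used for the AD field.
#' @export
write_vcf <- function(variants, path, contigs = NULL, total_depth = 12L) {
  samples <- sort(unique(variants$sample))
  v <- variants |>
    dplyr::mutate(site = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                               sep = "\r")) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  sites <- v |>
    dplyr::group_by(.data$site, .data$chrom, .data$pos, .data$ref,
                    .data$alt) |>
    dplyr::summarise(qual = max(.data$qual), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)

  gt_mat <- matrix("./.:.:.", nrow = nrow(sites), ncol = length(samples),
                   dimnames = list(sites$site, samples))
  ad_ref <- pmax(0L, total_depth - v$vad)
  cell <- sprintf("%s:%d,%d:%d", v$gt, ad_ref, v$vad,
                  pmax(total_depth, v$vad))
  gt_mat[cbind(match(v$site, sites$site), match(v$sample, samples))] <- cell

  contigs <- contigs %||% unique(sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radpanel",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                format(round(sites$qual, 2), trim = TRUE, scientific = FALSE),
                ".", ".", "GT:AD:DP",
                apply(gt_mat, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into sample-resolved variant records
#'
#' Parses with `vcfR` and explodes to one row per (site, carrier sample),
#' splitting multi-allelic sites into one record per ALT allele. The
#' variant-allele read depth (VAD) is taken from the AD genotype field.
#' Records start with an empty filter history.
#'
#' @param path VCF file path.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `qual`, `sample`,
#'   `gt`, `vad`, `filter` (`NA` until a filter removes the record) and
#'   `filter_history`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  out <- list()
  for (s in colnames(gt)) {
    carrier <- which(!is.na(gt[, s]) & !gt[, s] %in% c("./.", ".|.", "."))
    if (length(carrier) == 0) next
    alts <- strsplit(fix$ALT[carrier], ",", fixed = TRUE)
    ads <- strsplit(ad[carrier, s], ",", fixed = TRUE)
    n_alt <- lengths(alts)
    idx <- rep(seq_along(carrier), n_alt)
    alt_no <- unlist(lapply(n_alt, seq_len))
    vad <- suppressWarnings(as.integer(mapply(
      function(a, k) if (length(a) > k) a[k + 1L] else NA_character_,
      ads[idx], alt_no)))
    out[[s]] <- tibble::tibble(
      chrom = fix$CHROM[carrier][idx],
      pos = as.integer(fix$POS[carrier][idx]),
      ref = fix$REF[carrier][idx],
      alt = unlist(alts),
      qual = as.numeric(fix$QUAL[carrier][idx]),
      sample = s,
      gt = gt[carrier, s][idx],
      vad = vad)
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$sample) |>
    dplyr::mutate(filter = NA_character_, filter_history = "")
}
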