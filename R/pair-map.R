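#' Build a synthetic homoeologue pair map
#'
#' One row per A/C homoeologue gene pair, ordered by A-genome chromosome and
#' gene-order index: the coordinate system of all dosage analysis and of the
#' tile plots. Pairs are distributed over the 9 C chromosomes in contiguous
#' synteny blocks; C gene-order indices are inflated by `c_extra_frac` so the
#' C genome carries more genes than the A genome, as in *Brassica napus*.
#'
#' @param config A [panel_config()].
#' @return Tibble with columns `pair_id`, `gene_A`, `chrom_A`, `idx_A`,
#'   `len_A_bp`, `gene_C`, `chrom_C`, `idx_C`, `len_C_bp`. Gene-order
#'   indices are 0-based.
#' @export
make_pair_map <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n_per <- config$n_pairs_per_chrom
  if (sum(n_per) == 0) stop_bad_arg("zero homoeologue pairs requested")

  withr::with_seed(config$seed + 101L, {
    chrom_A <- rep(config$chrom_names_A, times = n_per)
    idx_A <- unlist(lapply(n_per, function(n) seq_len(n) - 1L))
    n_pairs <- length(idx_A)

    # contiguous synteny blocks over the 9 C chromosomes
    n_c <- length(config$chrom_names_C)
    block <- sort(rep_len(seq_len(n_c), n_pairs))
    chrom_C <- config$chrom_names_C[block]
    idx_in_block <- unlist(lapply(table(block), function(n) seq_len(n) - 1L),
                           use.names = FALSE)
    # gap paired genes along the C chromosome to leave room for unpaired genes
    idx_C <- as.integer(floor(idx_in_block * (1 + config$c_extra_frac)))

    len_A <- pmax(300L, as.integer(round(stats::rlnorm(n_pairs,
                                                       log(1500), 0.35))))
    len_C <- pmax(300L, as.integer(round(stats::rlnorm(n_pairs,
                                                       log(1600), 0.35))))
    tibble::tibble(
      pair_id = sprintf("pair%05d", seq_len(n_pairs)),
      gene_A = sprintf("%s.g%04d", chrom_A, idx_A),
      chrom_A = chrom_A, idx_A = idx_A, len_A_bp = len_A,
      gene_C = sprintf("%s.g%04d", chrom_C, idx_C),
      chrom_C = chrom_C, idx_C = idx_C, len_C_bp = len_C
    )
  })
}

#' Gene counts per chromosome implied by a pair map
#'
#' @param pair_map A pair map from [make_pair_map()] or [read_pair_map()].
#' @return Tibble with `subgenome`, `chrom`, `n_genes` (largest gene-order
#'   index + 1).
#' @export
chrom_sizes <- function(pair_map) {
  a <- pair_map |>
    dplyr::group_by(chrom = .data$chrom_A) |>
    dplyr::summarise(n_genes = max(.data$idx_A) + 1L, .groups = "drop") |>
    dplyr::mutate(subgenome = "A")
  c_ <- pair_map |>
    dplyr::group_by(chrom = .data$chrom_C) |>
    dplyr::summarise(n_genes = max(.data$idx_C) + 1L, .groups = "drop") |>
    dplyr::mutate(subgenome = "C")
  dplyr::bind_rows(a, c_) |>
    dplyr::select("subgenome", "chrom", "n_genes")
}

#' @rdname make_pair_map
#' @param path File path for the tab-separated pair map.
#' @export
write_pair_map <- function(pair_map, path) {
  readr::write_tsv(pair_map, path)
  invisible(path)
}

#' @rdname make_pair_map
#' @export
read_pair_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pair_id = "c", gene_A = "c", chrom_A = "c", idx_A = "i",
                    len_A_bp = "i", gene_C = "c", chrom_C = "c", idx_C = "i",
                    len_C_bp = "i"))
}

#' Sample sheet for a configured panel
#'
#' Enumerates the untreated controls and the M2 plants of every dose group.
#' Sample ids follow the panel convention, e.g. `G2000_4a` for sibling "a"
#' of gamma 2000 Gy M1 family 4.
#'
#' @param config A [panel_config()].
#' @return Tibble with `sample_id`, `role` (`control`/`treated`),
#'   `radiation_type`, `dose_Gy`, `m1_family`, `sib_label`.
#' @export
make_sample_sheet <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  controls <- tibble::tibble(
    sample_id = sprintf("Control_%02d", seq_len(config$n_controls)),
    role = "control", radiation_type = "none", dose_Gy = 0,
    m1_family = NA_character_, sib_label = NA_character_
  )
  treated <- dplyr::bind_rows(lapply(seq_len(nrow(config$doses)), function(i) {
    d <- config$doses[i, ]
    prefix <- if (d$radiation_type == "gamma") "G" else "FNT"
    fam <- rep(seq_len(d$n_m1), each = d$sibs_per_m1)
    sib <- rep(letters[seq_len(d$sibs_per_m1)], times = d$n_m1)
    tibble::tibble(
      sample_id = sprintf("%s%d_%d%s", prefix, d$dose_Gy, fam, sib),
      role = "treated",
      radiation_type = d$radiation_type,
      dose_Gy = d$dose_Gy,
      m1_family = sprintf("%s%d_%d", prefix, d$dose_Gy, fam),
      sib_label = sib
    )
  }))
  dplyr::bind_rows(controls, treated)
}
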