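#' RPKM normalization of a count matrix
#'
#' Reads per kilobase of gene per million mapped reads:
#' `rpkm = count / ((len/1000) * (total/1e6))`, with per-sample totals the
#' column sums of the raw counts. RPKM is scale-free within a sample, so
#' dosage ratios do not depend on sequencing depth.
#'
#' @param raw A `count_matrix` of raw counts, or a genes x samples matrix.
#' @param gene_lengths Gene lengths in bp (required for a bare matrix).
#' @return A `count_matrix` with `$unit = "rpkm"`.
#' @export
rpkm_normalize <- function(raw, gene_lengths = NULL) {
  if (inherits(raw, "count_matrix")) {
    m <- raw$counts
    len <- raw$genes$len_bp
    out <- raw
  } else {
    m <- as.matrix(raw)
    len <- gene_lengths
    out <- list(counts = m, genes = NULL, samples = NULL, unit = "count")
  }
  if (is.null(len) || length(len) != nrow(m)) {
    stop_bad_arg("gene lengths must match the rows of the count matrix")
  }
  if (any(len <= 0)) stop_bad_arg("zero-length gene in count matrix")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop_bad_arg("sample(s) with zero total mapped reads: %s",
                 paste(colnames(m)[totals <= 0], collapse = ", "))
  }
  rpkm <- sweep(m / (len / 1000), 2, totals / 1e6, "/")
  out$counts <- rpkm
  out$totals <- totals
  out$unit <- "rpkm"
  class(out) <- "count_matrix"
  out
}

#' Control baseline of per-gene RPKM
#'
#' Median RPKM across the untreated control samples, per gene. Genes whose
#' control median falls below `tau_min` are flagged unusable and masked in
#' downstream dosage estimation.
#'
#' @param rpkm An RPKM `count_matrix` (see [rpkm_normalize()]).
#' @param control_samples Sample ids to use; defaults to samples with
#'   `role == "control"` in the sample sheet.
#' @param tau_min Minimum usable control-median RPKM (default 0.5).
#' @return Tibble with `gene_id`, `median_rpkm`, `usable`.
#' @export
control_baseline <- function(rpkm, control_samples = NULL, tau_min = 0.5) {
  stopifnot(inherits(rpkm, "count_matrix"), rpkm$unit == "rpkm")
  if (tau_min <= 0) stop_bad_arg("`tau_min` must be > 0")
  control_samples <- control_samples %||%
    rpkm$samples$sample_id[rpkm$samples$role == "control"]
  if (length(control_samples) < 3) {
    stop_bad_arg("control baseline needs >= 3 control samples (got %d)",
                 length(control_samples))
  }
  m <- rpkm$counts[, control_samples, drop = FALSE]
  med <- apply(m, 1, stats::median)
  tibble::tibble(gene_id = rownames(rpkm$counts), median_rpkm = med,
                 usable = med >= tau_min)
}

#' Estimate per-gene copy numbers against the control baseline
#'
#' `k = 2 * rpkm / control_median`, i.e. the balanced euploid state maps to
#' k = 2 and a heterozygous deletion to k = 1. Values are not clipped;
#' callers decide how to treat extreme amplification. Genes unusable in the
#' baseline are masked (`NA`).
#'
#' @param rpkm An RPKM `count_matrix`.
#' @param baseline A [control_baseline()] on the same gene set.
#' @return Genes x samples matrix of copy-number estimates, with masked
#'   genes `NA`.
#' @export
estimate_copies <- function(rpkm, baseline) {
  stopifnot(inherits(rpkm, "count_matrix"), rpkm$unit == "rpkm")
  if (!all(rownames(rpkm$counts) %in% baseline$gene_id)) {
    miss <- setdiff(rownames(rpkm$counts), baseline$gene_id)
    stop_bad_arg("baseline is missing %d gene(s), e.g. %s",
                 length(miss), miss[1])
  }
  b <- baseline[match(rownames(rpkm$counts), baseline$gene_id), ]
  k <- 2 * rpkm$counts / b$median_rpkm
  k[!b$usable, ] <- NA_real_
  k
}

#' Build a homoeologue dosage profile
#'
#' Joins A and C copy-number estimates per homoeologue pair and attaches
#' CMYK tile colours. Pairs with either gene masked carry no colour.
#'
#' @param rpkm An RPKM `count_matrix` built from `pair_map` genes.
#' @param baseline A [control_baseline()].
#' @param pair_map The homoeologue pair map.
#' @return Tibble (one row per sample x pair) with `sample_id`, `pair_id`,
#'   `chrom_A`, `idx_A`, `chrom_C`, `idx_C`, `k_A`, `k_C`, `masked`, and
#'   colour channels `C`, `M`, `Y`, `K`.
#' @export
dosage_profile <- function(rpkm, baseline, pair_map) {
  k <- estimate_copies(rpkm, baseline)
  ka <- k[pair_map$gene_A, , drop = FALSE]
  kc <- k[pair_map$gene_C, , drop = FALSE]
  n_pair <- nrow(pair_map)
  samples <- colnames(k)
  prof <- tibble::tibble(
    sample_id = rep(samples, each = n_pair),
    pair_id = rep(pair_map$pair_id, length(samples)),
    chrom_A = rep(pair_map$chrom_A, length(samples)),
    idx_A = rep(pair_map$idx_A, length(samples)),
    chrom_C = rep(pair_map$chrom_C, length(samples)),
    idx_C = rep(pair_map$idx_C, length(samples)),
    k_A = as.vector(ka), k_C = as.vector(kc)
  )
  prof$masked <- is.na(prof$k_A) | is.na(prof$k_C)
  col <- colour_map(ifelse(prof$masked, 0, prof$k_A),
                    ifelse(prof$masked, 0, prof$k_C))
  prof$C <- ifelse(prof$masked, NA_real_, col$C)
  prof$M <- ifelse(prof$masked, NA_real_, col$M)
  prof$Y <- ifelse(prof$masked, NA_real_, col$Y)
  prof$K <- ifelse(prof$masked, NA_real_, col$K)
  prof
}

#' CMYK tile colour for a homoeologue dosage pair
#'
#' Cyan encodes A-genome dosage and magenta C-genome dosage, each scaled so
#' that two extra copies (k = 4) saturate the channel: the balanced AACC
#' state is the mid-tone (0.5, 0.5, 0, 0), deletions render lighter and
#' duplications darker.
#'
#' @param k_A,k_C Copy-number estimates (>= 0), recycled to a common length.
#' @return Tibble with columns `C`, `M`, `Y`, `K` in \[0, 1\].
#' @export
colour_map <- function(k_A, k_C) {
  if (any(k_A < 0, na.rm = TRUE) || any(k_C < 0, na.rm = TRUE)) {
    stop_bad_arg("copy numbers must be >= 0")
  }
  n <- max(length(k_A), length(k_C))
  tibble::tibble(
    C = pmin(1, pmax(0, rep_len(k_A, n) / 4)),
    M = pmin(1, pmax(0, rep_len(k_C, n) / 4)),
    Y = rep(0, n), K = rep(0, n)
  )
}

#' Diagnostic colour key of in-silico genotypes
#'
#' @param genotypes Two-column table (or list of pairs) of A and C copy
#'   numbers; the default key spans the deletion and duplication series of
#'   either subgenome plus the double null.
#' @return Tibble with `a_copies`, `c_copies`, `label` and CMYK channels.
#' @export
colour_key <- function(genotypes = NULL) {
  if (is.null(genotypes)) {
    genotypes <- tibble::tibble(
      a_copies = c(0, 1, 2, 3, 4, 2, 2, 2, 2, 0),
      c_copies = c(2, 2, 2, 2, 2, 0, 1, 3, 4, 0)
    )
  }
  g <- tibble::as_tibble(genotypes)
  names(g)[1:2] <- c("a_copies", "c_copies")
  if (any(g$a_copies < 0 | g$a_copies > 4 | g$c_copies < 0 | g$c_copies > 4)) {
    stop_bad_arg("key copy numbers must lie in [0, 4]")
  }
  g <- dplyr::distinct(g)
  col <- colour_map(g$a_copies, g$c_copies)
  dplyr::bind_cols(
    g,
    tibble::tibble(label = sprintf("A%dC%d", g$a_copies, g$c_copies)),
    col
  )
}

#' Dosage-profile input/output
#'
#' @param profile A dosage profile tibble from [dosage_profile()].
#' @param path TSV path.
#' @export
write_dosage <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
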