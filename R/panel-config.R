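#' Configuration for a synthetic irradiated panel
#'
#' Describes an AACC allotetraploid mutagenesis panel: the homoeologue-pair
#' coordinate system (10 A chromosomes, 9 C chromosomes), the irradiation
#' design (radiation types, doses in Gy, numbers of M1 families and of M2
#' siblings genotyped per family), per-Gray Poisson rate coefficients for
#' each lesion class, sibling reciprocal-inheritance probability, the
#' per-line homoeologous-exchange probability of the untreated seed lot, and
#' the panel seed.
#'
#' Default rate coefficients are per-plant lesion rates of the calibration
#' experiments divided by their dose, so simulated per-plant event means are
#' linear through the origin in dose. Rates may be given once (applied to
#' every radiation type) or as one named set per radiation type; the
#' defaults carry separate `gamma` and `fnt` sets because fast neutrons are
#' roughly twentyfold more damaging per Gray.
#'
#' @param n_pairs_per_chrom Homoeologue pairs per A chromosome (scalar or one
#'   value per A chromosome). The study-scale default (2000) gives ~20k
#'   pairs genome-wide.
#' @param chrom_names_A,chrom_names_C Chromosome labels.
#' @param doses Data frame with columns `radiation_type` (`"gamma"` or
#'   `"fnt"`), `dose_Gy`, `n_m1` (irradiated M1 families) and `sibs_per_m1`
#'   (M2 plants genotyped per family). Default reproduces the calibration
#'   design: gamma 750/1500/1750/2000 Gy with 8 families x 2 siblings,
#'   fast neutron 40/60/80/100 Gy with 8 families x 1 plant.
#' @param n_controls Untreated plants (default 16).
#' @param rate_coefficients Named list with elements `alpha_del_A`,
#'   `alpha_del_C`, `alpha_dup_A`, `alpha_dup_C`, `alpha_chromloss`,
#'   `alpha_chromgain` (events per plant per Gy), or a list of such lists
#'   keyed by radiation type.
#' @param recip_prob Probability that a segmental deletion arising in an M1
#'   plant is inherited reciprocally: one sibling receives the deletion, a
#'   second sibling the corresponding duplication.
#' @param he_prob_control Per-line probability of a pre-existing
#'   homoeologous exchange in the seed lot (controls and treated lines).
#' @param min_seg_genes Minimum segmental lesion length in genes; lengths
#'   are log-uniform between this and the chromosome length.
#' @param c_extra_frac Fractional excess of C-genome genes over paired
#'   genes, making the C genome the larger subgenome.
#' @param p_valid_gt2,p_valid_eq2 Probability that an emitted line-specific
#'   small-variant call is a true lesion, for variant-allele read depth > 2
#'   and = 2 respectively (defaults 0.38 and 0.035, the observed validation
#'   rates).
#' @param calls_gt2_per_line,calls_eq2_per_line Expected emitted
#'   line-specific small-variant calls per treated line in each depth
#'   stratum.
#' @param n_artifact_sites Number of shared artifact variant positions seen
#'   across many lines including controls.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical simulated outputs.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_pairs_per_chrom = 2000,
                         chrom_names_A = paste0("A", 1:10),
                         chrom_names_C = paste0("C", 1:9),
                         doses = default_doses(),
                         n_controls = 16,
                         rate_coefficients = default_rate_coefficients(),
                         recip_prob = 0.25,
                         he_prob_control = 0.1,
                         min_seg_genes = 5,
                         c_extra_frac = 0.1,
                         p_valid_gt2 = 0.38,
                         p_valid_eq2 = 0.035,
                         calls_gt2_per_line = 25,
                         calls_eq2_per_line = 55,
                         n_artifact_sites = 150,
                         seed = 1L) {
  doses <- tibble::as_tibble(doses)
  need <- c("radiation_type", "dose_Gy", "n_m1", "sibs_per_m1")
  if (!all(need %in% names(doses)) || nrow(doses) == 0) {
    stop_bad_arg("`doses` must be a non-empty table with columns %s",
                 paste(need, collapse = ", "))
  }
  if (any(doses$dose_Gy < 0)) stop_bad_arg("doses must be non-negative")
  n_pairs_per_chrom <- rep_len(as.integer(n_pairs_per_chrom),
                               length(chrom_names_A))
  if (any(n_pairs_per_chrom <= 0)) {
    stop_bad_arg("zero homoeologue pairs requested for a chromosome")
  }
  if (!is_rate_set(rate_coefficients)) {
    if (!all(vapply(rate_coefficients, is_rate_set, logical(1))) ||
        !all(unique(doses$radiation_type) %in% names(rate_coefficients))) {
      stop_bad_arg("`rate_coefficients` must name all six alpha_* rates, %s",
                   "once or per radiation type")
    }
    rates_flat <- unlist(rate_coefficients)
  } else {
    rates_flat <- unlist(rate_coefficients)
  }
  if (any(rates_flat < 0) || any(!is.finite(rates_flat))) {
    stop_bad_arg("rate coefficients must be finite and >= 0")
  }
  assert_prob(recip_prob, "recip_prob")
  assert_prob(he_prob_control, "he_prob_control")
  assert_prob(p_valid_gt2, "p_valid_gt2")
  assert_prob(p_valid_eq2, "p_valid_eq2")

  structure(list(
    n_pairs_per_chrom = n_pairs_per_chrom,
    chrom_names_A = chrom_names_A,
    chrom_names_C = chrom_names_C,
    doses = doses,
    n_controls = as.integer(n_controls),
    rate_coefficients = rate_coefficients,
    recip_prob = recip_prob,
    he_prob_control = he_prob_control,
    min_seg_genes = as.integer(min_seg_genes),
    c_extra_frac = c_extra_frac,
    p_valid_gt2 = p_valid_gt2,
    p_valid_eq2 = p_valid_eq2,
    calls_gt2_per_line = calls_gt2_per_line,
    calls_eq2_per_line = calls_eq2_per_line,
    n_artifact_sites = as.integer(n_artifact_sites),
    seed = as.integer(seed)
  ), class = "panel_config")
}

rate_names <- c("alpha_del_A", "alpha_del_C", "alpha_dup_A", "alpha_dup_C",
                "alpha_chromloss", "alpha_chromgain")

is_rate_set <- function(x) {
  is.list(x) && all(rate_names %in% names(x)) &&
    all(vapply(x[rate_names], is.numeric, logical(1)))
}

#' @rdname panel_config
#' @export
default_doses <- function() {
  dplyr::bind_rows(
    tibble::tibble(radiation_type = "gamma",
                   dose_Gy = c(750, 1500, 1750, 2000),
                   n_m1 = 8L, sibs_per_m1 = 2L),
    tibble::tibble(radiation_type = "fnt",
                   dose_Gy = c(40, 60, 80, 100),
                   n_m1 = 8L, sibs_per_m1 = 1L)
  )
}

#' @rdname panel_config
#' @export
default_rate_coefficients <- function() {
  list(
    gamma = list(alpha_del_A = 1.5 / 2000, alpha_del_C = 2.38 / 2000,
                 alpha_dup_A = 0.63 / 2000, alpha_dup_C = 0.31 / 2000,
                 alpha_chromloss = 0.06 / 2000, alpha_chromgain = 0.06 / 2000),
    fnt = list(alpha_del_A = 0.75 / 100, alpha_del_C = 2.38 / 100,
               alpha_dup_A = 1.25 / 100, alpha_dup_C = 0.75 / 100,
               alpha_chromloss = 0.13 / 100, alpha_chromgain = 0)
  )
}

# rate set applicable to one radiation type
rates_for <- function(config, radiation_type) {
  rc <- config$rate_coefficients
  if (is_rate_set(rc)) rc else rc[[radiation_type]]
}

#' Read-count noise model
#'
#' Negative-binomial gene-level read-count noise. Genome re-sequencing
#' (~12x coverage) gives tight counts; transcriptome mode adds per-gene,
#' per-sample lognormal expression variability on top.
#'
#' @param mode `"genome"` or `"transcriptome"`.
#' @param mean_depth Expected reads per kb of gene at balanced copy number
#'   (~80 matches 12x coverage with 150-base reads).
#' @param dispersion Negative-binomial dispersion (variance = mu + disp*mu^2).
#'   Genome coverage is close to Poisson with mild mapping overdispersion;
#'   transcriptome counts are looser.
#' @param expression_cv Extra lognormal coefficient of variation applied per
#'   gene and sample in transcriptome mode (between-plant expression
#'   variability).
#' @return A `noise_model` list.
#' @export
noise_model <- function(mode = c("genome", "transcriptome"),
                        mean_depth = 80,
                        dispersion = if (mode[1] == "genome") 0.005 else 0.05,
                        expression_cv = if (mode[1] == "genome") 0 else 0.2) {
  mode <- match.arg(mode)
  if (mean_depth <= 0) stop_bad_arg("`mean_depth` must be > 0")
  if (dispersion <= 0) stop_bad_arg("`dispersion` must be > 0")
  if (expression_cv < 0) stop_bad_arg("`expression_cv` must be >= 0")
  structure(list(mode = mode, mean_depth = mean_depth,
                 dispersion = dispersion, expression_cv = expression_cv),
            class = "noise_model")
}
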