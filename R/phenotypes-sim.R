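#' Trait-model parameters for seed oil fatty acids
#'
#' Linear gene-dosage model anchored on the high-erucic parent: wild type
#' (four functional fatty-acid elongase copies across the A8 and C3 loci,
#' two functional A5 desaturase copies) sits at 46 mol% erucic, 15 mol%
#' oleic and 15 mol% linoleic; complete loss of the A5 desaturase moves the
#' seed oil to 50% erucic, 19% oleic and 8% linoleic.
#'
#' @param erucic_wt,oleic_wt,linoleic_wt Wild-type anchor values (mol%).
#' @param fae1_erucic_per_copy,fae1_oleic_per_copy Effect of one functional
#'   elongase copy (relative to the 4-copy baseline) on erucic and oleic.
#' @param fad2_erucic_per_lost_copy,fad2_oleic_per_lost_copy,
#'   fad2_linoleic_per_lost_copy Effect of losing one functional A5
#'   desaturase copy.
#' @param resid_sd Gaussian residual standard deviation (mol%).
#' @return A `trait_params` list.
#' @export
trait_params <- function(erucic_wt = 46, oleic_wt = 15, linoleic_wt = 15,
                         fae1_erucic_per_copy = 5,
                         fae1_oleic_per_copy = -5,
                         fad2_erucic_per_lost_copy = 2,
                         fad2_oleic_per_lost_copy = 2,
                         fad2_linoleic_per_lost_copy = -3.5,
                         resid_sd = 1.5) {
  if (resid_sd < 0) stop_bad_arg("`resid_sd` must be >= 0")
  structure(as.list(environment()), class = "trait_params")
}

#' Simulate seed oil fatty-acid phenotypes from copy-number genotypes
#'
#' @param genotypes Tibble with `sample_id` and functional copy numbers
#'   `fae1_a8_copies`, `fae1_c3_copies` (baseline 2 each) and
#'   `fad2_a5_copies` (baseline 2); an optional `group` column is carried
#'   through.
#' @param params A [trait_params()].
#' @param seed Integer seed for the residual draw.
#' @return Tibble with `sample_id`, optional `group`, and mol% columns
#'   `erucic`, `oleic`, `linoleic`.
#' @export
simulate_phenotypes <- function(genotypes, params = trait_params(),
                                seed = 1L) {
  stopifnot(inherits(params, "trait_params"))
  g <- tibble::as_tibble(genotypes)
  fae1 <- g$fae1_a8_copies + g$fae1_c3_copies
  fad2_lost <- 2 - g$fad2_a5_copies
  n <- nrow(g)
  withr::with_seed(seed, {
    res <- function() stats::rnorm(n, 0, params$resid_sd)
    out <- tibble::tibble(
      sample_id = g$sample_id,
      erucic = pmax(0, params$erucic_wt +
                      params$fae1_erucic_per_copy * (fae1 - 4) +
                      params$fad2_erucic_per_lost_copy * fad2_lost + res()),
      oleic = pmax(0, params$oleic_wt +
                     params$fae1_oleic_per_copy * (fae1 - 4) +
                     params$fad2_oleic_per_lost_copy * fad2_lost + res()),
      linoleic = pmax(0, params$linoleic_wt +
                        params$fad2_linoleic_per_lost_copy * fad2_lost +
                        res())
    )
    if ("group" %in% names(g)) {
      out <- dplyr::bind_cols(out[, "sample_id"],
                              tibble::tibble(group = g$group),
                              out[, c("erucic", "oleic", "linoleic")])
    }
    out
  })
}
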