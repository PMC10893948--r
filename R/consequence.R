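# standard nuclear genetic code
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  paste(rev(comp_base[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

#' A minimal gene model for consequence prediction
#'
#' Ordered CDS intervals on one chromosome; `cds_seq` is the spliced coding
#' sequence read 5' to 3' on the coding strand and must be a whole number
#' of codons matching the interval widths.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param cds Tibble with 1-based inclusive `start`, `end` columns, sorted
#'   5' to 3' on the coding strand (descending genomic coordinates for
#'   `"-"` genes).
#' @param cds_seq Spliced coding sequence (A/C/G/T string).
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", cds, cds_seq) {
  cds <- tibble::as_tibble(cds)
  stopifnot(all(c("start", "end") %in% names(cds)), strand %in% c("+", "-"))
  widths <- cds$end - cds$start + 1L
  if (any(widths <= 0)) stop_bad_arg("CDS intervals must have end >= start")
  if (nrow(cds) > 1) {
    gstarts <- if (strand == "+") cds$start else rev(cds$start)
    if (is.unsorted(gstarts, strictly = TRUE)) {
      stop_bad_arg("CDS intervals must be sorted 5' to 3' on the %s strand",
                   strand)
    }
    genomic <- cds[order(cds$start), ]
    if (any(genomic$start[-1] <= genomic$end[-nrow(genomic)])) {
      stop_bad_arg("CDS intervals must not overlap")
    }
  }
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) != sum(widths)) {
    stop_bad_arg("cds_seq length (%d) != total CDS width (%d)",
                 nchar(cds_seq), sum(widths))
  }
  if (nchar(cds_seq) %% 3 != 0) {
    stop_bad_arg("coding sequence length must be divisible by 3")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, cds_seq = cds_seq),
            class = "gene_model")
}

# 1-based CDS coordinate of a genomic position, or NA if not in any CDS
cds_position <- function(model, gpos) {
  offset <- 0L
  for (i in seq_len(nrow(model$cds))) {
    s <- model$cds$start[i]; e <- model$cds$end[i]
    if (gpos >= s && gpos <= e) {
      within <- if (model$strand == "+") gpos - s + 1L else e - gpos + 1L
      return(offset + within)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

# distance to the nearest intron-facing CDS boundary (internal edges only)
splice_proximal <- function(model, gpos, within = 2L) {
  n <- nrow(model$cds)
  if (n < 2) return(FALSE)
  genomic <- model$cds[order(model$cds$start), ]
  for (i in seq_len(n - 1)) {
    intron_start <- genomic$end[i] + 1L
    intron_end <- genomic$start[i + 1] - 1L
    if (gpos >= intron_start && gpos <= intron_end) {
      if (gpos - intron_start < within || intron_end - gpos < within) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Classify the coding consequence of a variant
#'
#' A simplified consequence predictor: SNVs inside the CDS are translated
#' codon-wise (standard nuclear code, strand-aware) to synonymous /
#' missense / stop_gained / stop_lost; insertions and deletions whose
#' length is a multiple of 3 are in-frame with `aa_change = length / 3`
#' amino acids, otherwise frameshift; intronic variants within 2 nt of a
#' CDS boundary are splice_site; anything else is non_coding.
#'
#' @param chrom,pos,ref,alt The variant (VCF conventions: 1-based `pos`;
#'   indels anchored on a shared first base).
#' @param model A [gene_model()].
#' @return List with `consequence` and `aa_change` (amino acids inserted or
#'   deleted for in-frame indels, else `NA`).
#' @export
classify_consequence <- function(chrom, pos, ref, alt, model) {
  stopifnot(inherits(model, "gene_model"))
  ref <- toupper(ref); alt <- toupper(alt)
  no <- list(consequence = "non_coding", aa_change = NA_integer_)
  if (chrom != model$chrom) return(no)

  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    cpos <- cds_position(model, pos)
    if (is.na(cpos)) {
      if (splice_proximal(model, pos)) {
        return(list(consequence = "splice_site", aa_change = NA_integer_))
      }
      return(no)
    }
    base <- if (model$strand == "+") alt else comp_base[[alt]]
    ref_base <- if (model$strand == "+") ref else comp_base[[ref]]
    if (substr(model$cds_seq, cpos, cpos) != ref_base) {
      warning(sprintf("ref allele mismatch at CDS position %d of %s",
                      cpos, model$gene_id))
    }
    codon_i <- (cpos - 1L) %/% 3L
    codon <- substr(model$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    within <- cpos - codon_i * 3L
    mutated <- codon
    substr(mutated, within, within) <- base
    aa_ref <- codon_table[[codon]]
    aa_alt <- codon_table[[mutated]]
    cons <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gained"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
    return(list(consequence = cons, aa_change = NA_integer_))
  }

  # indel: changed bases follow the shared anchor base
  len <- abs(nchar(ref) - nchar(alt))
  affected_start <- pos + 1L
  affected_end <- pos + max(1L, nchar(ref) - 1L)
  in_cds <- !is.na(cds_position(model, affected_start)) ||
    !is.na(cds_position(model, affected_end)) ||
    !is.na(cds_position(model, pos))
  if (!in_cds) {
    if (splice_proximal(model, affected_start) ||
        splice_proximal(model, affected_end)) {
      return(list(consequence = "splice_site", aa_change = NA_integer_))
    }
    return(no)
  }
  if (len %% 3L == 0L) {
    kind <- if (nchar(ref) > nchar(alt)) "inframe_deletion"
    else "inframe_insertion"
    return(list(consequence = kind, aa_change = as.integer(len / 3L)))
  }
  list(consequence = "frameshift", aa_change = NA_integer_)
}
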