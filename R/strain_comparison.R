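snp_key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")

#' Per-strain SNP summary
#'
#' Tallies a strain's annotated variants at the SNP level: a SNP
#' overlapping one or more ORFs counts once toward `n_snps_in_orfs`; it
#' counts toward `n_nonsynonymous` if any overlapping-ORF record is
#' non-synonymous (missense, nonsense, stop-loss or start-loss — i.e.
#' the non-synonymous tally includes the ISCMs), and toward `n_iscm` if
#' any record is nonsense.
#'
#' @param annotations Annotation data.frame for one strain.
#' @return One-row data.frame with `strain_id`, `n_snps_total`,
#'   `n_snps_in_orfs`, `n_nonsynonymous`, `n_iscm`.
#' @export
summarize_strain <- function(annotations) {
  strain <- unique(annotations$strain)
  if (length(strain) > 1L) stop("annotations span multiple strains")
  if (length(strain) == 0L) strain <- NA_character_
  key <- snp_key(annotations)
  in_orf <- !is.na(annotations$orf_id)
  nonsyn <- annotations$effect %in% NONSYN_EFFECTS
  iscm <- annotations$effect == "nonsense"
  out <- data.frame(
    strain_id = strain,
    n_snps_total = length(unique(key)),
    n_snps_in_orfs = length(unique(key[in_orf])),
    n_nonsynonymous = length(unique(key[nonsyn])),
    n_iscm = length(unique(key[iscm])),
    stringsAsFactors = FALSE
  )
  stopifnot(out$n_iscm <= out$n_nonsynonymous,
            out$n_nonsynonymous <= out$n_snps_in_orfs,
            out$n_snps_in_orfs <= out$n_snps_total)
  out
}

#' ORF-by-strain ISCM presence/absence matrix
#'
#' Cell (orf, strain) is 1 iff at least one nonsense annotation exists
#' for that pair — presence is per ORF, not per site, so two different
#' premature stops in one ORF both set the same cell (they remain
#' distinguishable in the long-format output of [iscm_long_table()]).
#'
#' @param annotations Annotation data.frame covering the whole cohort.
#' @param strains Optional character vector fixing column order (strains
#'   with no ISCM still get an all-zero column).
#' @return Integer 0/1 matrix, rows = ORF ids, columns = strain ids.
#' @export
build_iscm_matrix <- function(annotations, strains = NULL) {
  ns <- annotations[annotations$effect == "nonsense", , drop = FALSE]
  if (is.null(strains)) strains <- sort(unique(annotations$strain))
  orf_ids <- sort(unique(ns$orf_id))
  m <- matrix(0L, nrow = length(orf_ids), ncol = length(strains),
              dimnames = list(orf_ids, strains))
  if (nrow(ns) > 0L)
    m[cbind(ns$orf_id, ns$strain)] <- 1L
  m
}

#' Long-format ISCM table
#'
#' One row per (orf, strain, site) nonsense annotation, with position and
#' notation, sorted for deterministic output.
#'
#' @param annotations Annotation data.frame.
#' @return data.frame with `orf_id`, `gene`, `strain`, `chrom`, `pos`,
#'   `notation`, `truncation_len`.
#' @export
iscm_long_table <- function(annotations) {
  ns <- annotations[annotations$effect == "nonsense",
                    c("orf_id", "gene", "strain", "chrom", "pos",
                      "notation", "truncation_len"), drop = FALSE]
  ns <- ns[order(ns$chrom, ns$pos, ns$strain), , drop = FALSE]
  rownames(ns) <- NULL
  ns
}

#' Classify a strain's ISCM ORFs as unique or shared
#'
#' @param matrix ISCM presence/absence matrix from [build_iscm_matrix()].
#' @param strain Strain (column) to classify.
#' @return List with `unique_orfs` (present in this strain only) and
#'   `shared_orfs` (present in this strain and at least one other).
#' @export
classify_sharing <- function(matrix, strain) {
  if (!strain %in% colnames(matrix)) stop("unknown strain: ", strain)
  present <- matrix[, strain] == 1L
  others <- matrix[, setdiff(colnames(matrix), strain), drop = FALSE]
  shared <- rowSums(others) > 0L
  list(unique_orfs = rownames(matrix)[present & !shared],
       shared_orfs = rownames(matrix)[present & shared])
}

#' Strain ISCM frequency
#'
#' Ratio of a strain's unique ISCMs to its unique non-synonymous SNPs,
#' rounded to 3 decimals. A zero denominator is undefined and returns
#' `NA` with a warning.
#'
#' @param n_unique_iscm Count of strain-unique ISCMs.
#' @param n_unique_nonsyn Count of strain-unique non-synonymous SNPs.
#' @return Numeric ratio rounded to 3 decimals, or `NA`.
#' @export
iscm_frequency <- function(n_unique_iscm, n_unique_nonsyn) {
  if (n_unique_nonsyn <= 0) {
    warning("undefined ISCM frequency: zero non-synonymous denominator")
    return(NA_real_)
  }
  round(n_unique_iscm / n_unique_nonsyn, 3)
}
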