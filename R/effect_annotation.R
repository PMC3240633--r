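#' Map a genomic position to its codon within an ORF
#'
#' Converts a 1-based genomic position lying inside a single-exon ORF to
#' the 1-based codon index and in-codon offset, counted from the ORF's
#' own 5' end. On the minus strand position 'end' is the first coding
#' base.
#'
#' @param orf One-row ORF data.frame (`chrom`, `start`, `end`, `strand`).
#' @param genome A `DNAStringSet`.
#' @param pos 1-based genomic position within the ORF span.
#' @return List with `codon_index`, `offset` (1-3) and `ref_codon` (the
#'   reference codon in coding orientation).
#' @export
map_to_codon <- function(orf, genome, pos) {
  if (pos < orf$start || pos > orf$end) stop("position outside ORF span")
  cds_pos <- if (identical(orf$strand, "-")) orf$end - pos + 1L
             else pos - orf$start + 1L
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  offset <- cds_pos - 3L * (codon_index - 1L)
  cds <- extract_cds(genome, orf)
  ref_codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  list(codon_index = codon_index, offset = offset, ref_codon = ref_codon)
}

#' Truncation length of a nonsense mutation
#'
#' Number of residues lost strictly downstream of the mutated codon:
#' `protein_len - codon_index`. This is the convention under which a
#' premature stop at the last sense codon truncates 0 residues; the
#' mutated residue itself is not counted as lost.
#'
#' @param protein_len Protein length in residues (stop codon excluded).
#' @param codon_index 1-based position of the codon converted to a stop.
#' @return Integer truncation length.
#' @export
truncation_length <- function(protein_len, codon_index) {
  stopifnot(codon_index >= 1L, codon_index <= protein_len)
  as.integer(protein_len - codon_index)
}

#' Mutation notation string
#'
#' Nonsense changes are written as one-letter reference amino acid,
#' codon index, then the stop codon as a DNA triplet (`"W244TGA"`);
#' missense (and other residue-level) changes as reference amino acid,
#' index, alternate amino acid (`"D524N"`).
#'
#' @param ref_aa One-letter reference amino acid (or `"*"`).
#' @param codon_index 1-based codon index.
#' @param alt Either a one-letter amino acid or a DNA stop codon triplet.
#' @return Notation string, uppercase.
#' @export
notation <- function(ref_aa, codon_index, alt) {
  toupper(paste0(ref_aa, codon_index, alt))
}

#' Can an amino acid reach a stop codon by one substitution?
#'
#' @param aa One-letter amino acid.
#' @param stop_codon One of TAA, TAG, TGA.
#' @param code Genetic code.
#' @return `TRUE` iff some codon of `aa` differs from `stop_codon` at
#'   exactly one position.
#' @export
single_substitution_reachable <- function(aa, stop_codon, code = genetic_code()) {
  stopifnot(stop_codon %in% STOP_CODONS)
  codons <- names(code)[code == aa]
  any(vapply(codons, function(cd) {
    sum(strsplit(cd, "")[[1]] != strsplit(stop_codon, "")[[1]]) == 1L
  }, logical(1)))
}

classify_codon_change <- function(ref_codon, alt_codon, codon_index,
                                  code = genetic_code()) {
  if (grepl("N", ref_codon) || grepl("N", alt_codon)) return("undetermined")
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (ref_aa == "*" && alt_aa == "*") return("stop_retained")
  if (ref_aa == "*") return("stop_loss")
  if (alt_aa == "*") return("nonsense")
  if (ref_aa == alt_aa) return("synonymous")
  if (codon_index == 1L && ref_codon == "ATG") return("start_loss")
  "missense"
}

empty_annotation <- function() {
  data.frame(strain = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), orf_id = character(),
             gene = character(), codon_index = integer(),
             ref_codon = character(), alt_codon = character(),
             ref_aa = character(), alt_aa = character(),
             effect = character(), truncation_len = integer(),
             notation = character(), stringsAsFactors = FALSE)
}

annotate_one <- function(variant, orf, genome, code, cds = NULL) {
  out <- list(strain = variant$strain_id, chrom = variant$chrom,
              pos = as.integer(variant$pos), ref = variant$ref,
              alt = variant$alt, orf_id = orf$orf_id,
              gene = orf$gene_name, codon_index = NA_integer_,
              ref_codon = NA_character_, alt_codon = NA_character_,
              ref_aa = NA_character_, alt_aa = NA_character_,
              effect = NA_character_, truncation_len = NA_integer_,
              notation = NA_character_)
  ref_obs <- genome_base(genome, variant$chrom, variant$pos)
  if (ref_obs != variant$ref) {
    warning("REF mismatch at ", variant$chrom, ":", variant$pos,
            " (genome ", ref_obs, ", variant ", variant$ref, ")")
    out$effect <- "undetermined"
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  if (is.null(cds)) cds <- extract_cds(genome, orf)
  mc <- map_to_codon(orf, genome, variant$pos)
  alt_coding <- if (identical(orf$strand, "-")) comp_base(variant$alt)
                else variant$alt
  alt_codon <- mc$ref_codon
  substr(alt_codon, mc$offset, mc$offset) <- alt_coding
  protein_len <- nchar(cds) %/% 3L - 1L  # terminal stop excluded
  effect <- classify_codon_change(mc$ref_codon, alt_codon, mc$codon_index, code)
  out$codon_index <- mc$codon_index
  out$ref_codon <- mc$ref_codon
  out$alt_codon <- alt_codon
  out$ref_aa <- if (grepl("N", mc$ref_codon)) "X" else unname(code[mc$ref_codon])
  out$alt_aa <- if (grepl("N", alt_codon)) "X" else unname(code[alt_codon])
  out$effect <- effect
  if (effect == "nonsense") {
    out$truncation_len <- truncation_length(protein_len, mc$codon_index)
    out$notation <- notation(out$ref_aa, mc$codon_index, alt_codon)
  } else if (effect %in% c("missense", "synonymous", "start_loss")) {
    out$notation <- notation(out$ref_aa, mc$codon_index, out$alt_aa)
  } else if (effect %in% c("stop_loss", "stop_retained")) {
    out$notation <- notation("*", mc$codon_index, out$alt_aa)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Annotate one variant against a set of ORFs
#'
#' Yields one annotation record per overlapping ORF (no canonical
#' selection) or a single intergenic record when none overlap. The
#' alternate codon is built by substituting the strand-adjusted base into
#' the reference codon; the consequence is read off the amino-acid
#' comparison: sense-to-stop is nonsense (an ISCM), stop-to-sense is
#' stop-loss, stop-to-stop is stop-retained, and a sense change in the
#' ATG start codon is start-loss. A REF that does not match the genome
#' gives effect `undetermined` with a warning. Codons containing N are
#' `undetermined`.
#'
#' @param variant One-row variant data.frame (`strain_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param orfs ORF data.frame.
#' @param genome A `DNAStringSet`.
#' @param code Genetic code.
#' @return Annotation data.frame (one row per overlapping ORF).
#' @export
annotate_variant <- function(variant, orfs, genome, code = genetic_code()) {
  hit <- which(orfs$chrom == variant$chrom &
               orfs$start <= variant$pos & orfs$end >= variant$pos)
  if (length(hit) == 0L) {
    ref_obs <- genome_base(genome, variant$chrom, variant$pos)
    eff <- "intergenic"
    if (ref_obs != variant$ref) {
      warning("REF mismatch at ", variant$chrom, ":", variant$pos)
      eff <- "undetermined"
    }
    out <- empty_annotation()[0, ]
    out[1, ] <- NA
    out$strain <- variant$strain_id
    out$chrom <- variant$chrom
    out$pos <- as.integer(variant$pos)
    out$ref <- variant$ref
    out$alt <- variant$alt
    out$effect <- eff
    return(out)
  }
  do.call(rbind, lapply(hit, function(i)
    annotate_one(variant, orfs[i, ], genome, code)))
}

#' Annotate a strain's variant table
#'
#' Vectorised driver over [annotate_variant()] semantics: ORF overlap is
#' resolved once with [GenomicRanges::findOverlaps()], coding sequences
#' are extracted once per ORF, and each SNP is annotated independently
#' against the reference codon. Two SNPs of the same strain falling in
#' one codon of one ORF are flagged with a "compound codon" message but
#' are not jointly re-evaluated. Output rows are sorted by
#' (chrom, pos, strain, orf_id).
#'
#' @param variants Variant data.frame for one or more strains.
#' @param orfs ORF data.frame.
#' @param genome A `DNAStringSet`.
#' @param code Genetic code.
#' @return Annotation data.frame, one row per (variant, overlapping ORF)
#'   pair plus one intergenic row per non-overlapping variant.
#' @export
annotate_strain <- function(variants, orfs, genome, code = genetic_code()) {
  if (nrow(variants) == 0L) return(empty_annotation())
  var_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, variants$pos))
  orf_gr <- GenomicRanges::GRanges(orfs$chrom,
                                   IRanges::IRanges(orfs$start, orfs$end))
  hits <- GenomicRanges::findOverlaps(var_gr, orf_gr, ignore.strand = TRUE)
  vh <- S4Vectors::queryHits(hits)
  oh <- S4Vectors::subjectHits(hits)
  cds_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(vh) + nrow(variants))
  k <- 0L
  for (j in seq_along(vh)) {
    orf <- orfs[oh[j], ]
    if (is.null(cds_cache[[orf$orf_id]]))
      cds_cache[[orf$orf_id]] <- extract_cds(genome, orf)
    k <- k + 1L
    rows[[k]] <- annotate_one(variants[vh[j], ], orf, genome, code,
                              cds = cds_cache[[orf$orf_id]])
  }
  for (i in setdiff(seq_len(nrow(variants)), unique(vh))) {
    k <- k + 1L
    rows[[k]] <- annotate_variant(variants[i, ], orfs[0, ], genome, code)
  }
  ann <- do.call(rbind, rows[seq_len(k)])
  cc <- !is.na(ann$orf_id)
  key <- paste(ann$strain[cc], ann$orf_id[cc], ann$codon_index[cc])
  if (anyDuplicated(key))
    message("compound codon: multiple SNPs of one strain in one codon (",
            paste(unique(key[duplicated(key)]), collapse = "; "), ")")
  ann[order(ann$chrom, ann$pos, ann$strain, ann$orf_id), , drop = FALSE]
}

#' Scan a variant at an ORF's natural stop codon for stop loss
#'
#' When the terminal stop codon is mutated to a sense codon, the protein
#' is extended until the next in-frame stop in the downstream genomic
#' sequence. The reported extension is the number of sense codons gained
#' strictly downstream of the (now read-through) mutated codon. A
#' stop-to-stop change is reported as stop-retained with extension 0.
#' When no in-frame stop exists before the chromosome end the record is
#' flagged `terminator_found = FALSE` ("runs off chromosome").
#'
#' @param variant One-row variant data.frame hitting the terminal stop.
#' @param orf One-row ORF data.frame.
#' @param genome A `DNAStringSet`.
#' @param code Genetic code.
#' @return List with `effect`, `extension` (NA when no terminator) and
#'   `terminator_found`.
#' @export
scan_stop_loss <- function(variant, orf, genome, code = genetic_code()) {
  mc <- map_to_codon(orf, genome, variant$pos)
  n_codons <- (orf$end - orf$start + 1L) %/% 3L
  if (mc$codon_index != n_codons)
    stop("variant does not hit the ORF's terminal stop codon")
  if (!mc$ref_codon %in% STOP_CODONS)
    stop("ORF does not end with a stop codon")
  alt_coding <- if (identical(orf$strand, "-")) comp_base(variant$alt)
                else variant$alt
  alt_codon <- mc$ref_codon
  substr(alt_codon, mc$offset, mc$offset) <- alt_coding
  if (unname(code[alt_codon]) == "*")
    return(list(effect = "stop_retained", extension = 0L,
                terminator_found = TRUE))
  chrom_seq <- as.character(genome[[orf$chrom]])
  if (identical(orf$strand, "+")) {
    down <- substr(chrom_seq, orf$end + 1L, nchar(chrom_seq))
  } else {
    down <- revcomp(substr(chrom_seq, 1L, orf$start - 1L))
  }
  n_full <- nchar(down) %/% 3L
  extension <- NA_integer_
  terminator <- FALSE
  if (n_full > 0L) {
    codons <- substring(down, seq(1L, 3L * n_full, 3L), seq(3L, 3L * n_full, 3L))
    stop_at <- which(codons %in% STOP_CODONS)
    if (length(stop_at) > 0L) {
      terminator <- TRUE
      extension <- stop_at[1] - 1L
    }
  }
  list(effect = "stop_loss", extension = extension,
       terminator_found = terminator)
}
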