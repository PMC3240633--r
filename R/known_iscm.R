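#' Catalogue of known premature stop codons in strains 74-D694 and G600
#'
#' Curated table of the single internal nonsense mutations (ISCMs)
#' observed in the [*PSI*+] laboratory strains 74-D694 (22 ORFs) and
#' G600 (4 ORFs) relative to the S288C reference: systematic ORF name,
#' gene name where assigned, genomic SNP position, the affected codon
#' (reference amino acid and 1-based codon index), the premature stop
#' codon created, the resulting truncation length in residues, and
#' whether the ISCM is unique to the strain among forty sequenced
#' S. cerevisiae strains.
#'
#' @return data.frame with columns `orf_id`, `gene_name`, `strain`,
#'   `pos`, `ref_aa`, `codon_index`, `stop_codon`, `truncation`,
#'   `strain_unique`. Protein length is `codon_index + truncation`.
#' @export
known_iscm_table <- function() {
  txt <- "
orf_id|gene_name|strain|pos|ref_aa|codon_index|stop_codon|truncation|strain_unique
YAL056W|GPB2|74-D694|41780|Q|841|TAA|39|TRUE
YAR015W|ADE1|74-D694|170101|W|244|TGA|62|TRUE
YAR028W|NA|74-D694|185308|W|141|TGA|93|FALSE
YAR031W|PRM9|74-D694|186930|W|34|TAG|264|FALSE
YBL037W|APL3|74-D694|150039|L|943|TAA|82|TRUE
YDR007W|TRP1|74-D694|462241|Q|135|TAG|89|TRUE
YDR147W|EKI1|74-D694|752397|W|257|TAG|277|TRUE
YFR057W|NA|74-D694|269422|Y|125|TAA|26|TRUE
YGR159C|NSR1|74-D694|806553|E|54|TAA|360|TRUE
YGR249W|MGA1|74-D694|989281|Q|410|TAA|46|FALSE
YGR281W|YOR1|74-D694|1054483|K|552|TAA|925|TRUE
YGR283W|NA|74-D694|1059136|L|304|TAG|37|TRUE
YHL003C|LAG1|74-D694|101280|W|200|TGA|211|TRUE
YHR143W|DSE2|74-D694|385718|L|69|TAA|256|FALSE
YIR028W|DAL4|74-D694|409511|W|349|TGA|286|TRUE
YKL062W|MSN4|74-D694|323577|Q|236|TAA|394|TRUE
YKR056W|TRM2|74-D694|549185|W|32|TGA|607|FALSE
YLR313C|SPH1|74-D694|760398|Q|649|TAG|23|FALSE
YNL065W|AQR1|74-D694|505411|Q|563|TAG|23|FALSE
YOL060C|MAM3|74-D694|214535|K|535|TAA|171|TRUE
YOR183W|FYV12|74-D694|678996|E|42|TAA|87|FALSE
YPL222W|FMP40|74-D694|130893|Q|245|TAA|443|TRUE
YBR074W|NA|G600|387247|Q|323|TAA|653|TRUE
YNL106C|INP52|G600|422546|W|651|TAG|532|TRUE
YOR128C|ADE2|G600|566003|E|64|TAA|507|FALSE
YOR129C|AFI1|G600|566901|E|887|TAA|6|FALSE
"
  tbl <- utils::read.delim(text = txt, sep = "|", header = TRUE,
                           stringsAsFactors = FALSE)
  tbl$gene_name <- ifelse(tbl$gene_name == "NA", NA_character_, tbl$gene_name)
  tbl$strand <- ifelse(grepl("C$", tbl$orf_id), "-", "+")
  tbl$protein_len <- tbl$codon_index + tbl$truncation
  tbl$notation <- notation(tbl$ref_aa, tbl$codon_index, tbl$stop_codon)
  tbl
}

.fixture_cache <- new.env(parent = emptyenv())

# A codon of ref_aa exactly one substitution away from stop_codon, with
# the differing offset. Deterministic: first candidate in sorted order.
codon_for_single_sub <- function(ref_aa, stop_codon, code = genetic_code()) {
  codons <- sort(names(code)[code == ref_aa])
  for (cd in codons) {
    diff <- which(strsplit(cd, "")[[1]] != strsplit(stop_codon, "")[[1]])
    if (length(diff) == 1L)
      return(list(codon = cd, offset = diff))
  }
  stop(ref_aa, " cannot reach ", stop_codon, " by one substitution")
}

chrom_roman <- function(orf_id) {
  letter <- substr(orf_id, 2L, 2L)
  idx <- match(letter, LETTERS)
  paste0("chr", as.character(utils::as.roman(idx)))
}

#' Synthetic genome fixture reproducing the known-ISCM catalogue
#'
#' Builds a synthetic multi-chromosome genome carrying, for every row of
#' [known_iscm_table()], a single-exon ORF of the catalogued protein
#' length on the catalogued strand, with a codon of the reference amino
#' acid (one substitution from the catalogued stop) at the catalogued
#' codon index, positioned so the variant's genomic coordinate equals
#' the catalogued SNP position. Two per-strain variant tables (74-D694,
#' G600) apply exactly those substitutions. ORF filler sequence is
#' synthetic (random sense codons under a fixed internal seed); only the
#' mutated codon, reading frame, strand, length and SNP coordinate are
#' faithful to the catalogue.
#'
#' @param seed Seed for the synthetic filler sequence.
#' @return List with `genome`, `orfs`, `variants` (both strains,
#'   row-bound), `variant_tables` (per strain) and `truth` (the
#'   catalogue with expected `notation` and `truncation`).
#' @export
known_iscm_fixture <- function(seed = 1891L) {
  key <- as.character(seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  .fixture_cache[[key]] <- with_rng(seed, {
    code <- genetic_code()
    tbl <- known_iscm_table()
    tbl$chrom <- chrom_roman(tbl$orf_id)

    orfs <- vector("list", nrow(tbl))
    vars <- vector("list", nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      r <- tbl[i, ]
      cs <- codon_for_single_sub(r$ref_aa, r$stop_codon, code)
      cds_pos <- 3L * (r$codon_index - 1L) + cs$offset
      if (r$strand == "+") {
        start <- r$pos - cds_pos + 1L
        end <- start + (r$protein_len + 1L) * 3L - 1L
      } else {
        end <- r$pos + cds_pos - 1L
        start <- end - (r$protein_len + 1L) * 3L + 1L
      }
      if (start < 1L) stop("fixture ORF would start before the chromosome")
      cds <- random_cds(r$protein_len, code)
      substr(cds, 3L * r$codon_index - 2L, 3L * r$codon_index) <- cs$codon
      ref_coding <- substr(cs$codon, cs$offset, cs$offset)
      alt_coding <- substr(r$stop_codon, cs$offset, cs$offset)
      orfs[[i]] <- data.frame(orf_id = r$orf_id, gene_name = r$gene_name,
                              chrom = r$chrom, start = start, end = end,
                              strand = r$strand, cds = cds,
                              stringsAsFactors = FALSE)
      vars[[i]] <- data.frame(
        strain_id = r$strain, chrom = r$chrom, pos = r$pos,
        ref = if (r$strand == "-") comp_base(ref_coding) else ref_coding,
        alt = if (r$strand == "-") comp_base(alt_coding) else alt_coding,
        stringsAsFactors = FALSE)
    }
    orfs <- do.call(rbind, orfs)
    variants <- do.call(rbind, vars)

    chroms <- list()
    for (ch in unique(orfs$chrom)) {
      len <- max(orfs$end[orfs$chrom == ch]) + 100L
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      for (j in which(orfs$chrom == ch)) {
        ins <- if (orfs$strand[j] == "-") revcomp(orfs$cds[j]) else orfs$cds[j]
        substr(s, orfs$start[j], orfs$end[j]) <- ins
      }
      chroms[[ch]] <- s
    }
    genome <- Biostrings::DNAStringSet(unlist(chroms))
    orfs$cds <- NULL
    variant_tables <- split(variants, variants$strain_id)
    list(genome = genome, orfs = orfs, variants = variants,
         variant_tables = variant_tables, truth = tbl)
  })
  .fixture_cache[[key]]
}
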