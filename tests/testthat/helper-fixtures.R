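# Small constructors shared across test files. All coordinates 1-based
# inclusive; ORF spans include the terminal stop codon.

toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

toy_orf <- function(orf_id, chrom, start, end, strand = "+",
                    gene_name = NA_character_) {
  data.frame(orf_id = orf_id, gene_name = gene_name, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

toy_variant <- function(chrom, pos, ref, alt, strain_id = "s1") {
  data.frame(strain_id = strain_id, chrom = chrom, pos = as.integer(pos),
              ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# Embed a coding sequence (given 5'->3' in coding orientation) into a
# chromosome of random flanking sequence; returns genome + orf row.
plant_orf <- function(cds, strand = "+", flank = 30L, chrom = "chrT",
                      orf_id = "ORF1") {
  bases <- c("A", "C", "G", "T")
  left <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  right <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  ins <- if (strand == "-") iscmscan::revcomp(cds) else cds
  seq <- paste0(left, ins, right)
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, chrom))
  orf <- toy_orf(orf_id, chrom, flank + 1L, flank + nchar(cds), strand)
  list(genome = genome, orf = orf)
}

# Random CDS of a given protein length: ATG + sense codons + stop.
random_test_cds <- function(protein_len) {
  code <- iscmscan::genetic_code()
  sense <- names(code)[code != "*"]
  paste0("ATG",
         paste(sample(sense, protein_len - 1L, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# Independent consequence oracle: apply the substitution to the
# chromosome string, re-extract and fully translate both CDSs, and read
# the effect off the protein diff. Shares no code path with
# annotate_variant's codon arithmetic.
oracle_effect <- function(variant, orf, genome) {
  chrom_seq <- as.character(genome[[variant$chrom]])
  mut_seq <- chrom_seq
  substr(mut_seq, variant$pos, variant$pos) <- variant$alt
  slice <- function(s) {
    x <- substr(s, orf$start, orf$end)
    if (orf$strand == "-")
      x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    x
  }
  tr <- function(cds) {
    suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(cds),
                            if.fuzzy.codon = "X")))
  }
  p_ref <- tr(slice(chrom_seq))
  p_mut <- tr(slice(mut_seq))
  if (identical(p_ref, p_mut)) {
    # which residue does the substituted base sit in?
    cds_pos <- if (orf$strand == "-") orf$end - variant$pos + 1L
               else variant$pos - orf$start + 1L
    idx <- (cds_pos - 1L) %/% 3L + 1L
    return(if (substr(p_ref, idx, idx) == "*") "stop_retained" else "synonymous")
  }
  diff_at <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])
  stopifnot(length(diff_at) == 1L)
  ra <- substr(p_ref, diff_at, diff_at)
  ma <- substr(p_mut, diff_at, diff_at)
  if (ra != "*" && ma == "*") return("nonsense")
  if (ra == "*" && ma != "*") return("stop_loss")
  if (diff_at == 1L && ra == "M") return("start_loss")
  "missense"
}

# Scaled-down simulation shared by module tests (acceptance tests use
# the package defaults).
small_sim_config <- function(seed, ...) {
  iscmscan::sim_config(seed = seed, n_chromosomes = 2L,
                       chromosome_length = 15000L, n_orfs = 15L,
                       orf_len_codons = c(60L, 150L), n_strains = 5L,
                       snps_per_branch = 6L, n_species_snps = 3L, ...)
}
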