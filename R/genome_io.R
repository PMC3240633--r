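#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement GENETIC_CODE
#' @importFrom S4Vectors mcols
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
NONSYN_EFFECTS <- c("missense", "nonsense", "stop_loss", "start_loss")
EFFECT_LEVELS <- c("intergenic", "synonymous", "missense", "nonsense",
                   "stop_loss", "stop_retained", "start_loss", "undetermined")

#' Standard nuclear genetic code
#'
#' Codon-to-amino-acid map used throughout the package. Stops are encoded
#' as `"*"`. The table is validated to hold exactly 64 codons and exactly
#' the three standard nuclear stop codons (TAA, TAG, TGA).
#'
#' @return Named character vector of length 64 (names are DNA codons).
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stopifnot(length(code) == 64L,
            identical(sort(names(code)[code == "*"]), sort(STOP_CODONS)))
  code
}

#' Read a genome from FASTA
#'
#' Loads every record of a FASTA file into a [Biostrings::DNAStringSet].
#' Sequence names are taken from the header up to the first whitespace;
#' lowercase bases are uppercased. Only A/C/G/T/N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("illegal characters in FASTA: ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_genome(Biostrings::DNAStringSet(toupper(as.character(seqs))))
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

validate_genome <- function(genome) {
  nm <- names(genome)
  if (is.null(nm) || anyDuplicated(nm)) stop("chromosome names must be unique and present")
  if (any(Biostrings::width(genome) == 0L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", as.character(genome))
  if (any(bad)) stop("illegal characters in sequence(s): ",
                     paste(nm[bad], collapse = ", "))
  genome
}

#' Read single-exon ORF annotations from GFF3
#'
#' Reads a GFF3 file whose CDS features each describe one complete
#' single-interval ORF (start codon through stop codon). Each CDS must
#' carry an `ID` attribute; an optional `gene` attribute supplies the gene
#' name. Two CDS lines sharing an ID (multi-exon ORFs) are rejected:
#' intron-containing ORFs are unsupported. Frame length (divisible by 3)
#' is enforced; start/stop codon content is validated against the genome
#' with a warning, not an error, when `genome` is supplied.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `DNAStringSet` for start/stop validation.
#' @return A data.frame with columns `orf_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @export
read_orf_gff <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == "")) stop("CDS feature without ID attribute")
  if (anyDuplicated(ids))
    stop("multi-exon ORFs unsupported: multiple CDS lines for ID(s) ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene <- if ("gene" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$gene) else rep(NA_character_, length(gr))
  orfs <- data.frame(
    orf_id    = ids,
    gene_name = gene,
    chrom     = as.character(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr),
    end       = GenomicRanges::end(gr),
    strand    = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_orfs(orfs, genome)
}

#' Write ORF records as GFF3
#'
#' @param orfs ORF data.frame as returned by [read_orf_gff()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_orf_gff <- function(orfs, path, source = "iscmscan") {
  attrs <- ifelse(is.na(orfs$gene_name),
                  paste0("ID=", orfs$orf_id),
                  paste0("ID=", orfs$orf_id, ";gene=", orfs$gene_name))
  lines <- paste(orfs$chrom, source, "CDS", orfs$start, orfs$end,
                 ".", orfs$strand, "0", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

validate_orfs <- function(orfs, genome = NULL) {
  stopifnot(all(orfs$strand %in% c("+", "-")))
  if (any(orfs$start > orfs$end)) stop("ORF with start > end")
  len <- orfs$end - orfs$start + 1L
  bad <- len %% 3L != 0L
  if (any(bad)) stop("CDS length not divisible by 3 for: ",
                     paste(orfs$orf_id[bad], collapse = ", "))
  if (anyDuplicated(orfs$orf_id)) stop("duplicate orf_id")
  if (!is.null(genome)) {
    if (!all(orfs$chrom %in% names(genome)))
      stop("ORF on unknown chromosome")
    clen <- Biostrings::width(genome)[match(orfs$chrom, names(genome))]
    if (any(orfs$end > clen)) stop("ORF coordinates exceed chromosome length")
    code <- genetic_code()
    for (i in seq_len(nrow(orfs))) {
      cds <- extract_cds(genome, orfs[i, ])
      first <- substr(cds, 1L, 3L)
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (first != "ATG")
        warning("ORF ", orfs$orf_id[i], " does not begin with ATG")
      if (!last %in% STOP_CODONS)
        warning("ORF ", orfs$orf_id[i], " does not end with a stop codon")
    }
  }
  orfs
}

#' Read a strain's SNVs from VCF
#'
#' Reads the fixed columns of a VCF 4.x file (genotype columns ignored)
#' and keeps single-nucleotide variants only; indels and other non-SNV
#' records are skipped with a message giving the count. Multiallelic ALT
#' fields are rejected. When `genome` is supplied, REF is cross-checked
#' against the reference base and a mismatch is an error.
#'
#' @param path Path to a VCF file.
#' @param strain_id Strain identifier attached to every variant.
#' @param genome Optional `DNAStringSet` for REF cross-checking.
#' @return A data.frame with columns `strain_id`, `chrom`, `pos`, `ref`,
#'   `alt` (plus-strand alleles, 1-based positions).
#' @export
read_variants_vcf <- function(path, strain_id, genome = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(strain_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(grepl(",", fix$ALT)))
    stop("multiallelic ALT records are not supported (", path, ")")
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) skipped in ", basename(path))
  fix <- fix[snv, , drop = FALSE]
  out <- data.frame(
    strain_id = rep(strain_id, nrow(fix)),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  validate_variants(out, genome)
}

#' Write variants as a minimal VCF
#'
#' @param variants Variant data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  variants <- variants[order(variants$chrom, variants$pos, variants$alt), ,
                       drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- if (nrow(variants) == 0L) character(0) else
    paste(variants$chrom, variants$pos, ".", variants$ref,
          variants$alt, ".", "PASS", ".", sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

validate_variants <- function(variants, genome = NULL) {
  if (any(variants$ref == variants$alt)) stop("REF equal to ALT")
  key <- paste(variants$chrom, variants$pos, variants$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, alt) in strain")
  site <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(site))
    stop("multiple ALT alleles at one site within a strain")
  if (!is.null(genome)) {
    ref_obs <- mapply(function(ch, p) genome_base(genome, ch, p),
                      variants$chrom, variants$pos)
    bad <- ref_obs != variants$ref
    if (any(bad))
      stop("REF mismatch with genome at ",
           paste(variants$chrom[bad], variants$pos[bad],
                 collapse = "; ")[1])
  }
  variants
}

genome_base <- function(genome, chrom, pos) {
  substr(as.character(genome[[chrom]]), pos, pos)
}

#' Extract a coding sequence
#'
#' Returns the 5'-to-3' coding sequence of a single-exon ORF. For
#' minus-strand ORFs the genomic slice is reverse complemented.
#'
#' @param genome A `DNAStringSet`.
#' @param orf One-row ORF data.frame (or list) with `chrom`, `start`,
#'   `end`, `strand`.
#' @return Nucleotide string, length divisible by 3.
#' @export
extract_cds <- function(genome, orf) {
  if (!orf$chrom %in% names(genome)) stop("unknown chromosome: ", orf$chrom)
  s <- substr(as.character(genome[[orf$chrom]]), orf$start, orf$end)
  if (identical(orf$strand, "-")) s <- revcomp(s)
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  s
}

#' Reverse complement of a nucleotide string
#' @param x Nucleotide string (ACGTN).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Translate a coding sequence
#'
#' Codon-by-codon translation under a genetic code; stops render as `"*"`
#' so a full ORF ends with a terminal stop marker. Codons containing N
#' translate to `"X"`.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param code Genetic code, as from [genetic_code()].
#' @return Protein string.
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
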