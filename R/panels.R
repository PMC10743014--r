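#' Construct a SNP locus panel
#'
#' A locus panel describes the biallelic SNPs segregating in a sequenced
#' promoter fragment: dbSNP identifier, genomic coordinate, reference and
#' alternative allele, and the 1-based offset of each site within the
#' amplicon. All downstream stages (phasing, LD, networks, burden, TFBS
#' scanning) are defined relative to a panel.
#'
#' Loci are ordered along the sequenced fragment (ascending amplicon
#' offset). For a promoter amplified from the plus strand this coincides
#' with ascending genomic position; for a minus-strand gene the amplicon
#' runs antiparallel to the reference and offsets descend in genomic
#' coordinates.
#'
#' @param name panel name, e.g. `"ATG16L1_promoter"`.
#' @param loci data frame with columns `rs_id`, `chrom`, `position`
#'   (1-based genomic), `ref`, `alt` (single bases in A/C/G/T) and
#'   `offset` (1-based position within the amplicon).
#' @param promoter_span length-2 integer vector of TSS-relative
#'   coordinates covered by the amplicon, e.g. `c(-1095, 153)`.
#' @return an object of class `locus_panel`.
#' @export
locus_panel <- function(name, loci, promoter_span) {
  stopifnot(is.character(name), length(name) == 1L)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("rs_id", "chrom", "position", "ref", "alt", "offset")
  if (!all(need %in% names(loci)))
    stop("loci must have columns: ", paste(need, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  if (!all(loci$ref %in% bases) || !all(loci$alt %in% bases))
    stop("ref and alt alleles must be single bases in {A,C,G,T}")
  if (any(loci$ref == loci$alt))
    stop("ref allele must differ from alt allele at every locus")
  if (any(loci$offset < 1L))
    stop("amplicon offsets are 1-based and must be >= 1")
  if (anyDuplicated(loci$rs_id))
    stop("duplicate rs_id in panel")
  loci <- loci[order(loci$offset), , drop = FALSE]
  rownames(loci) <- NULL
  structure(
    list(name = name, loci = loci,
         promoter_span = as.integer(promoter_span)),
    class = "locus_panel")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("Locus panel:", x$name, "(", nrow(x$loci), "loci )\n")
  cat("Promoter span (TSS-relative):", x$promoter_span[1], "..",
      x$promoter_span[2], "\n")
  print(x$loci, row.names = FALSE)
  invisible(x)
}

#' Number of loci in a panel
#' @param panel a `locus_panel`.
#' @return integer.
#' @export
n_loci <- function(panel) nrow(panel$loci)

#' Bundled ATG16L1 promoter panel
#'
#' Four promoter SNPs of the human ATG16L1 gene (chromosome 2, GRCh38
#' coordinates), as typed by Sanger sequencing of the -1095..+153 promoter
#' amplicon (1248 bp starting at position 233250476). Amplicon offsets are
#' the genomic positions relative to the amplicon start.
#'
#' @return a `locus_panel` with 4 loci.
#' @export
#' @examples
#' atg16l1_panel()
atg16l1_panel <- function() {
  locus_panel(
    name = "ATG16L1_promoter",
    loci = data.frame(
      rs_id = c("rs1816753", "rs12476635", "rs74599577", "rs77820970"),
      chrom = "2",
      position = c(233250963L, 233251039L, 233251112L, 233251563L),
      ref = c("T", "T", "A", "C"),
      alt = c("C", "C", "T", "T"),
      offset = c(488L, 564L, 637L, 1088L),
      stringsAsFactors = FALSE),
    promoter_span = c(-1095L, 153L))
}

#' Bundled ATG5 promoter panel
#'
#' Two promoter SNPs of the human ATG5 gene (chromosome 6, GRCh37
#' coordinates). ATG5 is transcribed from the minus strand, so the
#' promoter amplicon runs antiparallel to the reference assembly and
#' rs510432 precedes rs506027 along the sequenced fragment.
#'
#' @return a `locus_panel` with 2 loci.
#' @export
atg5_panel <- function() {
  locus_panel(
    name = "ATG5_promoter",
    loci = data.frame(
      rs_id = c("rs510432", "rs506027"),
      chrom = "6",
      position = c(106774464L, 106774030L),
      ref = c("T", "G"),
      alt = c("C", "A"),
      offset = c(301L, 735L),
      stringsAsFactors = FALSE),
    promoter_span = c(-929L, 90L))
}

#' Construct a haplotype set on a panel
#'
#' @param panel a `locus_panel`.
#' @param alleles character matrix, one row per haplotype and one column
#'   per panel locus; every entry must be the ref or alt allele of its
#'   locus.
#' @param labels optional row labels (default `hap1..hapK`).
#' @return character matrix with class attribute preserved as a plain
#'   matrix; rownames are the labels, colnames the panel rs identifiers.
#' @export
haplotype_set <- function(panel, alleles, labels = NULL) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != n_loci(panel))
    stop("haplotypes must have one allele per panel locus")
  ok <- sweep(alleles, 2, panel$loci$ref, "==") |
    sweep(alleles, 2, panel$loci$alt, "==")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("allele '%s' at %s is neither ref nor alt",
                 alleles[bad[1], bad[2]], panel$loci$rs_id[bad[2]]))
  }
  if (is.null(labels)) labels <- paste0("hap", seq_len(nrow(alleles)))
  dimnames(alleles) <- list(labels, panel$loci$rs_id)
  alleles
}

#' The seven ATG16L1 promoter haplotypes
#'
#' Allele vectors of the seven haplotypes segregating over the four
#' ATG16L1 promoter SNPs in the emulated case-control study. hap1 is the
#' wild type (all reference alleles); hap2 is the most frequent haplotype;
#' hap4-hap7 share the alternative T allele at rs77820970 and occur only
#' in patients.
#'
#' @return 7 x 4 character matrix of alleles.
#' @export
#' @examples
#' atg16l1_haplotypes()
atg16l1_haplotypes <- function() {
  haplotype_set(atg16l1_panel(), rbind(
    hap1 = c("T", "T", "A", "C"),
    hap2 = c("C", "T", "A", "C"),
    hap3 = c("C", "C", "A", "C"),
    hap4 = c("C", "T", "A", "T"),
    hap5 = c("C", "T", "T", "T"),
    hap6 = c("T", "T", "A", "T"),
    hap7 = c("T", "C", "A", "T")),
    labels = paste0("hap", 1:7))
}

#' The two ATG5 promoter haplotypes
#'
#' The ATG5 promoter SNPs rs510432 and rs506027 segregate as exactly two
#' haplotypes in complete linkage: TG (reference alleles) and CA.
#'
#' @return 2 x 2 character matrix of alleles.
#' @export
atg5_haplotypes <- function() {
  haplotype_set(atg5_panel(), rbind(
    hap1 = c("T", "G"),
    hap2 = c("C", "A")),
    labels = c("hap1", "hap2"))
}
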