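#' Construct a two-group diploid cohort
#'
#' A cohort holds unphased diploid genotypes for a set of individuals on a
#' shared locus panel, each individual labelled `control` or `patient`.
#' Genotypes are unordered allele pairs; per-cell missingness is allowed
#' (both alleles `NA`).
#'
#' @param panel a `locus_panel`.
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector, each `"control"` or `"patient"`.
#' @param a1,a2 character matrices (individuals x loci) holding the two
#'   alleles of each genotype; order within the pair carries no meaning.
#' @return an object of class `cohort`.
#' @export
cohort <- function(panel, sample_id, group, a1, a2) {
  stopifnot(inherits(panel, "locus_panel"))
  n <- length(sample_id)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id")
  if (length(group) != n || nrow(a1) != n || nrow(a2) != n)
    stop("sample_id, group and genotype matrices disagree in length")
  if (!all(group %in% c("control", "patient")))
    stop("group labels must be 'control' or 'patient'")
  L <- n_loci(panel)
  if (ncol(a1) != L || ncol(a2) != L)
    stop("genotype matrices must have one column per panel locus")
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_; a2[miss] <- NA_character_
  for (j in seq_len(L)) {
    legal <- c(panel$loci$ref[j], panel$loci$alt[j])
    bad1 <- !is.na(a1[, j]) & !(a1[, j] %in% legal)
    bad2 <- !is.na(a2[, j]) & !(a2[, j] %in% legal)
    if (any(bad1 | bad2)) {
      i <- which(bad1 | bad2)[1]
      stop(sprintf("sample '%s', locus %s: allele outside {%s,%s}",
                   sample_id[i], panel$loci$rs_id[j], legal[1], legal[2]))
    }
  }
  # store pairs in sorted order so C/T and T/C compare equal
  swap <- !miss & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(sample_id, panel$loci$rs_id)
  structure(list(panel = panel, sample_id = as.character(sample_id),
                 group = as.character(group), a1 = a1, a2 = a2),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort on panel", x$panel$name, "\n")
  tab <- table(factor(x$group, levels = c("control", "patient")))
  cat(sprintf("  %d individuals (%d control, %d patient), %d loci\n",
              length(x$sample_id), tab[["control"]], tab[["patient"]],
              n_loci(x$panel)))
  nm <- sum(is.na(x$a1))
  if (nm > 0) cat("  missing genotype cells:", nm, "\n")
  invisible(x)
}

n_individuals <- function(x) length(x$sample_id)

#' Read a genotype table
#'
#' Reads the tab-separated genotype dialect written by
#' [write_genotype_table()]: a header line
#' `sample_id<TAB>group<TAB><rs_id>...` followed by one row per
#' individual, genotype cells formatted `"X/Y"` (unordered), with `"./."`
#' or an empty cell marking a missing genotype.
#'
#' @param path file path.
#' @param panel the `locus_panel` whose rs identifiers the header must
#'   name (in any order).
#' @return a `cohort`.
#' @export
read_genotype_table <- function(path, panel) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("genotype table must have 'sample_id' and 'group' columns")
  rs <- panel$loci$rs_id
  missing_cols <- setdiff(rs, names(tab))
  if (length(missing_cols))
    stop("genotype table lacks panel column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(tab)
  L <- length(rs)
  a1 <- a2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    cell <- trimws(tab[[rs[j]]])
    is_miss <- cell %in% c("", "./.", "NA")
    parts <- strsplit(cell[!is_miss], "/", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed genotype cell in column ", rs[j])
    m <- do.call(rbind, parts)
    a1[!is_miss, j] <- m[, 1]
    a2[!is_miss, j] <- m[, 2]
  }
  cohort(panel, tab$sample_id, tab$group, a1, a2)
}

#' Write a genotype table
#'
#' @param x a `cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  cells <- matrix("./.", n_individuals(x), n_loci(x$panel))
  ok <- !is.na(x$a1)
  cells[ok] <- paste0(x$a1[ok], "/", x$a2[ok])
  out <- data.frame(sample_id = x$sample_id, group = x$group,
                    cells, check.names = FALSE)
  names(out) <- c("sample_id", "group", x$panel$loci$rs_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a VCF file
#'
#' Builds a locus panel from the CHROM/POS/ID/REF/ALT columns of
#' biallelic SNP records and decodes per-sample GT fields. Both unphased
#' (`0/1`) and phased (`0|1`) genotypes are accepted; any phase
#' information is discarded, since phase is re-estimated downstream by
#' [em_phase()]. Multi-allelic or non-SNP records are skipped with a
#' warning.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample_to_group named character vector mapping every VCF sample
#'   name to `"control"` or `"patient"`.
#' @param offsets optional integer vector of amplicon offsets, one per
#'   retained record (default: positions re-based to the first record).
#' @param name panel name for the constructed `locus_panel`.
#' @param promoter_span TSS-relative span recorded on the panel.
#' @return a `cohort`.
#' @export
read_vcf <- function(path, sample_to_group, offsets = NULL,
                     name = "vcf_panel", promoter_span = c(0L, 0L)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " multi-allelic or non-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in VCF")
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  unknown <- setdiff(samples, names(sample_to_group))
  if (length(unknown))
    stop("sample(s) absent from group mapping: ",
         paste(unknown, collapse = ", "))
  pos <- as.integer(fix$POS)
  if (is.null(offsets)) offsets <- pos - min(pos) + 1L
  panel <- locus_panel(name, data.frame(
    rs_id = fix$ID, chrom = fix$CHROM, position = pos,
    ref = fix$REF, alt = fix$ALT, offset = as.integer(offsets),
    stringsAsFactors = FALSE), promoter_span)
  ord <- order(as.integer(offsets))
  gt <- gt[ord, , drop = FALSE]
  L <- nrow(gt); n <- length(samples)
  a1 <- a2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    g <- gsub("|", "/", gt[j, ], fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    alleles <- c(panel$loci$ref[j], panel$loci$alt[j])
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (length(p) != 2L || anyNA(p) || any(p == ".")) next
      idx <- as.integer(p) + 1L
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > 2L))
        stop("unexpected GT code '", gt[j, i], "' for sample ", samples[i])
      a1[i, j] <- alleles[idx[1]]
      a2[i, j] <- alleles[idx[2]]
    }
  }
  cohort(panel, samples, unname(sample_to_group[samples]), a1, a2)
}

#' IUPAC single-letter encoding of a diploid genotype
#'
#' Homozygotes map to the base itself, heterozygotes to the IUPAC
#' ambiguity code for the unordered pair (the convention used when
#' recoding Sanger chromatogram calls).
#'
#' @param a,b character vectors of alleles in A/C/G/T (recycled).
#' @return character vector of single IUPAC letters.
#' @export
#' @examples
#' encode_iupac("C", "T")  # "Y"
#' encode_iupac("A", "G")  # "R"
encode_iupac <- function(a, b) {
  codes <- c(AA = "A", CC = "C", GG = "G", TT = "T",
             AC = "M", AG = "R", AT = "W",
             CG = "S", CT = "Y", GT = "K")
  a <- toupper(a); b <- toupper(b)
  if (!all(a %in% c("A", "C", "G", "T")) ||
      !all(b %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases in {A,C,G,T}")
  key <- paste0(pmin(a, b), pmax(a, b))
  unname(codes[key])
}
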