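#' Build a haplotype's promoter sequence
#'
#' Substitutes the haplotype's allele at every panel amplicon offset of
#' the reference promoter fragment; everything else is untouched. The
#' reference base at each offset must equal the locus's reference allele
#' (a mismatch indicates an offset/sequence disagreement and is an
#' error naming the locus).
#'
#' @param reference single character string (the sequenced fragment).
#' @param panel a `locus_panel` whose offsets the fragment covers.
#' @param hap haplotype allele vector (one allele per panel locus), or a
#'   row label when `haps` rownames are available via [haplotype_set()].
#' @return single character string of the same length as `reference`.
#' @export
haplotype_sequence <- function(reference, panel, hap) {
  stopifnot(is.character(reference), length(reference) == 1L)
  if (nchar(reference) < max(panel$loci$offset))
    stop("reference fragment does not cover all amplicon offsets")
  s <- strsplit(reference, "", fixed = TRUE)[[1]]
  off <- panel$loci$offset
  mism <- s[off] != panel$loci$ref
  if (any(mism))
    stop(sprintf("reference base '%s' at offset %d does not match the %s ref allele '%s'",
                 s[off][mism][1], off[mism][1],
                 panel$loci$rs_id[mism][1], panel$loci$ref[mism][1]))
  if (length(hap) != n_loci(panel))
    stop("haplotype must have one allele per panel locus")
  s[off] <- hap
  paste(s, collapse = "")
}

#' Log-odds PSSM scores along a sequence
#'
#' Scores every window of a sequence against a position frequency
#' matrix using log2 odds with background-split pseudocounts: position
#' `i` of base `b` contributes
#' `log2(((counts[b,i] + pc * bg[b]) / (colsum_i + pc)) / bg[b])`.
#' The reverse strand is scored on the reverse complement, with hit
#' coordinates mapped back to the forward strand (1-based start of the
#' overlapped window). Windows containing an ambiguous base are skipped
#' with a message.
#'
#' @param x a `pfm`.
#' @param sequence single character string over A/C/G/T (IUPAC
#'   ambiguity codes cause their windows to be skipped).
#' @param strand `"both"` or `"forward"`.
#' @return data frame with columns `start`, `strand`, `score`.
#' @export
pwm_scores <- function(x, sequence, strand = c("both", "forward")) {
  stopifnot(inherits(x, "pfm"))
  strand <- match.arg(strand)
  m <- motif_length(x)
  if (nchar(sequence) < m)
    stop("sequence shorter than the motif")
  lo <- .pfm_logodds(x)
  fwd <- .scan_one(lo, sequence, m)
  fwd$strand <- "+"
  out <- fwd
  if (strand == "both") {
    rc <- .revcomp(sequence)
    rev <- .scan_one(lo, rc, m)
    L <- nchar(sequence)
    rev$start <- L - (rev$start + m - 1L) + 1L
    rev$strand <- "-"
    out <- rbind(fwd, rev)
  }
  out <- out[order(out$start, out$strand), c("start", "strand", "score")]
  rownames(out) <- NULL
  out
}

.pfm_logodds <- function(x) {
  pc <- x$pseudocount
  bg <- x$background
  cs <- colSums(x$counts)
  p <- sweep(x$counts + pc * bg, 2, cs + pc, "/")
  log2(p / bg)
}

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

.scan_one <- function(lo, sequence, m) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(s, c("A", "C", "G", "T"))
  n <- length(s) - m + 1L
  starts <- seq_len(n)
  scores <- numeric(n)
  skipped <- 0L
  keep <- logical(n)
  for (p in starts) {
    w <- idx[p:(p + m - 1L)]
    if (anyNA(w)) { skipped <- skipped + 1L; next }
    scores[p] <- sum(lo[cbind(w, seq_len(m))])
    keep[p] <- TRUE
  }
  if (skipped > 0L)
    message(skipped, " window(s) skipped (ambiguous base)")
  data.frame(start = starts[keep], score = scores[keep])
}

#' Per-haplotype binding-score report around each SNP
#'
#' For every panel locus, builds each haplotype's promoter sequence,
#' scans the motif over all windows lying within `window` bases of the
#' SNP offset, and reports the best hit per haplotype. Haplotypes whose
#' sequences are identical throughout the scanned region necessarily
#' score identically and are merged into one allele group, so a
#' biallelic site yields at most two groups — the typical report
#' contrasts the reference-allele and alternative-allele haplotype
#' groups at each site.
#'
#' @param x a `pfm`.
#' @param reference reference promoter fragment (character string).
#' @param panel a `locus_panel`.
#' @param haps character matrix of haplotype allele vectors with row
#'   labels.
#' @param window half-width of the scanned region around each SNP
#'   offset; must be at least the motif length. Default: motif length
#'   plus 10.
#' @param strand passed to [pwm_scores()].
#' @return data frame of class `tfbs_report`: one row per locus and
#'   allele group with columns `rs_id`, `allele`, `haplotypes`
#'   (comma-separated labels), `best_score`, `best_start` (1-based,
#'   fragment coordinates), `strand`.
#' @export
tfbs_delta <- function(x, reference, panel, haps, window = NULL,
                       strand = "both") {
  stopifnot(inherits(x, "pfm"))
  haps <- as.matrix(haps)
  m <- motif_length(x)
  if (is.null(window)) window <- m + 10L
  if (window < m) stop("window must be at least the motif length")
  labels <- rownames(haps)
  if (is.null(labels)) labels <- paste0("hap", seq_len(nrow(haps)))
  L <- nchar(reference)
  rows <- list()
  for (j in seq_len(n_loci(panel))) {
    off <- panel$loci$offset[j]
    lo_b <- max(1L, off - window)
    hi_b <- min(L, off + window)
    key <- character(nrow(haps))
    seqs <- character(nrow(haps))
    for (h in seq_len(nrow(haps))) {
      full <- haplotype_sequence(reference, panel, haps[h, ])
      seqs[h] <- substr(full, lo_b, hi_b)
      key[h] <- seqs[h]
    }
    for (k in unique(key)) {
      members <- which(key == k)
      sc <- pwm_scores(x, k, strand = strand)
      best <- sc[which.max(sc$score), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        rs_id = panel$loci$rs_id[j],
        allele = haps[members[1], j],
        haplotypes = paste(labels[members], collapse = ","),
        best_score = best$score,
        best_start = best$start + lo_b - 1L,
        strand = best$strand, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tfbs_report", "data.frame")
  out
}

#' Read a promoter fragment from a FASTA file
#'
#' Thin wrapper over Biostrings returning the first record as a plain
#' upper-case character string.
#'
#' @param path FASTA file path.
#' @return single character string.
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  toupper(as.character(ss[[1]]))
}
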