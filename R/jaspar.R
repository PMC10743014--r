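#' Construct a position frequency matrix
#'
#' @param counts 4 x m non-negative numeric matrix of base counts with
#'   rows A, C, G, T.
#' @param tf_name transcription-factor name.
#' @param pseudocount total pseudocount added per column, split across
#'   bases in proportion to the background (default 0.8, the common
#'   JASPAR-style smoothing).
#' @param background named per-base probabilities summing to 1 (default
#'   uniform).
#' @return object of class `pfm`.
#' @export
pfm <- function(counts, tf_name = "TF", pseudocount = 0.8,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("a PFM needs exactly 4 rows (A, C, G, T)")
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("negative counts in PFM")
  if (any(colSums(counts) == 0)) stop("all-zero column in PFM")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  background <- background[c("A", "C", "G", "T")]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9)
    stop("background must name A,C,G,T and sum to 1")
  structure(list(tf_name = tf_name, counts = counts,
                 pseudocount = pseudocount, background = background),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM '%s': %d position(s), pseudocount %.2f\n",
              x$tf_name, ncol(x$counts), x$pseudocount))
  print(x$counts)
  invisible(x)
}

#' Motif length of a PFM
#' @param x a `pfm`.
#' @return integer number of positions.
#' @export
motif_length <- function(x) ncol(x$counts)

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR PFM text format: an optional `>ID NAME` header
#' followed by four labelled count rows (`A [ 1 2 ... ]`; the brackets
#' are optional).
#'
#' @param path file path.
#' @param pseudocount,background attached to the returned matrix (see
#'   [pfm()]).
#' @return a `pfm`.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "TF"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) != 4L)
    stop("a JASPAR PFM needs exactly 4 count rows, found ", length(lines))
  rows <- list()
  bases <- character(4)
  for (k in 1:4) {
    ln <- trimws(lines[k])
    base <- toupper(substr(ln, 1, 1))
    if (!base %in% c("A", "C", "G", "T"))
      stop("count row must start with a base label, got: ", ln)
    num <- gsub("[][]", " ", substr(ln, 2, nchar(ln)))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(num), "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric counts in row ", base)
    bases[k] <- base
    rows[[base]] <- vals
  }
  if (!setequal(bases, c("A", "C", "G", "T")))
    stop("PFM rows must be labelled A, C, G, T")
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged PFM: rows differ in length")
  counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  pfm(counts, tf_name = name, pseudocount = pseudocount,
      background = background)
}

#' Write a PFM in JASPAR format
#'
#' @param x a `pfm`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(x, path) {
  stopifnot(inherits(x, "pfm"))
  fmt <- function(base) paste0(base, "  [ ",
                               paste(format(x$counts[base, ],
                                            trim = TRUE),
                                     collapse = " "), " ]")
  writeLines(c(paste0(">", x$tf_name),
               fmt("A"), fmt("C"), fmt("G"), fmt("T")), path)
  invisible(path)
}
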