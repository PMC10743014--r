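#' Haplotype phasing by expectation-maximization
#'
#' Estimates haplotype frequencies and each individual's most likely
#' haplotype pair from unphased diploid genotypes by maximum-likelihood
#' EM (Excoffier-Slatkin gene counting). The E-step assigns each
#' genotype-compatible haplotype pair a probability proportional to
#' `2 * f_a * f_b` (heterozygous pair) or `f_a^2` (homozygous pair); the
#' M-step re-estimates frequencies from expected haplotype counts.
#' Iteration stops when the log-likelihood improves by less than `tol`
#' or after `max_iter` iterations; the best of `restarts` runs from
#' perturbed-uniform starting frequencies is returned (the first restart
#' starts from the exact uniform vector, so a single-restart call is
#' fully deterministic).
#'
#' Individuals with any missing genotype are excluded from phasing (with
#' a warning); the panel is small enough that imputation buys nothing.
#' A haplotype enters the reported set when its estimated frequency is
#' at least `1 / (4N)` (half an expected single copy among the `2N`
#' phased chromosomes) and it appears in at least one individual's
#' most-likely pair; maximum likelihood can leave trace mass on phase
#' resolutions no individual's reconstruction uses, and such haplotypes
#' are pruned. [n_haplotypes()] counts the survivors; the rule is
#' recorded in the result's `pruning` field.
#'
#' @param x a `cohort`.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param restarts number of EM restarts.
#' @param seed integer seed for the restart perturbations.
#' @return an object of class `hap_phasing` (also `phased_cohort`):
#'   a list with the haplotype allele matrix (`haplotypes`, reported
#'   haplotypes first, labelled `hap1..hapK` with the all-reference
#'   haplotype, when present, as `hap1` and the rest ordered by
#'   decreasing frequency), estimated frequencies (`freq`, summing to 1),
#'   a logical `reported` mask, per-individual best pairs (`pairs`,
#'   row indices into `haplotypes`) with posterior probabilities,
#'   `group` and `sample_id` of the phased individuals, the
#'   log-likelihood trace of the winning restart, and convergence flags.
#' @export
#' @examples
#' cc <- generate_cohort(promoter_cohort_spec("ATG5"), seed = 7)
#' fit <- em_phase(cc, restarts = 5)
#' fit
em_phase <- function(x, max_iter = 1000L, tol = 1e-8, restarts = 20L,
                     seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (n_individuals(x) == 0L) stop("empty cohort")
  L <- n_loci(x$panel)
  complete <- rowSums(is.na(x$a1)) == 0L
  if (any(!complete))
    warning(sum(!complete),
            " individual(s) with missing genotypes excluded from phasing")
  if (!any(complete)) stop("no individual with complete genotypes")
  # genotype codes: 0 hom-ref, 1 het, 2 hom-alt
  g <- matrix(0L, sum(complete), L)
  a1 <- x$a1[complete, , drop = FALSE]
  a2 <- x$a2[complete, , drop = FALSE]
  for (j in seq_len(L)) {
    alt <- x$panel$loci$alt[j]
    g[, j] <- (a1[, j] == alt) + (a2[, j] == alt)
  }
  # collapse identical multilocus genotypes into classes
  key <- apply(g, 1L, paste, collapse = "")
  classes <- !duplicated(key)
  class_of <- match(key, key[classes])
  w <- as.vector(table(factor(class_of, levels = seq_len(sum(classes)))))
  gc_mat <- g[classes, , drop = FALSE]

  # enumerate compatible haplotype pairs per genotype class
  hap_index <- new.env(parent = emptyenv())
  hap_list <- list()
  get_hap <- function(h) {
    k <- paste(h, collapse = "")
    id <- hap_index[[k]]
    if (is.null(id)) {
      id <- length(hap_list) + 1L
      hap_list[[id]] <<- h
      hap_index[[k]] <- id
    }
    id
  }
  class_pairs <- vector("list", nrow(gc_mat))
  for (c_i in seq_len(nrow(gc_mat))) {
    gv <- gc_mat[c_i, ]
    het <- which(gv == 1L)
    base <- as.integer(gv == 2L)
    if (length(het) == 0L) {
      id <- get_hap(base)
      class_pairs[[c_i]] <- matrix(id, 1L, 2L)
    } else {
      m <- length(het) - 1L
      n_res <- 2L^m
      pr <- matrix(0L, n_res, 2L)
      for (r in seq_len(n_res)) {
        hA <- base
        if (m > 0L) {
          bits <- as.integer(intToBits(r - 1L))[seq_len(m)]
          hA[het[-1L]] <- bits
        }
        hA[het[1L]] <- 0L
        hB <- hA
        hB[het] <- 1L - hA[het]
        pr[r, ] <- c(get_hap(hA), get_hap(hB))
      }
      class_pairs[[c_i]] <- pr
    }
  }
  H <- length(hap_list)
  hap_mat <- do.call(rbind, hap_list)

  # flatten pairs for vectorized E-steps
  pair_class <- rep(seq_along(class_pairs),
                    vapply(class_pairs, nrow, 0L))
  pa <- unlist(lapply(class_pairs, function(m) m[, 1]))
  pb <- unlist(lapply(class_pairs, function(m) m[, 2]))
  coef <- ifelse(pa == pb, 1, 2)
  cw <- w[pair_class]

  run_em <- function(f0) {
    f <- f0
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pp <- coef * f[pa] * f[pb]
      denom <- as.vector(rowsum(pp, pair_class))
      ll <- sum(w * log(denom))
      trace <- c(trace, ll)
      post <- pp / denom[pair_class]
      counts <- numeric(H)
      tmp <- rowsum(c(cw * post, cw * post), c(pa, pb))
      counts[as.integer(rownames(tmp))] <- tmp[, 1]
      f <- counts / sum(counts)
      if (is.finite(ll) && ll - ll_old < tol && it > 1L) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(f = f, loglik = trace, converged = converged,
         n_iter = length(trace))
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    f0 <- if (r == 1L) rep(1 / H, H) else {
      u <- stats::runif(H, 0.5, 1.5)
      u / sum(u)
    }
    fit <- run_em(f0)
    if (is.null(best) ||
        fit$loglik[fit$n_iter] > best$loglik[best$n_iter] + 1e-12)
      best <- fit
  }
  f <- best$f

  # most likely pair per individual, ties toward the smaller pair
  pp <- ifelse(pa == pb, 1, 2) * f[pa] * f[pb]
  best_pair <- matrix(0L, nrow(gc_mat), 2L)
  best_post <- numeric(nrow(gc_mat))
  hap_key <- apply(hap_mat, 1L, paste, collapse = "")
  for (c_i in seq_len(nrow(gc_mat))) {
    rows <- which(pair_class == c_i)
    pr <- pp[rows]
    post <- pr / sum(pr)
    top <- which(post >= max(post) - 1e-12)
    if (length(top) > 1L) {
      keys <- vapply(top, function(t) {
        k <- sort(c(hap_key[pa[rows[t]]], hap_key[pb[rows[t]]]))
        paste(k, collapse = "|")
      }, "")
      top <- top[order(keys)][1L]
    }
    r <- rows[top]
    ab <- c(pa[r], pb[r])
    best_pair[c_i, ] <- ab[order(hap_key[ab])]
    best_post[c_i] <- max(post)
  }

  # canonical ordering and labels: all-reference haplotype first (wild
  # type), remainder by decreasing frequency then allele string
  N <- sum(complete)
  threshold <- 1 / (4 * N)
  is_ref <- rowSums(hap_mat) == 0L
  ord <- order(-is_ref, -f, hap_key)
  rank <- match(seq_len(H), ord)
  hap_mat <- hap_mat[ord, , drop = FALSE]
  f <- f[ord]
  pairs <- matrix(rank[best_pair[class_of, ]], ncol = 2L)
  # keep each pair ordered by canonical haplotype index
  pairs <- t(apply(pairs, 1L, sort))
  # a haplotype is reported when it clears the frequency threshold AND
  # enters at least one individual's most-likely reconstruction
  support <- tabulate(pairs, nbins = H) > 0L
  reported <- f >= threshold & support
  alleles <- matrix(x$panel$loci$ref[col(hap_mat)], nrow(hap_mat), L)
  alleles[hap_mat == 1L] <- x$panel$loci$alt[col(hap_mat)][hap_mat == 1L]
  labels <- character(H)
  labels[reported] <- paste0("hap", seq_len(sum(reported)))
  if (any(!reported))
    labels[!reported] <- paste0("rare", seq_len(sum(!reported)))
  dimnames(alleles) <- list(labels, x$panel$loci$rs_id)

  structure(list(
    panel = x$panel,
    haplotypes = alleles,
    freq = stats::setNames(f, labels),
    reported = stats::setNames(reported, labels),
    threshold = threshold,
    pruning = "frequency >= 1/(4N) and best-pair support",
    pairs = pairs,
    posterior = best_post[class_of],
    sample_id = x$sample_id[complete],
    group = x$group[complete],
    excluded = x$sample_id[!complete],
    loglik = best$loglik,
    n_iter = best$n_iter,
    converged = best$converged,
    n_restarts = restarts),
    class = c("hap_phasing", "phased_cohort"))
}

#' @export
print.hap_phasing <- function(x, ...) {
  cat("EM haplotype phasing (", length(x$sample_id), "individuals,",
      ncol(x$haplotypes), "loci )\n")
  cat(sprintf("  log-likelihood %.4f after %d iteration(s); %s\n",
              x$loglik[x$n_iter], x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  %d haplotype(s) above reporting threshold %.4g\n",
              sum(x$reported), x$threshold))
  rep_idx <- which(x$reported)
  tab <- data.frame(
    haplotype = names(x$freq)[rep_idx],
    alleles = apply(x$haplotypes[rep_idx, , drop = FALSE], 1L,
                    paste, collapse = "-"),
    freq = round(x$freq[rep_idx], 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Number of distinct reported haplotypes
#'
#' Counts the haplotypes surviving the phasing frequency-pruning
#' threshold of `1 / (4N)`.
#'
#' @param fit a `hap_phasing` object.
#' @return integer.
#' @export
n_haplotypes <- function(fit) {
  stopifnot(inherits(fit, "hap_phasing"))
  sum(fit$reported)
}

#' Per-individual haplotype-pair genotype labels
#'
#' Labels each phased individual by its most likely haplotype pair,
#' e.g. `"hap2/hap5"`, with the pair unordered and printed in canonical
#' (ascending haplotype index) order.
#'
#' @param fit a `hap_phasing` object.
#' @return named character vector (names are sample ids).
#' @export
genotype_labels <- function(fit) {
  stopifnot(inherits(fit, "hap_phasing"))
  lab <- rownames(fit$haplotypes)
  stats::setNames(paste(lab[fit$pairs[, 1]], lab[fit$pairs[, 2]],
                        sep = "/"),
                  fit$sample_id)
}

#' Assemble a phased cohort from known haplotype pairs
#'
#' Builds the container consumed by [pairwise_ld()], [amova_fst()] and
#' [burden_test()] directly from a haplotype table and per-individual
#' pair indices — for instance the simulated truth attached by
#' [generate_cohort()], bypassing estimation.
#'
#' @param haplotypes character matrix of haplotype allele vectors.
#' @param pairs n x 2 integer matrix of row indices into `haplotypes`.
#' @param group character vector of group labels.
#' @param sample_id optional sample identifiers.
#' @return an object of class `phased_cohort`.
#' @export
phased_cohort <- function(haplotypes, pairs, group, sample_id = NULL) {
  haplotypes <- as.matrix(haplotypes)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs < 1L) || any(pairs > nrow(haplotypes)))
    stop("pair indices outside the haplotype table")
  if (length(group) != nrow(pairs))
    stop("one group label per individual required")
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_along(group))
  cnt <- tabulate(pairs, nbins = nrow(haplotypes))
  structure(list(haplotypes = haplotypes, pairs = pairs,
                 freq = cnt / sum(cnt),
                 group = as.character(group),
                 sample_id = as.character(sample_id)),
            class = "phased_cohort")
}
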