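#' Median-joining haplotype network
#'
#' Builds the median-joining network of a set of binary-site haplotypes:
#' (i) the minimum spanning network (all links co-minimal within
#' `epsilon` of the weight at which components join, so equally short
#' alternative connections are retained rather than arbitrarily
#' dropped); (ii) median (majority-per-site) vectors of mutually linked
#' triplets are added when their connection cost is within `epsilon` of
#' the best candidate, and the network is rebuilt until no new median
#' arises; (iii) median vectors not lying on any shortest path between
#' observed haplotypes are pruned. Cycles in the result (reticulations)
#' signal recombination or recurrent mutation.
#'
#' @param haps character matrix of observed haplotype allele vectors
#'   (rows labelled; each column biallelic).
#' @param freq optional named list or matrix of per-group frequencies
#'   (`control`, `patient`) attached to the nodes.
#' @param epsilon non-negative integer relaxation parameter (default 0,
#'   the usual strictly-minimal network).
#' @return an object of class `hap_network`: a list with `graph` (an
#'   igraph object), `nodes` (data frame: label, alleles, observed,
#'   control_freq, patient_freq) and `epsilon`. Edge attributes `steps`
#'   (Hamming distance between endpoints) and `loci` (the sites that
#'   change along the edge).
#' @export
#' @examples
#' net <- median_joining(atg16l1_haplotypes())
#' reticulations(net)
median_joining <- function(haps, freq = NULL, epsilon = 0L) {
  haps <- as.matrix(haps)
  if (nrow(haps) < 1L) stop("at least one haplotype is required")
  for (j in seq_len(ncol(haps)))
    if (length(unique(haps[, j])) > 2L)
      stop("non-binary site in column ", j)
  # merge duplicate haplotypes (frequency merge leaves the edge set alone)
  key <- apply(haps, 1L, paste, collapse = "")
  haps <- haps[!duplicated(key), , drop = FALSE]
  labels <- rownames(haps)
  if (is.null(labels)) labels <- paste0("hap", seq_len(nrow(haps)))
  nodes <- haps
  observed <- rep(TRUE, nrow(nodes))
  node_labels <- labels
  n_median <- 0L

  rebuild <- function(nodes) {
    d <- hamming_matrix(nodes)
    .msn_edges(d, epsilon)
  }

  repeat {  # median-vector augmentation
    edges <- rebuild(nodes)
    adj <- matrix(FALSE, nrow(nodes), nrow(nodes))
    if (nrow(edges)) {
      adj[cbind(edges$i, edges$j)] <- TRUE
      adj[cbind(edges$j, edges$i)] <- TRUE
    }
    cand <- list(); costs <- numeric(0)
    nkey <- apply(nodes, 1L, paste, collapse = "")
    if (nrow(nodes) >= 3L) {
      trip <- utils::combn(nrow(nodes), 3L)
      for (t in seq_len(ncol(trip))) {
        u <- trip[1, t]; v <- trip[2, t]; w <- trip[3, t]
        if (!(adj[u, v] && adj[u, w] && adj[v, w])) next
        med <- apply(nodes[c(u, v, w), , drop = FALSE], 2L, function(col) {
          tb <- table(col)
          names(tb)[which.max(tb)]
        })
        mk <- paste(med, collapse = "")
        if (mk %in% nkey) next
        cost <- sum(nodes[u, ] != med) + sum(nodes[v, ] != med) +
          sum(nodes[w, ] != med)
        cand[[length(cand) + 1L]] <- med
        costs <- c(costs, cost)
      }
    }
    if (!length(cand)) break
    lambda <- min(costs)
    keep <- which(costs <= lambda + epsilon)
    new_haps <- unique(do.call(rbind, cand[keep]))
    new_haps <- new_haps[!(apply(new_haps, 1L, paste, collapse = "")
                           %in% nkey), , drop = FALSE]
    if (!nrow(new_haps)) break
    for (r in seq_len(nrow(new_haps))) {
      n_median <- n_median + 1L
      nodes <- rbind(nodes, new_haps[r, ])
      observed <- c(observed, FALSE)
      node_labels <- c(node_labels, paste0("mv", n_median))
    }
  }

  # prune medians off every observed-to-observed shortest path
  repeat {
    edges <- rebuild(nodes)
    g <- .network_graph(nodes, node_labels, edges)
    if (all(observed)) break
    dg <- igraph::distances(g, weights = igraph::E(g)$steps)
    obs_i <- which(observed)
    drop <- logical(nrow(nodes))
    for (m in which(!observed)) {
      on_path <- FALSE
      for (u in obs_i) {
        if (on_path) break
        for (v in obs_i) {
          if (u >= v) next
          if (abs(dg[u, m] + dg[m, v] - dg[u, v]) < 1e-9) {
            on_path <- TRUE; break
          }
        }
      }
      drop[m] <- !on_path
    }
    if (!any(drop)) break
    nodes <- nodes[!drop, , drop = FALSE]
    observed <- observed[!drop]
    node_labels <- node_labels[!drop]
  }

  rownames(nodes) <- node_labels
  cf <- pf <- rep(NA_real_, nrow(nodes))
  if (!is.null(freq)) {
    freq <- as.data.frame(freq)
    m <- match(node_labels, rownames(freq))
    if ("control" %in% names(freq)) cf <- freq$control[m]
    if ("patient" %in% names(freq)) pf <- freq$patient[m]
    cf[!observed] <- 0; pf[!observed] <- 0
  }
  ndf <- data.frame(
    label = node_labels,
    alleles = apply(nodes, 1L, paste, collapse = "-"),
    observed = observed, control_freq = cf, patient_freq = pf,
    stringsAsFactors = FALSE)
  g <- .network_graph(nodes, node_labels, rebuild(nodes))
  igraph::V(g)$observed <- as.integer(observed)
  igraph::V(g)$control_freq <- ifelse(is.na(cf), -1, cf)
  igraph::V(g)$patient_freq <- ifelse(is.na(pf), -1, pf)
  structure(list(graph = g, nodes = ndf, haplotypes = nodes,
                 epsilon = epsilon),
            class = "hap_network")
}

# minimum spanning network: repeatedly join components with every link
# within epsilon of the current minimal inter-component distance
.msn_edges <- function(d, epsilon) {
  K <- nrow(d)
  comp <- seq_len(K)
  out <- list()
  while (length(unique(comp)) > 1L) {
    cross <- which(outer(comp, comp, "!=") & upper.tri(d), arr.ind = TRUE)
    delta <- min(d[cross])
    batch <- cross[d[cross] <= delta + epsilon, , drop = FALSE]
    for (r in seq_len(nrow(batch))) {
      i <- batch[r, 1]; j <- batch[r, 2]
      out[[length(out) + 1L]] <- c(i, j, d[i, j])
    }
    for (r in seq_len(nrow(batch))) {   # merge after the whole batch
      ci <- comp[batch[r, 1]]; cj <- comp[batch[r, 2]]
      comp[comp == cj] <- ci
    }
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], w = m[, 3])
}

.network_graph <- function(nodes, labels, edges) {
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  igraph::V(g)$name <- labels
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
    igraph::E(g)$steps <- edges$w
    loci <- colnames(nodes)
    if (is.null(loci)) loci <- paste0("L", seq_len(ncol(nodes)))
    igraph::E(g)$loci <- vapply(seq_len(nrow(edges)), function(r) {
      diff <- nodes[edges$i[r], ] != nodes[edges$j[r], ]
      paste(loci[diff], collapse = ",")
    }, "")
  }
  g
}

#' @export
print.hap_network <- function(x, ...) {
  cat("Median-joining haplotype network (epsilon =", x$epsilon, ")\n")
  cat(sprintf("  %d node(s) (%d observed, %d median vector(s)), %d edge(s)\n",
              nrow(x$nodes), sum(x$nodes$observed),
              sum(!x$nodes$observed), igraph::ecount(x$graph)))
  cyc <- reticulations(x)
  cat("  reticulations (independent cycles):", length(cyc), "\n")
  invisible(x)
}

#' Detect reticulations in a haplotype network
#'
#' Returns a cycle basis of the network graph (one fundamental cycle per
#' non-tree edge of a minimum spanning tree), each cycle annotated with
#' the loci whose state changes on two or more of its edges — the sites
#' whose recurrent changes create the loop.
#'
#' @param net a `hap_network`.
#' @return list of cycles; each element is a list with `nodes` (labels
#'   in cycle order) and `alternating_loci`.
#' @export
reticulations <- function(net) {
  stopifnot(inherits(net, "hap_network"))
  g <- net$graph
  n_cycles <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)
  if (n_cycles <= 0) return(list())
  tree <- igraph::mst(g, weights = igraph::E(g)$steps)
  ends_g <- igraph::ends(g, igraph::E(g))
  tree_ids <- igraph::get_edge_ids(tree, as.vector(t(ends_g)))
  extra <- which(tree_ids == 0)
  cycles <- list()
  for (e in extra) {
    uv <- igraph::ends(g, e)[1, ]
    path <- igraph::shortest_paths(tree, from = uv[1], to = uv[2],
                                   weights = NA)$vpath[[1]]
    cyc_nodes <- names(path)
    loci_runs <- character(0)
    seqn <- c(cyc_nodes, cyc_nodes[1])
    for (k in seq_len(length(seqn) - 1L)) {
      a <- net$haplotypes[seqn[k], ]
      b <- net$haplotypes[seqn[k + 1L], ]
      loci <- colnames(net$haplotypes)
      if (is.null(loci)) loci <- paste0("L", seq_along(a))
      loci_runs <- c(loci_runs, loci[a != b])
    }
    tab <- table(loci_runs)
    cycles[[length(cycles) + 1L]] <- list(
      nodes = cyc_nodes,
      alternating_loci = names(tab)[tab >= 2])
  }
  cycles
}

#' Export a haplotype network
#'
#' Writes the network with its node frequency annotations in GML, DOT or
#' a tab-separated edge list (deterministic node order).
#'
#' @param net a `hap_network`.
#' @param path output file path.
#' @param format `"gml"`, `"dot"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("gml", "dot", "edgelist")) {
  stopifnot(inherits(net, "hap_network"))
  format <- match.arg(format)
  if (format == "gml") {
    igraph::write_graph(net$graph, path, format = "gml")
  } else if (format == "dot") {
    igraph::write_graph(net$graph, path, format = "dot")
  } else {
    ends <- igraph::ends(net$graph, igraph::E(net$graph))
    df <- data.frame(from = ends[, 1], to = ends[, 2],
                     steps = igraph::E(net$graph)$steps,
                     loci = igraph::E(net$graph)$loci,
                     stringsAsFactors = FALSE)
    df <- df[order(df$from, df$to), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
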