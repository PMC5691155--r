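# Gene-gene co-membership graphs from pathway / GO annotation and their
# partition into communities by modularity optimisation.

#' Build a gene co-membership graph
#'
#' Edge weight between two genes is the number of annotation sets (pathways
#' or GO terms) containing both. Weights are symmetric non-negative
#' integers; there are no self-loops. Duplicate genes within one set are
#' deduplicated with a warning (via [read_gmt()] semantics).
#'
#' @param sets named list: set name -> character vector of gene ids (the
#'   return shape of [read_gmt()]).
#' @param source label recording where the annotation came from.
#' @return a `comembership` object: list with `weights` (gene x gene
#'   integer matrix) and `source`.
#' @export
build_comembership <- function(sets, source = "pathways") {
  if (!length(sets)) stop("empty membership table")
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (anyDuplicated(s)) {
      warning("duplicate gene(s) in set '", names(sets)[i], "' deduplicated")
      s <- unique(s)
    }
    s
  }) |> stats::setNames(names(sets))
  genes <- sort(unique(unlist(sets)))
  M <- matrix(0L, length(genes), length(sets),
              dimnames = list(genes, names(sets)))
  for (j in seq_along(sets)) M[sets[[j]], j] <- 1L
  W <- tcrossprod(M)
  diag(W) <- 0L
  structure(list(weights = W, source = source), class = "comembership")
}

# weighted Newman-Girvan modularity of a partition; independent of igraph's
# own computation so the reported Q can be cross-checked.
#' @keywords internal
.modularity_q <- function(W, membership) {
  two_m <- sum(W)
  if (two_m == 0) return(0)
  k <- rowSums(W)
  same <- outer(membership, membership, `==`)
  sum((W - outer(k, k) / two_m) * same) / two_m
}

#' Detect communities on a co-membership graph
#'
#' Partitions the gene graph by the Louvain multilevel modularity heuristic
#' (weighted by shared-set counts, or on the binarised graph with
#' `weighted = FALSE`). The node sweep order of the heuristic is fixed by
#' `seed`, so the partition is deterministic given it. The reported Q is
#' computed directly from the weight matrix, not taken from the optimiser.
#'
#' @param graph a `comembership` object.
#' @param seed integer seed controlling the heuristic's sweep order.
#' @param weighted use shared-set counts as edge weights (default) or the
#'   binarised co-membership indicator.
#' @return a `community_partition`: list with `membership` (named integer
#'   vector), `n_communities` and `Q` (weighted modularity).
#' @export
detect_communities <- function(graph, seed = 1L, weighted = TRUE) {
  stopifnot(inherits(graph, "comembership"))
  W <- graph$weights
  if (!weighted) W <- (W > 0) + 0L
  storage.mode(W) <- "double"
  if (sum(W) == 0) {
    membership <- stats::setNames(seq_len(nrow(W)), rownames(W))
    return(structure(list(membership = membership,
                          n_communities = nrow(W), Q = 0),
                     class = "community_partition"))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- .with_seed(seed, igraph::cluster_louvain(
    g, weights = igraph::E(g)$weight))
  membership <- igraph::membership(cl)
  membership <- stats::setNames(as.integer(membership), rownames(W))
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 Q = .modularity_q(W, membership)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d nodes in %d communities, Q = %.4f\n",
              length(x$membership), x$n_communities, x$Q))
  invisible(x)
}

#' Export a partition / a co-membership graph
#' @param partition a `community_partition`.
#' @param path output TSV (gene, community).
#' @export
write_partition <- function(partition, path) {
  out <- data.frame(gene = names(partition$membership),
                    community = as.integer(partition$membership))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @param graph a `comembership` object.
#' @export
write_edge_list <- function(graph, path) {
  W <- graph$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  out <- data.frame(gene1 = rownames(W)[idx[, 1]],
                    gene2 = colnames(W)[idx[, 2]],
                    weight = W[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
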