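#' Network relatedness between two gene networks
#'
#' R = N0 / N1 where N0 counts the unordered node pairs with one member in
#' each network whose shortest-path distance in the reference interaction
#' network is at most `cutoff` (distance 0 means the same gene, i.e. shared
#' nodes), and N1 is the same count taken over the combined node set against
#' itself. At cutoff 0 this reduces to the Jaccard index of the node sets.
#'
#' @param genes_i,genes_j node sets (gene symbols) of the two networks.
#' @param reference the full InteractionNetwork on which distances are
#'   measured (not just the two subnetworks).
#' @param cutoff shortest-path allowance: 0, 1 or 2 (default 0).
#' @return R in \[0, 1\], or NA (with a warning) when N1 = 0.
#' @export
network_relatedness <- function(genes_i, genes_j, reference, cutoff = 0) {
  if (!cutoff %in% c(0, 1, 2)) stop("cutoff must be 0, 1 or 2")
  u <- sort(union(genes_i, genes_j))
  if (!length(u)) {
    warning("both node sets empty; relatedness undefined")
    return(NA_real_)
  }
  if (cutoff == 0) {           # closed form: Jaccard of the node sets
    return(length(intersect(genes_i, genes_j)) / length(u))
  }
  g <- as_igraph_undirected(reference, nodes = u)
  d <- igraph::distances(g, v = u, to = u, weights = NA)
  ok <- is.finite(d) & d <= cutoff
  ina <- u %in% genes_i
  inb <- u %in% genes_j
  qual <- outer(ina, inb, "&") | outer(inb, ina, "&")
  upper <- upper.tri(ok, diag = TRUE)
  n0 <- sum(ok & qual & upper)
  n1 <- sum(ok & upper)
  if (n1 == 0) {
    warning("no qualifying pair in the combined network; R undefined")
    return(NA_real_)
  }
  n0 / n1
}

#' Pairwise relatedness matrix over several networks
#'
#' @param networks named list: label -> node set (gene symbols).
#' @param reference the full InteractionNetwork.
#' @param cutoff see [network_relatedness()].
#' @return Symmetric matrix with unit diagonal and labels as dimnames.
#' @export
relatedness_matrix <- function(networks, reference, cutoff = 0) {
  k <- length(networks)
  if (k < 2) stop("need >= 2 networks")
  R <- diag(1, k)
  dimnames(R) <- list(names(networks), names(networks))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    R[i, j] <- R[j, i] <- network_relatedness(
      networks[[i]], networks[[j]], reference, cutoff = cutoff)
  }
  R
}

#' Convert a relatedness matrix to a distance matrix
#'
#' D = 1 - R elementwise; the diagonal is zero. Undefined relatedness
#' entries propagate as NA.
#'
#' @param R symmetric relatedness matrix (unit diagonal).
#' @return Distance matrix of the same shape.
#' @export
distance_from_relatedness <- function(R) {
  D <- 1 - R
  diag(D) <- 0
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (unrooted). Negative branch lengths,
#' which NJ can produce on non-additive distances, are clamped to zero with
#' the deficit transferred to the adjacent (sister) branch, preserving
#' path lengths through the affected node; clamps are reported.
#'
#' @param D symmetric distance matrix with labels as dimnames, >= 3 taxa,
#'   finite entries.
#' @return List with `tree` (an `ape` "phylo" object) and `newick` (string).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 taxa")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  tree <- ape::nj(D)
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    message("clamped ", length(neg), " negative branch length(s) to zero")
    for (e in neg) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1]
      sib <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sib))
        tree$edge.length[sib[1]] <-
          max(0, tree$edge.length[sib[1]] + deficit)
    }
  }
  list(tree = tree, newick = ape::write.tree(tree))
}

#' Test whether two taxa are sisters (form a cherry) in an unrooted tree
#'
#' @param tree an `ape` "phylo" object.
#' @param a,b tip labels.
#' @return TRUE when the two tips attach to the same internal node.
#' @export
is_cherry <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (anyNA(c(ia, ib))) stop("tip label not in tree")
  pa <- tree$edge[tree$edge[, 2] == ia, 1]
  pb <- tree$edge[tree$edge[, 2] == ib, 1]
  identical(pa, pb)
}

#' Write a distance matrix in PHYLIP square format
#' @param D distance matrix with labels as dimnames.
#' @param path output path.
#' @export
write_phylip_distances <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  labs <- formatC(substr(rownames(D), 1, 10), width = -10)
  writeLines(paste(labs, apply(format(D, digits = 6), 1, paste,
                               collapse = " ")), con)
  invisible(path)
}
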