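#' Dice genetic similarity between populations
#'
#' For each pair of populations (i, j), with `a` the number of insertion
#' sites present in both, `b` the number present only in i and `c` only in j,
#' the genetic similarity is the Dice coefficient
#' `GS(ij) = 2a / (2a + b + c)`. A pair with no sites in either population
#' (a = b = c = 0) is assigned GS 0 with a warning; this cannot arise from a
#' valid presence matrix but is defined for safety.
#'
#' @param matrix A `presence_matrix` (or plain sites x populations 0/1
#'   matrix with column names).
#' @return Symmetric numeric matrix of class `similarity_matrix` with unit
#'   diagonal, labeled by population.
#' @export
genetic_similarity <- function(matrix) {
  m <- if (inherits(matrix, "presence_matrix")) matrix$values else {
    m0 <- as.matrix(matrix)
    storage.mode(m0) <- "integer"
    m0
  }
  if (ncol(m) < 2L) stop("need at least 2 populations", call. = FALSE)
  pops <- colnames(m)
  k <- ncol(m)
  gs <- matrix(1, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- sum(m[, i] == 1L & m[, j] == 1L)
      b <- sum(m[, i] == 1L & m[, j] == 0L)
      cc <- sum(m[, i] == 0L & m[, j] == 1L)
      denom <- 2 * a + b + cc
      if (denom == 0) {
        warning(sprintf("populations %s and %s share no scored sites; GS set to 0",
                        pops[i], pops[j]))
        val <- 0
      } else val <- 2 * a / denom
      gs[i, j] <- gs[j, i] <- val
    }
  }
  class(gs) <- c("similarity_matrix", class(gs))
  gs
}

# label used for deterministic tie-breaking: a cluster is represented by its
# lexicographically smallest leaf
cluster_label <- function(members) min(members)

#' UPGMA clustering of a similarity matrix
#'
#' Transforms similarities to distances `d = 1 - GS` and agglomerates by
#' classical (size-weighted) UPGMA: at each step the closest pair of
#' clusters is merged at height `d/2` and distances to the new cluster are
#' size-weighted arithmetic averages. Equal distances are resolved
#' deterministically by the lexicographically smallest pair of cluster
#' labels (each cluster labeled by its smallest leaf), so repeated runs and
#' label permutations give reproducible, isomorphic trees.
#'
#' @param similarity A `similarity_matrix` (or symmetric numeric matrix with
#'   unit diagonal and dimnames).
#' @return An `upgma_tree`: rooted binary ultrametric tree with leaf heights
#'   0, carrying the merge history used by [cut_tree()].
#' @export
upgma <- function(similarity) {
  sim <- unclass(similarity)
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  labels <- colnames(sim)
  if (is.null(labels)) labels <- paste0("L", seq_len(ncol(sim)))
  if (max(abs(sim - t(sim))) > 1e-12)
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (any(sim < 0) || any(sim > 1))
    stop("similarities must lie in [0, 1]", call. = FALSE)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 populations", call. = FALSE)
  D <- 1 - sim
  dimnames(D) <- list(labels, labels)

  clusters <- lapply(labels, function(l)
    list(members = l, height = 0, size = 1L, node = list(leaf = TRUE, label = l,
                                                         height = 0,
                                                         members = l)))
  history <- list()
  dist <- D
  active <- seq_len(n)
  while (length(active) > 1L) {
    # find minimum distance pair among active clusters, deterministic ties
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        dab <- dist[a, b]
        la <- cluster_label(clusters[[a]]$members)
        lb <- cluster_label(clusters[[b]]$members)
        key <- sort(c(la, lb))
        better <- dab < best_d - 1e-15 ||
          (abs(dab - best_d) <= 1e-15 && !is.null(best_key) &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (is.null(best) || better) {
          best <- c(a, b); best_d <- dab; best_key <- key
        }
      }
    }
    a <- best[1]; b <- best[2]
    h <- best_d / 2
    ca <- clusters[[a]]; cb <- clusters[[b]]
    kids <- list(ca$node, cb$node)
    ord <- order(c(cluster_label(ca$members), cluster_label(cb$members)))
    node <- list(leaf = FALSE, height = h,
                 members = sort(c(ca$members, cb$members)),
                 children = kids[ord])
    new_size <- ca$size + cb$size
    # size-weighted average distances (Lance-Williams for UPGMA)
    newd <- (ca$size * dist[a, ] + cb$size * dist[b, ]) / new_size
    dist[a, ] <- newd
    dist[, a] <- newd
    dist[a, a] <- 0
    clusters[[a]] <- list(members = node$members, height = h, size = new_size,
                          node = node)
    active <- setdiff(active, b)
    history[[length(history) + 1L]] <-
      lapply(clusters[active], function(cl) cl$members)
  }
  structure(list(root = clusters[[active]]$node, labels = sort(labels),
                 history = history),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4g\n",
              length(x$labels), x$root$height))
  cat(write_newick(x), "\n")
  invisible(x)
}

format_bl <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

#' Write a UPGMA tree as Newick text
#'
#' Branch lengths are parent height minus child height; children are ordered
#' by their smallest leaf label so output is deterministic.
#'
#' @param tree An `upgma_tree`.
#' @return Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  rec <- function(node, parent_height) {
    bl <- format_bl(parent_height - node$height)
    if (node$leaf) return(paste0(node$label, ":", bl))
    inner <- paste(vapply(node$children, rec, character(1),
                          parent_height = node$height), collapse = ",")
    paste0("(", inner, "):", bl)
  }
  root <- tree$root
  if (root$leaf) return(paste0(root$label, ":0;"))
  inner <- paste(vapply(root$children, rec, character(1),
                        parent_height = root$height), collapse = ",")
  paste0("(", inner, ");")
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' @param tree An `upgma_tree`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Ultrametric (cophenetic) distances implied by a UPGMA tree
#'
#' The tree distance between two leaves is twice the height of their lowest
#' common ancestor.
#'
#' @param tree An `upgma_tree`.
#' @return Symmetric matrix of leaf-to-leaf path distances.
#' @export
tree_cophenetic <- function(tree) {
  labels <- tree$labels
  n <- length(labels)
  out <- matrix(0, n, n, dimnames = list(labels, labels))
  rec <- function(node) {
    if (node$leaf) return(invisible(NULL))
    m1 <- node$children[[1]]$members
    m2 <- node$children[[2]]$members
    out[m1, m2] <<- 2 * node$height
    out[m2, m1] <<- 2 * node$height
    lapply(node$children, rec)
    invisible(NULL)
  }
  rec(tree$root)
  out
}

#' Cut a UPGMA tree into k groups
#'
#' Removes the k - 1 highest internal nodes (equivalently, undoes the last
#' k - 1 merges of the agglomeration), returning the resulting leaf groups.
#'
#' @param tree An `upgma_tree`.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return List of k character vectors (each sorted), ordered by first leaf.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  k <- as.integer(k)
  if (k < 1L || k > n)
    stop(sprintf("k must be between 1 and %d", n), call. = FALSE)
  groups <- if (k == n) as.list(tree$labels) else tree$history[[n - k]]
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, character(1), 1L))]
}
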