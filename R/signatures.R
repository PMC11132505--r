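# Whole-proteome LCD-content signatures and distance-based comparison.
#
# Each proteome is summarized by a 400-component vector of per-residue
# occupancy percentages (20 primary classes then 380 secondary classes,
# fixed lexicographic order), so organisms can be compared by percentile
# rank, raw difference, Manhattan distance and clustering.

#' Build the 400-component occupancy signature of one proteome
#'
#' @param table A \code{\link{count_class_table}}.
#' @return Object of class \code{occupancy_signature}: named numeric
#'   vector of length 400 (percentages in [0, 100]), with attributes
#'   proteome_id, domain_of_life, clade.
#' @export
build_signature <- function(table) {
  labels <- all_class_labels()
  total <- attr(table, "n_residues_total")
  if (is.null(total) || total <= 0) stop("proteome has no residues")
  idx <- match(labels, table$class_label)
  res <- table$n_lcd_residues[idx]
  res[is.na(res)] <- 0L
  v <- 100 * res / total
  names(v) <- labels
  structure(v,
            proteome_id = attr(table, "proteome_id"),
            domain_of_life = attr(table, "domain_of_life"),
            clade = attr(table, "clade"),
            class = "occupancy_signature")
}

#' @export
print.occupancy_signature <- function(x, ...) {
  nz <- sum(x > 0)
  cat(sprintf("<occupancy_signature %s> %d/400 classes occupied; top: %s\n",
              attr(x, "proteome_id"), nz,
              paste(names(sort(unclass(x), decreasing = TRUE))[
                seq_len(min(3, max(1, nz)))], collapse = ", ")))
  invisible(x)
}

#' Percentile ranks of one signature within a cohort
#'
#' Midrank convention with the organism itself included: per class,
#' 100 * (n_below + 0.5 * n_equal) / cohort size.
#'
#' @param sig An \code{occupancy_signature}.
#' @param cohort List of signatures (must include \code{sig}'s organism).
#' @param classes Class labels to report (default: all 400).
#' @return Named numeric vector of percentiles in (0, 100).
#' @export
percentile_ranks <- function(sig, cohort, classes = names(sig)) {
  if (!length(cohort)) stop("empty cohort")
  mat <- vapply(cohort, function(s) unclass(s)[classes],
                numeric(length(classes)))
  if (length(classes) == 1) mat <- matrix(mat, nrow = 1)
  v <- unclass(sig)[classes]
  n <- length(cohort)
  out <- vapply(seq_along(classes), function(i)
    100 * (sum(mat[i, ] < v[i]) + 0.5 * sum(mat[i, ] == v[i])) / n,
    numeric(1))
  names(out) <- classes
  out
}

#' Componentwise raw difference of two signatures
#'
#' @param a,b Signatures with identical key order.
#' @return Named numeric vector a - b (antisymmetric).
#' @export
signature_difference <- function(a, b) {
  if (!identical(names(a), names(b)))
    stop("signatures have mismatched class keys")
  out <- as.vector(unclass(a)) - as.vector(unclass(b))
  names(out) <- names(a)
  out
}

#' Manhattan distance between two signatures
#'
#' Sum of absolute componentwise differences over a key subset; the
#' default subset is the 380 secondary classes.
#'
#' @param a,b Signatures with identical key order.
#' @param keys Class labels to sum over (default: secondary classes).
#' @return Non-negative distance.
#' @export
manhattan_distance <- function(a, b, keys = secondary_class_labels()) {
  if (!identical(names(a), names(b)))
    stop("signatures have mismatched class keys")
  if (!all(keys %in% names(a))) stop("unknown key(s) in subset")
  sum(abs(unclass(a)[keys] - unclass(b)[keys]))
}

#' The 380 secondary class labels in canonical order
#' @return Character vector of length 380.
#' @export
secondary_class_labels <- function() {
  labs <- all_class_labels()
  labs[nchar(labs) == 2]
}

#' Pairwise Manhattan distance matrix over signatures
#'
#' @param signatures Named list of signatures (names = organism ids).
#' @param keys Key subset (default: secondary classes).
#' @param exclude_domains Domains of life to drop before computing
#'   (default "Viruses", whose tiny proteomes distort comparisons).
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
signature_distance_matrix <- function(signatures,
                                      keys = secondary_class_labels(),
                                      exclude_domains = "Viruses") {
  if (length(exclude_domains)) {
    keep <- !vapply(signatures, function(s)
      attr(s, "domain_of_life") %in% exclude_domains, logical(1))
    signatures <- signatures[keep]
  }
  n <- length(signatures)
  mat <- vapply(signatures, function(s) unclass(s)[keys],
                numeric(length(keys)))
  d <- as.matrix(stats::dist(t(mat), method = "manhattan"))
  dimnames(d) <- list(names(signatures), names(signatures))
  d
}

#' Mean pairwise distances within and between groups
#'
#' Within-group means exclude self-pairs; a group with a single organism
#' has an undefined (NA) within-group mean.
#'
#' @param dist Symmetric distance matrix with zero diagonal.
#' @param labels Named character vector organism -> group.
#' @return Symmetric matrix of group-level mean distances.
#' @export
group_mean_distances <- function(dist, labels) {
  orgs <- rownames(dist)
  if (is.null(orgs)) stop("distance matrix needs dimnames")
  grp <- labels[orgs]
  if (any(is.na(grp))) stop("missing group label for some organisms")
  groups <- sort(unique(grp))
  out <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i)) {
    ri <- which(grp == groups[i]); rj <- which(grp == groups[j])
    if (i == j) {
      if (length(ri) < 2) next
      pairs <- utils::combn(ri, 2)
      out[i, i] <- mean(dist[cbind(pairs[1, ], pairs[2, ])])
    } else {
      out[i, j] <- out[j, i] <- mean(dist[ri, rj, drop = FALSE])
    }
  }
  out
}

#' Complete-linkage agglomerative clustering of a distance matrix
#'
#' Thin wrapper over \code{stats::hclust(method = "complete")} returning
#' the merge tree as a data.frame plus the hclust object; heights are
#' non-decreasing (complete linkage admits no inversions).
#'
#' @param dist Symmetric non-negative matrix with zero diagonal.
#' @return Object of class \code{lcd_dendrogram}: list with
#'   \code{merges} (data.frame node_a, node_b, height; negative numbers
#'   are leaves, positive are earlier merges, hclust convention) and
#'   \code{hclust}.
#' @export
complete_linkage_cluster <- function(dist) {
  if (!isSymmetric(unname(as.matrix(dist)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(dist), method = "complete")
  structure(list(merges = data.frame(node_a = hc$merge[, 1],
                                     node_b = hc$merge[, 2],
                                     height = hc$height),
                 hclust = hc),
            class = "lcd_dendrogram")
}

#' @export
print.lcd_dendrogram <- function(x, ...) {
  cat(sprintf("<lcd_dendrogram> %d leaves, %d merges, max height %.4g\n",
              length(x$hclust$labels %||% x$hclust$order),
              nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' Export a merge tree as a Newick string
#'
#' @param tree An \code{lcd_dendrogram}.
#' @param path Optional file to write to.
#' @return Newick string (invisibly when \code{path} given).
#' @export
as_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
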