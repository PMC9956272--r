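# Distance-based phylogenetics for the mined protein sets: p-distances,
# neighbor joining, Felsenstein bootstrap and branch-group labelling.

#' Pairwise protein distances from an alignment
#'
#' Computes the p-distance of every pair over their mutually ungapped
#' columns, optionally Poisson-corrected (`-ln(1 - p)`).
#'
#' @param aln tibble with columns `id`, `sequence` (equal-length rows).
#' @param correction `"p"` (default) or `"poisson"`.
#' @param min_columns pairs with fewer comparable columns are flagged in
#'   the `"sparse_pairs"` attribute.
#' @return symmetric distance matrix with taxon dimnames; fails naming the
#'   pair if two rows share no comparable column.
#' @export
protein_distance <- function(aln, correction = c("p", "poisson"),
                             min_columns = 20L) {
  correction <- match.arg(correction)
  aln <- check_seqset(aln, "aln")
  if (nrow(aln) < 3) stop("need at least 3 sequences", call. = FALSE)
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  sparse <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0) {
        stop(sprintf("no comparable columns between %s and %s",
                     aln$id[i], aln$id[j]), call. = FALSE)
      }
      if (nc < min_columns) {
        sparse <- c(sparse, paste(aln$id[i], aln$id[j], sep = "~"))
      }
      p <- sum(mat[i, ok] != mat[j, ok]) / nc
      d[i, j] <- d[j, i] <- if (correction == "poisson") {
        if (p >= 1) stop("saturated pair, Poisson correction undefined",
                         call. = FALSE)
        -log(1 - p)
      } else {
        p
      }
    }
  }
  attr(d, "sparse_pairs") <- sparse
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion; ties are
#' broken by the smallest index pair.  On an additive matrix the returned
#' tree realizes the input distances exactly.  Negative branch-length
#' estimates are clamped to 0 and counted in the `"clamped"` attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) {
      clamped <<- clamped + 1L
      x <- 0
    }
    sprintf("%.15g", x)
  }
  # node representations as Newick fragments
  nodes <- labels
  D <- d
  active <- seq_len(n)
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest index pair among the minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    ai <- active[i]; aj <- active[j]
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    newick <- sprintf("(%s:%s,%s:%s)", nodes[ai], fmt(vi), nodes[aj], fmt(vj))
    # distances to the new node
    dnew <- 0.5 * (D[ai, active] + D[aj, active] - D[ai, aj])
    D <- rbind(cbind(D, 0), 0)
    newidx <- nrow(D)
    D[newidx, active] <- dnew
    D[active, newidx] <- dnew
    D[newidx, newidx] <- 0
    nodes <- c(nodes, newick)
    active <- c(setdiff(active, c(ai, aj)), newidx)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[a], fmt(va),
                    nodes[b], fmt(vb), nodes[c3], fmt(vc))
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  tree
}

# canonical bipartitions of an unrooted tree: for every internal edge, the
# tip-label side not containing the reference taxon, as a sorted key
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    tips <- tree$tip.label[p]
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) <= 1) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `B` times (seeded), rebuilds the tree per
#' replicate, and annotates every internal edge with the percentage of
#' replicates containing the same bipartition.
#'
#' @param aln tibble with columns `id`, `sequence` (equal-length rows).
#' @param B number of bootstrap replicates.
#' @param seed integer RNG seed; the same seed gives identical supports.
#' @param correction distance correction, see [protein_distance()].
#' @return a `phylo` tree whose `node.label` holds supports in `[0, 100]`
#'   (empty for the root).
#' @export
bootstrap_support <- function(aln, B = 1000L, seed = 1L,
                              correction = "p") {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  aln <- check_seqset(aln, "aln")
  tree <- neighbor_joining(protein_distance(aln, correction))
  width <- nchar(aln$sequence[1])
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  counts <- setNames(numeric(length(tree_splits(tree))), tree_splits(tree))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(width, width, replace = TRUE)
      rep_aln <- tibble::tibble(
        id = aln$id,
        sequence = apply(mat[, cols, drop = FALSE], 1, paste0, collapse = ""))
      rep_tree <- try(neighbor_joining(protein_distance(rep_aln, correction)),
                      silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      for (k in tree_splits(rep_tree)) {
        if (k %in% names(counts)) counts[k] <- counts[k] + 1
      }
    }
  })
  support <- round(100 * counts / B, 1)
  # attach supports to internal nodes
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  labs <- character(tree$Nnode)
  parts <- ape::prop.part(tree)
  for (pi in seq_along(parts)) {
    tips <- tree$tip.label[parts[[pi]]]
    if (length(tips) <= 1 || length(tips) >= n - 1) { labs[pi] <- ""; next }
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "|")
    labs[pi] <- if (key %in% names(support)) {
      as.character(support[[key]])
    } else ""
  }
  tree$node.label <- labs
  attr(tree, "B") <- B
  tree
}

#' Label supported ingroup branches
#'
#' Roots the tree on the outgroup, finds the maximal ingroup clades with
#' bootstrap support at or above `support_min`, and labels them `A`, `B`,
#' ... in decreasing size order (ties by smallest member label).
#'
#' @param tree a `phylo` with bootstrap `node.label` (see
#'   [bootstrap_support()]).
#' @param outgroup_ids tip labels of the outgroup (must be present).
#' @param support_min minimum support for a reported branch group.
#' @return tibble with columns `taxon`, `branch_group` (`"outgroup"` for
#'   outgroup tips, `NA` for unassigned ingroup tips).
#' @export
label_branches <- function(tree, outgroup_ids, support_min = 70) {
  if (!all(outgroup_ids %in% tree$tip.label)) {
    stop("outgroup taxa absent from the tree", call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  n <- length(rooted$tip.label)
  # tip sets per internal node
  clades <- vector("list", rooted$Nnode)
  get_tips <- function(node) {
    if (node <= n) return(rooted$tip.label[node])
    kids <- rooted$edge[rooted$edge[, 1] == node, 2]
    unlist(lapply(kids, get_tips))
  }
  cand <- list()
  for (node in (n + 1):(n + rooted$Nnode)) {
    tips <- get_tips(node)
    if (any(tips %in% outgroup_ids)) next
    lab <- rooted$node.label[node - n]
    sup <- suppressWarnings(as.numeric(lab))
    if (is.na(sup)) next
    if (sup >= support_min) {
      cand[[length(cand) + 1]] <- tips
    }
  }
  ingroup <- setdiff(rooted$tip.label, outgroup_ids)
  # a single fully-supported ingroup counts as one clade even when it is
  # the whole ingroup (its edge is the root edge)
  if (length(cand) == 0 && length(ingroup) > 0) {
    cand[[1]] <- ingroup
  }
  # maximal clades: drop any candidate contained in another
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i != j && keep[i] && all(cand[[i]] %in% cand[[j]]) &&
          length(cand[[i]]) < length(cand[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  cand <- cand[keep]
  ord <- order(-vapply(cand, length, integer(1)),
               vapply(cand, function(x) sort(x)[1], character(1)))
  cand <- cand[ord]
  out <- tibble::tibble(taxon = rooted$tip.label,
                        branch_group = NA_character_)
  out$branch_group[out$taxon %in% outgroup_ids] <- "outgroup"
  for (i in seq_along(cand)) {
    lab <- LETTERS[i]
    sel <- out$taxon %in% cand[[i]] & is.na(out$branch_group)
    out$branch_group[sel] <- lab
  }
  out
}
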