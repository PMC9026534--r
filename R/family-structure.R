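#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration: repeatedly join the pair minimising
#' `Q_ij = (r - 2) D_ij - R_i - R_j` (with `R_i` the row sums over the `r`
#' active nodes), assign branch lengths by the standard formulas, and replace
#' the pair by a node at distance `(D_ik + D_jk - D_ij) / 2` from every other
#' node. Ties are broken by the smallest `(i, j)` pair in the current node
#' order. Negative branch lengths are clamped to zero with the deficit moved
#' to the sibling branch of the same join, so path lengths through the join
#' are preserved; clamping is recorded in the returned metadata.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#'   (a base matrix or a `relationship_matrix` of kind `IBS_distance`),
#'   order >= 2.
#' @return An [ape::read.tree()] `phylo` object (unrooted for >= 3 leaves)
#'   with an extra attribute `clamped` giving the number of clamped branch
#'   lengths.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "relationship_matrix")) {
    labels <- d$sample_ids
    d <- d$values
  } else labels <- rownames(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n < 2L) stop("need at least 2 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")

  clamped <- 0L
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  clamp_pair <- function(li, lj) {
    # keep li + lj, never let either go negative
    if (li < 0) { lj <- lj + li; li <- 0; clamped <<- clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; clamped <<- clamped + 1L }
    if (li < 0) li <- 0
    if (lj < 0) lj <- 0
    c(li, lj)
  }

  # newick-safe labels (callers use plain ids; anything else is sanitized)
  node <- gsub("[^A-Za-z0-9_.|-]", "_", labels)
  if (anyDuplicated(node)) stop("labels collide after newick sanitization")
  if (n == 2L) {
    l <- d[1, 2] / 2
    nwk <- paste0("(", node[1], ":", fmt(l), ",", node[2], ":", fmt(l), ");")
    tr <- ape::read.tree(text = nwk)
    attr(tr, "clamped") <- 0L
    return(tr)
  }

  while (length(node) > 3L) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    best <- c(NA_integer_, NA_integer_)
    bq <- Inf
    for (i in seq_len(r - 1L)) for (j in seq.int(i + 1L, r)) {
      if (q[i, j] < bq) { bq <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj)
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    newd <- newd[-c(i, j)]
    merged <- paste0("(", node[i], ":", fmt(ll[1]), ",",
                     node[j], ":", fmt(ll[2]), ")")
    node <- c(node[-c(i, j)], merged)
    d <- rbind(cbind(d[-c(i, j), -c(i, j), drop = FALSE], newd),
               c(newd, 0))
  }

  # final three-node star: exact three-point branch lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (v in c("la", "lb", "lc")) if (get(v) < 0) {
    assign(v, 0); clamped <- clamped + 1L
  }
  nwk <- paste0("(", node[1], ":", fmt(la), ",", node[2], ":", fmt(lb), ",",
                node[3], ":", fmt(lc), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

#' Cut a tree into lineages
#'
#' Removes edges longest-first — internal edges before terminal ones, ties
#' resolved by the order the edges appear in the tree's edge table — until
#' the leaves fall into `k` connected components, which become the lineages,
#' numbered by the smallest leaf index they contain. For a resolved tree with
#' clear cluster structure this coincides with cutting the `k - 1` longest
#' internal edges; terminal edges only come into play near `k = ` leaf
#' count, where lineages degenerate to singletons.
#'
#' @param tree a `phylo` tree.
#' @param k number of lineages, between 1 and the leaf count.
#' @return Named integer vector mapping each leaf label to its lineage.
#' @export
cut_lineages <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  edges <- tree$edge
  len <- tree$edge.length
  internal <- which(edges[, 2] > n)
  terminal <- which(edges[, 2] <= n)
  ord <- c(internal[order(-len[internal])], terminal[order(-len[terminal])])

  leaf_partition <- function(drop) {
    parent <- seq_len(max(edges))
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (e in setdiff(seq_len(nrow(edges)), drop)) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
    comp <- vapply(seq_len(n), find, integer(1))
    match(comp, unique(comp))  # numbered by smallest leaf index
  }
  # cutting one edge raises the leaf-group count by at most one, so removing
  # edges in priority order until k groups exist lands exactly on k
  n_drop <- 0L
  lineage <- leaf_partition(integer(0))
  while (length(unique(lineage)) < k) {
    n_drop <- n_drop + 1L
    lineage <- leaf_partition(ord[seq_len(n_drop)])
  }
  names(lineage) <- tree$tip.label
  lineage
}

#' Assign individuals to families from boar lineages
#'
#' Boars (sires) inherit the family of their lineage. Every other individual
#' joins the family of the lineage with the strongest genomic relationship:
#' by default the largest mean `G` to the lineage's boars (`method = "mean"`),
#' optionally the largest single relationship (`method = "max"`). An
#' individual whose maximum relationship over all boars falls below
#' `threshold` is placed in a separate "unrelated" family numbered
#' `max(lineage) + 1`. Ties go to the lowest lineage index.
#'
#' @param g a `relationship_matrix` of kind `G` (or a plain symmetric matrix
#'   with sample-id dimnames) covering all boars and all individuals.
#' @param lineage_of_boar named integer vector: boar id -> lineage index.
#' @param threshold relationship below which an individual is "unrelated"
#'   to every boar (default 0.1).
#' @param method `"mean"` or `"max"` lineage-affinity rule.
#' @return data.frame with `sample_id`, `lineage` (NA for non-boars),
#'   `family`, `max_boar_relationship`.
#' @export
assign_families <- function(g, lineage_of_boar, threshold = 0.1,
                            method = c("mean", "max")) {
  method <- match.arg(method)
  if (inherits(g, "relationship_matrix")) g <- g$values
  ids <- rownames(g)
  boars <- names(lineage_of_boar)
  if (!length(boars)) stop("lineage_of_boar is empty")
  if (!all(boars %in% ids))
    stop("boars missing from G: ",
         paste(setdiff(boars, ids), collapse = ", "))
  lineages <- sort(unique(lineage_of_boar))
  unrelated_family <- max(lineages) + 1L

  out <- data.frame(sample_id = ids, lineage = NA_integer_,
                    family = NA_integer_,
                    max_boar_relationship = NA_real_,
                    stringsAsFactors = FALSE)
  out$lineage[match(boars, ids)] <- lineage_of_boar
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% boars) {
      out$family[i] <- lineage_of_boar[[id]]
      other <- setdiff(boars, id)
      out$max_boar_relationship[i] <-
        if (length(other)) max(g[id, other]) else NA_real_
      next
    }
    rel <- g[id, boars]
    out$max_boar_relationship[i] <- max(rel)
    if (max(rel) < threshold) {
      out$family[i] <- unrelated_family
      next
    }
    affinity <- vapply(lineages, function(l) {
      v <- rel[lineage_of_boar == l]
      if (method == "mean") mean(v) else max(v)
    }, numeric(1))
    out$family[i] <- lineages[which.max(affinity)]  # which.max: lowest index wins ties
  }
  out
}

#' Largest-gap suggestion for the number of lineages
#'
#' Finds the largest gap in the decreasing sequence of internal branch
#' lengths, treats every internal edge above the gap as a between-lineage
#' separator, and returns the number of leaf groups produced by cutting all
#' of them. Advisory only — never applied silently.
#'
#' @param tree a `phylo` tree.
#' @return Suggested `k` (integer >= 1).
#' @export
suggest_k_lineages <- function(tree) {
  n <- length(tree$tip.label)
  edges <- tree$edge
  internal <- which(edges[, 2] > n)
  if (length(internal) < 2L) return(1L)
  len <- sort(tree$edge.length[internal], decreasing = TRUE)
  thr <- len[which.max(-diff(len))]  # shortest edge above the largest gap
  drop <- internal[tree$edge.length[internal] >= thr]
  parent <- seq_len(max(edges))
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (e in setdiff(seq_len(nrow(edges)), drop)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) parent[rb] <- ra
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
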