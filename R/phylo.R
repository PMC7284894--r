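#' Remove alignment columns with gaps or missing data
#'
#' Complete deletion: retains exactly the columns where no record carries
#' a gap (`-`) or an `N`, the standard preprocessing before distance-based
#' phylogenetics so that every pairwise distance is computed over the same
#' positions.
#'
#' @param aln A [multi_alignment()] with at least two records.
#' @return A [multi_alignment()] over the surviving columns.
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "multi_alignment"))
  if (nrow(aln$records) < 2L) stop("complete_deletion() needs >= 2 records")
  m <- .aln_matrix(aln)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) stop("no columns survive complete deletion")
  .subset_aln_cols(aln, keep)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` with `p` the observed mismatch
#' fraction — the one-parameter correction of observed differences for
#' multiple substitutions, in substitutions per site. Undefined at
#' `p >= 0.75`.
#'
#' @param a,b Equal-length gap-free sequences (strings or `seq_records`
#'   rows), typically after [complete_deletion()].
#' @return Distance in substitutions per site (`>= p`).
#' @export
jc_distance <- function(a, b) {
  if (is.data.frame(a)) a <- a$seq[1L]
  if (is.data.frame(b)) b <- b$seq[1L]
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  if (any(ca == "-") || any(cb == "-"))
    stop("gap characters present; apply complete_deletion() first")
  p <- mean(ca != cb)
  if (p >= 0.75)
    stop("mismatch fraction ", signif(p, 4),
         " >= 0.75: Jukes-Cantor distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param aln A gap-free [multi_alignment()] (post [complete_deletion()]).
#' @return Symmetric labelled distance matrix (substitutions per site).
#' @export
jc_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "multi_alignment"))
  n <- nrow(aln$records)
  d <- matrix(0, n, n, dimnames = list(aln$records$id, aln$records$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- jc_distance(aln$records$seq[i], aln$records$seq[j])
  d
}

# recursively convert a nested node structure into an ape "phylo" object
.nodes_to_phylo <- function(node, tip_labels) {
  n_tip <- length(tip_labels)
  edge <- matrix(0L, 0L, 2L); edge_len <- numeric(0)
  next_internal <- n_tip + 1L
  walk <- function(nd) {
    if (is.character(nd$label)) return(match(nd$label, tip_labels))
    me <- next_internal; next_internal <<- next_internal + 1L
    for (ch in nd$children) {
      child_id <- walk(ch)
      edge <<- rbind(edge, c(me, child_id))
      edge_len <<- c(edge_len, ch$length)
    }
    me
  }
  walk(node)
  tr <- list(edge = edge, edge.length = edge_len, tip.label = tip_labels,
             Nnode = next_internal - n_tip - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Neighbour-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Additive matrices are recovered exactly (topology and branch lengths).
#' Ties in Q are broken deterministically by the smallest label pair (in
#' input label order). Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sibling edge, so path lengths
#' through the joined pair are preserved.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   labels (or a `dist` object).
#' @return An unrooted `phylo` tree (from the ape package) with branch
#'   lengths; for two taxa, a two-edge tree splitting the distance
#'   equally.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  nodes <- lapply(labels, function(l) list(label = l))
  if (n == 2L) {
    root <- list(children = list(c(nodes[[1L]], length = d[1L, 2L] / 2),
                                 c(nodes[[2L]], length = d[1L, 2L] / 2)))
    return(.nodes_to_phylo(root, labels))
  }
  active <- seq_len(n)          # indices into `nodes`; order = join priority
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    q <- (m - 2) * D - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    hit <- which(q - qmin <= qmin * 0 + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- list(children = list(c(nodes[[active[i]]], length = li),
                                     c(nodes[[active[j]]], length = lj)))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes[[length(nodes) + 1L]] <- new_node
    active <- c(active[keep], length(nodes))
    rownames(D) <- colnames(D) <- as.character(active)
  }
  if (length(active) == 3L) {
    la <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
    lb <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
    lc <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
    root <- list(children = list(c(nodes[[active[1L]]], length = max(la, 0)),
                                 c(nodes[[active[2L]]], length = max(lb, 0)),
                                 c(nodes[[active[3L]]], length = max(lc, 0))))
  }
  .nodes_to_phylo(root, labels)
}

#' Neighbour-joining with bootstrap supports
#'
#' Builds the point-estimate Jukes-Cantor/neighbour-joining tree from the
#' full alignment, then resamples alignment columns with replacement
#' `n_replicates` times, rebuilds a tree per replicate, and annotates each
#' internal edge of the point-estimate tree with the percentage of
#' replicates containing the same bipartition (majority mapping onto the
#' point estimate, not a consensus tree).
#'
#' @param aln A gap-free [multi_alignment()] (post [complete_deletion()]).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; supports are deterministic given the seed.
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   bootstrap percentages (root label empty).
#' @export
bootstrap_support <- function(aln, n_replicates = 500L, seed = 1L) {
  stopifnot(inherits(aln, "multi_alignment"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  point <- neighbor_joining(jc_distance_matrix(aln))
  m <- .aln_matrix(aln)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      recs <- aln$records
      recs$seq <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      neighbor_joining(jc_distance_matrix(multi_alignment(recs)))
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  pct <- round(100 * counts / n_replicates, 1)
  point$node.label <- as.character(pct)
  point$node.label[1L] <- ""  # basal node: not a bipartition
  point
}

#' Total branch length of a tree
#'
#' @param tree A `phylo` object.
#' @return Sum of all edge lengths (substitutions per site).
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length)
}

.newick_quote <- function(label) {
  if (grepl("[][():;,'\" \t]", label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

#' Serialize a tree to Newick
#'
#' Standard Newick with branch lengths; internal-node labels (e.g.
#' bootstrap supports) are written after the closing parenthesis. Labels
#' containing Newick metacharacters or whitespace are single-quoted.
#' `ape::read.tree()` parses the output back to an isomorphic tree.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  root <- n_tip + 1L
  fmt_len <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(node, blen) {
    if (node <= n_tip) {
      out <- .newick_quote(tree$tip.label[node])
    } else {
      kids <- children[[as.character(node)]]
      inner <- paste(vapply(kids, function(e)
        rec(tree$edge[e, 2L], tree$edge.length[e]), ""), collapse = ",")
      lab <- if (!is.null(tree$node.label)) {
        l <- tree$node.label[node - n_tip]
        if (is.na(l)) "" else .newick_quote(as.character(l))
      } else ""
      out <- paste0("(", inner, ")", lab)
    }
    if (is.na(blen)) out else paste0(out, ":", fmt_len(blen))
  }
  paste0(rec(root, NA), ";")
}
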