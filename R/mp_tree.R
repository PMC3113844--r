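## union-find helpers -------------------------------------------------------
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) { p[uf_find(p, i)] <- uf_find(p, j); p }

kruskal_weight <- function(nv, ei, ej, ew) {
  o <- order(ew)
  p <- uf_new(nv); w <- 0; used <- 0L
  for (k in o) {
    a <- uf_find(p, ei[k]); b <- uf_find(p, ej[k])
    if (a != b) { p <- uf_union(p, a, b); w <- w + ew[k]; used <- used + 1L }
    if (used == nv - 1L) break
  }
  if (used < nv - 1L) return(NA_real_)
  w
}

## enumerate all spanning trees with total weight == target
## over vertices 1..nv and edges (ei, ej, ew); returns list of edge-index sets
enum_spanning_trees <- function(nv, ei, ej, ew, target, max_trees = 10000L) {
  m <- length(ei)
  res <- list()
  if (nv == 1L) return(list(integer(0)))
  o <- order(ew)
  ei <- ei[o]; ej <- ej[o]; ew <- ew[o]
  recurse <- function(k, chosen, weight, parent) {
    if (length(res) >= max_trees) return()
    need <- (nv - 1L) - length(chosen)
    if (need == 0L) {
      if (weight == target) res[[length(res) + 1L]] <<- o[chosen]
      return()
    }
    if (k > m || m - k + 1L < need) return()
    ## optimistic bound: the `need` lightest remaining edges
    rem <- ew[k:m]
    if (weight + sum(sort(rem)[seq_len(need)]) > target) return()
    a <- uf_find(parent, ei[k]); b <- uf_find(parent, ej[k])
    if (a != b) recurse(k + 1L, c(chosen, k), weight + ew[k],
                        uf_union(parent, a, b))
    recurse(k + 1L, chosen, weight, parent)
  }
  recurse(1L, integer(0), 0, uf_new(nv))
  res
}

make_tree <- function(net, node_idx, edge_rows, root = NULL) {
  structure(list(nodes = net$nodes[node_idx],
                 edges = net$edges[edge_rows, , drop = FALSE],
                 labels = net$labels[edge_rows],
                 total_weighted_length = sum(net$edges$weight[edge_rows]),
                 root = root),
            class = "mp_tree")
}

#' Maximum-parsimony post-processing of a network
#'
#' Extracts every minimum-weighted-length tree connecting all *sampled*
#' nodes of the network, allowing median vectors as optional Steiner
#' points, by exact search (iteration over median-vector subsets with a
#' branch-and-bound spanning-tree enumeration, pruned by the best length
#' found). Median vectors on no minimal tree are pruned; the pruned network
#' is the union of all minimal trees.
#'
#' Above `size_cap` distinct nodes the exact search is refused and a
#' documented heuristic runs instead (with a warning): edges are deleted
#' heaviest-first whenever removal keeps the sampled nodes connected,
#' leaving a single tree; `n_trees` is then `NA`.
#'
#' @param net a `haplo_network` (connected).
#' @param size_cap exact-search limit on distinct nodes.
#' @param max_trees cap on the number of enumerated trees.
#' @return list with `trees` (list of `mp_tree`), `pruned` (the network
#'   restricted to the union of all minimal trees) and `n_trees`.
#' @export
mp_extract <- function(net, size_cap = 25L, max_trees = 10000L) {
  nn <- length(net$nodes)
  ids <- vapply(net$nodes, `[[`, character(1), "id")
  sampled <- vapply(net$nodes, `[[`, logical(1), "sampled")
  if (nn == 1L) {
    tr <- make_tree(net, 1L, integer(0))
    return(list(trees = list(tr), pruned = net, n_trees = 1L))
  }
  ei <- match(net$edges$from, ids); ej <- match(net$edges$to, ids)
  ew <- net$edges$weight
  g <- igraph::graph_from_data_frame(net$edges[, 1:2, drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (igraph::components(g)$no > 1L) stop("network must be connected")
  med_idx <- which(!sampled)

  if (nn > size_cap || length(med_idx) > 12L) {
    warning("network above exact-search size cap (", nn,
            " nodes); falling back to the iterated edge-deletion heuristic")
    return(mp_heuristic(net, ids, sampled))
  }

  best <- Inf; subs <- list()
  n_med <- length(med_idx)
  for (mask in 0:(2^n_med - 1)) {
    use <- if (n_med) med_idx[bitwAnd(mask, 2^(seq_len(n_med) - 1)) > 0] else integer(0)
    vset <- sort(c(which(sampled), use))
    emap <- which(ei %in% vset & ej %in% vset)
    nv <- length(vset)
    if (length(emap) < nv - 1L) next
    ridx <- match(ei[emap], vset); rjdx <- match(ej[emap], vset)
    w <- kruskal_weight(nv, ridx, rjdx, ew[emap])
    if (is.na(w)) next
    subs[[length(subs) + 1L]] <- list(vset = vset, emap = emap, mst = w)
    if (w < best) best <- w
  }
  if (!is.finite(best)) stop("sampled nodes are not connected in the network")

  trees <- list(); seen <- character(0)
  for (s in subs) {
    if (s$mst > best) next
    ridx <- match(ei[s$emap], s$vset); rjdx <- match(ej[s$emap], s$vset)
    ts <- enum_spanning_trees(length(s$vset), ridx, rjdx, ew[s$emap],
                              best, max_trees)
    for (t in ts) {
      rows <- s$emap[t]
      ## Steiner points must be genuine junctions on a minimal tree
      deg <- table(c(ei[rows], ej[rows]))
      meds <- intersect(s$vset, med_idx)
      if (length(meds) && any(deg[as.character(meds)] < 2L |
                              is.na(deg[as.character(meds)]))) next
      sig <- paste(sort(rows), collapse = ",")
      if (sig %in% seen) next
      seen <- c(seen, sig)
      trees[[length(trees) + 1L]] <- make_tree(net, s$vset, sort(rows))
    }
  }
  all_rows <- sort(unique(unlist(lapply(trees, function(t)
    match(paste(t$edges$from, t$edges$to), paste(net$edges$from, net$edges$to))))))
  keep_nodes <- sort(unique(c(which(sampled),
                              which(ids %in% unlist(lapply(trees, function(t)
                                vapply(t$nodes, `[[`, character(1), "id")))))))
  pruned <- structure(list(nodes = net$nodes[keep_nodes],
                           edges = net$edges[all_rows, , drop = FALSE],
                           labels = net$labels[all_rows], params = net$params),
                      class = "haplo_network")
  list(trees = trees, pruned = pruned, n_trees = length(trees))
}

mp_heuristic <- function(net, ids, sampled) {
  edges <- net$edges; labels <- net$labels
  keep <- rep(TRUE, nrow(edges))
  for (r in order(-edges$weight)) {
    trial <- keep; trial[r] <- FALSE
    g <- igraph::graph_from_data_frame(edges[trial, 1:2, drop = FALSE],
                                       directed = FALSE,
                                       vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    if (length(unique(comp[ids[sampled]])) == 1L) keep <- trial
  }
  rows <- which(keep)
  used_ids <- unique(c(edges$from[rows], edges$to[rows], ids[sampled]))
  ## drop pendant median vectors
  repeat {
    deg <- table(c(edges$from[rows], edges$to[rows]))
    leaf_med <- names(deg)[deg == 1L & !(names(deg) %in% ids[sampled])]
    if (!length(leaf_med)) break
    rows <- rows[!(edges$from[rows] %in% leaf_med | edges$to[rows] %in% leaf_med)]
  }
  node_idx <- which(ids %in% unique(c(edges$from[rows], edges$to[rows], ids[sampled])))
  tr <- make_tree(net, node_idx, rows)
  pruned <- structure(list(nodes = net$nodes[node_idx],
                           edges = edges[rows, , drop = FALSE],
                           labels = labels[rows], params = net$params),
                      class = "haplo_network")
  list(trees = list(tr), pruned = pruned, n_trees = NA_integer_)
}

#' Count back mutations on a tree
#'
#' A variant key appearing on `k > 1` edges of a tree requires `k - 1`
#' state changes beyond a single origin; the back-mutation count is the sum
#' of these excesses over all keys.
#'
#' @param tree an `mp_tree`.
#' @return integer count.
#' @export
count_back_mutations <- function(tree) {
  labs <- unlist(tree$labels)
  if (!length(labs)) return(0L)
  tab <- table(labs)
  as.integer(sum(pmax(tab - 1L, 0L)))
}

#' Build a star tree directly from a panel and a root motif
#'
#' Connects every distinct haplotype to an explicit root haplotype (the
#' motif), the genealogy assumed by rho-based dating of a recent expansion.
#' Sampled haplotypes identical to the root are merged into the root node
#' and still count as tips of path length zero.
#'
#' @param panel a [hap_panel()].
#' @param root_motif motif token vector (see [parse_motif()]) or a variant
#'   data.frame.
#' @param params an [mj_params()] (for weights/exclusions/deletion merging
#'   used on edge labels).
#' @return an `mp_tree` rooted at `"root"`.
#' @export
star_tree <- function(panel, root_motif, params = mj_params()) {
  v <- if (is.data.frame(root_motif)) root_motif else parse_motif(root_motif)
  nodes <- collapse_panel(panel)
  cov_all <- normalise_intervals(do.call(rbind, lapply(nodes, function(nd)
    nd$hap$covered)))
  root_hap <- haplotype("root", v, covered = interval_regions(cov_all))
  root_sig <- hap_signature(root_hap)
  is_root <- vapply(nodes, function(nd) hap_signature(nd$hap) == root_sig, logical(1))
  root_node <- list(id = "root", hap = root_hap,
                    sampled = any(is_root),
                    multiplicity = sum(vapply(nodes[is_root], `[[`, numeric(1),
                                              "multiplicity")),
                    members = unlist(lapply(nodes[is_root], `[[`, "members")),
                    annotations = list())
  tips <- nodes[!is_root]
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), n_mut = integer(0))
  labels <- list(); kept_tips <- list()
  for (nd in tips) {
    pd <- pairwise_distance(root_hap, nd$hap, params$weights, params$excluded,
                            params$merge_deletions)
    if (!length(pd$keys)) { # indistinguishable from root: fold into root node
      root_node$sampled <- TRUE
      root_node$multiplicity <- root_node$multiplicity + nd$multiplicity
      root_node$members <- c(root_node$members, nd$members)
      next
    }
    kept_tips[[length(kept_tips) + 1L]] <- nd
    edges <- rbind(edges, data.frame(from = "root", to = nd$id,
                                     weight = pd$distance,
                                     n_mut = length(pd$keys)))
    labels[[length(labels) + 1L]] <- vapply(pd$keys, paste, character(1),
                                            collapse = "+")
  }
  structure(list(nodes = c(list(root_node), kept_tips), edges = edges,
                 labels = labels,
                 total_weighted_length = sum(edges$weight), root = "root"),
            class = "mp_tree")
}

#' @export
print.mp_tree <- function(x, ...) {
  cat(sprintf("<mp_tree> %d node(s), %d edge(s), weighted length %s%s\n",
              length(x$nodes), nrow(x$edges), format(x$total_weighted_length),
              if (!is.null(x$root)) paste0(", rooted at ", x$root) else ""))
  invisible(x)
}

#' @export
plot.mp_tree <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, layout = igraph::layout_as_tree(
    g, root = if (!is.null(x$root)) x$root else 1), ...)
  invisible(x)
}
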