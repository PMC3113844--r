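#' Network construction parameters
#'
#' @param epsilon non-negative integer weighted tolerance: links within
#'   `epsilon` of the minimal connecting distance at each merge level are
#'   retained. 0 reproduces the strict minimum-spanning network (the usual
#'   software default).
#' @param weights a [weight_scheme()] or `NULL` (uniform).
#' @param excluded an [exclusion_set()] (or combination) or `NULL`.
#' @param merge_deletions see [pairwise_distance()].
#' @return object of class `mj_params`.
#' @export
mj_params <- function(epsilon = 0L, weights = NULL, excluded = NULL,
                      merge_deletions = TRUE) {
  epsilon <- as.integer(epsilon)
  if (is.na(epsilon) || epsilon < 0L) stop("epsilon must be a non-negative integer")
  structure(list(epsilon = epsilon, weights = weights, excluded = excluded,
                 merge_deletions = merge_deletions), class = "mj_params")
}

## state signature used to collapse identical haplotypes / dedupe medians;
## keys in `excluded` are ignored (sites dropped from the analysis cannot
## distinguish haplotypes)
hap_signature <- function(h, excluded = NULL) {
  s <- state_map(h)
  if (!is.null(excluded) && length(s)) s <- s[!key_excluded(names(s), excluded)]
  paste(sort(paste0(names(s), "=", s)), collapse = ";")
}

## collapse identical sampled haplotypes into nodes (same states AND coverage)
collapse_panel <- function(panel, excluded = NULL) {
  sig <- vapply(panel$haplotypes, function(h)
    paste(hap_signature(h, excluded), paste(h$covered, collapse = ","), sep = "|"),
    character(1))
  nodes <- list()
  for (s in unique(sig)) {
    members <- names(panel$haplotypes)[sig == s]
    members <- sort(members)
    nodes[[length(nodes) + 1L]] <- list(
      id = members[1], hap = panel$haplotypes[[members[1]]], sampled = TRUE,
      multiplicity = length(members), members = members, annotations = list())
  }
  nodes[order(vapply(nodes, `[[`, character(1), "id"))]
}

## minimax (bottleneck) distances from a distance matrix, via an MST
bottleneck_matrix <- function(D) {
  n <- nrow(D)
  if (n == 1) return(matrix(0, 1, 1))
  dimnames(D) <- NULL
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  t <- igraph::mst(g, algorithm = "prim")
  B <- matrix(0, n, n)
  adj <- igraph::as_adj_list(t)
  el <- igraph::as_edgelist(t, names = FALSE)
  wl <- igraph::E(t)$weight
  wmat <- matrix(0, n, n)
  for (k in seq_len(nrow(el))) wmat[el[k, 1], el[k, 2]] <- wmat[el[k, 2], el[k, 1]] <- wl[k]
  for (s in 1:n) { # DFS carrying the running max edge weight
    stack <- list(c(s, 0)); seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- cur[1]; mx <- cur[2]
      for (u in as.integer(adj[[v]])) if (!seen[u]) {
        seen[u] <- TRUE
        m2 <- max(mx, wmat[v, u])
        B[s, u] <- m2
        stack[[length(stack) + 1L]] <- c(u, m2)
      }
    }
  }
  B
}

## feasible-link mask and total length from a distance matrix alone
msn_links_from_matrix <- function(D, epsilon) {
  n <- nrow(D)
  if (n < 2) return(list(mask = matrix(FALSE, n, n), length = 0))
  B <- bottleneck_matrix(D)
  mask <- D <= B + epsilon & upper.tri(D)
  list(mask = mask, length = sum(D[mask]))
}

## internal: MSN over an explicit node list
msn_over_nodes <- function(nodes, params, D = NULL) {
  haps <- lapply(nodes, `[[`, "hap")
  n <- length(nodes)
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (is.null(D))
    D <- distance_matrix(haps, params$weights, params$excluded, params$merge_deletions)
  edges <- data.frame(from = character(0), to = character(0), weight = numeric(0),
                      n_mut = integer(0))
  labels <- list()
  if (n > 1) {
    B <- bottleneck_matrix(D)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (D[i, j] <= B[i, j] + params$epsilon) {
        pd <- pairwise_distance(haps[[i]], haps[[j]], params$weights,
                                params$excluded, params$merge_deletions)
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        edges <- rbind(edges, data.frame(from = a, to = b, weight = pd$distance,
                                         n_mut = length(pd$keys)))
        labels[[length(labels) + 1L]] <- vapply(pd$keys, paste, character(1),
                                                collapse = "+")
      }
    }
  }
  o <- order(edges$from, edges$to)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, labels = labels[o],
                 params = params),
            class = "haplo_network")
}

#' Minimum-spanning network of a haplotype panel
#'
#' Stage one of median-joining network construction: identical haplotypes
#' are collapsed into nodes with multiplicities, and the network retains
#' every link `(u, v)` whose weighted distance is within `epsilon` of the
#' minimal distance at which the components of `u` and `v` merge (i.e.
#' `d(u,v) <= bottleneck(u,v) + epsilon`). At `epsilon = 0` this is the
#' union of all minimum spanning trees.
#'
#' @param panel a [hap_panel()].
#' @param params an [mj_params()].
#' @return object of class `haplo_network`.
#' @export
build_msn <- function(panel, params = mj_params()) {
  msn_over_nodes(collapse_panel(panel, params$excluded), params)
}

## site-wise majority median of three haplotypes; NULL if undefined
triplet_median <- function(h1, h2, h3, mv_id) {
  hs <- list(h1, h2, h3)
  sms <- lapply(hs, state_map)
  keys <- unique(unlist(lapply(sms, names)))
  cov <- intersect_intervals(intersect_intervals(h1$covered, h2$covered), h3$covered)
  if (!nrow(cov)) return(NULL)
  med <- character(0)
  for (k in keys) {
    p <- key_pos(k)
    if (!pos_in_intervals(p, cov)) next
    votes <- vapply(seq_along(hs), function(i) {
      if (!pos_in_intervals(p, hs[[i]]$covered)) NA_character_
      else if (k %in% names(sms[[i]])) sms[[i]][[k]] else "ref"
    }, character(1))
    votes <- votes[!is.na(votes)]
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NULL) # no majority: skip triplet
    st <- names(tab)[1]
    if (st != "ref") med[k] <- st
  }
  v <- variants()
  if (length(med)) {
    all_v <- do.call(rbind, lapply(hs, `[[`, "variants"))
    all_v <- all_v[!duplicated(variant_keys(all_v)), , drop = FALSE]
    rownames(all_v) <- variant_keys(all_v)
    pick <- all_v[names(med), , drop = FALSE]
    v <- variants(pick$pos, pick$kind, pick$ref,
                  ifelse(pick$kind == "del", "", med), pick$ins_index)
  }
  haplotype(mv_id, v, covered = interval_regions(cov))
}

net_length <- function(net) sum(net$edges$weight)

#' Median-joining network
#'
#' Builds the minimum-spanning network and then iteratively proposes median
#' vectors - site-wise majority consensus haplotypes of node triplets that
#' are connected (at least two of the three links) in the current network.
#' At each round the candidate median whose addition most reduces the total
#' network length is added (ties broken by state signature); the procedure
#' stops when no candidate reduces the length. The returned network is the
#' minimum-spanning network over the final sampled + median node set,
#' augmented with any link of the original (sampled-only) minimum-spanning
#' network that is not realized in it by a path of equal total weight -
#' so the result always contains the sampled MSN up to equal-length
#' rerouting through median vectors.
#'
#' Sites where all three triplet states differ yield no consensus; such
#' triplets are skipped (control-region panels are overwhelmingly biallelic
#' per site, so quasi-median generation is not implemented).
#'
#' @inheritParams build_msn
#' @param max_iter safety cap on median-addition rounds.
#' @return object of class `haplo_network`; median vectors have
#'   `sampled = FALSE` and multiplicity 0.
#' @export
build_mj <- function(panel, params = mj_params(), max_iter = 200L) {
  nodes <- collapse_panel(panel, params$excluded)
  mv_counter <- 0L
  haps <- lapply(nodes, `[[`, "hap")
  D <- distance_matrix(haps, params$weights, params$excluded,
                       params$merge_deletions)
  msn0 <- msn_over_nodes(nodes, params, D = D)
  if (length(nodes) < 2L) return(msn0)
  net_mask <- msn_links_from_matrix(D, params$epsilon)
  repeat {
    if (mv_counter >= max_iter)
      stop("median-joining did not converge within max_iter additions")
    L0 <- net_mask$length
    sigs <- vapply(haps, hap_signature, character(1),
                   excluded = params$excluded)
    adj <- net_mask$mask | t(net_mask$mask)
    n <- length(haps)
    cands <- list(); seen <- character(0)
    if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (adj[i, j] + adj[i, k] + adj[j, k] < 2L) next
      m <- triplet_median(haps[[i]], haps[[j]], haps[[k]], "mv")
      if (is.null(m)) next
      sg <- hap_signature(m, params$excluded)
      if (sg %in% sigs || sg %in% seen) next
      seen <- c(seen, sg)
      cands[[length(cands) + 1L]] <- m
    }
    if (!length(cands)) break
    best <- NULL; best_len <- L0; best_sig <- ""; best_d <- NULL
    for (m in cands) {
      dm <- vapply(haps, function(h)
        pairwise_distance(m, h, params$weights, params$excluded,
                          params$merge_deletions)$distance, numeric(1))
      Dm <- rbind(cbind(D, dm), c(dm, 0))
      Lm <- msn_links_from_matrix(Dm, params$epsilon)$length
      sg <- hap_signature(m, params$excluded)
      if (Lm < best_len || (Lm == best_len && !is.null(best) && sg < best_sig)) {
        best <- m; best_len <- Lm; best_sig <- sg; best_d <- dm
      }
    }
    if (is.null(best) || best_len >= L0) break
    mv_counter <- mv_counter + 1L
    best$id <- sprintf("mv%d", mv_counter)
    nodes <- c(nodes, list(list(id = best$id, hap = best, sampled = FALSE,
                                multiplicity = 0L, members = character(0),
                                annotations = list())))
    haps <- c(haps, list(best))
    D <- rbind(cbind(D, best_d), c(best_d, 0))
    net_mask <- msn_links_from_matrix(D, params$epsilon)
  }
  restore_msn_links(msn_over_nodes(nodes, params, D = D), msn0)
}

## re-admit sampled-MSN links not realized by an equal-weight geodesic
restore_msn_links <- function(net, msn0) {
  if (!nrow(msn0$edges)) return(net)
  ids <- vapply(net$nodes, `[[`, character(1), "id")
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$weight),
    directed = FALSE, vertices = data.frame(name = ids))
  sp <- igraph::distances(g)
  add <- which(vapply(seq_len(nrow(msn0$edges)), function(r)
    sp[msn0$edges$from[r], msn0$edges$to[r]] > msn0$edges$weight[r], logical(1)))
  if (length(add)) {
    net$edges <- rbind(net$edges, msn0$edges[add, , drop = FALSE])
    net$labels <- c(net$labels, msn0$labels[add])
    o <- order(net$edges$from, net$edges$to)
    net$labels <- net$labels[o]
    net$edges <- net$edges[o, , drop = FALSE]
    rownames(net$edges) <- NULL
  }
  net
}

#' Annotate nodes with allele fractions at a position
#'
#' For each sampled node, computes the fraction of its member haplotypes
#' carrying each derived state at `pos` in `panel` (typically the untrimmed
#' panel, e.g. the coding-region np 7697 states behind an HVR-I network),
#' plus the fraction with no data (`unknown`).
#'
#' @param net a `haplo_network`.
#' @param panel the panel holding the full (untrimmed) haplotypes.
#' @param pos rCRS position to annotate.
#' @return the network with `annotations[[as.character(pos)]]` filled in.
#' @export
annotate_state_fractions <- function(net, panel, pos) {
  key <- paste0(pos, "s")
  net$nodes <- lapply(net$nodes, function(nd) {
    if (!nd$sampled) return(nd)
    states <- vapply(nd$members, function(id) {
      h <- panel$haplotypes[[id]]
      if (is.null(h) || !pos_in_intervals(pos, h$covered)) "unknown"
      else { s <- state_map(h); if (key %in% names(s)) s[[key]] else "ref" }
    }, character(1))
    nd$annotations[[as.character(pos)]] <- table(states) / length(states)
    nd
  })
  net
}

#' @export
print.haplo_network <- function(x, ...) {
  ns <- sum(vapply(x$nodes, `[[`, logical(1), "sampled"))
  cat(sprintf("<haplo_network> %d node(s) (%d sampled, %d median vector(s)), %d edge(s), total weighted length %s\n",
              length(x$nodes), ns, length(x$nodes) - ns, nrow(x$edges),
              format(net_length(x))))
  invisible(x)
}

#' @export
plot.haplo_network <- function(x, ...) {
  g <- as_igraph(x)
  mult <- vapply(x$nodes, `[[`, numeric(1), "multiplicity")
  igraph::plot.igraph(g, vertex.size = 6 + 4 * sqrt(mult),
                      vertex.color = ifelse(igraph::V(g)$sampled, "goldenrod1", "grey70"),
                      edge.label = igraph::E(g)$sites, ...)
  invisible(x)
}

## igraph view of a network or tree
as_igraph <- function(x) {
  ids <- vapply(x$nodes, `[[`, character(1), "id")
  g <- igraph::graph_from_data_frame(
    data.frame(from = x$edges$from, to = x$edges$to,
               weight = x$edges$weight,
               sites = vapply(x$labels, paste, character(1), collapse = ",")),
    directed = FALSE,
    vertices = data.frame(name = ids,
                          sampled = vapply(x$nodes, `[[`, logical(1), "sampled"),
                          multiplicity = vapply(x$nodes, `[[`, numeric(1),
                                                "multiplicity")))
  g
}

#' Export a network or MP tree
#'
#' `export_graphml()` writes GraphML via igraph; `export_edge_tsv()` writes
#' a plain edge list (node1, node2, site_labels, weight); `export_dot()`
#' writes Graphviz DOT with multiplicity-scaled nodes and optional pie-style
#' state-fraction annotations stored by [annotate_state_fractions()].
#'
#' @param x a `haplo_network` or `mp_tree`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_edge_tsv <- function(x, path) {
  df <- data.frame(node1 = x$edges$from, node2 = x$edges$to,
                   site_labels = vapply(x$labels, paste, character(1),
                                        collapse = ","),
                   weight = x$edges$weight)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_graphml
#' @param annotate_pos position whose state fractions label the nodes.
#' @export
export_dot <- function(x, path, annotate_pos = NULL) {
  lines <- c("graph haplonet {", "  node [style=filled];")
  for (nd in x$nodes) {
    extra <- ""
    if (!is.null(annotate_pos)) {
      a <- nd$annotations[[as.character(annotate_pos)]]
      if (!is.null(a))
        extra <- paste0("\\n", annotate_pos, ": ",
                        paste(sprintf("%s %.0f%%", names(a), 100 * a),
                              collapse = ", "))
    }
    lines <- c(lines, sprintf(
      "  \"%s\" [label=\"%s (n=%d)%s\", fillcolor=%s, width=%.2f];",
      nd$id, nd$id, nd$multiplicity, extra,
      if (nd$sampled) "\"goldenrod1\"" else "\"grey70\"",
      0.3 + 0.15 * sqrt(nd$multiplicity)))
  }
  for (r in seq_len(nrow(x$edges)))
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];",
                              x$edges$from[r], x$edges$to[r],
                              paste(x$labels[[r]], collapse = ",")))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
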