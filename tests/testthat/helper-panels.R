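# Shared fixtures: panels are built in code, never stored.

uruguay_panel_path <- function() {
  system.file("extdata", "uruguay_c1d_panel.tsv", package = "rhonet")
}

# panel from allele strings over consecutive synthetic sites: reference
# allele "A" everywhere, any other letter is a substitution A -> letter
mk_panel <- function(strs, start = 101L, ids = sprintf("H%02d", seq_along(strs))) {
  haps <- lapply(seq_along(strs), function(i) {
    s <- strsplit(strs[i], "")[[1]]
    idx <- which(s != "A")
    haplotype(ids[i],
              variants(start - 1L + idx, rep("sub", length(idx)),
                       rep("A", length(idx)), s[idx]))
  })
  hap_panel(haps)
}

# random binary panel: n rows over k sites, entry 1 = mutated
mk_random_panel <- function(n, k, p = 0.35, seed = 1L, start = 101L) {
  set.seed(seed)
  m <- matrix(stats::rbinom(n * k, 1L, p), nrow = n)
  strs <- apply(m, 1, function(r) paste(ifelse(r == 1L, "G", "A"), collapse = ""))
  mk_panel(strs, start = start)
}

# a hand-built rooted tree: edges as data.frame(from, to, labels) where
# labels is a list of per-edge key vectors; node spec: id -> multiplicity
# (NA multiplicity marks an unsampled node)
mk_tree <- function(nodes_mult, edges_from, edges_to, edge_labels, root = NULL) {
  nodes <- lapply(names(nodes_mult), function(id) {
    m <- nodes_mult[[id]]
    list(id = id, hap = haplotype(id), sampled = !is.na(m),
         multiplicity = if (is.na(m)) 0L else m,
         members = character(0), annotations = list())
  })
  w <- vapply(edge_labels, length, integer(1))
  structure(list(nodes = nodes,
                 edges = data.frame(from = edges_from, to = edges_to,
                                    weight = w, n_mut = w),
                 labels = edge_labels,
                 total_weighted_length = sum(w), root = root),
            class = "mp_tree")
}

# independent Steiner-minimum oracle: brute-force over every median subset
# and every (n-1)-edge subset of the network's edges, no pruning
steiner_min_oracle <- function(net) {
  ids <- vapply(net$nodes, `[[`, character(1), "id")
  sampled <- vapply(net$nodes, `[[`, logical(1), "sampled")
  ei <- match(net$edges$from, ids); ej <- match(net$edges$to, ids)
  ew <- net$edges$weight
  med <- which(!sampled)
  best <- Inf
  for (mask in 0:(2^length(med) - 1)) {
    use <- if (length(med)) med[bitwAnd(mask, 2^(seq_along(med) - 1)) > 0] else integer(0)
    vs <- sort(c(which(sampled), use))
    er <- which(ei %in% vs & ej %in% vs)
    nv <- length(vs)
    if (length(er) < nv - 1L) next
    for (cmb in utils::combn(length(er), nv - 1L, simplify = FALSE)) {
      rows <- er[cmb]
      g <- igraph::graph_from_data_frame(
        data.frame(from = net$edges$from[rows], to = net$edges$to[rows]),
        directed = FALSE, vertices = data.frame(name = ids[vs]))
      if (igraph::components(g)$no == 1L) best <- min(best, sum(ew[rows]))
    }
  }
  best
}
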