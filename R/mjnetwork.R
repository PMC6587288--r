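# ---- median-joining haplotype networks -----------------------------------

hamming_matrix <- function(seqs) {
  n <- length(seqs)
  raw <- lapply(seqs, charToRaw)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) d[i, j] <- d[j, i] <- sum(raw[[i]] != raw[[j]])
    }
  }
  d
}

# total weight of a minimum spanning tree (Prim) over a dense distance matrix
mst_cost <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0)
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n)
  in_tree[1] <- TRUE
  best <- d[1, ]
  best[1] <- Inf
  total <- 0
  for (step in seq_len(n - 1L)) {
    v <- which.min(best)
    total <- total + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
    best[in_tree] <- Inf
  }
  total
}

# minimum spanning network: all edges belonging to some MST, i.e. edges (u,v)
# of weight w whose endpoints are in different components of the graph built
# from all edges of weight < w (Kruskal evaluated level by level). With
# epsilon > 0, edges within epsilon of the level at which their endpoints
# first join are also kept.
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n <= 1L) return(matrix(integer(0), ncol = 3,
                             dimnames = list(NULL, c("from", "to", "weight"))))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  join_level <- rep(NA_integer_, length(w))
  for (lvl in sort(unique(w))) {
    at <- which(w == lvl)
    roots <- cbind(vapply(pairs[at, 1], find, integer(1)),
                   vapply(pairs[at, 2], find, integer(1)))
    differs <- roots[, 1] != roots[, 2]
    join_level[at][differs] <- lvl
    for (k in at[differs]) comp[find(pairs[k, 1])] <- find(pairs[k, 2])
  }
  keep <- !is.na(join_level)
  if (epsilon > 0) {
    # relaxed minimality: admit edges no heavier than the level at which
    # their endpoints first become connected, plus epsilon
    jt <- pair_join_threshold(d)
    keep <- w <= jt[cbind(pairs[, 1], pairs[, 2])] + epsilon
  }
  cbind(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep])
}

# weight level at which each pair of nodes first becomes connected under
# Kruskal on all edges
pair_join_threshold <- function(d) {
  n <- nrow(d)
  jt <- matrix(Inf, n, n)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  for (lvl in sort(unique(w))) {
    at <- which(w == lvl)
    for (k in at) {
      r1 <- find(pairs[k, 1]); r2 <- find(pairs[k, 2])
      if (r1 != r2) comp[r1] <- r2
    }
    conn <- outer(seq_len(n), seq_len(n),
                  Vectorize(function(i, j) find(i) == find(j)))
    jt[conn & !is.finite(jt)] <- lvl
  }
  diag(jt) <- 0
  jt
}

majority_median <- function(s1, s2, s3) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  c3 <- strsplit(s3, "", fixed = TRUE)[[1]]
  # canonical ordering: ties keep the state of the lexicographically first
  # of the three sequences, making builds deterministic
  ord <- order(c(s1, s2, s3))
  states <- rbind(a, b, c3)[ord, , drop = FALSE]
  vapply(seq_along(a), function(p) {
    col <- states[, p]
    tab <- table(col)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else col[1]
  }, character(1)) |> paste(collapse = "")
}

#' Median-joining haplotype network
#'
#' Builds the network iteratively: (a) compute the minimum spanning network
#' over the current node set (all minimum-length connections; with
#' `epsilon = 0` exactly the edges belonging to some minimum spanning tree);
#' (b) generate the position-wise majority consensus (median vector) of
#' every connected triplet and add the candidate that most reduces the
#' network cost (the total weight of a minimum spanning tree over the node
#' set), ties broken by lexicographically smallest sequence; (c) repeat to
#' convergence; (d) iteratively delete obsolete median vectors (frequency 0
#' and degree < 3). Gap columns are a fifth character state.
#'
#' @param ht A [collapse_haplotypes()] table (or character vector of
#'   equal-length sequences).
#' @param epsilon Tolerance on minimal connections, as in the original
#'   algorithm; the default 0 keeps only minimum-length links.
#' @return A `haplotype_network`: `nodes` data frame (`id`, `seq`, `freq`,
#'   `is_median`), `edges` data frame (`from`, `to`, `weight`) and the total
#'   `cost`.
#' @export
median_joining <- function(ht, epsilon = 0L) {
  if (is.character(ht)) {
    seqs <- unique(ht)
    freq <- as.integer(table(ht)[seqs])
    ids <- paste0("H", seq_along(seqs))
  } else {
    seqs <- ht$seq
    freq <- rowSums(ht$counts)
    ids <- ht$haplotype_id
  }
  if (length(unique(nchar(seqs))) > 1L) stop("haplotypes differ in length")
  is_median <- rep(FALSE, length(seqs))

  repeat {
    d <- hamming_matrix(seqs)
    edges <- msn_edges(d, epsilon)
    cur_cost <- mst_cost(d)
    # connected triplets: v with two distinct network neighbours u, w
    adj <- lapply(seq_along(seqs), function(v) {
      unique(c(edges[edges[, "from"] == v, "to"],
               edges[edges[, "to"] == v, "from"]))
    })
    cand <- character(0)
    for (v in seq_along(seqs)) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      prs <- utils::combn(nb, 2L)
      for (k in seq_len(ncol(prs))) {
        m <- majority_median(seqs[prs[1, k]], seqs[v], seqs[prs[2, k]])
        if (!(m %in% seqs)) cand <- c(cand, m)
      }
    }
    cand <- unique(cand)
    if (length(cand) == 0L) break
    new_costs <- vapply(cand, function(m) {
      mst_cost(hamming_matrix(c(seqs, m)))
    }, numeric(1))
    improving <- new_costs < cur_cost
    if (!any(improving)) break
    best <- cand[improving][order(new_costs[improving],
                                  cand[improving])][1]
    seqs <- c(seqs, best)
    freq <- c(freq, 0L)
    is_median <- c(is_median, TRUE)
    ids <- c(ids, paste0("mv", sum(is_median)))
  }

  # cleanup: drop median vectors that end up peripheral
  repeat {
    d <- hamming_matrix(seqs)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges[, "from"], edges[, "to"]), nbins = length(seqs))
    obsolete <- is_median & deg < 3L
    if (!any(obsolete)) break
    keep <- !obsolete
    seqs <- seqs[keep]; freq <- freq[keep]
    is_median <- is_median[keep]; ids <- ids[keep]
  }

  d <- hamming_matrix(seqs)
  edges <- msn_edges(d, epsilon)
  structure(list(
    nodes = data.frame(id = ids, seq = seqs, freq = freq,
                       is_median = is_median, stringsAsFactors = FALSE),
    edges = data.frame(from = ids[edges[, "from"]], to = ids[edges[, "to"]],
                       weight = edges[, "weight"], stringsAsFactors = FALSE),
    cost = mst_cost(d)
  ), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", sum(!x$nodes$is_median), " haplotypes + ",
      sum(x$nodes$is_median), " median vectors, ", nrow(x$edges),
      " links, cost ", x$cost, "\n", sep = "")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net A [median_joining()] network.
#' @return An `igraph` graph with node attributes `seq`, `freq`,
#'   `is_median` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a network as GraphML and/or a TSV edge list
#'
#' @param net A [median_joining()] network.
#' @param graphml_path,edges_path,nodes_path Output paths (`NULL` skips).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL,
                          nodes_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(nodes_path)) {
    utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path, nodes_path))
}

#' Classify an individual's haplotype pattern as star-like or divergent
#'
#' Operationalizes the visual dichotomy between a star-like pattern (one or
#' two majority haplotypes with closely related minority derivatives) and a
#' divergent pattern (many distantly related haplotypes at similar
#' frequencies). The quantitative rule is a package convention, not a field
#' standard, and its thresholds are configurable: star-like iff the top one
#' or two haplotypes carry at least `top_mass` of the clones AND every
#' minority haplotype lies within `max_dist` differences of a top
#' haplotype.
#'
#' @param counts Per-haplotype clone counts for one individual.
#' @param seqs Haplotype sequences aligned with `counts` (used for
#'   distances); alternatively pass a precomputed distance matrix as `d`.
#' @param d Optional pairwise difference matrix (overrides `seqs`).
#' @param top_mass Minimum combined frequency of the top <= 2 haplotypes.
#' @param max_dist Maximum distance of a minority haplotype from the nearest
#'   top haplotype.
#' @return `"star_like"` or `"divergent"`.
#' @export
classify_pattern <- function(counts, seqs = NULL, d = NULL,
                             top_mass = 0.6, max_dist = 2L) {
  pos <- which(counts > 0)
  counts <- counts[pos]
  if (length(counts) <= 1L) return("star_like")
  if (is.null(d)) {
    if (is.null(seqs)) stop("provide seqs or d")
    d <- hamming_matrix(seqs[pos])
  } else {
    d <- d[pos, pos, drop = FALSE]
  }
  ord <- order(-counts)
  top <- ord[seq_len(min(2L, length(ord)))]
  if (sum(counts[top]) / sum(counts) < top_mass) return("divergent")
  minor <- setdiff(seq_along(counts), top)
  if (length(minor) == 0L) return("star_like")
  near <- vapply(minor, function(i) min(d[i, top]), numeric(1))
  if (all(near <= max_dist)) "star_like" else "divergent"
}
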