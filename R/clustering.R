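# All-vs-all profile comparison, consensus cladograms and modularity
# clustering of thresholded similarity networks.

#' All-vs-all profile comparison
#'
#' Scores every ordered pair of profiles by local profile-profile
#' alignment and attaches shuffle-null significance. Two p-values are
#' carried per hit: `p_emp`, the rank-based estimate over the column
#' shuffles of the target (floored at `1/(n_shuffles+1)`; shuffling
#' stops early with the sequential `h/T` estimate once `h_stop` null
#' scores reach the observed one), and `p_value`, the Gumbel
#' (extreme-value) tail fitted to the same null - the calibrated
#' quantity that can resolve the deep significance range the
#' network weights are built from. `e_value = p_value * n profiles`.
#' With `n_shuffles = 0` only scores are computed.
#'
#' @param profiles Named list of `profile` objects.
#' @param n_shuffles Shuffles per pair (0 = scores only).
#' @param seed Integer seed (per-pair child seeds keep runs reproducible).
#' @param gap_open,gap_extend,band Alignment parameters.
#' @param h_stop Early-stop exceedance count (0 disables early stopping).
#' @param min_nulls Minimum null draws before early stopping may trigger
#'   (keeps the Gumbel fit usable on stopped pairs).
#' @return Data frame of class `hit_table`: one row per ordered pair with
#'   score, `p_value` (fitted), `p_emp` (rank-based), `e_value`, spans,
#'   `aln_len`, `n_pairs`, `q_coverage`.
#' @export
all_vs_all <- function(profiles, n_shuffles = 200L, seed = 1L,
                       gap_open = 10, gap_extend = 1, band = 64L,
                       h_stop = 5L, min_nulls = 40L) {
  stopifnot(length(profiles) >= 2L)
  ids <- names(profiles)
  n <- length(ids)
  rows <- list()
  for (qi in seq_len(n)) {
    p1 <- profiles[[qi]]
    for (ti in seq_len(n)) {
      p2 <- profiles[[ti]]
      S <- pp_cell_scores(p1, p2)
      gs1 <- 1 - p1$gap_frac
      gs2 <- 1 - p2$gap_frac
      tb <- dp_scoremat_cpp(S, gs1, gs2, gap_open, gap_extend, TRUE, TRUE,
                            NULL, band)
      hit <- if (tb$score <= 0) .empty_hit(ids[qi], ids[ti]) else
        data.frame(query_id = ids[qi], target_id = ids[ti],
                   score = tb$score, p_value = NA_real_,
                   e_value = NA_real_, q_start = tb$q_start,
                   q_end = tb$q_end, t_start = tb$t_start,
                   t_end = tb$t_end, aln_len = tb$aln_len,
                   n_pairs = tb$n_pairs,
                   q_coverage = (tb$q_end - tb$q_start + 1L) / p1$n_cols,
                   stringsAsFactors = FALSE)
      hit$p_emp <- NA_real_
      if (n_shuffles > 0L) {
        obs <- dp_local_score_cpp(S, gs1, gs2, gap_open, gap_extend, band)
        perms <- with_seed(child_seed(seed, paste0(ids[qi], "~", ids[ti])),
                           vapply(seq_len(n_shuffles), function(k)
                             sample.int(p2$n_cols),
                             integer(p2$n_cols)))
        nl1 <- dp_local_null_cpp(S, gs1, gs2, gap_open, gap_extend,
                                 perms[, seq_len(min(min_nulls,
                                                     n_shuffles)),
                                       drop = FALSE],
                                 band, NA_real_, 0L)
        nulls <- nl1$scores
        exceed <- sum(nulls >= obs)
        if (exceed < h_stop && n_shuffles > min_nulls) {
          nl2 <- dp_local_null_cpp(S, gs1, gs2, gap_open, gap_extend,
                                   perms[, (min_nulls + 1L):n_shuffles,
                                         drop = FALSE],
                                   band, obs, h_stop - exceed)
          nulls <- c(nulls, nl2$scores)
          exceed <- exceed + nl2$n_exceed
        }
        n_done <- length(nulls)
        hit$p_emp <- if (n_done < n_shuffles) max(exceed, 1L) / n_done
          else (exceed + 1) / (n_shuffles + 1)
        pf <- gumbel_tail(obs, gumbel_fit(nulls))
        hit$p_value <- max(pf, .Machine$double.xmin)
        hit$e_value <- hit$p_value * n
      }
      rows <- c(rows, list(hit))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hit_table", class(out))
  attr(out, "n_targets") <- n
  out
}

#' Symmetrised score and distance matrices from a hit table
#'
#' `S_ij = mean(value_ij, value_ji)`; the distance transform is
#' `D = max(S) - S` with a zeroed diagonal (rank-preserving; the
#' alternative `1 / (1 + S)` is available via `transform`). The value
#' can be the raw local-alignment score or, when significance was
#' computed, the calibrated weight `min(-log10 p, weight_cap)` - the
#' quantity the published comparisons cluster and display, which also
#' normalises out profile-quality differences between families.
#'
#' @param hits A `hit_table` covering all ordered pairs.
#' @param transform `"max_minus"` (default) or `"inverse"`.
#' @param value `"score"` (default) or `"weight"`.
#' @param weight_cap Cap on `-log10(p)` when `value = "weight"`.
#' @return List with `S` (symmetric values) and `D` (distances).
#' @export
score_matrix <- function(hits, transform = c("max_minus", "inverse"),
                         value = c("score", "weight"), weight_cap = 20) {
  transform <- match.arg(transform)
  value <- match.arg(value)
  ids <- sort(unique(c(hits$query_id, hits$target_id)))
  n <- length(ids)
  v <- if (value == "score") hits$score else
    pmin(-log10(pmax(hits$p_value, 1e-300)), weight_cap)
  sc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  sc[cbind(match(hits$query_id, ids), match(hits$target_id, ids))] <- v
  if (anyNA(sc)) stop("hit table is missing pairs")
  S <- (sc + t(sc)) / 2
  D <- if (transform == "max_minus") max(S) - S else 1 / (1 + S)
  diag(D) <- 0
  list(S = S, D = D)
}

#' UPGMA cladogram from a distance matrix
#'
#' Average-linkage agglomeration; labels are put in lexicographic order
#' first so equal-distance merges resolve deterministically.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @return Object of class `cladogram`: `hclust`, `phylo` (ape) and
#'   `labels`.
#' @export
hclust_tree <- function(D) {
  ord <- order(rownames(D))
  D <- D[ord, ord]
  hc <- hclust(as.dist(D), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 labels = rownames(D)),
            class = "cladogram")
}

#' @export
print.cladogram <- function(x, ...) {
  cat("cladogram over", length(x$labels), "leaves\n")
  invisible(x)
}

#' Majority-rule consensus of cladograms
#'
#' Keeps clades present in at least `ceiling(min_frac * n_trees)` trees
#' (strictly more than half); kept clades are annotated with their
#' support count, everything else collapses into polytomies.
#'
#' @param trees List of `cladogram` objects (or `phylo`) with identical
#'   leaf sets.
#' @param min_frac Minimal replication fraction (default 2/3).
#' @return A `phylo` consensus tree; `node.label` holds support as
#'   `"k/n"`.
#' @export
consensus_cladogram <- function(trees, min_frac = 2 / 3) {
  phys <- lapply(trees, function(t)
    if (inherits(t, "cladogram")) t$phylo else t)
  tipsets <- lapply(phys, function(p) sort(p$tip.label))
  if (length(unique(vapply(tipsets, paste, character(1),
                           collapse = "\r"))) != 1L)
    stop("leaf sets differ between trees")
  n <- length(phys)
  need <- ceiling(min_frac * n)
  p_thresh <- (need - 0.5) / n  # ape keeps clades with frequency > p
  cons <- ape::consensus(phys, p = p_thresh, rooted = TRUE)
  supp <- ape::prop.clades(cons, phys, rooted = TRUE)
  supp[is.na(supp)] <- n
  cons$node.label <- paste0(supp, "/", n)
  cons
}

#' Replicated clusters across the k-cuts of several trees
#'
#' Operationalises "clusters replicated in at least two of the three
#' analyses": for each k, every tree is cut into k groups; a group is
#' replicated when the identical leaf set occurs in at least
#' `ceiling(min_frac * n_trees)` of the cuts; a partition qualifies when
#' its replicated groups cover all leaves (replicated groups are
#' automatically disjoint once the threshold exceeds half). Among
#' qualifying partitions the reported one maximises the mean silhouette
#' width on `D`.
#'
#' @param trees List of `cladogram` objects.
#' @param min_frac Replication threshold (default 2/3).
#' @param D Optional distance matrix (e.g. the average of the analyses'
#'   matrices): among fully replicated partitions the one maximising the
#'   mean silhouette width is reported, which selects the natural depth
#'   of the shared structure. Without `D` the finest replicated
#'   partition is returned.
#' @return List: `k` (number of consensus clusters), `clusters` (named
#'   membership vector), `support` (per-cluster replication count),
#'   `quality` (selection score).
#' @export
consensus_clusters <- function(trees, min_frac = 2 / 3, D = NULL) {
  hcs <- lapply(trees, function(t) t$hclust)
  labels <- sort(hcs[[1L]]$labels)
  n_trees <- length(hcs)
  need <- ceiling(min_frac * n_trees)
  n_leaves <- length(labels)
  best <- NULL
  best_score <- -Inf
  for (k in seq_len(n_leaves)) {
    parts <- list()
    for (h in hcs) {
      ct <- cutree(h, k = k)
      for (g in split(names(ct), ct))
        parts <- c(parts, list(paste(sort(g), collapse = "\r")))
    }
    counts <- table(unlist(parts))
    rep_parts <- names(counts)[counts >= need]
    covered <- sort(unlist(strsplit(rep_parts, "\r", fixed = TRUE)))
    if (length(covered) == n_leaves && all(covered == labels)) {
      membership <- setNames(integer(n_leaves), labels)
      supp <- integer(length(rep_parts))
      for (i in seq_along(rep_parts)) {
        mem <- strsplit(rep_parts[i], "\r", fixed = TRUE)[[1]]
        membership[mem] <- i
        supp[i] <- counts[[rep_parts[i]]]
      }
      score <- if (is.null(D)) length(rep_parts)
        else .mean_silhouette(membership, D[labels, labels])
      if (score > best_score + 1e-12) {
        best_score <- score
        best <- list(k = length(rep_parts), clusters = membership,
                     support = supp, quality = score)
      }
    }
  }
  best
}

# mean silhouette width of a hard partition on a distance matrix;
# singletons contribute 0, a single all-covering cluster scores 0
.mean_silhouette <- function(membership, D) {
  ids <- names(membership)
  k <- length(unique(membership))
  if (k <= 1L || k >= length(ids)) return(0)
  s <- numeric(length(ids))
  for (i in seq_along(ids)) {
    own <- ids[membership == membership[ids[i]]]
    own <- setdiff(own, ids[i])
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[ids[i], own])
    b <- min(vapply(setdiff(unique(membership), membership[ids[i]]),
                    function(cl) mean(D[ids[i],
                                        ids[membership == cl]]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Build a similarity network from a hit table
#'
#' Undirected graph over profiles: an edge is drawn when either directed
#' hit passes all filters (`p < p_max`, optionally `aln_len >
#' min_aln_len`, optionally membership in the query's `top_k` non-self
#' hits by p-value). The filters are pure predicates on the directed hit
#' table, so their application order is irrelevant. Edge weight is
#' `min(-log10(best p of the pair), weight_cap)`.
#'
#' @param hits A `hit_table` with p-values.
#' @param p_max Significance threshold (strict `<`).
#' @param min_aln_len Minimal alignment length (strict `>`), or `NULL`.
#' @param top_k Per-query rank cut, or `NULL`.
#' @param weight_cap Cap on `-log10(p)` (default 20).
#' @return An `igraph` graph (all profiles as nodes, possibly isolated).
#' @export
build_graph <- function(hits, p_max = 1e-2, min_aln_len = NULL,
                        top_k = NULL, weight_cap = 20) {
  h <- hits[hits$query_id != hits$target_id, , drop = FALSE]
  nodes <- sort(unique(c(hits$query_id, hits$target_id)))
  pass <- h$p_value < p_max
  if (!is.null(min_aln_len)) pass <- pass & h$aln_len > min_aln_len
  if (!is.null(top_k)) {
    in_top <- logical(nrow(h))
    for (q in nodes) {
      qi <- which(h$query_id == q)
      ord <- qi[order(h$p_value[qi], -h$score[qi], h$target_id[qi])]
      in_top[utils::head(ord, top_k)] <- TRUE
    }
    pass <- pass & in_top
  }
  hp <- h[pass & !is.na(pass), , drop = FALSE]
  edges <- list()
  if (nrow(hp)) {
    key <- ifelse(hp$query_id < hp$target_id,
                  paste(hp$query_id, hp$target_id, sep = "\r"),
                  paste(hp$target_id, hp$query_id, sep = "\r"))
    for (kk in unique(key)) {
      ab <- strsplit(kk, "\r", fixed = TRUE)[[1]]
      # best p over both directions of the full table (not only passing)
      pb <- min(h$p_value[(h$query_id == ab[1] & h$target_id == ab[2]) |
                            (h$query_id == ab[2] & h$target_id == ab[1])],
                na.rm = TRUE)
      edges <- c(edges, list(data.frame(
        from = ab[1], to = ab[2],
        weight = min(-log10(pb), weight_cap),
        p = pb,
        aln_len = max(h$aln_len[(h$query_id == ab[1] &
                                   h$target_id == ab[2]) |
                                  (h$query_id == ab[2] &
                                     h$target_id == ab[1])]),
        stringsAsFactors = FALSE)))
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges)
    else data.frame(from = character(0), to = character(0),
                    weight = numeric(0), p = numeric(0),
                    aln_len = integer(0))
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

# weighted modularity recomputed from first principles
.modularity_q <- function(graph, membership) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  W <- sum(w)
  if (W == 0) return(0)
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  same <- membership[ends[, 1]] == membership[ends[, 2]]
  deg <- igraph::strength(graph, weights = w)
  q <- sum(w[same]) / W
  for (cl in unique(membership)) {
    dc <- sum(deg[names(membership)[membership == cl]])
    q <- q - (dc / (2 * W))^2
  }
  q
}

#' Modularity clustering of a similarity network
#'
#' Greedy modularity maximisation (Clauset-Newman-Moore agglomeration,
#' via `igraph::cluster_fast_greedy`; deterministic given the graph).
#' The returned Q is recomputed from the standard weighted-modularity
#' formula, independently of the optimiser.
#'
#' @param graph An `igraph` graph (weights used when present).
#' @param seed Seed (kept for interface stability; the CNM agglomeration
#'   itself is deterministic).
#' @return List of class `partition`: `membership` (named integer),
#'   `n_clusters`, `modularity_q`.
#' @export
modularity_partition <- function(graph, seed = 1L) {
  stopifnot(igraph::vcount(graph) >= 1L)
  if (igraph::ecount(graph) == 0L) {
    membership <- setNames(seq_len(igraph::vcount(graph)),
                           igraph::V(graph)$name)
  } else {
    cl <- with_seed(seed, igraph::cluster_fast_greedy(
      graph, weights = igraph::E(graph)$weight))
    membership <- setNames(as.integer(igraph::membership(cl)),
                           igraph::V(graph)$name)
    # guard: maximisation must never do worse than one community per
    # connected component (Q = 0)
    if (.modularity_q(graph, membership) < 0) {
      comp <- igraph::components(graph)
      membership <- setNames(as.integer(comp$membership),
                             igraph::V(graph)$name)
    }
  }
  structure(list(membership = membership,
                 n_clusters = length(unique(membership)),
                 modularity_q = .modularity_q(graph, membership)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", x$n_clusters, "clusters, Q =",
      format(x$modularity_q, digits = 4), "\n")
  invisible(x)
}

#' Re-cluster an induced subgraph
#'
#' @param graph An `igraph` graph.
#' @param node_subset Node names to keep (non-empty subset).
#' @param seed Passed to [modularity_partition()].
#' @return A `partition` over the subset.
#' @export
subcluster <- function(graph, node_subset, seed = 1L) {
  if (!length(node_subset)) stop("empty node subset")
  stopifnot(all(node_subset %in% igraph::V(graph)$name))
  sub <- igraph::induced_subgraph(graph, node_subset)
  modularity_partition(sub, seed = seed)
}

#' Write network / clustering artifacts
#'
#' `write_edge_list`: TSV `source target weight p aln_len`.
#' `write_clusters`: TSV `node cluster` with Q in a header comment.
#' `write_heatmap_matrices`: the asymmetric pair matrices (alignment
#' length above, log10 p below the diagonal conventionally displayed;
#' emitted as two full matrices).
#' @param graph igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  names(ed)[1:2] <- c("source", "target")
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param partition A `partition`.
#' @export
write_clusters <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# modularity_q\t",
                    format(partition$modularity_q, digits = 10)), con)
  write.table(data.frame(node = names(partition$membership),
                         cluster = partition$membership),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param hits A `hit_table`.
#' @param dir Output directory for `heatmap_aln_len.tsv` and
#'   `heatmap_log10p.tsv`.
#' @export
write_heatmap_matrices <- function(hits, dir) {
  ids <- sort(unique(c(hits$query_id, hits$target_id)))
  al <- matrix(NA_real_, length(ids), length(ids),
               dimnames = list(ids, ids))
  lp <- al
  idx <- cbind(match(hits$query_id, ids), match(hits$target_id, ids))
  al[idx] <- hits$aln_len
  lp[idx] <- log10(hits$p_value)
  write.table(al, file.path(dir, "heatmap_aln_len.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(lp, file.path(dir, "heatmap_log10p.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(dir)
}
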