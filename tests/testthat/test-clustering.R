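# All-vs-all comparison, cladograms, consensus, networks, modularity.

make_profiles <- function(seqs) {
  out <- lapply(names(seqs), function(id) seq_profile(seqs[[id]], id))
  names(out) <- names(seqs)
  out
}

test_that("all-vs-all produces n^2 hits with dominant self-hits", {
  withr::with_seed(41, {
    profs <- make_profiles(c(a = random_seq(40), b = random_seq(40),
                             c = random_seq(40)))
    hits <- all_vs_all(profs, n_shuffles = 0)
    expect_equal(nrow(hits), 9L)
    for (q in names(profs)) {
      sub <- hits[hits$query_id == q, ]
      expect_equal(sub$target_id[which.max(sub$score)], q)
    }
  })
})

test_that("score matrix symmetrisation and distance transform", {
  hits <- expand.grid(query_id = c("a", "b", "c"),
                      target_id = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  sc <- matrix(c(10, 4, 2,
                 6, 12, 1,
                 2, 3, 8), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hits$score <- sc[cbind(hits$query_id, hits$target_id)]
  sm <- score_matrix(hits)
  expect_equal(sm$S["a", "b"], 5)
  expect_equal(sm$S["a", "b"], sm$S["b", "a"])
  expect_equal(max(sm$S), 12)
  expect_equal(sm$D["a", "b"], 12 - 5)
  expect_equal(unname(diag(sm$D)), c(0, 0, 0))
  expect_error(score_matrix(hits[-1, ]), "missing")
})

test_that("UPGMA trees recover forced and ultrametric topologies", {
  D <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- hclust_tree(D)
  expect_s3_class(tr$phylo, "phylo")
  expect_true(ape::is.monophyletic(tr$phylo, c("A", "B")))

  # ultrametric distances from a known 6-leaf tree are recovered
  nwk <- "(((a:1,b:1):2,c:3):3,((d:2,e:2):1,f:3):3);"
  ph <- ape::read.tree(text = nwk)
  DD <- ape::cophenetic.phylo(ph)
  tr6 <- hclust_tree(DD)
  expect_true(ape::is.monophyletic(tr6$phylo, c("a", "b")))
  expect_true(ape::is.monophyletic(tr6$phylo, c("a", "b", "c")))
  expect_true(ape::is.monophyletic(tr6$phylo, c("d", "e")))
  expect_true(ape::is.monophyletic(tr6$phylo, c("d", "e", "f")))
})

test_that("majority-rule consensus keeps exactly the replicated clades", {
  t_ab <- ape::read.tree(text = "((A,B),C);")
  t_ac <- ape::read.tree(text = "((A,C),B);")
  t_bc <- ape::read.tree(text = "((B,C),A);")
  # identical trees: consensus is the tree itself with full support
  cons <- consensus_cladogram(list(t_ab, t_ab, t_ab))
  expect_true(ape::is.monophyletic(cons, c("A", "B")))
  expect_true(any(grepl("3/3", cons$node.label)))
  # 2 of 3: clade kept with 2/3
  cons2 <- consensus_cladogram(list(t_ab, t_ab, t_ac))
  expect_true(ape::is.monophyletic(cons2, c("A", "B")))
  expect_true(any(grepl("2/3", cons2$node.label)))
  # three incompatible resolutions: star
  cons3 <- consensus_cladogram(list(t_ab, t_ac, t_bc))
  expect_equal(cons3$Nnode, 1L)
  expect_error(consensus_cladogram(list(
    t_ab, ape::read.tree(text = "((A,B),D);"), t_ab)), "leaf sets")
})

test_that("replicated k-cut clusters find the finest shared partition", {
  # two trees agree on {AB}{CD}{EF}; the third splits differently inside
  d_base <- function(perm) {
    D <- matrix(8, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
    diag(D) <- 0
    D["A", "B"] <- D["B", "A"] <- 1
    D["C", "D"] <- D["D", "C"] <- 1
    D["E", "F"] <- D["F", "E"] <- 1
    D
  }
  t1 <- hclust_tree(d_base())
  t2 <- hclust_tree(d_base())
  D3 <- d_base()
  D3["A", "B"] <- D3["B", "A"] <- 7  # weakly clustered variant
  D3["A", "C"] <- D3["C", "A"] <- 1
  t3 <- hclust_tree(D3)
  Dm <- (d_base() + d_base() + D3) / 3
  cc <- consensus_clusters(list(t1, t2, t3), D = Dm)
  expect_equal(cc$k, 3L)
  expect_equal(unname(cc$clusters["A"]), unname(cc$clusters["B"]))
  expect_equal(unname(cc$clusters["C"]), unname(cc$clusters["D"]))
  # identical trees: the finest partition is every leaf alone
  cc_id <- consensus_clusters(list(t1, t1, t1))
  expect_equal(cc_id$k, 6L)
})

test_that("graph construction filters, caps weights, and commutes", {
  mk_hits <- function() {
    g <- expand.grid(query_id = c("a", "b", "c", "d"),
                     target_id = c("a", "b", "c", "d"),
                     stringsAsFactors = FALSE)
    g$score <- 10
    g$p_value <- 0.5
    g$aln_len <- 100L
    g$p_value[g$query_id == "a" & g$target_id == "b"] <- 1e-30
    g$aln_len[g$query_id == "a" & g$target_id == "b"] <- 400L
    g$p_value[g$query_id == "c" & g$target_id == "d"] <- 1e-3
    g
  }
  h <- mk_hits()
  g0 <- build_graph(h, p_max = 1e-40)
  expect_equal(igraph::ecount(g0), 0L)
  expect_equal(igraph::vcount(g0), 4L)
  g1 <- build_graph(h, p_max = 1e-2)
  expect_equal(igraph::ecount(g1), 2L)
  # weight cap at 20 despite p = 1e-30
  wab <- igraph::E(g1)$weight[igraph::get.edge.ids(g1, c("a", "b"))]
  expect_equal(wab, 20)
  # aln_len filter removes exactly the short-alignment edge
  g2 <- build_graph(h, p_max = 1e-2, min_aln_len = 300)
  expect_equal(igraph::ecount(g2), 1L)
  # filters commute: same edges regardless of composition order
  e_all <- igraph::as_data_frame(build_graph(h, p_max = 1e-2,
                                             min_aln_len = 300,
                                             top_k = 1))
  e_all2 <- igraph::as_data_frame(build_graph(h, p_max = 1e-2,
                                              top_k = 1,
                                              min_aln_len = 300))
  expect_equal(e_all, e_all2)
})

test_that("modularity clustering recovers planted structure", {
  # two disjoint 4-cliques: compare against brute force over all
  # partitions of the 8 nodes
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$weight <- 1
  part <- modularity_partition(g)
  expect_equal(part$n_clusters, 2L)
  expect_equal(length(unique(part$membership[1:4])), 1L)
  expect_equal(length(unique(part$membership[5:8])), 1L)
  # brute-force best modularity over all set partitions of 8 nodes
  parts <- function(set) {
    if (length(set) == 0) return(list(list()))
    out <- list()
    rest <- parts(set[-1])
    for (p in rest) {
      out <- c(out, list(c(p, list(set[1]))))
      for (i in seq_along(p)) {
        q <- p
        q[[i]] <- c(q[[i]], set[1])
        out <- c(out, list(q))
      }
    }
    out
  }
  best_q <- -Inf
  for (p in parts(paste0("n", 1:8))) {
    mem <- integer(8)
    names(mem) <- paste0("n", 1:8)
    for (i in seq_along(p)) mem[p[[i]]] <- i
    best_q <- max(best_q, profhom:::.modularity_q(g, mem))
  }
  expect_equal(part$modularity_q, best_q, tolerance = 1e-9)

  # a single clique holds together with Q <= 0
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  igraph::E(k5)$weight <- 1
  p5 <- modularity_partition(k5)
  expect_equal(p5$n_clusters, 1L)
  expect_lte(p5$modularity_q, 0)
})

test_that("planted partitions are recovered exactly across seeds", {
  for (sd in 1:10) {
    g <- withr::with_seed(sd, igraph::sample_sbm(
      30, pref.matrix = matrix(c(0.9, 0.05, 0.05,
                                 0.05, 0.9, 0.05,
                                 0.05, 0.05, 0.9), 3),
      block.sizes = c(10, 10, 10)))
    igraph::V(g)$name <- paste0("n", 1:30)
    igraph::E(g)$weight <- 1
    part <- modularity_partition(g, seed = sd)
    truth <- rep(1:3, each = 10)
    # adjusted Rand index must be 1 (perfect recovery)
    tab <- table(part$membership, truth)
    a <- sum(choose(tab, 2))
    b <- sum(choose(rowSums(tab), 2))
    cc <- sum(choose(colSums(tab), 2))
    n <- sum(tab)
    expected <- b * cc / choose(n, 2)
    ari <- (a - expected) / ((b + cc) / 2 - expected)
    expect_equal(ari, 1, info = paste("seed", sd))
  }
})

test_that("subclustering re-partitions an induced subgraph", {
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$weight <- 1
  full <- modularity_partition(g)
  all_sub <- subcluster(g, paste0("n", 1:8))
  expect_equal(all_sub$membership, full$membership)
  one <- subcluster(g, "n1")
  expect_equal(one$n_clusters, 1L)
  expect_error(subcluster(g, character(0)), "empty")
  # two sub-communities hidden inside one coarse community
  sub <- subcluster(g, paste0("n", 1:8))
  expect_equal(sub$n_clusters, 2L)
})
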