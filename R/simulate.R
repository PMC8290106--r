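# Synthetic protein-family simulator.
#
# Families descend from one ancestral tetramer: an ancestral dimer (one
# "body" and one "arm" protein) duplicates into a four-class tetramer
# (g51, g52, g53, g54; the g53/g54 split is the shallowest and the g52
# lineage the fastest-evolving), and tetramer duplications then radiate
# the full complexes, plus one half-complex that retains only its g53/g54
# subunits. Below the radiation (the LECA analogue) every family evolves
# along a common species tree whose taxa come in shallow sister pairs, so
# within-pair orthologs remain alignable while cross-clade orthologs sit
# in the twilight zone. All proteins share an N-terminal heptad coiled
# coil inherited from the ultimate ancestor and evolving at a fraction of
# the body rate: a deliberate confounder that injects spurious cross-class
# similarity unless masked.
#
# Substitution process: per site, a replacement event occurs on a branch of
# length t with probability 1 - exp(-r * t) (r = per-site gamma rate,
# inherited through the whole genealogy so the conserved core is shared by
# all families); the replacement is drawn from the off-diagonal
# BLOSUM62-conditional distribution, so branch lengths read as expected
# substitutions per site. Indels are Poisson along branches with
# geometric lengths and never touch the coiled-coil segment.

#' Simulation configuration
#'
#' Defaults encode the study conditions: ~22 families (5 full complexes of
#' 4 classes plus one 2-subunit half-complex) in 6 taxa, sequence length
#' 700 with a 56-residue N-terminal coiled coil, and a divergence schedule
#' placing cross-clade ortholog identity below 20%.
#'
#' @param n_taxa Number of taxa (grouped into clades; see
#'   `clade_split_depths`).
#' @param species_tree_depth Root-to-tip depth of the species tree
#'   (replacement events per site).
#' @param clade_split_depths Depths of the within-clade splits (the
#'   ladder of progressively more divergent relatives every seed taxon
#'   has); clade size is `length(clade_split_depths) + 1`.
#' @param classes Subunit class labels.
#' @param complexes Full-complex labels.
#' @param half_complex Label of the complex retaining only g53/g54
#'   subunits, or `NULL` for none.
#' @param class_split_depths Named list: depths (above the LECA analogue)
#'   of the `root` dimer origin, the `g51_g52` and the `g53_g54` splits.
#' @param class_extra Named extra stem lengths per class (rate
#'   acceleration; makes g52 the most remote lineage).
#' @param complex_radiation Two numbers `c(max, min)`: depth range of the
#'   tetramer-duplication radiation.
#' @param seq_length,cc_length,cc_start Protein length and coiled-coil
#'   segment geometry (residues).
#' @param cc_rate_scale Relative substitution rate of coiled-coil sites.
#' @param sub_rate_scale Global multiplier on all branch lengths (0 turns
#'   evolution off entirely).
#' @param indel_rate Indel events per site per unit branch length.
#' @param indel_len_mean Mean indel length (geometric).
#' @param gamma_shape Shape of the gamma site-rate distribution of
#'   non-core sites.
#' @param shift_class,shift_complex Neofunctionalization shifts: on each
#'   child branch of a dimer/class duplication (`shift_class`) or a
#'   complex duplication (`shift_complex`), this fraction of non-core
#'   body sites acquires a fresh lineage-specific residue pool -
#'   substitutions at the site are confined to the pool from then on.
#'   The pools model the changed functional constraint after
#'   duplication: descendants of the duplicate share a site-specific
#'   amino-acid preference that other lineages do not, which is what
#'   makes the groups diagnosable by profile comparison while pairwise
#'   identity barely moves.
#' @param shift_root Fraction of body sites carrying a residue pool in
#'   the ancestral protein already (baseline functional constraints).
#' @param pool_turnover Rate (per unit branch length) at which a pooled
#'   site exchanges its pool for a fresh one; pool sharing between two
#'   lineages therefore decays with their divergence, grading the
#'   profile similarity hierarchy.
#' @param shift_pool_size Number of residues per acquired pool.
#' @param core_frac,core_rate Fraction of sites forming the conserved
#'   structural core (helical-bundle packing positions) and their
#'   relative substitution rate. Core sites are drawn once at the
#'   ultimate root and inherited by every family, so remote homologs
#'   share them - the signal that makes profile detection possible in
#'   the twilight zone while overall pairwise identity stays low.
#' @param p_loss Per-taxon, per-family loss probability.
#' @param p_lineage_dup Per-taxon, per-family duplication probability.
#' @param dup_branch Extra branch length of lineage-duplicated copies.
#' @param seed Integer seed governing the entire simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 6L,
                       species_tree_depth = 3.6,
                       clade_split_depths = c(0.35, 1.3),
                       classes = c("g51", "g52", "g53", "g54"),
                       complexes = c("C1", "C2", "C3", "C4", "C5"),
                       half_complex = "H1",
                       class_split_depths = list(root = 2.8,
                                                 g51_g52 = 2.3,
                                                 g53_g54 = 1.5),
                       class_extra = c(g51 = 0.4, g52 = 1.0,
                                       g53 = 0, g54 = 0),
                       complex_radiation = c(0.8, 0.3),
                       seq_length = 700L,
                       cc_length = 56L,
                       cc_start = 1L,
                       cc_rate_scale = 0.25,
                       sub_rate_scale = 1,
                       indel_rate = 0.015,
                       indel_len_mean = 3,
                       gamma_shape = 2.0,
                       core_frac = 0.08,
                       core_rate = 0.2,
                       shift_root = 0.45,
                       shift_class = 0.35,
                       shift_complex = 0.05,
                       pool_turnover = 0.08,
                       shift_pool_size = 6L,
                       p_loss = 0.14,
                       p_lineage_dup = 0.05,
                       dup_branch = 0.3,
                       seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa),
              species_tree_depth = species_tree_depth,
              clade_split_depths = clade_split_depths,
              classes = classes, complexes = complexes,
              half_complex = half_complex,
              class_split_depths = class_split_depths,
              class_extra = class_extra,
              complex_radiation = complex_radiation,
              seq_length = as.integer(seq_length),
              cc_length = as.integer(cc_length),
              cc_start = as.integer(cc_start),
              cc_rate_scale = cc_rate_scale,
              sub_rate_scale = sub_rate_scale,
              indel_rate = indel_rate,
              indel_len_mean = indel_len_mean,
              gamma_shape = gamma_shape,
              core_frac = core_frac, core_rate = core_rate,
              shift_root = shift_root, shift_class = shift_class,
              shift_complex = shift_complex,
              pool_turnover = pool_turnover,
              shift_pool_size = as.integer(shift_pool_size),
              p_loss = p_loss, p_lineage_dup = p_lineage_dup,
              dup_branch = dup_branch, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_loss, cfg$p_lineage_dup, cfg$core_frac,
             cfg$shift_root, cfg$shift_class, cfg$shift_complex)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$n_taxa < 1L) stop("configuration error: n_taxa must be >= 1")
  depths <- c(unlist(cfg$class_split_depths), cfg$complex_radiation,
              cfg$species_tree_depth, cfg$clade_split_depths)
  if (any(depths <= 0)) stop("configuration error: depths must be > 0")
  if (any(diff(cfg$clade_split_depths) <= 0))
    stop("configuration error: clade split depths must increase")
  if (max(cfg$clade_split_depths) >= cfg$species_tree_depth)
    stop("configuration error: clade split deeper than species root")
  if (cfg$complex_radiation[1] < cfg$complex_radiation[2])
    stop("configuration error: complex radiation range reversed")
  if (length(cfg$classes) > 1L) {
    cs <- cfg$class_split_depths
    if (cfg$complex_radiation[1] >= min(unlist(cs)))
      stop("configuration error: complex radiation deeper than class split")
    if (!is.null(cs$root) && !is.null(cs$g51_g52) && cs$g51_g52 >= cs$root)
      stop("configuration error: class split deeper than root")
    if (!is.null(cs$root) && !is.null(cs$g53_g54) && cs$g53_g54 >= cs$root)
      stop("configuration error: class split deeper than root")
  }
  if (cfg$seq_length <= cfg$cc_start + cfg$cc_length)
    stop("configuration error: seq_length must exceed cc_start + cc_length")
  invisible(cfg)
}

# --- internal tree representation -----------------------------------------
# node: list(name = leaf name or NULL, branch = length to parent,
#            children = list of nodes)

.node <- function(name = NULL, branch = 0, children = list(),
                  shift = 0) {
  list(name = name, branch = branch, children = children, shift = shift)
}

.node_newick <- function(node) {
  inner <- function(nd) {
    if (length(nd$children) == 0L)
      return(paste0(nd$name, ":", format(nd$branch, digits = 10)))
    paste0("(", paste(vapply(nd$children, inner, character(1)),
                      collapse = ","),
           "):", format(nd$branch, digits = 10))
  }
  if (length(node$children) == 0L)
    return(paste0(node$name, ";"))
  paste0("(", paste(vapply(node$children, inner, character(1)),
                    collapse = ","), ");")
}

.node_leaves <- function(node) {
  if (length(node$children) == 0L) return(node$name)
  unlist(lapply(node$children, .node_leaves))
}

# caterpillar over complex labels with split depths from max to min
.complex_subtree <- function(labels, class_name, rad_max, rad_min, stem,
                             shift = 0) {
  k <- length(labels)
  leaf_name <- function(cpx) paste0(cpx, "_", class_name)
  if (k == 1L) return(.node(leaf_name(labels[1]), branch = stem + rad_max))
  d <- if (k == 2L) rad_max else seq(rad_max, rad_min, length.out = k - 1L)
  build <- function(i) {
    if (i == k - 1L)
      return(.node(children = list(
        .node(leaf_name(labels[i]), d[i], shift = shift),
        .node(leaf_name(labels[i + 1L]), d[i], shift = shift)),
        branch = 0))
    nd <- build(i + 1L)
    nd$branch <- d[i] - d[i + 1L]
    nd$shift <- shift
    .node(children = list(.node(leaf_name(labels[i]), d[i],
                                shift = shift), nd),
          branch = 0)
  }
  top <- build(1L)
  top$branch <- stem
  top
}

#' Simulate the duplication history of the family set
#'
#' Builds the rooted unit tree: ancestral dimer origin, dimer duplication
#' into the four class ancestors (g53/g54 split shallowest), and tetramer
#' duplications radiating the complexes; the half-complex retains only its
#' g53/g54 subunits (recorded as subunit-loss events). Deterministic given
#' the configuration.
#'
#' @param config A [sim_config()].
#' @return An object of class `duplication_history`: `tree` (internal node
#'   structure), `newick`, `leaves` (family ids `complex_class`), `labels`
#'   (data frame family/complex/class), `events` (data frame with
#'   `event_kind`, `parent`, `children`, `time` as relative depth in
#'   `[0, 1]`), `root_depth`.
#' @export
simulate_history <- function(config) {
  validate_sim_config(config)
  cls <- config$classes
  cs <- config$class_split_depths
  rad <- config$complex_radiation
  half <- config$half_complex
  cpx_for_class <- function(cl) {
    if (!is.null(half) && cl %in% c("g53", "g54"))
      c(config$complexes, half) else config$complexes
  }
  root_depth <- if (length(cls) > 1L) cs$root else rad[1]
  subtrees <- lapply(cls, function(cl) {
    depth_cl <- if (length(cls) == 1L) rad[1]
      else if (cl %in% c("g51", "g52")) cs$g51_g52 else cs$g53_g54
    extra <- if (!is.na(config$class_extra[cl])) config$class_extra[[cl]]
      else 0
    stem <- if (length(cls) == 1L) 0 else depth_cl - rad[1] + extra
    sub <- .complex_subtree(cpx_for_class(cl), cl, rad[1], rad[2], stem,
                            shift = config$shift_complex)
    sub$shift <- config$shift_class   # neofunctionalization at the
    sub                               # class-forming duplication
  })
  names(subtrees) <- cls
  if (length(cls) == 1L) {
    tree <- subtrees[[1]]
  } else {
    pair_node <- function(members, depth_pair) {
      .node(children = subtrees[members],
            branch = root_depth - depth_pair,
            shift = config$shift_class)  # dimer duplication
    }
    groups <- list()
    if (all(c("g51", "g52") %in% cls))
      groups <- c(groups, list(pair_node(c("g51", "g52"), cs$g51_g52)))
    else groups <- c(groups, subtrees[intersect(c("g51", "g52"), cls)])
    if (all(c("g53", "g54") %in% cls))
      groups <- c(groups, list(pair_node(c("g53", "g54"), cs$g53_g54)))
    else groups <- c(groups, subtrees[intersect(c("g53", "g54"), cls)])
    if (length(groups) == 1L) {
      tree <- groups[[1]]
      tree$branch <- 0
    } else {
      tree <- .node(children = groups, branch = 0)
    }
  }
  leaves <- .node_leaves(tree)
  labels <- data.frame(
    family = leaves,
    complex = sub("_g5[0-9]+$", "", leaves),
    class = sub("^.*_(g5[0-9]+)$", "\\1", leaves),
    stringsAsFactors = FALSE)
  ev <- list(data.frame(event_kind = "dimer_origin", parent = "root",
                        children = "dimer", time = 1,
                        stringsAsFactors = FALSE))
  rel <- function(d) d / root_depth
  if (all(c("g51", "g52") %in% cls))
    ev <- c(ev, list(data.frame(event_kind = "dimer_duplication",
                                parent = "dimer",
                                children = "g51+g52",
                                time = rel(cs$g51_g52))))
  if (all(c("g53", "g54") %in% cls))
    ev <- c(ev, list(data.frame(event_kind = "dimer_duplication",
                                parent = "dimer",
                                children = "g53+g54",
                                time = rel(cs$g53_g54))))
  k <- length(cpx_for_class(cls[1]))
  if (k > 1L) {
    d <- if (k == 2L) rad[1] else seq(rad[1], rad[2], length.out = k - 1L)
    for (i in seq_len(k - 1L))
      ev <- c(ev, list(data.frame(event_kind = "tetramer_duplication",
                                  parent = "tetramer",
                                  children = paste0("split", i),
                                  time = rel(d[i]))))
  }
  if (!is.null(half)) {
    lost <- setdiff(cls, c("g53", "g54"))
    for (cl in lost)
      ev <- c(ev, list(data.frame(event_kind = "subunit_loss",
                                  parent = half,
                                  children = paste0(half, "_", cl),
                                  time = rel(rad[2]) * 0.9)))
  }
  events <- do.call(rbind, ev)
  structure(list(tree = tree, newick = .node_newick(tree), leaves = leaves,
                 labels = labels, events = events, root_depth = root_depth),
            class = "duplication_history")
}

#' @export
print.duplication_history <- function(x, ...) {
  cat("duplication_history:", length(x$leaves), "families,",
      length(unique(x$labels$class)), "classes,",
      length(unique(x$labels$complex)), "complexes\n")
  invisible(x)
}

# --- sequence evolution ----------------------------------------------------

# state: list(res = integer codes, key = numeric site keys, rate = per-site
# rates, cc = logical coiled-coil flags, hp = heptad register position
# (1-7 for coiled-coil sites, 0 elsewhere))

# stationary heptad emission distributions (columns a-g): propensity-
# sharpened background; coiled-coil replacements draw from these, so the
# segment keeps its heptad character (selection) while its sequence
# diverges - the convergent composition that confounds unmasked searches
.heptad_dist <- function() {
  if (is.null(.ph$heptad_dist)) {
    w <- CC_PROPENSITY^2 * aa_background()
    .ph$heptad_dist <- sweep(w, 2L, colSums(w), "/")
  }
  .ph$heptad_dist
}

.assign_pool <- function(state, pos, cfg, bg = aa_background()) {
  pool <- sort(sample.int(20L, cfg$shift_pool_size, prob = bg))
  state$pool[[pos]] <- pool
  w <- bg[pool]
  state$res[pos] <- pool[sample.int(length(pool), 1L, prob = w / sum(w))]
  state$rate[pos] <- max(state$rate[pos], 1)
  state
}

.evolve_branch <- function(state, t, cfg, cond_cum, shift = 0) {
  if (shift > 0 && cfg$sub_rate_scale > 0) {
    # duplication-triggered neofunctionalization: eligible sites acquire
    # a fresh residue pool (changed functional constraint) and jump to a
    # pool member; substitutions there stay inside the pool
    eligible <- which(!state$cc & state$rate > cfg$core_rate * 1.001)
    hit <- eligible[runif(length(eligible)) < shift]
    for (pos in hit) state <- .assign_pool(state, pos, cfg)
  }
  t <- t * cfg$sub_rate_scale
  if (t <= 0) return(state)
  L <- length(state$res)
  # pool turnover: constrained sites occasionally exchange their pool
  if (cfg$pool_turnover > 0) {
    pooled <- which(!vapply(state$pool, is.null, logical(1)))
    if (length(pooled)) {
      turn <- pooled[runif(length(pooled)) <
                       -expm1(-cfg$pool_turnover * t)]
      for (pos in turn) state <- .assign_pool(state, pos, cfg)
    }
  }
  p <- -expm1(-t * state$rate)
  hit <- which(runif(L) < p)
  if (length(hit)) {
    hcc <- state$cc[hit]
    pooled <- !vapply(state$pool[hit], is.null, logical(1)) & !hcc
    u <- runif(length(hit))
    bodyhit <- hit[!hcc & !pooled]
    if (length(bodyhit))
      state$res[bodyhit] <-
        rowSums(cond_cum[state$res[bodyhit], , drop = FALSE] <
                  u[!hcc & !pooled]) + 1L
    for (pos in hit[pooled]) {
      pool <- state$pool[[pos]]
      w <- aa_conditional()[state$res[pos], pool]
      if (sum(w) <= 0) w <- rep(1, length(pool))
      state$res[pos] <- pool[sample.int(length(pool), 1L,
                                        prob = w / sum(w))]
    }
    cchit <- hit[hcc]
    if (length(cchit)) {
      hd <- .heptad_dist()
      for (s in seq_along(cchit)) {
        pos <- cchit[s]
        state$res[pos] <- sample.int(20L, 1L, prob = hd[, state$hp[pos]])
      }
    }
  }
  if (cfg$indel_rate > 0) {
    n_ev <- rpois(1L, t * cfg$indel_rate * L)
    for (k in seq_len(n_ev)) {
      L <- length(state$res)
      len <- rgeom(1L, 1 / cfg$indel_len_mean) + 1L
      if (runif(1) < 0.5) {  # deletion: only non-cc sites
        cand <- which(!state$cc)
        if (!length(cand)) next
        start <- cand[sample.int(length(cand), 1L)]
        run <- start
        while (length(run) < len && (last <- run[length(run)] + 1L) <= L &&
               !state$cc[last]) run <- c(run, last)
        state$res <- state$res[-run]
        state$key <- state$key[-run]
        state$rate <- state$rate[-run]
        state$cc <- state$cc[-run]
        state$hp <- state$hp[-run]
        state$pool <- state$pool[-run]
      } else {  # insertion: never inside the cc segment
        ok <- c(TRUE, !(state$cc[-L] & state$cc[-1L]), TRUE)
        pts <- which(ok) - 1L  # insertion after position pt (0 = prepend)
        pt <- pts[sample.int(length(pts), 1L)]
        prev_key <- if (pt == 0L) min(state$key) - 1 else state$key[pt]
        next_key <- if (pt == L) max(state$key) + 1 else state$key[pt + 1L]
        u <- sort(runif(len))
        newkey <- prev_key + (next_key - prev_key) * u
        newres <- sample.int(20L, len, replace = TRUE,
                             prob = aa_background())
        newrate <- .draw_rates(len, cfg)
        ins <- function(vec, val) append(vec, val, after = pt)
        state$res <- ins(state$res, newres)
        state$key <- ins(state$key, newkey)
        state$rate <- ins(state$rate, newrate)
        state$cc <- ins(state$cc, rep(FALSE, len))
        state$hp <- ins(state$hp, rep(0L, len))
        state$pool <- append(state$pool, vector("list", len), after = pt)
      }
    }
  }
  state
}

# site rates: a conserved-core fraction at a fixed slow rate, the rest
# gamma-distributed and rescaled so the overall mean stays 1
.draw_rates <- function(n, cfg) {
  core <- runif(n) < cfg$core_frac
  r <- numeric(n)
  r[core] <- cfg$core_rate
  scale <- (1 - cfg$core_frac * cfg$core_rate) /
    max(1 - cfg$core_frac, 1e-9)
  r[!core] <- rgamma(sum(!core), shape = cfg$gamma_shape,
                     rate = cfg$gamma_shape) * scale
  r
}

.root_state <- function(cfg) {
  L <- cfg$seq_length
  bg <- aa_background()
  res <- sample.int(20L, L, replace = TRUE, prob = bg)
  rate <- .draw_rates(L, cfg)
  cc <- rep(FALSE, L)
  hp <- integer(L)
  span <- cfg$cc_start:(cfg$cc_start + cfg$cc_length - 1L)
  cc[span] <- TRUE
  hp[span] <- ((seq_along(span) - 1L) %% 7L) + 1L
  hd <- .heptad_dist()
  for (i in seq_along(span))
    res[span[i]] <- sample.int(20L, 1L, prob = hd[, hp[span[i]]])
  rate[span] <- cfg$cc_rate_scale
  st <- list(res = res, key = as.numeric(seq_len(L)), rate = rate,
             cc = cc, hp = hp, pool = vector("list", L))
  rooted <- which(!cc & runif(L) < cfg$shift_root)
  for (pos in rooted) st <- .assign_pool(st, pos, cfg, bg)
  st
}

# taxa are grouped into clades of (length(clade_split_depths) + 1)
# members; within a clade the splits ladder outward at the configured
# depths, and the clades radiate from the species root. The ladder gives
# every seed taxon progressively more divergent relatives - the role a
# deep sequence database plays for iterative profile enrichment.
.species_tree <- function(cfg) {
  taxa <- paste0("tax", seq_len(cfg$n_taxa))
  k <- length(cfg$clade_split_depths) + 1L
  depths <- sort(cfg$clade_split_depths)
  clade_node <- function(members) {
    nm <- length(members)
    if (nm == 1L) return(.node(members[1], cfg$species_tree_depth))
    d <- depths[seq_len(nm - 1L)]
    nd <- .node(children = list(.node(members[1], d[1]),
                                .node(members[2], d[1])), branch = 0)
    if (nm > 2L) for (i in 2L:(nm - 1L)) {
      nd$branch <- d[i] - d[i - 1L]
      nd <- .node(children = list(nd, .node(members[i + 1L], d[i])),
                  branch = 0)
    }
    nd$branch <- cfg$species_tree_depth - d[nm - 1L]
    nd
  }
  starts <- seq(1L, cfg$n_taxa, by = k)
  kids <- lapply(starts, function(s)
    clade_node(taxa[s:min(s + k - 1L, cfg$n_taxa)]))
  if (length(kids) == 1L) kids[[1]] else .node(children = kids, branch = 0)
}

#' Evolve a synthetic dataset along a duplication history
#'
#' Sequences descend from one ancestral protein through the unit tree to
#' the family ancestors (the LECA analogue) and then along the species
#' tree to every taxon. Per-taxon losses and lineage-specific duplications
#' are applied last. Site identity is tracked through all indels, so the
#' true per-family alignment is recoverable via [truth_msa()].
#'
#' @param history A [simulate_history()] result.
#' @param config The matching [sim_config()].
#' @return An object of class `synthetic_dataset`: `proteomes` (named list
#'   of named character vectors), `truth` (data frame: protein_id, taxon,
#'   complex, class, family, events), `losses`, `history`, `sites` (per
#'   protein, numeric site-identity keys), `cc_sites` (per protein,
#'   logical coiled-coil flags), `config`.
#' @export
evolve_dataset <- function(history, config) {
  validate_sim_config(config)
  cond_cum <- t(apply(aa_conditional(), 1L, cumsum))
  sp_tree <- .species_tree(config)
  with_seed(config$seed, {
    # gene-content events are drawn up front: per taxon at least one
    # family is lost (zero-truncated losses - every lineage in this
    # regime shows absences), and lineage duplications are Bernoulli
    taxa_names <- paste0("tax", seq_len(config$n_taxa))
    n_fam <- length(history$leaves)
    u_loss <- matrix(runif(n_fam * config$n_taxa), n_fam,
                     dimnames = list(history$leaves, taxa_names))
    loss_mat <- u_loss < config$p_loss
    if (config$p_loss > 0)
      for (tx in seq_len(config$n_taxa))
        if (!any(loss_mat[, tx]))
          loss_mat[which.min(u_loss[, tx]), tx] <- TRUE
    dup_mat <- matrix(runif(n_fam * config$n_taxa), n_fam,
                      dimnames = list(history$leaves, taxa_names)) <
      config$p_lineage_dup
    root <- .root_state(config)
    fam_states <- list()
    descend <- function(node, state) {
      state <- .evolve_branch(state, node$branch, config, cond_cum,
                              shift = if (is.null(node$shift)) 0
                                      else node$shift)
      if (length(node$children) == 0L) {
        fam_states[[node$name]] <<- state
      } else {
        for (ch in node$children) descend(ch, state)
      }
    }
    for (ch in if (length(history$tree$children)) history$tree$children
         else list(history$tree))
      descend(ch, root)
    ancestors <- vapply(fam_states, function(st)
      paste(AA_ALPHABET[st$res], collapse = ""), character(1))
    proteomes <- setNames(
      vector("list", config$n_taxa),
      paste0("tax", seq_len(config$n_taxa)))
    for (tx in names(proteomes)) proteomes[[tx]] <- character(0)
    truth <- list()
    losses <- list()
    sites <- list()
    cc_sites <- list()
    lab <- history$labels
    for (fam in history$leaves) {
      fstate <- fam_states[[fam]]
      taxon_states <- list()
      descend_sp <- function(node, state) {
        state <- .evolve_branch(state, node$branch, config, cond_cum)
        if (length(node$children) == 0L) {
          taxon_states[[node$name]] <<- state
        } else {
          for (ch in node$children) descend_sp(ch, state)
        }
      }
      for (ch in if (length(sp_tree$children)) sp_tree$children
           else list(sp_tree))
        descend_sp(ch, fstate)
      row <- lab[lab$family == fam, ]
      for (tx in names(proteomes)) {
        lost <- loss_mat[fam, tx]
        dup <- dup_mat[fam, tx]
        if (lost) {
          losses <- c(losses, list(data.frame(taxon = tx, family = fam,
                                              stringsAsFactors = FALSE)))
          next
        }
        st <- taxon_states[[tx]]
        pid <- paste0(fam, "|", tx)
        proteomes[[tx]][pid] <- paste(AA_ALPHABET[st$res], collapse = "")
        truth <- c(truth, list(data.frame(
          protein_id = pid, taxon = tx, complex = row$complex,
          class = row$class, family = fam, events = "",
          stringsAsFactors = FALSE)))
        sites[[pid]] <- st$key
        cc_sites[[pid]] <- st$cc
        if (dup) {
          st2 <- .evolve_branch(st, config$dup_branch, config, cond_cum)
          pid2 <- paste0(fam, "|", tx, "|d2")
          proteomes[[tx]][pid2] <- paste(AA_ALPHABET[st2$res],
                                         collapse = "")
          truth <- c(truth, list(data.frame(
            protein_id = pid2, taxon = tx, complex = row$complex,
            class = row$class, family = fam, events = "lineage_dup",
            stringsAsFactors = FALSE)))
          sites[[pid2]] <- st2$key
          cc_sites[[pid2]] <- st2$cc
        }
      }
    }
    truth <- do.call(rbind, truth)
    losses <- if (length(losses)) do.call(rbind, losses)
      else data.frame(taxon = character(0), family = character(0))
    structure(list(proteomes = proteomes, truth = truth, losses = losses,
                   history = history, sites = sites, cc_sites = cc_sites,
                   ancestors = ancestors, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$truth), "proteins in",
      length(x$proteomes), "taxa,", length(unique(x$truth$family)),
      "families\n")
  invisible(x)
}

#' One-call simulation
#' @param config A [sim_config()].
#' @return A `synthetic_dataset`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  evolve_dataset(simulate_history(config), config)
}

#' True per-family alignment from site genealogy
#'
#' Reconstructs the gold-standard MSA of a family's proteins from the
#' site-identity keys tracked by the simulator.
#' @param dataset A `synthetic_dataset`.
#' @param family Family id.
#' @return An `msa` object.
#' @export
truth_msa <- function(dataset, family) {
  ids <- dataset$truth$protein_id[dataset$truth$family == family]
  if (!length(ids)) stop("unknown family: ", family)
  keys <- sort(unique(unlist(dataset$sites[ids])))
  seqs <- vapply(ids, function(pid) {
    tx <- dataset$truth$taxon[dataset$truth$protein_id == pid]
    chars <- rep("-", length(keys))
    pos <- match(dataset$sites[[pid]], keys)
    s <- strsplit(dataset$proteomes[[tx]][[pid]], "", fixed = TRUE)[[1]]
    chars[pos] <- s
    paste(chars, collapse = "")
  }, character(1))
  new_msa(ids, unname(seqs))
}

# --- dataset I/O -----------------------------------------------------------

#' Write a synthetic dataset to disk
#'
#' One FASTA per taxon (60-column wrap), `truth.tsv`, and `history.nwk`
#' (Newick of the family/unit tree). The files round-trip through
#' [read_dataset()].
#' @param dataset A `synthetic_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tx in names(dataset$proteomes)) {
    aa <- Biostrings::AAStringSet(dataset$proteomes[[tx]])
    Biostrings::writeXStringSet(aa, file.path(out_dir,
                                              paste0(tx, ".fasta")),
                                width = 60L)
  }
  write.table(dataset$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(dataset$history$newick, file.path(out_dir, "history.nwk"))
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `<taxon>.fasta` files, `truth.tsv` and
#'   `history.nwk`.
#' @return A `synthetic_dataset` (site genealogies, which are in-memory
#'   extras of the simulator, are `NULL`).
#' @export
read_dataset <- function(dir) {
  fastas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(fastas)) stop("no FASTA files in ", dir)
  proteomes <- lapply(fastas, function(f) {
    x <- Biostrings::readAAStringSet(f)
    setNames(as.character(x), names(x))
  })
  names(proteomes) <- sub("\\.fasta$", "", basename(fastas))
  truth <- read.delim(file.path(dir, "truth.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  truth$events[is.na(truth$events)] <- ""
  nwk <- readLines(file.path(dir, "history.nwk"))
  structure(list(proteomes = proteomes, truth = truth, losses = NULL,
                 history = list(newick = nwk,
                                leaves = unique(truth$family),
                                labels = unique(truth[, c("family",
                                                          "complex",
                                                          "class")])),
                 sites = NULL, cc_sites = NULL, config = NULL),
            class = "synthetic_dataset")
}

#' Identity/similarity of simulated orthologs against a reference taxon
#'
#' Globally aligns every ortholog of every family to the family's
#' representative in `reference_taxon` and reports percent identity and
#' similarity per pair (lineage-duplicated extra copies excluded).
#' @param dataset A `synthetic_dataset`.
#' @param reference_taxon Taxon providing the representative (default
#'   first taxon).
#' @param gap_open,gap_extend Gap penalties of the statistic's global
#'   alignment. The defaults are stiffer than the search alignments:
#'   with cheap gap extension the aligner pairs only matching stretches
#'   and the gapless-pair identity of even unrelated sequences floors
#'   near 22%, masking the twilight zone; at (14, 4) unrelated pairs
#'   sit near 13%, so the statistic is informative.
#' @return Data frame: family, protein_id, taxon, identity, similarity.
#' @export
ortholog_identity_stats <- function(dataset,
                                    reference_taxon =
                                      names(dataset$proteomes)[1L],
                                    gap_open = 14, gap_extend = 4) {
  tr <- dataset$truth[dataset$truth$events == "", ]
  out <- list()
  for (fam in unique(tr$family)) {
    sub <- tr[tr$family == fam, ]
    ref <- sub[sub$taxon == reference_taxon, ]
    if (nrow(ref) == 0L) next
    ref_seq <- dataset$proteomes[[reference_taxon]][[ref$protein_id[1L]]]
    oth <- sub[sub$taxon != reference_taxon, ]
    for (i in seq_len(nrow(oth))) {
      seq2 <- dataset$proteomes[[oth$taxon[i]]][[oth$protein_id[i]]]
      st <- pairwise_stats(pairwise_global_align(ref_seq, seq2,
                                                 gap_open = gap_open,
                                                 gap_extend = gap_extend))
      out <- c(out, list(data.frame(
        family = fam, protein_id = oth$protein_id[i], taxon = oth$taxon[i],
        identity = st[["identity"]], similarity = st[["similarity"]],
        stringsAsFactors = FALSE)))
    }
  }
  do.call(rbind, out)
}
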