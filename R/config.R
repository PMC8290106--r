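# Pipeline configuration: a plain nested list, serialisable to YAML and
# reloadable to an identical object.

#' Pipeline configuration
#'
#' Defaults reproduce the published workflow's thresholds: profile
#' enrichment 3 iterations at e <= 1e-5, forward search at 1e-3,
#' reciprocal enrichment 4 iterations at 1e-2, single-sequence route
#' 1e-2 / 1e-3 with coverage > 40%, MSA trimming at 80% gaps, 2/3 clade
#' congruence, network threshold P < 1e-2 with the 300-position /
#' top-4-hit variant, and a -log10(p) weight cap of 20.
#'
#' @param mode `"simulate"` (self-contained synthetic dataset) or
#'   `"user"` (FASTA proteomes plus a seed table).
#' @param seed Integer seed governing every stochastic step.
#' @param sim Named list of [sim_config()] overrides (simulate mode).
#' @param seed_taxa Seed taxa for the three analyses.
#' @param paths Named list for user mode: `proteome_dir` (one FASTA per
#'   taxon), `seed_file` (TSV: family, seed_taxon, seed_id).
#' @param orthology,msa,cc,clustering,align Stage parameter overrides.
#' @return Nested list of class-free structure (YAML round-trippable).
#' @export
pipeline_config <- function(mode = "simulate", seed = 1L, sim = list(),
                            seed_taxa = c("tax1", "tax2", "tax4"),
                            paths = list(proteome_dir = NULL,
                                         seed_file = NULL),
                            orthology = list(), msa = list(), cc = list(),
                            clustering = list(), align = list()) {
  stopifnot(mode %in% c("simulate", "user"))
  o <- utils::modifyList(list(
    iters = 3L, incl_e = 1e-5, fwd_e = 1e-3, recip_iters = 4L,
    recip_incl_e = 1e-2, single_e_fwd = 1e-2, single_e_back = 1e-3,
    min_cov = 0.4), orthology)
  m <- utils::modifyList(list(max_gap_frac = 0.8, pseudocount = 0.1,
                               merge_pseudocount = 1), msa)
  cc_ <- utils::modifyList(list(window = 28L, threshold = 0.5), cc)
  cl <- utils::modifyList(list(
    n_shuffles = 120L, min_frac = 2 / 3, p_max = 1e-2,
    min_aln_len = 300L, top_k = 4L, weight_cap = 20,
    variants = c("masked", "unmasked")), clustering)
  al <- utils::modifyList(list(gap_open = 10, gap_extend = 1,
                               stats_gap_open = 14, stats_gap_extend = 4,
                               band = 64L), align)
  for (nm in c("iters", "recip_iters")) o[[nm]] <- as.integer(o[[nm]])
  cc_$window <- as.integer(cc_$window)
  cl$n_shuffles <- as.integer(cl$n_shuffles)
  cl$min_aln_len <- as.integer(cl$min_aln_len)
  cl$top_k <- as.integer(cl$top_k)
  al$band <- as.integer(al$band)
  cfg <- list(mode = mode, seed = as.integer(seed), sim = sim,
              seed_taxa = as.character(seed_taxa), paths = paths,
              orthology = o, msa = m, cc = cc_, clustering = cl,
              align = al)
  .validate_pipeline_config(cfg)
  cfg
}

.validate_pipeline_config <- function(cfg) {
  thr <- c(cfg$orthology$incl_e, cfg$orthology$fwd_e,
           cfg$orthology$recip_incl_e, cfg$orthology$single_e_fwd,
           cfg$orthology$single_e_back, cfg$clustering$p_max)
  if (any(!is.finite(thr) | thr <= 0))
    stop("configuration error: thresholds must be finite and positive")
  if (cfg$orthology$min_cov < 0 || cfg$orthology$min_cov > 1)
    stop("configuration error: min_cov must lie in [0, 1]")
  if (cfg$msa$max_gap_frac < 0 || cfg$msa$max_gap_frac > 1)
    stop("configuration error: max_gap_frac must lie in [0, 1]")
  if (cfg$clustering$min_frac <= 0.5 || cfg$clustering$min_frac > 1)
    stop("configuration error: min_frac must lie in (0.5, 1]")
  if (!all(cfg$clustering$variants %in% c("masked", "unmasked")) ||
      !"masked" %in% cfg$clustering$variants)
    stop("configuration error: variants must include 'masked'")
  invisible(cfg)
}

#' Save / load a pipeline configuration (YAML)
#'
#' `load_config()` re-applies the [pipeline_config()] constructor, so a
#' saved configuration loads back to an identical object.
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `save_config`: `path` invisibly; `load_config`: the config.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(mode = raw$mode, seed = raw$seed,
                  sim = if (is.null(raw$sim)) list() else raw$sim,
                  seed_taxa = raw$seed_taxa, paths = raw$paths,
                  orthology = raw$orthology, msa = raw$msa, cc = raw$cc,
                  clustering = raw$clustering, align = raw$align)
}
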