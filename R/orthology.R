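# Reciprocal search orthology workflow.
#
# Mirrors the two-pronged strategy used for deeply divergent families:
# (1) profile route - iterative profile enrichment from each seed protein
# against the pooled proteomes, forward best-hit search into every target
# proteome, then a reciprocal check in which the hit is itself enriched
# into a profile and searched back against the seed proteome, requiring
# the rank-1 hit to be the original seed; (2) single-sequence route -
# plain reciprocal best hits from global alignments with a coverage
# filter. Results from the three seed taxa and both routes are combined
# by best e-value, with conflicts flagged instead of manually curated.

.ortho_defaults <- function() {
  list(iters = 3L, incl_e = 1e-5,        # forward profile enrichment
       fwd_e = 1e-3,                     # forward best-hit threshold
       recip_iters = 4L, recip_incl_e = 1e-2,  # reciprocal enrichment
       single_e_fwd = 1e-2, single_e_back = 1e-3, min_cov = 0.4,
       gap_open = 10, gap_extend = 1, band = 64L,
       # search profiles keep light smoothing (sharp columns are what
       # separates a family from the shared superfamily core); merge
       # alignments use strong smoothing or mismatch costs dwarf
       # substitution biology and alignments shred into gap blocks
       pseudocount = 0.1, merge_pseudocount = 1,
       # cap on profile alignment size (best-e members kept), in the
       # spirit of the diversity filtering iterative-search tools apply
       max_members = 20L)
}

#' Iteratively enrich a search profile from a seed protein
#'
#' Jackhmmer-style enrichment: in each round the current profile is
#' searched against the pooled database and targets with
#' `e <= incl_e` are aligned into the seed alignment (in order of
#' significance); the profile is rebuilt and the next round starts.
#' Exactly `iters` rounds are performed; once the member set stops
#' changing the remaining rounds are provably no-ops and are skipped.
#'
#' @param seed_id Seed protein id (must be present in `db_codes`).
#' @param seed_seq Seed sequence string.
#' @param db_codes Named list of integer-coded database sequences.
#' @param iters Number of enrichment rounds (0 = single-sequence profile).
#' @param incl_e Inclusion e-value threshold.
#' @param seed RNG seed for null calibration.
#' @param opts Alignment/search options (see internals).
#' @return List: `profile`, `members` (ids in the alignment), `msa`.
#' @export
build_search_profile <- function(seed_id, seed_seq, db_codes, iters = 3L,
                                 incl_e = 1e-5, seed = 1L,
                                 opts = .ortho_defaults()) {
  msa <- new_msa(seed_id, seed_seq)
  members <- seed_id
  hits <- NULL
  prof <- NULL
  if (iters >= 1L) {
    for (r in seq_len(iters)) {
      prof <- build_profile(msa, pseudocount_weight = opts$pseudocount,
                            source_id = seed_id)
      hits <- search_profile(prof, db_codes,
                             seed = child_seed(seed, paste0(seed_id, r)),
                             gap_open = opts$gap_open,
                             gap_extend = opts$gap_extend,
                             band = opts$band,
                             pseudocount_weight = opts$pseudocount)
      inc <- hits[hits$e_value <= incl_e, , drop = FALSE]
      inc <- inc[order(inc$e_value, inc$target_id), , drop = FALSE]
      inc <- utils::head(inc, opts$max_members)
      new_members <- union(seed_id, inc$target_id)
      if (setequal(new_members, members)) break  # fixed point
      members <- new_members
      msa <- new_msa(seed_id, seed_seq)
      add <- inc$target_id[inc$target_id != seed_id]
      for (tid in add) {
        seq_t <- paste(AA_ALPHABET[db_codes[[tid]]], collapse = "")
        msa <- .align_msa_seq(msa, tid, seq_t, opts$gap_open,
                              opts$gap_extend,
                              pseudocount_weight = opts$merge_pseudocount,
                              band = opts$band)
      }
    }
  }
  if (is.null(prof))
    prof <- build_profile(msa, pseudocount_weight = opts$pseudocount,
                          source_id = seed_id)
  # `hits` is the full-database scan of the final profile (the member set
  # did not change in the last round, so the profile is unchanged too):
  # callers can reuse it as the forward search
  list(profile = prof, members = members, msa = msa, hits = hits)
}

#' Best forward hit of a profile in one target proteome
#'
#' @param search_hits A [search_profile()] result restricted to or
#'   containing the target proteome's proteins.
#' @param proteome_ids Protein ids of the target proteome.
#' @param e_max Threshold; hits above it are ignored.
#' @return One-row data frame (`target_id`, `score`, `p_value`,
#'   `e_value`) or `NULL` when nothing passes (ABSENT). Ties on e-value
#'   are broken by score, then lexicographic id.
#' @export
forward_best_hit <- function(search_hits, proteome_ids, e_max = 1e-3) {
  h <- search_hits[search_hits$target_id %in% proteome_ids &
                     search_hits$e_value <= e_max, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(h$e_value, -h$score, h$target_id), , drop = FALSE]
  h[1L, ]
}

#' Reciprocal validation of a forward hit
#'
#' The hit is enriched into its own profile (`recip_iters` rounds at
#' `recip_incl_e`) against the pooled database and searched back against
#' the seed proteome with no e-value threshold; the check passes when the
#' rank-1 hit is the original seed protein.
#'
#' @param hit_id Forward-hit protein id.
#' @param db_codes Pooled database (integer-coded).
#' @param seed_proteome_ids Ids making up the seed taxon's proteome.
#' @param seed_id The original query.
#' @param recip_iters,recip_incl_e Enrichment settings for the back
#'   profile.
#' @param seed RNG seed.
#' @param cache Optional environment memoising enriched back-profiles by
#'   protein id.
#' @param opts Search options.
#' @return List: `status` (`"reciprocal_ok"` / `"reciprocal_fail"`),
#'   `back_hit` (rank-1 id), `back_score`.
#' @export
reciprocal_check <- function(hit_id, db_codes, seed_proteome_ids, seed_id,
                             recip_iters = 4L, recip_incl_e = 1e-2,
                             seed = 1L, cache = NULL,
                             opts = .ortho_defaults()) {
  if (!length(seed_proteome_ids)) stop("empty seed proteome")
  key <- paste0("rp_", hit_id)
  rp <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
    seq_h <- paste(AA_ALPHABET[db_codes[[hit_id]]], collapse = "")
    val <- build_search_profile(hit_id, seq_h, db_codes,
                                iters = recip_iters,
                                incl_e = recip_incl_e,
                                seed = child_seed(seed, hit_id),
                                opts = opts)
    if (!is.null(cache)) cache[[key]] <- val
    val
  }
  back <- search_profile(rp$profile, db_codes[seed_proteome_ids],
                         gap_open = opts$gap_open,
                         gap_extend = opts$gap_extend, band = opts$band,
                         pseudocount_weight = opts$pseudocount,
                         calibrate = FALSE)
  top <- back[1L, ]
  list(status = if (top$target_id == seed_id) "reciprocal_ok"
       else "reciprocal_fail",
       back_hit = top$target_id, back_score = top$score)
}

# coverage of the query in a global alignment: gapless pairs / query length
.nw_coverage <- function(q_codes, t_codes, matrix, gap_open, gap_extend) {
  res <- nw_affine_cpp(q_codes, t_codes, matrix, gap_open, gap_extend)
  sum(res$a_idx > 0L & res$b_idx > 0L) / length(q_codes)
}

# memoised full-database single-sequence scan; one scan per protein
# provides every forward and reciprocal slice of the single-sequence
# route (per-slice e-values are p * slice size)
.seq_scan <- function(pid, db_codes, cache, seed, opts) {
  key <- paste0("ss_", pid)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  res <- search_sequence(db_codes[[pid]], db_codes,
                         seed = child_seed(seed, paste0("ss", pid)),
                         query_id = pid, gap_open = opts$gap_open,
                         gap_extend = opts$gap_extend, band = opts$band)
  if (!is.null(cache)) cache[[key]] <- res
  res
}

#' Single-sequence reciprocal best hit
#'
#' phmmer-style route: the seed sequence is searched (global alignment
#' scores, shuffled-query Gumbel e-values) against the target proteome;
#' the best hit passing `e_fwd` and query coverage strictly above
#' `min_cov` is searched back against the seed proteome at `e_back`, and
#' must return the seed as rank-1 (with the same coverage rule).
#'
#' @param seed_id,seed_taxon Seed identity.
#' @param db_codes Pooled coded database (provides sequences).
#' @param target_ids,seed_proteome_ids Proteome memberships.
#' @param target_taxon Target taxon name.
#' @param e_fwd,e_back,min_cov Thresholds.
#' @param seed RNG seed.
#' @param cache Optional environment memoising full-database scans per
#'   protein (one scan serves every forward and reciprocal slice).
#' @param opts Search options.
#' @return One-row assignment data frame (`method = "single"`).
#' @export
single_seq_reciprocal <- function(seed_id, seed_taxon, db_codes, target_ids,
                                  target_taxon, seed_proteome_ids,
                                  e_fwd = 1e-2, e_back = 1e-3,
                                  min_cov = 0.4, seed = 1L,
                                  cache = NULL,
                                  opts = .ortho_defaults()) {
  mat <- blosum62()
  absent <- data.frame(family = NA_character_, seed_id = seed_id,
                       seed_taxon = seed_taxon, target_taxon = target_taxon,
                       target_id = NA_character_, e_value = NA_real_,
                       method = "single", status = "absent",
                       stringsAsFactors = FALSE)
  if (!length(target_ids)) return(absent)
  scan <- .seq_scan(seed_id, db_codes, cache, seed, opts)
  fwd <- scan[scan$target_id %in% target_ids, , drop = FALSE]
  fwd$e_value <- fwd$p_value * length(target_ids)
  fwd <- fwd[fwd$e_value <= e_fwd, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    cov <- .nw_coverage(db_codes[[seed_id]], db_codes[[fwd$target_id[i]]],
                        mat, opts$gap_open, opts$gap_extend)
    if (cov > min_cov) { best <- fwd[i, ]; break }
  }
  if (is.null(best)) return(absent)
  back_scan <- .seq_scan(best$target_id, db_codes, cache, seed, opts)
  back <- back_scan[back_scan$target_id %in% seed_proteome_ids, ,
                    drop = FALSE]
  back$e_value <- back$p_value * length(seed_proteome_ids)
  ok <- nrow(back) > 0L && back$target_id[1L] == seed_id &&
    back$e_value[1L] <= e_back &&
    .nw_coverage(db_codes[[best$target_id]], db_codes[[seed_id]], mat,
                 opts$gap_open, opts$gap_extend) > min_cov
  data.frame(family = NA_character_, seed_id = seed_id,
             seed_taxon = seed_taxon, target_taxon = target_taxon,
             target_id = best$target_id, e_value = best$e_value,
             method = "single",
             status = if (ok) "reciprocal_ok" else "reciprocal_fail",
             stringsAsFactors = FALSE)
}

#' Combine per-seed analyses into consensus assignments
#'
#' For every (family, target taxon), the reciprocally validated
#' assignment with the lowest e-value across all seed analyses and both
#' methods wins. Disagreement between validated assignments is flagged
#' `conflict` (the lowest-e target is still reported); a pair validated
#' by both methods is labelled method `both`. ABSENT only when every
#' analysis came up empty.
#'
#' @param analyses Data frame of per-seed assignment rows (columns:
#'   family, seed_id, seed_taxon, target_taxon, target_id, e_value,
#'   method, status).
#' @return Combined data frame, one row per family x target taxon.
#' @export
combine_seed_analyses <- function(analyses) {
  stopifnot(nrow(analyses) > 0L)
  out <- list()
  for (fam in sort(unique(analyses$family))) {
    sub_f <- analyses[analyses$family == fam, , drop = FALSE]
    for (tt in sort(unique(sub_f$target_taxon))) {
      sub <- sub_f[sub_f$target_taxon == tt, , drop = FALSE]
      ok <- sub[sub$status == "reciprocal_ok" & !is.na(sub$target_id), ,
                drop = FALSE]
      if (nrow(ok) == 0L) {
        status <- if (all(sub$status == "absent")) "absent"
          else "reciprocal_fail"
        out <- c(out, list(data.frame(
          family = fam, target_taxon = tt, target_id = NA_character_,
          e_value = NA_real_, method = NA_character_, status = status,
          n_support = 0L, stringsAsFactors = FALSE)))
        next
      }
      ok <- ok[order(ok$e_value, ok$target_id), , drop = FALSE]
      chosen <- ok[1L, ]
      agree <- ok[ok$target_id == chosen$target_id, , drop = FALSE]
      conflict <- length(unique(ok$target_id)) > 1L
      out <- c(out, list(data.frame(
        family = fam, target_taxon = tt, target_id = chosen$target_id,
        e_value = chosen$e_value,
        method = if (length(unique(agree$method)) > 1L) "both"
          else chosen$method,
        status = if (conflict) "conflict" else "reciprocal_ok",
        n_support = nrow(agree), stringsAsFactors = FALSE)))
    }
  }
  do.call(rbind, out)
}

#' Ortholog count table (taxon x family)
#'
#' Counts co-orthologs: all distinct target proteins of a taxon that were
#' reciprocally validated for a family by any analysis (the
#' lineage-duplication scan). Absences are 0.
#'
#' @param assignments Per-seed long assignment table (including secondary
#'   co-ortholog rows from the duplication scan).
#' @param families,taxa Row/column universe (defaults: observed values).
#' @return Integer matrix families x taxa.
#' @export
build_ortholog_table <- function(assignments,
                                 families = sort(unique(assignments$family)),
                                 taxa =
                                   sort(unique(assignments$target_taxon))) {
  tab <- matrix(0L, length(families), length(taxa),
                dimnames = list(families, taxa))
  ok <- assignments[assignments$status %in% c("reciprocal_ok", "conflict") &
                      !is.na(assignments$target_id), , drop = FALSE]
  for (i in seq_len(nrow(ok))) {
    f <- ok$family[i]
    t <- ok$target_taxon[i]
    if (f %in% families && t %in% taxa) {
      ids <- unique(ok$target_id[ok$family == f & ok$target_taxon == t])
      tab[f, t] <- length(ids)
    }
  }
  tab
}

#' Run the full orthology workflow on a set of proteomes
#'
#' Executes both routes (profile and single-sequence) from every seed
#' protein of every seed taxon against every target taxon, with a
#' secondary scan of further passing forward hits for lineage
#' duplications (co-orthologs), and combines everything by best e-value.
#'
#' @param proteomes Named list (taxon) of named character vectors.
#' @param seeds Data frame: `family`, `seed_taxon`, `seed_id` - the known
#'   subunit annotations of the seed taxa the analysis starts from.
#' @param params List overriding `.ortho_defaults()` entries.
#' @param seed Integer RNG seed.
#' @param log_con Optional connection for run logging.
#' @return List: `per_seed` (long table of all per-seed assignments incl.
#'   co-ortholog rows), `combined` ([combine_seed_analyses()] over best
#'   hits), `table` ([build_ortholog_table()]), `profiles` (enrichment
#'   profile per seed id).
#' @export
run_orthology <- function(proteomes, seeds, params = list(), seed = 1L,
                          log_con = NULL) {
  opts <- utils::modifyList(.ortho_defaults(), params)
  db <- unlist(unname(proteomes))
  db_codes <- code_proteome(db)
  taxon_of <- rep(names(proteomes), vapply(proteomes, length, integer(1)))
  names(taxon_of) <- names(db)
  cache <- new.env(parent = emptyenv())
  rows <- list()
  profiles <- list()
  for (k in seq_len(nrow(seeds))) {
    fam <- seeds$family[k]
    stax <- seeds$seed_taxon[k]
    sid <- seeds$seed_id[k]
    seed_ids <- names(db)[taxon_of == stax]
    enr <- build_search_profile(sid, db[[sid]], db_codes,
                                iters = opts$iters, incl_e = opts$incl_e,
                                seed = child_seed(seed, sid), opts = opts)
    profiles[[sid]] <- enr
    fwd_all <- if (!is.null(enr$hits)) enr$hits else
      search_profile(enr$profile, db_codes,
                     seed = child_seed(seed, paste0("fw", sid)),
                     gap_open = opts$gap_open,
                     gap_extend = opts$gap_extend, band = opts$band,
                     pseudocount_weight = opts$pseudocount)
    for (tt in names(proteomes)) {
      t_ids <- names(db)[taxon_of == tt]
      cand <- fwd_all[fwd_all$target_id %in% t_ids &
                        fwd_all$e_value <= opts$fwd_e, , drop = FALSE]
      cand <- cand[order(cand$e_value, -cand$score, cand$target_id), ,
                   drop = FALSE]
      # duplication scan: beyond the best hit, only candidates with
      # comparable support are plausible co-orthologs (lineage copies
      # diverge little); remote also-rans are not worth a reciprocal
      # profile
      if (nrow(cand) > 1L)
        cand <- cand[c(TRUE, cand$score[-1L] >= 0.5 * cand$score[1L]), ,
                     drop = FALSE]
      cand <- utils::head(cand, 3L)  # co-ortholog scan depth
      if (nrow(cand) == 0L) {
        rows <- c(rows, list(data.frame(
          family = fam, seed_id = sid, seed_taxon = stax,
          target_taxon = tt, target_id = NA_character_,
          e_value = NA_real_, method = "profile", status = "absent",
          rank = 1L, stringsAsFactors = FALSE)))
      } else {
        for (i in seq_len(nrow(cand))) {
          rc <- reciprocal_check(cand$target_id[i], db_codes, seed_ids,
                                 sid, recip_iters = opts$recip_iters,
                                 recip_incl_e = opts$recip_incl_e,
                                 seed = seed, cache = cache, opts = opts)
          rows <- c(rows, list(data.frame(
            family = fam, seed_id = sid, seed_taxon = stax,
            target_taxon = tt, target_id = cand$target_id[i],
            e_value = cand$e_value[i], method = "profile",
            status = rc$status, rank = i, stringsAsFactors = FALSE)))
        }
      }
      single <- single_seq_reciprocal(sid, stax, db_codes, t_ids, tt,
                                      seed_ids, e_fwd = opts$single_e_fwd,
                                      e_back = opts$single_e_back,
                                      min_cov = opts$min_cov, seed = seed,
                                      cache = cache, opts = opts)
      single$family <- fam
      single$rank <- 1L
      rows <- c(rows, list(single[, c("family", "seed_id", "seed_taxon",
                                      "target_taxon", "target_id",
                                      "e_value", "method", "status",
                                      "rank")]))
    }
    .log_line(log_con, "orthology seed ", sid, ": ",
              length(enr$members), " profile members")
  }
  per_seed <- do.call(rbind, rows)
  combined <- combine_seed_analyses(per_seed[per_seed$rank == 1L, ,
                                             drop = FALSE])
  tab <- build_ortholog_table(per_seed,
                              families = sort(unique(seeds$family)),
                              taxa = names(proteomes))
  list(per_seed = per_seed, combined = combined, table = tab,
       profiles = profiles)
}
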