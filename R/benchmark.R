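#' Enrichment factor
#'
#' Ratio of retrieved actives to retrieved decoys, normalised by the
#' dataset's active/decoy ratio:
#' \deqn{EF = (a / d) / (A / D)}
#' This is the `"printed"` convention. The more common alternative,
#' `"standard"`, normalises by retrieved-set and dataset sizes:
#' `(a / (a + d)) / (A / (A + D))`. Under the printed convention a zero
#' decoy count with `a > 0` is kept finite by substituting `d = 1` and
#' raising the degeneracy flag; `a = 0` always gives EF 0.
#'
#' @param a,d Actives and decoys retrieved at the level (0 <= a <= A, etc.).
#' @param A,D Total actives and decoys of the target (both >= 1).
#' @param convention `"printed"` (default) or `"standard"`.
#' @return List with `ef` and logical `degenerate_d_zero`.
#' @export
enrichment_factor <- function(a, d, A, D,
                              convention = c("printed", "standard")) {
  convention <- match.arg(convention)
  if (A < 1 || D < 1) .stopf("A and D must both be >= 1")
  if (a < 0 || d < 0 || a > A || d > D)
    .stopf("need 0 <= a <= A and 0 <= d <= D")
  flag <- FALSE
  if (a == 0) {
    ef <- 0
  } else if (convention == "printed") {
    dd <- d
    if (dd == 0) { dd <- 1; flag <- TRUE }
    ef <- (a / dd) / (A / D)
  } else {
    ef <- (a / (a + d)) / (A / (A + D))
  }
  list(ef = ef, degenerate_d_zero = flag)
}

#' Benchmark molecule and target set containers
#'
#' A benchmark molecule bundles the conformer ensemble of one compound with
#' its pharmacophore subsets (one subsets object per conformer). A target
#' set holds the actives and decoys of one screening target with disjoint
#' identifier sets; every active must provide conformer 0 (its
#' lowest-energy conformer), which is the only geometry used as a query.
#'
#' @param mol_id Identifier.
#' @param conformers List of [conformer_record()]s, conf_ids 0, 1, ...
#' @param subsets List of [pharmacophore_subsets()] parallel to `conformers`.
#' @export
benchmark_molecule <- function(mol_id, conformers, subsets) {
  if (length(conformers) < 1L) .stopf("molecule '%s' has no conformers", mol_id)
  if (length(subsets) != length(conformers))
    .stopf("need one subsets object per conformer for '%s'", mol_id)
  structure(list(mol_id = as.character(mol_id), conformers = conformers,
                 subsets = subsets), class = "benchmark_molecule")
}

#' @rdname benchmark_molecule
#' @param target_id Target identifier.
#' @param actives,decoys Lists of `benchmark_molecule`s (A >= 1, D >= 1).
#' @export
target_set <- function(target_id, actives, decoys) {
  if (length(actives) < 1L || length(decoys) < 1L)
    .stopf("target set needs at least one active and one decoy")
  aid <- vapply(actives, `[[`, "", "mol_id")
  did <- vapply(decoys, `[[`, "", "mol_id")
  if (anyDuplicated(c(aid, did)))
    .stopf("active and decoy mol_ids must be disjoint and unique")
  structure(list(target_id = as.character(target_id), actives = actives,
                 decoys = decoys), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %s: %d actives, %d decoys\n", x$target_id,
              length(x$actives), length(x$decoys)))
  invisible(x)
}

#' Screening method plug-ins
#'
#' A screening method encodes how molecules are represented and compared.
#' `screen_method_usrcat()` scores 60-element USRCAT vectors with
#' [usrcat_similarity()] and supports the probe-radius prefilter;
#' `screen_method_usr()` is its classic-USR special case (all-atom weight 1,
#' pharmacophore weights 0). `screen_method_fingerprint()` compares
#' topological fingerprints by Tanimoto similarity (no prefilter; requires
#' records with SDF blocks and the chemistry backend).
#'
#' @param weights [usrcat_weights()].
#' @param hydrogens Hydrogen policy for descriptor computation.
#' @export
screen_method_usrcat <- function(weights = usrcat_weights(),
                                 hydrogens = "exclude") {
  w <- .as_weights(weights)
  structure(list(
    name = sprintf("usrcat[%s]", paste(signif(w, 3), collapse = ",")),
    prepare = function(mols) {
      t(vapply(mols, function(m)
        usrcat_descriptor(m$record, m$subsets, hydrogens), numeric(60)))
    },
    score_all = function(query_i, ctx, idx) {
      .score_rows(ctx[idx, , drop = FALSE], ctx[query_i, ], w)
    },
    prefilter = function(query_i, ctx, idx, radius) {
      dif <- abs(sweep(ctx[idx, 1:12, drop = FALSE], 2, ctx[query_i, 1:12]))
      idx[rowSums(dif > radius) == 0L]
    }
  ), class = "screen_method")
}

#' @rdname screen_method_usrcat
#' @export
screen_method_usr <- function(hydrogens = "exclude") {
  m <- screen_method_usrcat(usrcat_weights(1, 0, 0, 0, 0), hydrogens)
  m$name <- "usr"
  m
}

#' @rdname screen_method_usrcat
#' @param fp_kind,nbits Fingerprint kind and length, see
#'   [tanimoto_topological()].
#' @export
screen_method_fingerprint <- function(fp_kind = "circular", nbits = 2048L) {
  structure(list(
    name = sprintf("fingerprint[%s/%d]", fp_kind, nbits),
    prepare = function(mols) {
      sdf <- vapply(mols, function(m) {
        if (is.null(m$record$sdf))
          .stopf("fingerprint method needs SDF blocks ('%s' has none)",
                 m$record$mol_id)
        m$record$sdf
      }, "")
      .fingerprint_bits(sdf, fp_kind, nbits)
    },
    score_all = function(query_i, ctx, idx) {
      q <- ctx[[query_i]]
      vapply(ctx[idx], function(b) .tanimoto_bits(q, b), 0)
    },
    prefilter = NULL
  ), class = "screen_method")
}

# flatten a target set to per-conformer rows with an active flag
.bench_rows <- function(ts) {
  rows <- list()
  for (role in c("actives", "decoys")) {
    for (mol in ts[[role]]) {
      for (k in seq_along(mol$conformers)) {
        rows[[length(rows) + 1L]] <- list(
          mol_id = mol$mol_id,
          conf_id = mol$conformers[[k]]$conf_id,
          record = mol$conformers[[k]],
          subsets = mol$subsets[[k]],
          is_active = role == "actives")
      }
    }
  }
  rows
}

#' Run a retrospective screening benchmark on one target
#'
#' Every active is used once as a query: its conformer 0 (the lowest-energy
#' conformer) is screened against all conformers of all other actives and
#' decoys — every conformer of the query molecule is excluded to avoid an
#' artificial self-retrieval boost. Molecule scores are collapsed to the
#' best conformer, ranked deterministically, and enrichment factors are
#' computed at each percentage level over the top `ceil(level/100 * M)`
#' molecules, `M` being the number of molecules screened. A probe-radius
#' prefilter (via `cfg$probe_radius`) can shrink the candidate list below
#' the cut, in which case fewer molecules are retrieved.
#'
#' @param ts [target_set()].
#' @param method A screening method plug-in, e.g. [screen_method_usrcat()].
#' @param cfg [screen_config()] (its `top_k`/`top_fraction` is ignored; the
#'   levels drive the cuts).
#' @param levels Percentage levels, default `c(1, 0.5, 0.25)`.
#' @param ef_convention Passed to [enrichment_factor()].
#' @return List of class `benchmark_result` with `ef` (one row per query and
#'   level: `target_id, query_mol_id, level, a, d, ef, degenerate_d_zero,
#'   all_tied`) and `hits` (the retrieved molecules per query and level).
#' @export
run_benchmark <- function(ts, method = screen_method_usrcat(),
                          cfg = screen_config(), levels = c(1, 0.5, 0.25),
                          ef_convention = c("printed", "standard")) {
  ef_convention <- match.arg(ef_convention)
  stopifnot(inherits(ts, "target_set"))
  rows <- .bench_rows(ts)
  mol_ids <- vapply(rows, `[[`, "", "mol_id")
  conf_ids <- vapply(rows, function(r) as.integer(r$conf_id), 0L)
  is_active_row <- vapply(rows, `[[`, TRUE, "is_active")
  active_flag <- tapply(is_active_row, mol_ids, any)
  A <- length(ts$actives)
  D <- length(ts$decoys)
  ctx <- method$prepare(rows)
  ef_out <- list(); hit_out <- list()
  for (mol in ts$actives) {
    qrow <- which(mol_ids == mol$mol_id & conf_ids == 0L)
    if (length(qrow) != 1L)
      .stopf("active '%s' has no conformer 0 to use as query", mol$mol_id)
    idx <- which(mol_ids != mol$mol_id)
    m_screened <- length(unique(mol_ids[idx]))
    cand <- idx
    if (!is.null(cfg$probe_radius)) {
      if (is.null(method$prefilter))
        .stopf("method '%s' does not support a probe-radius prefilter",
               method$name)
      cand <- method$prefilter(qrow, ctx, idx, cfg$probe_radius)
    }
    if (length(cand)) {
      scores <- method$score_all(qrow, ctx, cand)
      all_tied <- length(scores) > 1L && diff(range(scores)) == 0
      full_cfg <- screen_config(cfg$weights, top_fraction = 1,
                                conformer_collapse = TRUE)
      ranked <- .rank_hits(mol_ids[cand], conf_ids[cand], scores, full_cfg)
    } else {
      all_tied <- FALSE
      ranked <- .empty_hits()
    }
    for (lev in levels) {
      n_cut <- min(ceiling(lev / 100 * m_screened), nrow(ranked))
      top <- utils::head(ranked, n_cut)
      a <- sum(active_flag[top$mol_id])
      d <- nrow(top) - a
      ef <- enrichment_factor(a, d, A, D, ef_convention)
      ef_out[[length(ef_out) + 1L]] <- data.frame(
        target_id = ts$target_id, query_mol_id = mol$mol_id, level = lev,
        a = a, d = d, ef = ef$ef, degenerate_d_zero = ef$degenerate_d_zero,
        all_tied = all_tied, stringsAsFactors = FALSE)
      if (nrow(top))
        hit_out[[length(hit_out) + 1L]] <- data.frame(
          target_id = ts$target_id, query_mol_id = mol$mol_id, level = lev,
          rank = top$rank, mol_id = top$mol_id, conf_id = top$conf_id,
          score = top$score, is_active = unname(active_flag[top$mol_id]),
          stringsAsFactors = FALSE)
    }
  }
  structure(list(
    ef = do.call(rbind, ef_out),
    hits = if (length(hit_out)) do.call(rbind, hit_out) else NULL,
    method = method$name
  ), class = "benchmark_result")
}

#' Two-stage enrichment-factor averages
#'
#' Per-target unweighted mean over queries, then an unweighted mean over
#' targets (so targets with many actives do not dominate).
#'
#' @param records EF data frame(s) as produced by [run_benchmark()] (`$ef`),
#'   possibly row-bound over several targets.
#' @return List with `per_target` and `overall` data frames.
#' @export
average_ef <- function(records) {
  if (inherits(records, "benchmark_result")) records <- records$ef
  if (is.null(records) || nrow(records) == 0L) .stopf("no EF records")
  per_target <- stats::aggregate(ef ~ target_id + level, data = records,
                                 FUN = mean)
  overall <- stats::aggregate(ef ~ level, data = per_target, FUN = mean)
  names(per_target)[names(per_target) == "ef"] <- "mean_ef"
  names(overall)[names(overall) == "ef"] <- "mean_ef"
  list(per_target = per_target[order(per_target$target_id,
                                     -per_target$level), ],
       overall = overall[order(-overall$level), ])
}

#' Scaffold-hopping counts
#'
#' For each active query, the number of actives retrieved by the shape
#' method at the given EF level that the topological-fingerprint method did
#' not retrieve at the same level. Queries for which either method
#' retrieved zero actives are excluded; targets with no eligible queries
#' are reported with `n_queries = 0` and `NA` statistics.
#'
#' @param shape_hits,fp_hits `hits` data frames from [run_benchmark()] for
#'   the two methods, covering the same queries.
#' @param level EF level (percent) to analyse.
#' @return Data frame: `target_id, n_queries, min, max, avg`.
#' @export
scaffold_hop_counts <- function(shape_hits, fp_hits, level) {
  if (inherits(shape_hits, "benchmark_result")) shape_hits <- shape_hits$hits
  if (inherits(fp_hits, "benchmark_result")) fp_hits <- fp_hits$hits
  sh <- shape_hits[shape_hits$level == level, , drop = FALSE]
  fh <- fp_hits[fp_hits$level == level, , drop = FALSE]
  key <- function(h) unique(h[, c("target_id", "query_mol_id")])
  ks <- key(sh); kf <- key(fh)
  if (!setequal(paste(ks$target_id, ks$query_mol_id),
                paste(kf$target_id, kf$query_mol_id)))
    .stopf("shape and fingerprint registries cover different query sets")
  out <- list()
  for (tid in unique(ks$target_id)) {
    queries <- unique(ks$query_mol_id[ks$target_id == tid])
    counts <- integer(0)
    for (q in queries) {
      sa <- unique(sh$mol_id[sh$target_id == tid & sh$query_mol_id == q &
                               sh$is_active])
      fa <- unique(fh$mol_id[fh$target_id == tid & fh$query_mol_id == q &
                               fh$is_active])
      if (length(sa) == 0L || length(fa) == 0L) next  # exclusion rule
      counts <- c(counts, length(setdiff(sa, fa)))
    }
    out[[length(out) + 1L]] <- if (length(counts)) {
      data.frame(target_id = tid, n_queries = length(counts),
                 min = min(counts), max = max(counts), avg = mean(counts),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(target_id = tid, n_queries = 0L, min = NA_integer_,
                 max = NA_integer_, avg = NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Probe-radius sweep
#'
#' Re-runs the benchmark with the bounding-box prefilter at each radius and
#' once without any prefilter (reported as radius `Inf`). As the radius
#' grows the candidate boxes cover the whole table and the mean enrichment
#' factors converge to — and finally equal — the linear-scan values.
#'
#' @inheritParams run_benchmark
#' @param radii Nonnegative radii, sorted increasing.
#' @return Data frame `radius, level, mean_ef` (radius `Inf` = no prefilter).
#' @export
probe_radius_sweep <- function(ts, radii, method = screen_method_usrcat(),
                               cfg = screen_config(),
                               levels = c(1, 0.5, 0.25),
                               ef_convention = "printed") {
  if (any(radii < 0) || is.unsorted(radii))
    .stopf("radii must be nonnegative and sorted increasing")
  one <- function(r) {
    cfg_r <- cfg
    cfg_r$probe_radius <- if (is.finite(r)) r else NULL
    res <- run_benchmark(ts, method, cfg_r, levels, ef_convention)
    av <- average_ef(res$ef)$overall
    data.frame(radius = r, level = av$level, mean_ef = av$mean_ef)
  }
  out <- do.call(rbind, lapply(c(radii, Inf), one))
  rownames(out) <- NULL
  out
}
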