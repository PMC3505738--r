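test_that("enrichment factor arithmetic follows the printed formula", {
  expect_equal(enrichment_factor(2, 8, 10, 500)$ef, 12.5)
  # retrieval at the dataset ratio is the normalisation point
  expect_equal(enrichment_factor(1, 50, 10, 500)$ef, 1)
  # zero retrieved decoys: d := 1 with the degeneracy flag
  deg <- enrichment_factor(3, 0, 10, 500)
  expect_equal(deg$ef, 150)
  expect_true(deg$degenerate_d_zero)
  expect_equal(enrichment_factor(0, 5, 10, 500)$ef, 0)
  expect_error(enrichment_factor(1, 1, 0, 10), ">= 1")
  expect_error(enrichment_factor(11, 0, 10, 500), "a <= A")
  # standard convention for comparison
  expect_equal(enrichment_factor(2, 8, 10, 500, "standard")$ef,
               (2 / 10) / (10 / 510))
})

test_that("EF is scale-consistent under dataset duplication", {
  # duplicating every entry of a fixed ranking and doubling the cut doubles
  # a and d, leaving EF unchanged at matched fractional levels
  set.seed(31)
  ranking <- sample(c(rep(TRUE, 10), rep(FALSE, 490)))
  for (cut in c(5, 13, 50)) {
    a <- sum(ranking[1:cut]); d <- cut - a
    dup <- rep(ranking, each = 2)
    a2 <- sum(dup[1:(2 * cut)]); d2 <- 2 * cut - a2
    expect_equal(enrichment_factor(a2, d2, 20, 980)$ef,
                 enrichment_factor(a, d, 10, 490)$ef)
  }
})

test_that("two-stage EF averaging is per-target then overall", {
  rec <- data.frame(
    target_id = c("t1", "t1", "t1", "t2"),
    query_mol_id = c("q1", "q2", "q3", "q4"),
    level = 1, a = 1, d = 1,
    ef = c(1, 2, 3, 4), degenerate_d_zero = FALSE, all_tied = FALSE)
  av <- average_ef(rec)
  expect_equal(av$per_target$mean_ef, c(2, 4))
  # unweighted over targets: (2 + 4) / 2, not the query-weighted 2.5
  expect_equal(av$overall$mean_ef, 3)
  single <- average_ef(rec[1, ])
  expect_equal(single$overall$mean_ef, 1)
  # oracle recomputation on random records across targets and levels
  set.seed(3)
  rnd <- data.frame(target_id = rep(c("a", "b", "c"), each = 4),
                    query_mol_id = rep(c("q1", "q2"), 6),
                    level = rep(c(1, 0.25), each = 2),
                    a = 0, d = 0, ef = runif(12, 0, 20),
                    degenerate_d_zero = FALSE, all_tied = FALSE)
  av <- average_ef(rnd)
  for (lv in c(1, 0.25)) {
    manual <- mean(vapply(c("a", "b", "c"), function(t) {
      mean(rnd$ef[rnd$target_id == t & rnd$level == lv])
    }, 0))
    expect_equal(av$overall$mean_ef[av$overall$level == lv], manual)
  }
})

test_that("random rankings give mean EF compatible with 1", {
  set.seed(77)
  n_shuffle <- 500
  efs <- vapply(seq_len(n_shuffle), function(i) {
    ranking <- sample(c(rep(TRUE, 10), rep(FALSE, 490)))
    a <- sum(ranking[1:5])  # 1% of 500
    # the standard convention is centred on 1 for random retrieval
    enrichment_factor(a, 5 - a, 10, 490, convention = "standard")$ef
  }, 0)
  # EF_standard = 10a with a ~ Hypergeom(N=500, K=10, n=5): the null fully
  # specifies the sampling variance, so use the theoretical standard error
  var_a <- 5 * (10 / 500) * (490 / 500) * (495 / 499)
  se <- sqrt(100 * var_a / n_shuffle)
  expect_lt(abs(mean(efs) - 1), 3 * se)
})

test_that("benchmark excludes the query, collapses molecules and is deterministic", {
  spec <- fixture_spec(seed = 21, n_actives = 4, n_decoys = 12,
                       n_atoms = c(8, 8))
  ts <- build_benchmark_set(spec)
  res <- run_benchmark(ts, levels = c(25, 100))
  # the query molecule never appears in its own hit list
  for (q in unique(res$hits$query_mol_id))
    expect_false(q %in% res$hits$mol_id[res$hits$query_mol_id == q])
  # hit lists contain molecules, not conformer duplicates
  h1 <- res$hits[res$hits$query_mol_id == "active_001" &
                   res$hits$level == 100, ]
  expect_identical(anyDuplicated(h1$mol_id), 0L)
  expect_equal(nrow(h1), 15)  # all other molecules retrieved at 100%
  # whole-database retrieval: a and d are the full counts minus the query
  e1 <- res$ef[res$ef$query_mol_id == "active_001" & res$ef$level == 100, ]
  expect_equal(e1$a, 3)
  expect_equal(e1$d, 12)
  # byte-identical EF tables on a rebuilt, re-run benchmark
  res2 <- run_benchmark(build_benchmark_set(spec), levels = c(25, 100))
  expect_identical(res$ef, res2$ef)
})

test_that("indistinguishable actives and decoys raise the all-tied flag", {
  spec <- fixture_spec(seed = 5, n_atoms = c(6, 6), n_actives = 2,
                       n_decoys = 3, jitter_sigma = 0, twin_fraction = 0,
                       n_conformers = 1)
  tpl <- generate_cloud(spec, "tpl")
  mk <- function(id) benchmark_molecule(id, list(conformer_record(
    id, 0, tpl$record$coords)), list(tpl$subsets))
  ts <- target_set("degenerate", lapply(c("a1", "a2"), mk),
                   lapply(c("d1", "d2", "d3"), mk))
  res <- run_benchmark(ts, levels = 100)
  expect_true(all(res$ef$all_tied))
  expect_true(all(res$hits$score == 1))
})

test_that("missing query conformer 0 is an error naming the active", {
  spec <- fixture_spec(seed = 5, n_actives = 2, n_decoys = 2)
  ts <- build_benchmark_set(spec)
  ts$actives[[1]]$conformers[[1]]$conf_id <- 5L
  expect_error(run_benchmark(ts), "active_001.*no conformer 0")
})

test_that("scaffold-hop counting matches hand-built registries", {
  reg <- function(counts, shared = 2) {
    # build shape/fp hit registries where query qi has counts[i] actives
    # retrieved by shape only, plus `shared` actives retrieved by both
    rows_s <- list(); rows_f <- list()
    for (i in seq_along(counts)) {
      q <- sprintf("q%02d", i)
      shared_ids <- sprintf("both_%02d_%d", i, seq_len(shared))
      only_ids <- if (counts[i] > 0)
        sprintf("only_%02d_%d", i, seq_len(counts[i])) else character()
      rows_s[[i]] <- data.frame(target_id = "CDK2", query_mol_id = q,
                                level = 0.25,
                                rank = seq_along(c(shared_ids, only_ids)),
                                mol_id = c(shared_ids, only_ids),
                                conf_id = 0L, score = 0.9, is_active = TRUE)
      rows_f[[i]] <- data.frame(target_id = "CDK2", query_mol_id = q,
                                level = 0.25, rank = seq_along(shared_ids),
                                mol_id = shared_ids, conf_id = 0L,
                                score = 0.9, is_active = TRUE)
    }
    list(shape = do.call(rbind, rows_s), fp = do.call(rbind, rows_f))
  }
  # counts shaped like a published summary row: min 1, max 25, avg 6.48
  counts <- c(1, 25, 6, 2, 12, 4, 1, 2, 15, 2, 8, 4, 6, 25, 1, 5, 9, 1, 4, 3,
              2, 6, 8, 5, 22, 2, 4, 7, 3, 6, 13, 1, 2, 5, 4, 3, 2, 18, 6, 1,
              24, 2, 3, 1, 8, 2, 5, 17, 2, 4)
  stopifnot(abs(mean(counts) - 6.48) < 1e-9)
  r <- reg(counts)
  hop <- scaffold_hop_counts(r$shape, r$fp, 0.25)
  expect_equal(hop$min, 1)
  expect_equal(hop$max, 25)
  expect_equal(hop$avg, 6.48, tolerance = 1e-9)
  expect_equal(hop$n_queries, length(counts))
  # identical registries: zero exclusive hits everywhere
  same <- scaffold_hop_counts(r$shape, r$shape, 0.25)
  expect_identical(c(same$min, same$max, same$avg), c(0, 0, 0))
  # queries where one method finds no actives are excluded; none eligible
  # yields the explicit empty summary
  fp_none <- r$fp
  fp_none$is_active <- FALSE
  none <- scaffold_hop_counts(r$shape, fp_none, 0.25)
  expect_identical(none$n_queries, 0L)
  expect_true(is.na(none$avg))
  bad <- r$fp[r$fp$query_mol_id != "q01", ]
  expect_error(scaffold_hop_counts(r$shape, bad, 0.25), "different query")
})

test_that("fingerprint similarities are sane and pinned as regressions", {
  eth <- read_conformers(fixture_path("ethanol.sdf"))[[1]]
  prop <- read_conformers(fixture_path("propanol.sdf"))[[1]]
  expect_identical(tanimoto_topological(eth, eth), 1)
  t_cp <- tanimoto_topological(eth, prop, "circular")
  expect_true(t_cp > 0 && t_cp < 1)
  expect_identical(tanimoto_topological(eth, prop, "circular"), t_cp)
  # regression pins for the shipped backend (RDKit 2024.09)
  expect_equal(t_cp, 5 / 9, tolerance = 1e-12)
  expect_equal(tanimoto_topological(eth, prop, "maccs"), 9 / 14,
               tolerance = 1e-12)
  for (kind in c("path", "tree")) {
    v <- tanimoto_topological(eth, prop, kind)
    expect_true(v > 0 && v <= 1)
  }
  expect_error(tanimoto_topological(eth, prop, "hose"), "unsupported")
})
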