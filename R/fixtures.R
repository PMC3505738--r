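#' Synthetic fixture specification
#'
#' Parameters of the seeded generators that stand in for conformer data:
#' labelled 3D point clouds, label-permuted shape twins, and active/decoy
#' benchmark sets. Every generator output is a pure function of the spec
#' (including its seed).
#'
#' The defaults define the package's reference study conditions: 10 actives
#' built as label-preserving jittered copies of one template, 200 decoys
#' built entirely as label-permuted shape twins with the same jitter
#' (`twin_fraction = 1`), coordinate jitter of 0.15 Angstroms, and
#' drug-like heavy-atom counts (10-25). Label probabilities approximate a
#' drug-like feature balance — roughly half the heavy atoms hydrophobic, a
#' third aromatic, with donors scarcer than acceptors.
#'
#' @param seed Integer seed.
#' @param n_atoms Atom-count range `c(min, max)` (or a single count).
#' @param coordinate_model `"gaussian_blob"` (globular), `"chain"`
#'   (elongated zig-zag, ~1.5 A spacing) or `"ring_chain"` (hexagonal ring
#'   with a tail).
#' @param label_probs Named per-subset label probabilities.
#' @param jitter_sigma Conformer coordinate jitter (Angstroms); conformer
#'   `j` of a molecule is jittered with `jitter_sigma * (1 + j)`, so
#'   conformer 0 is the least perturbed, standing in for the lowest-energy
#'   conformer of a strain-sorted ensemble.
#' @param n_actives,n_decoys Benchmark set sizes.
#' @param twin_fraction Fraction of decoys built as shape twins of the
#'   active template (identical coordinate model, permuted labels); the
#'   rest are independent clouds.
#' @param n_conformers Conformers per molecule in benchmark sets.
#' @export
fixture_spec <- function(seed = 1L,
                         n_atoms = c(10L, 25L),
                         coordinate_model = c("gaussian_blob", "chain",
                                              "ring_chain"),
                         label_probs = c(hydrophobic = 0.45, aromatic = 0.30,
                                         acceptor = 0.25, donor = 0.15),
                         jitter_sigma = 0.15,
                         n_actives = 10L,
                         n_decoys = 200L,
                         twin_fraction = 1.0,
                         n_conformers = 3L) {
  coordinate_model <- match.arg(coordinate_model)
  if (length(n_atoms) == 1L) n_atoms <- c(n_atoms, n_atoms)
  if (any(n_atoms < 1L)) .stopf("n_atoms must be >= 1")
  if (!setequal(names(label_probs), .subset_order))
    .stopf("label_probs must be named %s",
           paste(.subset_order, collapse = ", "))
  if (any(label_probs < 0) || any(label_probs > 1))
    .stopf("label probabilities must lie in [0, 1]")
  if (jitter_sigma < 0) .stopf("jitter_sigma must be >= 0")
  if (twin_fraction < 0 || twin_fraction > 1)
    .stopf("twin_fraction must lie in [0, 1]")
  if (n_actives < 0 || n_decoys < 0) .stopf("counts must be >= 0")
  structure(list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
                 coordinate_model = coordinate_model,
                 label_probs = label_probs[.subset_order],
                 jitter_sigma = jitter_sigma,
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 twin_fraction = twin_fraction,
                 n_conformers = as.integer(n_conformers)),
            class = "fixture_spec")
}

.draw_coords <- function(model, n) {
  switch(model,
    gaussian_blob = matrix(stats::rnorm(n * 3, sd = 1.5), ncol = 3),
    chain = {
      k <- seq_len(n) - 1
      cbind(k * 1.5, 0.5 * cos(pi * k), 0) +
        matrix(stats::rnorm(n * 3, sd = 0.1), ncol = 3)
    },
    ring_chain = {
      nr <- min(6L, n)
      ang <- 2 * pi * (seq_len(nr) - 1) / 6
      ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
      tail_n <- n - nr
      xyz <- if (tail_n > 0) {
        rbind(ring, cbind(1.4 + 1.5 * seq_len(tail_n), 0, 0))
      } else ring
      xyz + matrix(stats::rnorm(n * 3, sd = 0.1), ncol = 3)
    },
    .stopf("unknown coordinate model '%s'", model))
}

.draw_labels <- function(n, probs) {
  do.call(pharmacophore_subsets, c(
    lapply(probs, function(p) which(stats::runif(n) < p)),
    list(n_atoms = n)))
}

#' Generate a labelled point-cloud conformer
#'
#' @param spec [fixture_spec()].
#' @param id Molecule identifier; also salts the derived RNG seed, so
#'   different ids give independent clouds under one spec.
#' @return List with `record` ([conformer_record()]) and `subsets`
#'   ([pharmacophore_subsets()]).
#' @export
generate_cloud <- function(spec, id = "cloud") {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(.derive_seed(spec$seed, id), {
    n <- if (spec$n_atoms[1] == spec$n_atoms[2]) spec$n_atoms[1]
         else sample(spec$n_atoms[1]:spec$n_atoms[2], 1L)
    coords <- .draw_coords(spec$coordinate_model, n)
    subsets <- .draw_labels(n, spec$label_probs)
    list(record = conformer_record(id, 0L, coords), subsets = subsets)
  })
}

#' Make a shape twin: identical coordinates, permuted labels
#'
#' Returns a conformer with exactly the same coordinates whose pharmacophore
#' label assignment has been permuted so that at least one subset differs.
#' The classic 12-element USR vector of the twin is therefore *identical*
#' to the original's, while the 60-element USRCAT vector differs — the
#' construction reproduces, in miniature, the failure mode of shape-only
#' screening on compounds with similar coordinate distributions but
#' unrelated pharmacophoric profiles. The permutation is retried (seeded,
#' deterministic) until the USRCAT vectors verifiably differ.
#'
#' @param record [conformer_record()] with >= 2 atoms.
#' @param subsets [pharmacophore_subsets()] with at least one subset that is
#'   neither empty nor the full atom set (otherwise no permutation can
#'   change the labelling and an error is raised).
#' @param seed Integer seed.
#' @return List with `record` (coordinates unchanged) and `subsets`.
#' @export
make_shape_twin <- function(record, subsets, seed = 1L) {
  n <- n_atoms(record)
  if (n < 2L) .stopf("shape twin needs >= 2 atoms")
  proper <- vapply(subsets, function(s) length(s) > 0L && length(s) < n, TRUE)
  if (!any(proper))
    .stopf("impossible permutation: all atoms identically labelled")
  orig <- usrcat_descriptor(record, subsets)
  with_local_seed(seed, {
    for (try in 1:100) {
      perm <- if (try < 100) sample.int(n) else {
        # constructive fallback: swap one member of a proper subset out
        s <- subsets[[which(proper)[1]]]
        p <- seq_len(n)
        a <- s[1]; b <- setdiff(seq_len(n), s)[1]
        p[c(a, b)] <- c(b, a)
        p
      }
      tw <- lapply(unclass(subsets), function(s) sort(perm[s]))
      tw <- pharmacophore_subsets(tw$hydrophobic, tw$aromatic, tw$acceptor,
                                  tw$donor, n_atoms = n)
      if (identical(lapply(unclass(tw), as.integer),
                    lapply(unclass(subsets), as.integer))) next
      if (max(abs(usrcat_descriptor(record, tw) - orig)) > 0)
        return(list(record = record, subsets = tw))
    }
  })
  .stopf("could not construct a distinguishable shape twin")
}

#' Build a synthetic active/decoy benchmark target set
#'
#' Actives are label-preserving jittered copies of one template cloud;
#' decoys are a `twin_fraction` mixture of label-permuted shape twins of
#' the template (jittered with the *same* sigma as the actives, so classic
#' shape similarity cannot separate them) and independent clouds. Each
#' molecule carries `n_conformers` conformers with increasing jitter;
#' conformer 0 is the least jittered.
#'
#' @param spec [fixture_spec()] with `n_actives >= 2` (one query plus at
#'   least one retrievable active) and `n_decoys >= 1`.
#' @param target_id Identifier for the resulting [target_set()].
#' @export
build_benchmark_set <- function(spec, target_id = "synthetic") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_actives < 2L)
    .stopf("need n_actives >= 2 (a query plus a retrievable active)")
  if (spec$n_decoys < 1L) .stopf("need n_decoys >= 1")
  template <- generate_cloud(spec, paste0(target_id, "_template"))
  n <- n_atoms(template$record)
  proper <- vapply(template$subsets,
                   function(s) length(s) > 0L && length(s) < n, TRUE)
  if (!any(proper))
    .stopf("template labelling admits no shape twin; choose another seed")
  jitter_mol <- function(base_coords, mol_id, subsets) {
    confs <- lapply(seq_len(spec$n_conformers) - 1L, function(j) {
      s <- spec$jitter_sigma * (1 + j)
      conformer_record(mol_id, j,
                       base_coords + matrix(stats::rnorm(length(base_coords),
                                                         sd = s),
                                            ncol = 3))
    })
    benchmark_molecule(mol_id, confs, rep(list(subsets), length(confs)))
  }
  with_local_seed(.derive_seed(spec$seed, paste0(target_id, "_set")), {
    actives <- lapply(seq_len(spec$n_actives), function(i) {
      jitter_mol(template$record$coords, sprintf("active_%03d", i),
                 template$subsets)
    })
    n_twins <- round(spec$twin_fraction * spec$n_decoys)
    decoys <- lapply(seq_len(spec$n_decoys), function(i) {
      id <- sprintf("decoy_%03d", i)
      if (i <= n_twins) {
        tw <- make_shape_twin(template$record, template$subsets,
                              seed = .derive_seed(spec$seed, id))
        jitter_mol(template$record$coords, id, tw$subsets)
      } else {
        cl <- generate_cloud(spec, id)
        jitter_mol(cl$record$coords, id, cl$subsets)
      }
    })
    target_set(target_id, actives, decoys)
  })
}
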