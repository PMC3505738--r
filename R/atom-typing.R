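#' Pharmacophore subsets of a conformer
#'
#' Four index sets over a conformer's atoms: hydrophobic, aromatic,
#' hydrogen-bond acceptor and donor. Subsets may overlap (a hydroxyl oxygen
#' is both donor and acceptor) and may be empty; indices are 1-based into
#' the parent record's atom list and always refer to heavy atoms.
#'
#' @param hydrophobic,aromatic,acceptor,donor Integer index vectors.
#' @param n_atoms Optional atom count of the parent record, used for range
#'   validation.
#' @return An object of class `pharmacophore_subsets`.
#' @export
pharmacophore_subsets <- function(hydrophobic = integer(),
                                  aromatic = integer(),
                                  acceptor = integer(),
                                  donor = integer(),
                                  n_atoms = NULL) {
  subsets <- list(hydrophobic = hydrophobic, aromatic = aromatic,
                  acceptor = acceptor, donor = donor)
  subsets <- lapply(subsets, function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) && (anyNA(s) || any(s < 1L)))
      .stopf("subset indices must be positive integers")
    s
  })
  if (!is.null(n_atoms)) {
    for (nm in names(subsets))
      if (length(subsets[[nm]]) && max(subsets[[nm]]) > n_atoms)
        .stopf("subset '%s' has index out of range (> %d atoms)", nm, n_atoms)
  }
  structure(subsets, class = "pharmacophore_subsets")
}

#' @export
print.pharmacophore_subsets <- function(x, ...) {
  cat("<pharmacophore_subsets>",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = " "), "\n")
  invisible(x)
}

#' Path of the shipped default SMARTS pattern file
#' @export
default_pattern_path <- function() {
  system.file("smarts", "default_patterns.yaml", package = "usrcatkit")
}

#' Load and compile a pharmacophore SMARTS pattern set
#'
#' The file is YAML mapping each of the four subset names (`hydrophobic`,
#' `aromatic`, `donor`, `acceptor`) to a list of SMARTS strings. All four
#' keys must be present (lists may be empty), unknown keys are rejected, and
#' every pattern must compile under the chemistry backend.
#'
#' @param path Pattern file; defaults to the shipped set.
#' @return A named list of class `pattern_set`.
#' @export
load_pattern_set <- function(path = default_pattern_path()) {
  if (!file.exists(path)) .stopf("pattern file not found: %s", path)
  raw <- yaml::read_yaml(path)
  required <- c("hydrophobic", "aromatic", "donor", "acceptor")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    .stopf("missing subset: %s", paste(missing, collapse = ", "))
  unknown <- setdiff(names(raw), required)
  if (length(unknown))
    .stopf("unknown subset name(s): %s", paste(unknown, collapse = ", "))
  patterns <- lapply(raw[required], function(p) as.character(unlist(p)))
  if (backend_available()) {
    res <- .backend_call("validate_smarts", input = list(patterns = lapply(patterns, I)))
    if (!isTRUE(res$ok)) {
      e <- res$errors[[1]]
      .stopf("invalid SMARTS in subset '%s' (pattern %d): %s",
             e$subset, e$index, e$pattern)
    }
  } else {
    warning("chemistry backend unavailable; SMARTS patterns not validated")
  }
  structure(patterns, class = "pattern_set")
}

#' Assign pharmacophore subsets by SMARTS matching
#'
#' An atom belongs to a subset iff it matches at least one of the subset's
#' SMARTS patterns. Matching runs on the molecular graph of the record's SDF
#' block; hydrogens never enter subsets.
#'
#' @param record A [conformer_record()] carrying its SDF text (`$sdf`), as
#'   produced by [read_conformers()].
#' @param patterns A `pattern_set` from [load_pattern_set()].
#' @return A [pharmacophore_subsets()] object.
#' @export
assign_subsets <- function(record, patterns = load_pattern_set()) {
  if (!inherits(record, "conformer_record"))
    .stopf("record must be a conformer_record")
  if (is.null(record$sdf))
    .stopf(paste("record '%s' has no molecular graph (no SDF block);",
                 "atom typing requires connectivity"), record$mol_id)
  if (!backend_available())
    .stopf("chemistry backend unavailable; cannot match SMARTS patterns")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(record$sdf, tmp)
  res <- .backend_call("match", args = tmp,
                       input = list(patterns = lapply(unclass(patterns), I)))
  if (!is.null(res$error))
    .stopf("atom typing failed for '%s': %s", record$mol_id, res$error)
  m <- res$records[[1]]$matches
  if (res$records[[1]]$n_atoms != n_atoms(record))
    .stopf("backend atom count mismatch for '%s'", record$mol_id)
  idx1 <- function(s) as.integer(unlist(m[[s]])) + 1L  # 0-based -> 1-based
  pharmacophore_subsets(hydrophobic = idx1("hydrophobic"),
                        aromatic = idx1("aromatic"),
                        acceptor = idx1("acceptor"),
                        donor = idx1("donor"),
                        n_atoms = n_atoms(record))
}
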