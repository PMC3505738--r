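# Benchmark directory layout: one directory per target containing
# actives.sdf and decoys.sdf, multi-conformer (consecutive records with the
# same title are conformers of one molecule, conformer 0 first). Synthetic
# point-cloud sets carry their pharmacophore labels in data fields
# (> <usrcatkit.hydrophobic> etc., 1-based atom indices) since they have no
# bonds for SMARTS typing.

.sdf_v2000 <- function(title, coords, elements, fields = list()) {
  n <- nrow(coords)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], elements)
  lines <- c(title, "  usrcatkit", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
             atoms, "M  END")
  for (nm in names(fields)) {
    lines <- c(lines, sprintf("> <%s>", nm), as.character(fields[[nm]]), "")
  }
  c(lines, "$$$$")
}

.subset_fields <- function(subsets) {
  out <- list()
  for (nm in .subset_order) {
    out[[paste0("usrcatkit.", nm)]] <-
      if (length(subsets[[nm]])) paste(subsets[[nm]], collapse = " ") else "-"
  }
  out
}

.labels_from_sdf <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  vals <- list()
  for (nm in .subset_order) {
    hit <- which(trimws(lines) == sprintf("> <usrcatkit.%s>", nm))
    if (length(hit) != 1L) return(NULL)
    v <- trimws(lines[hit + 1L])
    vals[[nm]] <- if (v == "-") integer() else
      as.integer(strsplit(v, "\\s+")[[1]])
  }
  do.call(pharmacophore_subsets, vals)
}

#' Write / read a benchmark target set as SDF files
#'
#' `write_target_set()` writes `actives.sdf` and `decoys.sdf` into `dir`;
#' `read_target_set()` reads that layout back. Records carrying
#' `usrcatkit.*` label fields (synthetic sets) are typed from those fields;
#' otherwise SMARTS typing with `patterns` is applied.
#'
#' @param ts [target_set()].
#' @param dir Target directory.
#' @export
write_target_set <- function(ts, dir) {
  stopifnot(inherits(ts, "target_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump <- function(mols, path) {
    lines <- unlist(lapply(mols, function(mol) {
      unlist(Map(function(rec, sub) {
        .sdf_v2000(mol$mol_id, rec$coords, rec$elements,
                   .subset_fields(sub))
      }, mol$conformers, mol$subsets))
    }))
    writeLines(lines, path)
  }
  dump(ts$actives, file.path(dir, "actives.sdf"))
  dump(ts$decoys, file.path(dir, "decoys.sdf"))
  invisible(dir)
}

#' @rdname write_target_set
#' @param target_id Identifier; defaults to the directory name.
#' @param patterns [load_pattern_set()] result for records without embedded
#'   label fields.
#' @export
read_target_set <- function(dir, target_id = basename(dir),
                            patterns = NULL) {
  one <- function(path) {
    recs <- read_conformers(path, fmt = "sdf")
    if (length(recs) == 0L) .stopf("no records in %s", path)
    subs <- lapply(recs, function(r) {
      s <- .labels_from_sdf(r$sdf)
      if (is.null(s)) {
        patterns <<- patterns %||% load_pattern_set()
        s <- assign_subsets(r, patterns)
      }
      s
    })
    ids <- vapply(recs, `[[`, "", "mol_id")
    lapply(unique(ids), function(id) {
      k <- which(ids == id)
      benchmark_molecule(id, recs[k], subs[k])
    })
  }
  target_set(target_id,
             actives = one(file.path(dir, "actives.sdf")),
             decoys = one(file.path(dir, "decoys.sdf")))
}
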