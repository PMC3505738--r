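#' Conformer record
#'
#' The package's container for one 3D geometry of a molecule: cartesian
#' coordinates in Angstroms plus element symbols. Hydrogens are read and
#' flagged but never silently dropped; whether they enter descriptor
#' computation is decided by the `hydrogens` policy of [usr_descriptor()].
#'
#' @param mol_id Molecule identifier (string).
#' @param conf_id Non-negative integer conformer index; 0 denotes the
#'   lowest-energy conformer of an energy-sorted ensemble.
#' @param coords Numeric matrix with one row per atom and three columns
#'   (x, y, z in Angstroms).
#' @param elements Character vector of element symbols, one per atom.
#'   Defaults to carbon, the convention for synthetic point clouds.
#' @param sdf Optional raw SDF (V2000) text of the record, retained so the
#'   chemistry backend can recover connectivity for atom typing and
#'   fingerprints.
#' @return An object of class `conformer_record`.
#' @export
conformer_record <- function(mol_id, conf_id, coords, elements = NULL,
                             sdf = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) < 1L)
    .stopf("coords must be an N x 3 matrix with N >= 1")
  if (!all(is.finite(coords)))
    .stopf("coords must be finite")
  n <- nrow(coords)
  elements <- elements %||% rep("C", n)
  if (length(elements) != n)
    .stopf("elements must have one entry per atom (%d != %d)",
           length(elements), n)
  conf_id <- as.integer(conf_id)
  if (is.na(conf_id) || conf_id < 0L)
    .stopf("conf_id must be a non-negative integer")
  structure(list(
    mol_id = as.character(mol_id),
    conf_id = conf_id,
    coords = unname(coords),
    elements = as.character(elements),
    is_hydrogen = as.character(elements) == "H",
    sdf = sdf
  ), class = "conformer_record")
}

#' @export
print.conformer_record <- function(x, ...) {
  cat(sprintf("<conformer_record> %s conf %d: %d atoms (%d H)%s\n",
              x$mol_id, x$conf_id, length(x$elements), sum(x$is_hydrogen),
              if (is.null(x$sdf)) "" else ", with SDF block"))
  invisible(x)
}

n_atoms <- function(record) nrow(record$coords)

# Split raw SDF lines into per-record character blocks on "$$$$".
.split_sdf_records <- function(lines) {
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) ends <- length(lines)  # single unterminated record
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  # drop trailing whitespace-only pseudo-records
  Filter(function(r) any(nzchar(trimws(setdiff(r, "$$$$")))), recs)
}

.parse_sdf_file <- function(path, recs) {
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) != length(recs))
    .stopf("unparsable SDF input in %s", path)
  # logic="|": a record with a well-formed atom block but no bonds is legal
  # (synthetic point clouds have coordinates and no connectivity)
  valid <- ChemmineR::validSDF(sdfset, logic = "|")
  if (!all(valid))
    .stopf("unparsable SDF record at index %d", which(!valid)[1])
  lapply(seq_along(recs), function(i) {
    ab <- ChemmineR::atomblock(sdfset[[i]])
    txt <- recs[[i]]
    if (trimws(txt[length(txt)]) != "$$$$") txt <- c(txt, "$$$$")
    list(title = trimws(recs[[i]][1]),
         coords = unname(ab[, c("C1", "C2", "C3"), drop = FALSE]),
         elements = sub("_.*$", "", rownames(ab)),
         text = paste(txt, collapse = "\n"))
  })
}

#' Read 3D conformers from SDF or SMILES input
#'
#' For SDF input each record must carry explicit 3D coordinates (planar
#' molecules, all-zero z, are legal). Consecutive records sharing a title are
#' treated as conformers of one molecule in file order, conformer 0 first —
#' matching ensembles stored sorted by increasing strain energy, where
#' conformer 0 is the lowest-energy conformer. SMILES input (one per line,
#' optional whitespace-separated id) is embedded into a single 3D conformer
#' by the chemistry backend.
#'
#' @param path Input file.
#' @param fmt `"sdf"` or `"smiles"`.
#' @param one_mol_per_record Disable title-based conformer grouping: every
#'   SDF record becomes its own molecule with `conf_id` 0.
#' @param seed Seed for coordinate embedding of SMILES input.
#' @return List of [conformer_record()] objects (empty list for empty input).
#' @export
read_conformers <- function(path, fmt = c("sdf", "smiles"),
                            one_mol_per_record = FALSE, seed = 1L) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (fmt == "smiles") {
    if (!backend_available())
      .stopf(paste("no 3D coordinates: SMILES input requires the chemistry",
                   "backend to embed conformers, and none is available"))
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    res <- .backend_call("embed", args = c(path, tmp, as.integer(seed)))
    if (!is.null(res$error))
      .stopf("SMILES record %s: %s", res$record %||% "?", res$error)
    return(read_conformers(tmp, fmt = "sdf", one_mol_per_record = TRUE))
  }
  lines <- readLines(path, warn = FALSE)
  recs <- .split_sdf_records(lines)
  if (length(recs) == 0L) return(list())
  parsed <- .parse_sdf_file(path, recs)
  titles <- vapply(parsed, `[[`, "", "title")
  mol_ids <- ifelse(nzchar(titles), titles,
                    sprintf("record_%d", seq_along(parsed)))
  if (one_mol_per_record) {
    mol_ids <- make.unique(mol_ids, sep = "_")
    conf_ids <- rep(0L, length(parsed))
  } else {
    grp <- cumsum(c(TRUE, mol_ids[-1L] != mol_ids[-length(mol_ids)]))
    conf_ids <- as.integer(stats::ave(grp, grp, FUN = seq_along)) - 1L
  }
  Map(function(p, id, cid) {
    conformer_record(id, cid, p$coords, p$elements, sdf = p$text)
  }, parsed, mol_ids, conf_ids)
}
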