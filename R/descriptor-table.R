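#' Build a descriptor table
#'
#' The package's flat-file unit of exchange: one row per conformer with its
#' 60 USRCAT moments, columns `mol_id, conf_id, m1..m60`.
#'
#' @param mol_id Character vector.
#' @param conf_id Integer vector.
#' @param moments Numeric matrix, one row per conformer, 60 columns.
#' @export
descriptor_table <- function(mol_id, conf_id, moments) {
  moments <- as.matrix(moments)
  storage.mode(moments) <- "double"
  if (ncol(moments) != 60L)
    .stopf("moments must have 60 columns, got %d", ncol(moments))
  if (length(mol_id) != nrow(moments) || length(conf_id) != nrow(moments))
    .stopf("mol_id/conf_id lengths must match moment rows")
  if (anyDuplicated(paste(mol_id, conf_id)))
    .stopf("(mol_id, conf_id) pairs must be unique")
  if (!all(is.finite(moments)))
    .stopf("moments must be finite")
  out <- data.frame(mol_id = as.character(mol_id),
                    conf_id = as.integer(conf_id),
                    stringsAsFactors = FALSE)
  colnames(moments) <- .moment_cols()
  cbind(out, as.data.frame(moments))
}

#' Write / read a descriptor table
#'
#' Comma-delimited with header `mol_id,conf_id,m1,...,m60`; moments printed
#' with 17 significant digits so that `read(write(x))` reproduces every
#' double bit-faithfully and files remain diffable.
#'
#' @param rows Descriptor table data frame (non-empty).
#' @param path Output/input CSV path.
#' @export
write_descriptor_table <- function(rows, path) {
  if (nrow(rows) == 0L) .stopf("refusing to write an empty descriptor table")
  cols <- c("mol_id", "conf_id", .moment_cols())
  if (!all(cols %in% names(rows)))
    .stopf("descriptor table must have columns mol_id, conf_id, m1..m60")
  if (any(grepl("[,\n\"]", rows$mol_id)))
    .stopf("mol_id must not contain commas, quotes or newlines")
  mm <- as.matrix(rows[, .moment_cols()])
  chr <- matrix(sprintf("%.17g", mm), nrow = nrow(mm))
  lines <- paste(rows$mol_id, rows$conf_id,
                 apply(chr, 1, paste, collapse = ","), sep = ",")
  writeLines(c(paste(cols, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  counts <- utils::count.fields(path, sep = ",", quote = "")
  bad <- which(counts != 62L)
  if (length(bad))
    .stopf("line %d: expected 62 fields (mol_id, conf_id, 60 moments), got %d",
           bad[1], counts[bad[1]])
  df <- utils::read.csv(path, colClasses = c("character", "integer",
                                             rep("numeric", 60)),
                        check.names = FALSE)
  expected <- c("mol_id", "conf_id", .moment_cols())
  if (!identical(names(df), expected))
    .stopf("unexpected header; expected mol_id,conf_id,m1,...,m60")
  df
}

#' Compute a descriptor table from conformer records
#'
#' Convenience wrapper: types each record with the pattern set (or uses
#' supplied subsets) and stacks the USRCAT vectors into a table.
#'
#' @param records List of [conformer_record()]s.
#' @param patterns [load_pattern_set()] result used when `subsets` is NULL.
#' @param subsets Optional list of [pharmacophore_subsets()], parallel to
#'   `records`, bypassing SMARTS typing (used for synthetic point clouds).
#' @param hydrogens Hydrogen policy for [usrcat_descriptor()].
#' @export
descriptorise <- function(records, patterns = NULL, subsets = NULL,
                          hydrogens = "exclude") {
  if (length(records) == 0L) .stopf("no records")
  if (is.null(subsets)) {
    patterns <- patterns %||% load_pattern_set()
    subsets <- lapply(records, assign_subsets, patterns = patterns)
  }
  mm <- t(mapply(function(r, s) usrcat_descriptor(r, s, hydrogens),
                 records, subsets))
  descriptor_table(vapply(records, `[[`, "", "mol_id"),
                   vapply(records, `[[`, 0L, "conf_id"), mm)
}
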