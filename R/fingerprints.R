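# Fingerprint bits for a vector of SDF record texts -> list of integer
# bit-index vectors (0-based, as emitted by the backend).
.fingerprint_bits <- function(sdf_texts, fp_kind, nbits) {
  kinds <- c("circular", "path", "tree", "maccs")
  if (!fp_kind %in% kinds)
    .stopf("unsupported fp_kind '%s' (use %s)", fp_kind,
           paste(kinds, collapse = "/"))
  if (!backend_available())
    .stopf("chemistry backend unavailable; cannot compute fingerprints")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(paste(sdf_texts, collapse = "\n"), tmp)
  res <- .backend_call("fingerprint", args = c(tmp, fp_kind,
                                               as.integer(nbits)))
  if (!is.null(res$error)) .stopf("fingerprint backend: %s", res$error)
  lapply(res$records, function(r) as.integer(unlist(r$bits)))
}

.tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)  # two empty bitsets: conventionally dissimilar
  length(intersect(a, b)) / u
}

#' Tanimoto similarity of topological fingerprints
#'
#' Hashed 2048-bit fingerprints from the chemistry backend: `"circular"`
#' (Morgan, radius 2), `"path"` (linear paths), `"tree"` (branched
#' subgraphs) or `"maccs"` (166 structural keys; `nbits` ignored). Values
#' are deterministic for a given backend version but not comparable across
#' toolkits, so tests pin them as regression fixtures.
#'
#' @param molA,molB [conformer_record()]s with SDF blocks, or raw SDF text.
#' @param fp_kind One of `"circular"`, `"path"`, `"tree"`, `"maccs"`.
#' @param nbits Fingerprint length in bits.
#' @return Tanimoto coefficient in \[0, 1\].
#' @export
tanimoto_topological <- function(molA, molB, fp_kind = "circular",
                                 nbits = 2048L) {
  as_sdf <- function(m) {
    if (inherits(m, "conformer_record")) {
      if (is.null(m$sdf)) .stopf("record '%s' has no SDF block", m$mol_id)
      m$sdf
    } else as.character(m)
  }
  bits <- .fingerprint_bits(c(as_sdf(molA), as_sdf(molB)), fp_kind, nbits)
  .tanimoto_bits(bits[[1]], bits[[2]])
}
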