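#' Chemistry backend bridge
#'
#' SMARTS matching, SMILES embedding and topological fingerprints are
#' delegated to RDKit through the `python` interpreter on the PATH (override
#' with `options(usrcatkit.python = ...)` or the `USRCATKIT_PYTHON`
#' environment variable). The numerical core of the package — reference
#' points, moments, similarity, screening, benchmarking — has no chemistry
#' dependency and works on labelled point clouds alone.
#'
#' @return `backend_available()` returns `TRUE` if the bridge answers a ping.
#' @export
backend_available <- function() {
  cached <- .backend_env$available
  if (!is.null(cached)) return(cached)
  ok <- tryCatch({
    res <- .backend_call("ping")
    isTRUE(res$ok)
  }, error = function(e) FALSE)
  .backend_env$available <- ok
  ok
}

.backend_env <- new.env(parent = emptyenv())

.backend_python <- function() {
  p <- getOption("usrcatkit.python",
                 Sys.getenv("USRCATKIT_PYTHON", unset = ""))
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) .stopf("no python interpreter found for chemistry backend")
  unname(p)
}

.backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "usrcatkit")
  if (!nzchar(path)) .stopf("chem_backend.py not found in installed package")
  path
}

.backend_call <- function(cmd, args = character(), input = NULL) {
  stdin_json <- if (is.null(input)) "" else
    jsonlite::toJSON(input, auto_unbox = TRUE)
  out <- suppressWarnings(system2(
    .backend_python(),
    args = c(shQuote(.backend_script()), cmd, shQuote(args)),
    input = stdin_json, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || length(out) == 0L)
    .stopf("chemistry backend call '%s' failed (exit %d)", cmd, status)
  jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
}
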