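`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset block order of the 60-element vector after the all-atom block.
# Fixed by the similarity metric's index ranges (hydrophobe weight applies to
# elements 13-24, aromatic 25-36, acceptor 37-48, donor 49-60).
.subset_order <- c("hydrophobic", "aromatic", "acceptor", "donor")

.moment_cols <- function(n = 60) paste0("m", seq_len(n))

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators are pure
#' functions of their arguments and never disturb the caller's stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit seed derived from a base seed and a string id,
# computed in double precision to avoid integer overflow.
.derive_seed <- function(seed, id) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.log_msg <- function(fmt, ...) message(sprintf(fmt, ...))
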