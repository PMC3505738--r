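#' USR reference points
#'
#' The four reference points of ultrafast shape recognition: the atomic
#' centroid (`ctd`), the atom closest to the centroid (`cst`), the atom
#' farthest from the centroid (`fct`) and the atom farthest from that atom
#' (`ftf`). `cst`, `fct` and `ftf` coincide with actual atom positions;
#' `ctd` need not. Distance ties are broken by the lowest atom index so the
#' computation is deterministic under a fixed input order.
#'
#' @param coords Numeric N x 3 coordinate matrix (Angstroms), N >= 1.
#' @return List with elements `ctd`, `cst`, `fct`, `ftf` (3-vectors) and
#'   `idx` (indices of the three atom-coincident points).
#' @export
compute_reference_points <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) .stopf("need at least one atom")
  ctd <- colMeans(coords)
  d_ctd <- sqrt(rowSums(sweep(coords, 2, ctd)^2))
  i_cst <- which.min(d_ctd)   # which.min/max take the first (lowest) index
  i_fct <- which.max(d_ctd)
  d_fct <- sqrt(rowSums(sweep(coords, 2, coords[i_fct, ])^2))
  i_ftf <- which.max(d_fct)
  list(ctd = unname(ctd),
       cst = unname(coords[i_cst, ]),
       fct = unname(coords[i_fct, ]),
       ftf = unname(coords[i_ftf, ]),
       idx = c(cst = i_cst, fct = i_fct, ftf = i_ftf))
}

#' First three moments of a distance distribution
#'
#' Mean, population standard deviation (1/N variance) and the
#' sign-preserving cube root of the population third central moment. The
#' cube root of the *unstandardised* third moment keeps Angstrom units and
#' stays finite for degenerate distributions (a single distance gives
#' exactly (d, 0, 0)), unlike standardised skewness which is 0/0 there.
#'
#' @param distances Numeric vector of distances, length >= 1.
#' @return Numeric triple `(mu, sigma, kappa)`.
#' @export
moment_triple <- function(distances) {
  if (length(distances) < 1L) .stopf("empty distance distribution")
  mu <- mean(distances)
  dev <- distances - mu
  sigma <- sqrt(mean(dev^2))
  m3 <- mean(dev^3)
  # An analytically zero third moment (<= 2 values, symmetric distributions)
  # accumulates ~1e-16 * sigma^3 of rounding noise, which the cube root
  # would amplify to ~1e-5 * sigma; snap it to exact zero at a relative
  # threshold far below any genuine skew.
  if (abs(m3) <= 1e-12 * sigma^3) m3 <- 0
  c(mu = mu, sigma = sigma, kappa = sign(m3) * abs(m3)^(1 / 3))
}

# 12 moments of one atom set against fixed reference points:
# (ctd mu,sigma,kappa), (cst ...), (fct ...), (ftf ...)
.moment_block <- function(coords, ref) {
  unlist(lapply(list(ref$ctd, ref$cst, ref$fct, ref$ftf), function(p) {
    moment_triple(sqrt(rowSums(sweep(coords, 2, p)^2)))
  }), use.names = FALSE)
}

.considered_coords <- function(record, hydrogens) {
  if (is.matrix(record)) return(record)  # bare point cloud: all considered
  if (!inherits(record, "conformer_record"))
    .stopf("expected a conformer_record or coordinate matrix")
  keep <- if (hydrogens == "exclude") !record$is_hydrogen
          else rep(TRUE, n_atoms(record))
  if (!any(keep))
    .stopf("no atoms to consider for '%s' under hydrogens='%s'",
           record$mol_id, hydrogens)
  record$coords[keep, , drop = FALSE]
}

#' Classic 12-element USR shape descriptor
#'
#' Distances from every considered atom to the four reference points of
#' [compute_reference_points()], each distribution summarised by
#' [moment_triple()]. The vector is invariant under rotation and
#' translation of the input coordinates (and, by construction, under
#' reflection — the method does not discriminate enantiomers).
#'
#' @param record A [conformer_record()] or a bare N x 3 coordinate matrix
#'   (treated as a heavy-atom point cloud).
#' @param hydrogens `"exclude"` (default) computes over heavy atoms only;
#'   `"include"` uses all atoms.
#' @return Numeric vector of length 12.
#' @export
usr_descriptor <- function(record, hydrogens = c("exclude", "include")) {
  hydrogens <- match.arg(hydrogens)
  coords <- .considered_coords(record, hydrogens)
  ref <- compute_reference_points(coords)
  .moment_block(coords, ref)
}

#' 60-element USRCAT shape descriptor
#'
#' Extends the USR vector with four further 12-moment blocks computed over
#' the pharmacophore subsets (hydrophobic, aromatic, acceptor, donor — the
#' block order the similarity weights apply to). Subset distance
#' distributions are taken to the *same* four all-atom reference points,
#' which anchors the location of pharmacophoric features in the overall
#' shape; an empty subset contributes twelve exact zeros. The first 12
#' elements are identical to [usr_descriptor()].
#'
#' @inheritParams usr_descriptor
#' @param subsets A [pharmacophore_subsets()] object indexing into the
#'   record's atoms.
#' @return Numeric vector of length 60.
#' @export
usrcat_descriptor <- function(record, subsets,
                              hydrogens = c("exclude", "include")) {
  hydrogens <- match.arg(hydrogens)
  coords_all <- if (is.matrix(record)) record else record$coords
  coords <- .considered_coords(record, hydrogens)
  ref <- compute_reference_points(coords)
  out <- numeric(60)
  out[1:12] <- .moment_block(coords, ref)
  for (b in seq_along(.subset_order)) {
    idx <- subsets[[.subset_order[b]]]
    if (length(idx) == 0L) next  # empty subset: block stays exactly zero
    if (any(idx > nrow(coords_all)))
      .stopf("subset '%s' index out of range", .subset_order[b])
    out[b * 12 + 1:12] <- .moment_block(coords_all[idx, , drop = FALSE], ref)
  }
  out
}
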