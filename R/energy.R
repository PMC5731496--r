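#' Coarse-grained C-alpha energy
#'
#' A simple pluggable potential for CA traces: a harmonic virtual-bond term
#' about the canonical 3.8 A CA-CA distance plus a soft-sphere repulsion
#' between residues at least 3 apart whenever they come closer than the
#' clash distance. Units are arbitrary (A^2-scaled penalties); the energy is
#' invariant under rigid motion. Any function \code{calpha -> numeric} can
#' replace it in the sampler.
#'
#' @param s a \code{calpha} structure.
#' @param k_bond harmonic force constant for the virtual bond term.
#' @param bond_length ideal CA-CA distance in Angstrom (3.8).
#' @param clash_distance repulsion onset in Angstrom (4.0).
#' @param k_clash repulsion force constant.
#' @return finite numeric energy.
#' @export
calpha_energy <- function(s, k_bond = 1, bond_length = 3.8,
                          clash_distance = 4.0, k_clash = 1) {
  xyz <- s$xyz
  n <- nrow(xyz)
  bl <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  e <- k_bond * sum((bl - bond_length)^2)
  if (n >= 4L) {
    d <- as.matrix(stats::dist(xyz))
    sep <- abs(row(d) - col(d))
    close <- d < clash_distance & sep >= 3L & row(d) < col(d)
    if (any(close)) e <- e + k_clash * sum((clash_distance - d[close])^2)
  }
  e
}

has_clash <- function(s, clash_distance = 4.0) {
  xyz <- s$xyz
  n <- nrow(xyz)
  if (n < 4L) return(FALSE)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(row(d) - col(d))
  any(d < clash_distance & sep >= 3L & row(d) < col(d))
}
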