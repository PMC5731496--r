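#' Construct a C-alpha trace
#'
#' A \code{calpha} object is an ordered alpha-carbon trace: one coordinate
#' triple per residue, in residue order. It is the coarse-grained protein
#' representation used throughout the package.
#'
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param resno integer vector of residue numbers, strictly increasing.
#'   Defaults to \code{1:N}.
#' @param id character label for the structure.
#' @return An object of class \code{calpha} with elements \code{id},
#'   \code{resno} and \code{xyz} (N x 3 matrix).
#' @export
calpha_structure <- function(coords, resno = NULL, id = "structure") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("a C-alpha trace needs at least 2 residues")
  if (is.null(resno)) resno <- seq_len(n)
  resno <- as.integer(resno)
  if (length(resno) != n) stop("resno length must match the number of residues")
  if (any(diff(resno) <= 0L)) stop("residue numbers must be strictly increasing")
  bl <- sqrt(rowSums((coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE])^2))
  if (any(bl == 0)) stop("consecutive C-alpha atoms at zero distance")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(id = id, resno = resno, xyz = coords), class = "calpha")
}

#' @export
print.calpha <- function(x, ...) {
  cat(sprintf("C-alpha trace '%s': %d residues (%d..%d)\n",
              x$id, nrow(x$xyz), x$resno[1], x$resno[length(x$resno)]))
  invisible(x)
}

n_residues <- function(s) nrow(s$xyz)

#' Flatten a structure to a 3N conformation vector
#'
#' @param s a \code{calpha} structure.
#' @return numeric vector \code{c(x1,y1,z1, x2,y2,z2, ...)} of length 3N.
#' @export
as_conformation_vector <- function(s) as.vector(t(s$xyz))

#' Rebuild a structure from a 3N conformation vector
#'
#' @param v numeric vector of length divisible by 3.
#' @param template a \code{calpha} structure supplying residue numbers and id.
#' @return a \code{calpha} structure.
#' @export
conformation_to_structure <- function(v, template) {
  if (length(v) %% 3L != 0L) stop("conformation vector length must be divisible by 3")
  xyz <- matrix(v, ncol = 3L, byrow = TRUE)
  if (nrow(xyz) != n_residues(template))
    stop("conformation vector does not match template size")
  calpha_structure(xyz, resno = template$resno, id = template$id)
}

#' Read a C-alpha trace from a PDB file
#'
#' Parses ATOM records with \pkg{bio3d} and extracts one CA atom per residue,
#' in residue order. Alternate locations are resolved to the highest-occupancy
#' record (first on ties).
#'
#' @param source path to a PDB file.
#' @param chain optional chain identifier; by default the first chain that
#'   contains CA atoms is used.
#' @param id label for the returned structure; defaults to the file name.
#' @return a \code{calpha} structure.
#' @export
read_calpha_pdb <- function(source, chain = NULL, id = NULL) {
  pdb <- bio3d::read.pdb(source, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha atoms found in ", source)
  if (!is.null(chain)) {
    if (!chain %in% at$chain) stop("chain '", chain, "' not found in ", source)
    at <- at[at$chain == chain, , drop = FALSE]
  } else {
    at <- at[at$chain == at$chain[1], , drop = FALSE]
  }
  # resolve altloc: keep highest occupancy per residue number
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$resno, -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  if (is.null(id)) id <- basename(as.character(source))
  calpha_structure(cbind(at$x, at$y, at$z), resno = at$resno, id = id)
}

#' Write a C-alpha trace (or several models) as PDB
#'
#' Writes CA-only ATOM records; a list of structures is written as a
#' multi-model file (MODEL/ENDMDL), the standard container for a sampled
#' trajectory.
#'
#' @param s a \code{calpha} structure or a list of them sharing residue
#'   numbering.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_calpha_pdb <- function(s, path) {
  models <- if (inherits(s, "calpha")) list(s) else s
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    st <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n_residues(st)), "A", st$resno,
      st$xyz[, 1], st$xyz[, 2], st$xyz[, 3], 1, 0)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read all models of a multi-model C-alpha PDB file
#'
#' @param path path to a (possibly multi-model) PDB file.
#' @param chain optional chain selector, as in \code{\link{read_calpha_pdb}}.
#' @return a list of \code{calpha} structures, one per model.
#' @export
read_calpha_models <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  first <- read_calpha_pdb(path, chain = chain)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  lapply(seq_len(nrow(xyz)), function(m) {
    conformation_to_structure(xyz[m, ], first)
  })
}

pair_structures <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  if (length(shared) == 0L) stop("structures share no residue numbers")
  list(a = a$xyz[match(shared, a$resno), , drop = FALSE],
       b = b$xyz[match(shared, b$resno), , drop = FALSE],
       resno = shared)
}

#' Minimal C-alpha RMSD after optimal superposition
#'
#' Pairs the two traces by residue number, superposes them optimally
#' (Kabsch, via \pkg{bio3d}) and returns the root-mean-square deviation in
#' Angstrom. Symmetric and zero iff the structures are congruent.
#'
#' @param a,b \code{calpha} structures.
#' @param fit superpose before measuring (default \code{TRUE}).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, fit = TRUE) {
  p <- pair_structures(a, b)
  if (nrow(p$a) < 3L && fit)
    stop("need at least 3 shared residues for superposition")
  as.numeric(bio3d::rmsd(as.vector(t(p$a)), as.vector(t(p$b)), fit = fit))
}

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- c(b1[2] * b2[3] - b1[3] * b2[2],
           b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
  c23 <- c(b2[2] * b3[3] - b2[3] * b3[2],
           b2[3] * b3[1] - b2[1] * b3[3],
           b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(c12 * c23)
  y <- sum(b1 * c23) * sqrt(sum(b2 * b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360  # range (-180, 180]
  ang
}

#' Pseudo-dihedral angles of a C-alpha trace
#'
#' The torsion defined by each window of four consecutive CA atoms
#' (IUPAC sign convention), in degrees within (-180, 180]. A trace of N
#' residues has N - 3 pseudo-dihedrals; dihedral i rotates about the virtual
#' bond between residues i + 1 and i + 2.
#'
#' @param s a \code{calpha} structure with at least 4 residues.
#' @return numeric vector of N - 3 angles in degrees.
#' @export
pseudo_dihedrals <- function(s) {
  n <- n_residues(s)
  if (n < 4L) stop("need at least 4 residues for a pseudo-dihedral")
  vapply(seq_len(n - 3L), function(i) {
    torsion_angle(s$xyz[i, ], s$xyz[i + 1L, ], s$xyz[i + 2L, ], s$xyz[i + 3L, ])
  }, numeric(1))
}

#' Rotate about a virtual C-alpha bond
#'
#' Applies a rigid rotation of \code{delta} degrees to the C-terminal side of
#' the trace about the axis through CA(k+1) and CA(k+2), where
#' \code{k = bond_index} addresses the k-th pseudo-dihedral. The N-terminal
#' side (residues 1..k+2) is untouched; all virtual bond lengths are
#' preserved. A positive \code{delta} increases the k-th pseudo-dihedral by
#' \code{delta}.
#'
#' @param s a \code{calpha} structure.
#' @param bond_index integer in 1..(N-3).
#' @param delta rotation in degrees.
#' @return the rotated \code{calpha} structure.
#' @export
apply_dihedral_rotation <- function(s, bond_index, delta) {
  n <- n_residues(s)
  if (bond_index < 1L || bond_index > n - 3L)
    stop("bond_index out of range 1..", n - 3L)
  if (delta == 0) return(s)
  origin <- s$xyz[bond_index + 1L, ]
  axis <- s$xyz[bond_index + 2L, ] - origin
  axis <- axis / sqrt(sum(axis^2))
  th <- delta * pi / 180
  ct <- cos(th); st <- sin(th)
  moving <- (bond_index + 3L):n
  v <- sweep(s$xyz[moving, , drop = FALSE], 2L, origin)
  # Rodrigues rotation, right-hand rule about the bond axis
  dot <- drop(v %*% axis)
  crossm <- cbind(axis[2] * v[, 3] - axis[3] * v[, 2],
                  axis[3] * v[, 1] - axis[1] * v[, 3],
                  axis[1] * v[, 2] - axis[2] * v[, 1])
  vr <- v * ct + crossm * st + outer(dot * (1 - ct), axis)
  xyz <- s$xyz
  xyz[moving, ] <- sweep(vr, 2L, origin, "+")
  calpha_structure(xyz, resno = s$resno, id = s$id)
}
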