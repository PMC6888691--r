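#' Build a procedural B-DNA duplex geometry
#'
#' Generates sugar-phosphate sensitive-volume centres on an ideal B-form
#' double helix: one site per (strand, base pair), with base pair `k` of
#' strand `s` at azimuth `k*twist + s*(180 + strand_offset)` degrees on a
#' cylinder of radius `backbone_radius`, at height `k*rise`. Defaults are the
#' canonical B-DNA values (0.34 nm rise, 36 degree twist, ~10.5 bp/turn at
#' 0.94 nm backbone radius).
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param rise Axial rise per base pair, nm.
#' @param twist Helical twist per base pair, degrees.
#' @param backbone_radius Radius of the backbone helix, nm.
#' @param capture_radius Sensitive-volume capture radius per site, nm.
#' @param origin 3-vector, nm: position of the (strand 0, bp 0) helix origin.
#' @param strand_offset Additional azimuthal offset of strand 1, degrees
#'   (0 places the strands antipodally; a negative value models the
#'   minor-groove asymmetry).
#' @return An object of class `duplex_geometry`: list with `sites` (data.frame
#'   `strand`, `bp_index`, `x`, `y`, `z`, `capture_radius`), `n_bp`, `source`.
#' @export
#' @examples
#' d <- build_bdna(10)
#' nrow(d$sites)  # 2 sites per base pair
build_bdna <- function(n_bp, rise = 0.34, twist = 36, backbone_radius = 0.94,
                       capture_radius = 0.35, origin = c(0, 0, 0),
                       strand_offset = 0) {
  if (n_bp < 1) stop("n_bp must be >= 1")
  if (capture_radius <= 0) stop("capture_radius must be positive")
  k <- rep(seq_len(n_bp) - 1L, times = 2)
  s <- rep(c(0L, 1L), each = n_bp)
  ang <- (k * twist + s * (180 + strand_offset)) * pi / 180
  sites <- data.frame(
    strand = s,
    bp_index = k,
    x = origin[1] + backbone_radius * cos(ang),
    y = origin[2] + backbone_radius * sin(ang),
    z = origin[3] + k * rise,
    capture_radius = capture_radius
  )
  structure(list(sites = sites, n_bp = as.integer(n_bp), source = "procedural"),
            class = "duplex_geometry")
}

#' @export
print.duplex_geometry <- function(x, ...) {
  cat(sprintf("duplex_geometry (%s): %d bp, %d sensitive sites\n",
              x$source, x$n_bp, nrow(x$sites)))
  invisible(x)
}

#' Rigid-body transform of a duplex geometry
#'
#' Applies `x -> rotation %*% x + translation` to every site centre.
#'
#' @param duplex A `duplex_geometry`.
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector, nm.
#' @return The transformed `duplex_geometry`.
#' @export
transform_duplex <- function(duplex, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(duplex, "duplex_geometry"))
  xyz <- as.matrix(duplex$sites[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  duplex$sites$x <- xyz[, 1] + translation[1]
  duplex$sites$y <- xyz[, 2] + translation[2]
  duplex$sites$z <- xyz[, 3] + translation[3]
  duplex
}

# backbone atom names recognised when collapsing residues to site centroids
NUCLEIC_BACKBONE <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'",
                      "O5*", "C5*", "C4*", "C3*", "O3*")
PROTEIN_BACKBONE <- c("N", "CA", "C", "O")

#' Load a duplex geometry from a PDB file
#'
#' Reads ATOM records via [bio3d::read.pdb()] and collapses each residue to
#' one sensitive site at the centroid of its backbone atoms (sugar-phosphate
#' atoms P, O5', C5', C4', C3', O3' for nucleic acids; N, CA, C, O for
#' proteins; all atoms of a residue if neither set is present). The first two
#' chains in file order map to strands 0 and 1; residue order within a chain
#' defines the base-pair index. Files with more than two chains are accepted
#' with a warning (extra chains dropped); chains of unequal length are
#' truncated to the shorter one.
#'
#' Pairing chains positionally is a structural convenience: a protein chain
#' pair (such as a crystal structure used as a plasmid-section surrogate)
#' acquires strand semantics only through this convention.
#'
#' @param path Path to a PDB file.
#' @param capture_radius Sensitive-volume capture radius per site, nm.
#' @return A `duplex_geometry` with `source = "pdb:<basename>"`.
#' @export
load_pdb <- function(path, capture_radius = 0.35) {
  if (capture_radius <= 0) stop("capture_radius must be positive")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records in ", path)

  chains <- unique(at$chain)
  if (length(chains) < 2)
    stop("need 2 chains to define a duplex; file has ", length(chains), " chain(s)")
  if (length(chains) > 2) {
    warning("file has ", length(chains), " chains; keeping the first two (",
            chains[1], ", ", chains[2], ")")
    chains <- chains[1:2]
  }

  chain_sites <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    res_ids <- unique(a$resno)
    cent <- t(vapply(res_ids, function(rn) {
      r <- a[a$resno == rn, , drop = FALSE]
      bb <- r[r$elety %in% c(NUCLEIC_BACKBONE, PROTEIN_BACKBONE), , drop = FALSE]
      if (nrow(bb) == 0) bb <- r
      # PDB coordinates are Angstrom; sites are stored in nm
      c(mean(bb$x), mean(bb$y), mean(bb$z)) / 10
    }, numeric(3)))
    cent
  })

  n0 <- nrow(chain_sites[[1]]); n1 <- nrow(chain_sites[[2]])
  n_bp <- min(n0, n1)
  if (n0 != n1)
    warning("chains have ", n0, " and ", n1,
            " residues; truncating to ", n_bp, " base pairs")
  s0 <- chain_sites[[1]][seq_len(n_bp), , drop = FALSE]
  s1 <- chain_sites[[2]][seq_len(n_bp), , drop = FALSE]
  sites <- data.frame(
    strand = rep(c(0L, 1L), each = n_bp),
    bp_index = rep(seq_len(n_bp) - 1L, times = 2),
    x = c(s0[, 1], s1[, 1]),
    y = c(s0[, 2], s1[, 2]),
    z = c(s0[, 3], s1[, 3]),
    capture_radius = capture_radius
  )
  structure(list(sites = sites, n_bp = as.integer(n_bp),
                 source = paste0("pdb:", basename(path))),
            class = "duplex_geometry")
}
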