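## Idealized 3-D fixtures in PDB format for the contact classifier. Each
## motif realizes a requested geometry exactly (at zero jitter), so the
## classifier can be validated against constructed ground truth.

hexRing <- function(center = c(0, 0, 0), radius = 1.39, names, elems,
                    resid, resno, chain = "A", tiltDeg = 0) {
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(radius * cos(ang), radius * sin(ang), 0)
  if (tiltDeg != 0) {   # rotate about the x-axis through the ring centroid
    th <- tiltDeg * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    xyz <- xyz %*% t(R)
  }
  xyz <- sweep(xyz, 2, center, "+")
  data.frame(elety = names, elem = elems, resid = resid, resno = resno,
             chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

atomRow <- function(elety, elem, resid, resno, xyz, chain = "A")
  data.frame(elety = elety, elem = elem, resid = resid, resno = resno,
             chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
             stringsAsFactors = FALSE)

BASE_RING_NAMES <- c("N1", "C2", "N3", "C4", "C5", "C6")
BASE_RING_ELEMS <- c("N", "C", "N", "C", "C", "C")

#' Write an idealized structural motif as a PDB file
#'
#' Emits a minimal valid PDB-format file whose geometry realizes the
#' requested motif exactly (before jitter):
#' \describe{
#'   \item{hbond_pair}{a Tyr-like donor hydroxyl (with hydrogen) and a
#'     modified-base nitrogen acceptor, donor-acceptor heavy-atom distance
#'     exactly `distance` and D-H...A angle exactly `angle`}
#'   \item{stacked_rings}{a Phe ring and a six-membered base ring with
#'     centroid separation `distance` and inter-plane angle `angle`}
#'   \item{probe_at_distance}{an Ile side-chain atom whose closest approach
#'     to the base ring is exactly `distance`}
#'   \item{metal_triad}{a Mn ion with His/Asp/His coordinating atoms
#'     (residues 171, 173, 236) each at `distance`}
#' }
#' Modified bases are written with the het code "1MA" so the default lesion
#' map of [readStructure()] recognizes them. Single model, single chain,
#' 1-based residue numbering, orthogonal Angstrom coordinates.
#'
#' @param motif one of "hbond_pair", "stacked_rings", "probe_at_distance",
#'   "metal_triad"
#' @param distance characteristic distance, Angstrom (> 0)
#' @param angle characteristic angle, degrees (0-180); D-H...A angle for
#'   hbond_pair, inter-plane angle for stacked_rings
#' @param jitterSd Gaussian coordinate jitter, Angstrom
#' @param seed RNG seed for the jitter
#' @param path output file path
#' @return the path, invisibly
#' @examples
#' p <- makeToyStructure("hbond_pair", 2.9, 170)
#' readStructure(p)
#' @export
makeToyStructure <- function(motif = c("hbond_pair", "stacked_rings",
                                       "probe_at_distance", "metal_triad"),
                             distance, angle = 0, jitterSd = 0, seed = 1L,
                             path = tempfile(fileext = ".pdb")) {
  motif <- match.arg(motif)
  if (distance <= 0) stop("distance must be > 0")
  if (angle < 0 || angle > 180) stop("angle must lie in [0, 180] degrees")

  atoms <- switch(motif,
    hbond_pair = {
      oh <- 0.96                              # O-H bond length
      alpha <- (180 - angle) * pi / 180       # direction of H->A from H->D
      s <- -oh * cos(alpha) +
        sqrt(max(oh^2 * cos(alpha)^2 - oh^2 + distance^2, 0))
      A <- c(oh, 0, 0) + s * c(cos(alpha), sin(alpha), 0)
      dirDA <- A / sqrt(sum(A^2))
      rbind(
        atomRow("CZ", "C", "TYR", 1L, c(-1.4, 0, 0)),
        atomRow("OH", "O", "TYR", 1L, c(0, 0, 0)),
        atomRow("HH", "H", "TYR", 1L, c(oh, 0, 0)),
        atomRow("N1", "N", "1MA", 2L, A),
        atomRow("C2", "C", "1MA", 2L, A + 1.4 * dirDA))
    },
    stacked_rings = rbind(
      hexRing(c(0, 0, 0), 1.39,
              c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), rep("C", 6),
              "PHE", 1L),
      hexRing(c(0, 0, distance), 1.39, BASE_RING_NAMES, BASE_RING_ELEMS,
              "1MA", 2L, tiltDeg = angle)),
    probe_at_distance = rbind(
      atomRow("CD1", "C", "ILE", 1L, c(1.39, 0, distance)),
      atomRow("CB",  "C", "ILE", 1L, c(1.39, 0, distance + 1.53)),
      hexRing(c(0, 0, 0), 1.39, BASE_RING_NAMES, BASE_RING_ELEMS,
              "1MA", 2L)),
    metal_triad = rbind(
      atomRow("NE2", "N", "HIS", 171L, c(distance, 0, 0)),
      atomRow("CB",  "C", "HIS", 171L, c(distance + 1.5, 0, 0)),
      atomRow("OD1", "O", "ASP", 173L, c(0, distance, 0)),
      atomRow("CB",  "C", "ASP", 173L, c(0, distance + 1.5, 0)),
      atomRow("NE2", "N", "HIS", 236L, c(0, 0, distance)),
      atomRow("CB",  "C", "HIS", 236L, c(0, 0, distance + 1.5)),
      atomRow("MN",  "MN", "MN", 500L, c(0, 0, 0))))

  if (jitterSd > 0) {
    n <- nrow(atoms)
    jit <- withSeed(seed, matrix(stats::rnorm(3 * n, 0, jitterSd), ncol = 3))
    atoms$x <- atoms$x + jit[, 1]
    atoms$y <- atoms$y + jit[, 2]
    atoms$z <- atoms$z + jit[, 3]
  }

  het <- atoms$resid %in% c("MN", "1MA")
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = rep("A", nrow(atoms)),
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)),
                   elesy = atoms$elem)
  invisible(path)
}
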