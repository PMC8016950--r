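# Seeded synthetic-data generators: Fv coordinate templates and decoy
# libraries, analytic-SASA sphere systems, toy interface complexes, and SPOT
# arrays with planted motifs. Assay-curve simulators live with the fitters.

.rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1] * a[1] * C + c_,        a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, a[2] * a[2] * C + c_,        a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3] * a[3] * C + c_),
    nrow = 3, byrow = TRUE)
}

#' Build a synthetic C-alpha Fv structure from a numbered pair
#'
#' Places one C-alpha per residue on two interleaved helical curves (one per
#' chain), giving a rigid, non-degenerate 3D scaffold keyed by Kabat label.
#' Purely geometric: no attempt at native-like packing.
#'
#' @param pair list with `numbered_vregion` elements `H` and `L` (e.g.
#'   [synthetic_fv_pair()]).
#' @return an `fv_structure`.
#' @export
make_fv_template <- function(pair) {
  pair <- .pair_check(pair)
  build <- function(region, offset) {
    n <- length(region$labels)
    i <- seq_len(n)
    t <- i * 100 * pi / 180
    data.frame(
      kabat = region$labels, aa = region$aa,
      resid = names(.aa3to1)[match(region$aa, .aa3to1)],
      elety = "CA", element = "C",
      x = 8 * cos(t) + offset[1], y = 8 * sin(t) + offset[2],
      z = 1.6 * i + offset[3], stringsAsFactors = FALSE)
  }
  fv <- list(heavy = build(pair$H, c(0, 0, 0)),
             light = build(pair$L, c(14, 6, 2)),
             ligands = list(),
             source = paste0("synthetic-template:", pair$H$source_id))
  class(fv) <- "fv_structure"
  fv
}

.transform_fv <- function(fv, rot, trans) {
  move <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rot)
    at$x <- xyz[, 1] + trans[1]
    at$y <- xyz[, 2] + trans[2]
    at$z <- xyz[, 3] + trans[3]
    at
  }
  fv$heavy <- move(fv$heavy)
  fv$light <- move(fv$light)
  fv
}

.jitter_fv <- function(fv, sigma) {
  jit <- function(at) {
    n <- nrow(at)
    at$x <- at$x + stats::rnorm(n, 0, sigma)
    at$y <- at$y + stats::rnorm(n, 0, sigma)
    at$z <- at$z + stats::rnorm(n, 0, sigma)
    at
  }
  if (sigma > 0) {
    fv$heavy <- jit(fv$heavy)
    fv$light <- jit(fv$light)
  }
  fv
}

#' Generate a rigid-body-perturbed Fv decoy library
#'
#' Each decoy is the template under a random rigid transform followed by
#' isotropic per-coordinate Gaussian noise of the requested sigma; noise is
#' applied after the rigid jitter, so the recorded sigma drives the expected
#' post-fit RMSD (about `sigma * sqrt(3)` for one-sided noise). Deterministic
#' per seed.
#'
#' @param template an `fv_structure` (e.g. [make_fv_template()]).
#' @param sigmas numeric vector: one decoy per element, with that noise level
#'   in angstrom.
#' @param rot_max maximal rotation angle (radians).
#' @param trans_max maximal translation per axis (angstrom).
#' @param seed RNG seed.
#' @return list with `library` (named list of `fv_structure`) and `truth`
#'   (data.frame id, sigma).
#' @export
make_decoy_library <- function(template, sigmas, rot_max = pi,
                               trans_max = 20, seed = 0) {
  stopifnot(inherits(template, "fv_structure"), all(sigmas >= 0))
  .with_seed(seed, {
    lib <- list()
    for (k in seq_along(sigmas)) {
      rot <- .rotation_matrix(stats::rnorm(3), stats::runif(1, 0, rot_max))
      trans <- stats::runif(3, -trans_max, trans_max)
      d <- .transform_fv(template, rot, trans)
      d <- .jitter_fv(d, sigmas[k])
      d$source <- sprintf("decoy%03d", k)
      lib[[sprintf("decoy%03d", k)]] <- d
    }
    list(library = lib,
         truth = data.frame(id = names(lib), sigma = sigmas,
                            stringsAsFactors = FALSE))
  })
}

#' Sphere system with analytic SASA
#'
#' Builds a pseudo-atom model from spheres with known radii and returns the
#' closed-form solvent-accessible area of each sphere (spherical-cap
#' formula), valid while overlaps are pairwise only.
#'
#' @param radii sphere radii (angstrom).
#' @param centers n-by-3 matrix of sphere centers.
#' @param probe_radius probe radius.
#' @return list with `model` (a [structure_model()], one chain per sphere),
#'   `radii`, and `analytic_sasa` per sphere.
#' @export
make_sphere_system <- function(radii, centers, probe_radius = 1.4) {
  centers <- matrix(centers, ncol = 3)
  stopifnot(length(radii) == nrow(centers))
  n <- length(radii)
  rp <- radii + probe_radius
  sasa <- 4 * pi * rp^2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (d >= rp[i] + rp[j]) next
      if (d + rp[i] <= rp[j]) {  # sphere i fully engulfed
        sasa[i] <- 0
        next
      }
      if (d + rp[j] <= rp[i]) next  # j inside i: no cap removed from i
      # cap height on the expanded sphere i occluded by expanded sphere j
      h <- rp[i] - (d^2 + rp[i]^2 - rp[j]^2) / (2 * d)
      sasa[i] <- sasa[i] - 2 * pi * rp[i] * h
    }
  }
  sasa <- pmax(sasa, 0)
  atoms <- data.frame(
    chain = LETTERS[seq_len(n)], resno = seq_len(n), resid = "SPH",
    elety = "X", element = "X",
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    stringsAsFactors = FALSE)
  list(model = structure_model(atoms, source = "synthetic-spheres"),
       radii = radii, analytic_sasa = sasa)
}

#' Synthetic binding-cleft complex
#'
#' A toy receptor-peptide complex with fully known interaction truth, used to
#' validate the interface pipeline end to end: a 9-residue peptide ligand
#' (chain `P`), a row of contacting receptor residues (chain `A`) including
#' one direct hydrogen-bond pair and one water-bridged pair, one remote
#' receptor residue that makes no contact, and a bridging water (chain `W`).
#'
#' @param separation extra rigid offset (angstrom) applied to the receptor
#'   and water along +y; large values separate the parts completely.
#' @return list with `model` and the construction `truth` (residue labels of
#'   contacts, direct and water-mediated hydrogen bonds).
#' @export
make_toy_complex <- function(separation = 0) {
  row_ <- function(chain, resno, resid, elety, element, x, y, z) {
    data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
               element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  }
  atoms <- list()
  # peptide ligand: CA carbon per residue, O on residues 2 and 4
  for (i in 1:9) {
    atoms[[length(atoms) + 1]] <- row_("P", i, "GLY", "CA", "C",
                                       3 * i, 0, 0)
  }
  atoms[[length(atoms) + 1]] <- row_("P", 2, "GLY", "O", "O", 6, 1.2, 0)
  atoms[[length(atoms) + 1]] <- row_("P", 4, "GLY", "O", "O", 12, 1.2, 0)
  # receptor residues above ligand residues 1-5 (contacts)
  for (i in 1:5) {
    atoms[[length(atoms) + 1]] <- row_("A", i, "ALA", "CB", "C",
                                       3 * i, 4.2 + separation, 0)
  }
  # direct H-bond: receptor N near the ligand O of residue 2
  atoms[[length(atoms) + 1]] <- row_("A", 2, "ALA", "N", "N",
                                     6, 4.1 + separation, 0)
  # water-mediated: receptor N above ligand residue 4, too far for direct
  atoms[[length(atoms) + 1]] <- row_("A", 4, "ALA", "N", "N",
                                     12, 6.8 + separation, 0)
  atoms[[length(atoms) + 1]] <- row_("W", 1, "HOH", "O", "O",
                                     12, 4.0 + separation, 0)
  # remote receptor residue: no contact
  atoms[[length(atoms) + 1]] <- row_("A", 9, "SER", "OG", "O", 0, 40, 0)
  model <- structure_model(do.call(rbind, atoms), source = "synthetic-complex")
  truth <- list(
    contact_residues = paste0("ALA(A", 1:5, ")"),
    no_contact_residues = "SER(A9)",
    direct_hbond = c("ALA(A2)"),
    water_mediated = c("ALA(A4)"))
  list(model = model, truth = truth)
}

#' SPOT array with a planted motif
#'
#' Tiles the antigen and assigns each spot whose peptide fully contains the
#' motif a high signal, all others background, plus seeded Gaussian noise;
#' intensities are max-normalized to 1.
#'
#' @param antigen_seq antigen sequence.
#' @param motif motif string (must occur in the antigen).
#' @param signal,background mean intensity of positive / negative spots.
#' @param noise_sd additive noise before normalization.
#' @param seed RNG seed.
#' @param window,step,region,max_spots tiling parameters, see
#'   [tile_peptides()].
#' @return the `spot_array` with `intensities` and a `truth` field holding
#'   the planted positive spot indices.
#' @export
make_spot_array <- function(antigen_seq, motif, signal = 0.9,
                            background = 0.1, noise_sd = 0, seed = 0,
                            window = 8, step = 2,
                            region = c(1, nchar(antigen_seq)),
                            max_spots = NULL) {
  occ <- locate_motif(antigen_seq, motif)
  if (occ$count == 0) stop("motif not present in the antigen")
  arr <- tile_peptides(antigen_seq, window, step, region, max_spots)
  contains <- grepl(motif, arr$peptides$sequence, fixed = TRUE)
  mu <- ifelse(contains, signal, background)
  y <- .with_seed(seed, mu + noise_sd * stats::rnorm(length(mu)))
  y <- pmax(y, 0)
  arr$intensities <- y / max(y)
  arr$truth <- list(positive = arr$peptides$index[contains], motif = motif,
                    occurrences = occ$positions, seed = seed)
  arr
}
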