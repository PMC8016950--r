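# Protein-peptide interface quantification: solvent-accessible surface area
# (Shrake-Rupley sphere sampling), buried areas, contact tables and
# hydrogen bonds.

#' SASA parameters
#'
#' @param probe_radius solvent probe radius in angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960; deterministic
#'   golden-spiral point set).
#' @param radii `"united"` for NACCESS-style united-atom radii resolved by
#'   atom class, or a named numeric vector of per-element radii.
#' @param include_hydrogens keep hydrogen atoms (default FALSE; crystal
#'   structures at typical resolution carry none).
#' @return list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960,
                        radii = "united", include_hydrogens = FALSE) {
  stopifnot(probe_radius > 0, n_points >= 100)
  structure(list(probe_radius = probe_radius, n_points = n_points,
                 radii = radii, include_hydrogens = include_hydrogens),
            class = "sasa_params")
}

# deterministic golden-spiral points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# united-atom (NACCESS-flavoured) radius per atom; aromatic/carbonyl carbons
# are slimmer than aliphatic united carbons
.aromatic_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1")
)

.atom_radii <- function(atoms, radii) {
  if (is.numeric(radii)) {
    r <- unname(radii[atoms$element])
    if (anyNA(r)) {
      bad <- which(is.na(r))[1]
      stop("no radius for atom ", atoms$elety[bad], " (element ",
           atoms$element[bad], ") in residue ", atoms$resid[bad])
    }
    return(r)
  }
  el <- atoms$element
  r <- rep(NA_real_, nrow(atoms))
  r[el == "N"] <- 1.65
  r[el == "O"] <- 1.40
  r[el == "S"] <- 1.85
  r[el == "P"] <- 1.90
  r[el == "H"] <- 1.00
  is_c <- el == "C"
  r[is_c] <- 1.87
  r[is_c & atoms$elety == "C"] <- 1.76  # backbone carbonyl carbon
  for (res in names(.aromatic_atoms)) {
    hit <- is_c & atoms$resid == res & atoms$elety %in% .aromatic_atoms[[res]]
    r[hit] <- 1.76
  }
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no radius for atom ", atoms$elety[bad], " (element ",
         atoms$element[bad], ") in residue ", atoms$resid[bad])
  }
  r
}

.select_atoms <- function(model, chains, params, drop_water = TRUE) {
  a <- model$atoms
  keep <- if (is.null(chains)) rep(TRUE, nrow(a)) else a$chain %in% chains
  if (drop_water) keep <- keep & a$resid != "HOH"
  if (!params$include_hydrogens) keep <- keep & a$element != "H"
  a[keep, , drop = FALSE]
}

# core Shrake-Rupley on an atom table; returns per-atom SASA
.sasa_atoms <- function(atoms, params, radius_override = NULL) {
  n <- nrow(atoms)
  if (n == 0) return(numeric(0))
  rad <- if (is.null(radius_override)) .atom_radii(atoms, params$radii) else
    radius_override
  rp <- rad + params$probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- .sphere_points(params$n_points)
  out <- numeric(n)
  # neighbour search via cell-free pairwise distances (systems here are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (rp[i] + rp)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * rp[i]^2
      next
    }
    sp <- sweep(pts * rp[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rp[j]^2
    }
    out[i] <- 4 * pi * rp[i]^2 * mean(free)
  }
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples `n_points` deterministic sphere points per atom at radius
#' (atom radius + probe) and counts the fraction not occluded by any
#' neighbouring sphere. Waters are excluded.
#'
#' @param model a [structure_model()].
#' @param chains chain identifiers to include (`NULL` = all).
#' @param params a [sasa_params()].
#' @param radius_override optional numeric vector of per-atom radii (used by
#'   the analytic sphere fixtures).
#' @return list with `atoms` (the selected atom table with a `sasa` column),
#'   `residue` (per-residue totals: chain, resno, insert, resid, sasa) and
#'   `total`.
#' @examples
#' m <- structure_model(data.frame(chain = "A", resno = 1, resid = "UNK",
#'                                 elety = "C", element = "C",
#'                                 x = 0, y = 0, z = 0))
#' shrake_rupley_sasa(m, radius_override = 1.7)$total  # ~ 4*pi*3.1^2
#' @export
shrake_rupley_sasa <- function(model, chains = NULL, params = sasa_params(),
                               radius_override = NULL) {
  atoms <- .select_atoms(model, chains, params)
  atoms$sasa <- .sasa_atoms(atoms, params, radius_override)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  per_res <- stats::aggregate(atoms$sasa, by = list(key = key), FUN = sum)
  first <- atoms[!duplicated(key), c("chain", "resno", "insert", "resid")]
  first$sasa <- per_res$x[match(paste(first$chain, first$resno, first$insert,
                                      sep = "|"), per_res$key)]
  rownames(first) <- NULL
  list(atoms = atoms, residue = first, total = sum(atoms$sasa))
}

.res_label <- function(df) {
  paste0(df$resid, "(", df$chain, df$resno,
         ifelse(nzchar(df$insert), df$insert, ""), ")")
}

#' Buried surface area between two selections
#'
#' Per-residue BSA = SASA(part alone) - SASA(part in complex), computed with
#' the same point set; totals and the buried fraction are reported for
#' selection B (the ligand side). Waters are excluded from all SASA
#' calculations.
#'
#' @param model a [structure_model()] containing both parts.
#' @param sel_a,sel_b chain identifier vectors for the two parts (disjoint).
#' @param params a [sasa_params()].
#' @return object of class `interface_report`: `total_sasa_B_free`,
#'   `buried_B`, `buried_fraction` (percent), `residues_a` / `residues_b`
#'   (per-residue tables with `sasa_free`, `sasa_complex`, `bsa`), `params`.
#' @export
buried_surface <- function(model, sel_a, sel_b, params = sasa_params()) {
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  if (length(intersect(sel_a, sel_b))) stop("selections must be disjoint")
  free_a <- shrake_rupley_sasa(model, sel_a, params)
  free_b <- shrake_rupley_sasa(model, sel_b, params)
  complx <- shrake_rupley_sasa(model, c(sel_a, sel_b), params)
  join <- function(free) {
    key <- paste(free$residue$chain, free$residue$resno, free$residue$insert)
    ckey <- paste(complx$residue$chain, complx$residue$resno,
                  complx$residue$insert)
    out <- free$residue
    names(out)[names(out) == "sasa"] <- "sasa_free"
    out$sasa_complex <- complx$residue$sasa[match(key, ckey)]
    out$bsa <- out$sasa_free - out$sasa_complex
    out$label <- .res_label(out)
    out
  }
  ra <- join(free_a)
  rb <- join(free_b)
  total_b <- sum(rb$sasa_free)
  buried_b <- sum(rb$bsa)
  structure(list(
    sel_a = sel_a, sel_b = sel_b,
    total_sasa_B_free = total_b, buried_B = buried_b,
    buried_fraction = 100 * buried_b / total_b,
    buried_A = sum(ra$bsa),
    residues_a = ra, residues_b = rb, params = params
  ), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0("Interface report: ligand SASA %.1f A^2, buried %.1f A^2",
                     " (%.1f%%)\n"),
              x$total_sasa_B_free, x$buried_B, x$buried_fraction))
  invisible(x)
}

.hydrophobic_aa <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP", "GLY")

#' Contact table of interface residues
#'
#' Residues of selection A whose BSA exceeds the threshold, annotated with a
#' polarity class (hydrophobic = A,V,L,I,P,F,M,W,G; polar = the rest) and,
#' when a [hydrogen_bonds()] result is supplied, the H-bond class.
#'
#' @param report a [buried_surface()] report.
#' @param bsa_threshold minimum BSA in square angstrom (default 1).
#' @param hbonds optional [hydrogen_bonds()] result for annotation.
#' @return data.frame sorted by chain then residue number: `label`, `chain`,
#'   `resno`, `insert`, `resid`, `bsa`, `polarity`, `hbond`.
#' @export
contact_table <- function(report, bsa_threshold = 1.0, hbonds = NULL) {
  stopifnot(inherits(report, "interface_report"))
  r <- report$residues_a
  r <- r[r$bsa > bsa_threshold, , drop = FALSE]
  r$polarity <- ifelse(r$resid %in% .hydrophobic_aa, "hydrophobic", "polar")
  r$hbond <- rep("none", nrow(r))
  if (!is.null(hbonds)) {
    r$hbond[r$label %in% hbonds$residues_water_mediated] <- "water_mediated"
    r$hbond[r$label %in% hbonds$residues_direct] <- "direct"
  }
  r <- r[order(r$chain, r$resno, r$insert), , drop = FALSE]
  rownames(r) <- NULL
  r[, c("label", "chain", "resno", "insert", "resid", "bsa", "polarity", "hbond")]
}

#' Hydrogen bonds across an interface
#'
#' Direct bonds: polar (N/O) heavy-atom pairs, one atom in each selection,
#' within `d_max`. Water-mediated bonds: a water oxygen within `d_max` of a
#' polar atom of both selections. No angle term is applied (deposited models
#' at typical resolution carry no hydrogens).
#'
#' @param model a [structure_model()].
#' @param sel_a,sel_b chain identifier vectors.
#' @param d_max donor-acceptor heavy-atom distance cutoff (default 3.5).
#' @return list with `direct` (data.frame atom_a, atom_b, res_a, res_b,
#'   distance), `water_mediated` (data.frame res_a, res_b, water, d_a, d_b),
#'   and residue label summaries `residues_direct`, `residues_water_mediated`
#'   (selection-A residues, water-mediated excluding those already direct).
#' @export
hydrogen_bonds <- function(model, sel_a, sel_b, d_max = 3.5) {
  a <- model$atoms
  polar <- a$element %in% c("N", "O") & a$resid != "HOH"
  pa <- a[polar & a$chain %in% sel_a, , drop = FALSE]
  pb <- a[polar & a$chain %in% sel_b, , drop = FALSE]
  w <- a[a$resid == "HOH" & a$element == "O", , drop = FALSE]
  direct <- data.frame(atom_a = character(0), atom_b = character(0),
                       res_a = character(0), res_b = character(0),
                       distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pa) && nrow(pb)) {
    for (i in seq_len(nrow(pa))) {
      d <- sqrt((pb$x - pa$x[i])^2 + (pb$y - pa$y[i])^2 + (pb$z - pa$z[i])^2)
      hit <- which(d <= d_max)
      if (length(hit)) {
        direct <- rbind(direct, data.frame(
          atom_a = paste0(.res_label(pa[i, ]), ":", pa$elety[i]),
          atom_b = paste0(.res_label(pb[hit, ]), ":", pb$elety[hit]),
          res_a = .res_label(pa[i, ]), res_b = .res_label(pb[hit, ]),
          distance = d[hit], stringsAsFactors = FALSE))
      }
    }
  }
  wm <- data.frame(res_a = character(0), res_b = character(0),
                   water = character(0), d_a = numeric(0), d_b = numeric(0),
                   stringsAsFactors = FALSE)
  if (nrow(w)) {
    for (k in seq_len(nrow(w))) {
      da <- sqrt((pa$x - w$x[k])^2 + (pa$y - w$y[k])^2 + (pa$z - w$z[k])^2)
      db <- sqrt((pb$x - w$x[k])^2 + (pb$y - w$y[k])^2 + (pb$z - w$z[k])^2)
      ia <- which(da <= d_max)
      ib <- which(db <= d_max)
      if (length(ia) && length(ib)) {
        grid <- expand.grid(i = ia, j = ib)
        wm <- rbind(wm, data.frame(
          res_a = .res_label(pa[grid$i, ]), res_b = .res_label(pb[grid$j, ]),
          water = .res_label(w[k, ]), d_a = da[grid$i], d_b = db[grid$j],
          stringsAsFactors = FALSE))
      }
    }
  }
  rd <- unique(direct$res_a)
  list(direct = direct, water_mediated = wm,
       residues_direct = rd,
       residues_water_mediated = setdiff(unique(wm$res_a), rd))
}

#' Full interface characterization
#'
#' Convenience wrapper: buried surface, contact table and hydrogen bonds in
#' one call.
#'
#' @inheritParams buried_surface
#' @param bsa_threshold contact-table threshold in square angstrom.
#' @param hbond_d_max hydrogen-bond distance cutoff in angstrom.
#' @return the [buried_surface()] report extended with `contacts` and
#'   `hbonds`.
#' @export
interface_report <- function(model, sel_a, sel_b, params = sasa_params(),
                             bsa_threshold = 1.0, hbond_d_max = 3.5) {
  rep <- buried_surface(model, sel_a, sel_b, params)
  hb <- hydrogen_bonds(model, sel_a, sel_b, hbond_d_max)
  rep$hbonds <- hb
  rep$contacts <- contact_table(rep, bsa_threshold, hb)
  rep
}
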