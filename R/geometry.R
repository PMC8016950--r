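# Backbone and disulfide geometry.

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

.atom_xyz <- function(sub, elety) {
  i <- which(sub$elety == elety)
  if (!length(i)) return(NULL)
  as.numeric(sub[i[1], c("x", "y", "z")])
}

#' Peptide-bond omega angles and cis bonds
#'
#' Computes the omega torsion (CA-C-N-CA) for every bonded pair of
#' consecutive residues and reports bonds in cis configuration. Residue pairs
#' are bonded when the C-N distance is below 2.0 angstrom; pairs with missing
#' backbone atoms are skipped and listed in `skipped`. Hydrogens are ignored.
#'
#' @param model a [structure_model()].
#' @param cis_cutoff_deg bonds with |omega| below this are classed cis
#'   (default 30, the standard stereochemical convention).
#' @return list of class `geometry_report`: `omega` (data.frame chain,
#'   res1, res2, omega), `cis` (subset with |omega| < cutoff), `skipped`.
#' @export
peptide_omega_and_cis <- function(model, cis_cutoff_deg = 30) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  a <- a[a$resid %in% names(.aa3to1) & a$element != "H", , drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    rkey <- paste(sub$resno, sub$insert)
    res <- unique(rkey)
    for (i in seq_len(length(res) - 1)) {
      r1 <- sub[rkey == res[i], , drop = FALSE]
      r2 <- sub[rkey == res[i + 1], , drop = FALSE]
      c1 <- .atom_xyz(r1, "C"); n2 <- .atom_xyz(r2, "N")
      ca1 <- .atom_xyz(r1, "CA"); ca2 <- .atom_xyz(r2, "CA")
      lab <- function(r) paste0(r$resid[1], "(", ch, r$resno[1], r$insert[1], ")")
      if (is.null(c1) || is.null(n2) || is.null(ca1) || is.null(ca2)) {
        skipped <- c(skipped, paste(lab(r1), lab(r2), sep = "-"))
        next
      }
      if (sqrt(sum((c1 - n2)^2)) >= 2.0) next
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, res1 = lab(r1), res2 = lab(r2),
        omega = .dihedral(ca1, c1, n2, ca2), stringsAsFactors = FALSE)
    }
  }
  omega <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), res1 = character(0),
               res2 = character(0), omega = numeric(0))
  structure(list(omega = omega,
                 cis = omega[abs(omega$omega) < cis_cutoff_deg, , drop = FALSE],
                 cis_cutoff_deg = cis_cutoff_deg, skipped = skipped),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("Geometry report: %d peptide bonds, %d cis (|omega| < %g deg)\n",
              nrow(x$omega), nrow(x$cis), x$cis_cutoff_deg))
  if (nrow(x$cis)) {
    cat(" ", paste(sprintf("%s-%s (%.1f)", x$cis$res1, x$cis$res2, x$cis$omega),
                   collapse = "; "), "\n")
  }
  invisible(x)
}

#' Find disulfide bridges
#'
#' All cysteine SG-SG pairs within the cutoff, each cysteine used at most
#' once (greedy nearest-first pairing). Results are independent of chain
#' ordering in the file.
#'
#' @param model a [structure_model()].
#' @param sg_cutoff_A maximum SG-SG distance in angstrom (default 2.3).
#' @return data.frame with columns `cys1`, `cys2`, `distance`.
#' @export
find_disulfides <- function(model, sg_cutoff_A = 2.3) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  sg <- a[a$resid == "CYS" & a$elety == "SG", , drop = FALSE]
  empty <- data.frame(cys1 = character(0), cys2 = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sg) < 2) return(empty)
  lab <- paste0("CYS(", sg$chain, sg$resno, sg$insert, ")")
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d <= sg_cutoff_A, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty)
  pd <- d[pairs]
  o <- order(pd, lab[pairs[, 1]], lab[pairs[, 2]])
  pairs <- pairs[o, , drop = FALSE]
  pd <- pd[o]
  used <- logical(nrow(sg))
  out <- empty
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, data.frame(cys1 = lab[i], cys2 = lab[j],
                                 distance = pd[k], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
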