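# Macromolecular structure handling: reading, writing, Fv extraction.
#
# Parsing and serialisation are delegated to bio3d; this module normalises the
# atom table (alternate-location resolution, element typing) and adds the
# Kabat-keyed Fv view used by superposition and grafting.

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.element_from_name <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  first2 <- toupper(substr(e, 1, 2))
  ifelse(first2 %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         first2, toupper(substr(e, 1, 1)))
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`; optional `insert`, `element`, `o`, `b`, `type`.
#' @param source free-text provenance.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$elety)
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate atom name within a residue: ",
                               key[anyDuplicated(key)][1])
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat(sprintf("Structure model (%d atoms, chains: %s)%s\n", nrow(x$atoms),
              paste(names(ch), collapse = ","),
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' All ATOM/HETATM records are retained; alternate locations are resolved to
#' the highest-occupancy conformer (ties to the first). Element symbols are
#' derived from atom names when the file omits them.
#'
#' @param path file path.
#' @param format `"pdb"` or `"cif"`; guessed from the extension by default.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE) else
      bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # alternate locations: keep the highest-occupancy record per atom slot
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    o <- at$o
    o[is.na(o)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(o[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at$element <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    toupper(trimws(at$elesy))
  } else {
    .element_from_name(at$elety)
  }
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  structure_model(at[, c("type", "chain", "resno", "insert", "resid",
                         "elety", "element", "x", "y", "z", "o", "b")],
                  source = basename(path))
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path, type = a$type, xyz = as.numeric(t(a[, c("x", "y", "z")])),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = a$b, elesy = a$element)
  invisible(path)
}

#' Residue-level view of a structure model
#'
#' @param model a [structure_model()].
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `aa` (one-letter or `NA` for non-standard residues).
#' @export
model_residues <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  r <- a[first, c("chain", "resno", "insert", "resid")]
  r$aa <- unname(.aa3to1[r$resid])
  rownames(r) <- NULL
  r
}

#' Extract a Kabat-keyed Fv portion from a structure
#'
#' @param model a [structure_model()].
#' @param chains named vector mapping `H` and `L` to chain identifiers in the
#'   file, e.g. `c(H = "H", L = "L")`.
#' @param numbering `"abdb"` treats author residue numbers plus insertion
#'   codes as Kabat labels (the convention of pre-numbered Fv libraries);
#'   `"renumber"` numbers the extracted polypeptide sequence with
#'   [kabat_number_sequence()] and maps the labels back onto the residues.
#' @return object of class `fv_structure`: list with `heavy` and `light` atom
#'   tables (each with columns `kabat`, `aa`, `elety`, `element`, `x`, `y`,
#'   `z`) and `ligands`, a list of atom tables for the remaining entities
#'   (peptide ligands, waters, ...).
#' @export
extract_fv <- function(model, chains = c(H = "H", L = "L"),
                       numbering = c("abdb", "renumber")) {
  stopifnot(inherits(model, "structure_model"))
  numbering <- match.arg(numbering)
  if (!all(c("H", "L") %in% names(chains))) {
    stop("chain map must name both H and L")
  }
  a <- model$atoms
  out <- list()
  vmax <- c(H = 113L, L = 107L)
  for (kind in c("H", "L")) {
    ch <- chains[[kind]]
    sel <- a$chain == ch & a$resid %in% names(.aa3to1)
    if (!any(sel)) stop("lookup error: chain ", ch, " not found or empty")
    sub <- a[sel, , drop = FALSE]
    if (numbering == "abdb") {
      sub <- sub[sub$resno <= vmax[[kind]], , drop = FALSE]
      sub$kabat <- paste0(kind, sub$resno, sub$insert)
    } else {
      res <- sub[!duplicated(paste(sub$resno, sub$insert)),
                 c("resno", "insert", "resid")]
      seq <- paste(.aa3to1[res$resid], collapse = "")
      num <- kabat_number_sequence(seq, kind, source_id = model$source)
      # labels map onto the first length(num) residues of the chain... locate
      # the numbered window by matching the numbered sequence in the chain
      win <- regexpr(vregion_seq(num), seq, fixed = TRUE)
      if (win < 0) stop("numbering failure: cannot locate numbered window")
      keep_res <- seq(win, win + length(num$labels) - 1)
      res_key <- paste(res$resno, res$insert)[keep_res]
      sub <- sub[paste(sub$resno, sub$insert) %in% res_key, , drop = FALSE]
      sub$kabat <- num$labels[match(paste(sub$resno, sub$insert), res_key)]
    }
    sub$aa <- unname(.aa3to1[sub$resid])
    out[[if (kind == "H") "heavy" else "light"]] <-
      sub[, c("kabat", "aa", "resid", "elety", "element", "x", "y", "z")]
  }
  lig_sel <- !(a$chain %in% chains) | !(a$resid %in% names(.aa3to1))
  ligands <- split(a[lig_sel, , drop = FALSE],
                   paste(a$chain[lig_sel], a$resid[lig_sel] == "HOH"))
  names(ligands) <- NULL
  fv <- list(heavy = out$heavy, light = out$light, ligands = ligands,
             source = model$source)
  class(fv) <- "fv_structure"
  fv
}

#' @export
print.fv_structure <- function(x, ...) {
  cat(sprintf("Fv structure: H %d residues, L %d residues, %d ligand entities\n",
              length(unique(x$heavy$kabat)), length(unique(x$light$kabat)),
              length(x$ligands)))
  invisible(x)
}

#' Framework C-alpha coordinates of an Fv, keyed by Kabat label
#'
#' @param fv an [extract_fv()] result or synthetic Fv.
#' @param labels optional restriction to a label set.
#' @return matrix with rownames = Kabat labels, columns x,y,z.
#' @export
fv_ca_coords <- function(fv, labels = NULL) {
  at <- rbind(fv$heavy, fv$light)
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!is.null(labels)) ca <- ca[ca$kabat %in% labels, , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$kabat
  m
}
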