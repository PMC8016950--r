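# Synthetic stand-in V-region sequence sets.
#
# These are NOT the cloned hybridoma or database sequences (which are not
# redistributable here); they are synthetic constructions on human
# germline-flavoured scaffolds, designed so that the rodent-like donor and the
# human-like acceptors differ at the framework positions that matter for the
# worked humanization example: vernier positions H71, L36, L46, L68 (plus H78
# only in the "3kym"-flavoured acceptor), N-terminal positions H2, L2, L3,
# refinement positions H46 and L4, and a handful of additional non-vernier
# framework positions for realism. The donor carries the canonical CDR
# insertions H52A and L27A-L27D.

.standin_regions <- function() {
  list(
    donor = list(
      H = c("FR-H1"  = "EIELQQSGAEVKKPGASLKISCKAS",
            "CDR-H1" = "GFTFTDYAIH",
            "FR-H2"  = "WVRQMPGKGLKWMG",
            "CDR-H2" = "WINTYTGEPIYADSVKG",
            "FR-H3"  = "QVTISLDKSTSTAYLQWSSLKASDTAMYYCAR",
            "CDR-H3" = "GTMRAYFD",
            "FR-H4"  = "WGQGTLVTVSS"),
      L = c("FR-L1"  = "DVVMTQSPSSLSASLGDRVTITC",
            "CDR-L1" = "RSSQSLVHDSNGYTY",
            "FR-L2"  = "WIQQKPGKSPKGLIY",
            "CDR-L2" = "KVSNRFS",
            "FR-L3"  = "GVPDRFSGSGSETDFTLTISSLQPEDFATYYC",
            "CDR-L3" = "WQATHFPLT",
            "FR-L4"  = "FGQGTKVEIK")
    ),
    acceptor_4nry = list(
      H = c("FR-H1"  = "EVELVQSGAEVKKPGESLKISCKGS",
            "CDR-H1" = "GYSFTSYWIG",
            "FR-H2"  = "WVRQMPGKGLEWMG",
            "CDR-H2" = "IIYPGDSDTRYSPSFQ",
            "FR-H3"  = "QVTISADKSISTAYLQWSSLKASDTAMYYCAR",
            "CDR-H3" = "DRGGYFDY",
            "FR-H4"  = "WGQGTLVTVSS"),
      L = c("FR-L1"  = "DIQLTQSPSSLSASVGDRVTITC",
            "CDR-L1" = "RASQGIRNDLG",
            "FR-L2"  = "WYQQKPGKAPKLLIY",
            "CDR-L2" = "AASSLQS",
            "FR-L3"  = "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC",
            "CDR-L3" = "QQANSFPWT",
            "FR-L4"  = "FGQGTKVEIK")
    )
  )
}

.standin_variants <- function() {
  base <- .standin_regions()
  v <- base
  # "3kym"-flavoured acceptor: vernier H78 differs from the donor as well
  v$acceptor_3kym <- base$acceptor_4nry
  v$acceptor_3kym$H[["FR-H3"]] <- "QVTISADKSISTVYLQWSSLKASDTAMYYCAR"
  v$acceptor_3kym$H[["FR-H2"]] <- "WVRQAPGKGLEWMG"
  v$acceptor_3kym$L[["FR-L3"]] <- "GVPSRFSGSGSGTDFTLSISSLQPEDFATYYC"
  # two further acceptor flavours (non-vernier framework tweaks only)
  v$acceptor_4kq3 <- base$acceptor_4nry
  v$acceptor_4kq3$H[["FR-H1"]] <- "EVELVQSGAEVKQPGESLKISCKGS"
  v$acceptor_5i8c <- base$acceptor_4nry
  v$acceptor_5i8c$L[["FR-L2"]] <- "WYQQKPGKAPQLLIY"
  v
}

#' Synthetic stand-in V-region sequences
#'
#' Returns one chain of a synthetic donor/acceptor stand-in set used for
#' worked examples and tests (see the package vignette for the design). The
#' donor emulates a rodent antibody with CDR insertions H52A and L27A-L27D;
#' the acceptors emulate human Fv frameworks differing from the donor at the
#' designed vernier, N-terminal and refinement positions.
#'
#' @param id one of `"donor"`, `"acceptor_4nry"`, `"acceptor_3kym"`,
#'   `"acceptor_4kq3"`, `"acceptor_5i8c"`.
#' @param chain `"H"` or `"L"`.
#' @param numbered if `TRUE` (default) return a [numbered_vregion()] with the
#'   construction labels; otherwise the plain sequence string.
#' @return a `numbered_vregion` or a string.
#' @examples
#' synthetic_vregion("donor", "H")
#' @export
synthetic_vregion <- function(id, chain = c("H", "L"), numbered = TRUE) {
  chain <- match.arg(chain)
  sets <- .standin_variants()
  if (!id %in% names(sets)) {
    stop("unknown stand-in id: ", id, " (available: ",
         paste(names(sets), collapse = ", "), ")")
  }
  regions <- sets[[id]][[chain]]
  seq <- paste(regions, collapse = "")
  if (!numbered) return(seq)
  labels <- unlist(lapply(names(regions), function(nm) {
    .standin_labels(nm, nchar(regions[[nm]]), chain)
  }), use.names = FALSE)
  numbered_vregion(chain, labels, strsplit(seq, "")[[1]],
                   source_id = paste0("synthetic:", id))
}

# ground-truth labels for a stand-in region of known length
.standin_labels <- function(region, n, chain) {
  rules <- .kabat_region_rules(chain)
  .label_segment(n, rules[[region]], region)
}

#' Synthetic stand-in Fv sequence pair
#'
#' @param id stand-in identifier, see [synthetic_vregion()].
#' @return list with elements `H` and `L`, each a [numbered_vregion()].
#' @export
synthetic_fv_pair <- function(id) {
  list(H = synthetic_vregion(id, "H"), L = synthetic_vregion(id, "L"))
}

#' Bundled reference acceptor-screen table
#'
#' Reads the reference ranking of 20 human Fv candidates (structural
#' similarity screen against an antibody Fv database) that ships with the
#' package as a plain TSV. It is used to check the closed-form Q-score against
#' independently printed Q/RMSD/N columns; see [q_score()].
#'
#' @return data.frame with columns `rank`, `q`, `rmsd`, `n_align`,
#'   `n_residue`, `seq_identity`, `source_tag`, `pdb_id`.
#' @export
acceptor_screen_reference <- function() {
  path <- system.file("extdata", "acceptor_screen_reference.tsv",
                      package = "graftkit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled galectin-3 N-terminal domain sequence (synthetic reconstruction)
#'
#' Residues 1-112 of the human galectin-3 N-terminal domain, reconstructed
#' from the canonical repeat architecture of UniProtKB P17931 (the database is
#' not consulted at run time; see the vignette for provenance). The domain
#' carries two Ala-Pro-Pro-Gly-Ala-Tyr repeats, at positions 49 and 58.
#'
#' @return single sequence string (112 residues).
#' @export
hgal3_nd_sequence <- function() {
  path <- system.file("extdata", "hgal3_nd_synthetic.fasta",
                      package = "graftkit", mustWork = TRUE)
  unname(read_fasta(path)[1])
}
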