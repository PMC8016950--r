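# CDR grafting with an auditable back-mutation ledger.

#' Built-in vernier-zone position table
#'
#' Framework positions that pack underneath the CDRs and tune their
#' conformation (the Foote-Winter vernier zone). Used as the default search
#' set by [propose_vernier_backmutations()]; positions falling inside the CDR
#' masks of the active partition are ignored there.
#'
#' @return character vector of Kabat labels.
#' @export
vernier_zone <- function() {
  c(paste0("H", c(2, 27, 28, 29, 30, 47, 48, 49, 67, 69, 71, 73, 78, 93, 94, 103)),
    paste0("L", c(2, 4, 35, 36, 46, 47, 48, 49, 64, 66, 68, 69, 71, 98)))
}

.empty_ledger <- function() {
  data.frame(position = character(0), chain = character(0),
             donor_aa = character(0), acceptor_aa = character(0),
             category = character(0), rationale = character(0),
             stringsAsFactors = FALSE)
}

.order_ledger <- function(bm) {
  if (nrow(bm) == 0) return(bm)
  key <- ifelse(bm$chain == "H", 0, 1e6) +
    vapply(seq_len(nrow(bm)), function(i) {
      kabat_sort_key(bm$position[i])
    }, numeric(1))
  bm[order(key), , drop = FALSE]
}

.pair_check <- function(pair) {
  stopifnot(is.list(pair), all(c("H", "L") %in% names(pair)))
  stopifnot(inherits(pair$H, "numbered_vregion"), pair$H$chain_kind == "H")
  stopifnot(inherits(pair$L, "numbered_vregion"), pair$L$chain_kind == "L")
  pair
}

.residue_at <- function(region, label) {
  i <- match(label, region$labels)
  if (is.na(i)) NA_character_ else region$aa[i]
}

# mismatches between two numbered pairs at a set of labels, restricted to
# framework positions of the partition
.mismatch_candidates <- function(donor, acceptor, labels, category, partition) {
  out <- .empty_ledger()
  for (lab in labels) {
    ch <- substr(lab, 1, 1)
    region <- tryCatch(kabat_region_of(lab, partition), error = function(e) NA)
    if (is.na(region) || !grepl("^FR", region)) next
    d <- .residue_at(donor[[ch]], lab)
    a <- .residue_at(acceptor[[ch]], lab)
    if (is.na(d) || is.na(a) || d == a) next
    out <- rbind(out, data.frame(
      position = lab, chain = ch, donor_aa = d, acceptor_aa = a,
      category = category,
      rationale = sprintf("%s: donor %s vs acceptor %s at %s", category, d, a, lab),
      stringsAsFactors = FALSE
    ))
  }
  .order_ledger(out)
}

#' Graft donor CDRs onto an acceptor framework
#'
#' Builds a humanized V-region pair: every CDR position (under `partition`,
#' including donor insertions/deletions inside the CDRs) carries the donor
#' residue, every framework position carries the acceptor residue. The
#' returned design starts with an empty back-mutation ledger; see
#' [apply_back_mutations()].
#'
#' @param donor,acceptor lists with `numbered_vregion` elements `H` and `L`.
#' @param partition a [kabat_partition()].
#' @return An object of class `graft_design` with fields `donor_id`,
#'   `acceptor_id`, `partition`, `cdr_seqs`, `back_mutations`, `heavy`,
#'   `light`, `log`.
#' @examples
#' d <- synthetic_fv_pair("donor"); a <- synthetic_fv_pair("acceptor_4nry")
#' design <- graft_cdrs(d, a)
#' design$cdr_seqs[["CDR-H2"]]
#' @export
graft_cdrs <- function(donor, acceptor, partition = kabat_partition()) {
  donor <- .pair_check(donor)
  acceptor <- .pair_check(acceptor)
  chains <- list()
  cdr_seqs <- list()
  for (ch in c("H", "L")) {
    d <- donor[[ch]]
    a <- acceptor[[ch]]
    d_reg <- kabat_region_of(d$labels, partition)
    a_reg <- kabat_region_of(a$labels, partition)
    for (nm in names(partition$cdr)) {
      if (substr(nm, 5, 5) == ch && !any(d_reg == nm)) {
        stop("donor CDR span missing: ", nm)
      }
    }
    keep_d <- grepl("^CDR", d_reg)
    keep_a <- grepl("^FR", a_reg)
    labels <- c(d$labels[keep_d], a$labels[keep_a])
    aa <- c(d$aa[keep_d], a$aa[keep_a])
    o <- order(kabat_sort_key(labels))
    chains[[ch]] <- numbered_vregion(ch, labels[o], aa[o],
                                     source_id = sprintf("graft(%s>%s)",
                                                         d$source_id, a$source_id))
    for (nm in unique(d_reg[keep_d])) {
      cdr_seqs[[nm]] <- paste(d$aa[d_reg == nm], collapse = "")
    }
  }
  structure(list(
    donor_id = donor$H$source_id, acceptor_id = acceptor$H$source_id,
    partition = partition, cdr_seqs = cdr_seqs,
    back_mutations = .empty_ledger(),
    heavy = chains$H, light = chains$L,
    acceptor = acceptor, donor = donor,
    log = sprintf("grafted %d CDR spans from donor onto acceptor frameworks",
                  length(cdr_seqs))
  ), class = "graft_design")
}

#' @export
print.graft_design <- function(x, ...) {
  cat("CDR graft design:", x$donor_id, "->", x$acceptor_id, "\n")
  cat("  CDRs transferred:", paste(names(x$cdr_seqs), collapse = ", "), "\n")
  cat("  back-mutations:", nrow(x$back_mutations), "\n")
  if (nrow(x$back_mutations) > 0) {
    cat("   ", paste(sprintf("%s%s>%s", x$back_mutations$position,
                             x$back_mutations$acceptor_aa,
                             x$back_mutations$donor_aa), collapse = " "), "\n")
  }
  invisible(x)
}

#' Propose vernier-zone back-mutations
#'
#' Every framework position of the vernier set where donor and acceptor
#' differ becomes a candidate back-mutation (category `"vernier"`), ordered
#' by chain (H before L) then position.
#'
#' @param donor,acceptor numbered pairs (lists with `H` and `L`).
#' @param vernier character vector of Kabat labels; default [vernier_zone()].
#' @param partition a [kabat_partition()].
#' @return data.frame ledger of candidates.
#' @export
propose_vernier_backmutations <- function(donor, acceptor,
                                          vernier = vernier_zone(),
                                          partition = kabat_partition()) {
  .mismatch_candidates(.pair_check(donor), .pair_check(acceptor),
                       vernier, "vernier", partition)
}

#' Propose N-terminal back-mutations
#'
#' Mismatches at the configured N-terminal positions (default H1-H3 and
#' L1-L4) become candidates (category `"n_terminal"`); positions where donor
#' and acceptor already agree are omitted.
#'
#' @inheritParams propose_vernier_backmutations
#' @param positions Kabat labels to inspect.
#' @export
propose_nterminal_backmutations <- function(donor, acceptor,
                                            positions = c("H1", "H2", "H3",
                                                          "L1", "L2", "L3", "L4"),
                                            partition = kabat_partition()) {
  .mismatch_candidates(.pair_check(donor), .pair_check(acceptor),
                       positions, "n_terminal", partition)
}

#' Propose refinement back-mutations at explicit positions
#'
#' Refinement positions (found by a second round of rational analysis rather
#' than by the vernier table) are config-driven: supply them explicitly.
#'
#' @inheritParams propose_nterminal_backmutations
#' @export
propose_refinement_backmutations <- function(donor, acceptor, positions,
                                             partition = kabat_partition()) {
  .mismatch_candidates(.pair_check(donor), .pair_check(acceptor),
                       positions, "refinement", partition)
}

#' Apply selected back-mutations to a graft design
#'
#' Sets the donor residue at each selected framework position and extends the
#' ledger. Re-applying a mutation already in the ledger is a no-op (with a
#' warning), so application is idempotent.
#'
#' @param design a [graft_cdrs()] design.
#' @param selected ledger data.frame (rows from the `propose_*` functions).
#' @return the updated `graft_design`.
#' @export
apply_back_mutations <- function(design, selected) {
  stopifnot(inherits(design, "graft_design"))
  if (is.null(selected) || nrow(selected) == 0) return(design)
  for (i in seq_len(nrow(selected))) {
    row <- selected[i, ]
    region <- kabat_region_of(row$position, design$partition)
    if (grepl("^CDR", region)) {
      stop("back-mutation position ", row$position, " lies inside ", region)
    }
    slot <- if (row$chain == "H") "heavy" else "light"
    chain <- design[[slot]]
    j <- match(row$position, chain$labels)
    if (is.na(j)) stop("position ", row$position, " absent from design")
    if (chain$aa[j] == row$donor_aa) {
      warning("donor residue already present at ", row$position, "; no-op")
      next
    }
    if (chain$aa[j] != row$acceptor_aa) {
      stop("current residue at ", row$position, " (", chain$aa[j],
           ") does not match the recorded acceptor residue ", row$acceptor_aa)
    }
    chain$aa[j] <- row$donor_aa
    design[[slot]] <- chain
    design$back_mutations <- .order_ledger(rbind(design$back_mutations, row))
  }
  design
}

#' Revert a back-mutation
#'
#' Restores the acceptor residue at a ledgered position and removes the ledger
#' row; applying then reverting a mutation restores the prior design.
#'
#' @param design a `graft_design`.
#' @param position Kabat label present in the ledger.
#' @export
revert_back_mutation <- function(design, position) {
  stopifnot(inherits(design, "graft_design"))
  i <- match(position, design$back_mutations$position)
  if (is.na(i)) stop("position ", position, " not in the ledger")
  row <- design$back_mutations[i, ]
  slot <- if (row$chain == "H") "heavy" else "light"
  chain <- design[[slot]]
  j <- match(position, chain$labels)
  chain$aa[j] <- row$acceptor_aa
  design[[slot]] <- chain
  design$back_mutations <- design$back_mutations[-i, , drop = FALSE]
  design
}

#' Framework and CDR differences between two numbered pairs
#'
#' @param a,b numbered pairs (lists with `H` and `L`).
#' @param partition a [kabat_partition()].
#' @return list with data.frames `framework` and `cdr`, each with columns
#'   `position`, `aa_a`, `aa_b`, `region`; positions present in only one pair
#'   are reported with `NA` for the missing side.
#' @export
diff_frameworks <- function(a, b, partition = kabat_partition()) {
  a <- .pair_check(a)
  b <- .pair_check(b)
  rows <- list()
  for (ch in c("H", "L")) {
    labels <- union(a[[ch]]$labels, b[[ch]]$labels)
    labels <- labels[order(kabat_sort_key(labels))]
    for (lab in labels) {
      ra <- .residue_at(a[[ch]], lab)
      rb <- .residue_at(b[[ch]], lab)
      if (identical(ra, rb)) next
      if (is.na(ra) && is.na(rb)) next
      rows[[length(rows) + 1]] <- data.frame(
        position = lab, aa_a = ra, aa_b = rb,
        region = kabat_region_of(lab, partition), stringsAsFactors = FALSE)
    }
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = character(0), aa_a = character(0),
               aa_b = character(0), region = character(0),
               stringsAsFactors = FALSE)
  list(framework = d[grepl("^FR", d$region), , drop = FALSE],
       cdr = d[grepl("^CDR", d$region), , drop = FALSE])
}

#' Final sequences of a design
#'
#' @param design a `graft_design`.
#' @return named character vector with elements `H` and `L`.
#' @export
design_sequences <- function(design) {
  stopifnot(inherits(design, "graft_design"))
  c(H = vregion_seq(design$heavy), L = vregion_seq(design$light))
}
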