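# Kabat numbering of antibody V-region sequences.
#
# Strategy: ends-free alignment of the input against a built-in consensus
# template per chain kind, then deterministic re-labelling of each region from
# its length using the canonical Kabat insertion/deletion sites. No external
# numbering service is consulted.

# Built-in templates. Region lengths are canonical Kabat lengths; FR-H3
# includes the near-universal 82A-82C insertions.
.kabat_templates <- function() {
  list(
    H = list(
      regions = c("FR-H1", "CDR-H1", "FR-H2", "CDR-H2", "FR-H3", "CDR-H3", "FR-H4"),
      seqs = c(
        "FR-H1"  = "EVQLVESGGGLVQPGGSLRLSCAAS",
        "CDR-H1" = "GFTFSSYAMS",
        "FR-H2"  = "WVRQAPGKGLEWVS",
        "CDR-H2" = "AISGSGGSTYYADSVK",
        "FR-H3"  = "GRFTISRDNSKNTLYLQMNSLRAEDTAVYCAR",
        "CDR-H3" = "DRGYSFDY",
        "FR-H4"  = "WGQGTLVTVSS"
      )
    ),
    L = list(
      regions = c("FR-L1", "CDR-L1", "FR-L2", "CDR-L2", "FR-L3", "CDR-L3", "FR-L4"),
      seqs = c(
        "FR-L1"  = "DIQMTQSPSSLSASVGDRVTITC",
        "CDR-L1" = "RASQSISSYLN",
        "FR-L2"  = "WYQQKPGKAPKLLIY",
        "CDR-L2" = "AASSLQS",
        "FR-L3"  = "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC",
        "CDR-L3" = "QQSYSTPWT",
        "FR-L4"  = "FGQGTKVEIK"
      )
    )
  )
}

# Canonical label list per region: base labels plus the index (within the base
# list) after which insertion letters are appended, and the index at which
# deletions are absorbed (removal proceeds backwards from there).
.kabat_region_rules <- function(chain) {
  lab <- function(ch, nums) paste0(ch, nums)
  if (chain == "H") {
    list(
      "FR-H1"  = list(base = lab("H", 1:25), kind = "fr", trunc = "start"),
      "CDR-H1" = list(base = lab("H", 26:35), kind = "cdr", ins_after = "H35"),
      "FR-H2"  = list(base = lab("H", 36:49), kind = "fr", trunc = "none"),
      "CDR-H2" = list(base = lab("H", 50:65), kind = "cdr", ins_after = "H52"),
      "FR-H3"  = list(base = c(lab("H", 66:82), "H82A", "H82B", "H82C", lab("H", 83:94)),
                      kind = "fr", trunc = "inserts"),
      "CDR-H3" = list(base = lab("H", 95:102), kind = "cdr", ins_after = "H100"),
      "FR-H4"  = list(base = lab("H", 103:113), kind = "fr", trunc = "end")
    )
  } else {
    list(
      "FR-L1"  = list(base = lab("L", 1:23), kind = "fr", trunc = "start"),
      "CDR-L1" = list(base = lab("L", 24:34), kind = "cdr", ins_after = "L27"),
      "FR-L2"  = list(base = lab("L", 35:49), kind = "fr", trunc = "none"),
      "CDR-L2" = list(base = lab("L", 50:56), kind = "cdr", ins_after = "L54"),
      "FR-L3"  = list(base = lab("L", 57:88), kind = "fr", trunc = "none"),
      "CDR-L3" = list(base = lab("L", 89:97), kind = "cdr", ins_after = "L95"),
      "FR-L4"  = list(base = lab("L", 98:107), kind = "fr", trunc = "end")
    )
  }
}

.kabat_anchors <- list(
  H = c(H22 = "C", H36 = "W", H92 = "C", H103 = "W"),
  L = c(L23 = "C", L35 = "W", L88 = "C")
)

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a numbered V-region from labels and residues
#'
#' The alternative ingestion path for pre-numbered residues (e.g. an
#' AbDb-style coordinate file whose author numbering already encodes Kabat
#' labels), bypassing the alignment-based numbering.
#'
#' @param chain_kind `"H"` or `"L"`.
#' @param labels character vector of Kabat labels, strictly increasing.
#' @param aa character vector of one-letter amino acids (same length).
#' @param source_id free-text identifier recorded with the domain.
#' @return An object of class `numbered_vregion` with fields `chain_kind`,
#'   `labels`, `aa`, `source_id`.
#' @export
numbered_vregion <- function(chain_kind, labels, aa, source_id = "") {
  chain_kind <- match.arg(chain_kind, c("H", "L"))
  stopifnot(length(labels) == length(aa))
  aa <- toupper(aa)
  if (!all(aa %in% .aa_alphabet)) {
    stop("non-standard amino acid code(s): ",
         paste(unique(aa[!aa %in% .aa_alphabet]), collapse = ", "))
  }
  pos <- parse_kabat_position(labels)
  if (!all(pos$chain == chain_kind)) {
    stop("labels must all belong to chain kind ", chain_kind)
  }
  if (anyDuplicated(labels)) stop("duplicate Kabat positions")
  key <- kabat_sort_key(labels)
  if (any(diff(key) <= 0)) stop("Kabat positions must be strictly increasing")
  structure(list(chain_kind = chain_kind, labels = labels, aa = aa,
                 source_id = source_id),
            class = "numbered_vregion")
}

#' @export
print.numbered_vregion <- function(x, ...) {
  cat(sprintf("Numbered V-region (%s chain, %d residues%s)\n", x$chain_kind,
              length(x$labels),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  cat(" ", paste0(x$aa, "(", x$labels, ")")[seq_len(min(8, length(x$labels)))],
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.numbered_vregion <- function(x, ...) {
  data.frame(label = x$labels, aa = x$aa, stringsAsFactors = FALSE)
}

#' Sequence of a numbered V-region
#' @param region a `numbered_vregion`.
#' @return single string of one-letter residues in position order.
#' @export
vregion_seq <- function(region) paste(region$aa, collapse = "")

# Align query to the chain template; returns, per query index, the template
# index it pairs with (NA for insertions) and the query range covered.
.align_to_template <- function(seq, template) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(template),
    type = "overlap", substitutionMatrix = e$BLOSUM62,
    gapOpening = 10, gapExtension = 4
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  ti <- Biostrings::start(Biostrings::subject(pa)) - 1L
  map_q <- integer(0)
  map_t <- integer(0)
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (ta[k] != "-") ti <- ti + 1L
    if (qa[k] != "-") {
      map_q <- c(map_q, qi)
      map_t <- c(map_t, if (ta[k] != "-") ti else NA_integer_)
    }
  }
  list(query_idx = map_q, template_idx = map_t)
}

# Assign each query residue to a template region. Aligned residues start from
# the region of their template column; unaligned (inserted) residues take the
# CDR among their flanking regions when the flanks straddle a boundary. A
# repair pass then enforces canonical framework lengths by shifting boundary
# residues into the adjacent CDRs, which absorb all length variation (the
# Kabat convention); without this, a chance identity at a CDR/framework
# boundary could smuggle a CDR insertion into the framework.
.attribute_regions <- function(al, tpl, rules, reg_start) {
  n <- length(al$query_idx)
  ok <- !is.na(al$template_idx)
  reg <- rep(NA_integer_, n)
  reg[ok] <- findInterval(al$template_idx[ok], reg_start)
  is_cdr <- grepl("^CDR", tpl$regions)
  for (k in which(!ok)) {
    prev <- if (k > 1) reg[k - 1] else NA_integer_
    nxt_i <- which(ok & seq_len(n) > k)
    nxt <- if (length(nxt_i)) reg[nxt_i[1]] else NA_integer_
    cand <- c(prev, nxt)
    cand <- cand[!is.na(cand)]
    if (!length(cand)) stop("numbering failure: empty alignment")
    cdrs <- cand[is_cdr[cand]]
    reg[k] <- if (length(cdrs)) cdrs[1] else cand[1]
  }
  canon <- vapply(tpl$regions, function(nm) length(rules[[nm]]$base), 1L)
  for (r in which(!is_cdr)) {
    trunc <- rules[[tpl$regions[r]]]$trunc
    # over-long framework: shed edge residues into a neighbouring CDR
    while (sum(reg == r) > canon[r]) {
      idx <- which(reg == r)
      if (r > 1 && is_cdr[r - 1]) {
        reg[idx[1]] <- r - 1
      } else if (r < length(canon) && is_cdr[r + 1]) {
        reg[idx[length(idx)]] <- r + 1
      } else {
        stop("numbering failure: framework region ", tpl$regions[r],
             " longer than canonical")
      }
    }
    # under-long interior framework: pull edge residues back from a CDR
    floor_len <- if (identical(trunc, "inserts")) canon[r] - 3 else canon[r]
    if (identical(trunc, "start") || identical(trunc, "end")) next
    while (sum(reg == r) < floor_len) {
      idx <- which(reg == r)
      if (r > 1 && is_cdr[r - 1] && sum(reg == r - 1) > 1) {
        prev_idx <- which(reg == r - 1)
        reg[prev_idx[length(prev_idx)]] <- r
      } else if (r < length(canon) && is_cdr[r + 1] && sum(reg == r + 1) > 1) {
        reg[which(reg == r + 1)[1]] <- r
      } else {
        stop("numbering failure: framework region ", tpl$regions[r],
             " shorter than canonical")
      }
    }
  }
  reg
}

# Label one region segment of the query given its length.
.label_segment <- function(n, rule, region) {
  base <- rule$base
  nb <- length(base)
  if (n == nb) return(base)
  if (n > nb) {
    extra <- n - nb
    if (identical(rule$kind, "fr")) {
      if (identical(rule$trunc, "inserts")) {
        stop("numbering failure: framework region ", region,
             " longer than canonical")
      }
      stop("numbering failure: framework region ", region,
           " longer than canonical (", n, " > ", nb, ")")
    }
    if (extra > 26) stop("numbering failure: too many insertions in ", region)
    at <- match(rule$ins_after, base)
    ins <- paste0(rule$ins_after, LETTERS[seq_len(extra)])
    return(append(base, ins, after = at))
  }
  # n < nb: deletions
  d <- nb - n
  if (identical(rule$kind, "fr")) {
    if (identical(rule$trunc, "start")) return(base[(d + 1):nb])
    if (identical(rule$trunc, "end")) return(base[1:(nb - d)])
    if (identical(rule$trunc, "inserts")) {
      ins_at <- grep("[A-Z]$", sub("^[HL][0-9]+", "", base))
      ins_at <- which(grepl("^[HL][0-9]+[A-Z]$", base))
      if (d > length(ins_at)) {
        stop("numbering failure: framework region ", region,
             " shorter than canonical")
      }
      drop <- rev(ins_at)[seq_len(d)]
      return(base[-drop])
    }
    stop("numbering failure: framework region ", region,
         " shorter than canonical")
  }
  # CDR deletions absorbed backwards from the canonical insertion site
  at <- match(rule$ins_after, base)
  if (d >= at) stop("numbering failure: ", region, " too short")
  base[-seq(at, at - d + 1)]
}

#' Kabat-number an antibody V-region sequence
#'
#' Assigns a unique Kabat label to every residue by ends-free alignment
#' against a built-in consensus template for the chain kind, followed by
#' deterministic per-region labelling: insertions receive letters only at the
#' canonical sites (after L27, L54, L95, H35, H52, H100; framework 82A-82C),
#' and length deficits are absorbed at the same sites. Residues aligning
#' beyond the template (e.g. appended constant-domain residues) are dropped,
#' so interior labels are stable under flanking extensions.
#'
#' @param seq amino-acid string, 60-140 residues.
#' @param chain_kind `"H"` or `"L"`.
#' @param source_id free-text identifier stored with the result.
#' @return A [numbered_vregion()].
#' @examples
#' vh <- kabat_number_sequence(vregion_seq(synthetic_vregion("donor", "H")), "H")
#' head(vh$labels)
#' @export
kabat_number_sequence <- function(seq, chain_kind, source_id = "") {
  chain_kind <- match.arg(chain_kind, c("H", "L"))
  seq <- toupper(gsub("\\s", "", seq))
  n <- nchar(seq)
  if (n < 60 || n > 140) {
    stop("length error: V-region sequence must have 60-140 residues, got ", n)
  }
  aa <- strsplit(seq, "")[[1]]
  if (!all(aa %in% .aa_alphabet)) {
    stop("non-standard amino acid code(s): ",
         paste(unique(aa[!aa %in% .aa_alphabet]), collapse = ", "))
  }
  tpl <- .kabat_templates()[[chain_kind]]
  template <- paste(tpl$seqs, collapse = "")
  reg_len <- nchar(tpl$seqs)
  reg_end <- cumsum(reg_len)
  reg_start <- reg_end - reg_len + 1L
  al <- .align_to_template(seq, template)
  rules <- .kabat_region_rules(chain_kind)
  t_region <- .attribute_regions(al, tpl, rules, reg_start)
  labels <- character(0)
  aa_out <- character(0)
  for (r in seq_along(tpl$regions)) {
    nm <- tpl$regions[r]
    idx <- al$query_idx[t_region == r]
    if (length(idx) == 0) {
      if (grepl("^CDR", nm)) stop("numbering failure: missing region ", nm)
      next
    }
    labels <- c(labels, .label_segment(length(idx), rules[[nm]], nm))
    aa_out <- c(aa_out, aa[idx])
  }

  res <- numbered_vregion(chain_kind, labels, aa_out, source_id)
  anchors <- .kabat_anchors[[chain_kind]]
  for (a in names(anchors)) {
    i <- match(a, res$labels)
    if (!is.na(i) && res$aa[i] != anchors[[a]]) {
      stop("numbering failure: anchor ", a, " expected ", anchors[[a]],
           " but found ", res$aa[i])
    }
  }
  res
}

#' Extract named regions from a numbered V-region
#'
#' Partitions the residues of a numbered domain into CDR and framework
#' subsequences. Every residue is assigned to exactly one region; a residue
#' outside all spans raises a partition-coverage error. Concatenating the
#' returned subsequences in position order reproduces the input sequence.
#'
#' @param region a [numbered_vregion()].
#' @param partition a [kabat_partition()].
#' @return Named list of region subsequences (strings), with a `"positions"`
#'   attribute holding the label vector per region.
#' @export
extract_regions <- function(region, partition = kabat_partition()) {
  stopifnot(inherits(region, "numbered_vregion"))
  rg <- kabat_region_of(region$labels, partition)
  nms <- unique(rg[order(kabat_sort_key(region$labels))])
  out <- lapply(nms, function(nm) paste(region$aa[rg == nm], collapse = ""))
  names(out) <- nms
  attr(out, "positions") <- lapply(stats::setNames(nms, nms),
                                   function(nm) region$labels[rg == nm])
  out
}
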