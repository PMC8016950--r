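#' Parse a Kabat position label
#'
#' A Kabat label is a chain letter (`H` or `L`), a positive residue number and
#' an optional single insertion letter, e.g. `"H52A"` or `"L27D"`. Ordering of
#' positions sharing a number is: no insertion < `A` < `B` < ... < `Z`.
#'
#' @param label character vector of labels such as `"H52A"`.
#' @return A data.frame with columns `chain` (`"H"`/`"L"`), `number` (integer)
#'   and `insertion` (single letter or `NA`), one row per label.
#' @examples
#' parse_kabat_position(c("H52A", "L27D", "H1"))
#' @export
parse_kabat_position <- function(label) {
  stopifnot(is.character(label), length(label) >= 1L)
  m <- regmatches(label, regexec("^([HL])([0-9]+)([A-Z]?)$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed Kabat label(s): ", paste(label[bad], collapse = ", "))
  }
  chain <- vapply(m, `[[`, "", 2L)
  number <- as.integer(vapply(m, `[[`, "", 3L))
  insertion <- vapply(m, `[[`, "", 4L)
  if (any(number < 1L)) stop("Kabat numbers must be positive")
  insertion[insertion == ""] <- NA_character_
  data.frame(chain = chain, number = number, insertion = insertion,
             stringsAsFactors = FALSE)
}

#' Format Kabat positions back to labels
#'
#' Inverse of [parse_kabat_position()]: `format_kabat_position(
#' parse_kabat_position(x))` reproduces `x`.
#'
#' @param pos data.frame with columns `chain`, `number`, `insertion`.
#' @return character vector of labels.
#' @export
format_kabat_position <- function(pos) {
  ins <- ifelse(is.na(pos$insertion), "", pos$insertion)
  paste0(pos$chain, pos$number, ins)
}

#' Sort key for Kabat labels
#'
#' Returns a numeric key that orders labels by (number, insertion) with
#' no-insertion sorting before `"A"`. Chains are not mixed: an error is raised
#' if labels from both chains are supplied, since H/L ordering is a
#' presentation choice handled by the caller.
#'
#' @param label character vector of Kabat labels (single chain kind).
#' @return numeric sort key.
#' @export
kabat_sort_key <- function(label) {
  pos <- parse_kabat_position(label)
  if (length(unique(pos$chain)) > 1L) {
    stop("kabat_sort_key() expects labels from a single chain kind")
  }
  ins_rank <- ifelse(is.na(pos$insertion), 0L, match(pos$insertion, LETTERS))
  pos$number * 100 + ins_rank
}

#' Compare Kabat labels
#'
#' @param a,b single Kabat labels on the same chain.
#' @return -1, 0 or 1 as `a` is before, equal to, or after `b`.
#' @export
kabat_compare <- function(a, b) {
  k <- kabat_sort_key(c(a, b))
  sign(k[1] - k[2])
}

# Inclusive span test on the numeric part: insertions inherit their number's
# span (H52A lies in H50-H65).
kabat_in_span <- function(label, chain, from, to) {
  pos <- parse_kabat_position(label)
  pos$chain == chain & pos$number >= from & pos$number <= to
}

#' CDR/framework partition of Kabat-numbered V-regions
#'
#' Returns the region masks used throughout the package: CDRs L24-34, L50-56,
#' L89-97, H26-35, H50-65, H95-102 and frameworks L1-23, L35-49, L57-88,
#' L98-107, H1-25, H36-49, H66-94, H103-`fr_h4_end`. Note that CDR-H1 is
#' defined as H26-35 (the extended mask used for graft design), not the strict
#' Kabat H31-35.
#'
#' @param chothia_l1 logical; if `TRUE` the CDR-L1 span is the union of the
#'   Kabat span (L24-34) and the Chothia span (L26-32). The union equals
#'   L24-34, so the flag documents intent (graft-transfer of L26-L30 with the
#'   loop) rather than changing membership.
#' @param fr_h4_end last heavy-chain framework-4 position. The default 113
#'   covers complete Kabat-numbered V_H domains; use 111 to reproduce the
#'   framework mask conventionally used for Calpha superposition (the default
#'   inside [superpose_frameworks()]).
#' @return An object of class `region_partition`: a list with elements `cdr`
#'   and `framework`, each a named list of `c(chain, from, to)` spans
#'   (inclusive), plus the `chothia_l1` flag.
#' @examples
#' p <- kabat_partition()
#' names(p$cdr)
#' @export
kabat_partition <- function(chothia_l1 = FALSE, fr_h4_end = 113) {
  span <- function(chain, from, to) list(chain = chain, from = from, to = to)
  part <- list(
    cdr = list(
      "CDR-L1" = span("L", 24, 34),
      "CDR-L2" = span("L", 50, 56),
      "CDR-L3" = span("L", 89, 97),
      "CDR-H1" = span("H", 26, 35),
      "CDR-H2" = span("H", 50, 65),
      "CDR-H3" = span("H", 95, 102)
    ),
    framework = list(
      "FR-L1" = span("L", 1, 23),
      "FR-L2" = span("L", 35, 49),
      "FR-L3" = span("L", 57, 88),
      "FR-L4" = span("L", 98, 107),
      "FR-H1" = span("H", 1, 25),
      "FR-H2" = span("H", 36, 49),
      "FR-H3" = span("H", 66, 94),
      "FR-H4" = span("H", 103, fr_h4_end)
    ),
    chothia_l1 = isTRUE(chothia_l1)
  )
  class(part) <- "region_partition"
  part
}

#' Assign each Kabat label to its region
#'
#' @param label character vector of Kabat labels.
#' @param partition a [kabat_partition()] object.
#' @param strict if `TRUE` (default) positions outside every span raise a
#'   partition-coverage error; if `FALSE` they yield `NA` (useful when a
#'   partition is used as a mask rather than a covering).
#' @return character vector of region names.
#' @export
kabat_region_of <- function(label, partition = kabat_partition(),
                            strict = TRUE) {
  spans <- c(partition$cdr, partition$framework)
  pos <- parse_kabat_position(label)
  out <- rep(NA_character_, length(label))
  for (nm in names(spans)) {
    s <- spans[[nm]]
    hit <- pos$chain == s$chain & pos$number >= s$from & pos$number <= s$to
    out[hit & is.na(out)] <- nm
  }
  if (strict && anyNA(out)) {
    stop("partition-coverage error: position(s) outside all spans: ",
         paste(label[is.na(out)], collapse = ", "))
  }
  out
}

#' @export
print.region_partition <- function(x, ...) {
  fmt <- function(s) sprintf("%s%d-%d", s$chain, s$from, s$to)
  cat("Kabat region partition\n")
  cat("  CDRs:      ", paste(names(x$cdr), vapply(x$cdr, fmt, ""),
                             sep = "=", collapse = "  "), "\n")
  cat("  Frameworks:", paste(names(x$framework), vapply(x$framework, fmt, ""),
                             sep = "=", collapse = "  "), "\n")
  if (x$chothia_l1) cat("  CDR-L1 includes the Chothia L26-L32 extension\n")
  invisible(x)
}
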