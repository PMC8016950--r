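# Framework-restricted Calpha superposition and Q-score ranking of human
# acceptor Fv candidates.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets (rows correspond).
#'
#' @param x,y n-by-3 matrices; `x` is moved onto `y`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd`; the fitted coordinates are `x %*% t(rotation) + translation`.
#' @export
kabsch <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3, all(dim(x) == dim(y)),
            nrow(x) >= 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  s <- svd(t(x0) %*% y0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- x0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - y0)^2)))
  list(rotation = rot, translation = as.numeric(cy - rot %*% cx), rmsd = rmsd)
}

#' Superpose two Fv structures on their framework C-alphas
#'
#' Correspondence is by identical Kabat label within the framework masks of
#' both chains (the deterministic recipe for framework-restricted
#' superposition); the rigid fit is the Kabsch least-squares solution.
#'
#' @param query,target `fv_structure` objects (Kabat-keyed).
#' @param masks a [kabat_partition()]; its framework spans define the mask.
#'   The default uses the published superposition mask ending at H111.
#' @param min_common minimum number of shared framework C-alpha positions.
#' @return list of class `superposition_result`: `rotation`, `translation`
#'   (moving query onto target), `rmsd`, `n_align`, `labels`.
#' @export
superpose_frameworks <- function(query, target,
                                 masks = kabat_partition(fr_h4_end = 111),
                                 min_common = 20) {
  fw_labels <- function(fv) {
    ca <- fv_ca_coords(fv)
    lab <- rownames(ca)
    reg <- kabat_region_of(lab, masks, strict = FALSE)
    lab[!is.na(reg) & grepl("^FR", reg)]
  }
  common <- intersect(fw_labels(query), fw_labels(target))
  if (length(common) < min_common) {
    stop("insufficient overlap: only ", length(common),
         " common framework positions (need >= ", min_common, ")")
  }
  qx <- fv_ca_coords(query, common)[common, , drop = FALSE]
  tx <- fv_ca_coords(target, common)[common, , drop = FALSE]
  fit <- kabsch(qx, tx)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_align = length(common), labels = common),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition: %d aligned Calpha, rmsd %.3f A\n",
              x$n_align, x$rmsd))
  invisible(x)
}

#' Length-weighted structural similarity score (Q)
#'
#' `Q = n_align^2 / ((1 + (rmsd/r0)^2) * n_query * n_target)`: the mean
#' square deviation weighted by alignment length, 1 only for a perfect
#' self-match. The default distance constant is `r0 = 3` angstrom (the SSM
#' convention).
#'
#' @param n_align matched position count.
#' @param rmsd RMSD over matched positions (angstrom).
#' @param n_query,n_target residue counts of the two structures.
#' @param r0 distance weighting constant in angstrom.
#' @return numeric Q in (0, 1].
#' @examples
#' q_score(220, 0.89, 227, 229)
#' @export
q_score <- function(n_align, rmsd, n_query, n_target, r0 = 3.0) {
  if (any(c(n_align, n_query, n_target) <= 0)) {
    stop("domain error: counts must be positive")
  }
  if (any(rmsd < 0) || r0 <= 0) stop("domain error: rmsd must be >= 0, r0 > 0")
  n_align^2 / ((1 + (rmsd / r0)^2) * n_query * n_target)
}

#' Rank acceptor candidates against a query Fv
#'
#' Each library entry is superposed on the query (framework-masked Kabsch
#' fit) and scored with [q_score()]. By default the RMSD and `n_align`
#' entering Q are computed over all shared Kabat positions (CDRs included)
#' under the framework-fitted transform — the full-Fv mode; set
#' `framework_only = TRUE` to restrict both to the framework mask. Sequence
#' identity is the percentage of matching residues over aligned positions.
#'
#' @param query an `fv_structure`.
#' @param library named list of `fv_structure` objects (names = identifiers).
#' @param meta optional data.frame with columns `pdb_id` and `source_tag`.
#' @param masks a [kabat_partition()] supplying the framework mask.
#' @param r0 Q-score constant (angstrom).
#' @param framework_only restrict scoring to the framework mask.
#' @return data.frame of class `acceptor_ranking`, sorted by Q descending
#'   (ties: rmsd ascending, then id), with columns `pdb_id`, `q`, `rmsd`,
#'   `n_align`, `n_residue`, `seq_identity`, `source_tag`. Entries that fail
#'   to superpose are skipped and recorded in the `"failed"` attribute.
#' @export
rank_acceptors <- function(query, library, meta = NULL,
                           masks = kabat_partition(fr_h4_end = 111),
                           r0 = 3.0, framework_only = FALSE) {
  stopifnot(length(library) >= 1)
  ids <- names(library)
  if (is.null(ids)) ids <- sprintf("entry%03d", seq_along(library))
  q_at <- rbind(query$heavy, query$light)
  q_aa <- q_at$aa[q_at$elety == "CA"]
  names(q_aa) <- q_at$kabat[q_at$elety == "CA"]
  n_query <- length(q_aa)
  rows <- list()
  failed <- character(0)
  for (k in seq_along(library)) {
    tgt <- library[[k]]
    res <- tryCatch({
      sup <- superpose_frameworks(query, tgt, masks = masks)
      t_at <- rbind(tgt$heavy, tgt$light)
      t_aa <- t_at$aa[t_at$elety == "CA"]
      names(t_aa) <- t_at$kabat[t_at$elety == "CA"]
      shared <- if (framework_only) sup$labels else
        intersect(names(q_aa), names(t_aa))
      qx <- fv_ca_coords(query, shared)[shared, , drop = FALSE]
      tx <- fv_ca_coords(tgt, shared)[shared, , drop = FALSE]
      qfit <- sweep(qx %*% t(sup$rotation), 2, sup$translation, "+")
      rmsd <- sqrt(mean(rowSums((qfit - tx)^2)))
      ident <- round(100 * mean(q_aa[shared] == t_aa[shared]))
      data.frame(
        pdb_id = ids[k],
        q = q_score(length(shared), rmsd, n_query, length(t_aa), r0),
        rmsd = rmsd, n_align = length(shared), n_residue = length(t_aa),
        seq_identity = ident, stringsAsFactors = FALSE)
    }, error = function(e) {
      failed <<- c(failed, sprintf("%s: %s", ids[k], conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  out$source_tag <- if (!is.null(meta)) {
    as.character(meta$source_tag[match(out$pdb_id, meta$pdb_id)])
  } else NA_character_
  out <- out[order(-out$q, out$rmsd, out$pdb_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  class(out) <- c("acceptor_ranking", class(out))
  out
}

#' Filter ranked candidates by source annotation
#'
#' @param candidates an acceptor ranking (or any data.frame with a
#'   `source_tag` column).
#' @param allowed character vector of allowed tags (e.g. `"Human"`).
#' @return the filtered candidates, order preserved.
#' @export
filter_by_source <- function(candidates, allowed) {
  candidates[candidates$source_tag %in% allowed, , drop = FALSE]
}
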