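# Conjugate and radiotracer arithmetic: average masses, adduct annotation,
# extinction coefficients, decay correction, specific activity, radiochemical
# purity and biodistribution (%ID/g) tables.

# average (not monoisotopic) residue masses in Da; ESI-MS of large proteins
# reports average mass
.aa_avg_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mass <- 18.0153
.disulfide_delta <- -2.0159  # loss of two hydrogens per bridge

#' Average molecular mass of a (multi-chain) protein
#'
#' Sum of average residue masses plus one water per chain, minus two
#' hydrogens per disulfide bridge, plus any modification deltas.
#'
#' @param sequences character vector of chain sequences.
#' @param modifications named numeric vector of mass additions in Da
#'   (e.g. `c(Cy7_maleimide = 830.10)`).
#' @param n_disulfides number of disulfide bridges formed.
#' @param observed_mass optional measured mass for the record.
#' @return list of class `mass_record`: `theoretical_mass`, `chain_masses`,
#'   `modifications`, `n_disulfides`, `observed_mass`.
#' @examples
#' average_mass("G")$theoretical_mass  # glycine, 75.07 Da
#' @export
average_mass <- function(sequences, modifications = numeric(0),
                         n_disulfides = 0, observed_mass = NULL) {
  chain_masses <- vapply(sequences, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(aa, names(.aa_avg_mass))
    if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
    sum(.aa_avg_mass[aa]) + .water_mass
  }, numeric(1))
  total <- sum(chain_masses) + sum(modifications) +
    n_disulfides * .disulfide_delta
  structure(list(theoretical_mass = total, chain_masses = chain_masses,
                 modifications = modifications, n_disulfides = n_disulfides,
                 observed_mass = observed_mass),
            class = "mass_record")
}

#' @export
print.mass_record <- function(x, ...) {
  cat(sprintf("Mass record: theoretical %.2f Da (%d chain(s), %d disulfide(s))\n",
              x$theoretical_mass, length(x$chain_masses), x$n_disulfides))
  if (!is.null(x$observed_mass)) {
    cat(sprintf("  observed %.2f Da (delta %+.0f Da)\n", x$observed_mass,
                x$observed_mass - x$theoretical_mass))
  }
  invisible(x)
}

#' Default adduct / conjugation mass table
#'
#' Mass additions (Da) of the conjugation species handled by default:
#' disulfide-bridged N-acetylcysteine methyl ester (177 Da), Cy7-maleimide
#' (830.10 Da) and deferoxamine(Dfo)-maleimide (711.80 Da).
#'
#' @return named numeric vector of mass deltas.
#' @export
adduct_table <- function() {
  c(N_acetylcysteine_methylester = 177.0,
    Cy7_maleimide = 830.10,
    Dfo_maleimide = 711.80)
}

#' Annotate an observed-vs-theoretical mass difference
#'
#' @param observed,theoretical masses in Da.
#' @param table named vector of candidate mass deltas ([adduct_table()]).
#' @param tolerance matching tolerance in Da.
#' @return list with `delta` (Da, also rounded in `delta_rounded`), `match`
#'   (adduct name, `"none"` for delta 0 within tolerance, `"unexplained"`
#'   otherwise).
#' @export
annotate_adduct <- function(observed, theoretical, table = adduct_table(),
                            tolerance = 2) {
  stopifnot(observed > 0, theoretical > 0)
  delta <- observed - theoretical
  match_name <- if (abs(delta) <= tolerance) "none" else {
    err <- abs(table - delta)
    if (length(table) && min(err) <= tolerance) names(table)[which.min(err)]
    else "unexplained"
  }
  list(delta = delta, delta_rounded = round(delta), match = match_name)
}

#' Molar extinction coefficient at 280 nm
#'
#' The standard convention: `5500 * nTrp + 1490 * nTyr + 125 * n_cystine`
#' (per mole of protein, 1/(M*cm)).
#'
#' @param sequences chain sequences.
#' @param n_cystine number of disulfide-bonded cysteine pairs.
#' @return numeric, 1/(M*cm).
#' @export
extinction_coefficient_280 <- function(sequences, n_cystine = 0) {
  aa <- strsplit(paste(toupper(sequences), collapse = ""), "")[[1]]
  5500 * sum(aa == "W") + 1490 * sum(aa == "Y") + 125 * n_cystine
}

#' Radioactive decay correction
#'
#' @param activity activity at time zero (any unit).
#' @param elapsed_h elapsed time in hours (>= 0).
#' @param half_life_h isotope half-life in hours; default 78.41 (zirconium-89).
#' @return remaining activity, `activity * 2^(-elapsed/half_life)`.
#' @export
decay_correct <- function(activity, elapsed_h, half_life_h = 78.41) {
  stopifnot(elapsed_h >= 0, half_life_h > 0)
  activity * 2^(-elapsed_h / half_life_h)
}

#' Specific activity
#'
#' @param activity_GBq activity in GBq.
#' @param amount_umol substance amount in micromol. Alternatively supply
#'   `mass_ug` and `mw_Da` to derive it.
#' @param mass_ug,mw_Da optional mass (microgram) and molar mass (Da).
#' @return GBq per micromol.
#' @examples
#' specific_activity(0.003, mass_ug = 9, mw_Da = 65007)  # ~21.7
#' @export
specific_activity <- function(activity_GBq, amount_umol = NULL,
                              mass_ug = NULL, mw_Da = NULL) {
  if (is.null(amount_umol)) {
    if (is.null(mass_ug) || is.null(mw_Da)) {
      stop("supply amount_umol, or mass_ug together with mw_Da")
    }
    amount_umol <- mass_ug / mw_Da  # ug / (g/mol) = umol
  }
  if (amount_umol <= 0) stop("amount must be positive")
  activity_GBq / amount_umol
}

#' Radiochemical purity from a radio-trace
#'
#' Trapezoidal integral of the signal inside the main-peak window divided by
#' the total integral, in percent.
#'
#' @param position trace positions (ascending).
#' @param signal nonnegative signal values.
#' @param window `c(lo, hi)` main-peak window on the position axis.
#' @return percent of total signal inside the window.
#' @export
radiochemical_purity <- function(position, signal, window) {
  stopifnot(length(position) == length(signal), all(signal >= -1e-12),
            length(window) == 2)
  total <- pracma::trapz(position, signal)
  if (total <= 0) stop("empty trace")
  inside <- signal
  inside[position < window[1] | position > window[2]] <- 0
  100 * pracma::trapz(position, inside) / total
}

#' Biodistribution analysis: percent injected dose per gram
#'
#' Computes decay-corrected %ID/g per organ, optional named organ ratios, and
#' an unpaired two-sided Student's t comparison between groups.
#'
#' @param records data.frame with columns `organ`, `activity`, `weight`
#'   (grams) and optionally `group` and `animal`.
#' @param injected_activity injected dose, same unit as `activity`, measured
#'   at injection time.
#' @param elapsed_h time from injection to counting (hours); the injected
#'   dose is decay-corrected to counting time so that tracer kinetics, not
#'   physical decay, drive the reported uptake.
#' @param half_life_h isotope half-life (hours).
#' @param ratios named list of `c(numerator_organ, denominator_organ)` pairs.
#' @param compare_groups optional character vector of two group labels to
#'   compare organ-wise with an unpaired two-sided t-test.
#' @return list of class `biodist_report`: `records` (with `pct_id_per_g`),
#'   `ratios`, `tests` (data.frame organ, p_value, significant at 0.05;
#'   zero-variance comparisons are flagged with `NA`).
#' @export
percent_id_per_gram <- function(records, injected_activity, elapsed_h = 0,
                                half_life_h = 78.41, ratios = NULL,
                                compare_groups = NULL) {
  stopifnot(all(c("organ", "activity", "weight") %in% names(records)))
  if (any(records$weight <= 0)) stop("organ weight must be positive")
  id_at_count <- decay_correct(injected_activity, elapsed_h, half_life_h)
  records$pct_id_per_g <- 100 * (records$activity / id_at_count) / records$weight
  mean_of <- function(org) {
    v <- records$pct_id_per_g[records$organ == org]
    if (!length(v)) stop("unknown organ: ", org)
    mean(v)
  }
  ratio_out <- NULL
  if (!is.null(ratios)) {
    ratio_out <- vapply(ratios, function(pr) mean_of(pr[1]) / mean_of(pr[2]),
                        numeric(1))
  }
  tests <- NULL
  if (!is.null(compare_groups)) {
    stopifnot(length(compare_groups) == 2, "group" %in% names(records))
    organs <- unique(records$organ)
    tests <- do.call(rbind, lapply(organs, function(org) {
      g1 <- records$pct_id_per_g[records$organ == org &
                                   records$group == compare_groups[1]]
      g2 <- records$pct_id_per_g[records$organ == org &
                                   records$group == compare_groups[2]]
      p <- if (length(g1) < 2 || length(g2) < 2 ||
               (stats::sd(g1) == 0 && stats::sd(g2) == 0)) NA_real_ else
        stats::t.test(g1, g2, var.equal = TRUE)$p.value
      data.frame(organ = org, p_value = p,
                 significant = !is.na(p) & p < 0.05,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(records = records, ratios = ratio_out, tests = tests),
            class = "biodist_report")
}

#' @export
print.biodist_report <- function(x, ...) {
  agg <- stats::aggregate(pct_id_per_g ~ organ, data = x$records, FUN = mean)
  cat("Biodistribution (%ID/g, organ means):\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-24s %.2f\n", agg$organ[i], agg$pct_id_per_g[i]))
  }
  if (!is.null(x$ratios)) {
    for (nm in names(x$ratios)) cat(sprintf("  ratio %s: %.2f\n", nm, x$ratios[nm]))
  }
  invisible(x)
}
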