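# Shared fixtures and independent oracles, all built in code.

# dipeptide with a prescribed peptide-bond omega (CA-C-N-CA torsion)
make_omega_dipeptide <- function(omega_deg, chain = "A") {
  ca1 <- c(0, 0, 0)
  c1 <- c(1.52, 0, 0)
  u <- c(0.58, 1.20, 0)          # C->N bond direction (non-collinear)
  u <- u / sqrt(sum(u^2))
  n2 <- c1 + 1.33 * u
  # reference perpendicular from the CA1 side
  w <- ca1 - c1
  v0 <- w - sum(w, u * 0)        # placeholder; recompute properly below
  v0 <- w - sum(w * u) * u
  v0 <- v0 / sqrt(sum(v0^2))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  om <- omega_deg * pi / 180
  d <- cos(om) * v0 - sin(om) * cr(u, v0)
  ca2 <- n2 + 0.9 * u + 1.2 * d
  atoms <- data.frame(
    chain = chain, resno = c(1, 1, 1, 2, 2, 2),
    resid = "ALA",
    elety = c("N", "CA", "C", "N", "CA", "C"),
    element = c("N", "C", "C", "N", "C", "C"),
    x = c(-1.2, ca1[1], c1[1], n2[1], ca2[1], ca2[1] + 1.4),
    y = c(0.8, ca1[2], c1[2], n2[2], ca2[2], ca2[2]),
    z = c(0, ca1[3], c1[3], n2[3], ca2[3], ca2[3] + 0.4),
    stringsAsFactors = FALSE)
  structure_model(atoms, source = sprintf("omega=%g", omega_deg))
}

rotate_model <- function(model, angle = 0.7, axis = c(1, 2, 3),
                         shift = c(5, -3, 11)) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  R <- matrix(c(
    a[1] * a[1] * C + c_,        a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, a[2] * a[2] * C + c_,        a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3] * a[3] * C + c_),
    nrow = 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

# independent longest-common-substring oracle: exhaustive substring
# intersection (set-based, no dynamic programming shared with the package)
oracle_common_motif <- function(peptides) {
  subs <- function(s) {
    n <- nchar(s)
    out <- character(0)
    for (i in seq_len(n)) for (j in i:n) out <- c(out, substr(s, i, j))
    unique(out)
  }
  common <- Reduce(intersect, lapply(peptides, subs))
  if (!length(common)) return("")
  lens <- nchar(common)
  best <- common[lens == max(lens)]
  # earliest occurrence in the first peptide among maximal candidates
  pos <- vapply(best, function(m) regexpr(m, peptides[1], fixed = TRUE)[1],
                numeric(1))
  best[order(pos)][1]
}

# independent rigid-fit oracle: random-restart quaternion search with local
# refinement (no SVD); returns the minimal rmsd found
oracle_quaternion_rmsd <- function(x, y, n_coarse = 400, rounds = 25) {
  set.seed(99)
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; a <- q[2]; b <- q[3]; c_ <- q[4]
    matrix(c(1 - 2 * (b^2 + c_^2), 2 * (a * b - c_ * w), 2 * (a * c_ + b * w),
             2 * (a * b + c_ * w), 1 - 2 * (a^2 + c_^2), 2 * (b * c_ - a * w),
             2 * (a * c_ - b * w), 2 * (b * c_ + a * w), 1 - 2 * (a^2 + b^2)),
           nrow = 3, byrow = TRUE)
  }
  x0 <- sweep(x, 2, colMeans(x))
  y0 <- sweep(y, 2, colMeans(y))
  score <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((x0 %*% t(R) - y0)^2)))
  }
  qs <- matrix(rnorm(4 * n_coarse), ncol = 4)
  vals <- apply(qs, 1, score)
  best <- qs[which.min(vals), ]
  best_val <- min(vals)
  width <- 0.5
  for (r in seq_len(rounds)) {
    cand <- matrix(rnorm(4 * 60, sd = width), ncol = 4)
    cand <- sweep(cand, 2, best, "+")
    v <- apply(cand, 1, score)
    if (min(v) < best_val) {
      best_val <- min(v)
      best <- cand[which.min(v), ]
    }
    width <- width * 0.5
  }
  best_val
}

# rigidly rotate + translate an fv_structure (for invariance checks)
rotate_fv <- function(fv, angle = 1.1, axis = c(2, -1, 3),
                      shift = c(-8, 4, 17)) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  R <- matrix(c(
    a[1] * a[1] * C + c_,        a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, a[2] * a[2] * C + c_,        a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3] * a[3] * C + c_),
    nrow = 3, byrow = TRUE)
  for (slot in c("heavy", "light")) {
    xyz <- as.matrix(fv[[slot]][, c("x", "y", "z")]) %*% t(R)
    fv[[slot]]$x <- xyz[, 1] + shift[1]
    fv[[slot]]$y <- xyz[, 2] + shift[2]
    fv[[slot]]$z <- xyz[, 3] + shift[3]
  }
  fv
}

# structure_model carrying a synthetic Fv with author numbering = Kabat
standin_fv_model <- function(id = "donor") {
  fv <- make_fv_template(synthetic_fv_pair(id))
  to_atoms <- function(at, chain) {
    pos <- parse_kabat_position(at$kabat)
    data.frame(chain = chain, resno = pos$number,
               insert = ifelse(is.na(pos$insertion), "", pos$insertion),
               resid = at$resid, elety = at$elety, element = at$element,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  }
  structure_model(rbind(to_atoms(fv$heavy, "H"), to_atoms(fv$light, "L")),
                  source = paste0("standin:", id))
}
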