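nd <- hgal3_nd_sequence()

test_that("tiling arithmetic covers the stated layouts", {
  arr <- tile_peptides(nd, window = 8, step = 2)
  expect_equal(nrow(arr$peptides), 53)            # (112 - 8) / 2 + 1
  expect_equal(arr$peptides$start, 1 + (arr$peptides$index - 1) * 2)
  expect_equal(arr$peptides$start[24], 47)        # spot 24 covers 47-54
  expect_equal(arr$peptides$start[29], 57)        # spot 29 covers 57-64
  expect_true(all(nchar(arr$peptides$sequence) == 8))
  # printed 45-spot layout is an explicit truncation
  expect_equal(nrow(tile_peptides(nd, max_spots = 45)$peptides), 45)
  # single-window and non-overlapping cases
  expect_equal(nrow(tile_peptides("ABCDEFGH", window = 8)$peptides), 1)
  expect_equal(nrow(tile_peptides(strrep("A", 26), window = 8,
                                  step = 8)$peptides), floor(26 / 8) - 0)
  expect_error(tile_peptides("ACDEF", window = 8), "window")
})

test_that("tiled windows reconstruct the covered region", {
  arr <- tile_peptides(nd, window = 8, step = 2)
  for (i in seq_len(nrow(arr$peptides))) {
    expect_identical(arr$peptides$sequence[i],
                     substr(nd, arr$peptides$start[i],
                            arr$peptides$start[i] + 7))
  }
})

test_that("positive-spot calling honors the threshold", {
  arr <- make_spot_array(nd, "APPGAY", noise_sd = 0, seed = 1)
  expect_equal(call_positive_spots(arr, 0.5), c(24, 25, 29))
  expect_equal(call_positive_spots(arr, 0), arr$peptides$index)
  expect_equal(length(call_positive_spots(arr, 1.000001)), 0)
  bare <- tile_peptides(nd)
  expect_error(call_positive_spots(bare), "no intensities")
})

test_that("the motif of the positive spots is the shared epitope hexamer", {
  arr <- tile_peptides(nd, window = 8, step = 2)
  m <- minimal_common_motif(arr, c(24, 25, 29))
  expect_equal(m$sequence, "APPGAY")
  expect_equal(m$occurrences, c(49, 58))
  expect_equal(locate_motif(nd, "APPGAY")$count, 2)
})

test_that("motif extraction edge cases behave", {
  arr <- tile_peptides(nd, window = 8, step = 2)
  # single positive spot -> the full peptide itself
  m1 <- minimal_common_motif(arr, 24)
  expect_equal(m1$sequence, arr$peptides$sequence[24])
  # support ordering does not matter
  expect_equal(minimal_common_motif(arr, c(29, 24, 25))$sequence, "APPGAY")
  # disjoint alphabets -> empty motif
  arr2 <- tile_peptides(paste0("AAAAAAAA", "TTTTTTTT"), window = 8, step = 8)
  m2 <- minimal_common_motif(arr2, c(1, 2))
  expect_equal(m2$sequence, "")
  expect_equal(locate_motif(nd, "ZZZZ")$count, 0)
  expect_equal(locate_motif("AAA", "AA")$positions, c(1, 2))  # overlaps count
})

test_that("motif extraction equals the exhaustive substring oracle", {
  set.seed(17)
  alph <- c("A", "P", "G", "Y", "S")
  for (k in 1:300) {
    n_pep <- sample(2:4, 1)
    w <- sample(4:10, 1)
    peps <- vapply(seq_len(n_pep), function(i) {
      paste(sample(alph, w, replace = TRUE), collapse = "")
    }, character(1))
    arr <- list(peptides = data.frame(index = seq_len(n_pep),
                                      start = 1 + (seq_len(n_pep) - 1) * w,
                                      sequence = peps,
                                      stringsAsFactors = FALSE),
                window = w, step = w, region = c(1, n_pep * w),
                intensities = NULL)
    class(arr) <- "spot_array"
    got <- minimal_common_motif(arr, seq_len(n_pep))$sequence
    want <- oracle_common_motif(peps)
    expect_identical(got, want,
                     label = paste("case", k, paste(peps, collapse = "/")))
  }
})

test_that("planted arrays are recovered exactly and reproducibly", {
  arr <- make_spot_array(nd, "APPGAY", noise_sd = 0, seed = 3)
  expect_equal(call_positive_spots(arr, 0.5), arr$truth$positive)
  expect_equal(arr$truth$positive, c(24, 25, 29))
  # positives are exactly the windows fully containing an occurrence
  contain <- vapply(seq_len(nrow(arr$peptides)), function(i) {
    any(vapply(arr$truth$occurrences, function(o) {
      arr$peptides$start[i] <= o &&
        o + nchar("APPGAY") - 1 <= arr$peptides$start[i] + arr$window - 1
    }, logical(1)))
  }, logical(1))
  expect_equal(arr$peptides$index[contain], arr$truth$positive)
  # same seed, same intensities; noisy arrays still recover the planted set
  a1 <- make_spot_array(nd, "APPGAY", noise_sd = 0.05, seed = 11)
  a2 <- make_spot_array(nd, "APPGAY", noise_sd = 0.05, seed = 11)
  expect_identical(a1$intensities, a2$intensities)
  expect_equal(call_positive_spots(a1, 0.5), c(24, 25, 29))
})
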