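donor <- synthetic_fv_pair("donor")
acc <- synthetic_fv_pair("acceptor_4nry")
acc3 <- synthetic_fv_pair("acceptor_3kym")

test_that("grafting a donor onto itself reproduces the donor", {
  des <- graft_cdrs(donor, donor)
  expect_identical(vregion_seq(des$heavy), vregion_seq(donor$H))
  expect_identical(vregion_seq(des$light), vregion_seq(donor$L))
  d <- diff_frameworks(list(H = des$heavy, L = des$light), donor)
  expect_equal(nrow(d$framework), 0)
  expect_equal(nrow(d$cdr), 0)
})

test_that("grafts carry donor CDRs on acceptor frameworks position by position", {
  des <- graft_cdrs(donor, acc)
  part <- kabat_partition()
  for (slot in c("heavy", "light")) {
    chain <- des[[slot]]
    src <- if (slot == "heavy") "H" else "L"
    reg <- kabat_region_of(chain$labels, part)
    for (i in seq_along(chain$labels)) {
      lab <- chain$labels[i]
      ref <- if (grepl("^CDR", reg[i])) donor[[src]] else acc[[src]]
      expect_identical(chain$aa[i], ref$aa[match(lab, ref$labels)],
                       label = paste("graft residue at", lab))
    }
  }
  # donor insertions inside CDRs are inherited
  expect_true("H52A" %in% des$heavy$labels)
  expect_true(all(paste0("L27", c("A", "B", "C", "D")) %in% des$light$labels))
})

test_that("CDR length differences are inherited from the donor", {
  # lengthen the donor CDR-H3 by two inserted residues
  long_h <- donor$H
  at <- match("H100", long_h$labels)
  labels <- append(long_h$labels, c("H100A", "H100B"), after = at)
  aa <- append(long_h$aa, c("G", "S"), after = at)
  donor_long <- list(H = numbered_vregion("H", labels, aa, "donor-longH3"),
                     L = donor$L)
  des <- graft_cdrs(donor_long, acc)
  reg <- kabat_region_of(des$heavy$labels)
  expect_equal(sum(reg == "CDR-H3"),
               sum(kabat_region_of(donor_long$H$labels) == "CDR-H3"))
  expect_true(all(c("H100A", "H100B") %in% des$heavy$labels))
})

test_that("vernier proposals flag exactly the designed mismatches", {
  v <- propose_vernier_backmutations(donor, acc)
  expect_true(all(c("H71", "L36", "L46", "L68") %in% v$position))
  expect_true(all(v$category == "vernier"))
  v3 <- propose_vernier_backmutations(donor, acc3)
  expect_true("H78" %in% v3$position)
  expect_setequal(setdiff(v3$position, v$position), "H78")
  # ordering: H chain before L, positions ascending within each chain
  expect_true(all(diff(match(v$chain, c("H", "L"))) >= 0))
  for (ch in c("H", "L")) {
    keys <- kabat_sort_key(v$position[v$chain == ch])
    expect_true(all(diff(keys) > 0))
  }
  expect_equal(nrow(propose_vernier_backmutations(donor, donor)), 0)
})

test_that("N-terminal proposals cover only mismatched positions", {
  nt <- propose_nterminal_backmutations(donor, acc)
  expect_true(all(c("H2", "L2", "L3") %in% nt$position))
  expect_true("L4" %in% nt$position)      # within the default H1-H3/L1-L4 set
  expect_false("H1" %in% nt$position)     # donor and acceptor agree at H1
  expect_false("H3" %in% nt$position)
  expect_equal(nrow(propose_nterminal_backmutations(donor, donor)), 0)
})

test_that("the worked humanization example yields 7 then 9 framework changes", {
  des <- graft_cdrs(donor, acc)
  v <- propose_vernier_backmutations(donor, acc)
  nt <- propose_nterminal_backmutations(donor, acc)
  initial_set <- rbind(v[v$position %in% c("H2", "H71", "L2", "L36", "L46", "L68"), ],
                       nt[nt$position == "L3", ])
  des1 <- apply_back_mutations(des, initial_set)
  d1 <- diff_frameworks(list(H = des1$heavy, L = des1$light), acc)
  expect_equal(nrow(d1$framework), 7)
  refine <- propose_refinement_backmutations(donor, acc, c("H46", "L4"))
  expect_setequal(refine$position, c("H46", "L4"))
  expect_true(all(refine$category == "refinement"))
  des2 <- apply_back_mutations(des1, refine)
  d2 <- diff_frameworks(list(H = des2$heavy, L = des2$light), acc)
  expect_setequal(d2$framework$position,
                  c("H2", "H46", "H71", "L2", "L3", "L4", "L36", "L46", "L68"))
  # ledger soundness: every framework difference is ledgered
  expect_equal(nrow(d2$framework), nrow(des2$back_mutations))
  # the final design still carries the donor paratope unchanged
  dd <- diff_frameworks(list(H = des2$heavy, L = des2$light), donor)
  expect_equal(nrow(dd$cdr), 0)
})

test_that("back-mutation application is guarded, idempotent and reversible", {
  des <- graft_cdrs(donor, acc)
  v <- propose_vernier_backmutations(donor, acc)
  one <- v[v$position == "H71", ]
  des1 <- apply_back_mutations(des, one)
  expect_warning(des1b <- apply_back_mutations(des1, one), "no-op")
  expect_identical(vregion_seq(des1b$heavy), vregion_seq(des1$heavy))
  expect_identical(design_sequences(apply_back_mutations(des, v[0, ])),
                   design_sequences(des))
  # revert restores the pre-mutation state
  back <- revert_back_mutation(des1, "H71")
  expect_identical(design_sequences(back), design_sequences(des))
  expect_equal(nrow(back$back_mutations), 0)
  # a CDR position is rejected
  bad <- data.frame(position = "H52A", chain = "H", donor_aa = "T",
                    acceptor_aa = "X", category = "vernier", rationale = "",
                    stringsAsFactors = FALSE)
  expect_error(apply_back_mutations(des, bad), "CDR")
})

test_that("ledger size always matches the framework diff (random subsets)", {
  v <- propose_vernier_backmutations(donor, acc)
  nt <- propose_nterminal_backmutations(donor, acc)
  all_prop <- rbind(v, nt)
  all_prop <- all_prop[!duplicated(all_prop$position), ]
  set.seed(5)
  for (k in 1:10) {
    sel <- all_prop[sample(nrow(all_prop), sample(nrow(all_prop), 1)), ]
    des <- apply_back_mutations(graft_cdrs(donor, acc), sel)
    d <- diff_frameworks(list(H = des$heavy, L = des$light), acc)
    expect_equal(nrow(d$framework), nrow(des$back_mutations))
    expect_setequal(d$framework$position, des$back_mutations$position)
  }
})
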