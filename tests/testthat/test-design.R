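# GMEC search, state scoring, failure-mode diagnosis, design enumeration,
# heterodimer-fraction model.

test_that("a forced single-rotamer site returns that placement", {
  em <- random_matrix(1, 1, seed = 2)
  sol <- gmec(em, "LEU")
  expect_equal(sol$assignment, 1L)
  expect_equal(sol$energy, em$E_template + em$E_self[1])
})

test_that("gmec equals brute force on a 3-site x 4-rotamer matrix", {
  em <- random_matrix(3, 4, seed = 42)
  want <- brute_force_gmec(em)
  got <- gmec(em, rep("LEU", 3))
  expect_equal(got$energy, want$energy)
  expect_equal(got$assignment, want$assignment)
})

test_that("exhaustive and DEE paths agree with brute force on 100 seeded instances", {
  set.seed(99)
  for (k in 1:100) {
    nsite <- sample(2:4, 1)
    nrot <- sample(2:6, 1)
    em <- random_matrix(nsite, nrot, seed = 1000 + k)
    want <- brute_force_gmec(em)
    ex <- gmec(em, rep("LEU", nsite), method = "exhaustive")
    de <- gmec(em, rep("LEU", nsite), method = "dee")
    expect_equal(ex$energy, want$energy)
    expect_identical(ex$assignment, want$assignment)
    expect_equal(de$energy, ex$energy)
    expect_identical(de$assignment, ex$assignment)
  }
})

test_that("gmec on fixture-derived matrices matches brute force", {
  em <- fix_h3_matrix()
  for (con in list(rep("L", 8), c("L", "A", "A", "V", "I", "W", "L", "I"))) {
    want <- NULL
    # restrict the brute-force oracle to the constrained sub-matrix
    keep <- unlist(lapply(seq_len(8), function(k)
      which(em$placements$site == k &
              em$placements$resid == bumphole:::norm_resid(con[k]))))
    sub <- em
    sub$placements <- em$placements[keep, ]
    sub$placements$site <- sub$placements$site
    sub$E_self <- em$E_self[keep]
    sub$E_pair <- em$E_pair[keep, keep]
    sub$atoms <- em$atoms[keep]
    want <- brute_force_gmec(sub)
    got <- gmec(em, con)
    expect_equal(got$energy, want$energy)
  }
})

test_that("ties break lexicographically by placement index", {
  em <- random_matrix(2, 3, seed = 7)
  em$E_self[] <- 0
  em$E_pair[] <- 0
  sol <- gmec(em, rep("LEU", 2))
  expect_equal(sol$assignment, c(1L, 4L))
})

test_that("empty constraint sets and oversized spaces are refused", {
  em <- random_matrix(2, 3, seed = 8)
  expect_error(gmec(em, c("LEU", "TRP")), "no placements")
  s <- search_options(enum_bound = 1, hard_bound = 1)
  expect_error(gmec(em, rep("LEU", 2), search = s), "reduce")
})

test_that("scoring a sequence against itself gives gap exactly zero", {
  reg <- fix_h3_region()
  for (s in list("LALL", "IWLI")) {
    sc <- score_states(reg, s, s, matrix = fix_h3_matrix(), contacts = FALSE)
    expect_identical(sc$gap, 0)
    expect_identical(sc$stability, sc$E_XY - sc$E_WT)
    expect_equal(sc$E_XX, sc$E_YY)
    expect_equal(sc$E_XX, sc$E_XY)
  }
})

test_that("relabeling X and Y swaps the homodimers and preserves gap", {
  reg <- fix_h3_region()
  em <- fix_h3_matrix()
  a <- score_states(reg, "LAAV", "IWLI", matrix = em, contacts = FALSE)
  b <- score_states(reg, "IWLI", "LAAV", matrix = em, contacts = FALSE)
  expect_equal(b$E_XX, a$E_YY)
  expect_equal(b$E_YY, a$E_XX)
  expect_equal(b$E_XY, a$E_XY)
  expect_equal(b$gap, a$gap)
})

test_that("gap and stability are plain arithmetic over the state energies", {
  sc <- fix_h3_pair_scores()
  expect_equal(sc$gap, min(sc$E_XX, sc$E_YY) - sc$E_XY)
  expect_equal(sc$stability, sc$E_XY - sc$E_WT)
})

test_that("wild type against itself classifies as none", {
  reg <- fix_h3_region()
  sc <- score_states(reg, "LALL", "LALL", matrix = fix_h3_matrix())
  cls <- classify_failure_mode(sc$states$XX, sc$states$WT)
  expect_equal(cls$mode, "none")
  expect_equal(cls$deficit, 0)
  expect_equal(nrow(cls$offending), 0)
})

test_that("clash and void calls follow the per-contact and deficit thresholds", {
  sc <- fix_h3_pair_scores()
  opt <- energy_options()
  fx <- classify_failure_mode(sc$states$XX, sc$states$WT, opt)
  fy <- classify_failure_mode(sc$states$YY, sc$states$WT, opt)
  # the small-residue homodimer loses packing without any clashing pair
  expect_equal(fx$mode, "void")
  expect_gte(fx$deficit, opt$void_cut)
  expect_equal(nrow(fx$offending), 0)
  # the bulky homodimer has at least one capped-scale cross-protomer contact
  expect_equal(fy$mode, "clash")
  expect_gte(max(sc$states$YY$per_contact$energy), opt$clash_cut)
  expect_true(all(fy$offending$energy >= opt$clash_cut))
})

test_that("heterodimer fraction has its closed-form anchors and monotonicity", {
  expect_equal(heterodimer_fraction(0, 0), 0.5)
  rt <- 0.0019872041 * 303
  expect_equal(heterodimer_fraction(rt * log(2), rt * log(2)), 2 / 3)
  expect_equal(heterodimer_fraction(1e6, 1e6), 1)
  expect_error(heterodimer_fraction(0, 0, temperature = 0), "positive")
  g <- seq(-3, 3, by = 0.25)
  f1 <- heterodimer_fraction(g, 0.7)
  f2 <- heterodimer_fraction(0.7, g)
  expect_true(all(diff(f1) > 0))
  expect_true(all(diff(f2) > 0))
  expect_true(all(f1 > 0 & f1 <= 1))
})

test_that("a wild-type-only alphabet yields one gap-zero candidate", {
  reg <- fix_h3_region()
  cand <- enumerate_designs(reg, c("L", "A"), search = search_options(budget = 200))
  wt_row <- cand[cand$sequence_X == "LALL" & cand$sequence_Y == "LALL", ]
  expect_equal(nrow(wt_row), 1)
  expect_equal(wt_row$gap, 0)
  # degenerate single-letter alphabet at restricted positions
  reg2 <- extract_design_region(fix_h3(), interface_spec("A", "B", c(110, 130)))
  one <- enumerate_designs(reg2, c("L"), search = search_options(budget = 10))
  expect_equal(nrow(one), 1)
  expect_equal(one$gap, 0)
  expect_equal(nrow(one[one$gap > 0, ]), 0)
})

test_that("exhaustive design matches a brute-force scan and ignores alphabet order", {
  reg <- extract_design_region(fix_h3(), interface_spec("A", "B", c(110, 130)))
  s <- search_options(budget = 200, delta_stab = 1e6)
  cand <- enumerate_designs(reg, c("A", "L", "W"), search = s)
  # brute force: score every unordered pair directly
  em <- compute_energy_matrix(reg, c("A", "L", "W"))
  seqs <- sort(apply(expand.grid(c("A", "L", "W"), c("A", "L", "W")), 1, paste,
                     collapse = ""))
  best <- -Inf
  for (i in seq_along(seqs)) for (j in i:length(seqs)) {
    sc <- score_states(reg, seqs[i], seqs[j], matrix = em, contacts = FALSE)
    best <- max(best, sc$gap)
  }
  expect_equal(cand$gap[1], best)
  # per-pair energies agree with direct scoring
  k <- which(cand$sequence_X == "AW" & cand$sequence_Y == "LA")
  sc <- score_states(reg, "AW", "LA", matrix = em, contacts = FALSE)
  expect_equal(cand$E_XY[k], sc$E_XY)
  expect_equal(cand$gap[k], sc$gap)
  # alphabet order must not matter
  cand2 <- enumerate_designs(reg, c("W", "A", "L"), search = s)
  expect_identical(as.data.frame(cand), as.data.frame(cand2))
})

test_that("the stability filter excludes destabilized heterodimers", {
  reg <- extract_design_region(fix_h3(), interface_spec("A", "B", c(110, 130)))
  loose <- enumerate_designs(reg, c("A", "L", "W"),
                             search = search_options(budget = 200,
                                                     delta_stab = 1e6))
  tight <- enumerate_designs(reg, c("A", "L", "W"),
                             search = search_options(budget = 200,
                                                     delta_stab = 0))
  expect_true(all(tight$stability <= 0))
  expect_lt(nrow(tight), nrow(loose))
  keys <- function(d) paste(d$sequence_X, d$sequence_Y)
  expect_true(all(keys(tight) %in% keys(loose)))
})

test_that("exhaustive budget overruns advise heuristic mode, which is seeded", {
  reg <- extract_design_region(fix_h3(), interface_spec("A", "B", c(110, 130)))
  expect_error(enumerate_designs(reg, c("A", "V", "I", "L", "W"),
                                 search = search_options(budget = 10)),
               "heuristic")
  s <- search_options(seed = 5, n_starts = 8, delta_stab = 1e6)
  h1 <- enumerate_designs(reg, c("A", "L", "W"), search = s, mode = "heuristic")
  h2 <- enumerate_designs(reg, c("A", "L", "W"), search = s, mode = "heuristic")
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  # heuristic search finds the exhaustive optimum on this small space
  ex <- enumerate_designs(reg, c("A", "L", "W"),
                          search = search_options(budget = 200,
                                                  delta_stab = 1e6))
  expect_equal(h1$gap[1], ex$gap[1])
})
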