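# PDB I/O, mutation threading, design-region extraction, fixture geometry.

test_that("a single well-formed ATOM line parses to one atom with correct fields", {
  line <- "ATOM      1  CA  ALA A   7       1.000   2.000   3.000  1.00  0.00           C"
  s <- read_structure(line)
  expect_equal(nrow(s), 1)
  expect_equal(s$atom, "CA")
  expect_equal(s$chain, "A")
  expect_equal(s$resno, 7)
  expect_equal(s$resid, "ALA")
  expect_true(s$is_backbone)
  expect_equal(unlist(s[, c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
})

test_that("unparsable ATOM records and empty inputs are rejected with context", {
  good <- "ATOM      1  CA  ALA A   7       1.000   2.000   3.000  1.00  0.00           C"
  bad <- "ATOM      2  CB  ALA A   7       xxxxx   2.000   3.000  1.00  0.00           C"
  expect_error(read_structure(c(good, bad)), "line 2")
  expect_error(read_structure("REMARK nothing here"), "no ATOM records")
})

test_that("altloc filtering keeps the highest-occupancy record, ties alphabetical", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C")
  s <- read_structure(lines)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$atom == "CA"], 9)  # higher occupancy wins
  expect_equal(s$x[s$atom == "CB"], 1)  # tie broken alphabetically (A)
})

test_that("the 2-helix poly-alanine fixture has 5 heavy atoms per residue", {
  b <- make_synthetic_bundle(2, 12, 10, seed = 1)
  expect_equal(nrow(b), 120)
  expect_setequal(unique(b$resid), "ALA")
  expect_setequal(unique(b$atom), c("N", "CA", "C", "O", "CB"))
})

test_that("PDB round trip preserves all atom fields and is byte-idempotent", {
  b <- fix_bundle()
  txt <- write_structure(b)
  b2 <- read_structure(txt)
  expect_equal(b2$atom, b$atom)
  expect_equal(b2$resno, b$resno)
  expect_equal(b2$resid, b$resid)
  expect_equal(b2$chain, b$chain)
  expect_equal(b2$is_backbone, b$is_backbone)
  expect_true(max(abs(as.matrix(b2[, c("x", "y", "z")]) -
                        as.matrix(b[, c("x", "y", "z")]))) <= 5e-4)
  # write -> read -> write is byte-identical on the second pair
  txt2 <- write_structure(b2)
  expect_identical(write_structure(read_structure(txt2)), txt2)
})

test_that("coordinates overflowing the fixed-width field are refused", {
  b <- fix_bundle()
  b$x[1] <- 123456.0
  expect_error(write_structure(b), "overflow")
})

test_that("mutation parsing accepts wt/pos/mut tokens and rejects malformed ones", {
  m <- parse_mutations(c("L126A", "L130V"))
  expect_equal(m$wt, c("L", "L"))
  expect_equal(m$position, c(126L, 130L))
  expect_equal(m$mut, c("A", "V"))
  expect_error(parse_mutations("L126"), "malformed")
  expect_error(parse_mutations("126A"), "malformed")
  expect_error(parse_mutations("L126L"), "identical")
})

test_that("apply_mutations threads identities, strips side chains, fixes backbone", {
  s <- fix_h3()
  m <- apply_mutations(s, "A", c("L109I", "A110W", "L130I"))
  res_at <- function(st, rn) unique(st$resid[st$chain == "A" & st$resno == rn])
  expect_equal(res_at(m, 109), "ILE")
  expect_equal(res_at(m, 110), "TRP")
  expect_equal(res_at(m, 130), "ILE")
  expect_equal(res_at(m, 126), "LEU")  # untouched
  # side chains of mutated residues removed
  expect_false(any(!m$is_backbone & m$chain == "A" & m$resno %in% c(109, 110, 130)))
  # backbone atoms bit-identical
  bb0 <- as.data.frame(s[s$is_backbone, ])[, c("chain", "resno", "atom",
                                               "x", "y", "z")]
  bb1 <- as.data.frame(m[m$is_backbone, ])[, c("chain", "resno", "atom",
                                               "x", "y", "z")]
  rownames(bb0) <- rownames(bb1) <- NULL
  expect_identical(bb1, bb0)
  # empty mutation list is the identity
  expect_identical(as.data.frame(apply_mutations(s, "A", character())),
                   as.data.frame(s))
})

test_that("wild-type mismatches and unknown positions are reported precisely", {
  s <- fix_h3()
  expect_error(apply_mutations(s, "A", "V109I"), "expected VAL, found LEU")
  expect_error(apply_mutations(s, "A", "L999I"), "no residue 999")
})

test_that("design region enumerates sites on both chains with wild types", {
  reg <- fix_h3_region()
  expect_equal(nrow(reg$sites), 8)  # 4 positions x 2 chains
  expect_equal(sum(reg$sites$chain == "A"), 4)
  expect_equal(reg$sites$wt[reg$sites$chain == "A"],
               c("LEU", "ALA", "LEU", "LEU"))
  expect_equal(wt_sequence(reg), c("L", "A", "L", "L"))
})

test_that("environment cutoff 0 keeps only design-site backbone atoms", {
  s <- fix_h3()
  reg0 <- extract_design_region(s, interface_spec("A", "B",
                                                  c(109, 110, 126, 130), 0))
  t <- as.data.frame(reg0$template)
  expect_true(all(t$resno %in% c(109, 110, 126, 130)))
  expect_true(all(t$is_backbone))
})

test_that("template membership equals a brute-force distance scan", {
  s <- fix_bundle()
  spec <- interface_spec("A", "B", c(6, 7), environment_cutoff = 6)
  reg <- extract_design_region(s, spec)
  df <- as.data.frame(s)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  is_design <- df$resno %in% c(6, 7)
  probe <- xyz[is_design & df$atom %in% c("CA", "CB"), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    dmin <- min(sqrt(rowSums((probe - matrix(xyz[i, ], nrow(probe), 3,
                                             byrow = TRUE))^2)))
    keep[i] <- (!is_design[i] && dmin <= 6) || (is_design[i] && df$is_backbone[i])
  }
  got <- paste(reg$template$chain, reg$template$resno, reg$template$atom)
  want <- paste(df$chain, df$resno, df$atom)[keep]
  expect_setequal(got, want)
})

test_that("fixture helices have ideal local geometry", {
  b <- make_synthetic_bundle(1, 8, 10, seed = 2)
  expect_equal(nrow(b), 40)  # 8 residues x 5 atoms
  df <- as.data.frame(b)
  ca <- as.matrix(df[df$atom == "CA", c("x", "y", "z")])
  dca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dca - 3.8) < 0.1))
  for (rn in 1:8) {
    r <- df[df$resno == rn, ]
    gc <- function(nm) unlist(r[r$atom == nm, c("x", "y", "z")])
    expect_lt(abs(sqrt(sum((gc("N") - gc("CA"))^2)) - 1.458), 0.05)
    expect_lt(abs(sqrt(sum((gc("C") - gc("CA"))^2)) - 1.525), 0.05)
  }
})

test_that("two-helix spacing matches the axis geometry and seeds reproduce", {
  # with CA atoms ~2.28 A off-axis, the closest approach of two helices
  # spaced 10 A can undercut the axis spacing by up to twice that radius
  b <- make_synthetic_bundle(2, 12, 10, seed = 1)
  df <- as.data.frame(b)
  ca1 <- as.matrix(df[df$chain == "A" & df$atom == "CA", c("x", "y", "z")])
  ca2 <- as.matrix(df[df$chain == "B" & df$atom == "CA", c("x", "y", "z")])
  dmin <- min(sqrt(outer(rowSums(ca1^2), rowSums(ca2^2), "+") -
                     2 * ca1 %*% t(ca2)))
  expect_gt(dmin, 10 - 2 * 2.4)
  expect_lt(dmin, 10 + 2 * 2.4)
  expect_identical(make_synthetic_bundle(2, 12, 10, seed = 7),
                   make_synthetic_bundle(2, 12, 10, seed = 7))
  expect_false(identical(make_synthetic_bundle(2, 12, 10, seed = 7),
                         make_synthetic_bundle(2, 12, 10, seed = 8)))
})

test_that("non-physical bundle parameters are refused", {
  expect_error(make_synthetic_bundle(2, 12, 3), "non-physical")
  expect_error(make_synthetic_bundle(2, 3, 10), ">= 4")
  expect_error(make_synthetic_bundle(0, 12, 10), ">= 1")
})
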