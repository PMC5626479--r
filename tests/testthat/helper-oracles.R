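# Independent oracles and shared fixtures for the test suite. Oracle code is
# deliberately written from the definitions, independent of the package's
# internal implementation paths.

# ---- independent geometry ----

ref_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

ang_diff <- function(a, b) abs((a - b + 180) %% 360 - 180)

# ---- independent energy oracle ----

# single-pair 12-6 LJ with Lorentz-Berthelot combining, radius scaling,
# cutoff and cap, straight from the formula
ref_lj <- function(r, s1, s2, e1, e2, opt) {
  if (r >= opt$cutoff) return(0)
  sig <- opt$radius_scale * (s1 + s2) / 2
  eps <- sqrt(e1 * e2)
  min(4 * eps * ((sig / r)^12 - (sig / r)^6), opt$repulsion_cap)
}

# independent parameter lookup straight from the packaged data files
.oracle <- new.env(parent = emptyenv())

ref_params <- function(df) {
  if (is.null(.oracle$lj)) {
    ext <- system.file("extdata", package = "bumphole")
    .oracle$lj <- read.delim(file.path(ext, "lj_params.tsv"), comment.char = "#")
    .oracle$cm <- read.delim(file.path(ext, "atom_classes.tsv"), comment.char = "#")
  }
  cm <- .oracle$cm; lj <- .oracle$lj
  cls <- cm$atom_class[match(paste(df$resid, df$atom), paste(cm$resid, cm$atom))]
  wild <- cm$atom_class[match(df$atom, ifelse(cm$resid == "*", cm$atom, ""))]
  cls <- ifelse(is.na(cls), wild, cls)
  i <- match(cls, lj$atom_class)
  list(sig = lj$sigma[i], eps = lj$epsilon[i])
}

# intra-residue bond separations from the packaged topology file via igraph
# (no ring-closure edges: oracle use is restricted to non-ring residues)
ref_bond_sep <- function(resid) {
  key <- paste0("sep_", resid)
  if (!is.null(.oracle[[key]])) return(.oracle[[key]])
  ext <- system.file("extdata", package = "bumphole")
  topo <- read.delim(file.path(ext, "topology.tsv"), comment.char = "#")
  topo <- topo[topo$resid == resid, , drop = FALSE]
  edges <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))
  if (resid != "GLY") edges <- rbind(edges, c("CA", "CB"))
  if (nrow(topo)) edges <- rbind(edges, cbind(topo$parent, topo$atom))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  d <- igraph::distances(g)
  .oracle[[key]] <- d
  d
}

# direct all-atom energy of an assembled structure under the stated model:
# all inter-residue pairs, intra-residue pairs only when > 3 bonds apart
ref_total_energy <- function(struct, opt) {
  df <- as.data.frame(struct)
  p <- ref_params(df)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sig <- opt$radius_scale * outer(p$sig, p$sig, "+") / 2
  eps <- sqrt(outer(p$eps, p$eps))
  dd <- pmax(d, 1e-2)
  e <- 4 * eps * ((sig / dd)^12 - (sig / dd)^6)
  e[d >= opt$cutoff] <- 0
  e <- pmin(e, opt$repulsion_cap)
  rkey <- paste(df$chain, df$resno)
  for (key in unique(rkey)) {
    idx <- which(rkey == key)
    if (length(idx) < 2) next
    sep <- ref_bond_sep(df$resid[idx[1]])[df$atom[idx], df$atom[idx]]
    eb <- e[idx, idx]
    eb[sep <= 3] <- 0
    e[idx, idx] <- eb
  }
  diag(e) <- 0
  sum(e[upper.tri(e)])
}

# assemble template + placement atoms of an assignment into a plain structure
ref_assemble <- function(region, em, assignment) {
  out <- as.data.frame(region$template)
  for (k in seq_along(assignment)) {
    i <- assignment[k]
    sel <- out$chain == region$sites$chain[k] & out$resno == region$sites$resno[k]
    out$resid[sel] <- em$placements$resid[i]
    at <- em$atoms[[i]]
    if (nrow(at) == 0) next
    out <- rbind(out, data.frame(
      atom = rownames(at), element = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3],
      resno = region$sites$resno[k], resid = em$placements$resid[i],
      chain = region$sites$chain[k], is_backbone = FALSE,
      stringsAsFactors = FALSE))
  }
  out
}

# ---- synthetic energy matrices and brute-force GMEC ----

# a random but valid energy_matrix over nsite sites with nrot rotamers each
# (single residue type "LEU"), for search-correctness tests
random_matrix <- function(nsite, nrot, seed) {
  set.seed(seed)
  np <- nsite * nrot
  site <- rep(seq_len(nsite), each = nrot)
  ep <- matrix(0, np, np)
  for (i in seq_len(nsite - 1)) for (j in (i + 1):nsite) {
    blk <- matrix(round(rnorm(nrot * nrot), 3), nrot)
    ep[site == i, site == j] <- blk
    ep[site == j, site == i] <- t(blk)
  }
  structure(list(
    sites = data.frame(chain = rep(c("A", "B"), length.out = nsite),
                       resno = 100 + seq_len(nsite),
                       wt = "LEU", stringsAsFactors = FALSE),
    placements = data.frame(site = site, resid = "LEU",
                            rot = rep(seq_len(nrot), nsite),
                            weight = 1 / nrot, stringsAsFactors = FALSE),
    atoms = rep(list(matrix(numeric(), 0, 3)), np),
    chi = rep(list(numeric()), np),
    E_template = round(rnorm(1), 3),
    E_self = round(rnorm(np), 3),
    E_pair = ep,
    options = energy_options(), alphabet = "LEU"),
    class = "energy_matrix")
}

# exhaustive brute force over all complete assignments, first-minimum wins
brute_force_gmec <- function(em) {
  nsite <- nrow(em$sites)
  cand <- lapply(seq_len(nsite), function(k) which(em$placements$site == k))
  best <- NULL; best_e <- Inf
  rec <- function(k, acc) {
    if (k > nsite) {
      e <- em$E_template + sum(em$E_self[acc])
      for (i in seq_len(nsite - 1))
        e <- e + sum(em$E_pair[acc[i], acc[(i + 1):nsite]])
      if (e < best_e) { best_e <<- e; best <<- acc }
      return(invisible())
    }
    for (p in cand[[k]]) rec(k + 1, c(acc, p))
  }
  rec(1, integer())
  list(assignment = best, energy = best_e)
}

# ---- shared fixtures (built once per test run) ----

.fix <- new.env(parent = emptyenv())

fix_bundle <- function() {
  if (is.null(.fix$bundle)) .fix$bundle <- make_synthetic_bundle(2, 12, 9, seed = 3)
  .fix$bundle
}

fix_h3 <- function() {
  if (is.null(.fix$h3)) .fix$h3 <- synthetic_h3_bundle()
  .fix$h3
}

fix_h3_region <- function() {
  if (is.null(.fix$h3reg))
    .fix$h3reg <- extract_design_region(
      fix_h3(), interface_spec("A", "B", c(109, 110, 126, 130)))
  .fix$h3reg
}

fix_h3_matrix <- function() {
  if (is.null(.fix$h3em))
    .fix$h3em <- compute_energy_matrix(fix_h3_region(),
                                       c("L", "A", "V", "I", "W"))
  .fix$h3em
}

fix_h3_pair_scores <- function() {
  if (is.null(.fix$h3sc)) {
    reg <- fix_h3_region()
    .fix$h3sc <- score_states(reg,
                              sequence_from_mutations(reg, c("L126A", "L130V")),
                              sequence_from_mutations(reg, c("L109I", "A110W", "L130I")),
                              matrix = fix_h3_matrix())
  }
  .fix$h3sc
}
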