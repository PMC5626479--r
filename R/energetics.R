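# Energetics module: united heavy-atom 12-6 Lennard-Jones scoring and the
# pairwise energy matrix (template constant, per-rotamer self energies,
# rotamer-rotamer pair energies) over the design sites.
#
# Energy model: steric packing only. Scored pairs are all inter-residue atom
# pairs plus intra-residue pairs separated by >= 4 bonds; 1-2/1-3/1-4 pairs
# within a residue are excluded. Rigid-rotamer internal energy (side-chain
# atom pairs of one placement) is omitted: it is nearly constant per rotamer
# and cancels in all state comparisons.

lj_table <- function() read_pkg_tsv("lj_params.tsv")
class_map <- function() read_pkg_tsv("atom_classes.tsv")

#' Look up united-atom Lennard-Jones parameters for protein heavy atoms
#'
#' Maps (residue, PDB atom name) to a packaged united-atom class and its
#' sigma/epsilon. Vectorized over atoms.
#'
#' @param atoms a \code{bh_structure} or data frame with columns \code{resid}
#'   and \code{atom}.
#' @return data frame with columns \code{atom_class}, \code{sigma},
#'   \code{epsilon}, one row per input atom.
#' @export
atom_params <- function(atoms) {
  cm <- class_map()
  lj <- lj_table()
  key <- paste(atoms$resid, atoms$atom)
  cls <- cm$atom_class[match(key, paste(cm$resid, cm$atom))]
  generic <- cm$atom_class[match(atoms$atom, cm$atom[cm$resid == "*"])]
  # residue-specific entries win over backbone wildcards
  cls <- ifelse(is.na(cls), generic, cls)
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1]
    stop("no atom class for ", atoms$resid[bad], " ", atoms$atom[bad])
  }
  i <- match(cls, lj$atom_class)
  data.frame(atom_class = cls, sigma = lj$sigma[i], epsilon = lj$epsilon[i],
             stringsAsFactors = FALSE)
}

#' Energy model options
#'
#' @param radius_scale multiplier on combined LJ radii (softening), in (0, 1].
#' @param repulsion_cap per-atom-pair cap on the repulsive energy, kcal/mol.
#' @param cutoff interaction distance cutoff, Angstrom.
#' @param clash_cut per-atom-pair energy at or above which a cross-protomer
#'   contact is called a steric clash, kcal/mol.
#' @param void_cut state-level energy deficit (homodimer minus wild type) at
#'   or above which a clash-free homodimer is called a packing void, kcal/mol.
#' @return an \code{energy_options} list.
#' @export
energy_options <- function(radius_scale = 0.9, repulsion_cap = 10,
                           cutoff = 8, clash_cut = 3, void_cut = 1) {
  if (radius_scale <= 0 || radius_scale > 1)
    stop("radius_scale must be in (0, 1]")
  if (!(repulsion_cap > clash_cut && clash_cut > 0))
    stop("need repulsion_cap > clash_cut > 0")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(radius_scale = radius_scale, repulsion_cap = repulsion_cap,
                 cutoff = cutoff, clash_cut = clash_cut, void_cut = void_cut),
            class = "energy_options")
}

# Core cross-set LJ energy matrix. xyz: n x 3; sig/eps: length n vectors.
# Returns an na x nb matrix of per-pair capped energies (0 beyond cutoff).
lj_cross <- function(xyz_a, sig_a, eps_a, xyz_b, sig_b, eps_b, opt) {
  if (nrow(xyz_a) == 0 || nrow(xyz_b) == 0)
    return(matrix(0, nrow(xyz_a), nrow(xyz_b)))
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * tcrossprod(xyz_a, xyz_b)
  d2 <- pmax(d2, 1e-4)  # guard exact overlaps; value is capped anyway
  sig <- opt$radius_scale * outer(sig_a, sig_b, "+") / 2
  eps <- sqrt(outer(eps_a, eps_b))
  s6 <- (sig * sig / d2)^3
  e <- 4 * eps * (s6 * s6 - s6)
  e[d2 >= opt$cutoff^2] <- 0
  pmin(e, opt$repulsion_cap)
}

params_of <- function(atoms) {
  p <- atom_params(atoms)
  list(xyz = coords_any(atoms), sig = p$sigma, eps = p$epsilon)
}

coords_any <- function(atoms) {
  m <- as.matrix(as.data.frame(atoms)[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Van der Waals interaction energy between two disjoint atom sets
#'
#' Sum over all cross pairs within the cutoff of a 12-6 Lennard-Jones term
#' with Lorentz-Berthelot combining; radii are scaled by
#' \code{options$radius_scale} and each pair's value is capped at
#' \code{options$repulsion_cap}. Symmetric in its arguments. No bonded
#' exclusions are applied: the two sets must not share a residue.
#'
#' @param atoms_a,atoms_b \code{bh_structure}s or data frames with columns
#'   \code{resid}, \code{atom}, \code{x}, \code{y}, \code{z}.
#' @param options an \code{\link{energy_options}}.
#' @return energy in kcal/mol (0 for empty sets).
#' @export
pair_energy <- function(atoms_a, atoms_b, options = energy_options()) {
  if (NROW(atoms_a) == 0 || NROW(atoms_b) == 0) return(0)
  a <- params_of(atoms_a)
  b <- params_of(atoms_b)
  sum(lj_cross(a$xyz, a$sig, a$eps, b$xyz, b$sig, b$eps, options))
}

# ---- intra-residue bond separations (for exclusions) ----

.bond_env <- new.env(parent = emptyenv())

# bond-separation matrix between all heavy atoms of one residue type
residue_bond_sep <- function(resid) {
  if (!is.null(.bond_env[[resid]])) return(.bond_env[[resid]])
  atoms <- c("N", "CA", "C", "O", "OXT",
             if (resid != "GLY") sidechain_atom_names(resid))
  edges <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))
  if (resid != "GLY") {
    edges <- rbind(edges, c("CA", "CB"))
    t <- residue_topology(resid)
    if (nrow(t)) edges <- rbind(edges, cbind(t$parent, t$atom))
    if (resid == "PRO") edges <- rbind(edges, c("CD", "N"))
    if (resid == "HIS") edges <- rbind(edges, c("CE1", "NE2"))
    if (resid %in% c("PHE", "TYR")) edges <- rbind(edges, c("CZ", "CE2"))
    if (resid == "TRP") edges <- rbind(edges, c("NE1", "CE2"),
                                       c("CH2", "CZ3"))
  }
  n <- length(atoms)
  d <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- match(edges[k, 1], atoms); j <- match(edges[k, 2], atoms)
    d[i, j] <- d[j, i] <- 1
  }
  for (m in seq_len(n)) # Floyd-Warshall; residues are tiny
    d <- pmin(d, outer(d[, m], d[m, ], "+"))
  .bond_env[[resid]] <- d
  d
}

# mask (TRUE = excluded) for atom name vectors of one residue type
exclusion_mask <- function(resid, names_a, names_b, max_sep = 3) {
  d <- residue_bond_sep(resid)
  d[names_a, names_b, drop = FALSE] <= max_sep
}

# LJ energy among the atoms of one structure, applying within-residue
# exclusions (bond separation <= 3); inter-residue pairs always scored.
# Used for the template constant and by the reconstruction contract.
self_set_energy <- function(atoms, opt) {
  n <- NROW(atoms)
  if (n < 2) return(0)
  p <- params_of(atoms)
  e <- lj_cross(p$xyz, p$sig, p$eps, p$xyz, p$sig, p$eps, opt)
  df <- as.data.frame(atoms)
  rk <- paste(df$chain, df$resno, df$resid, sep = "\r")
  for (key in unique(rk)) {
    idx <- which(rk == key)
    if (length(idx) < 2) next
    resid <- df$resid[idx[1]]
    e[idx, idx][exclusion_mask(resid, df$atom[idx], df$atom[idx])] <- 0
  }
  diag(e) <- 0
  sum(e[upper.tri(e)])
}

# ---- the pairwise energy matrix ----

#' Assemble the pairwise energy matrix over the design sites
#'
#' Builds every rotamer placement of every allowed residue type at every
#' design site and stores: the template constant (fixed-atom interactions),
#' per-placement self energies (placement vs. template, with within-residue
#' bonded exclusions against the site's own backbone), and pair energies for
#' placements at distinct sites. Placements at the same site are never paired.
#'
#' @param region a \code{\link{extract_design_region}} result.
#' @param alphabet residue types allowed at every site (1- or 3-letter codes);
#'   sorted internally so results do not depend on input order.
#' @param library a rotamer library from \code{\link{load_rotamer_library}}.
#' @param options an \code{\link{energy_options}}.
#' @param expansion optional sub-rotamer expansion passed to
#'   \code{\link{enumerate_placements}}.
#' @return an \code{energy_matrix}: list with \code{sites}, \code{placements}
#'   (data frame: \code{site}, \code{resid}, \code{rot}), \code{atoms} (list
#'   of placement atom matrices), \code{E_template}, \code{E_self},
#'   \code{E_pair} (dense, symmetric, zero within a site), \code{options}.
#' @export
compute_energy_matrix <- function(region, alphabet, library = load_rotamer_library(),
                                  options = energy_options(), expansion = NULL) {
  stopifnot(inherits(region, "design_region"))
  alphabet <- sort(unique(vapply(alphabet, norm_resid, "")))
  nsite <- nrow(region$sites)
  tmpl <- region$template
  tp <- params_of(tmpl)
  tdf <- as.data.frame(tmpl)
  E_template <- self_set_energy(tmpl, options)
  site <- integer(); resid <- character(); rot <- integer()
  atoms_l <- list(); chi_l <- list(); weight <- numeric()
  for (k in seq_len(nsite)) {
    fr <- region$frames[[k]]
    for (rs in alphabet) {
      pls <- enumerate_placements(library, fr, rs, expansion)
      for (j in seq_along(pls)) {
        site <- c(site, k); resid <- c(resid, rs); rot <- c(rot, j)
        atoms_l[[length(atoms_l) + 1]] <- pls[[j]]$atoms
        chi_l[[length(chi_l) + 1]] <- pls[[j]]$chi
        weight <- c(weight, pls[[j]]$weight)
      }
    }
    if (!any(site == k)) stop("no placements at site ",
                              region$sites$chain[k], region$sites$resno[k])
  }
  np <- length(site)
  pl_par <- lapply(seq_len(np), function(i) {
    a <- atoms_l[[i]]
    if (nrow(a) == 0) return(list(sig = numeric(), eps = numeric()))
    p <- atom_params(data.frame(resid = resid[i], atom = rownames(a),
                                stringsAsFactors = FALSE))
    list(sig = p$sigma, eps = p$epsilon)
  })
  # self energies: placement vs template, excluding own-backbone 1-2/1-3/1-4
  E_self <- numeric(np)
  for (i in seq_len(np)) {
    a <- atoms_l[[i]]
    if (nrow(a) == 0) { E_self[i] <- 0; next }
    e <- lj_cross(a, pl_par[[i]]$sig, pl_par[[i]]$eps,
                  tp$xyz, tp$sig, tp$eps, options)
    k <- site[i]
    own <- which(tdf$chain == region$sites$chain[k] &
                   tdf$resno == region$sites$resno[k])
    if (length(own)) {
      d <- sidechain_depths(resid[i])[rownames(a)]
      bbadd <- c(CA = 0L, N = 1L, C = 1L, O = 2L, OXT = 2L)[tdf$atom[own]]
      sep <- outer(d, bbadd, "+")
      e[, own][sep <= 3] <- 0
    }
    E_self[i] <- sum(e)
  }
  # pair energies, site-pair blocks at once
  E_pair <- matrix(0, np, np)
  for (ki in seq_len(nsite - 1)) for (kj in (ki + 1):nsite) {
    pi <- which(site == ki); pj <- which(site == kj)
    ai <- do.call(rbind, atoms_l[pi]); aj <- do.call(rbind, atoms_l[pj])
    if (is.null(ai) || is.null(aj) || nrow(ai) == 0 || nrow(aj) == 0) next
    gi <- rep(seq_along(pi), vapply(atoms_l[pi], nrow, 1L))
    gj <- rep(seq_along(pj), vapply(atoms_l[pj], nrow, 1L))
    e <- lj_cross(ai, unlist(lapply(pl_par[pi], `[[`, "sig")),
                  unlist(lapply(pl_par[pi], `[[`, "eps")),
                  aj, unlist(lapply(pl_par[pj], `[[`, "sig")),
                  unlist(lapply(pl_par[pj], `[[`, "eps")), options)
    tmp <- rowsum(e, gi)
    mi <- matrix(0, length(pi), ncol(e))
    mi[as.integer(rownames(tmp)), ] <- tmp
    tmp2 <- rowsum(t(mi), gj)
    blk <- matrix(0, length(pj), length(pi))  # npl_j x npl_i sums
    blk[as.integer(rownames(tmp2)), ] <- tmp2
    E_pair[pi, pj] <- t(blk)
    E_pair[pj, pi] <- blk
  }
  structure(list(
    sites = region$sites,
    placements = data.frame(site = site, resid = resid, rot = rot,
                            weight = weight, stringsAsFactors = FALSE),
    atoms = atoms_l, chi = chi_l,
    E_template = E_template, E_self = E_self, E_pair = E_pair,
    options = options, alphabet = alphabet),
    class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix> %d sites, %d placements, alphabet {%s}, E_template %.2f\n",
              nrow(x$sites), nrow(x$placements),
              paste(aa_one(x$alphabet), collapse = ","), x$E_template))
  invisible(x)
}

#' Total energy of a complete rotamer assignment
#'
#' \code{E_template + sum(E_self) + sum of E_pair over site pairs}, exact
#' arithmetic over the stored matrix entries.
#'
#' @param matrix an \code{\link{compute_energy_matrix}} result.
#' @param assignment integer vector: one global placement index per site, in
#'   site order.
#' @return energy in kcal/mol.
#' @export
total_energy <- function(matrix, assignment) {
  np <- nrow(matrix$placements)
  nsite <- nrow(matrix$sites)
  if (length(assignment) != nsite)
    stop("assignment must pick one placement per site (", nsite, " sites)")
  if (any(assignment < 1 | assignment > np))
    stop("assignment index out of range")
  if (!identical(matrix$placements$site[assignment], seq_len(nsite)))
    stop("assignment placements are not one-per-site in site order")
  if (nsite == 0) return(matrix$E_template)
  e <- matrix$E_template + sum(matrix$E_self[assignment])
  for (i in seq_len(nsite - 1))
    e <- e + sum(matrix$E_pair[assignment[i], assignment[(i + 1):nsite]])
  e
}

#' Write an energy matrix to a JSON cache file
#'
#' Layout: \code{sites}, \code{placements} (site/resid/rot/chi), scalars
#' \code{E_template}, arrays \code{E_self}, \code{E_pair} (dense row-major),
#' and the \code{options} used.
#'
#' @param matrix an \code{energy_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_energy_matrix_json <- function(matrix, path) {
  obj <- list(sites = matrix$sites,
              placements = cbind(matrix$placements,
                                 chi = I(lapply(matrix$chi, as.numeric))),
              E_template = matrix$E_template,
              E_self = matrix$E_self,
              E_pair = matrix$E_pair,
              options = unclass(matrix$options))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
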