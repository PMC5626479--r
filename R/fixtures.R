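# Synthetic idealized helix-bundle structures. These make the whole pipeline
# runnable and testable without any structure download.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# assemble one helix's residues into atom rows (poly-ALA: N, CA, C, O, CB)
helix_atoms <- function(resnos, chain, resid = "ALA", ...) {
  h <- analytic_helix(resnos, ...)
  rows <- lapply(seq_along(resnos), function(k) {
    r <- h[[k]]
    cb <- place_cb(r$N, r$CA, r$C)
    m <- rbind(N = r$N, CA = r$CA, C = r$C, O = r$O, CB = cb)
    data.frame(atom = rownames(m), element = c("N", "C", "C", "O", "C"),
               x = m[, 1], y = m[, 2], z = m[, 3],
               resno = resnos[k], resid = resid, chain = chain,
               is_backbone = rownames(m) %in% c("N", "CA", "C", "O"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic idealized helix bundle
#'
#' Builds ideal poly-alanine alpha helices (rise 1.5 A, ~100 degrees per
#' residue, generated from ideal internal coordinates) with parallel axes in a
#' row, alternating antiparallel orientation. Each helix is its own chain
#' (A, B, C, ...), residues numbered from 1. Helix phases about their own axes
#' are drawn from \code{seed}; the output is deterministic given the seed.
#'
#' @param n_helices number of helices (>= 1).
#' @param residues_per_helix residues per helix (>= 4).
#' @param inter_axis_spacing distance between neighboring helix axes, Angstrom
#'   (>= 4; smaller is sterically impossible).
#' @param seed integer seed for the helix phases.
#' @return a \code{bh_structure} (5 heavy atoms per ALA residue).
#' @examples
#' b <- make_synthetic_bundle(2, 12, 10, seed = 1)
#' nrow(b)  # 120
#' @export
make_synthetic_bundle <- function(n_helices = 2, residues_per_helix = 12,
                                  inter_axis_spacing = 10, seed = 1) {
  if (n_helices < 1) stop("n_helices must be >= 1")
  if (residues_per_helix < 4) stop("residues_per_helix must be >= 4")
  if (inter_axis_spacing < 4)
    stop("inter_axis_spacing below 4 A is non-physical")
  phases <- with_local_seed(seed, stats::runif(n_helices, 0, 360))
  resnos <- seq_len(residues_per_helix)
  ref <- (1 + residues_per_helix) / 2
  rows <- lapply(seq_len(n_helices), function(k) {
    helix_atoms(resnos, chain = LETTERS[k],
                axis_x = (k - 1) * inter_axis_spacing, axis_y = 0,
                direction = if (k %% 2 == 1) 1L else -1L,
                phase_deg = phases[k], ref_resno = ref, z_ref = 0)
  })
  new_structure(do.call(rbind, rows))
}

#' Synthetic analog of the H3-H3 four-helix bundle interface
#'
#' Constructs an idealized, C2-symmetric four-helix bundle that emulates the
#' histone H3-H3 C-terminal dimerization interface: two chains (default A and
#' B), each contributing two antiparallel helices, with the interface
#' identities of yeast H3 (L109, A110 on the first helix; L126, L130 on the
#' second) placed at core-facing positions. All other residues are alanine.
#'
#' This is a constructed stand-in, not an experimental structure: no
#' coordinates are taken from the PDB. Geometry is ideal (parallel helix axes
#' on a square, ideal helical parameters); it reproduces the topology and
#' core packing arrangement of the real interface well enough to exercise
#' bump-hole design logic, but absolute energies have no experimental meaning.
#'
#' @param chain_x,chain_y chain identifiers for the two protomers.
#' @param half_side half the side of the square on which the four helix axes
#'   sit, Angstrom (side = distance between a chain's two helices and between
#'   neighboring helices of different chains).
#' @return a \code{bh_structure} with chains \code{chain_x} and \code{chain_y},
#'   residues 102-116 (helix 1) and 120-134 (helix 2) per chain.
#' @export
synthetic_h3_bundle <- function(chain_x = "A", chain_y = "B",
                                half_side = 6.5) {
  h1_res <- 102:116  # contains design positions 109, 110
  h2_res <- 120:134  # contains design positions 126, 130
  # Helix phases realize the bump-hole contact topology of the real
  # interface: position 110 of each chain points across the bundle into the
  # groove between the partner chain's 126 and 130 side chains (the two
  # flanking it in azimuth and height), and 109 supports the core edge. The
  # bundle size was calibrated so the wild-type leucine core packs snugly but
  # strain-free (attractive contacts, no near-capped pair term).
  # helix 1: up, axis at (-h, -h); residue 110 faces the partner groove
  a1 <- helix_atoms(h1_res, chain = chain_x, axis_x = -half_side,
                    axis_y = -half_side, direction = 1L,
                    phase_deg = 99.385, ref_resno = 109, z_ref = 0.043)
  # helix 2: down (antiparallel), axis at (-h, +h); 126/130 flank the groove
  a2 <- helix_atoms(h2_res, chain = chain_x, axis_x = -half_side,
                    axis_y = half_side, direction = -1L,
                    phase_deg = 18.77, ref_resno = 126, z_ref = -4.73)
  xa <- rbind(a1, a2)
  # chain Y: C2 rotation about the bundle axis (z)
  ya <- xa
  ya$x <- -xa$x; ya$y <- -xa$y
  ya$chain <- chain_y
  s <- rbind(xa, ya)
  wt <- c("109" = "LEU", "110" = "ALA", "126" = "LEU", "130" = "LEU")
  s$resid <- ifelse(as.character(s$resno) %in% names(wt),
                    wt[as.character(s$resno)], s$resid)
  new_structure(s)
}
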