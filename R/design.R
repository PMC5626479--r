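# Design module: GMEC side-chain packing per sequence (exhaustive or dead-end
# elimination), scoring of the three dimeric states of a sequence pair,
# specificity-gap ranking of sequence space, clash/void diagnosis of designed
# homodimer failure, and a mass-action heterodimer-fraction model.

#' Search options for packing and design enumeration
#'
#' @param enum_bound conformation-space size up to which \code{\link{gmec}}
#'   enumerates exhaustively before trying dead-end elimination.
#' @param hard_bound size above which the post-elimination space is refused.
#' @param budget maximum number of sequence pairs scored in exhaustive design.
#' @param seed integer seed for heuristic design starts.
#' @param delta_stab stability filter: candidates with
#'   \code{E_XY - E_WT > delta_stab} (kcal/mol) are excluded.
#' @param n_starts random restarts in heuristic design mode.
#' @return a \code{search_options} list.
#' @export
search_options <- function(enum_bound = 2e5, hard_bound = 2e6,
                           budget = 2e4, seed = 1, delta_stab = 2,
                           n_starts = 10) {
  structure(list(enum_bound = enum_bound, hard_bound = hard_bound,
                 budget = budget, seed = as.integer(seed),
                 delta_stab = delta_stab, n_starts = n_starts),
            class = "search_options")
}

# candidate placement ids per site under a residue-type constraint
constrained_candidates <- function(matrix, sequence_constraint) {
  nsite <- nrow(matrix$sites)
  con <- vapply(sequence_constraint, norm_resid, "")
  if (length(con) != nsite)
    stop("sequence_constraint must give one residue type per site")
  lapply(seq_len(nsite), function(k) {
    ids <- which(matrix$placements$site == k & matrix$placements$resid == con[k])
    if (length(ids) == 0)
      stop("no placements of ", con[k], " at site ",
           matrix$sites$chain[k], matrix$sites$resno[k],
           " (is it in the matrix alphabet?)")
    ids
  })
}

# exhaustive minimum over the candidate product space; grid is generated in
# lexicographic order over (site 1 slowest ... site n fastest) so which.min
# breaks ties lexicographically by placement index
exhaustive_min <- function(matrix, cand) {
  nsite <- length(cand)
  grid <- as.matrix(expand.grid(rev(cand), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(nsite)), drop = FALSE]
  e <- rowSums(array(matrix$E_self[grid], dim(grid)))
  if (nsite >= 2)
    for (i in seq_len(nsite - 1)) for (j in (i + 1):nsite)
      e <- e + matrix$E_pair[cbind(grid[, i], grid[, j])]
  best <- which.min(e)
  list(assignment = unname(grid[best, ]),
       energy = matrix$E_template + e[best])
}

# Goldstein singles dead-end elimination within the constrained space
dee_prune <- function(matrix, cand) {
  nsite <- length(cand)
  if (nsite < 2) return(cand)
  repeat {
    changed <- FALSE
    for (k in seq_len(nsite)) {
      ids <- cand[[k]]
      if (length(ids) < 2) next
      keep <- rep(TRUE, length(ids))
      others <- setdiff(seq_len(nsite), k)
      # per competitor site: matrix of E_pair restricted to live rotamers
      blocks <- lapply(others, function(j)
        matrix$E_pair[ids, cand[[j]], drop = FALSE])
      for (ri in seq_along(ids)) {
        for (si in seq_along(ids)) {
          if (ri == si || !keep[si]) next
          v <- matrix$E_self[ids[ri]] - matrix$E_self[ids[si]]
          for (b in blocks) v <- v + min(b[ri, ] - b[si, ])
          if (v > 0) { keep[ri] <- FALSE; changed <- TRUE; break }
        }
      }
      cand[[k]] <- ids[keep]
    }
    if (!changed) return(cand)
  }
}

#' Global minimum-energy conformation for a fixed sequence
#'
#' Finds the rotamer assignment minimizing \code{\link{total_energy}} under a
#' per-site residue-type constraint. Spaces up to \code{enum_bound} are
#' enumerated exhaustively; larger spaces are first pruned by Goldstein
#' singles dead-end elimination, then enumerated. Ties are broken
#' lexicographically by (site order, placement index).
#'
#' @param matrix an \code{\link{compute_energy_matrix}} result.
#' @param sequence_constraint residue type per site (1- or 3-letter codes),
#'   in site order.
#' @param search a \code{\link{search_options}}.
#' @param method \code{"auto"} (default), \code{"exhaustive"} or \code{"dee"}
#'   to force a path (used for cross-checking).
#' @return a \code{state_solution} stub: list with \code{assignment} (global
#'   placement index per site), \code{energy} (kcal/mol) and \code{method}.
#' @export
gmec <- function(matrix, sequence_constraint, search = search_options(),
                 method = c("auto", "exhaustive", "dee")) {
  method <- match.arg(method)
  cand <- constrained_candidates(matrix, sequence_constraint)
  if (length(cand) == 0)
    return(list(assignment = integer(), energy = matrix$E_template,
                method = "degenerate"))
  space <- prod(vapply(cand, length, 1))
  used <- method
  if (method == "auto") used <- if (space <= search$enum_bound) "exhaustive" else "dee"
  if (used == "dee") {
    cand <- dee_prune(matrix, cand)
    space <- prod(vapply(cand, length, 1))
    if (space > search$hard_bound)
      stop("conformation space still ", format(space, big.mark = ","),
           " after dead-end elimination; reduce the sub-rotamer expansion ",
           "or the alphabet")
  }
  out <- exhaustive_min(matrix, cand)
  out$method <- used
  out
}

# cross-protomer atom-pair contact table of one assembled state
state_contacts <- function(region, matrix, assignment, options) {
  df <- assemble_state(region, matrix, assignment)
  cx <- region$spec$chain_x
  a <- df[df$chain == cx, , drop = FALSE]
  b <- df[df$chain != cx, , drop = FALSE]
  pa <- params_of(a); pb <- params_of(b)
  e <- lj_cross(pa$xyz, pa$sig, pa$eps, pb$xyz, pb$sig, pb$eps, options)
  idx <- which(e != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_contacts())
  d <- sqrt(rowSums((pa$xyz[idx[, 1], , drop = FALSE] -
                       pb$xyz[idx[, 2], , drop = FALSE])^2))
  out <- data.frame(
    chain_a = a$chain[idx[, 1]], resno_a = a$resno[idx[, 1]],
    resid_a = a$resid[idx[, 1]], atom_a = a$atom[idx[, 1]],
    chain_b = b$chain[idx[, 2]], resno_b = b$resno[idx[, 2]],
    resid_b = b$resid[idx[, 2]], atom_b = b$atom[idx[, 2]],
    distance = d, energy = e[idx], stringsAsFactors = FALSE)
  out[order(-out$energy, out$resno_a, out$atom_a), , drop = FALSE]
}

empty_contacts <- function() {
  data.frame(chain_a = character(), resno_a = integer(), resid_a = character(),
             atom_a = character(), chain_b = character(), resno_b = integer(),
             resid_b = character(), atom_b = character(),
             distance = numeric(), energy = numeric(),
             stringsAsFactors = FALSE)
}

#' Assemble the atoms of a packed state
#'
#' Template atoms plus the side-chain atoms of the assigned placements, with
#' design-residue identities updated to the assigned types.
#'
#' @param region a \code{design_region}.
#' @param matrix the energy matrix the assignment indexes into.
#' @param assignment one global placement index per site.
#' @return a \code{bh_structure} (template shell + placed side chains).
#' @export
assemble_state <- function(region, matrix, assignment) {
  out <- as.data.frame(region$template)
  for (k in seq_along(assignment)) {
    i <- assignment[k]
    sel <- out$chain == region$sites$chain[k] &
      out$resno == region$sites$resno[k]
    out$resid[sel] <- matrix$placements$resid[i]
    at <- matrix$atoms[[i]]
    if (nrow(at) == 0) next
    out <- rbind(out, data.frame(
      atom = rownames(at), element = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3],
      resno = region$sites$resno[k], resid = matrix$placements$resid[i],
      chain = region$sites$chain[k], is_backbone = FALSE,
      stringsAsFactors = FALSE))
  }
  out <- out[order(match(out$chain, unique(out$chain)), out$resno), ,
             drop = FALSE]
  new_structure(out)
}

seq_split <- function(x, npos) {
  s <- if (length(x) == 1 && nchar(x[1]) > 1) strsplit(x, "")[[1]] else x
  if (length(s) != npos)
    stop("sequence must give one residue per design position (", npos, ")")
  toupper(s)
}

#' Wild-type design-position sequence of a region
#' @param region a \code{design_region}.
#' @return character vector of 1-letter codes, one per design position
#'   (taken from chain X; the spec requires both chains to agree).
#' @export
wt_sequence <- function(region) {
  cx <- region$spec$chain_x
  s <- region$sites[region$sites$chain == cx, , drop = FALSE]
  aa_one(s$wt[match(region$spec$design_positions, s$resno)])
}

#' Apply mutation tokens to a design-position sequence
#' @param region a \code{design_region}.
#' @param mutations character vector like \code{c("L126A", "L130V")} (tokens
#'   at non-design positions are an error); empty means wild type.
#' @return 1-letter sequence over the design positions.
#' @export
sequence_from_mutations <- function(region, mutations = character()) {
  s <- wt_sequence(region)
  pos <- region$spec$design_positions
  if (length(mutations) == 0) return(s)
  m <- if (is.character(mutations)) parse_mutations(mutations) else mutations
  for (k in seq_len(nrow(m))) {
    i <- match(m$position[k], pos)
    if (is.na(i)) stop("mutation position ", m$position[k],
                       " is not a design position")
    if (s[i] != m$wt[k])
      stop("wild-type mismatch in mutation ", m$wt[k], m$position[k], m$mut[k],
           ": design position holds ", s[i])
    s[i] <- m$mut[k]
  }
  s
}

# residue-type constraint over all sites for (chain_x sequence, chain_y sequence)
state_constraint <- function(region, seq_cx, seq_cy) {
  pos <- region$spec$design_positions
  vapply(seq_len(nrow(region$sites)), function(k) {
    s <- if (region$sites$chain[k] == region$spec$chain_x) seq_cx else seq_cy
    s[match(region$sites$resno[k], pos)]
  }, "")
}

#' Score the dimeric states of a candidate sequence pair
#'
#' On one fixed backbone, packs (GMEC) the heterodimer X/Y, the two
#' homodimers X/X and Y/Y, and the wild type, all from one energy matrix over
#' the union alphabet. Homodimer protomers may adopt independent rotamers.
#' The heterodimer is scored as the better of its two threadings (X on chain
#' X / Y on chain Y and vice versa), which makes scores exactly symmetric
#' under relabeling X and Y.
#'
#' @param region a \code{design_region}.
#' @param x_seq,y_seq 1-letter sequences over the design positions (string or
#'   vector), or mutation token vectors via \code{\link{sequence_from_mutations}}.
#' @param library rotamer library.
#' @param options an \code{\link{energy_options}}.
#' @param search a \code{\link{search_options}}.
#' @param matrix optional precomputed \code{energy_matrix} covering all
#'   needed residue types (built automatically otherwise).
#' @param expansion optional sub-rotamer expansion.
#' @param contacts compute per-contact tables for the state solutions
#'   (needed by \code{\link{classify_failure_mode}}).
#' @return a \code{specificity_score}: list with \code{E_XY}, \code{E_XX},
#'   \code{E_YY}, \code{E_WT}, \code{gap = min(E_XX, E_YY) - E_XY},
#'   \code{stability = E_XY - E_WT}, and \code{states} (per-state solutions
#'   with assignments, energies and cross-protomer contact tables).
#' @export
score_states <- function(region, x_seq, y_seq, library = load_rotamer_library(),
                         options = energy_options(), search = search_options(),
                         matrix = NULL, expansion = NULL, contacts = TRUE) {
  pos <- region$spec$design_positions
  x <- seq_split(x_seq, length(pos))
  y <- seq_split(y_seq, length(pos))
  wt <- wt_sequence(region)
  if (is.null(matrix)) {
    alphabet <- unique(c(x, y, wt))
    matrix <- compute_energy_matrix(region, alphabet, library, options,
                                    expansion)
  }
  solve_state <- function(label, seq_cx, seq_cy) {
    sol <- gmec(matrix, state_constraint(region, seq_cx, seq_cy), search)
    sol$state_label <- label
    sol$per_contact <- if (contacts)
      state_contacts(region, matrix, sol$assignment, options)
    sol
  }
  xy1 <- solve_state("XY", x, y)
  xy <- if (identical(x, y)) xy1 else {
    xy2 <- solve_state("XY", y, x)
    if (xy2$energy < xy1$energy) xy2 else xy1
  }
  xx <- solve_state("XX", x, x)
  yy <- solve_state("YY", y, y)
  wts <- solve_state("WT", wt, wt)
  structure(list(
    x_seq = paste(x, collapse = ""), y_seq = paste(y, collapse = ""),
    positions = pos,
    E_XY = xy$energy, E_XX = xx$energy, E_YY = yy$energy, E_WT = wts$energy,
    gap = min(xx$energy, yy$energy) - xy$energy,
    stability = xy$energy - wts$energy,
    states = list(XY = xy, XX = xx, YY = yy, WT = wts),
    matrix = matrix),
    class = "specificity_score")
}

#' @export
print.specificity_score <- function(x, ...) {
  cat(sprintf("<specificity_score> X=%s Y=%s\n", x$x_seq, x$y_seq))
  cat(sprintf("  E_XY %.2f  E_XX %.2f  E_YY %.2f  E_WT %.2f kcal/mol\n",
              x$E_XY, x$E_XX, x$E_YY, x$E_WT))
  cat(sprintf("  gap %.2f  stability %.2f kcal/mol\n", x$gap, x$stability))
  invisible(x)
}

#' Diagnose why a designed homodimer fails
#'
#' \code{"clash"} if any cross-protomer atom-pair term in the packed
#' homodimer is at or above \code{options$clash_cut}; otherwise \code{"void"}
#' if the homodimer's energy exceeds the wild type's by at least
#' \code{options$void_cut}; otherwise \code{"none"}.
#'
#' @param homodimer,wt state solutions from \code{\link{score_states}}
#'   (computed with \code{contacts = TRUE}, on the same matrix/backbone).
#' @param options an \code{\link{energy_options}}.
#' @return list with \code{mode} ("clash", "void" or "none"),
#'   \code{deficit} (homodimer minus wild-type energy, kcal/mol) and
#'   \code{offending} (contact rows at or above the clash threshold).
#' @export
classify_failure_mode <- function(homodimer, wt, options = energy_options()) {
  pc <- homodimer$per_contact
  if (is.null(pc))
    stop("homodimer solution lacks contacts; score with contacts = TRUE")
  off <- pc[pc$energy >= options$clash_cut, , drop = FALSE]
  deficit <- homodimer$energy - wt$energy
  mode <- if (nrow(off) > 0) "clash"
  else if (deficit >= options$void_cut) "void"
  else "none"
  list(mode = mode, deficit = deficit, offending = off)
}

#' Expected heterodimer fraction from the two homodimer gaps
#'
#' Under equimolar, fully dimerized mass-action mixing of X and Y, with
#' Boltzmann weights on the three dimer states, the heterodimer fraction is
#' \code{2 / (2 + exp(-gap_XX/RT) + exp(-gap_YY/RT))}, where
#' \code{gap_ss = E_ss - E_XY}. Equal-energy states (gaps 0, 0) give 0.5;
#' large positive gaps approach 1.
#'
#' @param gap_XX,gap_YY homodimer energy gaps, kcal/mol.
#' @param temperature Kelvin.
#' @return fraction in (0, 1].
#' @export
heterodimer_fraction <- function(gap_XX, gap_YY, temperature = 303) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  rt <- 0.0019872041 * temperature
  2 / (2 + exp(-gap_XX / rt) + exp(-gap_YY / rt))
}

all_sequences <- function(alphabet, npos) {
  grid <- expand.grid(rep(list(alphabet), npos), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_len(npos)), drop = FALSE]
  sort(apply(grid, 1, paste, collapse = ""))
}

#' Enumerate and rank heterodimer designs by specificity gap
#'
#' Exhaustive mode scores every unordered sequence pair over the alphabet at
#' the design positions (up to X/Y relabeling symmetry); heuristic mode runs
#' seeded multi-start coordinate ascent on the gap objective and scores every
#' pair it visits. Candidates violating the stability filter
#' (\code{E_XY - E_WT > delta_stab}) are dropped; the rest are ranked by
#' descending gap (ties alphabetical). Deterministic given the seed.
#'
#' @param region a \code{design_region}.
#' @param alphabet allowed residue types (1- or 3-letter codes).
#' @param library rotamer library.
#' @param options an \code{\link{energy_options}}.
#' @param search a \code{\link{search_options}} (budget, seed, delta_stab,
#'   n_starts).
#' @param mode \code{"exhaustive"} or \code{"heuristic"}.
#' @param expansion optional sub-rotamer expansion.
#' @return a \code{design_candidates} data frame: \code{sequence_X},
#'   \code{sequence_Y}, state energies, \code{gap}, \code{stability},
#'   \code{failure_mode_XX}, \code{failure_mode_YY}, \code{rank}; attribute
#'   \code{positions}.
#' @export
enumerate_designs <- function(region, alphabet, library = load_rotamer_library(),
                              options = energy_options(),
                              search = search_options(),
                              mode = c("exhaustive", "heuristic"),
                              expansion = NULL) {
  mode <- match.arg(mode)
  pos <- region$spec$design_positions
  alphabet <- sort(unique(toupper(vapply(alphabet, function(a)
    aa_one(norm_resid(a)), ""))))
  wt <- wt_sequence(region)
  matrix <- compute_energy_matrix(region, unique(c(alphabet, wt)), library,
                                  options, expansion)
  wt_str <- paste(wt, collapse = "")
  cache <- new.env(parent = emptyenv())
  homo <- function(s) {  # homodimer energy + solution, cached per sequence
    key <- paste0("H", s)
    if (is.null(cache[[key]])) {
      sq <- strsplit(s, "")[[1]]
      cache[[key]] <- gmec(matrix, state_constraint(region, sq, sq), search)
    }
    cache[[key]]
  }
  hetero <- function(s1, s2) {  # symmetric heterodimer energy, cached
    if (s1 == s2) return(homo(s1)$energy)
    key <- paste0("P", min(s1, s2), max(s1, s2))
    if (is.null(cache[[key]])) {
      a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
      e1 <- gmec(matrix, state_constraint(region, a, b), search)$energy
      e2 <- gmec(matrix, state_constraint(region, b, a), search)$energy
      cache[[key]] <- min(e1, e2)
    }
    cache[[key]]
  }
  E_WT <- homo(wt_str)$energy
  fail_mode <- function(s) {  # homodimer failure mode, cached per sequence
    key <- paste0("F", s)
    if (is.null(cache[[key]])) {
      sol <- homo(s)
      sol$per_contact <- state_contacts(region, matrix, sol$assignment, options)
      cache[[key]] <- classify_failure_mode(sol, homo(wt_str), options)$mode
    }
    cache[[key]]
  }
  score_pair <- function(s1, s2) {
    sx <- min(s1, s2); sy <- max(s1, s2)  # canonical order under relabeling
    e_xy <- hetero(sx, sy)
    e_xx <- homo(sx)$energy; e_yy <- homo(sy)$energy
    data.frame(sequence_X = sx, sequence_Y = sy,
               E_XY = e_xy, E_XX = e_xx, E_YY = e_yy, E_WT = E_WT,
               gap = min(e_xx, e_yy) - e_xy, stability = e_xy - E_WT,
               stringsAsFactors = FALSE)
  }
  if (mode == "exhaustive") {
    seqs <- all_sequences(alphabet, length(pos))
    n <- length(seqs)
    npairs <- n * (n + 1) / 2
    if (npairs > search$budget)
      stop(format(npairs, big.mark = ","), " sequence pairs exceed the ",
           "exhaustive budget (", format(search$budget, big.mark = ","),
           "); use heuristic mode or restrict the alphabet")
    rows <- vector("list", npairs)
    r <- 0
    for (i in seq_len(n)) for (j in i:n) {
      r <- r + 1
      rows[[r]] <- score_pair(seqs[i], seqs[j])
    }
    cand <- do.call(rbind, rows)
  } else {
    nres <- length(alphabet)
    npos <- length(pos)
    starts <- with_local_seed(search$seed, {
      lapply(seq_len(search$n_starts), function(k)
        c(paste(sample(alphabet, npos, replace = TRUE), collapse = ""),
          paste(sample(alphabet, npos, replace = TRUE), collapse = "")))
    })
    visited <- new.env(parent = emptyenv())
    note <- function(s1, s2) {
      key <- paste(min(s1, s2), max(s1, s2))
      if (is.null(visited[[key]])) visited[[key]] <- score_pair(s1, s2)
    }
    objective <- function(s1, s2) {
      sc <- score_pair(s1, s2)
      sc$gap - 10 * max(0, sc$stability - search$delta_stab)
    }
    for (st in starts) {
      cur <- st
      best <- objective(cur[1], cur[2]); note(cur[1], cur[2])
      repeat {
        improved <- FALSE
        for (w in 1:2) for (p in seq_len(npos)) for (a in alphabet) {
          trial <- cur
          sq <- strsplit(trial[w], "")[[1]]
          if (sq[p] == a) next
          sq[p] <- a
          trial[w] <- paste(sq, collapse = "")
          note(trial[1], trial[2])
          ob <- objective(trial[1], trial[2])
          if (ob > best + 1e-12) { cur <- trial; best <- ob; improved <- TRUE }
        }
        if (!improved) break
      }
    }
    cand <- do.call(rbind, lapply(ls(visited, sorted = TRUE),
                                  function(k) visited[[k]]))
    cand <- unique(cand)
  }
  cand <- cand[cand$stability <= search$delta_stab, , drop = FALSE]
  cand$failure_mode_XX <- vapply(cand$sequence_X, fail_mode, "")
  cand$failure_mode_YY <- vapply(cand$sequence_Y, fail_mode, "")
  cand <- cand[order(-cand$gap, cand$sequence_X, cand$sequence_Y), ,
               drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  attr(cand, "positions") <- pos
  attr(cand, "wt") <- wt_str
  class(cand) <- c("design_candidates", "data.frame")
  cand
}
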