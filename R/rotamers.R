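# Rotamers module: discrete rotamer library, side-chain construction from chi
# angles by sequential torsion (internal-coordinate) building, and placement
# enumeration at a design site.

.pkg_data_env <- new.env(parent = emptyenv())

pkg_data_path <- function(name) {
  p <- system.file("extdata", name, package = "bumphole")
  if (nzchar(p)) return(p)
  # during development (package sourced, not installed)
  p <- file.path("inst", "extdata", name)
  if (file.exists(p)) return(p)
  stop("packaged data file not found: ", name)
}

read_pkg_tsv <- function(name) {
  if (!is.null(.pkg_data_env[[name]])) return(.pkg_data_env[[name]])
  d <- utils::read.delim(pkg_data_path(name), comment.char = "#",
                         stringsAsFactors = FALSE)
  .pkg_data_env[[name]] <- d
  d
}

topology_table <- function() read_pkg_tsv("topology.tsv")

residue_topology <- function(resid) {
  t <- topology_table()
  t[t$resid == resid, , drop = FALSE]
}

#' Side-chain heavy-atom names of a residue type
#' @param resid 3-letter residue code.
#' @return character vector (empty for GLY).
#' @export
sidechain_atom_names <- function(resid) {
  resid <- norm_resid(resid)
  if (resid == "GLY") return(character())
  c("CB", residue_topology(resid)$atom)
}

norm_resid <- function(residue_type) {
  r <- toupper(residue_type)
  if (nchar(r) == 1) r <- aa_three(r)
  if (!r %in% .aa3) stop("unknown residue type: ", residue_type)
  r
}

# number of chi angles per residue type, derived from the topology table
n_chi <- function(resid) {
  resid <- norm_resid(resid)
  t <- residue_topology(resid)
  ref <- regmatches(t$torsion, regexpr("chi[0-9]", t$torsion))
  if (length(ref) == 0) return(0L)
  max(as.integer(sub("chi", "", ref)))
}

# bond depth of each side-chain atom from CA (CB = 1), used for within-residue
# 1-2/1-3/1-4 exclusions against the own backbone
sidechain_depths <- function(resid) {
  resid <- norm_resid(resid)
  if (resid == "GLY") return(integer())
  d <- c(CB = 1L)
  t <- residue_topology(resid)
  for (k in seq_len(nrow(t))) d[t$atom[k]] <- d[[t$parent[k]]] + 1L
  d
}

#' Load a packaged rotamer library
#'
#' The default library is a compact backbone-independent set of canonical
#' gauche-/trans/gauche+ chi combinations with approximate literature
#' frequencies, shipped as a versioned TSV. Weights are normalized to sum to
#' one per residue type.
#'
#' @param source_id library identifier; currently \code{"compact_v1"}.
#' @return a \code{rotamer_library}: a list keyed by 3-letter residue code;
#'   each element is a list of rotamers with fields \code{chi} (numeric,
#'   degrees) and \code{weight}.
#' @examples
#' lib <- load_rotamer_library()
#' length(lib$ALA)  # 1
#' @export
load_rotamer_library <- function(source_id = "compact_v1") {
  available <- c("compact_v1")
  if (!source_id %in% available)
    stop("unknown rotamer library \"", source_id, "\"; available: ",
         paste(available, collapse = ", "))
  d <- read_pkg_tsv("rotamers.tsv")
  lib <- list()
  for (rs in unique(d$resid)) {
    rows <- d[d$resid == rs, , drop = FALSE]
    w <- rows$weight / sum(rows$weight)
    nc <- n_chi(rs)
    lib[[rs]] <- lapply(seq_len(nrow(rows)), function(k) {
      chi <- as.numeric(rows[k, paste0("chi", seq_len(nc))])
      chi <- chi[!is.na(chi)]
      list(residue_type = rs, chi = chi, weight = w[k])
    })
  }
  stopifnot(all(names(.aa3) %in% aa_one(names(lib))))
  structure(lib, class = "rotamer_library", source_id = source_id)
}

#' Backbone frame of one residue
#' @param N,CA,C numeric length-3 coordinates, Angstrom.
#' @return a \code{backbone_frame} list.
#' @export
backbone_frame <- function(N, CA, C) {
  for (d in c(vnorm(N - CA), vnorm(C - CA)))
    if (d < 1.2 || d > 1.8)
      stop("implausible backbone bond length (", round(d, 2), " A) in frame")
  structure(list(N = N, CA = CA, C = C), class = "backbone_frame")
}

#' Build side-chain heavy atoms from chi angles on a backbone frame
#'
#' CB is placed tetrahedrally from N/CA/C; subsequent atoms by sequential
#' torsion construction using the packaged ideal internal-coordinate table.
#' Chi torsions are realized exactly: re-measuring the dihedrals on the built
#' coordinates reproduces the requested values.
#'
#' @param frame a \code{\link{backbone_frame}} (or list with N, CA, C).
#' @param residue_type 1- or 3-letter residue code.
#' @param chi numeric vector of chi angles in degrees; length must match the
#'   residue's rotatable bonds (0 for ALA/GLY).
#' @return numeric matrix (atoms x 3) with side-chain atom names as rownames;
#'   zero rows for GLY.
#' @examples
#' fr <- list(N = c(1.46, 0, 0), CA = c(0, 0, 0), C = c(-0.55, 1.42, 0))
#' build_sidechain(fr, "LEU", c(-60, 180))
#' @export
build_sidechain <- function(frame, residue_type, chi = numeric()) {
  resid <- norm_resid(residue_type)
  nc <- n_chi(resid)
  if (length(chi) != nc)
    stop(resid, " takes ", nc, " chi angle(s), got ", length(chi))
  if (resid == "GLY")
    return(matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  pos <- list(N = frame$N, CA = frame$CA, C = frame$C)
  pos$CB <- place_cb(frame$N, frame$CA, frame$C)
  t <- residue_topology(resid)
  for (k in seq_len(nrow(t))) {
    tor <- t$torsion[k]
    m <- regmatches(tor, regexec("^chi([0-9])([+-][0-9.]+)?$", tor))[[1]]
    tors <- if (length(m)) {
      chi[as.integer(m[2])] + if (nzchar(m[3])) as.numeric(m[3]) else 0
    } else as.numeric(tor)
    pos[[t$atom[k]]] <- place_atom(pos[[t$ggparent[k]]], pos[[t$gparent[k]]],
                                   pos[[t$parent[k]]], t$bond[k], t$angle[k],
                                   tors)
  }
  nm <- sidechain_atom_names(resid)
  out <- do.call(rbind, pos[nm])
  dimnames(out) <- list(nm, c("x", "y", "z"))
  out
}

#' Enumerate rotamer placements of one residue type at a design site
#'
#' One placement per library rotamer, optionally expanded by sub-rotamer chi
#' perturbations. Order is deterministic: library order, then perturbation
#' order (chi1 offsets outer, chi2 offsets inner).
#'
#' @param library a \code{\link{load_rotamer_library}} result.
#' @param frame the site's \code{\link{backbone_frame}}.
#' @param residue_type 1- or 3-letter code.
#' @param expansion optional named list of chi offsets in degrees, e.g.
#'   \code{list(chi1 = c(-10, 0, 10))}; offsets apply to chi1 and/or chi2.
#' @return list of placements; each has \code{residue_type}, \code{chi},
#'   \code{weight}, \code{atoms} (matrix from \code{\link{build_sidechain}}).
#' @export
enumerate_placements <- function(library, frame, residue_type,
                                 expansion = NULL) {
  resid <- norm_resid(residue_type)
  rots <- library[[resid]]
  if (is.null(rots)) stop("library has no rotamers for ", resid)
  offs1 <- if (!is.null(expansion$chi1)) expansion$chi1 else 0
  offs2 <- if (!is.null(expansion$chi2)) expansion$chi2 else 0
  out <- list()
  for (r in rots) {
    nc <- length(r$chi)
    o1 <- if (nc >= 1) offs1 else 0
    o2 <- if (nc >= 2) offs2 else 0
    for (d1 in o1) for (d2 in o2) {
      chi <- r$chi
      if (nc >= 1) chi[1] <- chi[1] + d1
      if (nc >= 2) chi[2] <- chi[2] + d2
      out[[length(out) + 1]] <- list(
        residue_type = resid, chi = chi, weight = r$weight,
        atoms = build_sidechain(frame, resid, chi))
    }
  }
  out
}
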