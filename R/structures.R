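# Structures module: PDB-format I/O, mutation threading on a fixed backbone,
# design-region extraction with an environment shell.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.aa1 <- stats::setNames(names(.aa3), .aa3)

#' One- and three-letter amino-acid code conversion
#'
#' @param x character vector of codes.
#' @return character vector of converted codes.
#' @examples
#' aa_three("L")
#' aa_one("TRP")
#' @export
aa_three <- function(x) {
  out <- .aa3[toupper(x)]
  if (anyNA(out)) stop("unknown 1-letter code(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- .aa1[toupper(x)]
  if (anyNA(out)) stop("unknown 3-letter code(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

new_structure <- function(atoms) {
  need <- c("atom", "element", "x", "y", "z", "resno", "resid", "chain",
            "is_backbone")
  stopifnot(all(need %in% names(atoms)))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(atoms, class = c("bh_structure", "data.frame"))
}

#' @export
print.bh_structure <- function(x, ...) {
  cat(sprintf("<bh_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x), nrow(unique(x[, c("chain", "resno")])),
              paste(sort(unique(x$chain)), collapse = " ")))
  invisible(x)
}

coords <- function(s) as.matrix(s[, c("x", "y", "z"), drop = FALSE])

element_of <- function(atom_name) {
  # PDB heavy-atom names: first alphabetic character is the element for C/N/O/S
  substr(gsub("[0-9']", "", atom_name), 1, 1)
}

#' Read a protein structure from PDB-format text
#'
#' Parses PDB ATOM records (via \code{bio3d::read.pdb}) and returns protein
#' heavy atoms only: HETATM records, waters, hydrogens and all but the
#' highest-occupancy alternate location are dropped (altloc ties broken
#' alphabetically). Author residue numbering is preserved. The first model is
#' used.
#'
#' @param source path to a PDB file, or a character vector of PDB-format lines
#'   (a single string with embedded newlines is also accepted).
#' @return a \code{bh_structure}: a data frame of atoms with columns
#'   \code{atom}, \code{element}, \code{x}, \code{y}, \code{z}, \code{resno},
#'   \code{resid}, \code{chain}, \code{is_backbone}.
#' @examples
#' line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
#' read_structure(line)
#' @export
read_structure <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_at <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_at)) stop("no ATOM records found in input")
  # validate fixed-column numeric fields before parsing proper
  for (i in which(is_at)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("unparsable ATOM record at line ", i,
                             ": record shorter than coordinate fields")
    fields <- c(substr(ln, 23, 26), substr(ln, 31, 38), substr(ln, 39, 46),
                substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("unparsable ATOM record at line ", i,
           ": non-numeric residue number or coordinate field")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[a$resid %in% .aa3, , drop = FALSE]
  a <- a[element_of(a$elety) %in% c("C", "N", "O", "S"), , drop = FALSE]
  a <- a[!grepl("^H|^[0-9]H", a$elety), , drop = FALSE]
  if (nrow(a) == 0) stop("no protein heavy atoms after filtering")
  a$chain[is.na(a$chain)] <- " "
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc: keep highest occupancy; ties alphabetical by altloc code
  key <- paste(a$chain, a$resno, a$elety, sep = "\r")
  ord <- order(key, -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(match(paste(a$chain, a$resno, a$elety, sep = "\r"), key)), ,
         drop = FALSE]
  new_structure(data.frame(
    atom = a$elety, element = element_of(a$elety),
    x = a$x, y = a$y, z = a$z, resno = a$resno, resid = a$resid,
    chain = a$chain, is_backbone = a$elety %in% .backbone_names,
    stringsAsFactors = FALSE))
}

#' Write a structure as PDB-format text
#'
#' Emits fixed-column ATOM records. \code{read_structure(write_structure(s))}
#' reproduces every atom field, with coordinates at the format's 3-decimal
#' precision; a second write of the re-read structure is byte-identical.
#'
#' @param structure a \code{bh_structure}.
#' @param file optional path; when given, lines are written there.
#' @return character vector of PDB lines (invisibly when \code{file} is set).
#' @export
write_structure <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "bh_structure"))
  if (nrow(structure) == 0) stop("cannot write an empty structure")
  xyz <- coords(structure)
  if (any(abs(xyz) >= 10000) || any(xyz <= -1000))
    stop("coordinate overflows the fixed-width PDB field")
  nm <- structure$atom
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(structure)), nm4, structure$resid, structure$chain,
    structure$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, structure$element)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse mutation tokens like "L126A"
#'
#' @param tokens character vector, each \code{<wt><position><mut>} in 1-letter
#'   codes with author residue numbering.
#' @return data frame with columns \code{wt}, \code{position}, \code{mut}.
#' @examples
#' parse_mutations(c("L126A", "L130V"))
#' @export
parse_mutations <- function(tokens) {
  if (length(tokens) == 0)
    return(data.frame(wt = character(), position = integer(),
                      mut = character(), stringsAsFactors = FALSE))
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- vapply(m, length, 1L) != 4
  if (any(bad)) stop("malformed mutation token(s): ",
                     paste(tokens[bad], collapse = ", "),
                     " (expected e.g. \"L126A\")")
  out <- data.frame(
    wt = toupper(vapply(m, `[`, "", 2)),
    position = as.integer(vapply(m, `[`, "", 3)),
    mut = toupper(vapply(m, `[`, "", 4)),
    stringsAsFactors = FALSE)
  aa_three(out$wt); aa_three(out$mut)  # validate codes
  if (any(out$wt == out$mut)) stop("mutation with identical wt and mut: ",
                                   paste(tokens[out$wt == out$mut], collapse = ", "))
  if (any(out$position <= 0)) stop("mutation position must be positive")
  out
}

#' Thread mutations onto a fixed backbone
#'
#' Updates the residue identity at the mutated positions of one chain and
#' removes the side-chain atoms of those residues (they are rebuilt from
#' rotamers downstream). Backbone atoms are untouched.
#'
#' @param structure a \code{bh_structure}.
#' @param chain_id chain to mutate.
#' @param mutations a data frame from \code{\link{parse_mutations}} or a
#'   character vector of tokens like \code{"L126A"}.
#' @return the mutated \code{bh_structure}.
#' @export
apply_mutations <- function(structure, chain_id, mutations) {
  stopifnot(inherits(structure, "bh_structure"))
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  if (nrow(mutations) == 0) return(structure)
  s <- structure
  for (k in seq_len(nrow(mutations))) {
    wt <- mutations$wt[k]; pos <- mutations$position[k]; mut <- mutations$mut[k]
    sel <- s$chain == chain_id & s$resno == pos
    if (!any(sel)) stop("no residue ", pos, " on chain ", chain_id)
    found <- unique(s$resid[sel])
    if (!identical(found, aa_three(wt)))
      stop("wild-type mismatch at position ", pos, " chain ", chain_id,
           ": expected ", aa_three(wt), ", found ", paste(found, collapse = "/"))
    drop <- sel & !s$is_backbone
    s <- s[!drop, , drop = FALSE]
    s$resid[s$chain == chain_id & s$resno == pos] <- aa_three(mut)
  }
  new_structure(s)
}

#' Interface specification for a two-protomer design run
#'
#' @param chain_x,chain_y chain identifiers of the two protomers.
#' @param design_positions residue numbers (author numbering) designed on
#'   BOTH chains.
#' @param environment_cutoff shell radius in Angstrom around design-site
#'   CA/CB atoms used to collect fixed template atoms.
#' @return an \code{interface_spec} list.
#' @export
interface_spec <- function(chain_x, chain_y, design_positions,
                           environment_cutoff = 8) {
  if (identical(chain_x, chain_y)) stop("chain_x and chain_y must differ")
  if (length(design_positions) == 0) stop("design_positions must be nonempty")
  if (environment_cutoff < 0) stop("environment_cutoff must be >= 0")
  structure(list(chain_x = as.character(chain_x),
                 chain_y = as.character(chain_y),
                 design_positions = sort(unique(as.integer(design_positions))),
                 environment_cutoff = environment_cutoff),
            class = "interface_spec")
}

#' Extract the design region and its fixed environment shell
#'
#' Enumerates design sites (each design position on each of the two chains,
#' with its backbone frame and wild-type identity) and collects the template:
#' all non-design atoms within \code{environment_cutoff} of any design-site CA
#' or CB (brute-force distance criterion) plus all design-site backbone atoms.
#' Side-chain atoms of design residues are excluded from the template; they
#' are replaced by rotamer placements during packing.
#'
#' @param structure a \code{bh_structure} containing both chains.
#' @param spec an \code{\link{interface_spec}}.
#' @return a \code{design_region}: list with \code{sites} (data frame:
#'   \code{chain}, \code{resno}, \code{wt}), \code{frames} (per-site backbone
#'   N/CA/C coordinates), \code{template} (a \code{bh_structure}) and the spec.
#' @export
extract_design_region <- function(structure, spec) {
  stopifnot(inherits(structure, "bh_structure"), inherits(spec, "interface_spec"))
  for (ch in c(spec$chain_x, spec$chain_y))
    if (!any(structure$chain == ch)) stop("chain ", ch, " not present")
  sites <- expand.grid(chain = c(spec$chain_x, spec$chain_y),
                       resno = spec$design_positions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sites <- sites[order(match(sites$chain, c(spec$chain_x, spec$chain_y)),
                       sites$resno), , drop = FALSE]
  rownames(sites) <- NULL
  frames <- vector("list", nrow(sites))
  sites$wt <- NA_character_
  probe <- NULL  # design-site CA/CB coordinates for the shell criterion
  is_design <- rep(FALSE, nrow(structure))
  for (k in seq_len(nrow(sites))) {
    sel <- structure$chain == sites$chain[k] & structure$resno == sites$resno[k]
    if (!any(sel)) stop("design position ", sites$resno[k],
                        " missing on chain ", sites$chain[k])
    res <- structure[sel, , drop = FALSE]
    for (at in c("N", "CA", "C"))
      if (!at %in% res$atom) stop("missing backbone atom ", at, " at design site ",
                                  sites$chain[k], sites$resno[k])
    gc <- function(nm) as.numeric(res[match(nm, res$atom), c("x", "y", "z")])
    frames[[k]] <- list(N = gc("N"), CA = gc("CA"), C = gc("C"))
    sites$wt[k] <- res$resid[1]
    probe <- rbind(probe, gc("CA"),
                   if ("CB" %in% res$atom) gc("CB"))
    is_design <- is_design | sel
  }
  xyz <- coords(structure)
  d2min <- rep(Inf, nrow(structure))
  for (r in seq_len(nrow(probe))) {
    d2 <- (xyz[, 1] - probe[r, 1])^2 + (xyz[, 2] - probe[r, 2])^2 +
      (xyz[, 3] - probe[r, 3])^2
    d2min <- pmin(d2min, d2)
  }
  keep <- (!is_design & d2min <= spec$environment_cutoff^2) |
    (is_design & structure$is_backbone)
  template <- new_structure(structure[keep, , drop = FALSE])
  structure(list(sites = sites, frames = frames, template = template,
                 spec = spec),
            class = "design_region")
}

#' @export
print.design_region <- function(x, ...) {
  cat(sprintf("<design_region> %d sites (%s), template %d atoms, cutoff %.1f A\n",
              nrow(x$sites),
              paste0(x$sites$chain, x$sites$resno, collapse = " "),
              nrow(x$template), x$spec$environment_cutoff))
  invisible(x)
}
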