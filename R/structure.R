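# Structure handling: PDB parsing, distance-geometry SDR derivation,
# ligand binding-pocket extraction, Kabsch superposition, and mapping of
# template positions onto other structures.

#' Parse a PDB file
#'
#' Thin wrapper around `bio3d::read.pdb()`.  Only the first model of
#' multi-model (NMR-style) files is kept; waters (HOH) are excluded from the
#' ligand table; author residue numbering is preserved exactly.
#'
#' @param path path to a PDB-format file.
#' @return object of class `acs_structure` with data frames `atoms` (ATOM
#'   records) and `het` (non-water HETATM records); columns `chain`, `resno`,
#'   `resid`, `elety` (atom name), `elesy` (element), `x`, `y`, `z`.
#' @export
parse_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  cols <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  at$elesy <- .guess_element(at$elesy, at$elety)
  atoms <- at[at$type == "ATOM", cols]
  het <- at[at$type == "HETATM" & at$resid != "HOH", cols]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  rownames(atoms) <- rownames(het) <- NULL
  structure(list(atoms = atoms, het = het, path = path),
            class = "acs_structure")
}

.guess_element <- function(elesy, elety) {
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(miss)) {
    # derive from the atom name: first alphabetic character
    elesy[miss] <- substr(gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]*", "", elety[miss])), 1, 1)
  }
  toupper(trimws(elesy))
}

#' @export
print.acs_structure <- function(x, ...) {
  cat(sprintf("acs_structure: %d atoms, %d residues, ligands: %s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              if (nrow(x$het)) paste(unique(x$het$resid), collapse = ",")
              else "none"))
  invisible(x)
}

.heavy <- function(df) df[df$elesy != "H" & df$elesy != "D", , drop = FALSE]

.ligand_atoms <- function(structure, ligand_name, chain = NULL) {
  lig <- structure$het[structure$het$resid == ligand_name, , drop = FALSE]
  if (!is.null(chain)) lig <- lig[lig$chain == chain, , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand ", ligand_name, " not found in structure")
  .heavy(lig)
}

# residues of `atoms` having >= 1 heavy atom within cutoff of any row of ref
.residues_within <- function(atoms, ref_xyz, cutoff) {
  atoms <- .heavy(atoms)
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- matrix(0, nrow(axyz), nrow(ref_xyz))
  for (k in 1:3) d2 <- d2 + outer(axyz[, k], ref_xyz[, k], "-")^2
  near <- apply(d2 <= cutoff^2, 1, any)
  key <- paste(atoms$chain, atoms$resno)
  sel <- unique(key[near])
  hit <- atoms[!duplicated(key) & key %in% sel, c("chain", "resno", "resid")]
  hit[order(hit$chain, hit$resno), , drop = FALSE]
}

#' Derive specificity-determining residue (SDR) positions
#'
#' Identifies the residues whose side chains line the substrate pocket: all
#' residues with at least one heavy atom within `cutoff` of a single
#' reference atom of the bound substrate (by default the C-beta of the
#' ligand, the convention used with the phenylalanine substrate of the
#' gramicidin synthetase adenylation-domain template).  Positions known to
#' border the pocket at slightly larger distance can be appended through
#' `manual_additions`; their provenance is recorded.
#'
#' @param structure an [acs_structure].
#' @param ligand_name HET code of the substrate (e.g. `"PHE"`).
#' @param reference_atom atom name of the reference atom (default `"CB"`).
#' @param cutoff distance cutoff in Angstrom (default 6).
#' @param manual_additions residue numbers to append with provenance
#'   `"manual"`.
#' @param template_id identifier stored with the set.
#' @return object of class `sdr_set`: `template_id`, `positions` (ordered
#'   residue numbers), `provenance` (`"distance-derived"` or `"manual"`),
#'   `cutoff`.
#' @export
derive_sdr_positions <- function(structure, ligand_name,
                                 reference_atom = "CB", cutoff = 6,
                                 manual_additions = integer(),
                                 template_id = basename(structure$path %||% "template")) {
  lig <- .ligand_atoms(structure, ligand_name)
  ref <- lig[trimws(lig$elety) == reference_atom, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop("reference atom ", reference_atom, " absent from ligand ", ligand_name)
  if (nrow(ref) > 1L)
    stop("reference atom ", reference_atom, " present more than once in ligand ",
         ligand_name)
  hit <- .residues_within(structure$atoms,
                          as.matrix(ref[, c("x", "y", "z")]), cutoff)
  pos <- hit$resno
  prov <- rep("distance-derived", length(pos))
  manual_additions <- setdiff(as.integer(manual_additions), pos)
  pos <- c(pos, manual_additions)
  prov <- c(prov, rep("manual", length(manual_additions)))
  o <- order(pos)
  sdr_set(template_id, pos[o], prov[o], cutoff)
}

#' Construct an SDR position set
#' @param template_id template identifier.
#' @param positions ordered residue numbers (template author numbering).
#' @param provenance per-position provenance.
#' @param cutoff distance cutoff used for the distance-derived positions.
#' @return an `sdr_set`.
#' @export
sdr_set <- function(template_id, positions,
                    provenance = rep("distance-derived", length(positions)),
                    cutoff = 6) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("duplicate SDR positions")
  if (is.unsorted(positions, strictly = TRUE)) stop("SDR positions must be strictly ordered")
  structure(list(template_id = template_id, positions = positions,
                 provenance = provenance, cutoff = cutoff),
            class = "sdr_set")
}

#' @export
print.sdr_set <- function(x, ...) {
  cat(sprintf("sdr_set [%s]: %d positions (cutoff %g A, %d manual)\n  %s\n",
              x$template_id, length(x$positions), x$cutoff,
              sum(x$provenance == "manual"),
              paste(x$positions, collapse = " ")))
  invisible(x)
}

#' Write / read an SDR set as JSON
#' @param x an `sdr_set`.
#' @param path file path.
#' @return `path` (write) or an `sdr_set` (read).
#' @export
write_sdr_set <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sdr_set
#' @export
read_sdr_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sdr_set(j$template_id, j$positions, j$provenance, j$cutoff)
}

#' Extract the binding pocket around a ligand
#'
#' All residues with at least one heavy atom within `cutoff` of any heavy
#' atom of the named ligand.
#'
#' @inheritParams derive_sdr_positions
#' @return object of class `pocket_result`: data frame `residues` (`chain`,
#'   `resno`, `resid`), plus `cutoff` and `reference = "ligand-all-atoms"`.
#' @export
pocket_from_ligand <- function(structure, ligand_name, cutoff = 6) {
  lig <- .ligand_atoms(structure, ligand_name)
  hit <- .residues_within(structure$atoms,
                          as.matrix(lig[, c("x", "y", "z")]), cutoff)
  structure(list(residues = hit, cutoff = cutoff,
                 reference = "ligand-all-atoms"),
            class = "pocket_result")
}

#' Kabsch superposition and RMSD
#'
#' Least-squares optimal rigid superposition of two equal-length coordinate
#' sets (singular value decomposition of the covariance, reflection
#' corrected).
#'
#' @param coords_a,coords_b numeric n x 3 matrices (n >= 3).
#' @return list with `rotation` (3x3, applied to centred `coords_b`),
#'   `translation`, `rmsd` in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate counts differ")
  if (nrow(coords_a) < 3L) stop("need at least 3 points")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Brot <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - Brot)^2)))
  list(rotation = R, translation = ca - as.vector(R %*% cb), rmsd = rmsd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.structure_sequence <- function(structure, chain = NULL) {
  at <- structure$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  ca <- at[trimws(at$elety) == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  aa1 <- bio3d::aa321(ca$resid)
  aa1[is.na(aa1) | aa1 == ""] <- "X"
  list(seq = paste(aa1, collapse = ""), resno = ca$resno, chain = ca$chain,
       xyz = as.matrix(ca[, c("x", "y", "z")]))
}

#' Map template SDR positions onto another structure
#'
#' Aligns the template and target sequences (Needleman-Wunsch), superposes
#' the structures over the aligned C-alpha pairs (Kabsch), then maps each
#' SDR to the nearest target C-alpha within 8 Angstrom of its superposed
#' template C-alpha.  Unmapped SDRs are reported as `NA`.
#'
#' @param template,target [acs_structure] objects.
#' @param sdrs an `sdr_set` in template numbering.
#' @return data frame: `template_resno`, `target_chain`, `target_resno`,
#'   `distance` (Angstrom, `NA` where unmapped); RMSD of the superposition
#'   as attribute `"rmsd"`.
#' @export
map_positions_by_superposition <- function(template, target, sdrs) {
  st <- .structure_sequence(template)
  sq <- .structure_sequence(target)
  al <- needleman_wunsch(st$seq, sq$seq)
  matched <- which(!is.na(al$column_map))
  if (length(matched) < 20L) stop("insufficient structural overlap")
  A <- st$xyz[matched, , drop = FALSE]
  B <- sq$xyz[al$column_map[matched], , drop = FALSE]
  fit <- kabsch_rmsd(A, B)
  # target CAs into template frame
  Ball <- sweep(sq$xyz %*% t(fit$rotation), 2, fit$translation, "+")
  out <- data.frame(template_resno = sdrs$positions,
                    target_chain = NA_character_,
                    target_resno = NA_integer_,
                    distance = NA_real_)
  for (i in seq_along(sdrs$positions)) {
    k <- match(sdrs$positions[i], st$resno)
    if (is.na(k)) next
    d <- sqrt(rowSums(sweep(Ball, 2, st$xyz[k, ])^2))
    j <- which.min(d)
    if (d[j] <= 8) {
      out$target_chain[i] <- sq$chain[j]
      out$target_resno[i] <- sq$resno[j]
      out$distance[i] <- d[j]
    }
  }
  attr(out, "rmsd") <- fit$rmsd
  out
}
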