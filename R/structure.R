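#' Read a protein structure from PDB
#'
#' Wraps [bio3d::read.pdb()] with the conventions the measurement functions
#' assume: only the first MODEL is kept; HETATM records are dropped unless
#' requested; alternate locations are resolved per (chain, residue,
#' insertion, atom name) to the highest-occupancy altloc, ties going to
#' `'A'`.  ATOM/HETATM records are pre-checked line by line so a malformed
#' coordinate field is reported with its line number.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep HETATM records (default `FALSE`).
#' @return A `bio3d` `pdb` object.
#' @export
read_pdb <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop_kin("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  for (k in seq_along(lines)) {
    l <- lines[k]
    if (startsWith(l, "ATOM") || startsWith(l, "HETATM")) {
      if (nchar(l) < 54) stop_kin("unparseable ATOM record at line %d (too short)", k)
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                           substr(l, 47, 54))))
      if (anyNA(xyz)) stop_kin("unparseable coordinates at line %d", k)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom
  if (!keep_hetatm) atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atom)) stop_kin("no ATOM records in %s", path)
  # altloc resolution: highest occupancy, tie -> 'A' (blank altloc sorts first)
  alt <- ifelse(is.na(atom$alt) | atom$alt == "", "", atom$alt)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno,
               ifelse(is.na(atom$insert), "", atom$insert), atom$elety, sep = "|")
  ord <- order(key, -occ, alt, method = "radix")
  keep_idx <- ord[!duplicated(key[ord])]
  atom <- atom[sort(keep_idx), , drop = FALSE]
  as_pdb_object(atom)
}

# assemble a bio3d-style pdb object from an atom table
as_pdb_object <- function(atom) {
  rownames(atom) <- NULL
  xyz <- as.numeric(t(as.matrix(atom[, c("x", "y", "z")])))
  pdb <- list(atom = atom, xyz = bio3d::as.xyz(matrix(xyz, nrow = 1)),
              calpha = atom$elety == "CA")
  class(pdb) <- c("pdb", "sse")
  pdb
}

#' Write a structure to PDB
#'
#' @param pdb A `pdb` object.
#' @param path Output path.
#' @export
write_pdb <- function(pdb, path) {
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

#' One-letter sequence of a chain
#'
#' Reads the residue sequence off the Cα atoms of one chain.
#'
#' @param pdb A `pdb` object.
#' @param chain Chain id; default the first chain present.
#' @return A [seq_record] named `<chain>` with the chain sequence.
#' @export
chain_sequence <- function(pdb, chain = NULL) {
  atom <- pdb$atom
  if (is.null(chain)) chain <- atom$chain[1]
  ca <- atom[atom$chain == chain & atom$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop_kin("chain '%s' has no CA atoms", chain)
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | aa == ""] <- "X"
  seq_record(chain, paste0(aa, collapse = ""))
}

#' Pair residues of two structures through an alignment
#'
#' Given a pairwise alignment of the two chain sequences, returns the
#' residue pairs at co-aligned non-gap columns where both residues carry a
#' Cα atom — the pairing that feeds [kabsch_superpose()].  If more than
#' `max_mismatch` of the aligned positions disagree between the structure
#' sequence and the alignment row, the structures and alignment are deemed
#' inconsistent and an error is raised.
#'
#' @param structA,structB `pdb` objects.
#' @param alignment `pairwise_alignment` whose rows, once degapped, are the
#'   chain sequences of `structA` and `structB`.
#' @param chainA,chainB Chain ids (default: first chain of each).
#' @param max_mismatch Tolerated fraction of residue-letter disagreements
#'   (default 0.05).
#' @return data.frame with `resnoA`, `resnoB` (author numbering) and the
#'   residue letters.
#' @export
pair_residues <- function(structA, structB, alignment,
                          chainA = NULL, chainB = NULL, max_mismatch = 0.05) {
  caA <- ca_table(structA, chainA)
  caB <- ca_table(structB, chainB)
  chA <- str_chars(alignment$a$residues)
  chB <- str_chars(alignment$b$residues)
  ia <- cumsum(chA != GAP)
  ib <- cumsum(chB != GAP)
  both <- which(chA != GAP & chB != GAP)
  both <- both[ia[both] <= nrow(caA) & ib[both] <= nrow(caB)]
  if (!length(both)) stop_kin("no co-aligned residues with CA atoms")
  mmA <- mean(chA[both] != caA$aa[ia[both]])
  mmB <- mean(chB[both] != caB$aa[ib[both]])
  if (mmA > max_mismatch || mmB > max_mismatch) {
    stop_kin("structure/alignment sequence mismatch (%.1f%% / %.1f%%) exceeds %.1f%%",
             100 * mmA, 100 * mmB, 100 * max_mismatch)
  }
  data.frame(resnoA = caA$resno[ia[both]], resnoB = caB$resno[ib[both]],
             aaA = caA$aa[ia[both]], aaB = caB$aa[ib[both]],
             stringsAsFactors = FALSE)
}

ca_table <- function(pdb, chain = NULL) {
  atom <- pdb$atom
  if (is.null(chain)) chain <- atom$chain[1]
  ca <- atom[atom$chain == chain & atom$elety == "CA", , drop = FALSE]
  data.frame(resno = ca$resno, aa = {
    aa <- bio3d::aa321(ca$resid); aa[is.na(aa) | aa == ""] <- "X"; aa
  }, x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
}

ca_coords <- function(pdb, resno, chain = NULL) {
  tab <- ca_table(pdb, chain)
  idx <- match(resno, tab$resno)
  if (anyNA(idx)) stop_kin("residue %d has no CA atom", resno[which(is.na(idx))[1]])
  as.matrix(tab[idx, c("x", "y", "z")])
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body fit of paired coordinate sets by SVD with reflection
#' correction: finds the proper rotation `R` and translation `t` minimizing
#' the RMSD of `R %*% a + t` against `b` over all pairs, and reports that
#' minimal RMSD.
#'
#' @param coordsA,coordsB Numeric n-by-3 matrices of paired points (n >= 3,
#'   not all collinear).
#' @return A `superposition`: `rotation` (3x3, det +1), `translation`
#'   (length 3), `rmsd`, `n_pairs`.
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (ncol(A) != 3L || ncol(B) != 3L || nrow(A) != nrow(B)) {
    stop_kin("inputs must be paired n-by-3 coordinate matrices")
  }
  n <- nrow(A)
  if (n < 3L) stop_kin("need at least 3 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Ac, Bc)) # H = t(Ac) Bc; R = V U^T maps A onto B
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) stop_kin("degenerate (collinear) coordinates")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cb - R %*% ca)
  fitted <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Superpose two structures on alignment-paired Cα atoms
#'
#' Convenience composition of [pair_residues()] and [kabsch_superpose()].
#'
#' @inheritParams pair_residues
#' @return A `superposition`.
#' @export
superpose_structures <- function(structA, structB, alignment,
                                 chainA = NULL, chainB = NULL) {
  pairs <- pair_residues(structA, structB, alignment, chainA, chainB)
  kabsch_superpose(ca_coords(structA, pairs$resnoA, chainA),
                   ca_coords(structB, pairs$resnoB, chainB))
}

parse_selector <- function(sel) {
  if (is.character(sel) && length(sel) == 1L) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) return(list(chain = parts[1], resno = as.integer(parts[2])))
    return(list(chain = NA_character_, resno = as.integer(parts[1])))
  }
  list(chain = sel$chain %||% NA_character_, resno = as.integer(sel$resno))
}

residue_atoms <- function(pdb, sel) {
  atom <- pdb$atom
  ok <- atom$resno == sel$resno
  if (!is.na(sel$chain)) ok <- ok & atom$chain == sel$chain
  res <- atom[ok, , drop = FALSE]
  if (!nrow(res)) stop_kin("selector %s:%d matches no residue",
                           if (is.na(sel$chain)) "*" else sel$chain, sel$resno)
  res
}

BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Distance between two residues
#'
#' The catalytic-pocket "access" measurement: the minimum distance between
#' two residues, by default over heavy side-chain atoms (backbone N, CA, C,
#' O excluded; glycine falls back to its Cα).  Alternative modes measure
#' over all heavy atoms, or between one named atom of each residue.  The
#' achieving atom pair is always reported so the measurement is auditable.
#'
#' @param struct A `pdb` object.
#' @param selA,selB Residue selectors: `"A:309"` strings or
#'   `list(chain=, resno=)`.
#' @param mode `"min-side-chain-heavy"` (default), `"min-heavy"`, or
#'   `"atom-pair"`.
#' @param atomA,atomB Atom names for `mode = "atom-pair"`.
#' @return A `gate_measurement`: selectors, achieving atoms, `distance` (Å),
#'   and the mode used.
#' @export
residue_distance <- function(struct, selA, selB,
                             mode = c("min-side-chain-heavy", "min-heavy", "atom-pair"),
                             atomA = NULL, atomB = NULL) {
  mode <- match.arg(mode)
  sa <- parse_selector(selA); sb <- parse_selector(selB)
  ra <- residue_atoms(struct, sa); rb <- residue_atoms(struct, sb)
  pick <- function(res, atom_name) {
    heavy <- res[is.na(res$elesy) | res$elesy != "H", , drop = FALSE]
    heavy <- heavy[!grepl("^H", heavy$elety), , drop = FALSE]
    if (mode == "atom-pair") {
      sub <- res[res$elety == atom_name, , drop = FALSE]
      if (!nrow(sub)) stop_kin("residue %d has no atom '%s'", res$resno[1], atom_name)
      return(sub)
    }
    if (mode == "min-heavy") return(heavy)
    sc <- heavy[!heavy$elety %in% BACKBONE, , drop = FALSE]
    if (!nrow(sc)) {
      if (res$resid[1] == "GLY") return(heavy[heavy$elety == "CA", , drop = FALSE])
      stop_kin("residue %d (%s) has no side-chain atoms", res$resno[1], res$resid[1])
    }
    sc
  }
  aa <- pick(ra, atomA); bb <- pick(rb, atomB)
  A <- as.matrix(aa[, c("x", "y", "z")]); B <- as.matrix(bb[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  best <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  structure(list(selA = sa, selB = sb,
                 atomA = aa$elety[best[1]], atomB = bb$elety[best[2]],
                 distance = sqrt(d2[best[1], best[2]]), mode = mode),
            class = "gate_measurement")
}

#' @export
print.gate_measurement <- function(x, ...) {
  cat(sprintf("<gate_measurement> %s:%d %s -- %s:%d %s  %.2f A (%s)\n",
              x$selA$chain, x$selA$resno, x$atomA,
              x$selB$chain, x$selB$resno, x$atomB, x$distance, x$mode))
  invisible(x)
}

#' Pocket-access table over several structures
#'
#' One [residue_distance()] row per labelled structure, using that
#' structure's own gate residue numbers — the tabular form of comparing
#' pocket access across a reference structure and homology models.
#'
#' @param structures Named list of `pdb` objects.
#' @param gates List (recycled if length 1) of two-element selector vectors,
#'   e.g. `c("A:309", "A:518")`, one per structure.
#' @param mode Passed to [residue_distance()].
#' @return data.frame with `label`, selectors, achieving atoms,
#'   `distance_angstrom`, `mode`.
#' @export
gate_access_report <- function(structures, gates,
                               mode = "min-side-chain-heavy") {
  if (!length(structures)) {
    return(data.frame(label = character(0), gateA = character(0),
                      gateB = character(0), atomA = character(0),
                      atomB = character(0), distance_angstrom = numeric(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  if (!is.list(gates[[1]]) && !is.list(gates)) gates <- list(gates)
  if (length(gates) == 1L) gates <- rep(gates, length(structures))
  fmt_sel <- function(s) sprintf("%s:%d", if (is.na(s$chain)) "*" else s$chain, s$resno)
  rows <- Map(function(label, pdb, gate) {
    m <- residue_distance(pdb, gate[[1]], gate[[2]], mode = mode)
    data.frame(label = label,
               gateA = fmt_sel(m$selA),
               gateB = fmt_sel(m$selB),
               atomA = m$atomA, atomB = m$atomB,
               distance_angstrom = m$distance, mode = m$mode,
               stringsAsFactors = FALSE)
  }, names(structures), structures, gates)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
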