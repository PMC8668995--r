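#' Specify a synthetic sequence family
#'
#' Describes how to evolve a family of kinase-domain-like sequences down a
#' tree from a reference, with known ground truth: i.i.d. per-site
#' substitutions (uniform over the 19 alternatives), optional indels, and
#' planted substitutions at chosen reference positions on the terminal
#' branch of chosen taxa.  Indels never touch a protected window (±2
#' residues around protected positions — by default the planted sites), so
#' the homology of every tested site stays unambiguous.
#'
#' @param reference A [seq_record]; the root sequence.
#' @param n_taxa Number of tips when `tree` is `NULL` (a random
#'   [ape::rtree()] topology is drawn from the seed).
#' @param tree Optional `phylo` generating tree; tip labels become ids.
#' @param subst_prob Per-site substitution probability per branch, in
#'   `[0, 1]`.
#' @param planted data.frame with columns `taxon`, `ref_pos`, `new_residue`
#'   (each must differ from the reference residue there), or `NULL`.
#' @param indel_rate Expected indel events per branch (Poisson).
#' @param indel_len_mean Mean indel length (>= 1).
#' @param protected Integer reference positions whose ±2 neighbourhood
#'   indels must avoid; planted positions are always added.
#' @param seed Mandatory integer seed; identical seeds give identical
#'   families.
#' @return A `family_spec`.
#' @export
family_spec <- function(reference, n_taxa = 8, tree = NULL, subst_prob = 0.05,
                        planted = NULL, indel_rate = 0, indel_len_mean = 3,
                        protected = integer(0), seed) {
  if (missing(seed)) stop_kin("'seed' is mandatory for simulation")
  stopifnot(is_seq_record(reference))
  L <- nchar(reference$residues)
  if (subst_prob < 0 || subst_prob > 1) stop_kin("'subst_prob' must be in [0, 1]")
  if (indel_len_mean < 1) stop_kin("'indel_len_mean' must be >= 1")
  refch <- str_chars(reference$residues)
  if (!is.null(planted)) {
    stopifnot(all(c("taxon", "ref_pos", "new_residue") %in% names(planted)))
    if (any(planted$ref_pos < 1 | planted$ref_pos > L)) {
      stop_kin("planted position outside reference length %d", L)
    }
    same <- planted$new_residue == refch[planted$ref_pos]
    if (any(same)) {
      stop_kin("planted residue at position %d equals the reference residue (not an event)",
               planted$ref_pos[which(same)[1]])
    }
    protected <- union(protected, planted$ref_pos)
  }
  structure(list(reference = reference, n_taxa = n_taxa, tree = tree,
                 subst_prob = subst_prob, planted = planted,
                 indel_rate = indel_rate, indel_len_mean = indel_len_mean,
                 protected = as.integer(protected), seed = seed),
            class = "family_spec")
}

#' Simulate a sequence family with known truth
#'
#' Evolves the reference down the generating tree: on every branch each site
#' substitutes independently with the spec's probability (uniform over the
#' 19 alternative residues), and indel events (Poisson per branch,
#' insertion/deletion with equal probability, length 1 + Poisson) are placed
#' outside the protected windows.  Planted events are applied on the
#' terminal branch of their taxon and are guaranteed present in the output.
#'
#' @param spec A [family_spec()].
#' @return List with `records` (one [seq_record] per tip, in tip-label
#'   order) and `truth`: the generating `tree`, `homology` (per taxon, an
#'   integer vector mapping each of its positions to a reference position,
#'   `NA` for inserted residues), and `planted` as realized.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    tree <- spec$tree
    if (is.null(tree)) {
      tree <- ape::rtree(spec$n_taxa, tip.label = sprintf("t%02d", seq_len(spec$n_taxa)))
    }
    refch <- str_chars(spec$reference$residues)
    root_state <- data.frame(refpos = seq_along(refch), residue = refch,
                             stringsAsFactors = FALSE)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    states <- list()
    states[[root]] <- root_state
    tips <- list()

    prot <- spec$protected
    in_protected <- function(refpos) {
      if (!length(prot)) return(rep(FALSE, length(refpos)))
      !is.na(refpos) & vapply(refpos, function(p) any(abs(p - prot) <= 2L), logical(1))
    }

    evolve_branch <- function(st) {
      n <- nrow(st)
      mut <- stats::runif(n) < spec$subst_prob
      if (any(mut)) {
        st$residue[mut] <- vapply(st$residue[mut], function(a) {
          sample(setdiff(AA20, a), 1L)
        }, character(1))
      }
      if (spec$indel_rate > 0) {
        for (ev in seq_len(stats::rpois(1L, spec$indel_rate))) {
          len <- 1L + stats::rpois(1L, spec$indel_len_mean - 1)
          if (stats::runif(1) < 0.5) { # deletion
            ok_start <- which(!vapply(seq_len(nrow(st)), function(i) {
              idx <- i:min(i + len - 1L, nrow(st))
              any(in_protected(st$refpos[idx]))
            }, logical(1)))
            ok_start <- ok_start[ok_start + len - 1L <= nrow(st)]
            ok_start <- ok_start[ok_start > 1L] # keep a first residue
            if (length(ok_start)) {
              i <- ok_start[sample.int(length(ok_start), 1L)]
              st <- st[-(i:(i + len - 1L)), , drop = FALSE]
            }
          } else { # insertion after position i
            ok_after <- which(!in_protected(st$refpos))
            if (length(ok_after)) {
              i <- ok_after[sample.int(length(ok_after), 1L)]
              ins <- data.frame(refpos = NA_integer_,
                                residue = sample(AA20, len, replace = TRUE),
                                stringsAsFactors = FALSE)
              st <- rbind(st[seq_len(i), , drop = FALSE], ins,
                          st[seq_len(nrow(st)) > i, , drop = FALSE])
            }
          }
        }
      }
      st
    }

    # cladewise edge order is a preorder: parents are visited before children
    tree <- stats::reorder(tree, "cladewise")
    for (k in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      st <- evolve_branch(states[[parent]])
      if (child <= ntip) {
        lab <- tree$tip.label[child]
        if (!is.null(spec$planted)) {
          pl <- spec$planted[spec$planted$taxon == lab, , drop = FALSE]
          for (q in seq_len(nrow(pl))) {
            row <- which(st$refpos == pl$ref_pos[q])
            if (!length(row)) stop_kin("internal: planted site %d lost despite protection",
                                       pl$ref_pos[q])
            st$residue[row] <- pl$new_residue[q]
          }
        }
        tips[[lab]] <- st
      } else {
        states[[child]] <- st
      }
    }

    records <- lapply(tree$tip.label, function(lab) {
      seq_record(lab, paste0(tips[[lab]]$residue, collapse = ""),
                 species = "synthetic taxon")
    })
    homology <- lapply(tips, function(st) st$refpos)
    list(records = records,
         truth = list(tree = tree, homology = homology[tree$tip.label],
                      planted = spec$planted))
  })
}

rotation_from_spec <- function(rotation) {
  if (identical(rotation, "random")) {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    return(R)
  }
  axis <- as.numeric(rotation$axis)
  if (length(axis) != 3L || sqrt(sum(axis^2)) < 1e-12) {
    stop_kin("degenerate rotation axis")
  }
  k <- axis / sqrt(sum(axis^2))
  th <- rotation$angle_deg * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (k %o% k)
}

# assemble a bio3d-style pdb from minimal atom fields
make_pdb <- function(elety, resid, chain, resno, coords, elesy = NULL) {
  n <- length(elety)
  atom <- data.frame(
    type = rep("ATOM", n), eleno = seq_len(n), elety = elety, alt = rep("", n),
    resid = resid, chain = chain, resno = resno, insert = rep("", n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = rep(1, n), b = rep(0, n), segid = rep("", n),
    elesy = elesy %||% substr(elety, 1, 1), charge = rep("", n),
    stringsAsFactors = FALSE)
  as_pdb_object(atom)
}

#' Simulate a rigid-body structure pair
#'
#' Builds a smooth helix-like synthetic backbone (Cα plus a Cβ per residue,
#' alanine chain A) and a copy transformed by a known rotation and
#' translation plus optional isotropic Gaussian coordinate noise — the test
#' surface for [kabsch_superpose()].
#'
#' @param n_residues Number of residues (>= 3).
#' @param rotation `"random"`, or `list(axis = c(x, y, z), angle_deg = a)`.
#' @param translation Length-3 translation (Å).
#' @param noise_sd Gaussian noise s.d. per coordinate (Å), >= 0.
#' @param seed Integer seed.
#' @return List `A`, `B` (pdb objects) and `truth` (`rotation`,
#'   `translation`).
#' @export
simulate_structure_pair <- function(n_residues, rotation = "random",
                                    translation = c(5, -3, 2), noise_sd = 0,
                                    seed) {
  if (missing(seed)) stop_kin("'seed' is mandatory for simulation")
  if (n_residues < 3L) stop_kin("need at least 3 residues")
  if (noise_sd < 0) stop_kin("'noise_sd' must be >= 0")
  with_seed(seed, {
    R <- rotation_from_spec(rotation)
    i <- seq_len(n_residues)
    th <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    cb <- cbind(3.4 * cos(th), 3.4 * sin(th), 1.5 * i + 0.5)
    coords <- matrix(0, 2 * n_residues, 3)
    coords[seq(1, 2 * n_residues, 2), ] <- ca
    coords[seq(2, 2 * n_residues, 2), ] <- cb
    elety <- rep(c("CA", "CB"), n_residues)
    resno <- rep(i, each = 2)
    A <- make_pdb(elety, rep("ALA", 2 * n_residues), rep("A", 2 * n_residues),
                  resno, coords, elesy = rep("C", 2 * n_residues))
    coordsB <- coords %*% t(R) + matrix(translation, 2 * n_residues, 3, byrow = TRUE)
    if (noise_sd > 0) coordsB <- coordsB + matrix(stats::rnorm(length(coordsB), sd = noise_sd),
                                                  nrow(coordsB), 3)
    B <- make_pdb(elety, rep("ALA", 2 * n_residues), rep("A", 2 * n_residues),
                  resno, coordsB, elesy = rep("C", 2 * n_residues))
    list(A = A, B = B, truth = list(rotation = R, translation = translation))
  })
}

#' Simulate a gate-residue structure with a planted access distance
#'
#' Builds a synthetic structure containing a glutamate (numbered 309) and an
#' arginine (numbered 518) on chain A whose minimum side-chain heavy-atom
#' distance equals `target_distance` exactly (to floating precision): the
#' closest pair is OE2–NH1 and every other atom lies strictly farther away,
#' so it also validates that the measurement reports the right atom pair.
#' The whole structure is placed at a random (seeded) rigid orientation.
#'
#' @param target_distance Planted access distance in Å (> 0).
#' @param seed Integer seed (orientation only).
#' @return A `pdb` object.
#' @export
simulate_gate <- function(target_distance, seed = 1) {
  if (target_distance <= 0) stop_kin("'target_distance' must be > 0")
  d <- target_distance
  glu <- rbind(
    OE2 = c(0, 0, 0),
    OE1 = c(-1.4, 1.0, 0),
    CD = c(-1.0, -0.8, 0.2),
    CG = c(-2.4, -1.2, 0.4),
    CB = c(-3.3, -0.1, 0.9),
    CA = c(-4.6, 0.3, 1.4),
    N = c(-5.2, 1.5, 1.1),
    C = c(-5.5, -0.8, 1.9),
    O = c(-6.7, -0.7, 1.8))
  arg <- rbind(
    NH1 = c(d, 0, 0),
    NH2 = c(d + 1.2, 1.0, 0.1),
    CZ = c(d + 1.0, -0.6, 0),
    NE = c(d + 2.2, -1.0, 0.5),
    CD = c(d + 3.2, -0.2, 1.0),
    CG = c(d + 4.5, -0.7, 1.2),
    CB = c(d + 5.4, 0.2, 1.6),
    CA = c(d + 6.7, 0.0, 2.0),
    N = c(d + 7.3, 1.2, 1.7),
    C = c(d + 7.6, -1.1, 2.5),
    O = c(d + 8.8, -1.0, 2.4))
  coords <- rbind(glu, arg)
  with_seed(seed, {
    R <- rotation_from_spec("random")
    t <- stats::rnorm(3, sd = 5)
    coords <- coords %*% t(R) + matrix(t, nrow(coords), 3, byrow = TRUE)
  })
  elety <- c(rownames(glu), rownames(arg))
  make_pdb(elety,
           c(rep("GLU", nrow(glu)), rep("ARG", nrow(arg))),
           rep("A", nrow(coords)),
           c(rep(309L, nrow(glu)), rep(518L, nrow(arg))),
           coords,
           elesy = substr(elety, 1, 1))
}
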