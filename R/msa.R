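#' Multiple alignment container
#'
#' An `msa` holds equal-length gapped [seq_record]s plus bookkeeping for
#' residues trimmed off the ends (so reference numbering survives
#' [trim_ends()] and [extract_segment()]): `trim$lead[id]` / `trim$trail[id]`
#' count the residues of each row removed before the first and after the
#' last retained column.
#'
#' @param records List of gapped [seq_record]s of equal length.
#' @return An object of class `msa`.
#' @keywords internal
new_msa <- function(records, trim = NULL) {
  check_unique_ids(records)
  lens <- vapply(records, function(r) nchar(r$residues), integer(1))
  if (length(unique(lens)) > 1L) stop_kin("alignment rows have unequal lengths")
  ids <- record_ids(records)
  zero <- stats::setNames(integer(length(ids)), ids)
  if (is.null(trim)) trim <- list(lead = zero, trail = zero)
  structure(list(records = records, n_columns = lens[1], trim = trim),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$records), x$n_columns))
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, lapply(msa$records, function(r) str_chars(r$residues)))
}

msa_row <- function(msa, id) {
  i <- match(id, record_ids(msa$records))
  if (is.na(i)) stop_kin("sequence '%s' not present in alignment", id)
  msa$records[[i]]
}

#' Convert a pairwise alignment to a two-row msa
#'
#' @param aln A `pairwise_alignment` from [global_align()].
#' @return An [new_msa()] object with two rows.
#' @export
as_msa <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  new_msa(list(aln$a, aln$b))
}

#' Pairwise p-distance matrix
#'
#' Symmetric matrix of [p_distance()] values over all sequence pairs, used
#' both as the progressive-alignment guide distances and as input to
#' [neighbor_joining()].
#'
#' @param records List of [seq_record]s (>= 2, unique ids).
#' @param scheme A [scoring_scheme].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(records, scheme = default_scheme()) {
  if (length(records) < 2L) stop_kin("need at least 2 sequences")
  ids <- check_unique_ids(records)
  n <- length(records)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- p_distance(records[[i]], records[[j]], scheme)
    }
  }
  D
}

# profile of an alignment block: 22 x L frequency matrix (20 aa + X + gap);
# the gap row carries zero substitution score so gap-rich columns score low
profile_of <- function(rows) {
  L <- nchar(rows[[1]])
  P <- matrix(0, 22, L, dimnames = list(c(AAX, GAP), NULL))
  for (s in rows) {
    ch <- str_chars(s)
    idx <- match(ch, c(AAX, GAP))
    P[cbind(idx, seq_len(L))] <- P[cbind(idx, seq_len(L))] + 1
  }
  P / length(rows)
}

#' Progressive multiple sequence alignment
#'
#' Clustal-style progressive alignment: p-distances from pairwise global
#' alignments, a neighbor-joining guide tree (midpoint rooted), and
#' profile–profile merging in post-order with the same affine gap model as
#' [global_align()].  Profile columns are scored by the average substitution
#' score over their residue frequencies.  Children of each guide-tree node
#' are merged in deterministic order (smallest member id first), and rows
#' are never edited: degapping any output row reproduces its input sequence.
#'
#' @param records List of >= 2 [seq_record]s with unique ids.
#' @param scheme A [scoring_scheme].
#' @return An [new_msa()] object; rows keep the input order.
#' @export
progressive_align <- function(records, scheme = default_scheme()) {
  if (length(records) < 2L) stop_kin("need at least 2 sequences")
  ids <- check_unique_ids(records)
  if (length(records) == 2L) {
    return(as_msa(global_align(records[[1]], records[[2]], scheme)))
  }
  D <- distance_matrix(records, scheme)
  # an all-zero guide tree (identical inputs) has no midpoint; any rooting
  # of it yields the same merge order, so the warning is irrelevant here
  guide <- suppressWarnings(midpoint_root(neighbor_joining(D)))

  S22 <- rbind(cbind(scheme$matrix, 0), 0)
  dimnames(S22) <- list(c(AAX, GAP), c(AAX, GAP))

  # groups: named list id -> gapped string, merged bottom-up over the tree
  align_node <- function(node) {
    nt <- length(guide$tip.label)
    if (node <= nt) {
      g <- list()
      g[[guide$tip.label[node]]] <- records[[match(guide$tip.label[node], ids)]]$residues
      return(g)
    }
    children <- guide$edge[guide$edge[, 1] == node, 2]
    groups <- lapply(children, align_node)
    groups <- groups[order(vapply(groups, function(g) min(names(g)), character(1)))]
    merged <- groups[[1]]
    for (k in seq_along(groups)[-1]) merged <- merge_profiles(merged, groups[[k]], S22, scheme)
    merged
  }

  root <- length(guide$tip.label) + 1L
  merged <- align_node(root)
  out <- lapply(records, function(r) {
    seq_record(r$id, merged[[r$id]], r$species, r$accession, r$description,
               gapped = TRUE)
  })
  new_msa(out)
}

merge_profiles <- function(ga, gb, S22, scheme) {
  Fa <- profile_of(ga)
  Fb <- profile_of(gb)
  C <- t(Fa) %*% S22 %*% Fb
  res <- nw_affine_mat_cpp(C, scheme$gap_open, scheme$gap_extend)
  expand <- function(s, idx) {
    ch <- str_chars(s)
    paste0(ifelse(idx == 0L, GAP, ch[pmax(idx, 1L)]), collapse = "")
  }
  c(lapply(ga, expand, idx = res$ai), lapply(gb, expand, idx = res$bi))
}

#' Trim low-occupancy alignment ends
#'
#' Removes the maximal prefix and suffix runs of columns whose non-gap
#' fraction falls below `min_occupancy` — the usual cleanup when some family
#' members are incomplete at the termini.  Interior columns are never
#' touched and the operation is idempotent.  Trimmed-off residue counts are
#' recorded per row so reference numbering built later still refers to the
#' full-length sequences.
#'
#' @param msa An [new_msa()] object.
#' @param min_occupancy Fraction in (0, 1]; default 0.5.
#' @return A trimmed `msa`.
#' @export
trim_ends <- function(msa, min_occupancy = 0.5) {
  if (min_occupancy <= 0 || min_occupancy > 1) {
    stop_kin("'min_occupancy' must be in (0, 1]")
  }
  M <- msa_matrix(msa)
  occ <- colMeans(M != GAP)
  keep <- occ >= min_occupancy
  first <- which(keep)[1]
  if (is.na(first)) stop_kin("trimming at occupancy %.2f would remove every column",
                             min_occupancy)
  last <- max(which(keep))
  if (first == 1L && last == msa$n_columns) return(msa)
  ids <- record_ids(msa$records)
  lead <- msa$trim$lead
  trail <- msa$trim$trail
  recs <- vector("list", length(msa$records))
  for (i in seq_along(msa$records)) {
    ch <- M[i, ]
    lead[ids[i]] <- lead[ids[i]] + sum(ch[seq_len(first - 1L)] != GAP)
    trail[ids[i]] <- trail[ids[i]] +
      if (last < length(ch)) sum(ch[(last + 1L):length(ch)] != GAP) else 0L
    r <- msa$records[[i]]
    recs[[i]] <- seq_record(r$id, paste0(ch[first:last], collapse = ""),
                            r$species, r$accession, r$description, gapped = TRUE)
  }
  new_msa(recs, trim = list(lead = lead, trail = trail))
}
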