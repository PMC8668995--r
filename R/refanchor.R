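#' Map alignment columns to reference residue numbering
#'
#' Builds the column/position correspondence that lets every sequence in an
#' alignment be read in the coordinates of one full-length reference (for
#' the built-in catalog, human WEE1A: positions such as E309, N376, D426,
#' R518).  Numbering is 1-based over the complete reference sequence; if the
#' alignment was trimmed with [trim_ends()], the removed reference residues
#' keep their numbers and map to no column.
#'
#' @param msa An [new_msa()] object, or a `pairwise_alignment` (the pairwise
#'   mode used to transfer reference numbering onto a single homolog).
#' @param ref_id Id of the reference row.
#' @return A `column_map`: `ref_id`, `col_to_refpos` (integer per column,
#'   `NA` where the reference is gapped), `refpos_to_col` (integer per
#'   reference position over its full length, `NA` for positions outside the
#'   alignment), and `ref_length`.
#' @export
build_column_map <- function(msa, ref_id) {
  if (inherits(msa, "pairwise_alignment")) msa <- as_msa(msa)
  ref <- msa_row(msa, ref_id) # errors if absent
  ch <- str_chars(ref$residues)
  lead <- msa$trim$lead[[ref_id]]
  trail <- msa$trim$trail[[ref_id]]
  nongap <- ch != GAP
  col_to_refpos <- rep(NA_integer_, length(ch))
  col_to_refpos[nongap] <- lead + seq_len(sum(nongap))
  ref_length <- lead + sum(nongap) + trail
  refpos_to_col <- rep(NA_integer_, ref_length)
  refpos_to_col[col_to_refpos[nongap]] <- which(nongap)
  structure(list(ref_id = ref_id, col_to_refpos = col_to_refpos,
                 refpos_to_col = refpos_to_col, ref_length = ref_length),
            class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat(sprintf("<column_map> reference %s, %d columns, reference length %d\n",
              x$ref_id, length(x$col_to_refpos), x$ref_length))
  invisible(x)
}

#' Residue of any sequence at a reference position
#'
#' Looks up the alignment column carrying reference position `ref_pos` and
#' reports the `seq_id` row's symbol there, together with that sequence's
#' own 1-based position when it is not a gap.  This is how statements like
#' "human E309 corresponds to H259 in *A. thaliana*" are computed.
#'
#' @param msa Alignment (or `pairwise_alignment`).
#' @param cmap [build_column_map()] result for the same alignment.
#' @param seq_id Row to query.
#' @param ref_pos 1-based reference position (full-length numbering).
#' @return A `residue_obs` list: `residue` (letter or `"-"`), `seq_pos`
#'   (`NA` when gapped), and `status` — `"ok"`, `"gap"`, or `"outside"` when
#'   the position was trimmed out of the alignment.
#' @export
residue_at <- function(msa, cmap, seq_id, ref_pos) {
  if (inherits(msa, "pairwise_alignment")) msa <- as_msa(msa)
  if (ref_pos < 1 || ref_pos > cmap$ref_length) {
    stop_kin("ref_pos %d outside reference length %d", ref_pos, cmap$ref_length)
  }
  col <- cmap$refpos_to_col[ref_pos]
  if (is.na(col)) {
    return(structure(list(residue = NA_character_, seq_pos = NA_integer_,
                          ref_pos = ref_pos, seq_id = seq_id, status = "outside"),
                     class = "residue_obs"))
  }
  row <- msa_row(msa, seq_id)
  ch <- str_chars(row$residues)
  sym <- ch[col]
  if (sym == GAP) {
    structure(list(residue = GAP, seq_pos = NA_integer_, ref_pos = ref_pos,
                   seq_id = seq_id, status = "gap"), class = "residue_obs")
  } else {
    pos <- msa$trim$lead[[seq_id]] + sum(ch[seq_len(col)] != GAP)
    structure(list(residue = sym, seq_pos = pos, ref_pos = ref_pos,
                   seq_id = seq_id, status = "ok"), class = "residue_obs")
  }
}

#' @export
print.residue_obs <- function(x, ...) {
  cat(sprintf("<residue_obs> %s @ ref %d: %s%s (%s)\n", x$seq_id, x$ref_pos,
              x$residue %||% "?",
              if (!is.na(x$seq_pos)) paste0(" (own position ", x$seq_pos, ")") else "",
              x$status))
  invisible(x)
}

#' Extract the sub-alignment spanning a reference segment
#'
#' Returns the columns from reference position `ref_start` through `ref_end`
#' inclusive; columns where the reference is gapped inside the span are
#' retained.  Trim bookkeeping is updated so a column map rebuilt on the
#' segment still reports full-length reference numbering.
#'
#' @param msa Alignment.
#' @param cmap Its [build_column_map()].
#' @param ref_start,ref_end Reference positions, `1 <= ref_start <= ref_end`.
#' @return An `msa` restricted to the segment.
#' @export
extract_segment <- function(msa, cmap, ref_start, ref_end) {
  if (ref_start < 1 || ref_end > cmap$ref_length || ref_start > ref_end) {
    stop_kin("segment %d..%d out of range (reference length %d)",
             ref_start, ref_end, cmap$ref_length)
  }
  cols <- cmap$refpos_to_col[ref_start:ref_end]
  if (all(is.na(cols))) stop_kin("segment %d..%d lies entirely outside the alignment",
                                 ref_start, ref_end)
  first <- min(cols, na.rm = TRUE)
  last <- max(cols, na.rm = TRUE)
  if (first == 1L && last == msa$n_columns) return(msa)
  M <- msa_matrix(msa)
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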