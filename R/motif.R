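#' Physicochemical class of a residue
#'
#' The eight-way classification used to color conservation tables:
#' hydrophobic (A, I, L, M, F, V, W), acidic (D, E), basic (R, K), polar
#' (Q, S, N, T), aromatic (Y, H), and the three singletons cysteine,
#' proline, glycine.  `X` is `"unknown"`.  Histidine sits with the
#' aromatics, not the basics, in this scheme.
#'
#' @param aa Single residue letter (vectorized).
#' @return Character class name(s).
#' @examples
#' classify_residue("E") # acidic
#' @export
classify_residue <- function(aa) {
  classes <- c(A = "hydrophobic", I = "hydrophobic", L = "hydrophobic",
               M = "hydrophobic", F = "hydrophobic", V = "hydrophobic",
               W = "hydrophobic", D = "acidic", E = "acidic",
               R = "basic", K = "basic",
               Q = "polar", S = "polar", N = "polar", T = "polar",
               Y = "aromatic", H = "aromatic",
               C = "cysteine", P = "proline", G = "glycine", X = "unknown")
  aa <- toupper(aa)
  bad <- setdiff(aa, names(classes))
  if (length(bad)) stop_kin("not an amino-acid letter: '%s'", bad[1])
  unname(classes[aa])
}

HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W")

#' Scan a sequence for a consensus pattern
#'
#' Slides a consensus pattern (residue letters plus the wildcard `x`, which
#' matches any residue) along the sequence and reports every 1-based match
#' start.  In relaxed mode, positions where the pattern letter is itself
#' hydrophobic (A, I, L, M, F, V, W) accept any hydrophobic residue —
#' the usual reading of kinase consensus motifs such as `IVHxDLKPxNIx`,
#' whose hydrophobic anchors drift within the class.
#'
#' @param seq A [seq_record] or residue string.
#' @param pattern Consensus pattern, e.g. `"IVHxDLKPxNIx"` or `"EGD"`.
#' @param relaxed Allow within-class matches at hydrophobic pattern
#'   positions (default `FALSE`).
#' @return data.frame with columns `start` and `match`.
#' @export
scan_consensus <- function(seq, pattern, relaxed = FALSE) {
  s <- if (is_seq_record(seq)) seq$residues else toupper(seq)
  if (!nzchar(pattern)) stop_kin("'pattern' must be non-empty")
  pch <- str_chars(pattern)
  bad <- setdiff(pch, c(AA20, "x"))
  if (length(bad)) stop_kin("invalid pattern character '%s'", bad[1])
  sch <- str_chars(s)
  k <- length(pch)
  n <- length(sch)
  starts <- integer(0)
  if (n >= k) {
    ok_at <- function(p, c) {
      if (p == "x") return(TRUE)
      if (c == p) return(TRUE)
      relaxed && p %in% HYDROPHOBIC && c %in% HYDROPHOBIC
    }
    for (i in seq_len(n - k + 1L)) {
      hit <- TRUE
      for (j in seq_len(k)) {
        if (!ok_at(pch[j], sch[i + j - 1L])) { hit <- FALSE; break }
      }
      if (hit) starts <- c(starts, i)
    }
  }
  data.frame(start = starts,
             match = vapply(starts, function(i) substr(s, i, i + k - 1L),
                            character(1)),
             stringsAsFactors = FALSE)
}

#' Functional-site catalogs
#'
#' A `site_catalog` lists single-position (or short-motif) functional sites
#' in reference numbering, each with the residue(s) expected there and a
#' category, plus consensus patterns anchored to reference segments and
#' named segment views.  [builtin_wee1_catalog()] returns the WEE1 catalog;
#' [write_catalog_json()] / [read_catalog_json()] serialize catalogs so other
#' kinase families can be annotated the same way.
#'
#' @param sites data.frame with columns `name`, `ref_pos`, `expected`
#'   (string; several allowed residues are concatenated, e.g. `"LF"`),
#'   `category`.
#' @param patterns data.frame with columns `name`, `pattern`,
#'   `anchor_start`, `anchor_end` (reference positions of the expected
#'   match).
#' @param segments data.frame with columns `name`, `start`, `end`
#'   (reference segments reported by the pipeline).
#' @return An object of class `site_catalog`.
#' @export
site_catalog <- function(sites, patterns = NULL, segments = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("name", "ref_pos", "expected", "category") %in% names(sites)))
  if (anyDuplicated(sites$name)) stop_kin("duplicate site name in catalog")
  if (anyDuplicated(sites$ref_pos)) stop_kin("duplicate site position in catalog")
  for (e in sites$expected) {
    if (first_bad_char(e, AA20) > 0L) stop_kin("invalid expected residue set '%s'", e)
  }
  if (!is.null(patterns)) {
    stopifnot(all(c("name", "pattern", "anchor_start", "anchor_end") %in% names(patterns)))
  }
  structure(list(sites = sites, patterns = patterns, segments = segments),
            class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf("<site_catalog> %d sites, %d consensus patterns\n",
              nrow(x$sites), if (is.null(x$patterns)) 0L else nrow(x$patterns)))
  invisible(x)
}

#' @rdname site_catalog
#' @details
#' The built-in WEE1 catalog, in human WEE1A numbering: the G-loop glutamate
#' E309 implicated in tyrosine specificity; the ATP-contact residues K328,
#' C379, K428, N431; the gatekeeper asparagine N376 at the back of the ATP
#' pocket (methionine in most plant WEE1s); the catalytic aspartate D426;
#' the activation-segment DFG/DLG motif 463–465 (D is Mg-ATP-binding and
#' function-critical; position 464 tolerates L or F — human WEE1 has DLG,
#' plants DFG); the WEE1-signatory EGD motif 477–479; and the
#' substrate-docking arginines R481 and R518 (R518 is widely replaced by
#' glutamate in plants, widening pocket access).  The catalytic-segment
#' consensus `IVHxDLKPxNIx` is anchored at 422–433.
#' @export
builtin_wee1_catalog <- function() {
  sites <- data.frame(
    name = c("g-loop-E309", "atp-K328", "gatekeeper", "atp-C379",
             "catalytic-D", "atp-K428", "atp-N431",
             "dfg-D", "dfg-2", "dfg-G",
             "egd-E", "egd-G", "egd-D", "docking-R481", "docking-R518"),
    ref_pos = c(309L, 328L, 376L, 379L, 426L, 428L, 431L,
                463L, 464L, 465L, 477L, 478L, 479L, 481L, 518L),
    expected = c("E", "K", "N", "C", "D", "K", "N",
                 "D", "LF", "G", "E", "G", "D", "R", "R"),
    category = c("g-loop", "atp-contact", "gatekeeper", "atp-contact",
                 "catalytic", "atp-contact", "atp-contact",
                 "activation", "activation", "activation",
                 "egd", "egd", "egd", "docking", "docking"),
    stringsAsFactors = FALSE)
  patterns <- data.frame(
    name = c("catalytic-segment", "egd-motif"),
    pattern = c("IVHxDLKPxNIx", "EGD"),
    anchor_start = c(422L, 477L),
    anchor_end = c(433L, 479L),
    stringsAsFactors = FALSE)
  segments <- data.frame(
    name = c("g-loop", "atp-binding", "catalytic", "activation"),
    start = c(303L, 374L, 422L, 461L),
    end = c(312L, 381L, 433L, 482L),
    stringsAsFactors = FALSE)
  site_catalog(sites, patterns, segments)
}

#' @rdname site_catalog
#' @param catalog A `site_catalog`.
#' @param path JSON file path.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(list(sites = catalog$sites, patterns = catalog$patterns,
                            segments = catalog$segments),
                       path, dataframe = "rows", auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname site_catalog
#' @export
read_catalog_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  site_catalog(as.data.frame(x$sites),
               if (!is.null(x$patterns) && length(x$patterns)) as.data.frame(x$patterns),
               if (!is.null(x$segments) && length(x$segments)) as.data.frame(x$segments))
}

site_status <- function(expected, observed) {
  if (is.na(observed) || observed == GAP) return("missing")
  allowed <- str_chars(expected)
  if (observed %in% allowed) return("conserved")
  if (classify_residue(observed) == classify_residue(allowed[1])) return("conservative")
  "class-change"
}

#' Call functional-site conservation across an alignment
#'
#' For every sequence and catalog site, reads the residue at the site's
#' reference position through the column map and classifies it:
#' `conserved` (expected residue), `conservative` (different residue, same
#' physicochemical class), `class-change`, or `missing` (gap, or position
#' outside the trimmed alignment).
#'
#' @param msa Alignment (or `pairwise_alignment`).
#' @param cmap Its [build_column_map()].
#' @param catalog A [site_catalog]; default [builtin_wee1_catalog()].
#' @return A `conservation_table`: data.frame with one row per
#'   (sequence, site): `seq_id`, `site`, `ref_pos`, `expected`, `observed`,
#'   `seq_pos`, `class`, `status`.
#' @export
call_sites <- function(msa, cmap, catalog = builtin_wee1_catalog()) {
  if (inherits(msa, "pairwise_alignment")) msa <- as_msa(msa)
  if (any(catalog$sites$ref_pos > cmap$ref_length)) {
    stop_kin("catalog position %d beyond reference length %d",
             max(catalog$sites$ref_pos), cmap$ref_length)
  }
  ids <- record_ids(msa$records)
  rows <- list()
  for (id in ids) {
    for (k in seq_len(nrow(catalog$sites))) {
      s <- catalog$sites[k, ]
      obs <- residue_at(msa, cmap, id, s$ref_pos)
      observed <- if (obs$status == "ok") obs$residue else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, site = s$name, ref_pos = s$ref_pos, expected = s$expected,
        observed = observed %||% NA_character_,
        seq_pos = obs$seq_pos,
        class = if (!is.na(observed)) classify_residue(observed) else NA_character_,
        status = site_status(s$expected, observed),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("conservation_table", "data.frame")
  out
}

#' Summarize per-site conservation counts
#'
#' @param table A `conservation_table` from [call_sites()].
#' @return data.frame of status counts per site.
#' @export
site_summary <- function(table) {
  as.data.frame.matrix(base::table(table$site, table$status))
}

#' Write a conservation table as TSV
#'
#' Wide sequences-by-sites layout; each cell is `observed/status`.
#'
#' @param table A `conservation_table`.
#' @param path Output path.
#' @export
write_conservation_tsv <- function(table, path) {
  cell <- paste0(ifelse(is.na(table$observed), "-", table$observed), "/", table$status)
  wide <- stats::reshape(
    data.frame(seq_id = table$seq_id, site = table$site, cell = cell,
               stringsAsFactors = FALSE),
    idvar = "seq_id", timevar = "site", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive functionality flags from site calls
#'
#' Per sequence: `catalytic-dead` when the catalytic aspartate (human D426)
#' is not D; `ATP-binding-compromised` when the DFG/DLG aspartate (D463) is
#' not D; `EGD-variant` when any EGD-motif position departs from E-G-D;
#' `gatekeeper-variant`, `docking-R481-variant`, `R518-variant` when those
#' single sites are not the expected residue.  A sequence lacking both
#' aspartates — the situation of the *V. unguiculata* Chr6.1-like paralogs —
#' carries both `catalytic-dead` and `ATP-binding-compromised`.
#'
#' @param table A `conservation_table` from [call_sites()] under the WEE1
#'   catalog site names.
#' @return Named list (by `seq_id`) of character flag vectors (possibly
#'   empty), class `functional_flags`.
#' @export
assess_function <- function(table) {
  not_ok <- function(sub, site) {
    row <- sub[sub$site == site, ]
    nrow(row) > 0 && row$status[1] != "conserved"
  }
  ids <- unique(table$seq_id)
  out <- lapply(ids, function(id) {
    sub <- table[table$seq_id == id, ]
    flags <- character(0)
    if (not_ok(sub, "catalytic-D")) flags <- c(flags, "catalytic-dead")
    if (not_ok(sub, "dfg-D")) flags <- c(flags, "ATP-binding-compromised")
    if (not_ok(sub, "egd-E") || not_ok(sub, "egd-G") || not_ok(sub, "egd-D")) {
      flags <- c(flags, "EGD-variant")
    }
    if (not_ok(sub, "gatekeeper")) flags <- c(flags, "gatekeeper-variant")
    if (not_ok(sub, "docking-R481")) flags <- c(flags, "docking-R481-variant")
    if (not_ok(sub, "docking-R518")) flags <- c(flags, "R518-variant")
    flags
  })
  names(out) <- ids
  class(out) <- "functional_flags"
  out
}

#' @export
print.functional_flags <- function(x, ...) {
  for (id in names(x)) {
    cat(sprintf("%s: %s\n", id,
                if (length(x[[id]])) paste(x[[id]], collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Locate catalog motifs on one sequence by consensus scanning
#'
#' Runs [scan_consensus()] for each catalog pattern over the whole sequence.
#' When a pattern matches more than once, hits overlapping the pattern's
#' anchor segment are preferred; a unique hit is reported wherever it falls,
#' so the positions are measured, not assumed.
#'
#' @param seq A [seq_record].
#' @param catalog A [site_catalog].
#' @param relaxed Passed to [scan_consensus()].
#' @return data.frame with `pattern` name, `start` (sequence position of the
#'   match), and `match`.
#' @export
locate_motifs <- function(seq, catalog = builtin_wee1_catalog(), relaxed = FALSE) {
  out <- list()
  for (k in seq_len(nrow(catalog$patterns))) {
    p <- catalog$patterns[k, ]
    hits <- scan_consensus(seq, p$pattern, relaxed = relaxed)
    if (nrow(hits) > 1L) {
      plen <- nchar(p$pattern)
      inside <- hits$start <= p$anchor_end & hits$start + plen - 1L >= p$anchor_start
      if (any(inside)) hits <- hits[inside, , drop = FALSE]
    }
    if (nrow(hits)) {
      out[[length(out) + 1L]] <- data.frame(pattern = p$name, start = hits$start,
                                            match = hits$match,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(pattern = character(0), start = integer(0), match = character(0))
  }
}
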