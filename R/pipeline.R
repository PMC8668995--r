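#' Configure an end-to-end conservation run
#'
#' Collects everything [run_report()] needs: the input sequences, the
#' reference id whose numbering anchors the analysis, the site catalog, the
#' alignment/trimming/scoring parameters, optional structures with their
#' gate residues, the output directory, and a seed for any stochastic stage.
#'
#' @param fasta Path to a FASTA file, or a list of [seq_record]s.
#' @param ref_id Id of the reference row (must be among the inputs).
#' @param alignment Optional pre-computed alignment (path to aligned FASTA,
#'   or an [new_msa()] object); when supplied, progressive alignment is
#'   skipped.
#' @param catalog `"builtin-wee1"`, a path to a catalog JSON, or a
#'   [site_catalog].
#' @param min_occupancy End-trimming occupancy threshold, see [trim_ends()].
#' @param scheme A [scoring_scheme].
#' @param structures Optional named list: paths to PDB files or `pdb`
#'   objects.
#' @param gates Gate residue selectors for [gate_access_report()].
#' @param gate_mode Distance mode for [residue_distance()].
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest.
#' @return A `run_config`.
#' @export
run_config <- function(fasta, ref_id, alignment = NULL,
                       catalog = "builtin-wee1", min_occupancy = 0.5,
                       scheme = default_scheme(), structures = NULL,
                       gates = NULL, gate_mode = "min-side-chain-heavy",
                       outdir, seed = 1L) {
  if (is.character(fasta) && !file.exists(fasta)) {
    stop_kin("input FASTA not found: %s", fasta)
  }
  if (is.character(alignment) && !file.exists(alignment)) {
    stop_kin("alignment file not found: %s", alignment)
  }
  for (s in structures) {
    if (is.character(s) && !file.exists(s)) stop_kin("structure file not found: %s", s)
  }
  cat_obj <- if (inherits(catalog, "site_catalog")) catalog
             else if (identical(catalog, "builtin-wee1")) builtin_wee1_catalog()
             else read_catalog_json(catalog)
  structure(list(fasta = fasta, ref_id = ref_id, alignment = alignment,
                 catalog = cat_obj, catalog_name = if (is.character(catalog)) catalog else "custom",
                 min_occupancy = min_occupancy, scheme = scheme,
                 structures = structures, gates = gates, gate_mode = gate_mode,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

tsv_header <- function(config, extra = character(0)) {
  c(sprintf("# kinanchor %s", as.character(utils::packageVersion("kinanchor"))),
    sprintf("# reference: %s; catalog: %s; min_occupancy: %g; gap_open: %g; gap_extend: %g",
            config$ref_id, config$catalog_name, config$min_occupancy,
            config$scheme$gap_open, config$scheme$gap_extend),
    extra)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full conservation analysis and write a report bundle
#'
#' Orchestrates the pipeline: read (or accept) sequences; align them
#' progressively unless an alignment is supplied; trim low-occupancy ends;
#' anchor columns to the reference numbering; extract the catalog's segment
#' views; call site conservation and derive functionality flags; build a
#' midpoint-rooted neighbor-joining tree; and, when structures are given,
#' measure pocket access.  Outputs are deterministic: rerunning on the same
#' inputs produces byte-identical artifacts.
#'
#' Files written to `config$outdir`: `alignment.fasta`,
#' `segment_<name>.tsv`, `conservation.tsv`, `flags.json`, `tree.nwk`,
#' `gate_access.tsv` (with structures), and `manifest.json` (versions,
#' parameters, seed, input checksums).  Any stage error aborts the run,
#' removes partial outputs, and names the failing stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`msa`, `cmap`,
#'   `conservation`, `flags`, `tree`, `gate_table`, `paths`).
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- if (is.character(config$fasta)) read_fasta(config$fasta) else config$fasta
  ids <- check_unique_ids(records)
  if (!config$ref_id %in% ids) {
    stop_kin("stage input: reference id '%s' not among inputs [%s]",
             config$ref_id, paste(ids, collapse = ", "))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  on_fail <- function(stage, e) {
    unlink(written)
    stop_kin("stage %s: %s", stage, conditionMessage(e))
  }
  stage <- function(name, code) tryCatch(code, error = function(e) on_fail(name, e))

  msa <- stage("align", {
    aln <- config$alignment
    m <- if (is.null(aln)) progressive_align(records, config$scheme)
         else if (inherits(aln, "msa")) aln
         else read_alignment(aln, "aligned-fasta")
    trim_ends(m, config$min_occupancy)
  })
  stage("align", write_fasta(msa$records, emit(file.path(config$outdir, "alignment.fasta"))))

  cmap <- stage("anchor", build_column_map(msa, config$ref_id))

  catalog <- config$catalog
  stage("segments", {
    if (!is.null(catalog$segments)) {
      for (k in seq_len(nrow(catalog$segments))) {
        sg <- catalog$segments[k, ]
        sub <- extract_segment(msa, cmap, sg$start, sg$end)
        df <- data.frame(seq_id = record_ids(sub$records),
                         segment = vapply(sub$records, function(r) r$residues, character(1)),
                         stringsAsFactors = FALSE)
        write_tsv_with_header(df, emit(file.path(config$outdir, sprintf("segment_%s.tsv", sg$name))),
                              tsv_header(config, sprintf("# segment %s: reference %d..%d",
                                                         sg$name, sg$start, sg$end)))
      }
    }
  })

  conservation <- stage("annotate", call_sites(msa, cmap, catalog))
  stage("annotate", write_conservation_tsv(conservation,
                                           emit(file.path(config$outdir, "conservation.tsv"))))
  flags <- stage("annotate", assess_function(conservation))
  stage("annotate", jsonlite::write_json(unclass(flags),
                                         emit(file.path(config$outdir, "flags.json")),
                                         auto_unbox = FALSE))

  tree <- NULL
  if (length(records) >= 3L) {
    tree <- stage("tree", {
      D <- distance_matrix(records, config$scheme)
      midpoint_root(neighbor_joining(D))
    })
    stage("tree", to_newick(tree, emit(file.path(config$outdir, "tree.nwk"))))
  }

  gate_table <- NULL
  if (!is.null(config$structures)) {
    gate_table <- stage("measure", {
      structs <- lapply(config$structures, function(s) if (is.character(s)) read_pdb(s) else s)
      gate_access_report(structs, config$gates, mode = config$gate_mode)
    })
    stage("measure", write_tsv_with_header(gate_table,
                                           emit(file.path(config$outdir, "gate_access.tsv")),
                                           tsv_header(config, sprintf("# distance mode: %s", config$gate_mode))))
  }

  stage("manifest", {
    checksum <- function(x) {
      if (is.character(x) && length(x) == 1L && file.exists(x)) {
        unname(tools::md5sum(x))
      } else NA_character_
    }
    manifest <- list(
      package = "kinanchor",
      version = as.character(utils::packageVersion("kinanchor")),
      parameters = list(ref_id = config$ref_id, catalog = config$catalog_name,
                        min_occupancy = config$min_occupancy,
                        gap_open = config$scheme$gap_open,
                        gap_extend = config$scheme$gap_extend,
                        gate_mode = config$gate_mode),
      seed = config$seed,
      inputs = list(fasta = if (is.character(config$fasta)) config$fasta else "(in-memory records)",
                    fasta_md5 = checksum(config$fasta),
                    n_sequences = length(records)))
    jsonlite::write_json(manifest, emit(file.path(config$outdir, "manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(msa = msa, cmap = cmap, conservation = conservation,
                 flags = flags, tree = tree, gate_table = gate_table,
                 paths = written))
}
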