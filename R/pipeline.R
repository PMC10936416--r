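#' Default run configuration
#'
#' All pipeline tunables with their default values: anchor filters
#' (length > 7000 bp, coverage > 5), binning candidate floor
#' (>= 1000 bp), correlation threshold (R > 0.95), coverage band
#' (fold 2.5), bin-grouping link threshold (0.5), MLSA majority fraction
#' (0.5), and the chimera/quality cutoffs.
#'
#' @param contigs,annotations,coverage_table input paths (optional when an
#'   in-memory assembly is supplied to [run_pipeline()]).
#' @param out_dir output directory; `NULL` disables file output.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the input is simulated).
#' @param ... overrides for any tunable listed above.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(contigs = NULL, annotations = NULL,
                               coverage_table = NULL, out_dir = NULL,
                               seed = 42L, ...) {
  cfg <- list(contigs = contigs, annotations = annotations,
              coverage_table = coverage_table, out_dir = out_dir, seed = seed,
              min_length_bp = 7000, min_coverage = 5,
              min_contig_bp = 1000, r_threshold = 0.95,
              cov_fold = 2.5, link_threshold = 0.5,
              majority_fraction = 0.5,
              max_size_mbp = 8.0, min_completeness = 50.0,
              max_contamination = 5.0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML with overrides
#'
#' Precedence: explicit overrides > YAML file > defaults.
#'
#' @param path YAML file; keys as in [default_run_config()].
#' @param ... overrides applied on top of the file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(default_run_config, utils::modifyList(y, list(...)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full gene-anchored binning pipeline
#'
#' Executes mine (annotation scan + anchor selection) -> bin (signature
#' correlation) -> coverage filter -> bin grouping -> bin reports with
#' pathway classification, writing per-stage outputs and a machine-readable
#' manifest when `out_dir` is set. The run is deterministic: the same
#' configuration and inputs give byte-identical outputs.
#'
#' @param config a `RunConfig` from [default_run_config()] or
#'   [read_run_config()].
#' @param assembly optional in-memory `Assembly` (skips file input).
#' @param scores optional data.frame `bin_id, completeness, contamination`
#'   of externally computed quality scores (these are consumed, never
#'   computed here).
#' @return list with `assembly`, `hits`, `anchor_set`, `bins` (coverage
#'   filtered), `groups`, `reports`, `flags`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), assembly = NULL,
                         scores = NULL) {
  stopifnot(is(config, "RunConfig"))
  if (is.null(assembly)) {
    if (is.null(config$contigs)) stop("no input: supply config$contigs or an assembly")
    assembly <- stage("read", {
      a <- read_contigs(config$contigs, config$coverage_table)
      if (!is.null(config$annotations))
        a <- set_annotations(a, read_annotations(config$annotations))
      a
    })
  }
  mined <- stage("mine", mine_anchors(
    assembly, min_length_bp = config$min_length_bp,
    min_coverage = config$min_coverage))
  sig <- stage("signatures", signature_matrix(assembly, config$min_contig_bp))
  bins <- stage("bin", build_bins(mined$anchor_set, assembly,
                                  min_contig_bp = config$min_contig_bp,
                                  r_threshold = config$r_threshold, sig = sig))
  bins <- stage("coverage_filter",
                lapply(bins, coverage_filter, assembly = assembly,
                       fold = config$cov_fold))
  groups <- if (length(bins))
    stage("group", compare_bins(bins, config$link_threshold)) else NULL
  reports <- stage("stats", lapply(bins, function(b) {
    sc <- if (!is.null(scores) && b$bin_id %in% scores$bin_id)
      scores[scores$bin_id == b$bin_id, ] else
        data.frame(completeness = NA_real_, contamination = NA_real_)
    characterize_bin(b, assembly, mined$hits,
                     completeness = sc$completeness[1L],
                     contamination = sc$contamination[1L])
  }))
  flags <- stage("chimera_flag", vapply(reports, function(r)
    flag_chimeric(r, r$completeness, r$contamination,
                  max_size_mbp = config$max_size_mbp,
                  min_completeness = config$min_completeness,
                  max_contamination = config$max_contamination), ""))
  manifest <- list(
    package = "anchormag",
    version = as.character(utils::packageVersion("anchormag")),
    parameters = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    inputs = pipeline_input_checksums(config),
    counts = list(contigs = nrow(assembly$contigs),
                  annotations = nrow(assembly$annotations),
                  total_cds = assembly$total_cds,
                  hits = nrow(mined$hits),
                  anchors = length(mined$anchor_set$anchors),
                  bins = length(bins),
                  binned_contigs = length(unique(unlist(
                    lapply(bins, `[[`, "member_ids"))))))
  result <- list(assembly = assembly, hits = mined$hits,
                 anchor_set = mined$anchor_set, bins = bins, groups = groups,
                 reports = reports, flags = flags, manifest = manifest)
  if (!is.null(config$out_dir))
    result$manifest$outputs <- stage("write",
                                     write_pipeline_outputs(result, config))
  result
}

pipeline_input_checksums <- function(config) {
  paths <- Filter(function(p) is.character(p) && file.exists(p),
                  config[c("contigs", "annotations", "coverage_table")])
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  p <- function(f) file.path(config$out_dir, f)
  out <- c(out, write_tsv(result$hits, p("hits.tsv")))
  out <- c(out, write_tsv(
    data.frame(contig_id = result$anchor_set$anchors), p("anchors.tsv")))
  members <- do.call(rbind, lapply(result$bins, function(b)
    data.frame(bin_id = b$bin_id, contig_id = sort(b$member_ids),
               is_anchor = sort(b$member_ids) %in% b$anchor_ids,
               stringsAsFactors = FALSE)))
  if (!is.null(members)) out <- c(out, write_tsv(members, p("bin_members.tsv")))
  for (b in result$bins)
    out <- c(out, write_bin_fasta(b, result$assembly,
                                  p(paste0(b$bin_id, ".fasta"))))
  if (!is.null(result$groups))
    out <- c(out, write_tsv(result$groups$groups, p("groups.tsv")))
  if (length(result$reports)) {
    tab <- report_table(result$reports)
    tab$chimera_flag <- unname(result$flags[tab$bin_id])
    out <- c(out, write_tsv(tab, p("bin_reports.tsv")))
  }
  checks <- lapply(out, function(f) unname(tools::md5sum(f)))
  names(checks) <- basename(out)
  manifest <- result$manifest
  manifest$outputs <- checks
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  checks[["manifest.json"]] <- NA_character_
  checks
}
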