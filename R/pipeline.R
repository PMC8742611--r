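# End-to-end pipeline: simulate -> deconvolve -> contacts -> enrich, driven
# by a single YAML-serializable configuration, with a per-stage count report
# (reads in, statuses, contacts emitted, rejected) so every run leaves a
# reproducible processing-statistics table.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys `seed`, `outdir`, `bridge`,
#'   `simulate`, `analysis` (all but `outdir` optional).
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}

#' Write a pipeline configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

build_bridge_cfg <- function(config) {
  b <- config$bridge %||% list()
  b$bridge_seq <- b$bridge_seq %||% example_bridge()
  do.call(bridge_config, b)
}

build_sim_cfg <- function(config) {
  s <- config$simulate %||% list()
  s$seed <- s$seed %||% config$seed %||% 1L
  known <- names(formals(sim_config))
  unknown <- setdiff(names(s), known)
  if (length(unknown))
    stop("unknown simulate parameter: ", paste(unknown, collapse = ", "))
  do.call(sim_config, s)
}

#' Run the full synthetic pipeline
#'
#' Simulates a reference and ground-truth contacts, renders them as paired
#' FASTQ, deconvolves the reads, maps the parts with the exact-match
#' aligner, builds per-library contact tables, and runs the enrichment
#' analysis (per-gene fold-change table, state ratio, peak metaprofile).
#' Every stage writes its outputs under `outdir` and contributes counts to
#' the run report; the report's conservation identities (pairs in = sum of
#' statuses; OK reads = contacts + rejected) always hold.
#'
#' @param config Configuration list (see [read_pipeline_config()]); must
#'   contain `outdir`.
#' @return Invisibly, the run report (also written as `report.yaml`).
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  if (is.null(outdir)) stop("pipeline config needs an 'outdir'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  analysis <- config$analysis %||% list()
  window_bp <- analysis$window_bp %||% 1e6
  threshold <- analysis$threshold %||% 1.3
  min_count <- analysis$min_count %||% 10L
  flank_bp <- analysis$flank_bp %||% 10000L
  n_bins <- analysis$n_bins %||% 41L
  mode <- analysis$mode %||% "cis"
  bridge_cfg <- build_bridge_cfg(config)
  report <- list(parameters = list(
    seed = config$seed %||% 1L, window_bp = window_bp,
    threshold = threshold, min_count = min_count, mode = mode,
    bridge_seq = bridge_cfg$bridge_seq
  ))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ------------------------------------------------------------
  sim_cfg <- stage("simulate", build_sim_cfg(config))
  ref <- stage("simulate", simulate_reference(sim_cfg, sequences = TRUE))
  stage("simulate", write_reference(ref, outdir))
  sim <- stage("simulate", simulate_contacts(sim_cfg, ref))
  utils::write.table(sim$gene_truth, file.path(outdir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$simulate <- list(
    n_chroms = sim_cfg$n_chroms, n_genes = nrow(ref$genes),
    n_libraries = length(sim$tables),
    n_contacts_per_library = sim_cfg$n_contacts_per_fraction
  )

  # --- deconvolve + contacts per library ----------------------------------
  libraries <- names(sim$tables)
  tables <- list()
  lib_report <- list()
  for (lib in libraries) {
    truth_contacts <- sim$tables[[lib]]
    rr <- stage("deconvolve",
                contacts_to_reads(truth_contacts, ref, bridge_cfg, sim_cfg,
                                  seed = sim_cfg$seed + 50L + match(lib, libraries)))
    r1 <- file.path(outdir, sprintf("reads_%s_R1.fastq", lib))
    r2 <- file.path(outdir, sprintf("reads_%s_R2.fastq", lib))
    write_fastq_pairs(rr$reads, r1, r2)
    dec <- stage("deconvolve", deconvolve_library(rr$reads, cfg = bridge_cfg))
    write_deconvolved(dec, file.path(outdir, sprintf("parts_%s.tsv", lib)),
                      file.path(outdir, sprintf("stats_%s.tsv", lib)))
    parts <- ok_parts(dec$reads)
    alns <- stage("contacts", align_exact(parts, ref$genome))
    fraction <- sub("_\\d+$", "", lib)
    replicate <- as.integer(sub("^.*_", "", lib))
    ct <- stage("contacts",
                build_contacts(alns, alns, ref$genes, fraction, replicate,
                               read_ids = dec$reads$read_id[dec$reads$status == "OK"]))
    write_contacts(ct, file.path(outdir, sprintf("contacts_%s.tsv", lib)))
    tables[[lib]] <- ct
    st <- attr(ct, "stats")
    lib_report[[lib]] <- list(
      pairs_in = nrow(rr$reads),
      status_counts = as.list(dec$status_counts),
      ok_reads = unname(st[["n_reads"]]),
      both_unique = unname(st[["n_both_unique"]]),
      duplicates_removed = unname(st[["n_duplicate"]]),
      contacts = unname(st[["n_contacts"]]),
      rejected = unname(st[["n_reads"]] - st[["n_contacts"]])
    )
  }
  report$libraries <- lib_report

  # --- enrich --------------------------------------------------------------
  n_rep <- sim_cfg$n_replicates
  ip <- lapply(seq_len(n_rep), function(k) tables[[sprintf("IP_%d", k)]])
  input <- lapply(seq_len(n_rep), function(k) tables[[sprintf("input_%d", k)]])
  enr <- stage("enrich",
               enrichment_table(ip, input, ref$genes, mode = mode,
                                window_bp = window_bp, threshold = threshold,
                                min_count = min_count))
  utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pooled_ip <- do.call(rbind, ip)
  pooled_in <- do.call(rbind, input)
  sr <- stage("enrich", state_ratio_ip_input(pooled_ip, pooled_in, ref$states))
  utils::write.table(sr, file.path(outdir, "state_ratio.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mp <- stage("enrich", peak_metaprofile(pooled_ip, ref$peaks,
                                         flank_bp = flank_bp,
                                         n_bins = n_bins))
  utils::write.table(mp, file.path(outdir, "metaprofile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$enrich <- list(
    genes_tested = nrow(enr),
    genes_with_defined_fc = sum(stats::complete.cases(
      enr[, grep("^fc_rep", names(enr)), drop = FALSE])),
    genes_enriched = sum(enr$enriched)
  )
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))
  pipeline_log("pipeline complete: %d libraries, %d genes enriched",
               length(libraries), report$enrich$genes_enriched)
  invisible(report)
}
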