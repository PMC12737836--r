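#' Default pipeline configuration
#'
#' One nested list drives the whole analysis: a `simulation` section
#' (fields of [sim_config()]), an `align` section
#' ([align_config()] fields), a `filter` section ([filter_config()]
#' fields), a `tree` section (`n_resamples`), a `pca` section
#' (`variance_threshold`, percent), and `concordance_samples` (how many
#' diploid accessions to re-genotype in silico for the concordance
#' check). The top-level `seed` drives every random stage.
#'
#' @return nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(seed = 1,
       simulation = list(),
       align = list(max_flank_mismatch = 1, mismatch_mode = "per_arm"),
       filter = list(maf_threshold = 0.05, max_missing_fraction = 0.03,
                     missing_axis = "marker"),
       tree = list(n_resamples = 1000),
       pca = list(variance_threshold = 80),
       concordance_samples = 2)
}

.load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop("config missing required field: seed")
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(default_pipeline_config(), config)
  cfg$seed <- check_seed(cfg$seed)
  cfg
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full subgenome-origin analysis
#'
#' Orchestrates every stage on a simulated study: panel simulation with
#' ground truth, in-silico genotyping of the tetraploid subgenomes
#' (dissected), concordance spot-checks of in-silico versus array calls
#' for diploid accessions, panel merging, the three-step marker filter,
#' IBS nearest-neighbor ranking of each dissected subgenome tip, PCA of
#' the filtered panel, a bootstrapped neighbor-joining tree with
#' sister-group readouts, and lineage-specific variant window counts on
#' the truth variants. Deterministic given the config seed.
#'
#' @param config configuration list or YAML file path (see
#'   [default_pipeline_config()]); only `seed` is required.
#' @param outdir optional directory; when given, every stage's
#'   inputs/outputs are persisted (FASTA, TSV, Newick, VCF, BED, JSON
#'   report).
#' @return list of class `origin_report`; see Details.
#'
#' @details The report contains `seed`, `config_hash`, `package_version`,
#'   `truth` (parent ids), `concordance` (per-sample percent),
#'   `filter_report` (marker counts per step), `nearest_neighbors`
#'   (top-ranked wild accessions per dissected subgenome tip),
#'   `origin_call` (top neighbor per tip and whether it matches truth),
#'   `pca` (`variance_percent`, `n_pcs_80`), `sisters` (sister tip sets
#'   and stem supports per tip), `parent_clade_support` (support of the
#'   clade uniting each subgenome's tetraploid tips with the true parent
#'   species accessions), `tree` (Newick string), and variant window
#'   summaries (`lineage_specific`).
#' @export
run_pipeline <- function(config = list(seed = 1), outdir = NULL) {
  cfg <- .load_pipeline_config(config)
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulation))
  acfg <- do.call(align_config, cfg$align)
  fcfg <- do.call(filter_config, cfg$filter)

  panel <- simulate_panel(scfg)
  truth <- panel$truth
  tet_ids <- grep("^tet", names(panel$genomes), value = TRUE)
  diploid_ids <- setdiff(names(panel$genomes), tet_ids)

  # dissected in-silico genotyping of each tetraploid
  tet_calls <- do.call(cbind, lapply(tet_ids, function(id) {
    unclass(genotype_genome(panel$probes, panel$genomes[[id]],
                            sample_id = id, cfg = acfg))
  }))
  tet_calls <- call_matrix(tet_calls)
  tet_tips <- colnames(tet_calls)

  # concordance spot check: in-silico versus array calls for diploids
  n_check <- min(cfg$concordance_samples, length(diploid_ids))
  conc <- lapply(diploid_ids[seq_len(n_check)], function(id) {
    ins <- genotype_genome(panel$probes, panel$genomes[[id]],
                           sample_id = id, cfg = acfg)
    concordance(setNames(ins[, 1L], rownames(ins)),
                setNames(panel$array_calls[, id],
                         rownames(panel$array_calls)),
                id1 = paste0(id, "_insilico"), id2 = id)
  })
  names(conc) <- diploid_ids[seq_len(n_check)]

  merged <- merge_panels(panel$array_calls, tet_calls)

  # similarity ranking is imputation-free and robust to missingness, so
  # it runs on the merged panel after only the polymorphism filter
  poly <- filter_polymorphic(merged)
  sim <- ibs_matrix(poly$matrix)
  nn <- nearest_neighbors(sim, tet_tips)
  origin_call <- do.call(rbind, lapply(tet_tips, function(tip) {
    top <- nn[nn$query == tip & nn$rank == 1L, ]
    pool <- sub("^.*_", "", tip)
    truth_parent <- if (pool == "A") truth$parent_A_id else truth$parent_B_id
    data.frame(tip = tip, top_neighbor = top$neighbor,
               similarity = top$similarity, truth_parent = truth_parent,
               correct = top$neighbor == truth_parent,
               stringsAsFactors = FALSE)
  }))

  filt <- run_filter_pipeline(merged, fcfg)

  pca_res <- NULL
  if (nrow(filt$matrix) >= 2L) {
    pca_res <- pcoa(euclidean_distances(encode_dosage(filt$matrix)))
  }

  pseudo <- pseudosequences(filt$matrix)
  tree <- bootstrap_support(pseudo, n_resamples = cfg$tree$n_resamples,
                            seed = cfg$seed + 1L)
  sisters <- lapply(tet_tips, function(tip) find_sister(tree, tip))
  names(sisters) <- tet_tips
  parent_clade_support <- vapply(c("A", "B"), function(pool) {
    parent <- if (pool == "A") truth$parent_A_id else truth$parent_B_id
    sp <- sub("_[0-9]+$", "", parent)
    set <- c(grep(paste0("^", sp, "_"), tree$tip.label, value = TRUE),
             grep(paste0("_", pool, "$"), tet_tips, value = TRUE))
    split_support(tree, set)
  }, numeric(1))

  # lineage-specific variant readout on the truth variants: the close
  # lineage should carry far fewer specific variants than the far one
  lv_close <- classify_lineage_specific(truth$true_variants,
                                        focal = truth$lineage_close,
                                        other = truth$lineage_far)
  lv_far <- classify_lineage_specific(truth$true_variants,
                                      focal = truth$lineage_far,
                                      other = truth$lineage_close)
  genic_far <- restrict_to_regions(lv_far, truth$genic_bed)
  wc <- window_counts(lv_far, truth$chrom_lengths,
                      window_size = min(1e5, max(truth$chrom_lengths)))

  report <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("allokin")),
    config_hash = .config_hash(cfg),
    truth = list(parent_A_id = truth$parent_A_id,
                 parent_B_id = truth$parent_B_id),
    concordance = vapply(conc, `[[`, numeric(1), "percent"),
    filter_report = list(n_input = filt$report$n_input,
                         n_after_polymorphic = filt$report$n_after_polymorphic,
                         n_after_maf = filt$report$n_after_maf,
                         n_after_missing = filt$report$n_after_missing),
    nearest_neighbors = nn[nn$rank <= 5L, ],
    origin_call = origin_call,
    pca = if (!is.null(pca_res)) {
      list(variance_percent = pca_res$variance_percent,
           n_pcs_80 = select_pcs(pca_res, cfg$pca$variance_threshold))
    },
    sisters = sisters,
    parent_clade_support = parent_clade_support,
    lineage_specific = list(close = nrow(lv_close), far = nrow(lv_far),
                            far_genic = nrow(genic_far),
                            max_span = if (nrow(lv_far)) max_variant_span(lv_far) else 0L,
                            windows_far = wc),
    tree = ape::write.tree(tree))
  class(report) <- "origin_report"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genomes(panel$genomes, file.path(outdir, "genomes"))
    write_probes(panel$probes, file.path(outdir, "probes.tsv"))
    write_calls(panel$array_calls, file.path(outdir, "array_calls.tsv"))
    write_calls(tet_calls, file.path(outdir, "tetraploid_calls.tsv"))
    write_calls(merged, file.path(outdir, "merged.tsv"))
    write_calls(filt$matrix, file.path(outdir, "filtered.tsv"))
    write_pseudo_fasta(pseudo, file.path(outdir, "pseudosequences.fasta"))
    write_newick(tree, file.path(outdir, "tree.nwk"))
    write_truth(truth, file.path(outdir, "truth"))
    jsonlite::write_json(.report_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# JSON-friendly view of the report (data frames become row lists)
.report_json <- function(report) {
  out <- unclass(report)
  out$sisters <- lapply(out$sisters, function(s)
    list(sister = s$sister, support = s$support))
  out
}

#' @export
print.origin_report <- function(x, ...) {
  cat("origin report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  markers: %d -> %d -> %d -> %d after filtering\n",
              x$filter_report$n_input, x$filter_report$n_after_polymorphic,
              x$filter_report$n_after_maf, x$filter_report$n_after_missing))
  for (i in seq_len(nrow(x$origin_call))) {
    oc <- x$origin_call[i, ]
    cat(sprintf("  %s -> %s (IBS %.4f, truth %s, %s)\n", oc$tip,
                oc$top_neighbor, oc$similarity, oc$truth_parent,
                if (oc$correct) "correct" else "MISMATCH"))
  }
  if (length(x$concordance)) {
    cat("  concordance: ",
        paste(sprintf("%s=%.1f%%", names(x$concordance), x$concordance),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
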