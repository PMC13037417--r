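#' Default end-to-end pipeline configuration
#'
#' Assembles the run configuration with every analysis threshold at its
#' standard value: DE calling at |log2FC| >= 1 and FDR < 0.01, normalizer
#' FDR floor 0.05 with 50% CV retention, GeNorm V cutoff 0.15, volcano
#' thresholds |FR| >= 2 and p < 0.05, and target-score cutoff 60.
#'
#' @param sim a \code{\link{sim_config}} describing the synthetic cohort
#'   (its seed is overridden by \code{seed}).
#' @param seed single global seed; per-stage seeds are derived from it by
#'   fixed offsets (simulation uses \code{seed}, qPCR noise
#'   \code{seed + 1000003}, target simulation \code{seed + 2000003}), so
#'   adding a stage does not perturb earlier draws.
#' @param n_panel number of DE miRNAs carried onto the validation panel.
#' @param n_normalizers normalizers selected (default 3).
#' @param de_method,qpcr_test test choices for the DE and qPCR stages.
#' @param lfc_cut,fdr_cut,fdr_floor,retain_frac,v_cut,fr_cut,p_cut,score_min
#'   stage thresholds; defaults as above.
#' @param exclusion_list miRNA IDs excluded from normalizer candidacy.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(sim = sim_config(), seed = 1L, n_panel = 10L,
                       n_normalizers = 3L, de_method = "wald",
                       qpcr_test = "welch", lfc_cut = 1, fdr_cut = 0.01,
                       fdr_floor = 0.05, retain_frac = 0.5, v_cut = 0.15,
                       fr_cut = 2, p_cut = 0.05, score_min = 60,
                       exclusion_list = character(0)) {
  stopifnot(inherits(sim, "sim_config"))
  sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, seed = as.integer(seed), n_panel = as.integer(n_panel),
              n_normalizers = as.integer(n_normalizers),
              de_method = de_method, qpcr_test = qpcr_test,
              lfc_cut = lfc_cut, fdr_cut = fdr_cut, fdr_floor = fdr_floor,
              retain_frac = retain_frac, v_cut = v_cut, fr_cut = fr_cut,
              p_cut = p_cut, score_min = score_min,
              exclusion_list = exclusion_list)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' \code{\link{run_config}}, with simulation parameters nested under
#' \code{sim}.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- do.call(sim_config, sim_args)
  do.call(run_config, y)
}

#' Run the full synthetic validation pipeline
#'
#' Executes the whole workflow on a synthetic cohort with known truth:
#' simulate counts -> differential expression -> candidate ranking ->
#' normalizer selection -> GeNorm stability check -> simulated qPCR of the
#' panel -> delta-delta-CT quantification -> sequencing/qPCR concordance ->
#' target filtering and pathway over-representation. All stage outputs,
#' truth-recovery metrics and a manifest of thresholds and seeds are
#' returned; when \code{out_dir} is given, tables are also written there as
#' TSV/JSON and inputs on disk are never modified.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory (created if missing).
#' @return a list of class \code{"pipeline_run"} with components
#'   \code{sim}, \code{de}, \code{candidates}, \code{normalizers},
#'   \code{genorm}, \code{ct}, \code{qpcr}, \code{concordance},
#'   \code{enrichment}, \code{metrics}, \code{manifest}.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(sim_config(n_mirnas = 120, n_case = 8,
#'                                           n_control = 8), seed = 42))
#' run$metrics
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_counts(config$sim)
  de <- de_test(sim$counts, method = config$de_method,
                lfc_cut = config$lfc_cut, fdr_cut = config$fdr_cut)

  candidates <- suppressWarnings(
    rank_candidates(de, k = config$n_panel))
  normrep <- suppressWarnings(
    select_normalizers(sim$counts, de, config$exclusion_list,
                       n = config$n_normalizers,
                       fdr_floor = config$fdr_floor,
                       retain_frac = config$retain_frac))

  gfit <- NULL
  if (length(normrep$candidates) >= 2L) {
    q <- cpm(sim$counts)[normrep$candidates, , drop = FALSE] + 0.5
    gfit <- suppressWarnings(genorm(q, v_cut = config$v_cut))
  }

  panel <- panel_config(targets = candidates,
                        references = normrep$candidates)
  ct <- simulate_ct(sim$truth, config$sim, panel)
  qpcr <- suppressWarnings(
    ddct_quantify(delta_ct(ct, panel), test = config$qpcr_test,
                  fr_cut = config$fr_cut, p_cut = config$p_cut))
  conc <- direction_concordance(de, qpcr)

  validated <- qpcr$assay_id[qpcr$class != "ns"]
  enr <- NULL
  if (length(validated)) {
    genes <- sprintf("GENE%03d", 1:200)
    targets <- simulate_targets(validated, genes,
                                seed = config$seed + 2000003L)
    query <- filter_targets(targets, score_min = config$score_min)
    set.seed(config$seed + 3000003L)
    sets <- lapply(stats::setNames(1:15, sprintf("PATHWAY_%02d", 1:15)),
                   function(i) sample(genes, sample(10:40, 1)))
    enr <- ora_test(query, sets, universe = genes)
  }

  truth <- sim$truth
  called <- de$mirna_id[de$call != "ns"]
  de_truth <- truth$mirna_id[truth$is_de]
  metrics <- c(
    n_de_true = length(de_truth),
    n_de_called = length(called),
    de_sensitivity = if (length(de_truth))
      mean(de_truth %in% called) else NA_real_,
    de_fdr_observed = if (length(called))
      mean(!called %in% de_truth) else 0,
    normalizers_in_truth = if (length(normrep$candidates))
      mean(normrep$candidates %in% truth$mirna_id[truth$is_stable])
      else NA_real_,
    n_validated = unname(summarize_validation(qpcr)["n_validated"]),
    concordance = conc$fraction)

  manifest <- list(
    seed = config$seed,
    thresholds = config[c("lfc_cut", "fdr_cut", "fdr_floor", "retain_frac",
                          "v_cut", "fr_cut", "p_cut", "score_min")],
    methods = config[c("de_method", "qpcr_test")],
    sim = unclass(config$sim),
    stage_records = c(mirnas = nrow(de), panel_targets = length(candidates),
                      normalizers = length(normrep$candidates),
                      ct_rows = nrow(ct), qpcr_targets = nrow(qpcr),
                      enriched_sets = if (is.null(enr)) 0L else nrow(enr)))

  run <- list(sim = sim, de = de, candidates = candidates,
              normalizers = normrep, genorm = gfit, ct = ct, qpcr = qpcr,
              concordance = conc, enrichment = enr, metrics = metrics,
              manifest = manifest)
  class(run) <- "pipeline_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"),
                       file.path(out_dir, "groups.tsv"))
    write_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_tsv(as.data.frame(de), file.path(out_dir, "de.tsv"))
    write_tsv(as.data.frame(normrep$stability),
              file.path(out_dir, "stability.tsv"))
    write_ct_table(ct, file.path(out_dir, "ct.tsv"))
    write_tsv(as.data.frame(qpcr), file.path(out_dir, "qpcr.tsv"))
    write_tsv(conc$table, file.path(out_dir, "concordance.tsv"))
    if (!is.null(enr))
      write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Synthetic miRNA validation pipeline run\n")
  cat(sprintf("  seed %d; %d miRNAs, %d + %d samples\n",
              x$manifest$seed, x$manifest$sim$n_mirnas,
              x$manifest$sim$n_case, x$manifest$sim$n_control))
  m <- x$metrics
  cat(sprintf("  DE: %d planted, %d called (sensitivity %.2f, observed FDR %.2f)\n",
              m["n_de_true"], m["n_de_called"], m["de_sensitivity"],
              m["de_fdr_observed"]))
  cat(sprintf("  normalizers from planted stable set: %.0f%%\n",
              100 * m["normalizers_in_truth"]))
  cat(sprintf("  qPCR: %d validated; seq/qPCR direction concordance %.2f\n",
              m["n_validated"], m["concordance"]))
  invisible(x)
}
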