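#' Configuration for the synthetic small-RNA-seq / qPCR generator
#'
#' Builds and validates the parameter set controlling the synthetic cohort:
#' a negative-binomial miRNA count matrix with a planted differentially
#' expressed subset and a planted stable (normalizer-like) subset, plus
#' matched qPCR CT values tied to the same underlying abundances.
#'
#' @param n_mirnas number of miRNAs simulated.
#' @param n_case,n_control samples per group. Defaults mirror an archival
#'   FFPE cohort of 18 tumors vs 6 controls.
#' @param frac_de fraction of miRNAs with a planted fold change.
#' @param lfc_range range (log2 units) from which planted |log2 fold
#'   changes| are drawn uniformly; the lower bound must be positive so DE
#'   miRNAs are genuinely changed.
#' @param n_stable number of planted normalizer-like miRNAs: zero fold
#'   change and near-Poisson (minimal extra-Poisson) noise.
#' @param dispersion global negative-binomial dispersion \eqn{\alpha}
#'   (variance \eqn{\mu + \alpha \mu^2}); per-miRNA values are drawn
#'   log-normally around it.
#' @param lib_size_range range of per-sample library sizes; sizes are drawn
#'   log-uniformly within it.
#' @param ct_noise_sd technical CT noise, in cycles.
#' @param ct_offset cycles added to \code{-log2(relative abundance)} to map
#'   abundance onto the CT scale.
#' @param ct_limit detection limit in cycles; CT values beyond it are
#'   flagged undetermined.
#' @param seed integer seed making the whole simulation reproducible.
#' @return an object of class \code{"sim_config"} (a validated list).
#' @examples
#' cfg <- sim_config(n_mirnas = 50, n_case = 6, n_control = 6, seed = 1)
#' cfg$frac_de
#' @export
sim_config <- function(n_mirnas = 300L,
                       n_case = 18L,
                       n_control = 6L,
                       frac_de = 0.15,
                       lfc_range = c(1, 4),
                       n_stable = 10L,
                       dispersion = 0.05,
                       lib_size_range = c(2e5, 1e6),
                       ct_noise_sd = 0.25,
                       ct_offset = 12,
                       ct_limit = 35,
                       seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas), n_case = as.integer(n_case),
              n_control = as.integer(n_control), frac_de = frac_de,
              lfc_range = as.numeric(lfc_range), n_stable = as.integer(n_stable),
              dispersion = dispersion, lib_size_range = as.numeric(lib_size_range),
              ct_noise_sd = ct_noise_sd, ct_offset = ct_offset,
              ct_limit = ct_limit, seed = as.integer(seed))
  if (cfg$n_mirnas < 1L) stop("n_mirnas must be a positive integer")
  if (cfg$n_case < 1L || cfg$n_control < 1L)
    stop("both groups must contain at least one sample")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("frac_de must lie in [0, 1]")
  if (length(cfg$lfc_range) != 2L || cfg$lfc_range[1] <= 0 ||
      diff(cfg$lfc_range) < 0)
    stop("lfc_range must be an increasing pair with a positive lower bound")
  if (cfg$n_stable < 0L) stop("n_stable must be nonnegative")
  if (round(cfg$frac_de * cfg$n_mirnas) + cfg$n_stable > cfg$n_mirnas)
    stop("frac_de * n_mirnas + n_stable exceeds n_mirnas")
  if (cfg$dispersion < 0) stop("dispersion must be nonnegative")
  if (length(cfg$lib_size_range) != 2L || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0)
    stop("lib_size_range must be an increasing pair of positive sizes")
  if (cfg$ct_noise_sd < 0) stop("ct_noise_sd must be nonnegative")
  class(cfg) <- "sim_config"
  cfg
}

# Draw NB counts with mean mu and dispersion alpha (variance mu + alpha mu^2).
# alpha below 1e-8 degenerates to Poisson, matching the dispersion -> 0 limit.
rnb <- function(n, mu, alpha) {
  poisson_like <- alpha < 1e-8
  out <- numeric(n)
  if (any(poisson_like)) out[poisson_like] <- stats::rpois(sum(poisson_like),
                                                           mu[poisson_like])
  if (any(!poisson_like))
    out[!poisson_like] <- stats::rnbinom(sum(!poisson_like),
                                         mu = mu[!poisson_like],
                                         size = 1 / alpha[!poisson_like])
  out
}

#' Simulate a miRNA count matrix with known truth
#'
#' Draws a miRNA-by-sample count matrix of negative-binomial counts with
#' log-uniform per-sample library sizes. A configurable fraction of miRNAs
#' carries a planted log2 fold change between case and control group means
#' (random sign); a planted stable subset has identical group means and
#' minimal extra-Poisson noise, emulating good endogenous normalizers.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return a list with components
#'   \item{counts}{a \code{\link{count_matrix}}: integer counts with sample
#'     group labels,}
#'   \item{truth}{a data frame (the truth table) with one row per miRNA:
#'     \code{mirna_id}, \code{base_mean}, \code{true_log2fc}, \code{is_de},
#'     \code{is_stable}, \code{dispersion}.}
#' @examples
#' sim <- simulate_counts(sim_config(n_mirnas = 40, seed = 7))
#' dim(sim$counts$counts)
#' table(sim$truth$is_de, sim$truth$is_stable)
#' @seealso \code{\link{simulate_ct}} for the matched qPCR layer.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_mirnas
  n_de <- as.integer(round(config$frac_de * G))
  n_stable <- config$n_stable

  mirna_ids <- sprintf("miR-sim%03d", seq_len(G))
  sample_ids <- c(sprintf("case%02d", seq_len(config$n_case)),
                  sprintf("ctrl%02d", seq_len(config$n_control)))
  groups <- rep(c("case", "control"), c(config$n_case, config$n_control))

  # abundance spectrum: log-normal base means on the relative scale
  base_mean <- exp(stats::rnorm(G, mean = log(50), sd = 1.5))

  # DE is planted on sub-75th-percentile-abundance miRNAs with sign-balanced
  # fold changes so the library composition stays essentially unchanged
  # (small-RNA libraries are dominated by a few constitutive miRNAs that a
  # biomarker-scale perturbation leaves intact); planted normalizers come
  # from the above-median stratum, where real endogenous controls live
  eligible_de <- which(base_mean <= stats::quantile(base_mean, 0.75))
  if (length(eligible_de) < n_de) eligible_de <- seq_len(G)
  de_idx <- sample(eligible_de, n_de)
  eligible_st <- setdiff(which(base_mean >= stats::median(base_mean)), de_idx)
  if (length(eligible_st) < n_stable)
    eligible_st <- setdiff(seq_len(G), de_idx)
  stable_idx <- if (n_stable > 0L) sample(eligible_st, n_stable) else integer(0)

  true_log2fc <- numeric(G)
  if (n_de > 0L)
    true_log2fc[de_idx] <- sample(rep_len(c(-1, 1), n_de)) *
      stats::runif(n_de, config$lfc_range[1], config$lfc_range[2])

  # per-miRNA dispersions: log-normal scatter around the global value;
  # planted stable miRNAs get near-Poisson noise (below-median variance)
  alpha <- config$dispersion * exp(stats::rnorm(G, 0, 0.3))
  alpha[stable_idx] <- min(1e-4, config$dispersion / 100)

  lib_sizes <- exp(stats::runif(length(sample_ids),
                                log(config$lib_size_range[1]),
                                log(config$lib_size_range[2])))

  # expected per-group relative proportions; case means scaled by 2^lfc
  mu_control <- base_mean
  mu_case <- base_mean * 2^true_log2fc
  prop_control <- mu_control / sum(mu_control)
  prop_case <- mu_case / sum(mu_case)

  counts <- matrix(0, nrow = G, ncol = length(sample_ids),
                   dimnames = list(mirna_ids, sample_ids))
  for (s in seq_along(sample_ids)) {
    prop <- if (groups[s] == "case") prop_case else prop_control
    counts[, s] <- rnb(G, mu = prop * lib_sizes[s], alpha = alpha)
  }
  storage.mode(counts) <- "integer"

  truth <- data.frame(mirna_id = mirna_ids, base_mean = base_mean,
                      true_log2fc = true_log2fc,
                      is_de = seq_len(G) %in% de_idx,
                      is_stable = seq_len(G) %in% stable_idx,
                      dispersion = alpha, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, groups), truth = truth)
}

#' Simulate qPCR CT values from a simulation truth table
#'
#' Generates a long-format CT table for the assays of a panel. Each sample's
#' CT is \code{ct_offset - log2(relative abundance) + N(0, ct_noise_sd)},
#' where relative abundance is the miRNA's expected proportion of the
#' library in that sample's group — qPCR input mass is fixed, so CT is
#' depth-independent. CT values beyond \code{ct_limit} are flagged
#' undetermined (value retained for inspection, excluded downstream).
#'
#' @param truth truth table from \code{\link{simulate_counts}}.
#' @param config the same \code{\link{sim_config}}.
#' @param panel a \code{\link{panel_config}}; its target and reference
#'   assays must be simulated miRNAs. Reference assays not flagged stable in
#'   the truth table trigger a warning (useful for bad-normalizer
#'   experiments, but not the intended design).
#' @return a \code{ct_table} data frame with columns \code{sample_id},
#'   \code{group}, \code{assay_id}, \code{ct}, \code{undetermined}.
#' @examples
#' cfg <- sim_config(n_mirnas = 30, n_stable = 3, seed = 2)
#' sim <- simulate_counts(cfg)
#' pan <- panel_config(targets = sim$truth$mirna_id[sim$truth$is_de][1:3],
#'                     references = sim$truth$mirna_id[sim$truth$is_stable])
#' ct <- simulate_ct(sim$truth, cfg, pan)
#' head(ct)
#' @export
simulate_ct <- function(truth, config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "panel_config"))
  assays <- c(panel$targets, panel$references)
  missing_assays <- setdiff(assays, truth$mirna_id)
  if (length(missing_assays))
    stop("panel assays absent from the simulation: ",
         paste(missing_assays, collapse = ", "))
  bad_refs <- panel$references[!truth$is_stable[match(panel$references,
                                                      truth$mirna_id)]]
  if (length(bad_refs))
    warning("reference assays not planted as stable: ",
            paste(bad_refs, collapse = ", "))

  # derive a distinct stream from the count stream so the two layers can be
  # regenerated independently under one seed
  set.seed(config$seed + 1000003L)
  n_case <- config$n_case; n_control <- config$n_control
  sample_ids <- c(sprintf("case%02d", seq_len(n_case)),
                  sprintf("ctrl%02d", seq_len(n_control)))
  groups <- rep(c("case", "control"), c(n_case, n_control))

  mu_case <- truth$base_mean * 2^truth$true_log2fc
  prop <- cbind(case = mu_case / sum(mu_case),
                control = truth$base_mean / sum(truth$base_mean))
  rownames(prop) <- truth$mirna_id

  recs <- expand.grid(sample_id = sample_ids, assay_id = assays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs$group <- groups[match(recs$sample_id, sample_ids)]
  abund <- prop[cbind(recs$assay_id, recs$group)]
  ct <- config$ct_offset - log2(abund) +
    stats::rnorm(nrow(recs), 0, config$ct_noise_sd)
  out <- data.frame(sample_id = recs$sample_id, group = recs$group,
                    assay_id = recs$assay_id, ct = ct,
                    undetermined = ct > config$ct_limit,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$assay_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}
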