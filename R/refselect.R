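#' Filter out differentially expressed miRNAs
#'
#' First stage of normalizer selection: keep miRNAs that show no evidence of
#' differential expression, i.e. FDR strictly greater than the floor.
#'
#' @param de a \code{\link{de_test}} result (or data frame with
#'   \code{mirna_id} and \code{fdr}).
#' @param fdr_floor miRNAs with \code{fdr > fdr_floor} are retained
#'   (strict inequality); default 0.05.
#' @return character vector of retained miRNA IDs.
#' @export
filter_non_de <- function(de, fdr_floor = 0.05) {
  keep <- de$mirna_id[de$fdr > fdr_floor]
  if (length(keep) == 0L)
    stop("no miRNA has FDR > ", fdr_floor,
         "; relax fdr_floor or check the DE input")
  keep
}

#' Rank candidate normalizers by fold-change proximity to one
#'
#' Orders a candidate subset by how close each miRNA's fold change is to 1
#' on the ratio scale, i.e. by |log2 fold change| ascending. Ties are broken
#' by FDR descending (less evidence of change first), then by ID.
#'
#' @param de a \code{\link{de_test}} result.
#' @param subset character vector of candidate miRNA IDs.
#' @return the subset reordered, most change-neutral first.
#' @export
rank_fc_proximity <- function(de, subset) {
  if (length(subset) == 0L) stop("candidate subset is empty")
  idx <- match(subset, de$mirna_id)
  if (anyNA(idx))
    stop("candidates absent from the DE table: ",
         paste(subset[is.na(idx)], collapse = ", "))
  ord <- order(abs(de$log2fc[idx]), -de$fdr[idx], de$mirna_id[idx])
  subset[ord]
}

#' Coefficient-of-variation stability screen
#'
#' Computes mean, sample standard deviation (n-1 denominator) and CV of each
#' candidate's CPM across all samples (both groups pooled) and retains the
#' top 50% most stable — the \code{ceiling(m/2)} candidates with the lowest
#' CV. Candidates with zero mean CPM are dropped with a warning.
#'
#' @param cpm_matrix CPM matrix over all samples (see \code{\link{cpm}}).
#' @param subset character vector of candidate miRNA IDs (length >= 2).
#' @param retain_frac fraction retained at this stage; default 0.5.
#' @return a \code{stability_table} data frame with columns
#'   \code{mirna_id}, \code{mean_cpm}, \code{sd_cpm}, \code{cv},
#'   \code{passed_cv_cut}, ordered by CV ascending.
#' @export
cv_screen <- function(cpm_matrix, subset, retain_frac = 0.5) {
  if (length(subset) < 2L) stop("need at least 2 candidates for the CV screen")
  idx <- match(subset, rownames(cpm_matrix))
  if (anyNA(idx))
    stop("candidates absent from the CPM matrix: ",
         paste(subset[is.na(idx)], collapse = ", "))
  m <- cpm_matrix[idx, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- mu == 0
  if (any(zero)) {
    warning("dropping zero-expression candidates: ",
            paste(subset[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]; mu <- mu[!zero]; sdv <- sdv[!zero]
    subset <- subset[!zero]
  }
  cv <- sdv / mu
  n_keep <- ceiling(length(subset) * retain_frac)
  ord <- order(cv, subset)
  out <- data.frame(mirna_id = subset[ord], mean_cpm = mu[ord],
                    sd_cpm = sdv[ord], cv = cv[ord],
                    passed_cv_cut = seq_along(ord) <= n_keep,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

# case-insensitive ID normalization used when matching exclusion lists
norm_id <- function(x) tolower(trimws(x))

#' Remove cancer-implicated miRNAs from a candidate set
#'
#' Set difference against a user-supplied exclusion list (e.g. miRNAs
#' implicated in cancers by literature review). Matching is
#' case-insensitive after trimming.
#'
#' @param subset candidate miRNA IDs.
#' @param exclusion_list IDs to exclude; may be empty.
#' @return list with \code{kept} (surviving IDs, input order) and
#'   \code{hits} (excluded IDs as given in \code{subset}).
#' @export
apply_exclusion <- function(subset, exclusion_list = character(0)) {
  hit <- norm_id(subset) %in% norm_id(exclusion_list)
  list(kept = subset[!hit], hits = subset[hit])
}

#' Multi-step endogenous normalizer selection
#'
#' Composes the full selection strategy on a sequencing dataset:
#' \enumerate{
#'   \item drop miRNAs differentially expressed at FDR <= \code{fdr_floor},
#'   \item rank survivors by fold-change proximity to 1,
#'   \item CV screen on the all-sample CPM matrix, retaining the most stable
#'     half,
#'   \item exclude cancer-implicated IDs,
#' }
#' then report the top \code{n} survivors by CV as the proposed normalizer
#' set. Per-stage survivor counts are recorded for auditability.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param de matching \code{\link{de_test}} result.
#' @param exclusion_list character vector of IDs to exclude (default none).
#' @param n normalizers requested; default 3, the customary trio.
#' @param fdr_floor,retain_frac stage parameters (defaults 0.05 and 0.5).
#' @return an object of class \code{"normalizer_report"}: list with
#'   \code{candidates} (selected IDs, most stable first), \code{n_requested},
#'   \code{stage_counts}, \code{exclusion_hits} and the full
#'   \code{stability} table.
#' @examples
#' sim <- simulate_counts(sim_config(n_mirnas = 80, n_case = 6,
#'                                   n_control = 6, n_stable = 6, seed = 4))
#' de <- de_test(sim$counts)
#' select_normalizers(sim$counts, de)
#' @export
select_normalizers <- function(counts, de, exclusion_list = character(0),
                               n = 3L, fdr_floor = 0.05, retain_frac = 0.5) {
  x <- as_counts(counts)
  if (!setequal(de$mirna_id, rownames(x$counts)))
    stop("DE table and count matrix cover different miRNA sets")
  stage1 <- filter_non_de(de, fdr_floor)
  stage2 <- rank_fc_proximity(de, stage1)
  stab <- cv_screen(cpm(x), stage2, retain_frac)
  stage3 <- stab$mirna_id[stab$passed_cv_cut]
  excl <- apply_exclusion(stage3, exclusion_list)
  survivors <- excl$kept                       # already CV-ordered
  if (length(survivors) < n)
    warning(sprintf("only %d survivors for %d requested normalizers",
                    length(survivors), n))
  out <- list(candidates = utils::head(survivors, n),
              n_requested = as.integer(n),
              stage_counts = c(total = nrow(de),
                               non_de = length(stage1),
                               cv_retained = length(stage3),
                               after_exclusion = length(survivors)),
              exclusion_hits = excl$hits,
              stability = stab)
  class(out) <- "normalizer_report"
  out
}

#' @export
print.normalizer_report <- function(x, ...) {
  cat("Endogenous normalizer selection\n")
  sc <- x$stage_counts
  cat(sprintf("  %d miRNAs -> %d non-DE -> %d after CV screen -> %d after exclusion\n",
              sc["total"], sc["non_de"], sc["cv_retained"],
              sc["after_exclusion"]))
  if (length(x$exclusion_hits))
    cat("  excluded:", paste(x$exclusion_hits, collapse = ", "), "\n")
  cat(sprintf("  selected (%d of %d requested): %s\n",
              length(x$candidates), x$n_requested,
              paste(x$candidates, collapse = ", ")))
  invisible(x)
}
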