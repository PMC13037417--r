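#' Construct a two-group miRNA count matrix
#'
#' Thin validated container tying an integer miRNA-by-sample count matrix to
#' per-sample case/control labels.
#'
#' @param counts nonnegative integer matrix, miRNAs in rows (rownames = IDs),
#'   samples in columns (colnames = IDs).
#' @param groups character vector of \code{"case"}/\code{"control"}, one per
#'   column, or a named vector matched against column names.
#' @return an object of class \code{"count_matrix"}: a list with
#'   \code{counts} and \code{groups}.
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate miRNA IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("need one group label per sample")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (any(table(factor(groups, c("case", "control"))) < 2))
    stop("each group needs at least 2 samples")
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

as_counts <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  stop("expected a count_matrix; see count_matrix() or read_count_matrix()")
}

#' Counts per million
#'
#' Library-size normalization: each count divided by its sample's column sum,
#' times 1e6. Every CPM column sums to 1e6.
#'
#' @param counts a \code{\link{count_matrix}} or bare numeric matrix.
#' @return numeric matrix of CPM values with the input dimnames.
#' @examples
#' m <- matrix(c(500, 999500, 2, 999998), 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' cpm(m)["a", "s1"]   # 500
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  lib <- colSums(m)
  zero <- lib <= 0
  if (any(zero))
    stop("zero-depth sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  sweep(m, 2, lib, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over
#' miRNAs with all-positive counts of that sample's count divided by the
#' miRNA's geometric mean across samples. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts a \code{\link{count_matrix}} or numeric matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no miRNA has positive counts in every sample; filter low-count ",
         "samples or miRNAs first")
  logm <- log(m[pos, , drop = FALSE])
  logratio <- logm - rowMeans(logm)
  sf <- exp(apply(logratio, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (clipped at 1, monotone over the sorted input,
#' returned in input order). Wraps \code{stats::p.adjust} after validating
#' the input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression test for miRNA counts
#'
#' A simplified negative-binomial two-group test on size-factor-normalized
#' counts. The log2 fold change is the log-ratio of normalized group means
#' (pseudocount 0.5). With \code{method = "wald"}, a per-miRNA dispersion is
#' estimated by method of moments (floored at 1e-8), the standard error of
#' the log2 fold change follows from the delta method, and the two-sided
#' p-value uses a t reference with \code{n_case + n_control - 2} degrees of
#' freedom (a small-sample calibration of the Wald statistic). With
#' \code{method = "permutation"}, the same statistic is referred to its
#' group-label permutation distribution.
#'
#' Calls use the volcano-style rule: up if \code{log2fc >= lfc_cut} and
#' \code{fdr < fdr_cut}; down if \code{log2fc <= -lfc_cut} and
#' \code{fdr < fdr_cut}; otherwise ns.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param method \code{"wald"} (default) or \code{"permutation"}.
#' @param n_perm number of label permutations for the permutation method;
#'   fewer than 100 triggers a warning.
#' @param lfc_cut,fdr_cut calling thresholds; defaults are |log2FC| >= 1 and
#'   FDR < 0.01.
#' @return an object of class \code{"mirde"}: a data frame with one row per
#'   miRNA and columns \code{mirna_id}, \code{base_mean} (normalized mean),
#'   \code{log2fc}, \code{p}, \code{fdr}, \code{call}, plus attributes
#'   recording the method and thresholds.
#' @examples
#' sim <- simulate_counts(sim_config(n_mirnas = 60, n_case = 6,
#'                                   n_control = 6, seed = 3))
#' de <- de_test(sim$counts)
#' summary(de)
#' @export
de_test <- function(counts, method = c("wald", "permutation"),
                    n_perm = 1000L, lfc_cut = 1, fdr_cut = 0.01) {
  x <- as_counts(counts)
  method <- match.arg(method)
  groups <- x$groups
  if (any(table(factor(groups, c("case", "control"))) < 2))
    stop("each group needs at least 2 samples")
  sf <- size_factors(x)
  norm <- sweep(x$counts, 2, sf, "/")
  is_case <- groups == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)

  stat_fun <- function(case_cols) {
    m1 <- rowMeans(norm[, case_cols, drop = FALSE])
    m2 <- rowMeans(norm[, !case_cols, drop = FALSE])
    lfc <- log2(m1 + 0.5) - log2(m2 + 0.5)
    # pooled method-of-moments NB dispersion: alpha = (var - mu) / mu^2
    v1 <- apply(norm[, case_cols, drop = FALSE], 1, stats::var)
    v2 <- apply(norm[, !case_cols, drop = FALSE], 1, stats::var)
    mu <- (m1 * sum(case_cols) + m2 * sum(!case_cols)) / length(case_cols)
    vpool <- (v1 * (sum(case_cols) - 1) + v2 * (sum(!case_cols) - 1)) /
      (length(case_cols) - 2)
    alpha <- pmax((vpool - mu) / pmax(mu, 1e-8)^2, 1e-8)
    # delta method: var(log2(mean_g + 0.5)) = var(mean_g) / ((mean_g+.5) ln2)^2
    vm1 <- (m1 + alpha * m1^2) / sum(case_cols)
    vm2 <- (m2 + alpha * m2^2) / sum(!case_cols)
    se <- sqrt(vm1 / ((m1 + 0.5) * log(2))^2 + vm2 / ((m2 + 0.5) * log(2))^2)
    list(lfc = lfc, z = lfc / pmax(se, 1e-12))
  }

  obs <- stat_fun(is_case)
  base_mean <- rowMeans(norm)
  if (method == "wald") {
    p <- 2 * stats::pt(-abs(obs$z), df = n1 + n2 - 2)
  } else {
    n_perm <- as.integer(n_perm)
    if (n_perm < 100L) warning("fewer than 100 permutations; p-values coarse")
    exceed <- rep(0L, nrow(norm))
    for (b in seq_len(n_perm)) {
      perm <- sample(is_case)
      exceed <- exceed + (abs(stat_fun(perm)$z) >= abs(obs$z))
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  fdr <- bh_adjust(p)
  call <- rep("ns", nrow(norm))
  call[obs$lfc >= lfc_cut & fdr < fdr_cut] <- "up"
  call[obs$lfc <= -lfc_cut & fdr < fdr_cut] <- "down"

  out <- data.frame(mirna_id = rownames(x$counts), base_mean = base_mean,
                    log2fc = obs$lfc, p = p, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "lfc_cut") <- lfc_cut
  attr(out, "fdr_cut") <- fdr_cut
  class(out) <- c("mirde", "data.frame")
  out
}

#' @export
print.mirde <- function(x, ...) {
  cat(sprintf("Two-group miRNA differential expression (%s test)\n",
              attr(x, "method")))
  cat(sprintf("%d miRNAs; thresholds |log2FC| >= %g, FDR < %g\n",
              nrow(x), attr(x, "lfc_cut"), attr(x, "fdr_cut")))
  tab <- table(factor(x$call, c("up", "down", "ns")))
  cat(sprintf("calls: %d up, %d down, %d ns\n", tab["up"], tab["down"],
              tab["ns"]))
  invisible(x)
}

#' @export
summary.mirde <- function(object, ...) {
  sig <- object[object$call != "ns", , drop = FALSE]
  sig <- sig[order(sig$fdr, -abs(sig$log2fc)), , drop = FALSE]
  print.mirde(object)
  if (nrow(sig)) {
    cat("\nTop calls:\n")
    print(utils::head(as.data.frame(sig), 10), digits = 3, row.names = FALSE)
  }
  invisible(sig)
}

#' Rank DE miRNAs for a validation panel
#'
#' Composite ranking of called miRNAs for qPCR follow-up: the mean of the
#' rank by |log2 fold change| (descending) and the rank by FDR (ascending),
#' optionally tie-broken by a pathway-annotation count, then
#' lexicographically by ID so the order is deterministic.
#'
#' @param de a \code{\link{de_test}} result.
#' @param k number of candidates wanted; if more than the number of called
#'   miRNAs, all are returned with a warning.
#' @param pathway_weight optional named numeric vector (miRNA ID ->
#'   annotation count) used as a tie-break, higher first.
#' @return character vector of miRNA IDs, best candidate first.
#' @export
rank_candidates <- function(de, k, pathway_weight = NULL) {
  called <- de[de$call != "ns", , drop = FALSE]
  if (nrow(called) == 0L) {
    warning("no miRNAs called; returning empty candidate list")
    return(character(0))
  }
  r_fc <- rank(-abs(called$log2fc), ties.method = "average")
  r_fdr <- rank(called$fdr, ties.method = "average")
  comp <- (r_fc + r_fdr) / 2
  pw <- if (is.null(pathway_weight)) rep(0, nrow(called)) else {
    w <- pathway_weight[called$mirna_id]
    ifelse(is.na(w), 0, w)
  }
  ord <- order(comp, -pw, called$mirna_id)
  ids <- called$mirna_id[ord]
  if (k > length(ids)) {
    warning(sprintf("requested %d candidates but only %d called; returning all",
                    k, length(ids)))
    return(ids)
  }
  ids[seq_len(k)]
}
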