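#' GeNorm stability M values
#'
#' For each candidate reference gene j, the pairwise variation with another
#' gene k is the sample standard deviation (n-1 denominator) over samples of
#' \code{log2(q_j / q_k)}; the stability measure M_j is the mean of these
#' pairwise variations over all k != j. Lower M means more stable. M is
#' invariant to per-sample global scaling, so CPM, relative quantities or
#' \code{2^(-CT)} inputs are all acceptable.
#'
#' @param expr strictly positive numeric matrix, genes in rows, samples in
#'   columns (>= 2 genes, >= 2 samples; >= 3 genes for a meaningful M).
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (any(expr <= 0) || any(!is.finite(expr)))
    stop("expression quantities must be strictly positive and finite; ",
         "apply a pseudocount upstream")
  lg <- log2(expr)
  G <- nrow(expr)
  V <- matrix(0, G, G)
  for (j in seq_len(G - 1)) for (k in (j + 1):G) {
    V[j, k] <- V[k, j] <- stats::sd(lg[j, ] - lg[k, ])
  }
  m <- rowSums(V) / (G - 1)
  names(m) <- rownames(expr)
  m
}

#' GeNorm stability analysis
#'
#' Full GeNorm evaluation of candidate reference genes: M values, a
#' stability ranking by iterative exclusion of the least stable gene, and
#' the pairwise-variation curve V(n, n+1) used to decide how many reference
#' genes suffice.
#'
#' The ranking repeatedly removes the gene with the highest M (ties broken
#' by ID, reverse-alphabetical removed first so earlier IDs rank better) and
#' recomputes M on the remainder until two genes are left; those two share
#' rank 1. V(n, n+1) is the standard deviation over samples of
#' \code{log2(NF_n / NF_(n+1))}, where NF_n is the per-sample geometric mean
#' of the top-n genes. The recommended number of references is the smallest
#' n with \code{V(n, n+1) < v_cut} (strict); if no n qualifies, all genes
#' are recommended with a warning.
#'
#' @param expr strictly positive matrix (genes x samples), or a
#'   \code{ct_table} via \code{\link{ct_to_expression}}.
#' @param v_cut pairwise-variation threshold; 0.15 by convention.
#' @return an object of class \code{"genorm_fit"}: list with
#'   \code{m_values} (input order), \code{ranking} (data frame
#'   \code{gene}, \code{rank}), \code{v_curve} (named vector, entries
#'   \code{"V2/3"}, ...), \code{recommended_n}, \code{v_cut}.
#' @examples
#' set.seed(1)
#' q <- 2^matrix(rnorm(24, 5, 0.2), 4, 6,
#'               dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' fit <- genorm(q)
#' fit$recommended_n
#' @export
genorm <- function(expr, v_cut = 0.15) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  m_all <- genorm_m(expr)
  ranking <- rank_by_stability(expr)
  pv <- pairwise_variation(expr, ranking$gene[order(ranking$rank,
                                                    ranking$gene)],
                           v_cut = v_cut)
  out <- list(m_values = m_all, ranking = ranking, v_curve = pv$v_curve,
              recommended_n = pv$recommended_n, v_cut = v_cut)
  class(out) <- "genorm_fit"
  out
}

#' Rank reference genes by iterative GeNorm exclusion
#'
#' @param expr strictly positive matrix (genes x samples).
#' @return data frame with columns \code{gene} and \code{rank}; the final
#'   two genes share rank 1.
#' @export
rank_by_stability <- function(expr) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  genes <- rownames(expr)
  if (length(genes) < 3L)
    return(data.frame(gene = sort(genes), rank = rep(1L, length(genes)),
                      stringsAsFactors = FALSE))
  remaining <- expr
  removed <- character(0)
  while (nrow(remaining) > 2L) {
    m <- genorm_m(remaining)
    # worst first; among ties drop the later ID so earlier IDs rank better
    worst <- names(m)[order(-m, rownames(remaining),
                            decreasing = c(FALSE, TRUE),
                            method = "radix")][1]
    removed <- c(worst, removed)
    remaining <- remaining[setdiff(rownames(remaining), worst), , drop = FALSE]
  }
  out <- data.frame(gene = c(sort(rownames(remaining)), removed),
                    rank = c(1L, 1L, seq_along(removed) + 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' GeNorm pairwise-variation curve
#'
#' @param expr strictly positive matrix (genes x samples).
#' @param ranking gene IDs ordered most stable first (e.g. from
#'   \code{\link{rank_by_stability}}).
#' @param v_cut threshold for the recommended number of references.
#' @return list with \code{v_curve} (named numeric, \code{"V2/3"} ...) and
#'   \code{recommended_n}.
#' @export
pairwise_variation <- function(expr, ranking, v_cut = 0.15) {
  expr <- as.matrix(expr)
  G <- length(ranking)
  if (G < 3L) {
    warning("fewer than 3 genes: pairwise-variation curve is empty")
    return(list(v_curve = stats::setNames(numeric(0), character(0)),
                recommended_n = 2L))
  }
  lg <- log2(expr[ranking, , drop = FALSE])
  v <- numeric(G - 2)
  for (n in 2:(G - 1)) {
    nf_n <- colMeans(lg[seq_len(n), , drop = FALSE])        # log2 geomean
    nf_n1 <- colMeans(lg[seq_len(n + 1), , drop = FALSE])
    v[n - 1] <- stats::sd(nf_n - nf_n1)
  }
  names(v) <- sprintf("V%d/%d", 2:(G - 1), 3:G)
  below <- which(v < v_cut)
  if (length(below)) {
    recommended_n <- below[1] + 1L
  } else {
    warning("no V(n, n+1) below ", v_cut,
            "; recommending all ", G, " genes")
    recommended_n <- G
  }
  list(v_curve = v, recommended_n = as.integer(recommended_n))
}

#' Convert a CT table to a linear expression matrix
#'
#' Maps CT values to relative quantities \code{2^(-CT)} (100% amplification
#' efficiency; per-assay efficiencies may be supplied, quantity =
#' \code{(1 + efficiency)^(-CT)}). Undetermined CTs become NA and any assay
#' or sample containing NA is unusable for GeNorm, so complete cases over
#' the requested assays are required.
#'
#' @param ct a \code{ct_table} data frame.
#' @param assays assays to include (default all).
#' @param efficiency single value or named per-assay vector of amplification
#'   efficiencies (1 = perfect doubling).
#' @return numeric matrix, assays in rows, samples in columns.
#' @export
ct_to_expression <- function(ct, assays = unique(ct$assay_id),
                             efficiency = 1) {
  ct <- ct[ct$assay_id %in% assays & !ct$undetermined, , drop = FALSE]
  eff <- if (length(efficiency) == 1L && is.null(names(efficiency)))
    stats::setNames(rep(efficiency, length(assays)), assays) else efficiency[assays]
  q <- (1 + eff[ct$assay_id])^(-ct$ct)
  m <- tapply(q, list(ct$assay_id, ct$sample_id), mean)
  if (anyNA(m))
    stop("undetermined or missing CT values leave gaps; GeNorm needs ",
         "complete assay x sample coverage")
  m[assays, , drop = FALSE]
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("GeNorm reference-gene stability\n")
  ord <- order(x$m_values)
  cat("  M values (stable first):\n")
  for (i in ord)
    cat(sprintf("    %-12s %.4f\n", names(x$m_values)[i], x$m_values[i]))
  if (length(x$v_curve)) {
    cat("  pairwise variation:",
        paste(sprintf("%s=%.4f", names(x$v_curve), x$v_curve),
              collapse = "  "), "\n")
  }
  cat(sprintf("  recommended number of references (V < %g): %d\n",
              x$v_cut, x$recommended_n))
  invisible(x)
}

#' @export
plot.genorm_fit <- function(x, ...) {
  if (!length(x$v_curve)) {
    warning("nothing to plot: empty V curve")
    return(invisible(x))
  }
  graphics::barplot(x$v_curve, ylab = "Pairwise variation V(n, n+1)",
                    xlab = "Number of reference genes", ...)
  graphics::abline(h = x$v_cut, lty = 2)
  invisible(x)
}
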