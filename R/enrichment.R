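#' Score-filter a miRNA target table
#'
#' Extracts the unique union of predicted target genes whose prediction
#' score passes the cutoff (inclusive). Scores follow the 0-100 convention
#' of target-prediction databases; the customary confidence cutoff is 60.
#'
#' @param targets data frame with columns \code{mirna_id},
#'   \code{gene_symbol}, \code{target_score}.
#' @param score_min minimum score retained (inclusive); default 60.
#' @return character vector of unique gene symbols (upper-cased).
#' @export
filter_targets <- function(targets, score_min = 60) {
  need <- c("mirna_id", "gene_symbol", "target_score")
  if (!all(need %in% names(targets)))
    stop("target table needs columns: ", paste(need, collapse = ", "))
  if (any(targets$target_score < 0 | targets$target_score > 100))
    stop("target scores must lie in [0, 100]")
  genes <- unique(toupper(targets$gene_symbol[targets$target_score >= score_min]))
  if (length(genes) == 0L)
    warning("no targets pass score >= ", score_min)
  genes
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list against
#' a background universe. For a set with K members in a universe of N genes
#' and a query of n genes overlapping the set in k, the p-value is the
#' upper-tail hypergeometric probability P(X >= k) and fold enrichment is
#' (k/n) / (K/N). P-values are BH-adjusted across sets.
#'
#' Gene symbols are upper-cased before matching. Query genes outside the
#' universe are dropped with a message; set members outside the universe are
#' dropped likewise. Sets smaller than \code{min_size} or larger than
#' \code{max_size} after harmonization are skipped.
#'
#' @param query character vector of gene symbols.
#' @param sets named list of gene-symbol vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe background gene symbols; default is the union of all set
#'   genes, with a warning that this differs from a genome-wide background.
#' @param min_size,max_size set-size bounds applied after harmonization
#'   (defaults 2 and 2000).
#' @return an \code{enrichment_table} data frame sorted by FDR then fold
#'   enrichment (descending): \code{set}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{fold_enrichment}, \code{p}, \code{fdr}, \code{genes}
#'   (semicolon-joined overlap).
#' @examples
#' sets <- list(SetA = c("G1", "G2", "G3"), SetB = c("G4", "G5"))
#' ora_test(c("G1", "G2"), sets, universe = paste0("G", 1:20))
#' @export
ora_test <- function(query, sets, universe = NULL,
                     min_size = 2L, max_size = 2000L) {
  if (length(sets) == 0L || is.null(names(sets)))
    stop("sets must be a nonempty named list")
  sets <- lapply(sets, toupper)
  if (is.null(universe)) {
    warning("no universe supplied; using the union of all set genes, which ",
            "differs from a genome-wide background")
    universe <- unique(unlist(sets, use.names = FALSE))
  }
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(toupper(query))
  if (length(query) == 0L) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside))
    message(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (length(query) == 0L) stop("no query genes in the universe")

  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    if (K < min_size || K > max_size) return(NULL)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no gene set within the size bounds after harmonization")
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$fdr, -out$fold_enrichment, out$set), ,
             drop = FALSE]
  out <- out[, c("set", "k", "n", "K", "N", "fold_enrichment", "p", "fdr",
                 "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Simulate a plausible miRNA target-prediction table
#'
#' Emits a score-distributed target table for a set of miRNAs over a gene
#' universe, for exercising the target-filtering and enrichment stages:
#' each miRNA receives a random number of predicted targets with scores
#' spread over 40-100 so the score cutoff is consequential.
#'
#' @param mirnas miRNA IDs.
#' @param genes gene-symbol universe to draw targets from.
#' @param mean_targets average predicted targets per miRNA.
#' @param seed integer seed.
#' @return data frame with \code{mirna_id}, \code{gene_symbol},
#'   \code{target_score}.
#' @export
simulate_targets <- function(mirnas, genes, mean_targets = 30, seed = 1L) {
  set.seed(seed)
  rows <- lapply(mirnas, function(m) {
    k <- min(length(genes), max(1L, stats::rpois(1, mean_targets)))
    data.frame(mirna_id = m, gene_symbol = sample(genes, k),
               target_score = round(stats::runif(k, 40, 100), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("mirna_id", "gene_symbol")]), , drop = FALSE]
}
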