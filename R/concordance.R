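#' Summarize a qPCR validation run
#'
#' Counts of validated (non-ns), up- and down-classified assays.
#'
#' @param results a \code{\link{ddct_quantify}} result, or any data frame
#'   with a \code{class} column of \code{"up"}/\code{"down"}/\code{"ns"}.
#' @return named integer vector \code{c(n_validated, n_up, n_down)}.
#' @examples
#' tab <- hsa_qpcr_table("splenic")
#' summarize_validation(tab)   # 13 validated: 5 up, 8 down
#' @export
summarize_validation <- function(results) {
  cls <- factor(results$class, c("up", "down", "ns"))
  tab <- table(cls)
  c(n_validated = sum(tab[c("up", "down")]),
    n_up = unname(tab["up"]), n_down = unname(tab["down"]))
}

#' Signed-set overlap between two miRNA call sets
#'
#' Partitions two sets of signed calls (direction "up"/"down" per ID) into
#' concordant (shared ID, same direction), discordant (shared ID, opposite
#' direction) and platform-unique IDs — the Venn-with-directions view used
#' to compare validation runs across tissues or platforms.
#'
#' @param set_a,set_b data frames with columns \code{mirna_id} and
#'   \code{direction} (\code{"up"}/\code{"down"}), e.g. the significant rows
#'   of two validation runs.
#' @return an object of class \code{"comparison_report"}: list with
#'   \code{concordant}, \code{discordant}, \code{unique_a}, \code{unique_b}
#'   (ID vectors), \code{shared} (data frame with both directions), and
#'   counts.
#' @examples
#' a <- hsa_qpcr_table("splenic"); b <- hsa_qpcr_table("cardiac")
#' sig <- function(x) data.frame(mirna_id = x$mirna_id[x$class != "ns"],
#'                               direction = x$class[x$class != "ns"])
#' overlap_sets(sig(a), sig(b))
#' @export
overlap_sets <- function(set_a, set_b) {
  for (s in list(set_a, set_b)) {
    if (anyDuplicated(s$mirna_id))
      stop("duplicate IDs within a set: ",
           paste(unique(s$mirna_id[duplicated(s$mirna_id)]), collapse = ", "))
    if (!all(s$direction %in% c("up", "down")))
      stop("directions must be 'up' or 'down'")
  }
  shared_ids <- sort(intersect(set_a$mirna_id, set_b$mirna_id))
  dir_a <- set_a$direction[match(shared_ids, set_a$mirna_id)]
  dir_b <- set_b$direction[match(shared_ids, set_b$mirna_id)]
  shared <- data.frame(mirna_id = shared_ids, direction_a = dir_a,
                       direction_b = dir_b,
                       concordant = dir_a == dir_b, stringsAsFactors = FALSE)
  out <- list(concordant = shared_ids[shared$concordant],
              discordant = shared_ids[!shared$concordant],
              unique_a = sort(setdiff(set_a$mirna_id, shared_ids)),
              unique_b = sort(setdiff(set_b$mirna_id, shared_ids)),
              shared = shared,
              counts = c(n_a = nrow(set_a), n_b = nrow(set_b),
                         n_shared = length(shared_ids),
                         n_concordant = sum(shared$concordant),
                         n_discordant = sum(!shared$concordant)))
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("Signed-set comparison: %d vs %d calls, %d shared\n",
              ct["n_a"], ct["n_b"], ct["n_shared"]))
  cat(sprintf("  concordant (%d): %s\n", ct["n_concordant"],
              paste(x$concordant, collapse = ", ")))
  cat(sprintf("  discordant (%d): %s\n", ct["n_discordant"],
              paste(x$discordant, collapse = ", ")))
  cat(sprintf("  unique: %d / %d\n", length(x$unique_a), length(x$unique_b)))
  invisible(x)
}

#' Direction concordance between sequencing and qPCR calls
#'
#' Over miRNAs significant on both platforms, the fraction whose sequencing
#' log2 fold change and qPCR fold regulation point the same way.
#'
#' @param de a \code{\link{de_test}} result (sequencing calls).
#' @param qpcr a \code{\link{ddct_quantify}} result; its \code{assay_id}
#'   values must use the same IDs as the DE table.
#' @return list with \code{fraction} (NA when no miRNA is significant on
#'   both platforms) and \code{table}, a per-ID data frame over the ID
#'   intersection with both calls and a \code{concordant} flag (NA unless
#'   both significant).
#' @export
direction_concordance <- function(de, qpcr) {
  ids <- intersect(de$mirna_id, qpcr$assay_id)
  if (length(ids) == 0L)
    stop("no shared IDs between sequencing and qPCR results")
  d <- de[match(ids, de$mirna_id), , drop = FALSE]
  q <- qpcr[match(ids, qpcr$assay_id), , drop = FALSE]
  both_sig <- d$call != "ns" & q$class != "ns"
  conc <- ifelse(both_sig, d$call == q$class, NA)
  tab <- data.frame(mirna_id = ids, seq_call = d$call,
                    seq_log2fc = d$log2fc, qpcr_class = q$class,
                    qpcr_fr = q$fold_regulation, concordant = conc,
                    stringsAsFactors = FALSE)
  frac <- if (any(both_sig)) mean(conc[both_sig]) else NA_real_
  list(fraction = frac, table = tab)
}
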