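#' qPCR panel definition
#'
#' Describes a custom qPCR plate: target assays, endogenous reference
#' (normalizer) assays, and technical spike/control assays (recorded but
#' not used in quantification).
#'
#' @param targets character vector of target assay IDs.
#' @param references character vector of reference assay IDs (>= 1).
#' @param controls character vector of technical control assay IDs.
#' @return an object of class \code{"panel_config"}.
#' @export
panel_config <- function(targets, references, controls = character(0)) {
  targets <- as.character(targets); references <- as.character(references)
  if (length(references) < 1L) stop("at least one reference assay required")
  if (length(intersect(targets, references)))
    stop("targets and references overlap: ",
         paste(intersect(targets, references), collapse = ", "))
  if (anyDuplicated(targets) || anyDuplicated(references))
    stop("duplicate assay IDs within a role")
  structure(list(targets = targets, references = references,
                 controls = as.character(controls)),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("qPCR panel: %d targets, %d references, %d controls\n",
              length(x$targets), length(x$references), length(x$controls)))
  cat("  references:", paste(x$references, collapse = ", "), "\n")
  invisible(x)
}

# average technical replicates per (sample, assay); NA-undetermined rows kept
collapse_replicates <- function(ct) {
  key <- interaction(ct$sample_id, ct$assay_id, drop = TRUE)
  if (!anyDuplicated(key)) return(ct)
  det <- ct[!ct$undetermined, , drop = FALSE]
  dkey <- interaction(det$sample_id, det$assay_id, drop = TRUE)
  mean_ct <- tapply(det$ct, dkey, mean)
  first <- ct[!duplicated(key), , drop = FALSE]
  fkey <- as.character(interaction(first$sample_id, first$assay_id,
                                   drop = TRUE))
  m <- mean_ct[fkey]
  first$ct <- ifelse(is.na(m), first$ct, m)
  first$undetermined <- is.na(m)
  first
}

#' Per-sample delta-CT relative to the reference assays
#'
#' For each sample, the reference level is the arithmetic mean of the
#' determined reference CT values (equivalently the geometric mean of
#' their linear quantities); each target's delta-CT is its CT minus that
#' level. Undetermined target CTs give missing delta-CT; samples with no
#' determined reference are dropped with a warning naming them. Technical
#' replicates are averaged per (sample, assay) first.
#'
#' @param ct a \code{ct_table} data frame (columns \code{sample_id},
#'   \code{group}, \code{assay_id}, \code{ct}, \code{undetermined}).
#' @param panel a \code{\link{panel_config}}.
#' @return data frame with columns \code{sample_id}, \code{group},
#'   \code{assay_id}, \code{dct} (NA where the target was undetermined).
#' @export
delta_ct <- function(ct, panel) {
  stopifnot(inherits(panel, "panel_config"))
  ct <- collapse_replicates(as.data.frame(ct))
  refs <- ct[ct$assay_id %in% panel$references & !ct$undetermined, ,
             drop = FALSE]
  ref_mean <- tapply(refs$ct, refs$sample_id, mean)
  tgt <- ct[ct$assay_id %in% panel$targets, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$sample_id), names(ref_mean))
  if (length(no_ref)) {
    warning("dropping sample(s) with no determined reference CT: ",
            paste(no_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample_id %in% no_ref, , drop = FALSE]
  }
  out <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                    assay_id = tgt$assay_id,
                    dct = ifelse(tgt$undetermined, NA_real_,
                                 tgt$ct - ref_mean[tgt$sample_id]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fold regulation from fold change
#'
#' Signed representation of a fold change: FC itself when FC >= 1, else
#' -1/FC, so magnitudes are always >= 1 and the sign carries direction.
#'
#' @param fc positive fold change(s).
#' @return fold regulation value(s).
#' @export
fold_regulation <- function(fc) ifelse(fc >= 1, fc, -1 / fc)

#' Fold change from fold regulation
#'
#' Inverse of \code{\link{fold_regulation}} on |FR| >= 1.
#' @param fr fold regulation value(s), |fr| >= 1.
#' @return positive fold change(s).
#' @export
fold_change_from_fr <- function(fr) ifelse(fr >= 0, fr, -1 / fr)

#' Delta-delta-CT relative quantification
#'
#' Per target assay: delta-delta-CT is the case-group mean delta-CT minus
#' the control-group mean; fold change is \code{2^(-ddct)}; fold regulation
#' converts FC < 1 to a negative magnitude. The p-value compares per-sample
#' delta-CT between groups by Welch's two-sided t-test (default) or by a
#' label-permutation test on the difference of group means. Targets with
#' fewer than two usable samples in a group are reported with missing p and
#' flagged.
#'
#' @param dct output of \code{\link{delta_ct}}.
#' @param test \code{"welch"} (default) or \code{"permutation"}.
#' @param n_perm permutations when \code{test = "permutation"}.
#' @param fr_cut,p_cut volcano thresholds for the class column (defaults: 2
#'   on fold regulation, 0.05 on p).
#' @return an object of class \code{"qpcr_result"}: data frame with one row
#'   per target — \code{assay_id}, \code{n_case}, \code{n_control},
#'   \code{dct_case_mean}, \code{dct_control_mean}, \code{ddct},
#'   \code{fold_change}, \code{fold_regulation}, \code{p}, \code{class}.
#' @examples
#' ct <- data.frame(
#'   sample_id = rep(c("c1", "c2", "n1", "n2"), each = 2),
#'   group = rep(c("case", "case", "control", "control"), each = 2),
#'   assay_id = rep(c("miR-x", "ref"), 4),
#'   ct = c(23, 20, 23.2, 20, 25, 20, 25.1, 20),
#'   undetermined = FALSE)
#' res <- ddct_quantify(delta_ct(ct, panel_config("miR-x", "ref")))
#' res$fold_change   # about 4: the case group runs ~2 cycles earlier
#' @export
ddct_quantify <- function(dct, test = c("welch", "permutation"),
                          n_perm = 10000L, fr_cut = 2, p_cut = 0.05) {
  test <- match.arg(test)
  dct <- dct[!is.na(dct$dct), , drop = FALSE]
  assays <- unique(dct$assay_id)
  rows <- lapply(assays, function(a) {
    d <- dct[dct$assay_id == a, , drop = FALSE]
    xc <- d$dct[d$group == "case"]; xn <- d$dct[d$group == "control"]
    m1 <- mean(xc); m2 <- mean(xn)
    ddct <- m1 - m2
    fc <- 2^(-ddct)
    p <- NA_real_
    if (length(xc) >= 2L && length(xn) >= 2L) {
      if (test == "welch") {
        p <- tryCatch(stats::t.test(xc, xn)$p.value, error = function(e) NA_real_)
      } else {
        obs <- abs(m1 - m2)
        pool <- c(xc, xn); nc <- length(xc)
        exceed <- sum(vapply(seq_len(n_perm), function(i) {
          idx <- sample.int(length(pool), nc)
          abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
        }, logical(1)))
        p <- (exceed + 1) / (n_perm + 1)
      }
    }
    data.frame(assay_id = a, n_case = length(xc), n_control = length(xn),
               dct_case_mean = m1, dct_control_mean = m2, ddct = ddct,
               fold_change = fc, fold_regulation = fold_regulation(fc),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- classify_volcano(out, fr_cut = fr_cut, p_cut = p_cut)
  insufficient <- out$n_case < 2L | out$n_control < 2L
  if (any(insufficient))
    warning("target(s) with <2 usable samples in a group (p set NA): ",
            paste(out$assay_id[insufficient], collapse = ", "))
  attr(out, "test") <- test
  attr(out, "fr_cut") <- fr_cut
  attr(out, "p_cut") <- p_cut
  rownames(out) <- NULL
  class(out) <- c("qpcr_result", "data.frame")
  out
}

#' Volcano classification of qPCR results
#'
#' Classifies each assay as up (\code{fold_regulation >= fr_cut} and
#' \code{p < p_cut}), down (\code{fold_regulation <= -fr_cut} and
#' \code{p < p_cut}) or ns. Missing p-values give ns.
#'
#' @param results data frame with \code{fold_regulation} and \code{p}.
#' @param fr_cut fold-regulation magnitude threshold (default 2).
#' @param p_cut p-value threshold (default 0.05).
#' @return character vector of \code{"up"}, \code{"down"}, \code{"ns"}.
#' @export
classify_volcano <- function(results, fr_cut = 2, p_cut = 0.05) {
  fr <- results$fold_regulation
  p <- results$p
  cls <- rep("ns", length(fr))
  sig <- !is.na(p) & p < p_cut
  cls[sig & fr >= fr_cut] <- "up"
  cls[sig & fr <= -fr_cut] <- "down"
  cls
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("delta-delta-CT quantification (%s test), %d targets\n",
              attr(x, "test"), nrow(x)))
  tab <- table(factor(x$class, c("up", "down", "ns")))
  cat(sprintf("  volcano (|FR| >= %g, p < %g): %d up, %d down, %d ns\n",
              attr(x, "fr_cut"), attr(x, "p_cut"),
              tab["up"], tab["down"], tab["ns"]))
  print(utils::head(as.data.frame(
    x[order(x$p), c("assay_id", "fold_regulation", "p", "class")]), 10),
    digits = 4, row.names = FALSE)
  invisible(x)
}

#' Volcano plot of qPCR fold regulation
#'
#' @param x a \code{qpcr_result}.
#' @param ... passed to \code{plot}.
#' @export
plot.qpcr_result <- function(x, ...) {
  fr_cut <- attr(x, "fr_cut") %||% 2
  p_cut <- attr(x, "p_cut") %||% 0.05
  col <- c(up = "firebrick", down = "steelblue", ns = "grey60")[x$class]
  graphics::plot(x$fold_regulation, -log10(pmax(x$p, 1e-12)), col = col,
                 pch = 19, xlab = "Fold regulation",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(v = c(-fr_cut, fr_cut), h = -log10(p_cut), lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
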