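#' @name mirvalid-io
#' @title Tab-delimited readers and writers
#' @description All tables use a tab-delimited, header-row, UTF-8, `.`
#'   decimal dialect. Readers validate structure and report offending
#'   columns or line numbers; \code{read(write(x))} round-trips every table
#'   type.
NULL

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a miRNA count matrix with its sample-group map
#'
#' @param counts_path TSV with miRNA IDs in the first column, one column per
#'   sample.
#' @param groups_path two-column TSV \code{sample_id}, \code{group}
#'   (case/control).
#' @return a \code{\link{count_matrix}}.
#' @rdname mirvalid-io
#' @export
read_count_matrix <- function(counts_path, groups_path) {
  tab <- read_tsv(counts_path)
  if (ncol(tab) < 3L) stop("count matrix needs an ID column and >= 2 samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate miRNA IDs in ", counts_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(tab)[-1]))
    stop("duplicate sample column in ", counts_path, ": ",
         paste(unique(names(tab)[-1][duplicated(names(tab)[-1])]),
               collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(tab)[-1][!vapply(tab[-1], is.numeric, logical(1))]
    stop("non-numeric count column(s): ", paste(bad, collapse = ", "))
  }
  rownames(m) <- ids
  g <- read_tsv(groups_path)
  if (!all(c("sample_id", "group") %in% names(g)))
    stop("group map needs columns sample_id and group")
  missing <- setdiff(colnames(m), g$sample_id)
  if (length(missing))
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  count_matrix(m, stats::setNames(g$group, g$sample_id)[colnames(m)])
}

#' @param x object to write (matching the reader's return type).
#' @param path,counts_path,groups_path file paths.
#' @rdname mirvalid-io
#' @export
write_count_matrix <- function(x, counts_path, groups_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(mirna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(sample_id = colnames(x$counts), group = x$groups,
                       stringsAsFactors = FALSE), groups_path)
  invisible(counts_path)
}

#' Read a long-format qPCR CT table
#'
#' Expected columns: \code{sample_id}, \code{group}, \code{assay_id},
#' \code{ct}, \code{undetermined} (logical or TRUE/FALSE text). \code{ct}
#' may be empty on undetermined rows.
#' @rdname mirvalid-io
#' @export
read_ct_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("sample_id", "group", "assay_id", "ct", "undetermined")
  if (!all(need %in% names(tab)))
    stop("CT table needs columns: ", paste(need, collapse = ", "))
  tab$undetermined <- as.logical(tab$undetermined)
  tab$ct <- suppressWarnings(as.numeric(tab$ct))
  bad <- which(is.na(tab$ct) & !tab$undetermined)
  if (length(bad))
    stop("non-numeric ct on determined row(s), line(s): ",
         paste(bad + 1L, collapse = ", "))
  if (!all(tab$group %in% c("case", "control")))
    stop("unknown group label(s): ",
         paste(setdiff(unique(tab$group), c("case", "control")),
               collapse = ", "))
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' @rdname mirvalid-io
#' @export
write_ct_table <- function(x, path) write_tsv(as.data.frame(x), path)

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated.
#' @return named list of gene-symbol vectors.
#' @rdname mirvalid-io
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' @param sets named list of gene vectors; descriptions are written as "na".
#' @rdname mirvalid-io
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an exclusion list (one ID per line, `#` comments allowed)
#' @rdname mirvalid-io
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  trimws(lines[nzchar(trimws(lines))])
}

#' Read a qPCR panel definition TSV
#'
#' Columns \code{assay_id} and \code{role} (target / normalizer / control);
#' extra columns are ignored.
#' @rdname mirvalid-io
#' @export
read_panel <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("assay_id", "role") %in% names(tab)))
    stop("panel needs columns assay_id and role")
  bad <- setdiff(unique(tab$role), c("target", "normalizer", "control"))
  if (length(bad)) stop("unknown panel role(s): ", paste(bad, collapse = ", "))
  panel_config(targets = tab$assay_id[tab$role == "target"],
               references = tab$assay_id[tab$role == "normalizer"],
               controls = tab$assay_id[tab$role == "control"])
}

#' Bundled hemangiosarcoma qPCR validation tables
#'
#' The published RT-qPCR validation results for canine visceral
#' hemangiosarcoma: per-miRNA fold regulation and p-value for the splenic
#' and cardiac panels, with the volcano class recomputed from those values
#' at the standard thresholds (|FR| >= 2, p < 0.05).
#'
#' @param tissue \code{"splenic"} or \code{"cardiac"}.
#' @return data frame with \code{mirna_id}, \code{fold_regulation},
#'   \code{p}, \code{class}.
#' @examples
#' summarize_validation(hsa_qpcr_table("cardiac"))
#' @export
hsa_qpcr_table <- function(tissue = c("splenic", "cardiac")) {
  tissue <- match.arg(tissue)
  path <- system.file("extdata", paste0("hsa_", tissue, "_qpcr.tsv"),
                      package = "mirvalid", mustWork = TRUE)
  tab <- read_tsv(path)
  tab$class <- classify_volcano(tab)
  tab
}

#' Bundled hemangiosarcoma custom qPCR panel
#'
#' The 46-assay custom plate behind the validation study: 40 target miRNAs,
#' 3 candidate endogenous normalizers (miR-8859a, miR-8859b, miR-8884) and
#' 3 technical controls (U6 snRNA, UniSP3, UniSp6).
#'
#' @param as \code{"panel_config"} (default) or \code{"data.frame"} for the
#'   full annotation table including catalog numbers and target sequences.
#' @return a \code{\link{panel_config}} or data frame.
#' @examples
#' hsa_panel()
#' @export
hsa_panel <- function(as = c("panel_config", "data.frame")) {
  as <- match.arg(as)
  path <- system.file("extdata", "hsa_qpcr_panel.tsv",
                      package = "mirvalid", mustWork = TRUE)
  tab <- read_tsv(path)
  if (as == "data.frame") return(tab)
  panel_config(targets = tab$assay_id[tab$role == "target"],
               references = tab$assay_id[tab$role == "normalizer"],
               controls = tab$assay_id[tab$role == "control"])
}
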