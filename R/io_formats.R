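#' Read a gene set collection from a GMT file
#'
#' GMT is the tab-separated format used by MSigDB: one gene set per line,
#' with the set name, a description (often a URL), and then the member gene
#' symbols. Member symbols are uppercased, empty fields dropped, and
#' duplicates within a line removed (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per gene set and columns `set_id`, `label`
#'   (the description field) and `genes` (a list-column of character
#'   vectors). The source filename is kept in attribute `source_tag`.
#' @export
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("GO_B_CELL_ACTIVATION\thttp://x\tCD19\tCD79A", gmt)
#' read_gmt(gmt)
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed GMT line %d: fewer than 3 tab-separated fields.", bad[1]
    ))
  }
  set_id <- vapply(parts, `[[`, character(1), 1L)
  dup <- unique(set_id[duplicated(set_id)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate gene set name(s) in GMT: ",
                 paste(dup, collapse = ", ")))
  }
  genes <- lapply(parts, function(p) {
    g <- normalize_symbol(p[-c(1L, 2L)])
    unique(g[nzchar(g)])
  })
  empty <- which(lengths(genes) == 0L)
  if (length(empty) > 0L) {
    abort(sprintf("Gene set '%s' has no members.", set_id[empty[1]]))
  }
  out <- tibble::tibble(
    set_id = set_id,
    label = vapply(parts, `[[`, character(1), 2L),
    genes = genes
  )
  attr(out, "source_tag") <- basename(path)
  out
}

#' Write a gene set collection to a GMT file
#'
#' Member symbols are written sorted, so `read_gmt(write_gmt(x))` is the
#' identity on canonicalized collections.
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(all(c("set_id", "genes") %in% names(collection)))
  label <- collection$label %||% rep("na", nrow(collection))
  lines <- purrr::pmap_chr(
    list(collection$set_id, label, collection$genes),
    function(id, lab, g) paste(c(id, lab, sort(g)), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects sample identifiers in the first row and gene symbols in the first
#' column. Values are used only ordinally downstream, so no normalization or
#' log transform is applied. Profiles (sample columns) containing missing
#' data are discarded by default, mirroring the dataset selection rule that
#' whole profiles with missing values are dropped; `on_missing = "error"`
#' aborts instead.
#'
#' @param path Path to a tab-separated matrix.
#' @param on_missing Either `"drop_sample"` (default: remove any sample
#'   column containing a missing value, with a warning) or `"error"`.
#' @return A numeric matrix (genes x samples) with unique uppercase gene
#'   symbols as row names and sample ids as column names.
#' @export
read_expression <- function(path, on_missing = c("drop_sample", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL)
  if (ncol(raw) < 2L || nrow(raw) < 1L) {
    abort("Expression table needs at least one gene row and one sample column.")
  }
  genes <- normalize_symbol(raw[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate gene symbol(s) in expression matrix: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                 dimnames = list(genes, colnames(body))))
  # Cells that are non-empty text but fail numeric conversion are parse
  # errors; empty cells are missing data handled by the profile policy.
  bad <- which(is.na(vals) & nzchar(trimws(body)) &
                 !toupper(trimws(body)) %in% c("NA", "NAN"), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("Non-numeric value at gene '%s', sample '%s'.",
                  genes[bad[1, 1]], colnames(body)[bad[1, 2]]))
  }
  miss <- which(colSums(is.na(vals)) > 0L)
  if (length(miss) > 0L) {
    if (on_missing == "error") {
      abort(paste0("Missing data in sample(s): ",
                   paste(colnames(vals)[miss], collapse = ", ")))
    }
    warn(paste0("Dropping sample profile(s) containing missing data: ",
                paste(colnames(vals)[miss], collapse = ", ")))
    vals <- vals[, -miss, drop = FALSE]
  }
  if (ncol(vals) == 0L) abort("All sample profiles were discarded.")
  if (anyDuplicated(colnames(vals))) abort("Duplicate sample identifiers.")
  vals
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric matrix (genes x samples) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' @param path TSV with columns `sample_id`, `group`, `dataset_id` and
#'   optionally `platform_id`.
#' @param group_labels Allowed group labels; defaults to the four tumor
#'   stages plus `"control"`.
#' @return A tibble keyed by `sample_id`.
#' @export
read_annotation <- function(path, group_labels = default_group_labels()) {
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "group", "dataset_id")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0L) {
    abort(paste0("Annotation lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(ann$sample_id)) {
    abort("Duplicate sample_id in annotation.")
  }
  bad <- !ann$group %in% group_labels
  if (any(bad)) {
    abort(paste0(
      "Unknown group label(s): ",
      paste(unique(ann$group[bad]), collapse = ", "),
      " (rows ", paste(which(bad), collapse = ", "), ")."
    ))
  }
  dplyr::select(ann, dplyr::all_of(need),
                dplyr::any_of("platform_id"))
}

#' Write a sample annotation table
#' @param annotation Tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' Reconcile annotation and expression sample identifiers
#'
#' @param expr Expression matrix (genes x samples).
#' @param annotation Annotation tibble.
#' @return A tibble of discrepancies with columns `sample_id` and `problem`
#'   (`"missing_from_expression"` or `"missing_from_annotation"`); zero rows
#'   when the two agree.
#' @export
reconcile_samples <- function(expr, annotation) {
  in_expr <- colnames(expr)
  in_ann <- annotation$sample_id
  dplyr::bind_rows(
    tibble::tibble(sample_id = setdiff(in_ann, in_expr),
                   problem = "missing_from_expression"),
    tibble::tibble(sample_id = setdiff(in_expr, in_ann),
                   problem = "missing_from_annotation")
  )
}
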