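#' Convert an expression vector to ordinal ranks
#'
#' Expression levels for the member genes of a set are used only through
#' their ordering, so each sample's values are converted to ranks with
#' average ranks on ties.
#'
#' @param values Numeric vector (length >= 2 for pairwise use).
#' @return Numeric rank vector, smallest value gets rank 1.
#' @export
#' @examples
#' to_ranks(c(5, 1, 3))  # 3 1 2
to_ranks <- function(values) {
  rank(values, ties.method = "average")
}

# Pair index bookkeeping: all unordered pairs (i < j) over n genes in
# lexicographic gene order. Returns a 2-column integer matrix.
pair_index <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- utils::combn(n, 2L)
  cbind(i = idx[1L, ], j = idx[2L, ])
}

# For a ranks matrix (genes x samples) and a pair index matrix, a logical
# P x S matrix: does gene_i rank strictly below gene_j in each sample?
# Ties are FALSE: a tied pair never satisfies a strict "<".
pair_less <- function(rank_mat, pairs) {
  lt <- rank_mat[pairs[, 1L], , drop = FALSE] <
    rank_mat[pairs[, 2L], , drop = FALSE]
  lt
}

#' Build a rank template for one gene set from the control cohort
#'
#' The template records, for each unordered pair of member genes present in
#' the matrix, the majority ordering across the control samples: `order` is
#' `TRUE` when gene_i (lexicographically first) ranks below gene_j in a
#' majority of controls. Within a sample, a tied pair counts as *not*
#' "gene_i below gene_j". An exact 50/50 split resolves to `TRUE`, so
#' templates are deterministic. `support` is the fraction of controls
#' agreeing with the majority and is always in `[0.5, 1]`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param control_ids Sample ids of the control cohort (must be columns of
#'   `expr`).
#' @param gene_set Character vector of member gene symbols.
#' @param set_id Optional identifier stored on the template.
#' @return An object of class `gsr_template`: list with `set_id`,
#'   `genes_used` (sorted), and `pairs` (tibble: `gene_i`, `gene_j`,
#'   `order`, `support`); or an object of class `gsr_set_skipped` when
#'   fewer than 2 member genes are present.
#' @export
build_rank_template <- function(expr, control_ids, gene_set,
                                set_id = NULL) {
  if (length(control_ids) < 1L) abort("No control samples given.")
  missing_ctrl <- setdiff(control_ids, colnames(expr))
  if (length(missing_ctrl) > 0L) {
    abort(paste0("Control sample(s) absent from matrix: ",
                 paste(head(missing_ctrl, 5), collapse = ", ")))
  }
  genes_used <- sort(intersect(normalize_symbol(gene_set), rownames(expr)))
  if (length(genes_used) < 2L) {
    return(structure(
      list(set_id = set_id, reason = "too_few_genes",
           n_genes = length(genes_used)),
      class = "gsr_set_skipped"))
  }
  sub <- expr[genes_used, control_ids, drop = FALSE]
  rank_mat <- apply(sub, 2L, to_ranks)
  pairs <- pair_index(length(genes_used))
  lt <- pair_less(rank_mat, pairs)
  votes <- rowSums(lt)
  n <- length(control_ids)
  ord <- votes >= n / 2  # 50/50 resolves to TRUE (lexicographic first lower)
  support <- pmax(votes, n - votes) / n
  structure(
    list(set_id = set_id,
         genes_used = genes_used,
         pairs = tibble::tibble(
           gene_i = genes_used[pairs[, 1L]],
           gene_j = genes_used[pairs[, 2L]],
           order = unname(ord),
           support = unname(support))),
    class = "gsr_template")
}

#' @export
print.gsr_template <- function(x, ...) {
  cat(sprintf("<gsr_template> %s: %d genes, %d pairs, mean support %.3f\n",
              x$set_id %||% "(unnamed)", length(x$genes_used),
              nrow(x$pairs), mean(x$pairs$support)))
  invisible(x)
}

#' Gene set regularity index of one sample against a template
#'
#' The GSR index is the fraction of template pair orderings that the
#' sample's expression ordering matches: 1 means the within-set ordering is
#' fully conserved relative to the normal-control majority ordering, 0 means
#' it is fully reversed. A tied pair in the sample fails a strict "<"
#' template entry (and matches a ">=" entry).
#'
#' @param sample_expr Named numeric vector of expression values covering at
#'   least the template's `genes_used`.
#' @param template A `gsr_template`.
#' @return GSR index in `[0, 1]`.
#' @export
gsr_index <- function(sample_expr, template) {
  stopifnot(inherits(template, "gsr_template"))
  g <- template$genes_used
  if (!all(g %in% names(sample_expr))) {
    abort("Sample lacks values for some template genes.")
  }
  r <- to_ranks(sample_expr[g])
  lt <- r[match(template$pairs$gene_i, g)] < r[match(template$pairs$gene_j, g)]
  mean(lt == template$pairs$order)
}

# Vectorized scorer: GSR index of every column of `expr` against a
# template built on genes_used (rows of expr are assumed to cover them).
score_samples <- function(expr, template) {
  g <- template$genes_used
  sub <- expr[g, , drop = FALSE]
  rank_mat <- apply(sub, 2L, to_ranks)
  if (is.null(dim(rank_mat))) rank_mat <- matrix(rank_mat, nrow = length(g))
  pairs <- cbind(match(template$pairs$gene_i, g),
                 match(template$pairs$gene_j, g))
  lt <- pair_less(rank_mat, pairs)
  colMeans(lt == template$pairs$order)
}

# Leave-one-out control scores: each control is matched against the
# majority template rebuilt from the remaining controls (same tie and
# 50/50 rules as build_rank_template).
score_controls_loo <- function(ctrl, template) {
  g <- template$genes_used
  sub <- ctrl[g, , drop = FALSE]
  rank_mat <- apply(sub, 2L, to_ranks)
  pairs <- cbind(match(template$pairs$gene_i, g),
                 match(template$pairs$gene_j, g))
  lt <- pair_less(rank_mat, pairs)
  votes <- rowSums(lt)
  n <- ncol(lt)
  vapply(seq_len(n), function(s) {
    ord <- (votes - lt[, s]) >= (n - 1) / 2
    mean(lt[, s] == ord)
  }, numeric(1))
}

#' Reconstruct case and control functionomes
#'
#' For every gene set in the collection: the set is restricted to genes
#' common to the case and control matrices, a rank template is built from
#' *all* control samples, and every case and every control sample is scored
#' against it. Sets with fewer than 2 common genes yield an `NA` column and
#' a `skipped_sets` entry; they are never zero-filled.
#'
#' Because every control sample also votes into the template, in-sample
#' control scores carry a small optimism. `loo_controls = TRUE` instead
#' scores each control against the template rebuilt from the other controls
#' (leave-one-out), which removes that optimism; use it when the
#' case-versus-control comparison must be calibrated under the null.
#' Cases are always scored against the full-control template.
#'
#' @param case_expr,control_expr Expression matrices (genes x samples)
#'   sharing at least one gene.
#' @param collection Gene set collection tibble (`set_id`, `genes`
#'   list-column).
#' @param loo_controls Score controls leave-one-out (default `FALSE`:
#'   controls are scored against the all-controls template). Requires at
#'   least 2 controls.
#' @return A list of class `gsr_functionome_pair` with elements `case` and
#'   `control` (tibbles: `sample_id` plus one GSR column per set),
#'   `skipped_sets` (tibble: `set_id`, `reason`) and `templates` (named list
#'   of `gsr_template`).
#' @export
reconstruct_functionome <- function(case_expr, control_expr, collection,
                                    loo_controls = FALSE) {
  common <- intersect(rownames(case_expr), rownames(control_expr))
  if (length(common) == 0L) {
    abort("Case and control matrices share no genes.")
  }
  ctrl <- control_expr[common, , drop = FALSE]
  case <- case_expr[common, , drop = FALSE]
  control_ids <- colnames(ctrl)
  n_case <- ncol(case)
  n_ctrl <- ncol(ctrl)
  case_mat <- matrix(NA_real_, nrow = n_case, ncol = nrow(collection),
                     dimnames = list(colnames(case), collection$set_id))
  ctrl_mat <- matrix(NA_real_, nrow = n_ctrl, ncol = nrow(collection),
                     dimnames = list(control_ids, collection$set_id))
  skipped <- list()
  templates <- list()
  for (k in seq_len(nrow(collection))) {
    tpl <- build_rank_template(ctrl, control_ids,
                               collection$genes[[k]],
                               set_id = collection$set_id[k])
    if (inherits(tpl, "gsr_set_skipped")) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        set_id = collection$set_id[k], reason = tpl$reason)
      next
    }
    templates[[collection$set_id[k]]] <- tpl
    case_mat[, k] <- score_samples(case, tpl)
    ctrl_mat[, k] <- if (loo_controls) {
      if (n_ctrl < 2L) abort("loo_controls needs at least 2 control samples.")
      score_controls_loo(ctrl, tpl)
    } else {
      score_samples(ctrl, tpl)
    }
  }
  structure(
    list(case = as_functionome(case_mat),
         control = as_functionome(ctrl_mat),
         skipped_sets = if (length(skipped)) dplyr::bind_rows(skipped) else
           tibble::tibble(set_id = character(), reason = character()),
         templates = templates),
    class = "gsr_functionome_pair")
}

#' @export
print.gsr_functionome_pair <- function(x, ...) {
  cat(sprintf(
    "<gsr_functionome_pair> %d case, %d control samples; %d sets (%d skipped)\n",
    nrow(x$case), nrow(x$control), ncol(x$case) - 1L, nrow(x$skipped_sets)))
  invisible(x)
}

#' Extract the immunofunctionome from a functionome
#'
#' Restricts a functionome to the gene sets whose mapped ontology terms lie
#' in an offspring closure (typically the offspring of "immune system
#' process" and "inflammatory response"). Column order is preserved.
#'
#' @param functionome Functionome tibble (`sample_id` + set columns).
#' @param mapping Tibble (`set_id`, `term_id`) from [map_sets_to_terms()].
#' @param offspring_ids Character vector of term ids (from
#'   [go_offspring()]).
#' @return Functionome tibble restricted to the matching set columns.
#' @export
extract_immunofunctionome <- function(functionome, mapping, offspring_ids) {
  keep_sets <- mapping$set_id[!is.na(mapping$term_id) &
                                mapping$term_id %in% offspring_ids]
  cols <- intersect(setdiff(names(functionome), "sample_id"), keep_sets)
  if (length(cols) == 0L) {
    abort("No functionome column maps into the offspring set; check the mapping and ontology.")
  }
  dplyr::select(functionome, "sample_id", dplyr::all_of(cols))
}

#' Control-averaged correction of per-group mean GSR indices
#'
#' Stage groups are scored against control cohorts whose common-gene
#' universes differ slightly across dataset pairings, so their raw mean GSR
#' indices are not directly comparable. Each group's raw case mean is
#' rescaled by the grand mean of the per-group control means divided by that
#' group's own control mean:
#' \deqn{corrected_g = raw_g \times \bar{c} / c_g}
#' With equal control means the correction is the identity.
#'
#' @param case_means Numeric vector of per-group raw case mean GSR indices.
#' @param control_means Numeric vector (same length/order) of per-group
#'   control mean GSR indices, all positive.
#' @return Numeric vector of corrected case means (names preserved).
#' @export
#' @examples
#' corrected_group_means(c(0.6195, 0.6021, 0.5748, 0.5588),
#'                       c(0.6461, 0.6459, 0.6518, 0.6486))
corrected_group_means <- function(case_means, control_means) {
  stopifnot(length(case_means) == length(control_means))
  if (any(!is.finite(control_means)) || any(control_means <= 0)) {
    abort("Control means must all be positive.")
  }
  case_means * mean(control_means) / control_means
}

#' Per-set case/control mean GSR ratio
#'
#' The deregulation ratio of a gene set: its case-group mean GSR divided by
#' its control mean. Values below 1 indicate deregulation relative to the
#' normal cohort. A zero control mean yields `NA` with a warning.
#'
#' @param case_mean,control_mean Numeric vectors (recycled pairwise).
#' @return Elementwise ratio, `NA` where the control mean is 0.
#' @export
sc_control_ratio <- function(case_mean, control_mean) {
  out <- case_mean / control_mean
  zero <- !is.na(control_mean) & control_mean == 0
  if (any(zero)) {
    warn("Control mean of 0 encountered; ratio set to NA.")
    out[zero] <- NA_real_
  }
  out
}

#' Group-level functionome summary in Table-1 form
#'
#' Summarizes a case/control functionome pair per case group: mean and SD of
#' all GSR indices in the group, the matching control statistics, the
#' corrected case mean (see [corrected_group_means()]) and a two-sided
#' Mann-Whitney p-value comparing the pooled group GSR indices against the
#' pooled control indices.
#'
#' @param fpair A `gsr_functionome_pair` from [reconstruct_functionome()].
#' @param annotation Annotation tibble covering the case samples.
#' @param groups Group order for the output (defaults to the stage labels
#'   present).
#' @return Tibble with columns `group`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`, `corrected_case_mean`, `p_value`.
#' @export
functionome_group_means <- function(fpair, annotation, groups = NULL) {
  stopifnot(inherits(fpair, "gsr_functionome_pair"))
  case_m <- functionome_matrix(fpair$case)
  ctrl_m <- functionome_matrix(fpair$control)
  ann <- annotation[match(rownames(case_m), annotation$sample_id), ]
  if (anyNA(ann$group)) abort("Some case samples lack annotation.")
  groups <- groups %||% intersect(default_group_labels(), unique(ann$group))
  ctrl_vals <- as.vector(ctrl_m)
  ctrl_vals <- ctrl_vals[!is.na(ctrl_vals)]
  per <- purrr::map_dfr(groups, function(g) {
    vals <- as.vector(case_m[ann$group == g, , drop = FALSE])
    vals <- vals[!is.na(vals)]
    tibble::tibble(
      group = g,
      case_mean = mean(vals), case_sd = stats::sd(vals),
      control_mean = mean(ctrl_vals), control_sd = stats::sd(ctrl_vals),
      p_value = suppressWarnings(
        wilcox.test(vals, ctrl_vals, exact = FALSE, correct = TRUE)$p.value)
    )
  })
  per$corrected_case_mean <- corrected_group_means(per$case_mean,
                                                   per$control_mean)
  dplyr::select(per, "group", "case_mean", "case_sd", "control_mean",
                "control_sd", "corrected_case_mean", "p_value")
}

#' Write a functionome to TSV (with a JSON sidecar of skipped sets)
#'
#' @param fpair A `gsr_functionome_pair`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_functionome <- function(fpair, dir, prefix = "functionome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    case = file.path(dir, paste0(prefix, "_case.tsv")),
    control = file.path(dir, paste0(prefix, "_control.tsv")),
    skipped = file.path(dir, paste0(prefix, "_skipped.json"))
  )
  readr::write_tsv(fpair$case, paths[["case"]])
  readr::write_tsv(fpair$control, paths[["control"]])
  jsonlite::write_json(fpair$skipped_sets, paths[["skipped"]],
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(paths)
}
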