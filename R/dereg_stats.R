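#' Two-sided Mann-Whitney U p-value for one gene set
#'
#' Compares the case-arm and control-arm GSR indices of a set. `NA` values
#' are removed per arm; if an arm is empty afterwards the p-value is `NA`
#' with a warning. The exact null distribution is used when both arms have
#' at most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param case_vals,control_vals Numeric vectors of GSR indices.
#' @return Two-sided p-value (or `NA`).
#' @export
mann_whitney_per_set <- function(case_vals, control_vals) {
  x <- case_vals[!is.na(case_vals)]
  y <- control_vals[!is.na(control_vals)]
  if (length(x) == 0L || length(y) == 0L) {
    warn("Empty arm after NA removal; p-value is NA.")
    return(NA_real_)
  }
  if (length(unique(c(x, y))) == 1L) return(1)  # no ordering evidence
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= 8L && length(y) <= 8L && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j},
#' clipped at 1. `NA` p-values propagate `NA` and do not count towards `m`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Per-set, per-group deregulation table
#'
#' For every gene set and every case group: case mean GSR, control mean,
#' case/control ratio, two-sided Mann-Whitney p-value, BH q-value (adjusted
#' within group across sets) and significance rank (ascending p; ties broken
#' by larger deviation of the ratio from 1, then by set id).
#'
#' @param fpair A `gsr_functionome_pair` (possibly already restricted to an
#'   immunofunctionome via [extract_immunofunctionome()] applied to both
#'   elements — see [deregulation_table()]'s `sets` argument to subset).
#' @param annotation Annotation tibble covering the case samples.
#' @param groups Case group labels to test (default: stage labels present).
#' @param sets Optional character vector restricting the sets tested.
#' @return Tibble of class `gsr_dereg` with columns `set_id`, `group`,
#'   `case_mean`, `control_mean`, `ratio`, `p_value`, `q_value`, `rank`.
#' @export
deregulation_table <- function(fpair, annotation, groups = NULL,
                               sets = NULL) {
  stopifnot(inherits(fpair, "gsr_functionome_pair"))
  case_m <- functionome_matrix(fpair$case)
  ctrl_m <- functionome_matrix(fpair$control)
  if (!is.null(sets)) {
    keep <- intersect(colnames(case_m), sets)
    case_m <- case_m[, keep, drop = FALSE]
    ctrl_m <- ctrl_m[, keep, drop = FALSE]
  }
  ann <- annotation[match(rownames(case_m), annotation$sample_id), ]
  if (anyNA(ann$group)) abort("Some case samples lack annotation.")
  groups <- groups %||% intersect(default_group_labels(), unique(ann$group))
  out <- purrr::map_dfr(groups, function(g) {
    gm <- case_m[ann$group == g, , drop = FALSE]
    res <- purrr::map_dfr(colnames(gm), function(s) {
      cv <- gm[, s]
      xv <- ctrl_m[, s]
      tibble::tibble(
        set_id = s,
        group = g,
        case_mean = mean(cv, na.rm = TRUE),
        control_mean = mean(xv, na.rm = TRUE),
        p_value = if (all(is.na(cv)) || all(is.na(xv))) NA_real_ else
          mann_whitney_per_set(cv, xv)
      )
    })
    res$ratio <- sc_control_ratio(res$case_mean, res$control_mean)
    res$q_value <- bh_fdr(res$p_value)
    ok <- !is.na(res$p_value)
    ord <- order(res$p_value[ok], -abs(1 - res$ratio[ok]), res$set_id[ok])
    res$rank <- NA_integer_
    res$rank[which(ok)[ord]] <- seq_len(sum(ok))
    res
  })
  out <- dplyr::select(out, "set_id", "group", "case_mean", "control_mean",
                       "ratio", "p_value", "q_value", "rank")
  class(out) <- c("gsr_dereg", class(out))
  out
}

#' Rank the deregulated sets of one group
#'
#' Orders set ids by ascending p-value; ties are broken by the larger
#' deviation of the case/control ratio from 1, then lexicographically by set
#' id, so rankings are deterministic. Sets with `NA` p-values are excluded.
#'
#' @param dereg A `gsr_dereg` tibble from [deregulation_table()].
#' @param group Group label to rank.
#' @param top_k Optional truncation; `NULL` returns the full ranking.
#' @return Character vector of set ids, most significant first.
#' @export
rank_deregulated <- function(dereg, group, top_k = NULL) {
  d <- dereg[dereg$group == group & !is.na(dereg$p_value), , drop = FALSE]
  ids <- d$set_id[order(d$p_value, -abs(1 - d$ratio), d$set_id)]
  if (!is.null(top_k)) {
    if (top_k > length(ids)) {
      warn(sprintf("Only %d ranked sets available for group '%s' (top_k = %d).",
                   length(ids), group, top_k))
      top_k <- length(ids)
    }
    ids <- ids[seq_len(top_k)]
  }
  ids
}

#' Intersection structure of the per-group top-k deregulated sets
#'
#' Truncates each group's ranked list to its top `k` entries and partitions
#' the union by membership signature (the full Venn partition: with 4 groups
#' there are 15 non-empty regions). The elements present in *every* list are
#' the commonly deregulated sets.
#'
#' @param top_lists Named list of ranked set-id vectors (one per group).
#' @param k Truncation depth (default 75). Lists shorter than `k` are used
#'   whole, with a warning.
#' @return An object of class `gsr_venn`: list with `partition` (tibble:
#'   `set_id`, `signature` — group names joined by `&`), `counts` (tibble:
#'   `signature`, `n`), `common` (character vector present in all lists) and
#'   `k`.
#' @export
common_deregulated <- function(top_lists, k = 75) {
  stopifnot(is.list(top_lists), length(top_lists) >= 2L,
            !is.null(names(top_lists)))
  short <- names(top_lists)[lengths(top_lists) < k]
  if (length(short) > 0L) {
    warn(paste0("List(s) shorter than k; using whole list for: ",
                paste(short, collapse = ", ")))
  }
  trunc <- lapply(top_lists, function(x) head(x, k))
  univ <- sort(unique(unlist(trunc, use.names = FALSE)))
  member <- vapply(trunc, function(x) univ %in% x,
                   logical(length(univ)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(univ))
  sig <- apply(member, 1L, function(m)
    paste(names(top_lists)[m], collapse = "&"))
  partition <- tibble::tibble(set_id = univ, signature = sig)
  counts <- dplyr::count(partition, .data$signature, name = "n")
  common <- univ[rowSums(member) == length(trunc)]
  structure(list(partition = partition, counts = counts,
                 common = common, k = k),
            class = "gsr_venn")
}

#' @export
print.gsr_venn <- function(x, ...) {
  cat(sprintf("<gsr_venn> top-%d lists, union %d, common %d\n",
              x$k, nrow(x$partition), length(x$common)))
  invisible(x)
}

#' Progressively deregulated sets across ordered stages
#'
#' Keeps the sets that are significant (q-value below `alpha`) in *all*
#' stages and whose case/control ratio strictly decreases along the stage
#' order — the signature of a function deteriorating with disease
#' progression. Sets with an `NA` ratio or q-value in any stage are excluded
#' (reported via a message).
#'
#' @param dereg A `gsr_dereg` tibble covering all `stages`.
#' @param stages Stage labels in progression order (default stage I..IV).
#' @param alpha Per-stage significance threshold on the q-value (default
#'   0.05).
#' @param epsilon Minimum decrease per step (default 0: strict decrease).
#' @return Character vector of set ids (sorted).
#' @export
progressive_filter <- function(dereg, stages = stage_labels(),
                               alpha = 0.05, epsilon = 0) {
  d <- dereg[dereg$group %in% stages, c("set_id", "group", "ratio", "q_value")]
  wide_r <- tidyr::pivot_wider(d[, c("set_id", "group", "ratio")],
                               names_from = "group", values_from = "ratio")
  wide_q <- tidyr::pivot_wider(d[, c("set_id", "group", "q_value")],
                               names_from = "group", values_from = "q_value")
  missing_stage <- setdiff(stages, names(wide_r))
  if (length(missing_stage) > 0L) {
    abort(paste0("Deregulation table lacks stage(s): ",
                 paste(missing_stage, collapse = ", ")))
  }
  rmat <- as.matrix(wide_r[stages])
  qmat <- as.matrix(wide_q[stages])
  has_na <- rowSums(is.na(rmat)) + rowSums(is.na(qmat)) > 0
  if (any(has_na)) {
    inform(sprintf("%d set(s) excluded for NA ratio or q-value.",
                   sum(has_na)))
  }
  sig_all <- rowSums(qmat < alpha) == length(stages)
  dec <- rmat[, -ncol(rmat), drop = FALSE] -
    rmat[, -1L, drop = FALSE] > epsilon
  monotone <- rowSums(dec) == length(stages) - 1L
  keep <- !has_na & sig_all & monotone
  sort(wide_r$set_id[keep])
}

#' Core and auxiliary deregulated elements
#'
#' Combines the cross-stage common deregulated functions with the
#' progressively deregulated ones. Terms shallower than `min_depth` in the
#' ontology are discarded as non-specific upper-level terms. A common-side
#' term and a progressive-side term are matched when they are identical or
#' their ancestor-closure Jaccard similarity is at least `tau`; matched
#' terms are grouped into core clusters by single linkage over the
#' thresholded similarity graph. Surviving terms with no partner on the
#' other side form the auxiliary elements (the symmetric difference).
#'
#' @param common_set,progressive_set Character vectors of set ids.
#' @param dag A `go_dag`.
#' @param mapping Tibble (`set_id`, `term_id`).
#' @param tau Similarity threshold in `[0, 1]` (default 0.5).
#' @param min_depth Minimum ontology depth retained (default 3; depths 0-2
#'   count as upper-level).
#' @return An object of class `gsr_core_aux`: list with `core` (tibble:
#'   `cluster`, `term_id`, `set_id`, `source`), `pairs` (tibble of matched
#'   common/progressive term pairs with similarities), `auxiliary` (tibble:
#'   `term_id`, `set_id`, `source`) and `excluded_upper_level` (character).
#' @export
extract_core_auxiliary <- function(common_set, progressive_set, dag, mapping,
                                   tau = 0.5, min_depth = 3) {
  if (length(common_set) == 0L && length(progressive_set) == 0L) {
    warn("Both input sets are empty.")
  }
  to_terms <- function(ids) {
    idx <- match(ids, mapping$set_id)
    if (anyNA(idx)) {
      abort(paste0("Set id(s) missing from mapping: ",
                   paste(ids[is.na(idx)], collapse = ", ")))
    }
    tibble::tibble(set_id = ids, term_id = mapping$term_id[idx])
  }
  com <- to_terms(common_set)
  pro <- to_terms(progressive_set)
  all_terms <- unique(c(com$term_id, pro$term_id))
  depths <- vapply(all_terms, function(t) go_depth(dag, t), integer(1))
  shallow <- all_terms[depths < min_depth]
  com <- com[!com$term_id %in% shallow, , drop = FALSE]
  pro <- pro[!pro$term_id %in% shallow, , drop = FALSE]
  # All cross-side term pairs at or above the similarity threshold.
  pairs <- tidyr::expand_grid(term_common = unique(com$term_id),
                              term_progressive = unique(pro$term_id))
  if (nrow(pairs) > 0L) {
    pairs$similarity <- purrr::map2_dbl(
      pairs$term_common, pairs$term_progressive,
      function(a, b) if (a == b) 1 else go_semantic_similarity(dag, a, b))
    pairs <- pairs[pairs$similarity >= tau, , drop = FALSE]
  } else {
    pairs$similarity <- numeric(0)
  }
  matched <- unique(c(pairs$term_common, pairs$term_progressive))
  # Single-linkage clusters = connected components of the thresholded graph.
  cluster_of <- integer(0)
  if (length(matched) > 0L) {
    g <- igraph::graph_from_data_frame(
      pairs[, c("term_common", "term_progressive")],
      directed = FALSE, vertices = matched)
    comp <- igraph::components(g)$membership
    cluster_of <- comp[matched]
  }
  side <- dplyr::bind_rows(
    dplyr::mutate(com, source = "common"),
    dplyr::mutate(pro, source = "progressive"))
  side <- dplyr::distinct(side)
  core <- side[side$term_id %in% matched, , drop = FALSE]
  if (nrow(core) > 0L) {
    core$cluster <- unname(cluster_of[core$term_id])
    core <- dplyr::arrange(core, .data$cluster, .data$term_id)
    core <- dplyr::select(core, "cluster", "term_id", "set_id", "source")
  } else {
    core <- tibble::tibble(cluster = integer(), term_id = character(),
                           set_id = character(), source = character())
  }
  auxiliary <- side[!side$term_id %in% matched, , drop = FALSE]
  structure(
    list(core = core,
         pairs = tibble::as_tibble(pairs),
         auxiliary = tibble::as_tibble(auxiliary),
         excluded_upper_level = shallow),
    class = "gsr_core_aux")
}

#' @export
print.gsr_core_aux <- function(x, ...) {
  cat(sprintf(
    "<gsr_core_aux> %d core terms in %d cluster(s); %d auxiliary; %d upper-level excluded\n",
    nrow(x$core), length(unique(x$core$cluster)), nrow(x$auxiliary),
    length(x$excluded_upper_level)))
  invisible(x)
}

#' Write a deregulation table to TSV
#' @param dereg A `gsr_dereg` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deregulation_table <- function(dereg, path) {
  readr::write_tsv(dereg, path)
  invisible(path)
}
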