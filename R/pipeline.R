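#' Run the functionome stage of the pipeline
#'
#' Splits the expression matrix into case and control arms using the
#' annotation, reconstructs the case/control functionomes, and optionally
#' writes them (plus the skipped-set report) to disk.
#'
#' @param expr Expression matrix (genes x samples).
#' @param annotation Annotation tibble (`sample_id`, `group`, ...), with
#'   controls labeled `"control"`.
#' @param collection Gene set collection tibble.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A `gsr_functionome_pair` (see [reconstruct_functionome()]).
#' @export
run_functionome <- function(expr, annotation, collection, out_dir = NULL) {
  rec <- reconcile_samples(expr, annotation)
  if (nrow(rec) > 0L) {
    abort(paste0(
      "Annotation/expression mismatch for sample(s): ",
      paste(head(paste0(rec$sample_id, " (", rec$problem, ")"), 5),
            collapse = ", ")))
  }
  ctrl_ids <- annotation$sample_id[annotation$group == "control"]
  case_ids <- annotation$sample_id[annotation$group != "control"]
  if (length(ctrl_ids) == 0L) abort("No control samples in annotation.")
  if (length(case_ids) == 0L) abort("No case samples in annotation.")
  fpair <- reconstruct_functionome(expr[, case_ids, drop = FALSE],
                                   expr[, ctrl_ids, drop = FALSE],
                                   collection)
  if (!is.null(out_dir)) write_functionome(fpair, out_dir)
  fpair
}

#' Run the full staged analysis
#'
#' End-to-end orchestration: functionome reconstruction, optional
#' immunofunctionome extraction (when an ontology, mapping and ancestor
#' terms are supplied), Table-1-shaped corrected group means, per-stage
#' deregulation tables and top-k rankings, the cross-stage intersection,
#' the progressive filter, core/auxiliary extraction, per-stage binary SVM
#' classification plus the multiclass task, and hierarchical clustering of
#' the group mean profiles.
#'
#' @inheritParams run_functionome
#' @param dag Optional `go_dag` for immunofunctionome extraction and
#'   core/auxiliary merging.
#' @param mapping Optional set-to-term mapping tibble.
#' @param ancestors Ancestor term ids whose offspring define the
#'   immunofunctionome (used when `dag` is given).
#' @param k_top Truncation depth for the cross-stage intersection (default
#'   75).
#' @param alpha Significance threshold for the progressive filter (default
#'   0.05).
#' @param tau Semantic-similarity threshold for core merging (default 0.5).
#' @param min_depth Minimum ontology depth for core/auxiliary candidates
#'   (default 3).
#' @param cv_k Fold count for the SVM tasks (default 5).
#' @param cv_repeats CV repetitions (default 10).
#' @param seed Seed for the classification stage.
#' @param classify Run the SVM stage (default `TRUE`; the slowest stage).
#' @return A list of class `gsr_bundle` with elements `functionome`,
#'   `immunofunctionome` (or `NULL`), `group_means`, `dereg`, `top_lists`,
#'   `venn`, `progressive`, `core_aux` (or `NULL`), `cv` (named list of
#'   `gsr_cv`), and `dendrogram`.
#' @export
gsr_pipeline <- function(expr, annotation, collection,
                         dag = NULL, mapping = NULL, ancestors = NULL,
                         k_top = 75, alpha = 0.05, tau = 0.5, min_depth = 3,
                         cv_k = 5, cv_repeats = 10, seed = 1,
                         classify = TRUE) {
  fpair <- run_functionome(expr, annotation, collection)

  use_immuno <- !is.null(dag)
  if (use_immuno && (is.null(mapping) || is.null(ancestors))) {
    abort("Immunofunctionome extraction needs `mapping` and `ancestors` along with `dag`.")
  }
  working <- fpair
  immuno <- NULL
  if (use_immuno) {
    offspring <- go_offspring(dag, ancestors)
    immuno <- list(
      case = extract_immunofunctionome(fpair$case, mapping, offspring),
      control = extract_immunofunctionome(fpair$control, mapping, offspring))
    working <- structure(
      c(immuno, list(skipped_sets = fpair$skipped_sets,
                     templates = fpair$templates)),
      class = "gsr_functionome_pair")
  }

  stages <- intersect(stage_labels(), unique(annotation$group))
  group_means <- functionome_group_means(working, annotation, stages)
  dereg <- deregulation_table(working, annotation, stages)
  top_lists <- setNames(
    lapply(stages, function(g) rank_deregulated(dereg, g, top_k = k_top)),
    stages)
  venn <- common_deregulated(top_lists, k = k_top)
  progressive <- if (length(stages) == 4L) {
    progressive_filter(dereg, stages, alpha = alpha)
  } else character(0)

  core_aux <- NULL
  if (use_immuno) {
    core_aux <- extract_core_auxiliary(venn$common, progressive, dag,
                                       mapping, tau = tau,
                                       min_depth = min_depth)
  }

  cv <- list()
  dendro <- NULL
  feat <- working$case
  ctrl_feat <- working$control
  ann <- annotation[match(feat$sample_id, annotation$sample_id), ]
  if (classify) {
    for (g in stages) {
      x <- dplyr::bind_rows(feat[ann$group == g, , drop = FALSE], ctrl_feat)
      y <- c(rep(g, sum(ann$group == g)), rep("control", nrow(ctrl_feat)))
      cv[[paste0(g, "_vs_control")]] <-
        cv_classify(x, y, k = cv_k, repeats = cv_repeats,
                    seed = derive_seed(seed, match(g, stages)),
                    positive = g)
    }
    if (length(stages) >= 2L) {
      cv[["multiclass"]] <- cv_classify(feat, ann$group, k = cv_k,
                                        repeats = cv_repeats,
                                        seed = derive_seed(seed, 99L))
    }
  }
  case_m <- functionome_matrix(feat)
  prof <- do.call(rbind, lapply(stages, function(g)
    colMeans(case_m[ann$group == g, , drop = FALSE], na.rm = TRUE)))
  rownames(prof) <- stages
  if (length(stages) >= 2L) dendro <- cluster_group_profiles(prof)

  structure(
    list(functionome = fpair, immunofunctionome = immuno,
         group_means = group_means, dereg = dereg, top_lists = top_lists,
         venn = venn, progressive = progressive, core_aux = core_aux,
         cv = cv, dendrogram = dendro),
    class = "gsr_bundle")
}

#' @export
print.gsr_bundle <- function(x, ...) {
  cat("<gsr_bundle>\n")
  print(x$group_means)
  cat(sprintf("common: %d, progressive: %d set(s)\n",
              length(x$venn$common), length(x$progressive)))
  invisible(x)
}

#' Write a result bundle to disk
#'
#' Emits the corrected group means table, the deregulation table, per-stage
#' top-k rankings, the Venn partition JSON, the progressive list, the
#' core/auxiliary JSON, per-task classification summaries and the group
#' dendrogram in Newick form, under fixed file names.
#'
#' @param bundle A `gsr_bundle` from [gsr_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_gsr_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(group_means = file.path(dir, "group_means.tsv"),
             dereg = file.path(dir, "deregulation.tsv"),
             top_lists = file.path(dir, "top_lists.json"),
             venn = file.path(dir, "venn_partition.json"),
             progressive = file.path(dir, "progressive_sets.txt"),
             core_aux = file.path(dir, "core_auxiliary.json"),
             cv = file.path(dir, "classification.tsv"),
             dendrogram = file.path(dir, "group_dendrogram.nwk"))
  readr::write_tsv(bundle$group_means, paths[["group_means"]])
  readr::write_tsv(bundle$dereg, paths[["dereg"]])
  jsonlite::write_json(bundle$top_lists, paths[["top_lists"]])
  venn_sig <- split(bundle$venn$partition$set_id,
                    bundle$venn$partition$signature)
  jsonlite::write_json(venn_sig, paths[["venn"]])
  writeLines(bundle$progressive, paths[["progressive"]])
  if (!is.null(bundle$core_aux)) {
    jsonlite::write_json(
      list(core = bundle$core_aux$core,
           auxiliary = bundle$core_aux$auxiliary,
           excluded_upper_level = bundle$core_aux$excluded_upper_level),
      paths[["core_aux"]], dataframe = "rows", auto_unbox = TRUE)
  }
  if (length(bundle$cv) > 0L) {
    readr::write_tsv(
      purrr::imap_dfr(bundle$cv, function(r, task)
        dplyr::bind_cols(tibble::tibble(task_id = task), glance(r))),
      paths[["cv"]])
  }
  if (!is.null(bundle$dendrogram)) {
    writeLines(bundle$dendrogram$newick, paths[["dendrogram"]])
  }
  invisible(paths)
}
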