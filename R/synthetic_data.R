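#' Configuration for a synthetic staged expression cohort
#'
#' Defines the study conditions the generator emulates: a normal control
#' cohort with a stable within-set gene ordering, and four tumor-stage case
#' groups in which designated gene sets have that ordering disrupted with
#' graded severity. Disruption severity is the fraction `pi` of a set's
#' member genes whose values are randomly permuted among themselves in each
#' case sample; "common" planted sets use one `pi` at every stage, while
#' "progressive" sets use a strictly increasing per-stage `pi`.
#'
#' @param n_genes Size of the gene universe (default 2500). Gene sets are
#'   drawn with mutually disjoint membership so planted truth stays
#'   identifiable, so `n_sets * max(set_size)` must not exceed `n_genes`.
#' @param n_sets Number of gene sets (default 200).
#' @param set_size Length-2 range of set sizes (default `c(10, 10)`).
#' @param n_controls Control cohort size (default 40).
#' @param n_cases Per-stage case counts, length 4 (default 40 each). Preset
#'   `"printed"` uses the full published cohort sizes
#'   (34/39/695/131 cases, 136 controls).
#' @param noise_sd SD of the Gaussian jitter added to the per-gene baseline
#'   (log2-intensity-like units; default 1.5).
#' @param n_planted_common Number of sets deregulated equally at all stages
#'   (default 10).
#' @param n_planted_progressive Number of sets with stage-increasing
#'   disruption (default 10).
#' @param pi_common Disruption fraction for common planted sets (default
#'   0.5).
#' @param pi_progressive Length-4 strictly increasing per-stage disruption
#'   for progressive sets (default `c(0.5, 0.65, 0.8, 0.95)`).
#' @param seed Base seed for all randomness (default 1).
#' @param preset Either `"scaled"` (default) or `"printed"` cohort sizes.
#' @return A list of class `gsr_synth_config`.
#' @export
synthetic_config <- function(n_genes = 2500, n_sets = 200,
                             set_size = c(10, 10),
                             n_controls = 40,
                             n_cases = c(stageI = 40, stageII = 40,
                                         stageIII = 40, stageIV = 40),
                             noise_sd = 1.5,
                             n_planted_common = 10,
                             n_planted_progressive = 10,
                             pi_common = 0.5,
                             pi_progressive = c(0.5, 0.65, 0.8, 0.95),
                             seed = 1,
                             preset = c("scaled", "printed")) {
  preset <- match.arg(preset)
  if (preset == "printed") {
    n_cases <- c(stageI = 34, stageII = 39, stageIII = 695, stageIV = 131)
    n_controls <- 136
  }
  stopifnot(length(set_size) == 2L, set_size[1] <= set_size[2])
  if (set_size[1] < 2L) abort("Gene sets need at least 2 members.")
  if (length(n_cases) != 4L) abort("n_cases must have one entry per stage.")
  names(n_cases) <- stage_labels()
  if (length(pi_progressive) != 4L ||
      any(diff(pi_progressive) <= 0) ||
      any(pi_progressive < 0 | pi_progressive > 1)) {
    abort("pi_progressive must be 4 strictly increasing values in [0, 1].")
  }
  if (pi_common < 0 || pi_common > 1) abort("pi_common must lie in [0, 1].")
  if (n_sets * set_size[2] > n_genes) {
    abort("Gene universe too small for disjoint sets: need n_sets * max(set_size) <= n_genes.")
  }
  if (n_planted_common + n_planted_progressive > n_sets) {
    abort("More planted sets than sets.")
  }
  structure(
    list(n_genes = n_genes, n_sets = n_sets, set_size = set_size,
         n_controls = n_controls, n_cases = n_cases, noise_sd = noise_sd,
         baseline_mean = 8, baseline_sd = 2,
         n_planted_common = n_planted_common,
         n_planted_progressive = n_planted_progressive,
         pi_common = pi_common, pi_progressive = pi_progressive,
         seed = as.integer(seed)),
    class = "gsr_synth_config")
}

# Disjoint gene set collection over the configured universe.
synth_collection <- function(config) {
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  sizes <- if (config$set_size[1] == config$set_size[2]) {
    rep(config$set_size[1], config$n_sets)
  } else {
    sample(seq(config$set_size[1], config$set_size[2]),
           config$n_sets, replace = TRUE)
  }
  pool <- sample(genes)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble::tibble(
    set_id = sprintf("SET_%03d", seq_len(config$n_sets)),
    label = sprintf("synthetic set %03d", seq_len(config$n_sets)),
    genes = purrr::map2(starts, ends, function(a, b) sort(pool[a:b]))
  )
}

# Truth assignment: which sets are planted, and each stage's pi.
synth_truth <- function(config, set_ids) {
  planted <- sample(set_ids,
                    config$n_planted_common + config$n_planted_progressive)
  common <- planted[seq_len(config$n_planted_common)]
  progressive <- setdiff(planted, common)
  cls <- rep("null", length(set_ids))
  cls[set_ids %in% common] <- "common"
  cls[set_ids %in% progressive] <- "progressive"
  pis <- matrix(0, nrow = length(set_ids), ncol = 4L,
                dimnames = list(set_ids, stage_labels()))
  if (any(cls == "common")) {
    pis[set_ids %in% common, ] <- config$pi_common
  }
  if (any(cls == "progressive")) {
    pis[set_ids %in% progressive, ] <-
      matrix(config$pi_progressive, sum(cls == "progressive"), 4L,
             byrow = TRUE)
  }
  tibble::tibble(
    set_id = set_ids, class = cls,
    pi_stageI = pis[, 1], pi_stageII = pis[, 2],
    pi_stageIII = pis[, 3], pi_stageIV = pis[, 4])
}

# One cohort arm: baseline + Gaussian jitter, then per-sample within-set
# permutation of a pi-fraction of each planted set's member genes.
synth_arm <- function(baseline, n, prefix, noise_sd,
                      collection = NULL, truth = NULL, stage = NULL) {
  genes <- names(baseline)
  mat <- matrix(baseline, nrow = length(baseline), ncol = n) +
    matrix(rnorm(length(baseline) * n, sd = noise_sd),
           nrow = length(baseline))
  dimnames(mat) <- list(genes, sprintf("%s_%03d", prefix, seq_len(n)))
  if (!is.null(truth) && !is.null(stage)) {
    pi_col <- paste0("pi_", stage)
    for (k in which(truth[[pi_col]] > 0)) {
      members <- collection$genes[[k]]
      pi_k <- truth[[pi_col]][k]
      n_dis <- max(2L, round(pi_k * length(members)))
      n_dis <- min(n_dis, length(members))
      idx <- match(members, genes)
      for (s in seq_len(n)) {
        pick <- sample(idx, n_dis)
        mat[pick, s] <- mat[sample(pick), s]
      }
    }
  }
  mat
}

#' Generate a synthetic staged expression cohort
#'
#' Draws a per-gene baseline defining the canonical control ordering,
#' control samples as baseline plus Gaussian jitter, and per-stage case
#' samples identical in distribution except that within each planted set a
#' fraction `pi` of member genes (rounded, at least 2 when `pi > 0`) have
#' their values randomly permuted among themselves, independently per
#' sample. Null sets are untouched. With the same config (including seed)
#' the output is identical.
#'
#' @param config A `gsr_synth_config` from [synthetic_config()].
#' @param collection Optional gene set collection tibble; by default a
#'   disjoint collection is drawn from the configured universe.
#' @return A list of class `gsr_synth_cohort` with `expression` (genes x
#'   samples matrix, controls and all stage cases), `annotation` (tibble),
#'   `collection` (tibble), and `truth` (tibble: `set_id`, `class`,
#'   per-stage `pi_*`).
#' @export
generate_cohort <- function(config, collection = NULL) {
  stopifnot(inherits(config, "gsr_synth_config"))
  withr::with_seed(config$seed, {
    if (is.null(collection)) collection <- synth_collection(config)
    truth <- synth_truth(config, collection$set_id)
    baseline <- setNames(
      rnorm(config$n_genes, config$baseline_mean, config$baseline_sd),
      sprintf("G%05d", seq_len(config$n_genes)))
    # Keep universe consistent when a custom collection is passed in.
    extra <- setdiff(unique(unlist(collection$genes)), names(baseline))
    if (length(extra) > 0L) {
      baseline <- c(baseline,
                    setNames(rnorm(length(extra), config$baseline_mean,
                                   config$baseline_sd), extra))
    }
    ctrl <- synth_arm(baseline, config$n_controls, "CTRL", config$noise_sd)
    cases <- purrr::imap(as.list(config$n_cases), function(n, stage) {
      synth_arm(baseline, n, toupper(stage), config$noise_sd,
                collection, truth, stage)
    })
    expr <- cbind(ctrl, do.call(cbind, unname(cases)))
    annotation <- tibble::tibble(
      sample_id = colnames(expr),
      group = c(rep("control", config$n_controls),
                rep(stage_labels(), times = config$n_cases)),
      dataset_id = "synthetic"
    )
    structure(
      list(expression = expr, annotation = annotation,
           collection = collection, truth = truth, config = config),
      class = "gsr_synth_cohort")
  })
}

#' @export
print.gsr_synth_cohort <- function(x, ...) {
  cat(sprintf(
    "<gsr_synth_cohort> %d genes x %d samples; %d sets (%d planted)\n",
    nrow(x$expression), ncol(x$expression), nrow(x$collection),
    sum(x$truth$class != "null")))
  invisible(x)
}

#' Generate a synthetic ontology with matching gene sets and mapping
#'
#' Builds a random acyclic ontology with a single root, a layer of
#' top-level branches including two designated "immune" ancestors whose
#' offspring cover roughly `immune_fraction` of all terms, one gene set per
#' term (disjoint membership) and a set-to-term mapping consistent with the
#' name-normalization rule. Occasional `part_of` edges are added alongside
#' the primary `is_a` parents. Deterministic given `seed`.
#'
#' @param n_terms Number of ontology terms including root and ancestors
#'   (minimum 4; default 60).
#' @param seed Integer seed.
#' @param immune_fraction Target fraction of non-root terms placed under
#'   the two immune ancestors (default 0.4).
#' @param n_genes Gene universe size (default `25 * n_terms`).
#' @param set_size Range of gene set sizes (default `c(10, 10)`).
#' @return A list of class `gsr_synth_ontology` with `dag` (a `go_dag`),
#'   `collection` (tibble), `mapping` (tibble `set_id`, `term_id`),
#'   `ancestors` (the two immune ancestor term ids) and `immune_terms`
#'   (character: the true offspring closure of the ancestors).
#' @export
generate_ontology <- function(n_terms = 60, seed = 1, immune_fraction = 0.4,
                              n_genes = 25 * n_terms,
                              set_size = c(10, 10)) {
  stopifnot(n_terms >= 4L)
  withr::with_seed(seed, {
    ids <- sprintf("GO:S%06d", seq_len(n_terms))
    root <- ids[1]
    ancestors <- ids[2:3]
    names <- c("biological process",
               "immune system process",
               "inflammatory response",
               sprintf("synthetic process %03d", seq_len(n_terms - 3L)))
    n_immune <- max(0L, min(n_terms - 3L,
                            round(immune_fraction * n_terms) - 2L))
    rest <- ids[-(1:3)]
    immune_pool <- rest[seq_len(n_immune)]
    other_pool <- setdiff(rest, immune_pool)
    edges <- list(tibble::tibble(child = ancestors, parent = root,
                                 relation = "is_a"))
    # Immune terms attach below the ancestors (or earlier immune terms);
    # other terms attach below root or earlier non-immune terms.
    grow <- function(pool, parents0) {
      placed <- parents0
      out <- list()
      for (t in pool) {
        parent <- sample(placed, 1L)
        out[[length(out) + 1L]] <- tibble::tibble(
          child = t, parent = parent, relation = "is_a")
        if (length(placed) > 1L && runif(1) < 0.15) {
          extra <- sample(setdiff(placed, parent), 1L)
          out[[length(out) + 1L]] <- tibble::tibble(
            child = t, parent = extra, relation = "part_of")
        }
        placed <- c(placed, t)
      }
      dplyr::bind_rows(out)
    }
    if (length(immune_pool) > 0L) {
      edges[[length(edges) + 1L]] <- grow(immune_pool, ancestors)
    }
    if (length(other_pool) > 0L) {
      edges[[length(edges) + 1L]] <- grow(other_pool, root)
    }
    dag <- new_go_dag(
      tibble::tibble(term_id = ids, name = names,
                     namespace = "biological_process", obsolete = FALSE),
      dplyr::bind_rows(edges))
    genes <- sprintf("G%05d", seq_len(n_genes))
    sizes <- if (set_size[1] == set_size[2]) {
      rep(set_size[1], n_terms)
    } else {
      sample(seq(set_size[1], set_size[2]), n_terms, replace = TRUE)
    }
    if (sum(sizes) > n_genes) abort("Gene universe too small for disjoint sets.")
    pool <- sample(genes)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    collection <- tibble::tibble(
      set_id = normalize_term_name(names),
      label = names,
      genes = purrr::map2(starts, ends, function(a, b) sort(pool[a:b]))
    )
    mapping <- tibble::tibble(set_id = collection$set_id, term_id = ids)
    structure(
      list(dag = dag, collection = collection, mapping = mapping,
           ancestors = ancestors,
           immune_terms = sort(c(ancestors, immune_pool))),
      class = "gsr_synth_ontology")
  })
}

#' Evaluate pipeline outputs against the planted synthetic truth
#'
#' Computes recovery metrics for a pipeline run on a synthetic cohort:
#' precision and recall of each stage's top-k ranking against all planted
#' sets, of the progressive filter output against the planted progressive
#' sets, and of the cross-stage common sets against all planted sets.
#'
#' @param top_lists Named list of per-stage ranked set-id vectors (already
#'   truncated to the k of interest).
#' @param progressive_ids Character vector from [progressive_filter()].
#' @param common_ids Character vector from [common_deregulated()]'s
#'   `common` element.
#' @param truth Truth tibble from [generate_cohort()].
#' @return Tibble with columns `metric`, `precision`, `recall`, `n_selected`,
#'   `n_truth`. Precision/recall are `NA` when their denominator is 0.
#' @export
truth_recovery <- function(top_lists, progressive_ids, common_ids, truth) {
  unknown <- setdiff(
    unique(c(unlist(top_lists), progressive_ids, common_ids)),
    truth$set_id)
  if (length(unknown) > 0L) {
    abort(paste0("Output set id(s) absent from truth: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  planted <- truth$set_id[truth$class != "null"]
  planted_prog <- truth$set_id[truth$class == "progressive"]
  pr <- function(selected, positives) {
    tibble::tibble(
      precision = if (length(selected) == 0L) NA_real_ else
        mean(selected %in% positives),
      recall = if (length(positives) == 0L) NA_real_ else
        mean(positives %in% selected),
      n_selected = length(selected),
      n_truth = length(positives))
  }
  dplyr::bind_rows(
    purrr::imap_dfr(top_lists, function(ids, stage) {
      dplyr::bind_cols(tibble::tibble(metric = paste0("top_", stage)),
                       pr(ids, planted))
    }),
    dplyr::bind_cols(tibble::tibble(metric = "progressive"),
                     pr(progressive_ids, planted_prog)),
    dplyr::bind_cols(tibble::tibble(metric = "common"),
                     pr(common_ids, planted))
  )
}

#' Write a synthetic cohort to the pipeline's input formats
#'
#' Emits the expression TSV, annotation TSV, GMT collection and truth JSON,
#' so the on-disk readers can be exercised end to end.
#'
#' @param cohort A `gsr_synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths[["expression"]])
  write_annotation(cohort$annotation, paths[["annotation"]])
  write_gmt(cohort$collection, paths[["gmt"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
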