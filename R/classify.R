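#' Repeated stratified k-fold SVM classification of functionome profiles
#'
#' Trains a radial-basis-kernel support vector machine (via
#' [kernlab::ksvm()], with the median-heuristic bandwidth and unit cost) on
#' functionome rows and evaluates it by stratified k-fold cross-validation,
#' repeated with fresh fold reshuffles. Binary tasks report per-repeat
#' sensitivity, specificity, accuracy and AUC (from pooled decision values,
#' via \pkg{pROC}); multiclass tasks report per-repeat accuracy plus
#' per-class one-vs-rest AUCs computed from the pairwise-voting scores.
#' These one-vs-rest AUCs are a convenience diagnostic and are not
#' comparable to a single binary AUC.
#'
#' @param features Functionome tibble (`sample_id` plus feature columns) or
#'   a numeric matrix (samples x features). Columns containing `NA` are
#'   dropped before fitting.
#' @param labels Factor (or coercible) of class labels, one per row.
#' @param k Number of folds (default 5). Every class must have at least `k`
#'   members.
#' @param repeats Number of CV repetitions (default 10).
#' @param seed Integer seed controlling all fold shuffles and the kernel
#'   bandwidth estimate; fixed seed gives bit-reproducible reports.
#' @param positive For binary tasks, the label treated as positive; default
#'   is the first non-"control" level.
#' @return Object of class `gsr_cv`: list with `task`, `k`, `repeats`,
#'   `positive`, `per_repeat` (tibble of per-repeat metrics) and `summary`
#'   (tibble of means and SDs).
#' @export
cv_classify <- function(features, labels, k = 5, repeats = 10, seed = 1,
                        positive = NULL) {
  if (is.data.frame(features)) features <- functionome_matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels))
  if (nlevels(labels) < 2L) abort("Need at least 2 classes.")
  keep <- colSums(is.na(features)) == 0L
  features <- features[, keep, drop = FALSE]
  if (ncol(features) == 0L) abort("No complete feature columns remain.")
  sizes <- table(labels)
  if (any(sizes < k)) {
    abort(sprintf(
      "Class '%s' has %d members, fewer than k = %d folds; use a smaller k.",
      names(sizes)[which.min(sizes)], min(sizes), k))
  }
  binary <- nlevels(labels) == 2L
  if (binary) {
    positive <- positive %||% setdiff(levels(labels), "control")[1] %||%
      levels(labels)[1]
    negative <- setdiff(levels(labels), positive)
  }

  one_repeat <- function(r) {
    # Stratified fold assignment, reshuffled each repeat.
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    pred <- factor(rep(NA_character_, length(labels)),
                   levels = levels(labels))
    dec <- rep(NA_real_, length(labels))
    votes <- matrix(NA_real_, nrow = length(labels),
                    ncol = nlevels(labels),
                    dimnames = list(NULL, levels(labels)))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- kernlab::ksvm(features[tr, , drop = FALSE], labels[tr],
                           kernel = "rbfdot", kpar = "automatic",
                           C = 1, scaled = FALSE)
      test_x <- features[!tr, , drop = FALSE]
      pred[!tr] <- kernlab::predict(fit, test_x)
      if (binary) {
        d <- kernlab::predict(fit, test_x, type = "decision")
        # Orient decision values so larger means "positive class"
        # (ksvm codes the first training level as the negative margin side).
        sign_flip <- if (kernlab::lev(fit)[2] == positive) 1 else -1
        dec[!tr] <- sign_flip * d[, 1]
      } else {
        v <- t(kernlab::predict(fit, test_x, type = "votes"))
        colnames(v) <- kernlab::lev(fit)
        votes[!tr, colnames(v)] <- v
      }
    }
    acc <- mean(pred == labels)
    if (binary) {
      tp <- sum(pred == positive & labels == positive)
      tn <- sum(pred == negative & labels == negative)
      auc <- as.numeric(pROC::auc(
        response = labels, predictor = dec,
        levels = c(negative, positive), direction = "<", quiet = TRUE))
      tibble::tibble(
        repeat_id = r,
        sensitivity = tp / sum(labels == positive),
        specificity = tn / sum(labels == negative),
        accuracy = acc,
        auc = auc)
    } else {
      ovr <- vapply(levels(labels), function(cl) {
        as.numeric(pROC::auc(
          response = factor(labels == cl, levels = c(FALSE, TRUE)),
          predictor = votes[, cl], levels = c("FALSE", "TRUE"),
          direction = "<", quiet = TRUE))
      }, numeric(1))
      dplyr::bind_cols(
        tibble::tibble(repeat_id = r, accuracy = acc),
        tibble::as_tibble(as.list(setNames(
          ovr, paste0("auc_ovr_", levels(labels))))))
    }
  }

  per_repeat <- withr::with_seed(
    seed, purrr::map_dfr(seq_len(repeats), one_repeat))
  metrics <- setdiff(names(per_repeat), "repeat_id")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(per_repeat[metrics], mean, numeric(1)),
    sd = vapply(per_repeat[metrics], stats::sd, numeric(1)))
  structure(
    list(task = if (binary) "binary" else "multiclass",
         k = k, repeats = repeats,
         positive = if (binary) positive else NA_character_,
         per_repeat = per_repeat, summary = summary),
    class = "gsr_cv")
}

#' @export
print.gsr_cv <- function(x, ...) {
  cat(sprintf("<gsr_cv> %s, k = %d, %d repeats\n", x$task, x$k, x$repeats))
  print(x$summary)
  invisible(x)
}

#' @describeIn cv_classify Per-repeat metrics as a tibble.
#' @param x A `gsr_cv` object.
#' @param ... Unused.
#' @method tidy gsr_cv
#' @export
tidy.gsr_cv <- function(x, ...) x$per_repeat

#' @describeIn cv_classify One-row summary (means and SDs of each metric).
#' @method glance gsr_cv
#' @export
glance.gsr_cv <- function(x, ...) {
  wide <- c(setNames(x$summary$mean, paste0(x$summary$metric, "_mean")),
            setNames(x$summary$sd, paste0(x$summary$metric, "_sd")))
  dplyr::bind_cols(tibble::tibble(task = x$task, k = x$k,
                                  repeats = x$repeats),
                   tibble::as_tibble(as.list(wide)))
}

#' Hierarchical clustering of group mean functionome profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of
#' per-group mean GSR profiles — the unsupervised view of how the stage
#' immunofunctionomes relate. Input rows are sorted by label first so leaf
#' order is deterministic.
#'
#' @param profiles Tibble with a `group` column plus numeric feature
#'   columns, or a numeric matrix with group labels as row names. `NA`
#'   columns are removed; any remaining `NA` is an error.
#' @return Object of class `gsr_dendro`: list with `hclust` (the
#'   [stats::hclust] tree), `labels` (leaf order) and `newick` (Newick
#'   string with branch lengths, via \pkg{ape}).
#' @export
cluster_group_profiles <- function(profiles) {
  if (is.data.frame(profiles)) {
    stopifnot("group" %in% names(profiles))
    m <- as.matrix(profiles[setdiff(names(profiles), "group")])
    rownames(m) <- profiles$group
  } else {
    m <- profiles
  }
  if (nrow(m) < 2L) abort("Need at least 2 group profiles.")
  m <- m[order(rownames(m)), , drop = FALSE]
  m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  if (ncol(m) == 0L) abort("No complete feature columns remain.")
  if (anyNA(m)) abort("NA values remain in the profiles.")
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  phy <- ape::as.phylo(hc)
  structure(
    list(hclust = hc, labels = hc$labels[hc$order],
         newick = ape::write.tree(phy)),
    class = "gsr_dendro")
}

#' @export
print.gsr_dendro <- function(x, ...) {
  cat("<gsr_dendro> leaf order:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn cluster_group_profiles Merge table as a tibble (one row per
#'   agglomeration step with its height).
#' @param x A `gsr_dendro` object.
#' @param ... Unused.
#' @method tidy gsr_dendro
#' @export
tidy.gsr_dendro <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height)
}
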