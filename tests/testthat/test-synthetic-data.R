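test_that("cohort generation is deterministic and writes valid input formats", {
  cfg <- synthetic_config(n_genes = 300, n_sets = 20, set_size = c(6, 10),
                          n_controls = 8, n_cases = rep(6, 4), seed = 5)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$expression, coh2$expression)
  expect_identical(coh1$truth, coh2$truth)
  expect_equal(ncol(coh1$expression), 8 + 24)
  expect_equal(nrow(coh1$truth), 20)
  expect_equal(sum(coh1$truth$class == "common"), 10)
  expect_equal(sum(coh1$truth$class == "progressive"), 10)
  # sets are disjoint, so planted truth is identifiable
  all_genes <- unlist(coh1$collection$genes)
  expect_equal(anyDuplicated(all_genes), 0L)
  # round trip through the on-disk formats
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh1, dir)
  expect_equal(read_expression(paths[["expression"]]), coh1$expression)
  expect_equal(read_annotation(paths[["annotation"]]), coh1$annotation)
  reread <- read_gmt(paths[["gmt"]])
  expect_equal(reread$set_id, coh1$collection$set_id)
  expect_equal(reread$genes, coh1$collection$genes)
})

test_that("config validation rejects inconsistent study designs", {
  expect_error(synthetic_config(set_size = c(1, 1)), "at least 2")
  expect_error(synthetic_config(pi_progressive = c(0.5, 0.4, 0.6, 0.7)),
               "strictly increasing")
  expect_error(synthetic_config(n_genes = 100, n_sets = 50,
                                set_size = c(10, 10)),
               "universe too small")
  expect_error(synthetic_config(n_planted_common = 150,
                                n_planted_progressive = 100),
               "More planted")
  cfg <- synthetic_config(preset = "printed")
  expect_equal(unname(cfg$n_cases),
               c(34, 39, 695, 131))  # published cohort sizes
  expect_equal(cfg$n_controls, 136)
})

test_that("full disruption under vanishing noise halves the match rate of size-10 sets", {
  cfg <- synthetic_config(n_genes = 300, n_sets = 10, set_size = c(10, 10),
                          n_planted_common = 10, n_planted_progressive = 0,
                          pi_common = 1, noise_sd = 1e-6,
                          n_controls = 10, n_cases = c(30, 2, 2, 2),
                          seed = 8)
  coh <- generate_cohort(cfg)
  fp <- run_functionome(coh$expression, coh$annotation, coh$collection)
  ann <- coh$annotation[match(fp$case$sample_id, coh$annotation$sample_id), ]
  m <- gsreg:::functionome_matrix(fp$case)[ann$group == "stageI", ]
  # a fully permuted ordering matches about half the template pairs
  expect_lt(mean(m), 0.7)
  expect_gt(mean(m), 0.3)
  # the noiseless controls match their own template exactly
  expect_equal(mean(as.matrix(fp$control[-1])), 1)
})

test_that("mean planted-set GSR is non-increasing in the disruption fraction", {
  pis <- c(0, 0.25, 0.5, 0.75, 1)
  reps <- 5
  curves <- matrix(NA_real_, reps, length(pis))
  for (r in seq_len(reps)) {
    for (j in seq_along(pis)) {
      pi <- pis[j]
      cfg <- synthetic_config(
        n_genes = 200, n_sets = 12, set_size = c(10, 10),
        n_planted_common = 6, n_planted_progressive = 0,
        pi_common = pi, n_controls = 12, n_cases = c(12, 2, 2, 2),
        seed = 1000 + r)
      coh <- generate_cohort(cfg)
      fp <- run_functionome(coh$expression, coh$annotation, coh$collection)
      ann <- coh$annotation[match(fp$case$sample_id,
                                  coh$annotation$sample_id), ]
      planted <- coh$truth$set_id[coh$truth$class == "common"]
      m <- gsreg:::functionome_matrix(fp$case)[ann$group == "stageI",
                                               planted, drop = FALSE]
      curves[r, j] <- mean(m)
    }
  }
  avg <- colMeans(curves)
  expect_true(all(diff(avg) <= 0))
  expect_lte(suppressWarnings(cor(avg, pis, method = "spearman")), 0)
})

test_that("synthetic ontology is deterministic with immune offspring near target", {
  o1 <- generate_ontology(n_terms = 40, seed = 3, immune_fraction = 0.4,
                          set_size = c(4, 6), n_genes = 300)
  o2 <- generate_ontology(n_terms = 40, seed = 3, immune_fraction = 0.4,
                          set_size = c(4, 6), n_genes = 300)
  expect_identical(o1$dag$edges, o2$dag$edges)
  expect_identical(o1$collection, o2$collection)
  # the designated ancestors sit directly under the root
  expect_true(all(vapply(o1$ancestors,
                         function(t) go_depth(o1$dag, t), integer(1)) == 1L))
  # declared immune terms are exactly the offspring closure of the ancestors
  expect_setequal(go_offspring(o1$dag, o1$ancestors), o1$immune_terms)
  expect_equal(length(o1$immune_terms), round(0.4 * 40))
  # mapping is consistent with name normalization
  suppressMessages(
    remap <- map_sets_to_terms(o1$collection, o1$dag))
  expect_equal(remap$term_id, o1$mapping$term_id)
})

test_that("truth recovery computes precision and recall with NA on empty truth", {
  truth <- tibble::tibble(set_id = paste0("S", 1:6),
                          class = c("common", "progressive", rep("null", 4)),
                          pi_stageI = 0, pi_stageII = 0, pi_stageIII = 0,
                          pi_stageIV = 0)
  res <- truth_recovery(list(stageI = c("S1", "S3")), "S2", c("S1", "S2"),
                        truth)
  top <- res[res$metric == "top_stageI", ]
  expect_equal(top$precision, 0.5)
  expect_equal(top$recall, 0.5)
  prog <- res[res$metric == "progressive", ]
  expect_equal(prog$precision, 1)
  expect_equal(prog$recall, 1)
  # no planted sets: precision NA when nothing selected, count 0
  null_truth <- dplyr::mutate(truth, class = "null")
  res2 <- truth_recovery(list(stageI = character(0)), character(0),
                         character(0), null_truth)
  expect_true(all(is.na(res2$precision)))
  expect_equal(res2$n_selected, rep(0L, 3))
  expect_error(truth_recovery(list(stageI = "NOPE"), character(0),
                              character(0), truth), "absent from truth")
})
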