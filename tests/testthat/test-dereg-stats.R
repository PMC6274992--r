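test_that("Mann-Whitney p-values match exact enumeration and its symmetries", {
  expect_equal(mann_whitney_per_set(c(0.1, 0.2), c(0.8, 0.9)), 1 / 3)
  # swapped arms give the same two-sided p
  expect_equal(mann_whitney_per_set(c(0.8, 0.9), c(0.1, 0.2)), 1 / 3)
  expect_equal(
    suppressWarnings(mann_whitney_per_set(c(0.5, 0.5), c(0.5, 0.5))), 1)
  expect_warning(p <- mann_whitney_per_set(numeric(0), c(0.5)), "Empty arm")
  expect_true(is.na(p))
  # exact mode agrees with full enumeration for all small tie-free draws
  for (seed in 1:15) {
    nm <- withr::with_seed(seed, sample(2:6, 2, replace = TRUE))
    xy <- withr::with_seed(seed + 50, runif(sum(nm)))
    x <- xy[seq_len(nm[1])]
    y <- xy[-seq_len(nm[1])]
    expect_equal(mann_whitney_per_set(x, y), brute_mwu_exact(x, y))
  }
})

test_that("BH q-values follow the step-up rule, propagate NA, match brute force", {
  expect_equal(bh_fdr(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  expect_equal(bh_fdr(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))  # m excludes NA
  for (seed in 1:10) {
    p <- withr::with_seed(seed, runif(1 + seed * 37))
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone along p order
  }
})

test_that("significance ranking is deterministic with the documented tie-breaks", {
  d <- tibble::tibble(
    set_id = c("S2", "S1", "S3", "S4"),
    group = "stageI",
    case_mean = 0.5, control_mean = 0.7,
    ratio = c(0.9, 0.8, 0.7, 0.9),
    p_value = c(0.01, 0.001, 0.02, 0.02),
    q_value = NA_real_, rank = NA_integer_)
  class(d) <- c("gsr_dereg", class(d))
  expect_equal(rank_deregulated(d, "stageI"), c("S1", "S2", "S3", "S4"))
  # p tie between S3 (ratio .7) and S4 (ratio .9): larger |1 - ratio| first
  expect_equal(rank_deregulated(d, "stageI", top_k = 3),
               c("S1", "S2", "S3"))
  expect_warning(ids <- rank_deregulated(d, "stageI", top_k = 10), "top_k")
  expect_length(ids, 4)
})

test_that("top-list intersection produces a full membership partition", {
  lists <- list(stageI = paste0("S", 1:5), stageII = paste0("S", 1:5),
                stageIII = paste0("S", 1:5), stageIV = paste0("S", 1:5))
  v <- common_deregulated(lists, k = 5)
  expect_equal(length(v$common), 5)
  expect_equal(nrow(v$counts), 1)
  disj <- list(a = c("A1", "A2"), b = c("B1", "B2"),
               c = c("C1", "C2"), d = c("D1", "D2"))
  v2 <- common_deregulated(disj, k = 2)
  expect_length(v2$common, 0)
  # region sizes always sum to the union
  mixed <- list(a = c("X", "Y", "A"), b = c("X", "B"), c = c("X", "Y", "C"),
                d = c("X", "D"))
  v3 <- suppressWarnings(common_deregulated(mixed, k = 75))
  expect_equal(sum(v3$counts$n), length(unique(unlist(mixed))))
  expect_equal(v3$common, "X")
  expect_equal(
    v3$partition$signature[v3$partition$set_id == "Y"], "a&c")
})

test_that("progressive filter needs all-stage significance and a strict ratio decrease", {
  mk <- function(id, ratios, qs) {
    tibble::tibble(set_id = id, group = c("stageI", "stageII", "stageIII", "stageIV"),
                   case_mean = 0.5, control_mean = 0.7, ratio = ratios,
                   p_value = qs, q_value = qs, rank = NA_integer_)
  }
  d <- dplyr::bind_rows(
    mk("KEEP", c(0.95, 0.90, 0.85, 0.80), rep(0.001, 4)),
    mk("NONMONO", c(0.95, 0.96, 0.85, 0.80), rep(0.001, 4)),
    mk("NOTSIG", c(0.95, 0.90, 0.85, 0.80), c(0.001, 0.2, 0.001, 0.001)),
    mk("HASNA", c(0.95, NA, 0.85, 0.80), rep(0.001, 4)))
  class(d) <- c("gsr_dereg", class(d))
  expect_message(kept <- progressive_filter(d), "excluded")
  expect_equal(kept, "KEEP")
  # adding non-monotone sets never changes the result
  d2 <- dplyr::bind_rows(d, mk("NONMONO2", c(0.8, 0.9, 0.7, 0.6),
                               rep(0.001, 4)))
  class(d2) <- class(d)
  expect_message(kept2 <- progressive_filter(d2))
  expect_equal(kept2, kept)
  # epsilon turns near-flat decreases off
  d3 <- mk("FLAT", c(0.90, 0.89999, 0.7, 0.6), rep(0.001, 4))
  class(d3) <- class(d)
  expect_equal(progressive_filter(d3), "FLAT")
  expect_length(progressive_filter(d3, epsilon = 0.01), 0)
})

test_that("core/auxiliary extraction merges by similarity and drops upper-level terms", {
  onto <- generate_ontology(n_terms = 12, seed = 9, set_size = c(3, 4),
                            n_genes = 100)
  dag <- onto$dag
  mapping <- onto$mapping
  deep <- mapping$set_id[vapply(mapping$term_id,
                                function(t) go_depth(dag, t),
                                integer(1)) >= 3]
  expect_gte(length(deep), 2)  # this ontology draw contains deep terms
  # exact match becomes core, never auxiliary
  res <- extract_core_auxiliary(deep[1], deep[1], dag, mapping,
                                tau = 0.5, min_depth = 3)
  expect_setequal(res$core$set_id, deep[1])
  expect_equal(nrow(res$auxiliary), 0)
  # chain parent/child at similarity 2/3 >= tau merge into one cluster
  chain <- chain_dag()
  chain_map <- tibble::tibble(set_id = c("CA", "CB"),
                              term_id = c("GO:A", "GO:B"))
  res2 <- extract_core_auxiliary("CA", "CB", chain, chain_map,
                                 tau = 0.5, min_depth = 0)
  expect_equal(sort(unique(res2$core$term_id)), c("GO:A", "GO:B"))
  expect_equal(length(unique(res2$core$cluster)), 1)
  # disjoint terms fall into the symmetric difference
  two <- gsreg:::new_go_dag(
    tibble::tibble(term_id = c("GO:R1", "GO:R2"),
                   name = c("r1", "r2"), namespace = "bp", obsolete = FALSE),
    tibble::tibble(child = character(), parent = character(),
                   relation = character()))
  res3 <- extract_core_auxiliary(
    "X", "Y", two,
    tibble::tibble(set_id = c("X", "Y"), term_id = c("GO:R1", "GO:R2")),
    tau = 0.5, min_depth = 0)
  expect_equal(nrow(res3$core), 0)
  expect_setequal(res3$auxiliary$set_id, c("X", "Y"))
  # upper-level terms are excluded before matching
  res4 <- extract_core_auxiliary("CA", "CB", chain, chain_map,
                                 tau = 0.5, min_depth = 2)
  expect_equal(res4$excluded_upper_level, "GO:A")
  # core and auxiliary never overlap
  expect_length(intersect(res2$core$term_id, res2$auxiliary$term_id), 0)
})

test_that("deregulation table separates planted from null sets on a small cohort", {
  cfg <- synthetic_config(n_genes = 400, n_sets = 30, set_size = c(8, 8),
                          n_planted_common = 5, n_planted_progressive = 0,
                          pi_common = 0.8, n_controls = 20,
                          n_cases = c(20, 2, 2, 2), seed = 11)
  coh <- generate_cohort(cfg)
  fp <- run_functionome(coh$expression, coh$annotation, coh$collection)
  d <- deregulation_table(fp, coh$annotation, groups = "stageI")
  expect_true(all(d$p_value >= 0, d$p_value <= 1))
  expect_true(all(sort(d$rank) == seq_len(nrow(d))))
  planted <- coh$truth$set_id[coh$truth$class == "common"]
  top5 <- rank_deregulated(d, "stageI", top_k = 5)
  expect_setequal(top5, planted)
  expect_true(all(d$ratio[d$set_id %in% planted] < 1))
})
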