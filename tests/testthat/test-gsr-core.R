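test_that("rank conversion uses average ranks on ties", {
  expect_equal(to_ranks(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(to_ranks(c(2, 2, 1)), c(2.5, 2.5, 1))
  expect_equal(to_ranks(1:6), as.numeric(1:6))
})

test_that("rank template reproduces the worked majority example", {
  expr <- tiny_expr()
  tpl <- build_rank_template(expr, tiny_controls(), c("A", "B", "C"), "S")
  expect_s3_class(tpl, "gsr_template")
  expect_equal(tpl$genes_used, c("A", "B", "C"))
  expect_equal(tpl$pairs$order, c(TRUE, TRUE, TRUE))       # A<B, A<C, B<C
  expect_equal(tpl$pairs$support, c(2 / 3, 1, 2 / 3))
  # single control: template equals that sample's ordering, support 1
  tpl1 <- build_rank_template(expr, "s1", c("A", "B", "C"))
  expect_true(all(tpl1$pairs$order))
  expect_true(all(tpl1$pairs$support == 1))
  # fewer than two present genes: skipped, not errored
  sk <- build_rank_template(expr, tiny_controls(), c("A", "ZZZ"))
  expect_s3_class(sk, "gsr_set_skipped")
  expect_equal(sk$reason, "too_few_genes")
  expect_error(build_rank_template(expr, character(0), c("A", "B")),
               "control")
})

test_that("GSR index matches the worked per-sample values and identities", {
  expr <- tiny_expr()
  tpl <- build_rank_template(expr, tiny_controls(), c("A", "B", "C"))
  expect_equal(gsr_index(expr[, "case_rev"], tpl), 0)          # fully reversed
  expect_equal(gsr_index(expr[, "case_mid"], tpl), 2 / 3)
  expect_equal(gsr_index(c(A = 1, B = 2, C = 3), tpl), 1)      # exact match
  # gene input order of the set never matters
  tpl2 <- build_rank_template(expr, tiny_controls(), c("C", "A", "B"))
  expect_equal(tpl2$pairs, tpl$pairs)
  expect_error(gsr_index(c(A = 1, B = 2), tpl), "lacks values")
})

test_that("template and index agree with brute-force enumeration on random fixtures", {
  for (seed in 1:12) {
    n_genes <- 2 + (seed %% 3)          # 2..4 genes
    n_ctrl <- 2 + (seed %% 5)           # 2..6 controls
    expr <- random_fixture(n_genes, n_ctrl + 2, seed)
    controls <- colnames(expr)[seq_len(n_ctrl)]
    genes <- rownames(expr)
    tpl <- build_rank_template(expr, controls, genes)
    oracle <- brute_template(expr, controls, genes)
    expect_equal(tpl$pairs$order, unname(oracle$order))
    expect_equal(tpl$pairs$support, unname(oracle$support))
    for (s in colnames(expr)) {
      expect_equal(gsr_index(expr[, s], tpl), brute_gsr(expr[, s], oracle))
    }
  }
})

test_that("the majority template maximizes the mean control matching score", {
  for (seed in 1:6) {
    n_genes <- 3 + (seed %% 2)          # 3..4 genes -> up to 2^6 assignments
    n_ctrl <- 3 + (seed %% 4)           # 3..6 controls
    expr <- random_fixture(n_genes, n_ctrl, seed + 100)
    controls <- colnames(expr)
    genes <- rownames(expr)
    tpl <- build_rank_template(expr, controls, genes)
    p <- nrow(tpl$pairs)
    scores <- vapply(seq_len(2^p) - 1L, function(code) {
      assignment <- as.logical(bitwAnd(code, 2^(seq_len(p) - 1L)) > 0)
      brute_assignment_score(expr, controls, genes, assignment)
    }, numeric(1))
    tpl_score <- brute_assignment_score(expr, controls, genes,
                                        tpl$pairs$order)
    expect_equal(tpl_score, max(scores))
  }
})

test_that("GSR bounds hold and tie-free reversal flips the index", {
  expr <- tiny_expr()
  tpl <- build_rank_template(expr, tiny_controls(), c("A", "B", "C"))
  for (seed in 1:50) {
    v <- withr::with_seed(seed, setNames(sample(100, 3), c("A", "B", "C")))
    g <- gsr_index(v, tpl)
    expect_gte(g, 0); expect_lte(g, 1)
    expect_equal(gsr_index(-v, tpl), 1 - g)
  }
})

test_that("functionome reconstruction restricts to common genes and scores both arms", {
  expr <- tiny_expr()
  coll <- tibble::tibble(set_id = c("S", "ABSENT"), label = "x",
                         genes = list(c("A", "B", "C"), c("X1", "X2")))
  fp <- reconstruct_functionome(expr[, c("case_rev", "case_mid"), drop = FALSE],
                                expr[, tiny_controls()], coll)
  expect_equal(fp$case$S, c(0, 2 / 3))
  expect_equal(fp$control$S, c(1, 2 / 3, 2 / 3))
  expect_equal(mean(fp$control$S), 7 / 9)
  expect_true(all(is.na(fp$case$ABSENT)))
  expect_equal(fp$skipped_sets$reason, "too_few_genes")
  # a case identical to a control sample gets that control's score
  case_same <- expr[, "s2", drop = FALSE]
  colnames(case_same) <- "twin"
  fp2 <- reconstruct_functionome(case_same, expr[, tiny_controls()], coll[1, ])
  expect_equal(fp2$case$S, fp2$control$S[2])
  expect_error(
    reconstruct_functionome(matrix(1, 1, 1, dimnames = list("Q", "c1")),
                            expr[, tiny_controls()], coll),
    "no genes")
})

test_that("leave-one-out control scoring matches per-sample template rebuilds", {
  expr <- random_fixture(4, 6, 42)
  controls <- colnames(expr)
  coll <- tibble::tibble(set_id = "S", label = "x",
                         genes = list(rownames(expr)))
  fp <- reconstruct_functionome(expr[, 1, drop = FALSE], expr, coll,
                                loo_controls = TRUE)
  want <- vapply(controls, function(s) {
    tpl <- build_rank_template(expr[, setdiff(controls, s), drop = FALSE],
                               setdiff(controls, s), rownames(expr))
    gsr_index(expr[, s], tpl)
  }, numeric(1))
  expect_equal(fp$control$S, unname(want))
})

test_that("corrected group means follow the control-average rescaling", {
  # equal control means leave the case means unchanged
  expect_equal(corrected_group_means(c(0.6, 0.5), c(0.7, 0.7)), c(0.6, 0.5))
  # a single group is its own grand mean
  expect_equal(corrected_group_means(0.61, 0.65), 0.61)
  expect_error(corrected_group_means(c(0.5, 0.5), c(0.5, 0)), "positive")
})

test_that("case/control ratio is elementwise with NA on zero controls", {
  expect_equal(sc_control_ratio(0.45, 0.9), 0.5)
  expect_equal(sc_control_ratio(0.7, 0.7), 1)
  expect_equal(sc_control_ratio(c(0.2, 0.4), c(0.4, 0.5)), c(0.5, 0.8))
  expect_warning(r <- sc_control_ratio(c(0.2, 0.4), c(0.4, 0)), "NA")
  expect_equal(r, c(0.5, NA))
})

test_that("immunofunctionome extraction subsets mapped columns in order", {
  fun <- tibble::as_tibble(setNames(as.list(c(0.5, 0.6, 0.7, 0.8)),
                                    paste0("SET", 1:4)))
  fun <- dplyr::bind_cols(tibble::tibble(sample_id = "s1"), fun)
  mapping <- tibble::tibble(set_id = paste0("SET", 1:4),
                            term_id = paste0("GO:", 1:4))
  im <- extract_immunofunctionome(fun, mapping, c("GO:2", "GO:4"))
  expect_equal(names(im), c("sample_id", "SET2", "SET4"))
  # all terms -> identity
  expect_equal(extract_immunofunctionome(fun, mapping, paste0("GO:", 1:4)),
               fun)
  expect_error(extract_immunofunctionome(fun, mapping, "GO:99"), "offspring")
})
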