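# Small in-code fixtures shared by several test files.

# The worked 3-gene example: 3 controls with a 2/3-majority ordering
# A < B < C and one fully reversed case sample.
tiny_expr <- function() {
  m <- rbind(A = c(1, 1, 2, 3, 2),
             B = c(2, 3, 1, 2, 1),
             C = c(3, 2, 3, 1, 3))
  colnames(m) <- c("s1", "s2", "s3", "case_rev", "case_mid")
  m
}

tiny_controls <- function() c("s1", "s2", "s3")

# Chain ontology: root <- a <- b (is_a).
chain_dag <- function() {
  gsreg:::new_go_dag(
    tibble::tibble(term_id = c("GO:R", "GO:A", "GO:B"),
                   name = c("root proc", "a proc", "b proc"),
                   namespace = "bp", obsolete = FALSE),
    tibble::tibble(child = c("GO:A", "GO:B"),
                   parent = c("GO:R", "GO:A"),
                   relation = "is_a"))
}

# Diamond: d is_a b, d is_a c, b and c is_a root.
diamond_dag <- function() {
  gsreg:::new_go_dag(
    tibble::tibble(term_id = c("GO:R", "GO:B", "GO:C", "GO:D"),
                   name = paste(c("root", "b", "c", "d"), "proc"),
                   namespace = "bp", obsolete = FALSE),
    tibble::tibble(child = c("GO:B", "GO:C", "GO:D", "GO:D"),
                   parent = c("GO:R", "GO:R", "GO:B", "GO:C"),
                   relation = "is_a"))
}

# Random tie-free expression fixture over a small gene universe.
random_fixture <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(sample(seq_len(n_genes * n_samples)) + runif(n_genes * n_samples) / 2,
                nrow = n_genes)
    dimnames(m) <- list(paste0("G", seq_len(n_genes)),
                        paste0("S", seq_len(n_samples)))
    m
  })
}

# A two-arm cohort whose case group has every set disrupted at `pi`;
# returns the functionome pair plus labels, for classification tests.
separable_fixture <- function(pi = 0.9, seed = 7) {
  cfg <- synthetic_config(n_sets = 50, n_genes = 600, n_planted_common = 50,
                          n_planted_progressive = 0, pi_common = pi,
                          n_controls = 20, n_cases = c(20, 2, 2, 2),
                          seed = seed)
  coh <- generate_cohort(cfg)
  fp <- run_functionome(coh$expression, coh$annotation, coh$collection)
  ann <- coh$annotation
  keep <- ann$group == "stageI"
  x <- dplyr::bind_rows(
    fp$case[match(ann$sample_id[keep], fp$case$sample_id), ],
    fp$control)
  list(features = x,
       labels = c(rep("case", sum(keep)), rep("control", nrow(fp$control))))
}
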