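# Internal helpers shared across modules.

# Uppercase gene symbols; GMT collections are uppercase, array tables vary.
normalize_symbol <- function(x) toupper(trimws(x))

# MSigDB-style normalization of an ontology term name: "B cell activation"
# -> "GO_B_CELL_ACTIVATION". Every non-alphanumeric becomes one underscore.
normalize_term_name <- function(name) {
  paste0("GO_", gsub("[^A-Za-z0-9]", "_", toupper(trimws(name))))
}

# The default group label set: four tumor stages plus the control cohort.
default_group_labels <- function() {
  c("stageI", "stageII", "stageIII", "stageIV", "control")
}

stage_labels <- function() c("stageI", "stageII", "stageIII", "stageIV")

# Functionome tibbles carry sample_id first and one column per gene set.
functionome_matrix <- function(functionome) {
  stopifnot(is.data.frame(functionome), "sample_id" %in% names(functionome))
  m <- as.matrix(functionome[setdiff(names(functionome), "sample_id")])
  rownames(m) <- functionome$sample_id
  storage.mode(m) <- "double"
  m
}

as_functionome <- function(mat) {
  tibble::as_tibble(mat, rownames = "sample_id")
}

# Deterministic seed streams derived from one user seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2048L + as.integer(offset) %% 2048L
}
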