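#' Read a minimal Gene Ontology DAG from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete`. Obsolete terms are recorded
#' but carry no edges and are excluded from traversals. The graph is checked
#' to be acyclic and free of dangling edge endpoints.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag`: a list with `terms` (tibble:
#'   `term_id`, `name`, `namespace`, `obsolete`) and `edges` (tibble:
#'   `child`, `parent`, `relation`).
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  # Split into stanzas; only [Term] stanzas matter here.
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) abort("No stanzas found in OBO file.")
  ends <- c(starts[-1L] - 1L, length(lines))
  terms <- list()
  edges <- list()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[(starts[s] + 1L):ends[s]]
    block <- block[nzchar(block)]
    field <- function(key) {
      hits <- grep(paste0("^", key, ":"), block, value = TRUE)
      trimws(sub(paste0("^", key, ":\\s*"), "", hits))
    }
    id <- field("id")
    if (length(id) != 1L) abort("Term stanza without a single id.")
    obsolete <- any(field("is_obsolete") == "true")
    terms[[length(terms) + 1L]] <- tibble::tibble(
      term_id = id,
      name = field("name")[1] %||% NA_character_,
      namespace = field("namespace")[1] %||% NA_character_,
      obsolete = obsolete
    )
    if (!obsolete) {
      isa <- sub("\\s*!.*$", "", field("is_a"))
      rel <- field("relationship")
      part <- sub("\\s*!.*$", "", sub("^part_of\\s+", "",
                                      grep("^part_of\\s", rel, value = TRUE)))
      if (length(isa) > 0L) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          child = id, parent = trimws(isa), relation = "is_a")
      }
      if (length(part) > 0L) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          child = id, parent = trimws(part), relation = "part_of")
      }
    }
  }
  terms <- dplyr::bind_rows(terms)
  edges <- if (length(edges) > 0L) dplyr::bind_rows(edges) else
    tibble::tibble(child = character(), parent = character(),
                   relation = character())
  if (anyDuplicated(terms$term_id)) abort("Duplicate term id in OBO file.")
  new_go_dag(terms, edges)
}

# Validating constructor shared by the reader and the synthetic generator.
new_go_dag <- function(terms, edges) {
  known <- terms$term_id[!terms$obsolete]
  dangling <- setdiff(unique(c(edges$child, edges$parent)), known)
  if (length(dangling) > 0L) {
    abort(paste0("Edge endpoint(s) not defined as non-obsolete terms: ",
                 paste(head(dangling, 5), collapse = ", ")))
  }
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = known)
    if (!igraph::is_dag(g)) {
      scc <- igraph::components(g, mode = "strong")
      in_cycle <- names(scc$membership)[
        scc$membership %in% which(scc$csize > 1L)]
      member <- if (length(in_cycle) > 0L) in_cycle[1] else
        edges$child[edges$child == edges$parent][1]
      abort(sprintf("Ontology graph contains a cycle (involving '%s').",
                    member))
    }
  }
  structure(list(terms = terms, edges = edges), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

dag_check_terms <- function(dag, ids, allow_obsolete = FALSE) {
  unknown <- setdiff(ids, dag$terms$term_id)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown term id(s): ", paste(unknown, collapse = ", ")))
  }
  if (!allow_obsolete) {
    obs <- intersect(ids, dag$terms$term_id[dag$terms$obsolete])
    if (length(obs) > 0L) {
      abort(paste0("Obsolete term id(s): ", paste(obs, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Offspring closure of ancestor terms
#'
#' All terms reachable from the given ancestors by descending child-direction
#' edges of the chosen relation types, transitively. This is how the
#' immunofunctionome is defined: the offspring of "immune system process"
#' and "inflammatory response" within the functionome.
#'
#' @param dag A `go_dag`.
#' @param ancestor_ids Character vector of ancestor term ids.
#' @param relations Edge types to follow; default both `is_a` and `part_of`.
#' @param include_self Include the ancestors themselves (default `TRUE`).
#' @return Character vector of term ids (a set; no duplicates).
#' @export
go_offspring <- function(dag, ancestor_ids,
                         relations = c("is_a", "part_of"),
                         include_self = TRUE) {
  dag_check_terms(dag, ancestor_ids)
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  children_of <- split(e$child, e$parent)
  seen <- character(0)
  frontier <- unique(ancestor_ids)
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  out <- unique(seen)
  if (!include_self) out <- setdiff(out, ancestor_ids)
  out
}

#' Shortest-path depth of a term
#'
#' Length of the shortest parent path from the term to any root (a
#' non-obsolete term with no parents). Roots have depth 0. Used to
#' operationalize the exclusion of non-specific upper-level terms.
#'
#' @inheritParams go_offspring
#' @param term_id A single term id (not obsolete).
#' @param relations Edge types to follow.
#' @return Non-negative integer depth.
#' @export
go_depth <- function(dag, term_id, relations = c("is_a", "part_of")) {
  stopifnot(length(term_id) == 1L)
  dag_check_terms(dag, term_id)
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  parents_of <- split(e$parent, e$child)
  has_parent <- names(parents_of)
  depth <- 0L
  frontier <- term_id
  seen <- character(0)
  repeat {
    if (any(!frontier %in% has_parent)) return(depth)
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(parents_of[frontier], use.names = FALSE)), seen)
    depth <- depth + 1L
    if (length(frontier) == 0L) return(depth - 1L)  # defensive; DAG has roots
  }
}

# Ancestor closure including the term itself.
ancestor_closure <- function(dag, term_id, relations = c("is_a", "part_of")) {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  parents_of <- split(e$parent, e$child)
  seen <- character(0)
  frontier <- term_id
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(parents_of[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

#' Ancestor-closure Jaccard semantic similarity of two terms
#'
#' The similarity of two terms is the Jaccard index of their ancestor
#' closures (each closure includes the term itself). It is symmetric,
#' bounded in \eqn{[0,1]}, and equals 1 exactly when the closures coincide.
#' This deterministic, DAG-only measure needs no external information
#' content and is used to merge related deregulated functions into core
#' elements.
#'
#' @inheritParams go_offspring
#' @param term_a,term_b Term ids (not obsolete).
#' @param relations Edge types defining ancestry.
#' @return Similarity in `[0, 1]`.
#' @export
go_semantic_similarity <- function(dag, term_a, term_b,
                                   relations = c("is_a", "part_of")) {
  dag_check_terms(dag, c(term_a, term_b))
  a <- ancestor_closure(dag, term_a, relations)
  b <- ancestor_closure(dag, term_b, relations)
  length(intersect(a, b)) / length(union(a, b))
}

#' Map gene set names to ontology term ids
#'
#' Gene set names in MSigDB c5-style collections are not GO accessions, so
#' sets are matched to terms by name normalization: the term name is
#' uppercased, every non-alphanumeric becomes an underscore, and the result
#' is prefixed with `GO_`. An explicit mapping (tibble with `set_id`,
#' `term_id`) takes precedence over name matching. Unmapped sets are kept in
#' the output with `term_id = NA` and reported via a message, never silently
#' dropped.
#'
#' @param collection Gene set collection tibble (from [read_gmt()]).
#' @param dag A `go_dag`.
#' @param explicit_mapping Optional tibble with columns `set_id`, `term_id`.
#' @return Tibble with columns `set_id`, `term_id` (NA when unmapped), in
#'   collection order.
#' @export
map_sets_to_terms <- function(collection, dag, explicit_mapping = NULL) {
  active <- dag$terms[!dag$terms$obsolete, , drop = FALSE]
  norm <- normalize_term_name(active$name)
  lookup <- setNames(active$term_id, norm)
  mapped <- unname(lookup[collection$set_id])
  clash <- unique(norm[duplicated(norm)])
  hit_clash <- intersect(collection$set_id, clash)
  if (length(hit_clash) > 0L) {
    abort(paste0(
      "Ambiguous normalized term name(s): ",
      paste(hit_clash, collapse = ", "),
      " match more than one ontology term."
    ))
  }
  if (!is.null(explicit_mapping)) {
    stopifnot(all(c("set_id", "term_id") %in% names(explicit_mapping)))
    dag_check_terms(dag, explicit_mapping$term_id)
    idx <- match(collection$set_id, explicit_mapping$set_id)
    mapped <- ifelse(!is.na(idx), explicit_mapping$term_id[idx], mapped)
  }
  out <- tibble::tibble(set_id = collection$set_id, term_id = mapped)
  n_un <- sum(is.na(out$term_id))
  if (n_un > 0L) {
    inform(sprintf("%d gene set(s) could not be mapped to ontology terms.",
                   n_un))
  }
  if (anyDuplicated(stats::na.omit(out$term_id))) {
    abort("Mapping is not injective: two sets map to the same term.")
  }
  out
}

#' Write an OBO 1.2 file for a `go_dag`
#'
#' Emits only the fields this package reads (id, name, namespace, is_a,
#' relationship: part_of, is_obsolete); used chiefly by the synthetic
#' fixture generator.
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(dag$edges, dag$edges$child)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    lines <- c("[Term]", paste0("id: ", t$term_id),
               paste0("name: ", t$name))
    if (!is.na(t$namespace)) {
      lines <- c(lines, paste0("namespace: ", t$namespace))
    }
    if (t$obsolete) {
      lines <- c(lines, "is_obsolete: true")
    } else {
      e <- by_child[[t$term_id]]
      if (!is.null(e)) {
        isa <- e$parent[e$relation == "is_a"]
        part <- e$parent[e$relation == "part_of"]
        lines <- c(lines,
                   if (length(isa)) paste0("is_a: ", isa),
                   if (length(part)) paste0("relationship: part_of ", part))
      }
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}
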