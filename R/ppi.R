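#' Construct a protein-protein interaction graph
#'
#' Undirected, unweighted edges between gene symbols; the experimental
#' evidence label (affinity chromatography, cross-linking MS, ...) is
#' carried as an annotation only. Self-loops are rejected and duplicate
#' edges (in either orientation) collapsed.
#'
#' @param edges data frame with columns `gene_a`, `gene_b` and optionally
#'   `evidence`.
#' @return object of class `interaction_graph`.
#' @export
interaction_graph <- function(edges = data.frame(gene_a = character(0),
                                                 gene_b = character(0),
                                                 evidence = character(0))) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  if (is.null(edges$evidence)) edges$evidence <- NA_character_
  if (any(edges$gene_a == edges$gene_b)) stop("self-loop in edge list")
  key <- ifelse(edges$gene_a < edges$gene_b,
                paste(edges$gene_a, edges$gene_b),
                paste(edges$gene_b, edges$gene_a))
  edges <- edges[!duplicated(key), c("gene_a", "gene_b", "evidence"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction graph: %d edges, %d genes\n", nrow(x$edges),
              length(unique(c(x$edges$gene_a, x$edges$gene_b)))))
  invisible(x)
}

#' Read an interaction edge list
#'
#' Whitespace/tab-delimited `gene_a gene_b [evidence]`; a header row
#' starting with `gene_a` is skipped; an empty file yields an empty graph.
#'
#' @param path file path.
#' @return an [interaction_graph()].
#' @export
read_edges <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^gene_a\\b", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) return(interaction_graph())
  parts <- strsplit(lines, "[ \t]+")
  interaction_graph(data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    evidence = vapply(parts, function(p) if (length(p) >= 3L) paste(p[-(1:2)], collapse = " ") else NA_character_,
                      character(1)),
    stringsAsFactors = FALSE))
}

#' Write an interaction edge list (round-trips through [read_edges()])
#' @param graph an [interaction_graph()].
#' @param path output path.
#' @export
write_edges <- function(graph, path) {
  e <- graph$edges
  writeLines(c("gene_a\tgene_b\tevidence",
               sprintf("%s\t%s\t%s", e$gene_a, e$gene_b,
                       ifelse(is.na(e$evidence), ".", e$evidence))), path)
  invisible(path)
}

as_igraph <- function(graph, extra_vertices = character(0)) {
  verts <- unique(c(graph$edges$gene_a, graph$edges$gene_b, extra_vertices))
  igraph::graph_from_data_frame(graph$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Bounded-length simple paths from candidate genes to a target gene set
#'
#' Enumerates all simple paths of at most `max_edges` edges from each
#' source gene to any target gene, deduplicated and sorted by (length,
#' lexicographic order). When searching from one source the other sources
#' are removed from the graph interior (unless they are themselves
#' targets), so a candidate is linked through shared biology, not through
#' another candidate. A source that is itself a target is returned as a
#' length-0 path and flagged.
#'
#' @param graph an [interaction_graph()].
#' @param source_genes,target_genes character vectors of gene symbols.
#' @param max_edges maximum path length in edges (>= 1).
#' @return named list (one entry per source) of lists with `paths` (each a
#'   character vector of genes, source first) and `self_target` flag.
#' @export
find_paths <- function(graph, source_genes, target_genes, max_edges = 2) {
  stopifnot(max_edges >= 1)
  out <- stats::setNames(vector("list", length(source_genes)), source_genes)
  for (src in source_genes) {
    self_target <- src %in% target_genes
    drop <- setdiff(setdiff(source_genes, src), target_genes)
    g <- as_igraph(graph, extra_vertices = src)
    g <- igraph::delete_vertices(g, intersect(drop, igraph::V(g)$name))
    paths <- list()
    if (self_target) paths <- c(paths, list(src))
    for (tgt in setdiff(intersect(target_genes, igraph::V(g)$name), src)) {
      sp <- igraph::all_simple_paths(g, from = src, to = tgt,
                                     cutoff = max_edges)
      paths <- c(paths, lapply(sp, function(p) igraph::V(g)$name[p]))
    }
    paths <- unique(paths)
    ord <- order(lengths(paths),
                 vapply(paths, paste, character(1), collapse = "\r"))
    out[[src]] <- list(paths = paths[ord], self_target = self_target)
  }
  out
}

#' Append interaction-path columns to a candidate report
#'
#' @param candidates data frame with a `gene` column (e.g. germline
#'   survivors joined with their tiers).
#' @param paths result of [find_paths()].
#' @return `candidates` with `connected_targets` (comma-separated genes
#'   reached) and `shortest_path` (`"A -> B -> C"`, empty when
#'   unconnected) columns.
#' @export
annotate_candidates <- function(candidates, paths) {
  candidates$connected_targets <- rep("", nrow(candidates))
  candidates$shortest_path <- rep("", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    p <- paths[[candidates$gene[i]]]
    if (is.null(p) || length(p$paths) == 0L) next
    ends <- unique(vapply(p$paths, function(x) x[length(x)], character(1)))
    candidates$connected_targets[i] <- paste(sort(ends), collapse = ",")
    best <- p$paths[[1L]]
    candidates$shortest_path[i] <- paste(best, collapse = " -> ")
  }
  candidates
}
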