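#' Read a protein-to-term annotation
#'
#' Accepts a two-column TSV (`protein_id`, `term_id`; terms may repeat
#' across proteins) or a GAF-like tab-separated file from which columns 2
#' (object identifier) and 5 (term) are extracted. An optional two-column
#' term-label TSV supplies descriptive names.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param labels Optional path to a `term_id<TAB>label` TSV.
#' @return A `term_annotation` list: `terms` (data frame `protein_id`,
#'   `term_id`) and `labels` (named character vector, possibly empty).
#' @export
read_term_annotation <- function(path, format = c("tsv", "gaf"),
                                 labels = NULL) {
  format <- match.arg(format)
  stop_if(!file.exists(path), "term annotation not found: ", path)
  if (format == "tsv") {
    d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
    terms <- data.frame(protein_id = d[[1]], term_id = d[[2]],
                        stringsAsFactors = FALSE)
  } else {
    d <- utils::read.delim(path, header = FALSE, comment.char = "!",
                           colClasses = "character")
    terms <- data.frame(protein_id = d[[2]], term_id = d[[5]],
                        stringsAsFactors = FALSE)
  }
  terms <- unique(terms)
  lab <- character(0)
  if (!is.null(labels)) {
    ld <- utils::read.delim(labels, header = TRUE, colClasses = "character")
    lab <- stats::setNames(ld[[2]], ld[[1]])
  }
  structure(list(terms = terms, labels = lab), class = "term_annotation")
}

#' Hypergeometric annotation enrichment with BH correction
#'
#' For each term, tests overrepresentation of the target set within an
#' explicit background universe using the upper-tail hypergeometric
#' probability P[X >= k], where k is the number of target proteins carrying
#' the term, K the term's size in the background, n the target size and N
#' the background size. P-values are Benjamini-Hochberg adjusted across all
#' tested terms. The background should be the quantified proteome (post
#' detection filtering), not a whole-genome universe.
#'
#' @param target Character vector of target proteins; must be a subset of
#'   `background`.
#' @param background Character vector, the annotation universe.
#' @param annotation A `term_annotation` (or a data frame with columns
#'   `protein_id`, `term_id`).
#' @param fdr_alpha BH q-value cutoff used when `filter = TRUE`.
#' @param filter If `TRUE` (default) return only terms with
#'   `q_value < fdr_alpha`; the full table is kept in attribute `"all"`.
#' @return An `enrichment_result` data frame with columns `term_id`,
#'   `label`, `k`, `K`, `n`, `N`, `p_value`, `q_value`, sorted by q then p.
#' @export
hypergeometric_enrichment <- function(target, background, annotation,
                                      fdr_alpha = 0.001, filter = TRUE) {
  stop_if(length(target) == 0, "empty target set")
  stop_if(!all(target %in% background), "target must be a subset of background")
  terms <- if (inherits(annotation, "term_annotation")) annotation$terms
           else annotation
  labels <- if (inherits(annotation, "term_annotation")) annotation$labels
            else character(0)
  terms <- terms[terms$protein_id %in% background, , drop = FALSE]
  stop_if(nrow(terms) == 0, "no annotations overlap the background")
  N <- length(unique(background))
  n <- length(unique(target))
  K <- table(terms$term_id)
  in_target <- terms$protein_id %in% target
  k <- table(factor(terms$term_id, levels = names(K))[in_target])
  p <- stats::phyper(as.integer(k) - 1, as.integer(K), N - as.integer(K),
                     n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(K),
                    label = ifelse(names(K) %in% names(labels),
                                   labels[names(K)], names(K)),
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p_value = p, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  if (filter) {
    all_tab <- out
    out <- out[out$q_value < fdr_alpha, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("enrichment_result", "data.frame")
    attr(out, "all") <- all_tab
  }
  out
}

#' Read a signed regulator-to-target edge list
#'
#' Three-column TSV `regulator<TAB>target<TAB>sign` with sign +1 (the
#' regulator increases the target) or -1 (decreases).
#'
#' @param path Path to the TSV file.
#' @return Data frame `regulator`, `target`, `sign`.
#' @export
read_regulator_network <- function(path) {
  stop_if(!file.exists(path), "regulator network not found: ", path)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  stop_if(ncol(d) < 3, "regulator network needs three columns")
  out <- data.frame(regulator = as.character(d[[1]]),
                    target = as.character(d[[2]]),
                    sign = as.integer(d[[3]]), stringsAsFactors = FALSE)
  stop_if(!all(out$sign %in% c(-1L, 1L)), "edge signs must be +1 or -1")
  stop_if(anyDuplicated(out[, c("regulator", "target")]) > 0,
          "duplicate (regulator, target) edges")
  out
}

#' Upstream regulator activation z-scores
#'
#' For each regulator, considers its targets among the significantly
#' changed proteins of a contrast. A target is consistent with activation
#' when edge sign times observed direction (+1 up, -1 down) is positive.
#' The activation score is
#' `z = (n_consistent - n_inconsistent) / sqrt(n_consistent + n_inconsistent)`;
#' large positive z predicts an activated regulator, large negative z an
#' inhibited one. Regulators with fewer than `min_targets` significant
#' targets are omitted (small target sets give noise-dominated scores).
#'
#' @param tab A contrast table with direction calls.
#' @param network Signed edge list (data frame `regulator`, `target`,
#'   `sign`).
#' @param min_targets Minimum significant targets required (default 4).
#' @return Data frame `regulator`, `n_consistent`, `n_inconsistent`,
#'   `n_targets`, `z`, sorted by decreasing z.
#' @export
regulator_activation_z <- function(tab, network, min_targets = 4) {
  stop_if(nrow(network) == 0, "empty regulator network")
  sig <- tab[tab$significant, , drop = FALSE]
  dir_num <- stats::setNames(ifelse(sig$direction == "up", 1L, -1L),
                             sig$protein_id)
  net <- network[network$target %in% names(dir_num), , drop = FALSE]
  if (nrow(net) == 0) {
    return(data.frame(regulator = character(0), n_consistent = integer(0),
                      n_inconsistent = integer(0), n_targets = integer(0),
                      z = numeric(0), stringsAsFactors = FALSE))
  }
  consistent <- net$sign * dir_num[net$target] > 0
  nc <- tapply(consistent, net$regulator, sum)
  nt <- tapply(consistent, net$regulator, length)
  ni <- nt - nc
  keep <- nt >= min_targets
  out <- data.frame(regulator = names(nt)[keep],
                    n_consistent = as.integer(nc[keep]),
                    n_inconsistent = as.integer(ni[keep]),
                    n_targets = as.integer(nt[keep]),
                    z = as.numeric((nc[keep] - ni[keep]) / sqrt(nt[keep])),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a first-neighbor network around seed proteins
#'
#' Returns the subgraph induced by the seed proteins together with their
#' immediate neighbors in a user-supplied undirected interaction network.
#' Seeds without any interaction are retained as isolated nodes.
#'
#' @param seeds Character vector of seed proteins.
#' @param interactions Two-column data frame (or matrix) of undirected
#'   edges.
#' @return A `neighborhood_network` list: `graph` (igraph), `nodes`,
#'   `edges` (two-column data frame), `seeds`, `n_nodes`, `n_edges`.
#' @export
build_neighborhood_network <- function(seeds, interactions) {
  stop_if(NROW(interactions) == 0, "empty interaction list")
  em <- cbind(as.character(interactions[[1]]),
              as.character(interactions[[2]]))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g)
  present <- intersect(seeds, igraph::V(g)$name)
  nbr <- if (length(present) > 0)
    unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                         function(v) v$name))) else
    character(0)
  keep <- union(seeds, nbr)
  sub <- igraph::induced_subgraph(g, intersect(keep, igraph::V(g)$name))
  iso <- setdiff(seeds, igraph::V(sub)$name)
  if (length(iso) > 0) sub <- igraph::add_vertices(sub, length(iso),
                                                   name = iso)
  ed <- igraph::as_edgelist(sub)
  structure(list(graph = sub,
                 nodes = igraph::V(sub)$name,
                 edges = data.frame(from = ed[, 1], to = ed[, 2],
                                    stringsAsFactors = FALSE),
                 seeds = seeds,
                 n_nodes = igraph::vcount(sub),
                 n_edges = igraph::ecount(sub)),
            class = "neighborhood_network")
}

#' Node overlap between two networks or sets
#'
#' Shared and unique node counts, plus the retention fraction
#' `|a intersect b| / |a|` — the fraction of the first network's nodes
#' retained in the second. Also applicable to enriched-term sets, giving
#' the Venn triple of a two-condition comparison.
#'
#' @param a,b `neighborhood_network` objects or character vectors.
#' @return A list with `n_a`, `n_b`, `n_shared`, `n_unique_a`,
#'   `n_unique_b`, `retention` (3 decimals).
#' @export
network_overlap <- function(a, b) {
  na_ <- if (inherits(a, "neighborhood_network")) a$nodes else
    unique(as.character(a))
  nb_ <- if (inherits(b, "neighborhood_network")) b$nodes else
    unique(as.character(b))
  shared <- length(intersect(na_, nb_))
  list(n_a = length(na_), n_b = length(nb_), n_shared = shared,
       n_unique_a = length(na_) - shared,
       n_unique_b = length(nb_) - shared,
       retention = if (length(na_) > 0)
         round(shared / length(na_), 3) else NA_real_)
}

#' Write a neighborhood network as TSV edge and node tables
#'
#' Edge list plus a node-attribute table flagging seed nodes, importable by
#' standard graph viewers.
#'
#' @param net A `neighborhood_network`.
#' @param edge_path,node_path Output paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- data.frame(node = net$nodes,
                      is_seed = net$nodes %in% net$seeds)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
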