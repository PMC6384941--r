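#' @import igraph
NULL

# tag an igraph object with our node-class bookkeeping
as_fossil_network <- function(g, bipartite = FALSE, classes = NULL) {
  graph_attr(g, "fossil_bipartite") <- bipartite
  if (bipartite) {
    stopifnot(length(classes) == 2L)
    graph_attr(g, "fossil_classes") <- classes
    V(g)$type <- V(g)$node_class == classes[2L]
  }
  g
}

is_bipartite_network <- function(net) {
  isTRUE(graph_attr(net, "fossil_bipartite"))
}

#' Taxon co-occurrence network
#'
#' Builds the unipartite network of body-fossil genera: two genera are linked
#' if they co-occur at one or more collection points. Genera without any
#' co-occurrence partner (isolated nodes) are excluded, consistent with the
#' index-taxa filter.
#'
#' @param tab An `occurrence_table`.
#' @param include_ichnogenera Include trace-fossil genera as nodes
#'   (default `FALSE`).
#' @return An `igraph` network with vertex attributes `node_class` (`"taxon"`),
#'   `kind`, `preservational_mode`, `group`, and `paleocommunity`.
#' @export
cooccurrence_network <- function(tab, include_ichnogenera = FALSE) {
  validate_occurrence_table(tab)
  kinds <- if (include_ichnogenera) c("body_genus", "ichnogenus") else "body_genus"
  taxa <- tab$taxa$name[tab$taxa$kind %in% kinds]
  if (length(taxa) < 2L) stop("input error: fewer than 2 taxa")
  occ <- tab$occurrences[tab$occurrences$taxon %in% taxa, , drop = FALSE]
  pairs <- do.call(rbind, lapply(split(occ$taxon, occ$collection_id), function(tx) {
    tx <- sort(unique(tx))
    if (length(tx) < 2L) return(NULL)
    t(utils::combn(tx, 2L))
  }))
  if (is.null(pairs)) stop("input error: no co-occurring taxa")
  pairs <- unique(as.data.frame(pairs, stringsAsFactors = FALSE))
  g <- graph_from_data_frame(pairs, directed = FALSE)
  g <- simplify(g)
  idx <- match(V(g)$name, tab$taxa$name)
  V(g)$node_class <- "taxon"
  V(g)$kind <- tab$taxa$kind[idx]
  V(g)$preservational_mode <- tab$taxa$preservational_mode[idx]
  V(g)$group <- tab$taxa$group[idx]
  V(g)$paleocommunity <- tab$taxa$paleocommunity[idx]
  as_fossil_network(g, bipartite = FALSE)
}

#' Bipartite taxon network
#'
#' Links taxa either to their paleoenvironments (taxon--environment link iff
#' the environment belongs to the taxon's environment set) or to the geologic
#' formations in which they occur.
#'
#' @param tab An `occurrence_table`.
#' @param partner `"environments"` or `"formations"`.
#' @param include_ichnogenera Include ichnogenera (default `TRUE` for
#'   formation networks, `FALSE` for environment networks, mirroring the
#'   standard network variants).
#' @param taxa_subset Optional character vector restricting the taxon side.
#' @return A bipartite `igraph` network; `node_class` is `"taxon"` on one side
#'   and `partner` (singular) on the other.
#' @export
bipartite_network <- function(tab, partner = c("environments", "formations"),
                              include_ichnogenera = (partner == "formations"),
                              taxa_subset = NULL) {
  partner <- match.arg(partner)
  force(include_ichnogenera)
  validate_occurrence_table(tab)
  kinds <- if (include_ichnogenera) c("body_genus", "ichnogenus") else "body_genus"
  taxa <- tab$taxa$name[tab$taxa$kind %in% kinds]
  if (!is.null(taxa_subset)) taxa <- intersect(taxa, taxa_subset)
  if (!length(taxa)) stop("input error: no taxa selected")

  if (partner == "environments") {
    envs <- tab$taxon_environments[taxa]
    edges <- data.frame(
      taxon = rep(names(envs), lengths(envs)),
      partner = unlist(envs, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    occ <- tab$occurrences[tab$occurrences$taxon %in% taxa, , drop = FALSE]
    edges <- unique(data.frame(
      taxon = occ$taxon,
      partner = tab$points$formation[match(occ$collection_id, tab$points$id)],
      stringsAsFactors = FALSE
    ))
  }
  if (nrow(edges) == 0L) stop("input error: empty partner side")
  partner_class <- sub("s$", "", partner)
  # prefix guard against a taxon and partner sharing a label
  vnames <- c(unique(edges$taxon), unique(edges$partner))
  if (anyDuplicated(vnames)) stop("taxon and ", partner_class,
                                  " labels collide: ",
                                  paste(vnames[duplicated(vnames)], collapse = ", "))
  g <- graph_from_data_frame(edges, directed = FALSE)
  V(g)$node_class <- ifelse(V(g)$name %in% edges$taxon, "taxon", partner_class)
  idx <- match(V(g)$name, tab$taxa$name)
  V(g)$kind <- tab$taxa$kind[idx]
  V(g)$preservational_mode <- tab$taxa$preservational_mode[idx]
  V(g)$group <- tab$taxa$group[idx]
  V(g)$paleocommunity <- tab$taxa$paleocommunity[idx]
  as_fossil_network(simplify(g), bipartite = TRUE,
                    classes = c("taxon", partner_class))
}

#' One-mode projection of a bipartite network
#'
#' Projects a bipartite network onto one node class: two nodes are linked iff
#' they share at least one neighbor in the other class. The projection is
#' unweighted by default; shared-neighbor counts are kept in the edge
#' attribute `weight` when `weighted = TRUE`.
#'
#' @param net A bipartite network from [bipartite_network()].
#' @param side The node class to project onto (e.g. `"taxon"`,
#'   `"formation"`).
#' @param weighted Keep shared-neighbor multiplicities as edge weights.
#' @return A unipartite `igraph` network on the chosen class.
#' @export
one_mode_projection <- function(net, side, weighted = FALSE) {
  if (!is_bipartite_network(net)) stop("net is not bipartite")
  classes <- graph_attr(net, "fossil_classes")
  if (!side %in% classes) stop("parameter error: '", side,
                               "' is not a node class of this network")
  proj <- bipartite_projection(net, multiplicity = TRUE)
  # bipartite_projection: proj1 = type FALSE (classes[1]), proj2 = type TRUE
  g <- if (side == classes[1L]) proj[[1L]] else proj[[2L]]
  if (!weighted) g <- delete_edge_attr(g, "weight")
  as_fossil_network(g, bipartite = FALSE)
}

#' Degree centrality
#'
#' Number of distinct neighbors of each node, excluding self-loops.
#'
#' @param net An `igraph` network.
#' @return Named integer vector.
#' @export
degree_centrality <- function(net) {
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  degree(g)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness with equal splitting across tied
#' shortest paths, computed per connected component.
#'
#' @param net An `igraph` network.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Assortativity (homophily) coefficient
#'
#' Newman's assortativity: for `attribute = "degree"` the Pearson correlation
#' of degrees at link endpoints, otherwise the nominal assortativity of a
#' categorical vertex attribute. An undefined coefficient (zero variance,
#' e.g. a regular graph or a single category) is signalled with a warning and
#' returned as `NA`.
#'
#' @param net An `igraph` network.
#' @param attribute `"degree"` or the name of a vertex attribute.
#' @return A single number in `[-1, 1]`, or `NA` with a warning when
#'   undefined.
#' @export
assortativity_coefficient <- function(net, attribute = "degree") {
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  r <- if (identical(attribute, "degree")) {
    assortativity_degree(g, directed = FALSE)
  } else {
    vals <- vertex_attr(g, attribute)
    if (is.null(vals)) stop("attribute '", attribute, "' not defined on all nodes")
    if (anyNA(vals)) stop("attribute '", attribute, "' not defined on all nodes")
    assortativity_nominal(g, as.integer(factor(vals)), directed = FALSE)
  }
  if (is.na(r) || is.nan(r)) {
    warning("assortativity undefined (zero variance) for attribute '",
            attribute, "'")
    return(NA_real_)
  }
  r
}

#' Export a network
#'
#' @param net An `igraph` network.
#' @param path Output path.
#' @param format `"graphml"` (node attributes included) or `"edgelist"` (CSV).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    write_graph(net, path, format = "graphml")
  } else {
    el <- as_data_frame(net, what = "edges")
    utils::write.csv(el, path, row.names = FALSE)
  }
  invisible(path)
}

#' Import a network written by [write_network()]
#'
#' @param path GraphML file path.
#' @return An `igraph` network with the package's node-class bookkeeping
#'   restored.
#' @export
read_network <- function(path) {
  g <- read_graph(path, format = "graphml")
  bip <- !is.null(vertex_attr(g, "node_class")) &&
    length(unique(V(g)$node_class)) == 2L
  if (bip) {
    classes <- unique(V(g)$node_class)
    classes <- c(intersect("taxon", classes), setdiff(classes, "taxon"))
    g <- as_fossil_network(g, bipartite = TRUE, classes = classes)
  } else {
    g <- as_fossil_network(g, bipartite = FALSE)
  }
  g
}
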