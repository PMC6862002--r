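#' Classify users by the credibility of what they share
#'
#' A user is a `high-sharer` when they shared at least 2 high-band pages
#' and no low-band pages, a `low-sharer` when they shared at least 2
#' low-band pages and no high-band pages, and `other` otherwise. The three
#' categories are exclusive and exhaustive.
#'
#' @param profiles tibble from [user_credibility_profiles()] (user_id plus
#'   a `bands` list-column, one entry per distinct shared page).
#' @return tibble: user_id, n_pages, n_low, n_high, category.
#' @export
classify_users_by_sharing <- function(profiles) {
  stopifnot(all(c("user_id", "bands") %in% names(profiles)))
  n_low <- vapply(profiles$bands, function(b) sum(b == "low"), integer(1))
  n_high <- vapply(profiles$bands, function(b) sum(b == "high"), integer(1))
  category <- rep("other", nrow(profiles))
  category[n_high >= 2L & n_low == 0L] <- "high-sharer"
  category[n_low >= 2L & n_high == 0L] <- "low-sharer"
  tibble::tibble(user_id = profiles$user_id,
                 n_pages = vapply(profiles$bands, length, integer(1)),
                 n_low = n_low, n_high = n_high, category = category)
}

#' Build the sharer follower network
#'
#' Keeps users who shared at least `min_shared_pages` distinct scored
#' pages, restricts the directed follower graph (edges follower ->
#' followed) to those users, and retains the largest weakly connected
#' component; among equally large components the one containing the
#' lexicographically smallest user id is kept. Vertices carry the sharer
#' category ([classify_users_by_sharing()]) and follower count.
#'
#' @param edges tibble with `follower_id`, `followed_id`.
#' @param profiles tibble from [user_credibility_profiles()].
#' @param follower_counts optional tibble `user_id`/`follower_count` for
#'   vertex attributes.
#' @param min_shared_pages minimum distinct shared pages (default 2).
#' @return directed `igraph` with vertex attributes `category` and
#'   `follower_count`, and graph attribute `min_shared_pages`; an empty
#'   graph (with a warning) when no users survive.
#' @export
build_follower_network <- function(edges, profiles, follower_counts = NULL,
                                   min_shared_pages = 2L) {
  stopifnot(all(c("follower_id", "followed_id") %in% names(edges)))
  cats <- classify_users_by_sharing(profiles)
  eligible <- cats$user_id[cats$n_pages >= min_shared_pages]
  e <- edges[edges$follower_id %in% eligible &
               edges$followed_id %in% eligible, , drop = FALSE]
  if (length(eligible) == 0L) {
    warning("no users meet the sharing threshold; returning empty network")
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::set_graph_attr(g, "min_shared_pages", min_shared_pages)
    return(g)
  }
  g <- igraph::graph_from_data_frame(
    e, directed = TRUE,
    vertices = data.frame(name = sort(eligible), stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "weak")
  max_size <- max(comp$csize)
  cand <- which(comp$csize == max_size)
  if (length(cand) > 1L) {
    # deterministic tie-break: component holding the smallest member id
    firsts <- vapply(cand, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    cand <- cand[order(firsts)][1]
  }
  g <- igraph::induced_subgraph(g, comp$membership == cand)
  nm <- igraph::V(g)$name
  g <- igraph::set_vertex_attr(
    g, "category", value = cats$category[match(nm, cats$user_id)])
  fc <- if (!is.null(follower_counts)) {
    follower_counts$follower_count[match(nm, follower_counts$user_id)]
  } else rep(NA_integer_, length(nm))
  g <- igraph::set_vertex_attr(g, "follower_count", value = fc)
  igraph::set_graph_attr(g, "min_shared_pages", min_shared_pages)
}

#' Categorical assortativity of sharer categories
#'
#' Newman's nominal assortativity of the `category` vertex attribute over
#' the network's edges: 1 when every edge joins same-category users, about
#' 0 when categories are independent of the graph.
#'
#' @param network igraph from [build_follower_network()].
#' @return coefficient in [-1, 1].
#' @export
sharing_assortativity <- function(network) {
  if (igraph::ecount(network) == 0L) {
    stop("assortativity undefined: network has no edges", call. = FALSE)
  }
  types <- igraph::V(network)$category
  if (is.null(types) || anyNA(types)) {
    stop("all vertices must carry a sharer category", call. = FALSE)
  }
  igraph::assortativity_nominal(network,
                                types = as.integer(factor(types)),
                                directed = igraph::is_directed(network))
}

#' Community detection on the follower network
#'
#' Louvain modularity optimization on the undirected collapse of the
#' follower graph; used to check whether planted communities (or real
#' subpopulations) are recoverable from the follow structure.
#'
#' @param network igraph.
#' @return integer membership vector named by user id.
#' @export
detect_communities <- function(network) {
  und <- igraph::as_undirected(network, mode = "collapse")
  cl <- igraph::cluster_louvain(und)
  setNames(igraph::membership(cl), igraph::V(network)$name)
}

#' Export a follower network to GraphML
#'
#' @param network igraph.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
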