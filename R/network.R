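# Array-level interaction graphs: condensates abstracted to graphs whose
# nodes are array molecules and whose edges carry the number and summed
# class-weighted energy of inter-array nucleosome contacts.

.default_class_weights <- c("face-to-face" = 3, "face-to-side" = 2,
                            "side-to-side" = 1)

#' Build the array interaction graph of a condensate
#'
#' Nodes are arrays; an edge joins two arrays when at least one inter-array
#' nucleosome contact exists between them.  Edge attributes: `weight_count`
#' (number of contacts) and `weight_energy` (sum of class weights; face
#' contacts are the most energetically favourable, defaults 3:2:1 for
#' face-to-face, face-to-side, side-to-side).
#'
#' @param m A `condensate_model` with every pose assigned to an array.
#' @param class_weights Named numeric vector of geometry-class weights.
#' @param census Optional precomputed [contact_census()] result (re-used
#'   instead of recomputing contacts).
#' @return An `igraph` graph with vertex attribute `name` (array id).
#' @export
build_interaction_graph <- function(m, class_weights = .default_class_weights,
                                    census = NULL) {
  stopifnot(inherits(m, "condensate_model"))
  if (is.null(m$array_of)) stop("all poses must be assigned to arrays")
  un <- setdiff(m$ids, as.integer(names(m$array_of)))
  if (length(un))
    stop("unassigned pose ids: ", paste(utils::head(un, 10), collapse = ", "))
  rec <- if (is.null(census)) contact_records(m) else census$records
  graph_from_contacts(rec, m$array_of, class_weights)
}

# assemble the array graph from a contact record table
graph_from_contacts <- function(rec, array_of,
                                class_weights = .default_class_weights) {
  arrays <- sort(unique(unname(array_of)))
  g <- igraph::make_empty_graph(n = length(arrays), directed = FALSE)
  igraph::V(g)$name <- as.character(arrays)
  inter <- rec[rec$scope == "inter-array", , drop = FALSE]
  if (nrow(inter)) {
    a1 <- unname(array_of[as.character(inter$pose_i)])
    a2 <- unname(array_of[as.character(inter$pose_j)])
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    key <- paste(lo, hi)
    w <- class_weights[inter$geometry_class]
    agg_n <- tapply(rep(1, length(key)), key, sum)
    agg_e <- tapply(w, key, sum)
    ends <- do.call(rbind, strsplit(names(agg_n), " "))
    g <- igraph::add_edges(g, as.vector(t(cbind(
      match(as.numeric(ends[, 1]), arrays),
      match(as.numeric(ends[, 2]), arrays)))))
    igraph::E(g)$weight_count <- as.numeric(agg_n)
    igraph::E(g)$weight_energy <- as.numeric(agg_e)
  }
  g
}

# second-smallest eigenvalue of the unweighted graph Laplacian
algebraic_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  L <- as.matrix(igraph::laplacian_matrix(g, weights = NA))
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  max(0, ev[2])
}

# deterministic (near-)k-regular circulant reference graph on n nodes:
# each node linked to floor(k/2) ring neighbours on each side; odd k adds
# the antipodal link (exact only for even n; flagged otherwise).
reference_circulant <- function(n, k) {
  if (k >= n - 1) return(igraph::make_full_graph(n))
  edges <- NULL
  for (d in seq_len(k %/% 2))
    edges <- rbind(edges, cbind(seq_len(n), (seq_len(n) - 1 + d) %% n + 1))
  if (k %% 2 == 1) {
    if (n %% 2 == 1)
      warning("no k-regular graph exists for odd k on odd n; ",
              "using a near-regular circulant reference")
    half <- cbind(seq_len(n), (seq_len(n) - 1 + floor(n / 2)) %% n + 1)
    edges <- rbind(edges, half)
  }
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  keep <- !duplicated(cbind(a, b)) & a != b
  igraph::graph_from_edgelist(cbind(a, b)[keep, , drop = FALSE],
                              directed = FALSE)
}

#' Normalized algebraic connectivity
#'
#' The second-smallest eigenvalue of the unweighted graph Laplacian, divided
#' by that of a deterministic circulant k-regular reference graph on the same
#' number of nodes (k = `reference_degree`, or the graph's maximum degree
#' when `"auto"`), clipped to \[0, 1\].  0 means no connections; 1 means as
#' cohesive as the reference in which every node has the highest degree.
#'
#' @param g An `igraph` graph.
#' @param reference_degree Integer reference degree, or `"auto"`.
#' @return Normalized connectivity in \[0, 1\]; attribute `disconnected` set
#'   (with a warning) when the graph is disconnected.
#' @export
#' @examples
#' p3 <- igraph::make_graph(~ A - B, B - C)
#' normalized_algebraic_connectivity(p3, reference_degree = 2)  # 1/3
normalized_algebraic_connectivity <- function(g, reference_degree = "auto") {
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  lam <- algebraic_connectivity(g)
  disconnected <- !igraph::is_connected(g)
  if (disconnected) warning("graph is disconnected; connectivity is 0")
  if (lam <= 1e-12) {
    # no normalization needed (and an edgeless graph has no meaningful
    # reference degree): no connections means 0 on the 0-1 scale
    val <- 0
    attr(val, "lambda2") <- lam
    attr(val, "lambda2_reference") <- NA_real_
    attr(val, "disconnected") <- disconnected
    return(val)
  }
  k <- if (identical(reference_degree, "auto")) {
    max(1, max(igraph::degree(g)))
  } else as.integer(reference_degree)
  ref <- reference_circulant(n, k)
  lam_ref <- algebraic_connectivity(ref)
  val <- min(1, max(0, lam / lam_ref))
  attr(val, "lambda2") <- lam
  attr(val, "lambda2_reference") <- lam_ref
  attr(val, "disconnected") <- disconnected
  val
}

#' Summary statistics of an interaction graph
#'
#' @param g An `igraph` graph with optional `weight_count` / `weight_energy`
#'   edge attributes.
#' @return List with mean degree, mean edge weights and the degree
#'   distribution table.
#' @export
graph_summary <- function(g) {
  deg <- igraph::degree(g)
  wc <- igraph::E(g)$weight_count
  we <- igraph::E(g)$weight_energy
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       mean_degree = mean(deg),
       mean_weight_count = if (is.null(wc)) NA_real_ else mean(wc),
       mean_weight_energy = if (is.null(we)) NA_real_ else mean(we),
       degree_distribution = table(deg))
}

#' Digestion (valence-reduction) percolation curve
#'
#' Emulates progressive tail digestion by deleting each nucleosome-level
#' contact independently with probability p, rebuilding the array graph from
#' the surviving contacts, and recording the largest connected component as
#' a fraction of all arrays; averaged over replicates.
#'
#' @param m A `condensate_model` with array assignments.
#' @param removal_fractions Numeric vector of deletion probabilities in
#'   \[0, 1\].
#' @param replicates Number of replicates per fraction (>= 2 for SDs).
#' @param seed Integer seed.
#' @param census Optional precomputed [contact_census()].
#' @return Data.frame with columns `fraction_removed`,
#'   `mean_largest_component`, `sd_largest_component`.
#' @export
digestion_curve <- function(m, removal_fractions, replicates = 20, seed = 1,
                            census = NULL) {
  stopifnot(all(removal_fractions >= 0 & removal_fractions <= 1))
  if (replicates < 2) stop("at least 2 replicates are needed for SDs")
  if (is.null(census)) census <- contact_census(m)
  rec <- census$records
  n_arrays <- length(unique(unname(m$array_of)))
  with_seed(seed, {
    out <- lapply(removal_fractions, function(p) {
      fr <- vapply(seq_len(replicates), function(rep) {
        keep <- runif(nrow(rec)) >= p
        g <- graph_from_contacts(rec[keep, , drop = FALSE], m$array_of)
        max(igraph::components(g)$csize) / n_arrays
      }, 0)
      data.frame(fraction_removed = p, mean_largest_component = mean(fr),
                 sd_largest_component = sd(fr))
    })
    do.call(rbind, out)
  })
}

#' Export an interaction graph
#'
#' Writes the edge list as CSV (`node_a`, `node_b`, `weight_count`,
#' `weight_energy`) or the full graph as GraphML.
#'
#' @param g An `igraph` graph.
#' @param path Output file path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_interaction_graph <- function(g, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                     weight_count = igraph::E(g)$weight_count %||%
                       rep(NA_real_, nrow(el)),
                     weight_energy = igraph::E(g)$weight_energy %||%
                       rep(NA_real_, nrow(el)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
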