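#' Enumerate all k-cliques of a co-expression network
#'
#' All node subsets of size `k` inducing a complete subgraph under the
#' chosen edge-sign filter, each reported once with members sorted;
#' the clique list is ordered lexicographically.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param k clique size, >= 3.
#' @param signMode `"both"` (default; an edge of either sign connects)
#'   or `"positive_only"`.
#' @return list of sorted character vectors of gene ids.
#' @export
enumerateKCliques <- function(network, k,
                              signMode = c("both", "positive_only")) {
  stopifnot(is(network, "CoexpressionNetwork"))
  signMode <- match.arg(signMode)
  if (k < 3L) stop("k must be >= 3")
  g <- networkToIgraph(network, signMode = signMode)
  if (igraph::vcount(g) < k) return(list())
  cl <- igraph::cliques(g, min = k, max = k)
  out <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  key <- vapply(out, paste, character(1), collapse = "\r")
  out[order(key)]
}

#' Overlapping communities by k-clique percolation (CPM)
#'
#' Two k-cliques are adjacent iff they share k-1 nodes; communities are
#' the connected components of this clique graph, and each community's
#' members are the union of its cliques' nodes. Communities may overlap
#' in genes. Module ids are assigned deterministically from the sorted
#' member lists.
#'
#' Adjacency is found by hashing each clique's (k-1)-subsets: two
#' distinct k-cliques share k-1 nodes exactly when they share a
#' (k-1)-subset, so cliques are unioned per hash bucket rather than by
#' pairwise comparison.
#'
#' @inheritParams enumerateKCliques
#' @return A [CommunityModules-class].
#' @export
cpmCommunities <- function(network, k,
                           signMode = c("both", "positive_only")) {
  signMode <- match.arg(signMode)
  cl <- enumerateKCliques(network, k, signMode)
  if (!length(cl))
    return(new("CommunityModules", modules = list(),
               k = as.integer(k), signMode = signMode))
  n <- length(cl)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_len(n)) {
    members <- cl[[ci]]
    for (drop in seq_len(k)) {
      key <- paste(members[-drop], collapse = "\r")
      prev <- buckets[[key]]
      if (is.null(prev)) buckets[[key]] <- ci
      else {
        ra <- find(prev); rb <- find(ci)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  mods <- lapply(comps, function(idx)
    sort(unique(unlist(cl[idx], use.names = FALSE))))
  key <- vapply(mods, paste, character(1), collapse = "\r")
  mods <- mods[order(key)]
  names(mods) <- sprintf("M%04d", seq_along(mods))
  new("CommunityModules", modules = mods, k = as.integer(k),
      signMode = signMode)
}

#' Link modules into a module-connection graph
#'
#' Modules A and B are linked when at least `minLinkingNodes` distinct
#' nodes of one module are shared with the other module or have a
#' network edge (either sign) into it; the reported
#' `linking_nodes` is the larger of the two per-side counts.
#'
#' @param modules a [CommunityModules-class].
#' @param network the [CoexpressionNetwork-class] the modules came from.
#' @param minLinkingNodes minimum linking-node count (default 3).
#' @return list with `modules` (the input) and `links`, a data.frame
#'   `module_a`, `module_b`, `linking_nodes`.
#' @export
moduleConnections <- function(modules, network, minLinkingNodes = 3) {
  stopifnot(is(modules, "CommunityModules"),
            is(network, "CoexpressionNetwork"))
  if (minLinkingNodes < 1) stop("minLinkingNodes must be >= 1")
  mods <- modules@modules
  ids <- names(mods)
  ed <- network@edges
  nbr <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(ed)) {
    for (r in seq_len(nrow(ed))) {
      a <- ed$gene_a[r]; b <- ed$gene_b[r]
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  neighbours <- function(g) {
    v <- nbr[[g]]
    if (is.null(v)) character() else v
  }
  sideCount <- function(A, B) {
    sum(vapply(A, function(g)
      g %in% B || length(intersect(neighbours(g), B)) > 0, logical(1)))
  }
  links <- list()
  if (length(mods) >= 2L) {
    for (i in seq_len(length(mods) - 1L)) {
      for (j in seq.int(i + 1L, length(mods))) {
        cA <- sideCount(mods[[i]], mods[[j]])
        cB <- sideCount(mods[[j]], mods[[i]])
        cnt <- max(cA, cB)
        if (cnt >= minLinkingNodes)
          links[[length(links) + 1L]] <-
            data.frame(module_a = ids[i], module_b = ids[j],
                       linking_nodes = cnt, stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(links)) do.call(rbind, links)
  else data.frame(module_a = character(), module_b = character(),
                  linking_nodes = integer(), stringsAsFactors = FALSE)
  list(modules = modules, links = links)
}

#' CPM parameter report over a range of clique sizes
#'
#' For each `k`, reports the module count, gene coverage (distinct
#' genes in any module) and the number of gene-sharing module pairs —
#' the quantities used to pick a clique size (more modules, more
#' coverage, more community overlap).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param ks integer vector of clique sizes (default 3:8).
#' @param signMode edge-sign filter (see [cpmCommunities()]).
#' @return data.frame `k`, `n_modules`, `gene_coverage`,
#'   `overlapping_pairs`.
#' @export
cpmParameterReport <- function(network, ks = 3:8,
                               signMode = c("both", "positive_only")) {
  signMode <- match.arg(signMode)
  rows <- lapply(ks, function(k) {
    cm <- cpmCommunities(network, k, signMode)
    mods <- cm@modules
    ov <- 0L
    if (length(mods) >= 2L)
      for (i in seq_len(length(mods) - 1L))
        for (j in seq.int(i + 1L, length(mods)))
          if (length(intersect(mods[[i]], mods[[j]]))) ov <- ov + 1L
    data.frame(k = k, n_modules = length(mods),
               gene_coverage = length(unique(unlist(mods))),
               overlapping_pairs = ov)
  })
  do.call(rbind, rows)
}

#' Write modules and the module graph to TSV
#'
#' @param connections result of [moduleConnections()] (or a bare
#'   [CommunityModules-class] for the modules table only).
#' @param modulesPath output TSV (`module_id`, `k`, `size`, `members`).
#' @param linksPath optional output TSV for the module links.
#' @return Invisibly, the path(s) written.
#' @export
writeModules <- function(connections, modulesPath, linksPath = NULL) {
  if (is(connections, "CommunityModules"))
    connections <- list(modules = connections, links = NULL)
  cm <- connections$modules
  mods <- cm@modules
  tab <- data.frame(module_id = names(mods), k = cm@k,
                    size = lengths(mods),
                    members = vapply(mods, paste, character(1),
                                     collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(tab, modulesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- modulesPath
  if (!is.null(linksPath) && !is.null(connections$links)) {
    write.table(connections$links, linksPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, linksPath)
  }
  invisible(paths)
}
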