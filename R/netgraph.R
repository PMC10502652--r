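NETWORKS_17 <- c("VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA",
                 "DorsAttnB", "SalVentAttnA", "SalVentAttnB", "LimbicA",
                 "LimbicB", "ContA", "ContB", "ContC", "DefaultA",
                 "DefaultB", "DefaultC", "TempPar")

#' Consolidation scheme from 17 subnetworks to macro networks
#'
#' Maps each of the 17 functional subnetworks to its macro network
#' (control subnetworks A/B/C to one control network, and so on).
#'
#' @return named character vector: subnetwork -> macro network.
#' @export
subnetworkScheme <- function() {
  c(VisCent = "Visual", VisPeri = "Visual",
    SomMotA = "Somatomotor", SomMotB = "Somatomotor",
    DorsAttnA = "DorsAttn", DorsAttnB = "DorsAttn",
    SalVentAttnA = "SalVentAttn", SalVentAttnB = "SalVentAttn",
    LimbicA = "Limbic", LimbicB = "Limbic",
    ContA = "Cont", ContB = "Cont", ContC = "Cont",
    DefaultA = "Default", DefaultB = "Default", DefaultC = "Default",
    TempPar = "TempPar")
}

#' Synthetic region-to-network lookup
#'
#' Assigns `nRegions` regions round-robin to the 17 subnetworks - a
#' synthetic stand-in for an atlas lookup, sufficient for network-graph
#' summaries of simulated cohorts.
#'
#' @param nRegions number of regions.
#' @return data.frame: region (index), region_name, network.
#' @export
makeNetworkLookup <- function(nRegions) {
  data.frame(region = seq_len(nRegions),
             region_name = paste0("R", seq_len(nRegions)),
             network = NETWORKS_17[((seq_len(nRegions) - 1) %% 17) + 1],
             stringsAsFactors = FALSE)
}

#' Network graph of FDR-significant edges
#'
#' Groups FDR-significant region pairs for one factor (optionally one
#' direction) by the functional networks of their endpoints. Each distinct
#' region pair contributes to exactly one network edge. With
#' `weightMode = "regions"` (default) a cross-network edge is weighted by
#' the larger count of distinct regions contributing on either side - two
#' control regions significantly connected to two default-mode regions
#' give a control-default weight of 2 however those four significant pairs
#' are arranged; with `weightMode = "pairs"` the weight is the count of
#' distinct significant region pairs. Within-network (self-loop) edges
#' always carry the pair count. A node's degree is the sum of the weights
#' of its incident edges, self-loops counted once.
#'
#' @param effects an [EdgeEffectTable-class].
#' @param lookup data.frame with columns `region` (index) and `network`.
#' @param factor effect family to summarise (e.g. `"seq"`).
#' @param direction `"+"`, `"-"` or `"any"`.
#' @param alpha FDR threshold (default .05).
#' @param weightMode `"regions"` or `"pairs"`.
#' @return a [NetworkGraph-class].
#' @export
buildNetworkGraph <- function(effects, lookup, factor = "seq",
                              direction = c("any", "+", "-"), alpha = 0.05,
                              weightMode = c("regions", "pairs")) {
  direction <- match.arg(direction)
  weightMode <- match.arg(weightMode)
  e <- edgeEffects(effects)
  e <- e[e$factor == factor & !is.na(e$q_fdr) & e$q_fdr < alpha, ]
  if (direction == "+") e <- e[e$direction > 0, ]
  if (direction == "-") e <- e[e$direction < 0, ]
  regions <- unique(c(e$region_i, e$region_j))
  unmapped <- setdiff(regions, lookup$region)
  if (length(unmapped))
    stop("region(s) not mapped to a network: ",
         paste(unmapped, collapse = ", "))
  net <- lookup$network[match(seq_len(max(c(lookup$region, 1))),
                              lookup$region)]
  nodes <- sort(unique(lookup$network))
  if (nrow(e) == 0) {
    return(new("NetworkGraph",
               nodes = data.frame(network = nodes, degree = 0),
               edges = data.frame(net_a = character(0),
                                  net_b = character(0),
                                  weight = integer(0), n_pairs = integer(0)),
               factor = factor, direction = direction,
               weightMode = weightMode))
  }
  # each unordered region pair exactly once
  e <- e[!duplicated(paste(e$region_i, e$region_j)), ]
  na <- net[e$region_i]
  nb <- net[e$region_j]
  a <- pmin(na, nb)
  b <- pmax(na, nb)
  key <- paste(a, b, sep = "\r")
  edges <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    nets <- strsplit(k, "\r", fixed = TRUE)[[1]]
    n_pairs <- sum(sel)
    if (nets[1] == nets[2]) {
      w <- n_pairs
    } else if (weightMode == "pairs") {
      w <- n_pairs
    } else {
      side_a <- ifelse(na[sel] == nets[1], e$region_i[sel], e$region_j[sel])
      side_b <- ifelse(na[sel] == nets[1], e$region_j[sel], e$region_i[sel])
      w <- max(length(unique(side_a)), length(unique(side_b)))
    }
    data.frame(net_a = nets[1], net_b = nets[2], weight = w,
               n_pairs = n_pairs, stringsAsFactors = FALSE)
  }))
  deg <- stats::setNames(rep(0, length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    if (edges$net_a[r] == edges$net_b[r]) {
      deg[edges$net_a[r]] <- deg[edges$net_a[r]] + edges$weight[r]
    } else {
      deg[edges$net_a[r]] <- deg[edges$net_a[r]] + edges$weight[r]
      deg[edges$net_b[r]] <- deg[edges$net_b[r]] + edges$weight[r]
    }
  }
  new("NetworkGraph",
      nodes = data.frame(network = nodes, degree = as.numeric(deg)),
      edges = edges, factor = factor, direction = direction,
      weightMode = weightMode)
}

#' Consolidate subnetworks into macro networks
#'
#' Re-aggregates a network graph under a subnetwork-to-macro scheme,
#' summing the weights of edges that map to the same macro pair. With
#' `display = TRUE` (the visualisation rule) within-macro edges and
#' degree-0 nodes are dropped; cross-macro weight is conserved either way.
#'
#' @param graph a [NetworkGraph-class].
#' @param scheme named character vector mapping every node network to a
#'   macro network (default [subnetworkScheme()]).
#' @param display apply the display rule (default TRUE).
#' @return a consolidated [NetworkGraph-class].
#' @export
consolidateSubnetworks <- function(graph, scheme = subnetworkScheme(),
                                   display = TRUE) {
  edges <- graphEdges(graph)
  nets <- graphNodes(graph)$network
  missing_nets <- setdiff(nets, names(scheme))
  if (length(missing_nets))
    stop("scheme does not map network(s): ",
         paste(missing_nets, collapse = ", "))
  macro_nodes <- sort(unique(unname(scheme[nets])))
  if (nrow(edges)) {
    ma <- unname(scheme[edges$net_a])
    mb <- unname(scheme[edges$net_b])
    a <- pmin(ma, mb)
    b <- pmax(ma, mb)
    agg <- stats::aggregate(cbind(weight = edges$weight,
                                  n_pairs = edges$n_pairs),
                            by = list(net_a = a, net_b = b), FUN = sum)
  } else {
    agg <- data.frame(net_a = character(0), net_b = character(0),
                      weight = integer(0), n_pairs = integer(0))
  }
  if (display && nrow(agg)) agg <- agg[agg$net_a != agg$net_b, ]
  deg <- stats::setNames(rep(0, length(macro_nodes)), macro_nodes)
  for (r in seq_len(nrow(agg))) {
    deg[agg$net_a[r]] <- deg[agg$net_a[r]] + agg$weight[r]
    if (agg$net_b[r] != agg$net_a[r])
      deg[agg$net_b[r]] <- deg[agg$net_b[r]] + agg$weight[r]
  }
  nodes <- data.frame(network = macro_nodes, degree = as.numeric(deg))
  if (display) nodes <- nodes[nodes$degree > 0, ]
  rownames(nodes) <- rownames(agg) <- NULL
  new("NetworkGraph", nodes = nodes, edges = agg, factor = graph@factor,
      direction = graph@direction, weightMode = graph@weightMode)
}
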