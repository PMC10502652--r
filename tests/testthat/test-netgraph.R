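# lookup placing regions 1-2 in a control subnetwork and 3-4 in a default
# subnetwork (others spread over the remaining networks)
example_lookup <- function() {
  lk <- makeNetworkLookup(10)
  lk$network <- c("ContA", "ContA", "DefaultA", "DefaultA",
                  "VisCent", "VisCent", "SomMotA", "SomMotA",
                  "DorsAttnA", "DorsAttnA")
  lk
}

test_that("two control regions linked to two default regions weigh 2", {
  # all four cross pairs significant
  sig <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  eff <- make_effect_table(sig, factor = "seq", direction = 1L)
  g <- buildNetworkGraph(eff, example_lookup(), factor = "seq",
                         direction = "+")
  ed <- graphEdges(g)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$weight, 2)         # regions on each side, not pairs
  expect_equal(ed$n_pairs, 4)
  gp <- buildNetworkGraph(eff, example_lookup(), factor = "seq",
                          direction = "+", weightMode = "pairs")
  expect_equal(graphEdges(gp)$weight, 4)
  # a matched two-pair pattern also weighs 2 in both modes
  eff2 <- make_effect_table(rbind(c(1, 3), c(2, 4)), factor = "seq",
                            direction = 1L)
  expect_equal(graphEdges(buildNetworkGraph(eff2, example_lookup(),
                                            "seq", "+"))$weight, 2)
  expect_equal(graphEdges(buildNetworkGraph(eff2, example_lookup(), "seq",
                                            "+", weightMode = "pairs"))$weight,
               2)
})

test_that("graphs without significant edges are empty with zero degrees", {
  eff <- make_effect_table(matrix(numeric(0), 0, 2))
  g <- buildNetworkGraph(eff, example_lookup(), factor = "seq")
  expect_equal(nrow(graphEdges(g)), 0)
  expect_true(all(graphNodes(g)$degree == 0))
})

test_that("region pairs are never double-counted", {
  sig <- rbind(c(1, 3), c(1, 3), c(1, 3))  # same pair repeated
  eff <- make_effect_table(sig, factor = "seq", direction = 1L)
  ed <- graphEdges(buildNetworkGraph(eff, example_lookup(), "seq", "+",
                                     weightMode = "pairs"))
  expect_equal(ed$n_pairs, 1)
  expect_equal(ed$weight, 1)
})

test_that("direction filtering separates increases from decreases", {
  up <- make_effect_table(rbind(c(1, 3)), factor = "seq", direction = 1L)
  eup <- edgeEffects(up)
  # add a significant negative edge 2-4
  hit <- eup$factor == "seq" & eup$region_i == 2 & eup$region_j == 4
  eup$q_fdr[hit] <- 1e-4; eup$p[hit] <- 1e-6; eup$direction[hit] <- -1L
  both <- new("EdgeEffectTable", effects = eup, nSubjects = 12L)
  gpos <- buildNetworkGraph(both, example_lookup(), "seq", "+")
  gneg <- buildNetworkGraph(both, example_lookup(), "seq", "-")
  gany <- buildNetworkGraph(both, example_lookup(), "seq", "any")
  expect_equal(sum(graphEdges(gpos)$n_pairs), 1)
  expect_equal(sum(graphEdges(gneg)$n_pairs), 1)
  expect_equal(sum(graphEdges(gany)$n_pairs), 2)
})

test_that("unmapped regions and incomplete schemes are rejected", {
  eff <- make_effect_table(rbind(c(1, 9)), factor = "seq", direction = 1L)
  lk <- example_lookup()[1:5, ]
  expect_error(buildNetworkGraph(eff, lk, "seq", "+"), "not mapped")
  g <- buildNetworkGraph(eff, example_lookup(), "seq", "+")
  expect_error(consolidateSubnetworks(g, scheme = c(ContA = "Cont")),
               "does not map")
})

test_that("consolidation aggregates weights and conserves cross-macro totals", {
  edges <- data.frame(net_a = c("ContA", "ContB", "DefaultA"),
                      net_b = c("DefaultA", "DefaultC", "DefaultB"),
                      weight = c(2L, 3L, 4L), n_pairs = c(2L, 3L, 4L))
  nodes <- data.frame(network = sort(unique(c(edges$net_a, edges$net_b,
                                              "VisCent"))),
                      degree = 0)
  g <- new("NetworkGraph", nodes = nodes, edges = edges, factor = "seq",
           direction = "+", weightMode = "regions")
  cg <- consolidateSubnetworks(g)
  ce <- graphEdges(cg)
  expect_equal(ce$weight[ce$net_a == "Cont" & ce$net_b == "Default"], 5)
  # the within-default edge is dropped under the display rule ...
  expect_false(any(ce$net_a == ce$net_b))
  # ... but cross-macro weight is conserved
  expect_equal(sum(ce$weight), 5)
  cg_full <- consolidateSubnetworks(g, display = FALSE)
  expect_equal(sum(graphEdges(cg_full)$weight), 9)
  # only within-macro edges -> empty displayed graph
  g2 <- new("NetworkGraph", nodes = nodes,
            edges = data.frame(net_a = "DefaultA", net_b = "DefaultB",
                               weight = 3L, n_pairs = 3L),
            factor = "seq", direction = "+", weightMode = "regions")
  expect_equal(nrow(graphEdges(consolidateSubnetworks(g2))), 0)
  expect_equal(nrow(graphNodes(consolidateSubnetworks(g2))), 0)
})

test_that("degrees satisfy the handshake identity on random graphs", {
  set.seed(6)
  for (rep in 1:5) {
    n_sig <- 12
    pairs <- t(replicate(n_sig, sort(sample(10, 2))))
    pairs <- unique(pairs)
    eff <- make_effect_table(pairs, factor = "perc", direction = 1L)
    g <- buildNetworkGraph(eff, example_lookup(), "perc", "+",
                           weightMode = "pairs")
    ed <- graphEdges(g)
    cross <- ed$net_a != ed$net_b
    expect_equal(sum(graphNodes(g)$degree),
                 2 * sum(ed$weight[cross]) + sum(ed$weight[!cross]))
  }
})

test_that("relabelling networks permutes the graph, not the degrees", {
  sig <- rbind(c(1, 3), c(1, 5), c(3, 7))
  eff <- make_effect_table(sig, factor = "seq", direction = 1L)
  lk <- example_lookup()
  g1 <- buildNetworkGraph(eff, lk, "seq", "+")
  lk2 <- lk
  swap <- c(ContA = "DorsAttnA", DorsAttnA = "ContA")
  lk2$network <- ifelse(lk$network %in% names(swap),
                        unname(swap[lk$network]), lk$network)
  g2 <- buildNetworkGraph(eff, lk2, "seq", "+")
  expect_equal(sort(graphNodes(g1)$degree), sort(graphNodes(g2)$degree))
})
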