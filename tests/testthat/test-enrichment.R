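test_that("hypergeometric ORA matches exhaustive enumeration", {
  # the worked fixture: 3 of 4 set members among 5 of 10
  uni <- paste0("m", 1:10)
  r <- oraHypergeometric(uni[1:5], uni[c(1, 2, 3, 6)], uni)
  expect_equal(r$p, 66 / 252, tolerance = 1e-12)
  expect_identical(c(r$N, r$K, r$n, r$k), c(10L, 4L, 5L, 3L))
  # random spot checks against the enumeration oracle
  set.seed(31)
  for (i in 1:20) {
    N <- sample(4:11, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- paste0("x", seq_len(N))
    sel <- sample(uni, n)
    st <- uni[seq_len(K)]
    k <- length(intersect(sel, st))
    expect_equal(oraHypergeometric(sel, st, uni)$p,
                 oraEnumOracle(N, K, n, k), tolerance = 1e-10)
  }
})

test_that("ORA degenerate cases and input validation", {
  uni <- paste0("m", 1:8)
  # zero overlap: the tail includes >= 0, i.e. everything
  expect_identical(oraHypergeometric(uni[1:3], uni[4:6], uni)$p, 1)
  # set == universe: overlap is n deterministically
  expect_identical(oraHypergeometric(uni[1:4], uni, uni)$p, 1)
  expect_error(oraHypergeometric(character(0), uni[1:2], uni),
               "empty selection")
  expect_error(oraHypergeometric(uni[1:2], uni[1:2], character(0)),
               "empty universe")
  expect_error(oraHypergeometric(uni[1:2], c(uni[1:2], "alien"), uni),
               "alien")
})

test_that("msea BH-adjusts across sets and handles out-of-universe members", {
  coll <- MetaboliteSetCollection(
    c("hit", "miss", "outside"),
    list(paste0("m", 1:4), paste0("m", 7:9), paste0("z", 1:3)))
  uni <- paste0("m", 1:20)
  res <- msea(paste0("m", 1:5), coll, uni)
  expect_identical(res["outside", "K"], 0L)
  expect_identical(res["outside", "p"], 1)
  expect_equal(res$p_adj, bhOracle(res$p), tolerance = 1e-12)
  expect_lt(res["hit", "p"], res["miss", "p"])
})

test_that("centrality kinds match their closed forms and brute force", {
  p3 <- PathwayGraph("p3", c("A", "B", "C"),
                     rbind(c("A", "B"), c("B", "C")))
  expect_equal(computeCentrality(p3, "betweenness"),
               c(A = 0, B = 1, C = 0))
  star <- PathwayGraph("star", c("H", "L1", "L2", "L3"),
                       cbind("H", c("L1", "L2", "L3")))
  expect_equal(computeCentrality(star, "degree"),
               c(H = 3, L1 = 1, L2 = 1, L3 = 1))
  iso <- PathwayGraph("iso", c("A", "B", "C"), rbind(c("A", "B")))
  expect_equal(computeCentrality(iso, "equal"), c(A = 1, B = 1, C = 1))
  expect_equal(unname(computeCentrality(iso, "degree")["C"]), 0)
  # randomized 12-node graphs against the enumeration oracle
  for (s in 1:3) {
    set.seed(s)
    nodes <- paste0("n", 1:12)
    edges <- unique(t(replicate(18, sort(sample(nodes, 2)))))
    g <- PathwayGraph("rand", nodes, edges)
    expect_equal(computeCentrality(g, "betweenness"),
                 bruteBetweenness(nodes, edgeTable(g))[nodeIds(g)],
                 tolerance = 1e-10)
  }
})

test_that("permutation enrichment honors its degenerate contracts", {
  uni <- paste0("g", 1:12)
  pg <- PathwayGraph("pw", uni[1:4],
                     rbind(uni[1:2], uni[2:3], uni[3:4]))
  # differential genes disjoint from the pathway: score 0, every null >= 0
  r0 <- cepaOra(pg, uni[9:11], uni, nPerm = 200, seed = 1)
  expect_identical(r0$score, 0)
  expect_identical(r0$p, 1)
  # selection equals the universe: a single possible draw
  rAll <- cepaOra(pg, uni, uni, nPerm = 200, seed = 1)
  expect_identical(rAll$p, 1)
  expect_error(cepaOra(pg, c(uni, "extra"), uni, nPerm = 200, seed = 1),
               "universe")
  expect_error(cepaOra(pg, uni[1:3], uni, nPerm = 50, seed = 1), "nPerm")
  # fixed seed reproduces the p-value exactly
  a <- cepaOra(pg, uni[1:3], uni, nPerm = 500, seed = 7)
  b <- cepaOra(pg, uni[1:3], uni, nPerm = 500, seed = 7)
  expect_identical(a$p, b$p)
})

test_that("equal-weight permutation p agrees with the hypergeometric tail", {
  uni <- paste0("g", 1:8)
  pg <- PathwayGraph("pw", uni[1:4],
                     rbind(uni[1:2], uni[2:3], uni[3:4]))
  sel <- uni[c(1, 2, 5)]
  r <- cepaOra(pg, sel, uni, nPerm = 20000, seed = 3)
  exact <- oraEnumOracle(8, 4, 3, r$k)
  expect_lt(abs(r$p - exact), 0.01)
})

test_that("cepaEnrichment is deterministic and BH-adjusts across pathways", {
  set.seed(41)
  uni <- paste0("g", 1:30)
  graphs <- lapply(1:4, function(i) {
    nodes <- sample(uni, 8)
    PathwayGraph(paste0("pw", i), nodes,
                 cbind(nodes[1:7], nodes[2:8]))
  })
  names(graphs) <- paste0("pw", 1:4)
  sel <- sample(uni, 6)
  a <- cepaEnrichment(graphs, sel, uni, nPerm = 400, seed = 11)
  b <- cepaEnrichment(graphs, sel, uni, nPerm = 400, seed = 11)
  expect_identical(a, b)
  expect_equal(a$p_adj, bhOracle(a$p), tolerance = 1e-12)
})

test_that("mapSelection unions gene sets and reports coverage", {
  v <- data.frame(metabolite = c("M1", "M2", "M3", "M4"),
                  class = c("efficacy", "efficacy", "bias_up",
                            "unclassified"),
                  stringsAsFactors = FALSE)
  mp <- MappingTable(list(M1 = c("G1", "G2"), M2 = c("G2", "G3"),
                          M3 = "G4"))
  eff <- mapSelection(v, mp, "efficacy")
  expect_identical(as.character(eff), c("G1", "G2", "G3"))
  bias <- mapSelection(v, mp, "bias")
  expect_identical(as.character(bias), "G4")
  expect_warning(empty <- mapSelection(v, mp, "bias_down"),
                 "no metabolites")
  expect_length(empty, 0)
  # selected metabolite absent from the mapping counts as unmapped
  v2 <- v; v2$metabolite[2] <- "Mmissing"
  eff2 <- mapSelection(v2, mp, "efficacy")
  expect_identical(attr(eff2, "unmapped"), 1L)
})

test_that("most planted-pathway genes reach the mapped efficacy selection", {
  fracs <- vapply(1:50, function(s) {
    co <- generateCohort(cohortSpec(nPerGroup = 7, nMetabolites = 100,
                                    nEfficacy = 10, nBias = 10, seed = s))
    k <- generateKnowledge(co$truth, 5, seed = s + 500, pathwaySize = 8)
    an <- analyzeCohort(co)
    sel <- suppressWarnings(mapSelection(an$verdicts, k$mapping, "efficacy"))
    mean(nodeIds(k$graphs$PW_EFFICACY) %in% sel)
  }, 0)
  expect_gte(mean(fracs), 0.8)
})
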