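de_fixture <- function(ids, dirs) {
  data.frame(feature_id = ids, logFC = ifelse(dirs == "up", 3, -3),
             p = 0.001, adj_p = 0.01, direction = dirs,
             stringsAsFactors = FALSE)
}

hit_fixture <- function(mirs, targets, energies) {
  data.frame(mirna_id = mirs, target_id = targets, score = 150,
             energy = energies, target_start = 1L, target_end = 22L,
             stringsAsFactors = FALSE)
}

test_that("ceRNA pair filters apply concordance and strict energy sum", {
  circ_de <- de_fixture("circ1", "up")
  mrna_de <- de_fixture("mrnaA", "up")
  ch <- hit_fixture(c("mir1", "mir2"), "circ1", c(-25, -25))
  mh <- hit_fixture(c("mir1", "mir2"), "mrnaA", c(-25, -25))
  net <- build_cerna(circ_de, mrna_de, ch, mh, energy_sum_max = -90)
  expect_equal(nrow(net$triples), 2)           # sum = -100 < -90: retained
  expect_setequal(net$triples$mir_id, c("mir1", "mir2"))
  expect_equal(unique(net$triples$sum_max_energy), -100)
  # discordant directions are excluded regardless of energy
  net2 <- build_cerna(circ_de, de_fixture("mrnaA", "down"), ch, mh)
  expect_equal(nrow(net2$triples), 0)
  # energy sum exactly at the threshold is excluded (strict <)
  ch90 <- hit_fixture(c("mir1", "mir2"), "circ1", c(-22.5, -22.5))
  mh90 <- hit_fixture(c("mir1", "mir2"), "mrnaA", c(-22.5, -22.5))
  net3 <- build_cerna(circ_de, mrna_de, ch90, mh90, energy_sum_max = -90)
  expect_equal(nrow(net3$triples), 0)
  net4 <- build_cerna(circ_de, mrna_de, ch90, mh90, energy_sum_max = -89.999)
  expect_equal(nrow(net4$triples), 2)
})

test_that("the strongest site per molecule drives the energy sum", {
  circ_de <- de_fixture("circ1", "down")
  mrna_de <- de_fixture("mrnaA", "down")
  # two sites for mir1 on the circ: best (most negative) must be used
  ch <- rbind(hit_fixture("mir1", "circ1", -21),
              hit_fixture("mir1", "circ1", -60))
  mh <- hit_fixture("mir1", "mrnaA", -35)
  net <- build_cerna(circ_de, mrna_de, ch, mh, energy_sum_max = -90)
  expect_equal(net$triples$sum_max_energy, -95)  # -60 + -35
})

test_that("network assembly is invariant to input row order", {
  set.seed(12)
  circ_de <- de_fixture(c("c1", "c2"), c("up", "down"))
  mrna_de <- de_fixture(c("m1", "m2"), c("up", "down"))
  ch <- rbind(hit_fixture(c("x1", "x2"), "c1", c(-30, -40)),
              hit_fixture(c("x1", "x3"), "c2", c(-50, -45)))
  mh <- rbind(hit_fixture(c("x1", "x2"), "m1", c(-35, -28)),
              hit_fixture(c("x1", "x3"), "m2", c(-33, -47)))
  a <- build_cerna(circ_de, mrna_de, ch, mh, energy_sum_max = -60)
  b <- build_cerna(circ_de[2:1, ], mrna_de[2:1, ],
                   ch[sample(nrow(ch)), ], mh[sample(nrow(mh)), ],
                   energy_sum_max = -60)
  expect_identical(a$triples, b$triples)
  # post-hoc audit: every retained pair satisfies both predicates
  expect_true(all(a$triples$circ_direction == a$triples$mrna_direction))
  expect_true(all(a$triples$sum_max_energy < -60))
  # no orphan miRNA: each miRNA touches a circ and an mRNA edge
  for (mir in unique(a$triples$mir_id)) {
    e <- a$edges
    expect_true(any(e$type == "circ-mir" & e$to == mir))
    expect_true(any(e$type == "mir-mrna" & e$from == mir))
  }
})

test_that("MCC matches closed forms on canonical graphs", {
  k4 <- data.frame(from = c("a", "a", "a", "b", "b", "c"),
                   to = c("b", "c", "d", "c", "d", "d"))
  s <- mcc_scores(k4)
  expect_equal(s$mcc, rep(6, 4))               # single K4: 3! each
  path <- data.frame(from = c("a", "b"), to = c("b", "c"))
  sp <- mcc_scores(path)
  expect_equal(sp$mcc[sp$gene_id == "b"], 2)
  expect_equal(sp$mcc[sp$gene_id %in% c("a", "c")], c(1, 1))
  iso <- mcc_scores(data.frame(from = "a", to = "b"), nodes = c("a", "b", "z"))
  expect_equal(iso$mcc[iso$gene_id == "z"], 1)
})

test_that("MCC equals the subset-enumeration oracle on random graphs", {
  set.seed(303)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < runif(1, 0.15, 0.6)
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        stringsAsFactors = FALSE)
    got <- mcc_scores(edges, nodes = nodes)
    want <- oracle_mcc(edges, nodes)
    expect_equal(stats::setNames(got$mcc, got$gene_id)[names(want)], want)
  }
})

test_that("hub extraction is deterministic and recovers planted cliques", {
  set.seed(17)
  nodes <- sprintf("g%03d", 1:100)
  p <- gen_ppi(nodes, list(nodes[1:6]), noise_edges = 50, seed = 23)
  hubs <- top_hubs(mcc_scores(p$edges, nodes = nodes), 10)
  expect_true(all(nodes[1:6] %in% hubs))
  # K4 with k = 1: lexicographically smallest of the tied vertices
  k4 <- data.frame(from = c("d", "d", "d", "b", "b", "c"),
                   to = c("b", "c", "a", "c", "a", "a"))
  expect_equal(top_hubs(mcc_scores(k4), 1), "a")
  expect_warning(h <- top_hubs(mcc_scores(k4), 10), "exceeds")
  expect_equal(length(h), 4)
  expect_warning(e <- mcc_scores(data.frame(from = character(),
                                            to = character())), "empty")
  expect_warning(expect_equal(top_hubs(e, 3), character(0)), "no nodes")
  expect_error(mcc_scores(k4, max_cliques_budget = 0), "budget")
})

test_that("subnetwork restriction keeps exactly the requested mRNAs", {
  circ_de <- de_fixture(c("c1", "c2"), c("up", "up"))
  mrna_de <- de_fixture(c("m1", "m2"), c("up", "up"))
  ch <- rbind(hit_fixture(c("x1", "x2", "x3"), "c1", -50),
              hit_fixture("x1", "c2", -50))
  mh <- rbind(hit_fixture(c("x1", "x2", "x3"), "m1", -50),
              hit_fixture("x1", "m2", -50))
  net <- build_cerna(circ_de, mrna_de, ch, mh)
  expect_identical(subnetwork(net, c("m1", "m2"))$triples, net$triples)
  expect_equal(nrow(subnetwork(net, character(0))$triples), 0)
  sub1 <- subnetwork(net, "m1")
  expect_equal(sum(sub1$edges$type == "mir-mrna"), 3)
  expect_false("m2" %in% names(sub1$node_kinds))
  expect_error(subnetwork(net, "nope"), "unknown")
})
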