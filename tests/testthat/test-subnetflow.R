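# Flow-model construction, solving (exact and relaxed), extraction,
# size bounds and the exhaustive oracle.

test_that("build_flow_model encodes nodes, arcs and target constraints", {
  net <- path_net(c("A", "B", "C"))
  m <- build_flow_model(net, NULL, "A", 2)
  expect_equal(length(m$nodes), 3)
  expect_equal(nrow(m$arcs), 4)           # both directions of 2 edges
  expect_equal(length(m$target_idx), 1)   # one dummy arc
  m2 <- build_flow_model(net, NULL, c("A", "B"), 2)
  expect_setequal(m2$targets, c("A", "B"))
  expect_error(build_flow_model(net, NULL, "X", 2), "X")
  expect_error(build_flow_model(net, NULL, c("A", "B"), 1), "smaller")
})

test_that("exact solve matches hand enumeration on star and path", {
  # star: only {A,B}, {A,C}, {A,D} are connected size-2 supersets of A
  star <- star_net("A", c("B", "C", "D"))
  w <- c(A = 1, B = 5, C = 1, D = 0)
  m <- build_flow_model(star, w, "A", 2)
  s <- solve_flow(m, exact = TRUE)
  expect_equal(s$objective, 6)
  expect_setequal(extract_subnetwork(m, s)$genes, c("A", "B"))

  # path: a single connected size-3 superset of A exists
  pathn <- path_net(c("A", "B", "C"))
  m3 <- build_flow_model(pathn, c(A = 1, B = 0, C = 10), "A", 3)
  expect_equal(solve_flow(m3, exact = TRUE)$objective, 11)

  # all-zero weights: any feasible selection scores 0
  m0 <- build_flow_model(pathn, c(A = 0, B = 0, C = 0), "A", 2)
  expect_equal(solve_flow(m0, exact = TRUE)$objective, 0)
})

test_that("relaxed objective bounds the exact objective", {
  for (s in 101:120) {
    inst <- random_instance(s)
    m <- build_flow_model(inst$net, inst$weights, inst$targets, inst$R)
    lp <- solve_flow(m, exact = FALSE)
    ip <- solve_flow(m, exact = TRUE)
    expect_gte(lp$objective, ip$objective - 1e-6)
  }
})

test_that("extract_subnetwork thresholds x and prunes target-free parts", {
  net <- path_net(c("A", "B", "C"))
  m <- build_flow_model(net, c(A = 1, B = 1, C = 0), "A", 2)
  fake <- list(x = c(A = 1, B = 1, C = 0), objective = 2, integral = TRUE)
  expect_setequal(extract_subnetwork(m, fake)$genes, c("A", "B"))
  # fractional values above threshold are included
  frac <- list(x = c(A = 1, B = 1, C = 0.5), objective = 2.5,
               integral = FALSE)
  sub <- extract_subnetwork(m, frac)
  expect_true("C" %in% sub$genes)
  expect_false(sub$lp_integral)
  # everything below threshold except the targets
  tiny <- list(x = c(A = 1, B = 1e-9, C = 1e-9), objective = 1,
               integral = FALSE)
  expect_equal(extract_subnetwork(m, tiny)$genes, "A")
  # a selected gene disconnected from every target is dropped
  net2 <- molecular_network(data.frame(gene_a = c("A", "C"),
                                       gene_b = c("B", "D")))
  m2 <- build_flow_model(net2, NULL, "A", 2)
  orphan <- list(x = c(A = 1, B = 1, C = 1, D = 0), objective = 2,
                 integral = TRUE)
  expect_message(sub2 <- extract_subnetwork(m2, orphan), "dropped")
  expect_setequal(sub2$genes, c("A", "B"))
})

test_that("r_bounds counts shortest-path genes and caps at 10% of nodes", {
  pad <- data.frame(gene_a = sprintf("P%02d", 1:36),
                    gene_b = c("D", sprintf("P%02d", 1:35)))
  net40 <- molecular_network(rbind(
    data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D")), pad))
  expect_equal(length(net40$nodes), 40)
  b <- r_bounds(net40, c("A", "C"))
  expect_equal(b$R_min, 3L)   # path A-B-C has 3 genes
  expect_equal(b$R_max, 4L)   # floor(0.1 * 40)

  expect_equal(r_bounds(net40, "A")$R_min, 1L)
  expect_equal(r_bounds(net40, c("A", "B"))$R_min, 2L)

  two <- molecular_network(data.frame(gene_a = c("A", "C"),
                                      gene_b = c("B", "D")))
  expect_error(r_bounds(two, c("A", "C")), "not connected")
})

test_that("brute_force_oracle enumerates rooted-connected subsets", {
  star <- star_net("A", c("B", "C", "D"))
  w <- c(A = 1, B = 5, C = 1, D = 0)
  o <- brute_force_oracle(star, w, "A", 2)
  expect_equal(o$genes, c("A", "B"))
  expect_equal(o$objective, 6)

  all4 <- brute_force_oracle(star, w, "A", 4)
  expect_equal(all4$genes, sort(star$nodes))

  # two far-apart targets are still feasible at R = 2: the dummy node
  # roots each of them separately, matching the flow model's semantics
  p4 <- path_net(c("A", "B", "C", "D"))
  split2 <- brute_force_oracle(p4, c(A = 1, B = 5, C = 5, D = 1),
                               c("A", "D"), 2)
  expect_true(split2$feasible)
  expect_equal(split2$genes, c("A", "D"))

  # genuinely unreachable size: target's component has only 2 nodes
  twocomp <- molecular_network(data.frame(gene_a = c("A", "C"),
                                          gene_b = c("B", "D")))
  inf <- brute_force_oracle(twocomp, NULL, "A", 3)
  expect_false(inf$feasible)

  big <- path_net(sprintf("N%02d", 1:17))
  expect_error(brute_force_oracle(big, NULL, "N01", 3), "16")
})

test_that("find_affected_subnetwork maximizes the normalized score", {
  # heavy hub beside the target: smallest set containing it wins
  net <- star_net("T", c("H", sprintf("L%02d", 1:23)))
  w <- c(T = 0, H = 10)
  sub <- find_affected_subnetwork(net, w, "T")
  expect_true("H" %in% sub$genes)
  expect_equal(sub$normalized_score, 10 / sqrt(2))

  # equal weights: score w*sqrt(k) grows with k, largest R wins
  netE <- path_net(sprintf("E%02d", 1:20))
  wE <- stats::setNames(rep(2, 20), netE$nodes)
  subE <- find_affected_subnetwork(netE, wE, "E01")
  expect_equal(length(subE$genes), r_bounds(netE, "E01")$R_max)

  # all-zero weights: tie on score 0 resolved toward the smallest set
  sub0 <- find_affected_subnetwork(netE, NULL, "E01")
  expect_equal(length(sub0$genes), 1)
  expect_equal(sub0$normalized_score, 0)
})

test_that("infeasible models raise an informative error", {
  # R larger than the target's component forces infeasibility
  net <- molecular_network(data.frame(gene_a = c("A", "C", "C"),
                                      gene_b = c("B", "D", "E")))
  m <- build_flow_model(net, NULL, "A", 3)
  expect_error(solve_flow(m), "infeasible")
})
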