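# Probe collapsing, metadata filtering, case/control aggregation, ratios
# and differential-expression weights.

mk_meta <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "batch_id", "cell_line", "perturbagen",
                 "dose", "control_ids")[seq_along(df)]
  df
}

test_that("collapse_probes averages per symbol then per /// token", {
  m <- matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  map <- data.frame(probe = c("p1", "p2"), symbol = c("X", "X"))
  expect_equal(unname(collapse_probes(m, map)["X", ]), 3)

  m2 <- matrix(c(2, 6), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  map2 <- data.frame(probe = c("p1", "p2"), symbol = c("X", "X /// Y"))
  out <- collapse_probes(m2, map2)
  expect_equal(unname(out["X", ]), 4)   # mean(2, 6)
  expect_equal(unname(out["Y", ]), 6)

  one <- matrix(5, 1, 2, dimnames = list("p1", c("s1", "s2")))
  expect_equal(collapse_probes(one, data.frame(probe = "p1", symbol = "G"))["G", ],
               c(s1 = 5, s2 = 5))

  expect_error(collapse_probes(m[, 0, drop = FALSE], map), "zero samples")
  expect_message(collapse_probes(m, map[1, , drop = FALSE]), "unmapped")
})

test_that("collapse_probes output stays within contributing probe range", {
  for (s in 1:5) {
    set.seed(s)
    np <- 12
    m <- matrix(runif(np * 3, 1, 100), np, 3,
                dimnames = list(sprintf("p%02d", 1:np), c("a", "b", "c")))
    map <- data.frame(probe = rownames(m),
                      symbol = sample(c("G1", "G2", "G1 /// G2", "G3"),
                                      np, replace = TRUE))
    out <- collapse_probes(m, map)
    expect_true(all(out >= min(m) - 1e-12 & out <= max(m) + 1e-12))
  }
})

test_that("filter_samples merges batches 2/2a, drops single-drug batches and off cell lines", {
  meta <- mk_meta(
    c("c1", "x1", "c2", "x2", "x3", "c3", "x4", "h1"),
    c("1", "1", "2", "2", "2a", "3", "3", "3"),
    c(rep("MCF7", 7), "HL60"),
    c("CONTROL", "D1", "CONTROL", "D1", "D3", "CONTROL", "D1", "D2"),
    c(0, 10, 0, 10, 5, 0, 10, 10),
    c("", "c1", "", "c2", "c2", "", "c3", "c3"))
  out <- filter_samples(meta)
  # batch 1 (D1 only) removed; 2+2a merged (drugs D1,D3) kept;
  # batch 3 loses its HL60 row, leaving D1 only — but the single-drug test
  # runs on the full batch (D1 + D2), so batch 3 survives the batch filter
  expect_false(any(out$batch_id == "1"))
  expect_false(any(out$batch_id == "2a"))
  expect_setequal(out$sample_id[out$batch_id == "2"], c("c2", "x2", "x3"))
  expect_setequal(out$sample_id[out$batch_id == "3"], c("c3", "x4"))
  expect_true(all(out$cell_line == "MCF7"))
})

test_that("aggregate_case_control averages controls, replicates and batches", {
  genes <- c("g1", "g2")
  gm <- cbind(case1 = c(2, 4), ctlA = c(1, 3), ctlB = c(3, 5))
  rownames(gm) <- genes
  meta <- mk_meta(c("case1", "ctlA", "ctlB"), "b1", "MCF7",
                  c("D", "CONTROL", "CONTROL"), c(10, 0, 0),
                  c("ctlA;ctlB", "", ""))
  tc <- aggregate_case_control(gm, meta, "D", 10)
  expect_equal(unname(tc$T), c(2, 4))
  expect_equal(unname(tc$C), c(2, 4))

  # replicate cases averaged within a batch
  gm2 <- cbind(r1 = c(1, 1), r2 = c(3, 3), ctl = c(1, 1))
  rownames(gm2) <- genes
  meta2 <- mk_meta(c("r1", "r2", "ctl"), "b1", "MCF7",
                   c("D", "D", "CONTROL"), c(10, 10, 0), c("ctl", "ctl", ""))
  expect_equal(unname(aggregate_case_control(gm2, meta2, "D", 10)$T), c(2, 2))

  # per-batch values averaged across batches
  gm3 <- cbind(x1 = 2, x2 = 4, c1 = 1, c2 = 3)
  rownames(gm3) <- "g"
  meta3 <- mk_meta(c("x1", "x2", "c1", "c2"), c("b1", "b2", "b1", "b2"),
                   "MCF7", c("D", "D", "CONTROL", "CONTROL"),
                   c(10, 10, 0, 0), c("c1", "c2", "", ""))
  tc3 <- aggregate_case_control(gm3, meta3, "D", 10)
  expect_equal(unname(tc3$T), 3)
  expect_equal(unname(tc3$C), 2)

  expect_error(aggregate_case_control(gm, meta, "NOPE", 10), "NOPE")
  meta_bad <- mk_meta("case1", "b1", "MCF7", "D", 10, "")
  expect_error(aggregate_case_control(gm, meta_bad, "D", 10),
               "no linked controls")
})

test_that("aggregation is invariant to sample order and control duplication", {
  set.seed(42)
  gm <- matrix(runif(12, 10, 100), 3, 4,
               dimnames = list(c("g1", "g2", "g3"),
                               c("x1", "x2", "c1", "c2")))
  meta <- mk_meta(c("x1", "x2", "c1", "c2"), "b1", "MCF7",
                  c("D", "D", "CONTROL", "CONTROL"), c(10, 10, 0, 0),
                  c("c1;c2", "c1;c2", "", ""))
  base <- aggregate_case_control(gm, meta, "D", 10)
  shuf <- aggregate_case_control(gm[, c(3, 1, 4, 2)], meta[c(4, 2, 1, 3), ],
                                 "D", 10)
  expect_equal(shuf, base)
  # duplicating a control sample (same values under a new id) is a no-op
  gm_dup <- cbind(gm, c1bis = gm[, "c1"])
  meta_dup <- meta
  meta_dup$control_ids[1:2] <- "c1;c1bis;c2;c2"
  dup <- aggregate_case_control(gm_dup, meta_dup, "D", 10)
  expect_equal(dup$C, base$C, tolerance = 1e-12)
})

test_that("compute_ratios divides and applies the control floor", {
  expect_equal(unname(compute_ratios(c(g = 4), c(g = 2))), 2)
  expect_equal(unname(compute_ratios(c(g = 3), c(g = 3))), 1)
  expect_message(
    r <- compute_ratios(c(a = 4, b = 5), c(a = 2, b = 0)), "floor")
  expect_equal(names(r), "a")
  expect_error(suppressMessages(compute_ratios(c(a = 1), c(a = 0))),
               "all genes dropped")
})

test_that("weights are |log2 ratio|: symmetric, zero at 1, monotone", {
  expect_equal(unname(compute_weights(c(g = 2))), 1)
  expect_equal(unname(compute_weights(c(g = 0.5))), 1)
  expect_equal(unname(compute_weights(c(g = 1))), 0)
  expect_error(compute_weights(c(g = -1)), "positive")
  set.seed(7)
  r <- exp(stats::rnorm(100))
  expect_equal(compute_weights(r), compute_weights(1 / r), tolerance = 1e-12)
  ordr <- order(abs(log(r)))
  expect_true(all(diff(compute_weights(r)[ordr]) >= -1e-12))
})

test_that("drug_profile averages ratio profiles across doses", {
  gm <- cbind(x5 = c(2, 8), x10 = c(4, 16), ctl = c(1, 4))
  rownames(gm) <- c("g1", "g2")
  meta <- mk_meta(c("x5", "x10", "ctl"), "b1", "MCF7",
                  c("D", "D", "CONTROL"), c(5, 10, 0), c("ctl", "ctl", ""))
  p5 <- drug_profile(gm, meta, "D", dose = 5)
  expect_equal(unname(p5$ratios), c(2, 2))
  pall <- drug_profile(gm, meta, "D")
  expect_equal(unname(pall$ratios), c(3, 3))   # mean of per-dose ratios
  expect_error(drug_profile(gm, meta, "NOPE"), "NOPE")
})
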