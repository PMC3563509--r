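make_dataset <- function(values, n1 = NULL) {
  values <- as.matrix(values)
  if (is.null(n1)) n1 <- ncol(values) / 2
  expression_dataset(values, rep(c("control", "condition"),
                                 c(n1, ncol(values) - n1)))
}

test_that("direct evidence is a two-sided t-test with sensible edge cases", {
  set.seed(42)
  m <- matrix(rnorm(50 * 12), 50, dimnames = list(sprintf("g%02d", 1:50)))
  ds <- make_dataset(m)
  p <- direct_evidence(ds)

  # agrees with the reference Welch test gene by gene
  ref <- apply(m, 1, function(row) {
    stats::t.test(row[1:6], row[7:12])$p.value
  })
  expect_equal(unname(p), unname(ref), tolerance = 1e-12)

  # pooled-variance flavour agrees with var.equal = TRUE
  ps <- direct_evidence(ds, method = "student")
  refs <- apply(m, 1, function(row) {
    stats::t.test(row[1:6], row[7:12], var.equal = TRUE)$p.value
  })
  expect_equal(unname(ps), unname(refs), tolerance = 1e-12)

  # swapping group labels changes nothing
  swapped <- expression_dataset(m, rep(c("condition", "control"), each = 6))
  expect_equal(direct_evidence(swapped), p)

  # constant gene: no mean difference -> p = 1
  flat <- make_dataset(matrix(5, 1, 8, dimnames = list("flat")))
  expect_equal(unname(direct_evidence(flat)), 1)

  # zero variance but different means: smallest positive double
  step <- make_dataset(matrix(rep(c(0, 1), each = 4), 1, 8,
                              dimnames = list("step")))
  expect_equal(unname(direct_evidence(step)), .Machine$double.xmin)
})

test_that("datasets with undersized groups or bad identifiers are rejected", {
  m <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b")))
  expect_error(expression_dataset(m, c("x", "x", "x", "y")), "at least 2")
  expect_error(expression_dataset(m, c("x", "x", "y", "z")), "two levels")
  rownames(m) <- c("a", "a")
  expect_error(expression_dataset(m, c("x", "x", "y", "y")), "unique")
})

test_that("indirect scores sum -log10 p over out-neighbours", {
  pooled <- make_pooled(
    data.frame(source = c("i", "i"), target = c("j", "k")),
    genes = "z")
  p <- c(i = 0.5, j = 0.1, k = 0.01, z = 1)
  si <- indirect_scores(pooled, p)
  expect_equal(unname(si["i"]), 3)       # 1 + 2
  expect_equal(unname(si["z"]), 0)       # no outgoing edges
  expect_equal(unname(si["j"]), 0)

  one <- make_pooled(data.frame(source = "i", target = "j"))
  expect_equal(unname(indirect_scores(one, c(i = 1, j = 1e-3))["i"]), 3)

  # orientation switches
  expect_equal(unname(indirect_scores(pooled, p, direction = "in")["j"]),
               -log10(0.5))
  expect_equal(unname(indirect_scores(pooled, p, direction = "both")["i"]),
               3)

  expect_warning(indirect_scores(one, c(i = 0, j = 0.5)), "clamped")
  expect_error(indirect_scores(one, c(i = 0.5)), "cover every gene")
})

test_that("identical direct p-values drive every permutation p to the 1/N floor", {
  pooled <- make_pooled(data.frame(source = c("a", "b", "c"),
                                   target = c("b", "c", "a")))
  p <- stats::setNames(rep(0.2, 3), c("a", "b", "c"))
  pi <- suppressWarnings(
    indirect_pvalues(pooled, p, n_shuffles = 200, seed = 1))
  expect_equal(unname(pi), rep(1 / 200, 3))
})

test_that("permutation p-values sit on the 1/N grid and match the exhaustive oracle", {
  pooled <- make_pooled(data.frame(source = c("a", "a", "b", "c"),
                                   target = c("b", "c", "d", "d")))
  p <- c(a = 0.02, b = 0.4, c = 0.11, d = 0.003)
  N <- 2000
  pi <- indirect_pvalues(pooled, p, n_shuffles = N, seed = 99)

  mult <- pi * N
  expect_equal(mult, round(mult))
  expect_true(all(pi >= 1 / N))

  exact <- oracle_indirect_p(pooled$adjacency, -log10(p[pooled$genes]))
  names(exact) <- pooled$genes
  for (g in names(pi)) {
    se <- sqrt(exact[g] * (1 - exact[g]) / N)
    expect_lte(abs(pi[g] - exact[g]), 3 * se + 1 / N)
  }

  # connected genes only: d has no out-edge
  expect_false("d" %in% names(pi))

  # determinism: same seed, same result, and global RNG is untouched
  before <- .Random.seed
  expect_identical(pi, indirect_pvalues(pooled, p, n_shuffles = N, seed = 99))
  expect_identical(before, .Random.seed)
})

test_that("decreasing a neighbour's p weakly increases SI and decreases exact p", {
  pooled <- make_pooled(data.frame(source = c("a", "a", "b"),
                                   target = c("b", "c", "c")))
  p1 <- c(a = 0.3, b = 0.2, c = 0.5)
  p2 <- p1; p2["b"] <- 0.01
  si1 <- indirect_scores(pooled, p1)
  si2 <- indirect_scores(pooled, p2)
  expect_gte(si2["a"], si1["a"])
  w1 <- -log10(p1[pooled$genes]); w2 <- -log10(p2[pooled$genes])
  e1 <- oracle_indirect_p(pooled$adjacency, w1)
  e2 <- oracle_indirect_p(pooled$adjacency, w2)
  expect_lte(e2[match("a", pooled$genes)], e1[match("a", pooled$genes)])
})

test_that("permutation nulls are valid: p_indirect is stochastically >= uniform", {
  spec <- synthetic_spec(n_pathways = 10, genes_per_pathway = 25,
                         overlap_fraction = 0.2, edge_density = 0.08,
                         seed = 17)
  pooled <- build_pooled(generate_pathways(spec))
  expect_gte(length(pooled$genes), 200)
  p <- withr::with_seed(4, stats::setNames(
    stats::runif(length(pooled$genes)), pooled$genes))
  pi <- indirect_pvalues(pooled, p, n_shuffles = 2000, seed = 5)
  n <- length(pi)
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pi <= t), t + 3 * sqrt(t * (1 - t) / n))
  }
})

test_that("Fisher combination matches its closed form and isolates pass through", {
  expect_equal(unname(combine_evidence(c(g = 1), c(g = 1))), 1)
  # q(1 - ln q) with q = 0.01
  expect_equal(unname(combine_evidence(c(g = 0.1), c(g = 0.1))),
               0.01 * (1 - log(0.01)), tolerance = 1e-12)
  expect_equal(round(unname(combine_evidence(c(g = 0.1), c(g = 0.1))), 4),
               0.0561)
  # isolated gene: p_combined = p_direct
  out <- combine_evidence(c(iso = 0.03, conn = 0.2), c(conn = 0.5))
  expect_equal(unname(out["iso"]), 0.03)
  expect_error(combine_evidence(c(a = 0.5), c(b = 0.5)), "absent")
})

test_that("the evidence table respects its own invariants", {
  spec <- synthetic_spec(n_pathways = 4, genes_per_pathway = 10,
                         edge_density = 0.15, seed = 8)
  paths <- generate_pathways(spec)
  pooled <- build_pooled(paths)
  ds <- generate_expression(paths, spec)
  N <- 500
  ev <- suppressWarnings(
    evidence_table(pooled, dataset = ds, n_shuffles = N, seed = 3))

  expect_setequal(ev$gene, pooled$genes)
  expect_true(all(ev$p_direct > 0 & ev$p_direct <= 1))
  expect_true(all(ev$p_combined > 0 & ev$p_combined <= 1))
  expect_identical(is.na(ev$p_indirect), !ev$connected)
  pin <- ev$p_indirect[ev$connected]
  expect_true(all(pin >= 1 / N))
  expect_equal(pin * N, round(pin * N))
  iso <- !ev$connected
  expect_equal(ev$p_combined[iso], ev$p_direct[iso])
  expect_equal(ev$significant, ev$p_combined < 0.05)

  # bitwise determinism with a shared seed
  ev2 <- suppressWarnings(
    evidence_table(pooled, dataset = ds, n_shuffles = N, seed = 3))
  expect_identical(ev, ev2)

  # plug-in p-values replace the t-test
  p_ext <- stats::setNames(rep(0.5, length(pooled$genes)), pooled$genes)
  ev3 <- suppressWarnings(
    evidence_table(pooled, p_direct = p_ext, n_shuffles = N, seed = 3))
  expect_equal(unique(ev3$p_direct), 0.5)
})

test_that("shuffle counts below the safety margins are rejected or flagged", {
  pooled <- make_pooled(data.frame(source = "a", target = "b"))
  p <- c(a = 0.5, b = 0.5)
  expect_error(indirect_pvalues(pooled, p, n_shuffles = 50), "at least 100")
  expect_warning(indirect_pvalues(pooled, p, n_shuffles = 200, seed = 1),
                 "coarse")
})
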