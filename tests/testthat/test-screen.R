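test_that("differential expression applies the joint lfc/FDR rule", {
  m <- matrix(0, 3, 8,
              dimnames = list(c("flat", "shifted", "small"),
                              paste0("s", 1:8)))
  m["flat", ] <- rep(c(5, 5.01), 4)
  m["shifted", ] <- c(rnorm(4, 8, 0.1), rnorm(4, 5, 0.1))
  m["small", ] <- c(rnorm(4, 5.5, 0.1), rnorm(4, 5, 0.1))  # lfc 0.5 < 1
  cohort <- expression_cohort(
    m, condition = setNames(rep(c("tumor", "normal"), each = 4),
                            colnames(m)))
  de <- differential_expression(cohort)
  expect_false(de$passes[de$gene_id == "flat"])
  expect_true(de$passes[de$gene_id == "shifted"])
  expect_false(de$passes[de$gene_id == "small"])  # fdr small but |lfc| <= 1
  expect_error(differential_expression(
    subset_cohort(cohort, samples = c("s1", "s2", "s3", "s5"))),
    "at least 2")
})

test_that("a planted 1.5 log2 shift is detected at n = 50 per group", {
  hits <- vapply(1:20, function(s) {
    v <- withr::with_seed(s, {
      rbind(g1 = c(rnorm(50, 6.5, 0.5), rnorm(50, 5, 0.5)),
            g2 = rnorm(100, 5, 0.5))
    })
    colnames(v) <- paste0("s", 1:100)
    cohort <- expression_cohort(
      v, condition = setNames(rep(c("tumor", "normal"), each = 50),
                              colnames(v)))
    differential_expression(cohort)$passes[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("DE p-values are uniform on a null cohort", {
  cohort <- generate_null_cohort(3000, 100, seed = 31, n_normal = 50)
  de <- differential_expression(cohort)
  ks <- suppressWarnings(stats::ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("RWR matches its closed form and boundary behaviour", {
  net <- toy_network()
  res <- rwr(net, seeds = "a", r = 0.85)
  A <- transition_matrix(net)
  p0 <- setNames(numeric(5), net$nodes)
  p0["a"] <- 1
  closed <- 0.85 * solve(diag(5) - 0.15 * A, p0)
  expect_lt(max(abs(res$score[match(net$nodes, res$node)] - closed)), 1e-8)
  expect_equal(sum(res$score), 1, tolerance = 1e-10)
  expect_true(all(res$score >= 0))

  # r = 1: no diffusion, scores equal the personalisation vector
  res1 <- rwr(net, seeds = c("a", "b"), r = 1)
  expect_equal(sort(res1$score, decreasing = TRUE)[1:2], c(0.5, 0.5))
  expect_equal(sum(res1$score[res1$node %in% c("a", "b")]), 1)

  # single-node network seeded at that node
  single <- weighted_network(tibble::tibble(from = character(),
                                            to = character(),
                                            weight = numeric()),
                             nodes = "x")
  expect_equal(rwr(single, "x")$score, 1)
  expect_error(rwr(net, seeds = "zz"), "not in network")
})

test_that("RWR is invariant to node relabelling/order permutations", {
  net <- toy_network()
  res <- rwr(net, seeds = "a", r = 0.7)
  shuffled <- weighted_network(net$edges[c(4, 2, 5, 1, 3), ])
  res2 <- rwr(shuffled, seeds = "a", r = 0.7)
  expect_equal(res2$score[match(res$node, res2$node)], res$score,
               tolerance = 1e-12)
})

test_that("top-fraction selection rounds up and breaks ties lexically", {
  nodes <- sprintf("n%03d", 1:100)
  scores <- rep(seq(1, 0.1, length.out = 10), each = 10)
  res <- structure(tibble::tibble(node = nodes, score = scores),
                   class = c("propagation_result", "tbl_df", "tbl", "data.frame"),
                   seeds = character())
  top5 <- select_top_fraction(res, 0.05)
  expect_length(top5, 5)  # ceiling(0.05 * 100)
  expect_equal(top5, nodes[1:5])  # tie at the cutoff -> smaller ids
  expect_length(select_top_fraction(res, 1), 100)
  # seeds excluded from the eligible set by default
  attr(res, "seeds") <- "n001"
  expect_false("n001" %in% select_top_fraction(res, 0.05))
})

test_that("co-expression edges require both |r| and FDR criteria", {
  withr::with_seed(41, {
    x <- rnorm(60)
    m <- rbind(g1 = x, g2 = x + rnorm(60, sd = 1e-6),
               g3 = -x + rnorm(60, sd = 0.4), g4 = rnorm(60))
    colnames(m) <- paste0("s", 1:60)
  })
  cohort <- expression_cohort(m, gene_class = setNames(
    c("lncRNA", "SSG", "immune", "immune"), rownames(m)))
  net <- build_coexpression_network(cohort)
  e12 <- net$edges[net$edges$from == "g1" & net$edges$to == "g2", ]
  expect_equal(e12$weight, 1, tolerance = 1e-9)
  e13 <- net$edges[net$edges$from == "g1" & net$edges$to == "g3", ]
  expect_gt(e13$weight, 0.8)       # |r| as weight
  expect_lt(e13$signed_r, -0.8)    # sign kept in the attribute

  # constant gene: warned and dropped
  m2 <- rbind(m, flat = rep(1, 60))
  cohort2 <- expression_cohort(m2, gene_class = setNames(
    c("lncRNA", "SSG", "immune", "immune", "immune"), rownames(m2)))
  expect_warning(build_coexpression_network(cohort2), "constant")
})

test_that("null co-expression networks stay sparse under FDR control", {
  rates <- vapply(1:5, function(s) {
    cohort <- generate_null_cohort(20, 200, seed = 100 + s)
    net <- build_coexpression_network(cohort, min_abs_r = 0)
    nrow(net$edges) / choose(20, 2)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("personalised PageRank equals RWR with restart 1 - damping", {
  net <- weighted_network(tibble::tibble(
    from = c("ssg1", "ssg1", "lnc1", "lnc2", "imm1"),
    to   = c("lnc1", "imm1", "lnc2", "imm2", "imm2"),
    weight = c(2, 1, 1, 0.5, 1)))
  cls <- c(ssg1 = "SSG", lnc1 = "lncRNA", lnc2 = "lncRNA",
           imm1 = "immune", imm2 = "immune")
  pri <- pagerank_prioritize(net, "ssg1", cls, damping = 0.85)
  res <- rwr(net, "ssg1", r = 0.15)
  expect_equal(pri$score,
               res$score[match(pri$gene_id, res$node)], tolerance = 1e-9)
  # independent oracle: igraph's personalised PageRank on the same graph
  g <- as_igraph(net)
  pers <- as.numeric(igraph::V(g)$name == "ssg1")
  ig <- igraph::page_rank(g, personalized = pers, damping = 0.85,
                          weights = igraph::E(g)$weight)$vector
  expect_equal(pri$score, unname(ig[pri$gene_id]), tolerance = 1e-6)
})

test_that("star-graph symmetry returns all tied leaves", {
  net <- weighted_network(tibble::tibble(
    from = rep("hub", 3), to = c("l1", "l2", "l3"), weight = 1))
  cls <- c(hub = "SSG", l1 = "lncRNA", l2 = "lncRNA", l3 = "lncRNA")
  pri <- suppressWarnings(pagerank_prioritize(net, "hub", cls, top_k = 3))
  lnc <- pri[pri$class == "lncRNA", ]
  expect_equal(lnc$gene_id, c("l1", "l2", "l3"))
  expect_equal(diff(range(lnc$score)), 0, tolerance = 1e-12)
})

test_that("a structurally tied lncRNA outranks null lncRNAs", {
  ranks <- vapply(1:10, function(s) {
    specs <- list(triplet_spec("CR"), triplet_spec("LIS"),
                  triplet_spec("LSI"))
    cfg <- synthetic_cohort_config(300, specs, n_null_genes = 150,
                                   seed = 500 + s)
    res <- generate_cohort(cfg)
    net <- build_coexpression_network(res$cohort)
    pri <- pagerank_prioritize(net, intersect(res$provenance$ssg, net$nodes),
                               gene_classes(res$cohort), top_k = 1000)
    lnc <- pri[pri$class == "lncRNA", ]
    match(res$provenance$lncRNA[1], lnc$gene_id) / nrow(lnc)
  }, numeric(1))
  expect_gte(mean(ranks <= 0.10), 0.9)
})
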