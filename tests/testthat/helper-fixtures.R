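# Shared fixtures, built in code at test time.

# Minimal 3-gene x 4-sample cohort with one gene per class.
tiny_cohort <- function() {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                0, 1, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("L1", "S1", "G1"), paste0("s", 1:4)))
  expression_cohort(m, gene_class = c(L1 = "lncRNA", S1 = "SSG",
                                      G1 = "immune"))
}

# Write a tiny expression TSV (plus classes/metadata) and return the paths.
tiny_tsv_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr <- file.path(dir, "expr.tsv")
  cls <- file.path(dir, "classes.tsv")
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "L1\t1\t2\t3\t4",
               "S1\t2\t4\t6\t8",
               "G1\t0\t1\t0\t1"), expr)
  writeLines(c("gene\tclass", "L1\tlncRNA", "S1\tSSG", "G1\timmune"), cls)
  writeLines(c("sample\tcondition\tpurity\ttime\tevent",
               "s1\ttumor\t0.8\t5\t1",
               "s2\ttumor\t0.6\t3\t0",
               "s3\tnormal\tNA\tNA\tNA",
               "s4\tnormal\tNA\tNA\tNA"), meta)
  list(expr = expr, cls = cls, meta = meta)
}

# 5-node toy network with asymmetric weights for propagation oracles.
toy_network <- function() {
  weighted_network(tibble::tibble(
    from = c("a", "a", "b", "c", "d"),
    to   = c("b", "c", "c", "d", "e"),
    weight = c(1, 2, 1, 1, 3)))
}

# Independent log-rank chi-square computed from first principles
# (sum over event times of observed-minus-expected in group 1).
logrank_chisq_oracle <- function(time, event, group1) {
  stopifnot(is.logical(group1))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group1)
    if (n < 2) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}
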