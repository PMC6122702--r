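test_that("moderated t with d0 = 0 reproduces the pooled two-sample t", {
  # one probe, groups {1,2,3} vs {4,5,6}: s2 = 1, se = sqrt(2/3)
  ds <- make_dataset(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1),
                     groups = c("a", "a", "a", "b", "b", "b"))
  res <- moderated_t_test(ds, c("a", "b"), shrinkage = list(d0 = 0, s0_sq = 1))
  expect_equal(res$logFC, -3)
  expect_equal(abs(res$t), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(abs(res$t), 3), 3.674)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("identical constant groups give logFC 0, t 0, p 1", {
  ds <- make_dataset(matrix(5, nrow = 2, ncol = 6),
                     groups = rep(c("a", "b"), each = 3))
  res <- moderated_t_test(ds, c("a", "b"), shrinkage = list(d0 = 0, s0_sq = 1))
  expect_equal(res$logFC, c(0, 0))
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("the d0 -> Inf limit uses the prior variance for every probe", {
  set.seed(31)
  ds <- random_dataset(n_probes = 10, n_per_group = 4)
  res <- moderated_t_test(ds, c("a", "b"), shrinkage = list(d0 = Inf, s0_sq = 2))
  expect_equal(res$t, res$logFC / sqrt(2 * (1 / 4 + 1 / 4)), tolerance = 1e-12)
})

test_that("sign(t) matches sign(logFC) and groups need >= 2 samples", {
  set.seed(32)
  ds <- random_dataset(n_probes = 50, n_per_group = 5)
  res <- moderated_t_test(ds, c("a", "b"))
  expect_true(all(sign(res$t) == sign(res$logFC) | res$logFC == 0))
  one <- make_dataset(matrix(rnorm(9), nrow = 3),
                      groups = c("a", "b", "b"))
  expect_error(moderated_t_test(one, c("a", "b")), ">= 2 samples")
})

test_that("shrinkage estimation handles degenerate and simulated variances", {
  expect_error(estimate_shrinkage(rep(2, 5), 4), "at least 10")
  flat <- estimate_shrinkage(rep(2, 100), 4)
  expect_identical(flat$d0, Inf)
  expect_equal(flat$s0_sq, 2)

  # recovery from a known scaled inverse-chi-square prior (d0 = 4, s0^2 = 1)
  set.seed(42)
  d0 <- 4; d <- 10; m <- 10000
  sigma2 <- d0 * 1 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, d) / d
  fit <- estimate_shrinkage(s2, d)
  expect_gte(fit$d0, 3)
  expect_lte(fit$d0, 5)
  expect_equal(fit$s0_sq, 1, tolerance = 0.25)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(33)
  # heterogeneous probe variances so the prior df is finite and the
  # comparison exercises genuine shrinkage
  probe_sd <- sqrt(4 / rchisq(300, 4))
  x <- matrix(rnorm(300 * 12, 8, rep(probe_sd, 12)), 300, 12,
              dimnames = list(sprintf("p%03d", 1:300), sprintf("s%02d", 1:12)))
  ds <- make_dataset(x, groups = rep(c("a", "b"), each = 6))
  mine <- moderated_t_test(ds, c("a", "b"))
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, rep(c(1, 0), each = 6))))
  expect_equal(mine$t, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-9)
  expect_equal(attr(mine, "shrinkage")$d0, fit$df.prior, tolerance = 1e-6)
})

test_that("null p-values are approximately uniform", {
  set.seed(34)
  ds <- random_dataset(n_probes = 10000, n_per_group = 6, sd = 0.7)
  res <- moderated_t_test(ds, c("a", "b"))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("BH adjustment matches the step-up computation and its bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(35)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("probe collapsing keeps the best probe and flags sign conflicts", {
  tab <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    gene = c("GENE1", "GENE1", "SOLO", "CONF", "CONF", ""),
    logFC = c(1, 2, 0.5, 1, -1, 3),
    t = c(3, 2, 1, 4, -4, 5),
    p = c(0.01, 0.04, 0.2, 0.001, 0.002, 1e-5),
    adj_p = c(0.03, 0.08, 0.3, 0.006, 0.006, 6e-5),
    stringsAsFactors = FALSE)
  out <- collapse_probes(tab)
  expect_false("" %in% out$gene)                      # unannotated dropped
  g1 <- out[out$gene == "GENE1", ]
  expect_equal(g1$p, 0.01)                            # smallest p wins
  expect_equal(g1$n_probes, 2L)
  expect_equal(out$n_probes[out$gene == "SOLO"], 1L)
  expect_true(out$ambiguous[out$gene == "CONF"])      # sign conflict flagged
  expect_false(any(out$ambiguous[out$gene != "CONF"]))
  expect_lte(nrow(out), nrow(tab))
  expect_true(all(out$gene %in% tab$gene))
})

test_that("collapse tie-breaks prefer larger |logFC| then probe id", {
  tab <- data.frame(probe_id = c("pB", "pA"), gene = c("G", "G"),
                    logFC = c(1, 2), t = c(1, 2), p = c(0.02, 0.02),
                    adj_p = c(0.04, 0.04), stringsAsFactors = FALSE)
  expect_equal(collapse_probes(tab)$probe_id, "pA")  # larger |logFC| wins
  tab$logFC <- c(2, 2)
  expect_equal(collapse_probes(tab)$probe_id, "pA")  # then smaller probe id
})

test_that("GEO2R exports are auto-detected and collapsed", {
  dir <- withr::local_tempdir()
  writeLines(c("ID\tadj.P.Val\tP.Value\tt\tlogFC\tGene.symbol",
               "1007_s_at\t0.01\t0.001\t5.2\t1.4\tDDR1",
               "1053_at\t0.9\t0.8\t0.2\t0.05\tRFC2",
               "121_at\t0.02\t0.004\t-4.0\t-1.1\tPAX8"),
             file.path(dir, "geo2r.tsv"))
  tab <- read_diffexpr_table(file.path(dir, "geo2r.tsv"), dataset_id = "GSEX")
  expect_s3_class(tab, "DiffExprTable")
  expect_setequal(tab$gene, c("DDR1", "RFC2", "PAX8"))
  expect_equal(attr(tab, "dataset_id"), "GSEX")
  expect_equal(tab$logFC[tab$gene == "PAX8"], -1.1)
})

test_that("welch engine matches t.test and is exposed via diff_expr", {
  set.seed(36)
  x <- matrix(rnorm(5 * 8, 8, 1), 5, 8)
  ds <- make_dataset(x, groups = rep(c("a", "b"), each = 4))
  res <- moderated_t_test(ds, c("a", "b"), engine = "welch")
  ref <- t.test(x[3, 1:4], x[3, 5:8])
  expect_equal(res$t[3], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p[3], ref$p.value, tolerance = 1e-12)
  de <- diff_expr(ds, c("a", "b"), engine = "welch")
  expect_s3_class(de, "DiffExprTable")
  expect_equal(nrow(de), 5)
})
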