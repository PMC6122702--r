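test_that("z-score of fold standardises with the sample sd", {
  tab <- make_de_table(c("A", "B", "C"), c(1, 2, 3), c(0.01, 0.01, 0.01))
  z <- zscore_fold(tab)
  expect_equal(unname(z[c("A", "B", "C")]), c(-1, 0, 1))
})

test_that("z-score handles degenerate and undersized inputs", {
  flat <- make_de_table(c("A", "B"), c(2, 2), c(0.01, 0.01))
  expect_equal(unname(zscore_fold(flat)), c(0, 0))
  one <- make_de_table("A", 1, 0.01)
  expect_error(zscore_fold(one), "at least 2")
})

test_that("z vectors have mean 0 and sample sd 1 on non-degenerate input", {
  set.seed(61)
  for (rep in 1:10) {
    tab <- make_de_table(sprintf("G%02d", 1:25), rnorm(25), runif(25, 0, 0.04))
    z <- zscore_fold(tab)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("only significant genes enter the standardisation", {
  tab <- make_de_table(c("A", "B", "C", "D"), c(1, 2, 3, 100),
                       c(0.01, 0.01, 0.01, 0.9))
  z <- zscore_fold(tab)
  expect_false("D" %in% names(z))
  expect_equal(unname(z[c("A", "B", "C")]), c(-1, 0, 1))
})

test_that("average z ranking averages available datasets and orders densely", {
  profiles <- list(T1 = c(A = 1, B = -1), T2 = c(A = 2, C = 0.5))
  out <- average_z_rank(profiles)
  expect_equal(out$avg_z[out$gene == "A"], 1.5)   # mean over present datasets
  expect_equal(out$n_datasets[out$gene == "B"], 1)
  expect_equal(out$gene, c("A", "C", "B"))        # descending avg z
  expect_equal(out$rank, 1:3)
  one <- average_z_rank(profiles["T1"])
  expect_equal(one$gene[1], "A")                  # single dataset = its own order
})

test_that("average z ranking is invariant to dataset order and affine rescaling", {
  set.seed(62)
  tabs <- lapply(1:3, function(i)
    make_de_table(sprintf("G%02d", 1:20), rnorm(20), runif(20, 0, 0.04),
                  id = paste0("T", i)))
  profiles <- lapply(tabs, zscore_fold)
  names(profiles) <- paste0("T", 1:3)
  base <- average_z_rank(profiles)
  perm <- average_z_rank(profiles[c(3, 1, 2)])
  expect_equal(perm$gene, base$gene)
  expect_equal(perm$avg_z, base$avg_z)
  expect_equal(perm$rank, base$rank)
  # positive-slope affine transform of logFC leaves z (hence ranks) unchanged
  rescaled <- lapply(tabs, function(t) { t$logFC <- 3.7 * t$logFC + 1.2; t })
  prof2 <- lapply(rescaled, zscore_fold)
  names(prof2) <- names(profiles)
  again <- average_z_rank(prof2)
  expect_equal(again$avg_z, base$avg_z, tolerance = 1e-12)
  expect_equal(again$gene, base$gene)
})

test_that("concordance calls follow the majority tumour sign", {
  up <- consensus_select(list(make_de_table("GOOD", 1, 0.01, id = "D1"),
                              make_de_table("GOOD", 1, 0.01, id = "D2")),
                         "up", k_min = 2)
  dn <- consensus_select(list(make_de_table(c("AFP", "FABP1"), c(-1, -2), c(0.01, 0.01), id = "D1"),
                              make_de_table(c("AFP", "FABP1"), c(-1, -2), c(0.01, 0.01), id = "D2")),
                         "down", k_min = 2)
  # tumours: AFP consistently up (discordant with the down call),
  # FABP1 consistently down (concordant), GOOD significant nowhere
  tumours <- lapply(1:3, function(i)
    make_de_table(c("AFP", "FABP1", "GOOD"), c(2, -1.5, 0.2),
                  c(0.001, 0.001, 0.6), id = paste0("T", i)))
  calls <- classify_concordance(list(up, dn), tumours)
  expect_equal(calls$call[calls$gene == "AFP"], "discordant")
  expect_equal(calls$tumour_direction[calls$gene == "AFP"], "up")
  expect_equal(calls$call[calls$gene == "FABP1"], "concordant")
  expect_equal(calls$call[calls$gene == "GOOD"], "unclassified")
  expect_equal(calls$tumour_direction[calls$gene == "GOOD"], "none")
})

test_that("an exact tumour sign tie is unclassified", {
  dn <- consensus_select(list(make_de_table("X", -1, 0.01, id = "D1"),
                              make_de_table("X", -1, 0.01, id = "D2")),
                         "down", k_min = 2)
  tumours <- list(make_de_table("X", 1, 0.01, id = "T1"),
                  make_de_table("X", -1, 0.01, id = "T2"))
  calls <- classify_concordance(dn, tumours)
  expect_equal(calls$call, "unclassified")
})

test_that("concordance partitions every consensus gene into exactly one call", {
  set.seed(63)
  cl <- lapply(1:3, function(i)
    make_de_table(sprintf("G%02d", 1:40), rnorm(40), runif(40, 0, 0.1),
                  id = paste0("D", i)))
  up <- suppressMessages(consensus_select(cl, "up", 2))
  dn <- suppressMessages(consensus_select(cl, "down", 2))
  tumours <- lapply(1:4, function(i)
    make_de_table(sprintf("G%02d", 1:40), rnorm(40), runif(40),
                  id = paste0("T", i)))
  calls <- classify_concordance(list(up, dn), tumours)
  expect_equal(nrow(calls), length(up$members) + length(dn$members))
  expect_true(all(calls$call %in% c("concordant", "discordant", "unclassified")))
  expect_false(anyDuplicated(calls$gene) > 0)
  # invariant linking call to the direction pair
  expect_true(all((calls$call == "concordant") ==
                    (calls$tumour_direction != "none" &
                       calls$tumour_direction == calls$cellline_direction)))
  expect_true(all((calls$call == "unclassified") ==
                    (calls$tumour_direction == "none")))
})
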