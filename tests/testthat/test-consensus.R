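# Brute-force consensus membership for one gene given its per-dataset
# status ("up" = significant positive, "down" = significant negative,
# "ns" = not significant). Mirrors the selection rule by enumeration.
brute_consensus <- function(statuses, k_min) {
  up <- sum(statuses == "up") >= k_min
  down <- sum(statuses == "down") >= k_min
  if (up && down) return("excluded")
  if (up) return("up")
  if (down) return("down")
  "none"
}

status_tables <- function(statuses, alpha = 0.05) {
  lapply(seq_along(statuses), function(i) {
    s <- statuses[i]
    make_de_table("G1",
                  logFC = switch(s, up = 1, down = -1, ns = 0.5),
                  p = if (s == "ns") 0.5 else 0.01,
                  id = paste0("D", i))
  })
}

test_that("consensus selection matches enumeration over all 27 status patterns", {
  grid <- expand.grid(d1 = c("up", "down", "ns"), d2 = c("up", "down", "ns"),
                      d3 = c("up", "down", "ns"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    statuses <- unlist(grid[i, ])
    tables <- status_tables(statuses)
    in_up <- "G1" %in% names(suppressMessages(
      consensus_select(tables, "up", k_min = 2))$members)
    in_down <- "G1" %in% names(suppressMessages(
      consensus_select(tables, "down", k_min = 2))$members)
    expected <- brute_consensus(statuses, 2)
    expect_equal(in_up, expected == "up",
                 info = paste(statuses, collapse = ","))
    expect_equal(in_down, expected == "down",
                 info = paste(statuses, collapse = ","))
  }
})

test_that("consensus support tracks dataset ids and thresholds", {
  t1 <- make_de_table(c("A", "B"), c(1, 1), c(0.01, 0.2), id = "D1")
  t2 <- make_de_table(c("A", "B"), c(2, -1), c(0.01, 0.01), id = "D2")
  t3 <- make_de_table("C", 1, 0.01, id = "D3")
  up <- consensus_select(list(t1, t2, t3), "up", k_min = 2)
  expect_equal(names(up$members), "A")
  expect_setequal(up$members$A, c("D1", "D2"))
  expect_error(consensus_select(list(t1, t2), "up", k_min = 3), "k_min")
})

test_that("genes qualifying in both directions are excluded from both sets", {
  # up-significant in 2 datasets and down-significant in 2 others
  mk <- function(lfc, id) make_de_table("X", lfc, 0.01, id = id)
  tabs <- list(mk(1, "D1"), mk(1, "D2"), mk(-1, "D3"), mk(-1, "D4"))
  expect_message(up <- consensus_select(tabs, "up", k_min = 2), "X")
  dn <- suppressMessages(consensus_select(tabs, "down", k_min = 2))
  expect_false("X" %in% names(up$members))
  expect_false("X" %in% names(dn$members))
})

test_that("ambiguous genes contribute no support", {
  t1 <- make_de_table("A", 1, 0.01, id = "D1", ambiguous = TRUE)
  t2 <- make_de_table("A", 1, 0.01, id = "D2")
  t3 <- make_de_table("A", 1, 0.01, id = "D3")
  up <- consensus_select(list(t1, t2, t3), "up", k_min = 3)
  expect_equal(length(up$members), 0)
})

test_that("consensus membership is monotone in alpha and k_min", {
  set.seed(55)
  for (rep in 1:20) {
    tabs <- lapply(1:3, function(i)
      make_de_table(sprintf("G%02d", 1:30), rnorm(30), runif(30),
                    id = paste0("D", i)))
    loose <- suppressMessages(consensus_select(tabs, "up", 2, alpha = 0.2))
    tight <- suppressMessages(consensus_select(tabs, "up", 2, alpha = 0.05))
    lower_k <- suppressMessages(consensus_select(tabs, "up", 1, alpha = 0.05))
    # raising alpha or lowering k_min can only exclude via the exclusivity
    # rule; genes never in the opposite set must be preserved
    dn_loose <- suppressMessages(consensus_select(tabs, "down", 2, alpha = 0.2))
    kept <- setdiff(names(tight$members), names(dn_loose$members))
    expect_true(all(kept %in% names(loose$members)))
    dn_k1 <- suppressMessages(consensus_select(tabs, "down", 1, alpha = 0.05))
    kept_k <- setdiff(names(tight$members), names(dn_k1$members))
    expect_true(all(kept_k %in% names(lower_k$members)))
  }
})

test_that("top core genes: identical tables return each table's own top-n", {
  set.seed(56)
  tab <- make_de_table(sprintf("G%02d", 1:40), abs(rnorm(40)) + 0.1,
                       runif(40, 1e-8, 1e-5), id = "D1")
  tab$adj_p <- tab$p * 2
  tabs <- list(tab, tab, tab)
  attr(tabs[[2]], "dataset_id") <- "D2"; attr(tabs[[3]], "dataset_id") <- "D3"
  core <- top_core_genes(tabs, "up", n = 10, alpha_adj = 1e-4)
  own <- tab[order(tab$adj_p, -abs(tab$logFC), tab$gene), ]
  expect_setequal(core, head(own$gene, 10))
  expect_equal(core, head(own$gene, 10))  # ordered by mean rank = own rank
})

test_that("top core genes: disjoint top lists give an empty result", {
  t1 <- make_de_table(c("A", "B"), c(1, 1), c(1e-6, 1e-6), adj_p = c(1e-5, 1e-5), id = "D1")
  t2 <- make_de_table(c("C", "D"), c(1, 1), c(1e-6, 1e-6), adj_p = c(1e-5, 1e-5), id = "D2")
  expect_equal(top_core_genes(list(t1, t2), "up", n = 2), character())
})

test_that("top core genes match a brute-force intersection on random tables", {
  set.seed(57)
  for (rep in 1:10) {
    tabs <- lapply(1:3, function(i) {
      g <- sprintf("G%02d", 1:30)
      make_de_table(g, rnorm(30), runif(30, 0, 0.2),
                    adj_p = runif(30, 0, 2e-4), id = paste0("D", i))
    })
    n <- 8
    core <- top_core_genes(tabs, "up", n = n, alpha_adj = 1e-4)
    brute <- Reduce(intersect, lapply(tabs, function(t) {
      t <- t[t$logFC > 0, ]
      head(t$gene[order(t$adj_p, -abs(t$logFC), t$gene)], n)
    }))
    brute <- Filter(function(g) all(vapply(tabs, function(t)
      t$adj_p[match(g, t$gene)] < 1e-4, TRUE)), brute)
    expect_setequal(core, brute)
  }
})
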