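test_that("a pure node stays a single leaf", {
  d <- tibble::tibble(x = runif(200), success = TRUE)
  tr <- fit_ctree(d, "x", min_leaf = 20, n_perm = 199, seed = 1)
  expect_equal(nrow(tr$nodes), 1)
  expect_true(tr$nodes$is_leaf)
})

test_that("a noise-free threshold is recovered at the data resolution, agreeing with CART", {
  set.seed(201)
  n <- 2000
  d <- tibble::tibble(x1 = runif(n), x2 = runif(n))
  d$success <- d$x1 < 0.4
  tr <- fit_ctree(d, c("x1", "x2"), min_leaf = 50, n_perm = 499, seed = 2)
  root <- tr$nodes[is.na(tr$nodes$parent), ]
  expect_equal(root$axis, "x1")
  xs <- sort(d$x1)
  gap <- max(diff(xs))
  expect_lt(abs(root$split - 0.4), gap + 1e-9)
  # independent recursive-partitioning cross-check
  cart <- rpart::rpart(success ~ x1 + x2, data = d, method = "class")
  cart_split <- cart$splits[1, "index"]
  expect_lt(abs(root$split - cart_split), 2 * gap + 1e-9)
  # the two leaves are pure and partition the records
  leaves <- tr$nodes[tr$nodes$is_leaf, ]
  expect_equal(sum(leaves$n), n)
  expect_equal(sum(leaves$successes), sum(d$success))
})

test_that("partition identities hold at every node", {
  rec <- box_records(1500, seed = 3)
  tr <- fit_ctree(rec, c("q1", "q2"), n_perm = 299, seed = 4)
  nd <- tr$nodes
  for (id in nd$id[!nd$is_leaf]) {
    row <- nd[nd$id == id, ]
    kids <- nd[nd$id %in% c(row$left, row$right), ]
    expect_equal(sum(kids$n), row$n)
    expect_equal(sum(kids$successes), row$successes)
  }
  # every record reaches exactly one leaf
  leaf_of <- predict_leaf(tr, rec)
  expect_true(all(leaf_of %in% nd$id[nd$is_leaf]))
  expect_equal(length(leaf_of), nrow(rec))
  # child boxes nest inside parent boxes
  for (id in nd$id[!is.na(nd$parent)]) {
    bx <- node_box(tr, id)
    pbx <- node_box(tr, nd$parent[nd$id == id])
    for (ax in pbx$axis) {
      expect_gte(bx$lower[bx$axis == ax], pbx$lower[pbx$axis == ax])
      expect_lte(bx$upper[bx$axis == ax], pbx$upper[pbx$axis == ax])
    }
  }
})

test_that("the 99% robust-leaf rule is a sharp boundary and respects weight", {
  mk <- function(successes_left) {
    x <- c(runif(1000, 0, 0.49), runif(1000, 0.51, 1))
    y <- c(rep(c(TRUE, FALSE), c(successes_left, 1000 - successes_left)),
           rep(FALSE, 1000))
    tibble::tibble(x = x, success = y)
  }
  set.seed(202)
  tr990 <- label_robust_leaves(fit_ctree(mk(990), "x", n_perm = 499, seed = 5))
  leaves <- tr990$nodes[tr990$nodes$is_leaf, ]
  expect_equal(sum(leaves$robust), 1)
  expect_gte(leaves$prop[leaves$robust], 0.99)
  tr989 <- label_robust_leaves(fit_ctree(mk(989), "x", n_perm = 499, seed = 5))
  expect_equal(sum(tr989$nodes$robust[tr989$nodes$is_leaf]), 0)
  # a single failure blocks robustness at threshold 1
  tr_all <- label_robust_leaves(fit_ctree(mk(999), "x", n_perm = 499, seed = 5),
                                success_threshold = 1)
  expect_equal(sum(tr_all$nodes$robust[tr_all$nodes$is_leaf]), 0)
  # high success but low weight: flagged, not robust
  tr_w <- label_robust_leaves(fit_ctree(mk(990), "x", n_perm = 499, seed = 5),
                              min_weight = 0.6)
  lv <- tr_w$nodes[tr_w$nodes$is_leaf, ]
  expect_equal(sum(lv$robust), 0)
  expect_equal(sum(lv$low_weight), 1)
})

test_that("subtrees grow only under non-robust leaves, on disjoint natural axes", {
  rec <- box_records(2500, seed = 6)
  main <- label_robust_leaves(fit_ctree(rec, c("q1", "q2"), n_perm = 299, seed = 7))
  expect_error(grow_subtrees(main, rec, c("q1", "u1")), "disjoint")
  subs <- grow_subtrees(main, rec, c("u1", "u2"), n_perm = 299, seed = 8)
  nd <- main$nodes
  eligible <- nd$id[nd$is_leaf & !nd$robust & nd$n >= 100]
  expect_setequal(as.integer(names(subs)), eligible)
  # subtree roots carry exactly the parent leaf's records
  leaf_of <- predict_leaf(main, rec)
  for (nm in names(subs))
    expect_equal(subs[[nm]]$n, sum(leaf_of == as.integer(nm)))
  # a fully robust main tree yields no subtrees
  pure <- tibble::tibble(q1 = runif(400), u1 = runif(400), success = TRUE)
  main_pure <- label_robust_leaves(fit_ctree(pure, "q1", n_perm = 199, seed = 9))
  expect_length(grow_subtrees(main_pure, pure, "u1", n_perm = 199), 0)
})

test_that("stability analysis is reproducible, bookkeeps frequencies, and is degenerate on separable data", {
  set.seed(203)
  n <- 1200
  d <- tibble::tibble(x1 = runif(n), x2 = runif(n))
  d$success <- d$x1 < 0.4
  st <- stability_analysis(d, c("x1", "x2"), B = 30, frac = 0.95, seed = 10,
                           test = "asymptotic")
  expect_equal(sum(st$fingerprints$freq), 30)
  expect_equal(st$fingerprints$freq[1], 30)  # one modal topology
  expect_equal(nrow(st$modal_splits), 1)
  expect_lt(st$modal_splits$sd_split, max(diff(sort(d$x1))) + 1e-9)
  st2 <- stability_analysis(d, c("x1", "x2"), B = 30, frac = 0.95, seed = 10,
                            test = "asymptotic")
  expect_equal(st$fingerprints, st2$fingerprints)
  expect_equal(st$modal_splits, st2$modal_splits)
  # B = 1 bookkeeping
  st1 <- stability_analysis(d, c("x1", "x2"), B = 1, seed = 11, test = "asymptotic")
  expect_equal(nrow(st1$fingerprints), 1)
  # weak signal: several topologies, frequencies still sum to B
  set.seed(204)
  w <- tibble::tibble(x1 = runif(300), x2 = runif(300))
  w$success <- runif(300) < plogis(2 * (0.5 - w$x1))
  stw <- stability_analysis(w, c("x1", "x2"), B = 25, seed = 12,
                            test = "asymptotic", min_leaf = 30)
  expect_equal(sum(stw$fingerprints$freq), 25)
})

test_that("regions convert tree boxes into margins around the reference", {
  set.seed(205)
  n <- 4000
  sc <- make_toy_scenario("box-recovery")
  sp <- build_space(sc)
  rec <- tibble::tibble(run_id = 1:n, q1 = runif(n), q2 = runif(n),
                        u1 = runif(n), u2 = runif(n))
  rec$success <- rec$u1 > 0.26  # pure natural-axis condition
  main <- label_robust_leaves(fit_ctree(rec, c("q1", "q2"), n_perm = 299, seed = 13))
  subs <- grow_subtrees(main, rec, c("u1", "u2"), n_perm = 299, seed = 14)
  subs <- lapply(subs, label_robust_leaves)
  rgn <- extract_regions(main, subs, sp)
  expect_s3_class(rgn, "ri_regions")
  expect_gte(nrow(rgn$regions), 1)
  cons <- tidy(rgn)
  u1c <- cons[cons$axis == "u1" & cons$lower > 0, ]
  expect_gte(nrow(u1c), 1)
  # split near 0.26, margin near 0.5 - 0.26 = 0.24
  expect_lt(abs(u1c$lower[1] - 0.26), 0.02)
  expect_lt(abs(u1c$margin[1] - 0.24), 0.02)
  # unconstrained natural axis keeps the full half-window margin
  u2c <- cons[cons$axis == "u2", ]
  expect_equal(u2c$margin[1], 0.5)
  expect_true(all(rgn$regions$contains_reference))
  p <- ggplot2::autoplot(rgn)
  expect_s3_class(p, "ggplot")
  rep_lines <- write_region_report(rgn)
  expect_true(any(grepl("tolerated margin", rep_lines)))
})

test_that("a robust box excluding the reference is flagged as needing management change", {
  set.seed(206)
  n <- 3000
  sp <- build_space(make_toy_scenario("box-recovery"))
  rec <- tibble::tibble(run_id = 1:n, q1 = runif(n), q2 = runif(n),
                        u1 = runif(n), u2 = runif(n))
  rec$success <- rec$u1 > 0.6
  main <- label_robust_leaves(fit_ctree(rec, c("q1", "q2"), n_perm = 299, seed = 15))
  subs <- lapply(grow_subtrees(main, rec, c("u1", "u2"), n_perm = 299, seed = 16),
                 label_robust_leaves)
  rgn <- extract_regions(main, subs, sp)
  expect_gte(nrow(rgn$regions), 1)
  expect_false(any(rgn$regions$contains_reference))
  # margin to the binding bound is 0 once the box excludes 0.5
  u1c <- rgn$constraints[rgn$constraints$axis == "u1" & rgn$constraints$lower > 0.5, ]
  expect_true(all(u1c$margin == 0))
})

test_that("the robustness horizon equals the brute-force scan exactly", {
  for (seed in 1:4) {
    rec <- box_records(800, seed = seed)
    got <- robustness_horizon(rec, c("u1", "u2"))
    expect_identical(got, horizon_brute_force(rec, c("u1", "u2")))
    filt <- list(q1 = c(0, 0.4))
    got_f <- robustness_horizon(rec, c("u1", "u2"), management_filter = filt)
    brute <- horizon_brute_force(rec[rec$q1 >= 0 & rec$q1 <= 0.4, ], c("u1", "u2"))
    expect_identical(got_f, brute)
  }
  # all-success and failure-at-reference corner cases
  allok <- tibble::tibble(u1 = runif(50), u2 = runif(50), success = TRUE)
  expect_equal(robustness_horizon(allok, c("u1", "u2")), 0.5)
  atref <- tibble::tibble(u1 = c(0.5, runif(50)), u2 = c(0.5, runif(50)),
                          success = c(FALSE, rep(TRUE, 50)))
  expect_equal(robustness_horizon(atref, c("u1", "u2")), 0)
  expect_error(robustness_horizon(allok, c("u1", "u2"),
                                  management_filter = list(u1 = c(2, 3))),
               "no records")
})

test_that("the synthetic edge-failure rule yields a horizon near 0.3", {
  set.seed(207)
  n <- 5000
  rec <- tibble::tibble(u1 = runif(n), u2 = runif(n))
  rec$success <- !(rec$u1 < 0.2 | rec$u1 > 0.8 | rec$u2 < 0.2 | rec$u2 > 0.8)
  got <- robustness_horizon(rec, c("u1", "u2"))
  expect_identical(got, horizon_brute_force(rec, c("u1", "u2")))
  expect_lt(abs(got - 0.3), 0.02)
})

test_that("trees serialize to JSON and DOT, and tidiers expose the node table", {
  rec <- box_records(600, seed = 30)
  tr <- label_robust_leaves(fit_ctree(rec, c("q1", "q2"), n_perm = 199, seed = 17))
  expect_s3_class(tidy(tr), "tbl_df")
  expect_equal(glance(tr)$n, 600)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, tmp)
  parsed <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(nrow(parsed$nodes), nrow(tr$nodes))
  expect_equal(parsed$nodes$split, tr$nodes$split)
  dot <- tree_to_dot(tr)
  expect_match(dot, "digraph")
  p <- ggplot2::autoplot(tr)
  expect_s3_class(p, "ggplot")
})
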