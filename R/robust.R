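#' Flag robust leaves
#'
#' A leaf is an isle of robustness when its success proportion reaches the
#' threshold (99% by default, leaving room for a few mislabelled points near
#' a boundary) *and* it carries enough of the data to be trusted
#' (`min_weight` fraction of the root records). Leaves that pass the success
#' test but not the weight test are flagged `low_weight`.
#'
#' @param tree An `ri_tree`.
#' @param success_threshold Minimum success proportion (default 0.99).
#' @param min_weight Minimum fraction of root records (default 0.05).
#' @return The tree with `robust` and `low_weight` columns on its node
#'   table and the thresholds recorded in `robust_config`.
#' @export
label_robust_leaves <- function(tree, success_threshold = 0.99, min_weight = 0.05) {
  nd <- tree$nodes
  prop_ok <- nd$is_leaf & nd$prop >= success_threshold
  weight_ok <- nd$weight >= min_weight
  nd$robust <- prop_ok & weight_ok
  nd$low_weight <- prop_ok & !weight_ok
  tree$nodes <- nd
  tree$robust_config <- list(success_threshold = success_threshold,
                             min_weight = min_weight)
  tree
}

#' Grow natural-parameter subtrees under the main tree
#'
#' The main tree is fitted on management axes (Q) only. For each of its
#' non-robust leaves, a subtree is fitted on the influential natural axes
#' (U) using only that leaf's records, asking: within this management box,
#' which states of Nature still let the goal be reached? Robust main-tree
#' leaves need no subtree. Leaves with fewer than `2 * min_leaf` records are
#' skipped with a message.
#'
#' @param main_tree A robust-labelled `ri_tree` fitted on Q axes.
#' @param records The campaign records the main tree was fitted on.
#' @param u_axes Natural-axis names (disjoint from the main tree's axes).
#' @param ... Passed to [fit_ctree()] (alpha, min_leaf, n_perm, test, seed).
#' @return A named list of `ri_tree` subtrees keyed by main-leaf id.
#' @export
grow_subtrees <- function(main_tree, records, u_axes, ...) {
  if (length(intersect(u_axes, main_tree$axes)))
    abort("`u_axes` must be disjoint from the main tree's axes")
  if (is.null(main_tree$nodes$robust))
    abort("label the main tree with label_robust_leaves() first")
  leaf_of <- predict_leaf(main_tree, records)
  leaves <- main_tree$nodes[main_tree$nodes$is_leaf & !main_tree$nodes$robust, ]
  min_leaf <- list(...)$min_leaf %||% 50
  out <- list()
  for (id in leaves$id) {
    idx <- which(leaf_of == id)
    if (length(idx) < 2 * min_leaf) {
      inform(sprintf("main leaf %d has %d records (< 2 * min_leaf); no subtree",
                     id, length(idx)))
      next
    }
    out[[as.character(id)]] <- fit_ctree(records[idx, ], u_axes,
                                         response = main_tree$response, ...)
  }
  out
}

tree_fingerprint <- function(tree) {
  nd <- tree$nodes
  # breadth-first, depth-tagged sequence of split axes (leaves marked)
  queue <- nd$id[is.na(nd$parent)]
  tokens <- character(0)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    row <- nd[nd$id == id, ]
    tokens <- c(tokens,
                if (row$is_leaf) paste0("leaf@", row$depth)
                else paste0(row$axis, "@", row$depth))
    if (!row$is_leaf) queue <- c(queue, row$left, row$right)
  }
  paste(tokens, collapse = "|")
}

bfs_splits <- function(tree) {
  nd <- tree$nodes
  queue <- nd$id[is.na(nd$parent)]
  axis <- character(0); split <- numeric(0); depth <- integer(0)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    row <- nd[nd$id == id, ]
    if (!row$is_leaf) {
      axis <- c(axis, row$axis); split <- c(split, row$split)
      depth <- c(depth, row$depth)
      queue <- c(queue, row$left, row$right)
    }
  }
  tibble(position = seq_along(axis), depth = depth, axis = axis, split = split)
}

#' Tree-stability analysis by resampling
#'
#' Refits the tree on `B` random subsets of `ceiling(frac * n)` records,
#' fingerprints each topology (depth-tagged breadth-first split-axis
#' sequence, ignoring split values), identifies the modal topology, and for
#' the replicates matching it reports the per-node mean split values and
#' standard deviations -- the indicators of how trustworthy each split
#' value is.
#'
#' @param records Campaign records.
#' @param axes Axes to fit on.
#' @param B Number of replicates (default 500).
#' @param frac Subset fraction (default 0.95).
#' @param seed Seed controlling subset draws (and MC permutations).
#' @param ... Passed to [fit_ctree()].
#' @return An `ri_stability` list: `fingerprints` (tibble of topology
#'   frequencies, summing to `B`), `modal_fingerprint`, `modal_splits`
#'   (position, depth, axis, mean_split, sd_split), `B`, `frac`.
#' @export
stability_analysis <- function(records, axes, B = 500, frac = 0.95,
                               seed = 1L, ...) {
  n <- nrow(records)
  m <- ceiling(frac * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fps <- character(B)
  splits <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, m)
    tr <- fit_ctree(records[idx, ], axes, ...)
    fps[b] <- tree_fingerprint(tr)
    splits[[b]] <- bfs_splits(tr)
  }
  tab <- sort(table(fps), decreasing = TRUE)
  modal <- names(tab)[1]
  match_idx <- which(fps == modal)
  modal_splits <- bind_rows(splits[match_idx], .id = "rep") |>
    group_by(.data$position, .data$depth, .data$axis) |>
    summarise(mean_split = mean(.data$split), sd_split = sd(.data$split),
              .groups = "drop") |>
    arrange(.data$position)
  if (length(match_idx) == 1) modal_splits$sd_split <- 0
  structure(list(
    fingerprints = tibble(fingerprint = names(tab), freq = as.integer(tab)),
    modal_fingerprint = modal,
    modal_splits = modal_splits,
    B = B, frac = frac, seed = seed
  ), class = "ri_stability")
}

#' @export
print.ri_stability <- function(x, ...) {
  cat(sprintf("<ri_stability> %d replicates (%.0f%% subsets), %d topologies\n",
              x$B, 100 * x$frac, nrow(x$fingerprints)))
  cat(sprintf("  modal topology frequency: %d/%d\n",
              x$fingerprints$freq[1], x$B))
  print(x$modal_splits)
  invisible(x)
}

#' @export
tidy.ri_stability <- function(x, ...) x$modal_splits

#' @export
glance.ri_stability <- function(x, ...) {
  tibble(B = x$B, frac = x$frac, n_topologies = nrow(x$fingerprints),
         modal_freq = x$fingerprints$freq[1])
}

#' Extract robust regions from the labelled trees
#'
#' One region per robust leaf: robust main-tree leaves give management-only
#' boxes; robust subtree leaves combine their main leaf's management box
#' with the subtree's natural-axis box. Normalized bounds are converted to
#' natural units through the space, and every natural axis gets a tolerated
#' uncertainty margin: the normalized distance from the reference (0.5) to
#' the nearest binding bound (0.5 when unconstrained, 0 when the box
#' excludes the reference), also expressed as a percentage of the reference
#' value. A region "contains the reference" when 0.5 lies inside all its
#' natural-axis intervals; otherwise reaching it requires a management
#' change.
#'
#' @param main_tree Robust-labelled main tree (Q axes).
#' @param subtrees Robust-labelled subtrees from [grow_subtrees()].
#' @param space The `ri_space` of the campaign.
#' @return An `ri_regions` list with `regions` (per-region stats and the
#'   contains-reference flag) and `constraints` (per axis: normalized and
#'   natural bounds plus margins).
#' @export
extract_regions <- function(main_tree, subtrees, space) {
  if (is.null(main_tree$nodes$robust))
    abort("label the main tree with label_robust_leaves() first")
  u_names <- space$name[space$set == "U"]
  regions <- list(); constraints <- list(); rid <- 0L

  add_region <- function(main_leaf, sub_leaf, stats, q_box, u_box) {
    rid <<- rid + 1L
    cons <- bind_rows(
      if (nrow(q_box)) mutate(q_box, set = "Q"),
      {
        # every natural axis gets a row so unconstrained margins show as 0.5
        relevant <- if (is.null(sub_leaf)) character(0) else u_names
        full <- tibble(axis = setdiff(relevant, u_box$axis), lower = 0, upper = 1)
        ub <- bind_rows(u_box, full)
        if (nrow(ub)) mutate(ub, set = "U") else NULL
      }
    )
    if (is.null(cons) || !nrow(cons)) cons <- tibble(axis = character(), lower = numeric(),
                                                     upper = numeric(), set = character())
    sp <- space[match(cons$axis, space$name), ]
    cons$lower_nat <- sp$lower + cons$lower * (sp$upper - sp$lower)
    cons$upper_nat <- sp$lower + cons$upper * (sp$upper - sp$lower)
    cons$reference <- sp$reference
    cons$margin <- ifelse(cons$set == "U",
                          pmax(0, pmin(0.5 - cons$lower, cons$upper - 0.5)),
                          NA_real_)
    cons$margin_pct <- ifelse(
      cons$set == "U" & is.finite(sp$reference) & sp$reference != 0,
      cons$margin * (sp$upper - sp$lower) / abs(sp$reference) * 100,
      NA_real_)
    contains_ref <- all(cons$lower[cons$set == "U"] <= 0.5 &
                        cons$upper[cons$set == "U"] >= 0.5)
    regions[[rid]] <<- tibble(
      region_id = rid, main_leaf = main_leaf,
      subtree_leaf = sub_leaf %||% NA_integer_,
      n = stats$n, successes = stats$successes, prop = stats$prop,
      contains_reference = contains_ref
    )
    constraints[[rid]] <<- mutate(cons, region_id = rid, .before = 1)
  }

  nd <- main_tree$nodes
  for (id in nd$id[nd$is_leaf & nd$robust]) {
    add_region(id, NULL, nd[nd$id == id, ], node_box(main_tree, id),
               tibble(axis = character(), lower = numeric(), upper = numeric()))
  }
  for (leaf_chr in names(subtrees)) {
    st <- subtrees[[leaf_chr]]
    if (is.null(st$nodes$robust)) next
    q_box <- node_box(main_tree, as.integer(leaf_chr))
    snd <- st$nodes
    for (sid in snd$id[snd$is_leaf & snd$robust]) {
      add_region(as.integer(leaf_chr), sid, snd[snd$id == sid, ],
                 q_box, node_box(st, sid))
    }
  }
  structure(list(regions = bind_rows(regions) %||% tibble(),
                 constraints = bind_rows(constraints) %||% tibble(),
                 space = space),
            class = "ri_regions")
}

#' @export
print.ri_regions <- function(x, ...) {
  cat(sprintf("<ri_regions> %d robust region(s)\n",
              if (is.null(x$regions) || !nrow(x$regions)) 0 else nrow(x$regions)))
  if (!is.null(x$regions) && nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' @export
tidy.ri_regions <- function(x, ...) {
  left_join(x$constraints, x$regions, by = "region_id")
}

#' Human-readable robust-region report
#'
#' Mirrors the block layout of the published result tables: one block per
#' region, management conditions first, then the tolerated natural-axis
#' margins relative to the reference parameterisation.
#'
#' @param regions An `ri_regions`.
#' @param path Optional file; when `NULL` the lines are returned.
#' @return Character lines (invisibly when written to file).
#' @export
write_region_report <- function(regions, path = NULL) {
  lines <- character(0)
  rg <- regions$regions
  if (is.null(rg) || !nrow(rg)) {
    lines <- "No robust regions identified."
  } else for (i in seq_len(nrow(rg))) {
    r <- rg[i, ]
    cons <- regions$constraints[regions$constraints$region_id == r$region_id, ]
    lines <- c(lines, sprintf(
      "Region %d (main leaf %d%s): %d/%d successes (%.1f%%)%s",
      r$region_id, r$main_leaf,
      if (is.na(r$subtree_leaf)) "" else sprintf(", subtree leaf %d", r$subtree_leaf),
      r$successes, r$n, 100 * r$prop,
      if (r$contains_reference) " -- compatible with the reference parameterisation"
      else " -- requires management change"))
    qc <- cons[cons$set == "Q", ]
    for (j in seq_len(nrow(qc)))
      lines <- c(lines, sprintf("  management: %.3g < %s < %.3g (natural: %.4g..%.4g)",
                                qc$lower[j], qc$axis[j], qc$upper[j],
                                qc$lower_nat[j], qc$upper_nat[j]))
    uc <- cons[cons$set == "U", ]
    for (j in seq_len(nrow(uc))) {
      pct <- if (is.na(uc$margin_pct[j])) "" else sprintf(" (+/-%.0f%% of reference)", uc$margin_pct[j])
      lines <- c(lines, sprintf("  nature:     %.3g < %s < %.3g, tolerated margin %.3g%s",
                                uc$lower[j], uc$axis[j], uc$upper[j], uc$margin[j], pct))
    }
    lines <- c(lines, "")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Info-gap robustness horizon
#'
#' The greatest horizon of uncertainty around the reference state of Nature
#' (normalized 0.5 on every natural axis) within which no explored state
#' fails the goal: records are ranked by Chebyshev distance of their
#' natural-axis coordinates to the reference, and the horizon is the
#' distance of the nearest failure (0.5, the full half-window, when no
#' failure exists; 0 when a failure sits at the reference itself). An
#' optional management filter restricts the records to a management box
#' first.
#'
#' @param records Labelled campaign records.
#' @param natural_axes Names of the natural (U) axis columns.
#' @param management_filter Optional named list `axis = c(lower, upper)` in
#'   normalized units.
#' @param reference Normalized reference coordinate (default 0.5).
#' @param response Name of the logical success column.
#' @return The estimated horizon, a number in \[0, `reference`\].
#' @export
robustness_horizon <- function(records, natural_axes, management_filter = NULL,
                               reference = 0.5, response = "success") {
  keep <- rep(TRUE, nrow(records))
  for (nm in names(management_filter)) {
    rng <- management_filter[[nm]]
    keep <- keep & records[[nm]] >= rng[1] & records[[nm]] <= rng[2]
  }
  rec <- records[keep, ]
  if (!nrow(rec)) abort("no records inside the management filter")
  dev <- do.call(pmax, lapply(natural_axes, function(a) abs(rec[[a]] - reference)))
  fail <- !rec[[response]]
  if (!any(fail)) return(reference)
  min(dev[fail])
}
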