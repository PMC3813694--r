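#' Conditional-inference classification tree
#'
#' Recursive binary partitioning with a permutation-test stopping rule, in
#' the conditional-inference framework: at each node every candidate axis is
#' tested for association with the binary response through the standardized
#' linear statistic `T_j = sum_i (x_ij - mean(x_j)) (y_i - mean(y))`; the
#' p-value comes from Monte-Carlo permutation of the response
#' (`test = "mc"`, default) or the asymptotic normal approximation
#' (`test = "asymptotic"`), Bonferroni-adjusted across axes. If the smallest
#' adjusted p-value exceeds `alpha` the node becomes a leaf; otherwise the
#' winning axis is split at the cutpoint maximizing the absolute
#' standardized two-sample statistic, subject to `min_leaf` observations per
#' side (ties broken toward the cutpoint closest to the axis median), and
#' the procedure recurses. Significance-based stopping makes the tree free
#' of the variable-selection bias and overfitting pruning is meant to fix.
#'
#' @param data A data frame with the axis columns and a binary response.
#' @param axes Axis (covariate) column names.
#' @param response Name of the binary (logical or 0/1) response column.
#' @param alpha Significance level of the stopping rule.
#' @param min_leaf Minimum records per leaf.
#' @param n_perm Monte-Carlo permutation draws.
#' @param test `"mc"` or `"asymptotic"`.
#' @param seed Optional seed for the permutation draws (local to the fit).
#' @return An `ri_tree`: node table (`id`, `parent`, `depth`, `axis`,
#'   `split`, `p_value`, `n`, `successes`, `prop`, `weight`, `is_leaf`,
#'   `left`, `right`) plus the fitting configuration.
#' @export
fit_ctree <- function(data, axes, response = "success", alpha = 0.05,
                      min_leaf = 50, n_perm = 9999,
                      test = c("mc", "asymptotic"), seed = NULL) {
  test <- match.arg(test)
  y <- data[[response]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("response must be binary (logical or 0/1)")
  X <- as.matrix(data[axes])
  n_root <- length(y)
  if (n_root < 2 * min_leaf) abort("need at least 2 * min_leaf records")

  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }

  nodes <- list()
  next_id <- 1L

  grow <- function(idx, depth, parent) {
    id <- next_id; next_id <<- next_id + 1L
    yi <- y[idx]
    node <- list(id = id, parent = parent, depth = depth,
                 axis = NA_character_, split = NA_real_, p_value = NA_real_,
                 n = length(idx), successes = sum(yi),
                 prop = mean(yi), weight = length(idx) / n_root,
                 is_leaf = TRUE, left = NA_integer_, right = NA_integer_)
    pure <- sum(yi) %in% c(0, length(yi))
    if (!pure && length(idx) >= 2 * min_leaf) {
      tst <- node_association(X[idx, , drop = FALSE], yi, test, n_perm)
      node$p_value <- min(tst$p_adj)
      if (node$p_value <= alpha) {
        win <- axes[order(tst$p_adj, -abs(tst$z))[1]]
        sp <- best_split(X[idx, win], yi, min_leaf)
        if (!is.null(sp)) {
          node$axis <- win
          node$split <- sp
          node$is_leaf <- FALSE
          nodes[[id]] <<- node  # reserve slot before recursing
          l <- grow(idx[X[idx, win] <= sp], depth + 1L, id)
          r <- grow(idx[X[idx, win] > sp], depth + 1L, id)
          node$left <- l; node$right <- r
        }
      }
    }
    nodes[[id]] <<- node
    id
  }
  grow(seq_len(n_root), 0L, NA_integer_)

  structure(list(
    nodes = bind_rows(nodes),
    axes = axes, response = response, n = n_root,
    config = list(alpha = alpha, min_leaf = min_leaf, n_perm = n_perm,
                  test = test),
    robust_config = NULL
  ), class = "ri_tree")
}

# standardized linear association statistics for all axes at one node
node_association <- function(Xn, y, test, n_perm, chunk = 500L) {
  n <- length(y)
  xc <- sweep(Xn, 2, colMeans(Xn))
  yc <- y - mean(y)
  sx2 <- colSums(xc^2)
  sy2 <- sum(yc^2)
  T_obs <- drop(crossprod(xc, yc))
  sd_T <- sqrt(sx2 * sy2 / (n - 1))
  z <- ifelse(sd_T > 0, T_obs / sd_T, 0)
  if (test == "asymptotic") {
    p <- 2 * pnorm(-abs(z))
  } else {
    exceed <- numeric(ncol(Xn))
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      Yp <- vapply(seq_len(k), function(j) yc[sample.int(n)], numeric(n))
      Tp <- abs(crossprod(xc, Yp))  # d x k
      exceed <- exceed + rowSums(Tp >= abs(T_obs) - 1e-12)
      done <- done + k
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(z = z, p = p, p_adj = pmin(1, p * ncol(Xn)))
}

# exhaustive cutpoint scan maximizing the standardized two-sample statistic
best_split <- function(x, y, min_leaf) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  yc <- (y - mean(y))[o]
  cs <- cumsum(yc)[-n]
  k <- seq_len(n - 1)
  sy2 <- sum(yc^2)
  sd_k <- sqrt(k * (n - k) / (n * (n - 1)) * sy2)
  stat <- ifelse(sd_k > 0, abs(cs) / sd_k, 0)
  valid <- k >= min_leaf & k <= n - min_leaf & xs[-n] < xs[-1]
  if (!any(valid)) return(NULL)
  stat[!valid] <- -Inf
  best <- max(stat)
  cand <- which(stat >= best - 1e-12)
  mids <- (xs[cand] + xs[cand + 1]) / 2
  mids[which.min(abs(mids - median(x)))]
}

#' Leaf membership of records
#'
#' @param tree An `ri_tree`.
#' @param data Records with the tree's axis columns.
#' @return Integer vector of leaf node ids, one per row.
#' @export
predict_leaf <- function(tree, data) {
  nd <- tree$nodes
  out <- integer(nrow(data))
  walk <- function(rows, id) {
    row <- nd[nd$id == id, ]
    if (row$is_leaf) { out[rows] <<- id; return(invisible()) }
    v <- data[[row$axis]][rows]
    walk(rows[v <= row$split], row$left)
    walk(rows[v > row$split], row$right)
  }
  walk(seq_len(nrow(data)), nd$id[is.na(nd$parent)])
  out
}

#' Axis box of a node
#'
#' Conjunction of the ancestor split constraints, as normalized intervals.
#'
#' @param tree An `ri_tree`.
#' @param id Node id.
#' @param default Interval assumed for unconstrained axes (normalized
#'   \[0,1\]).
#' @return A tibble `axis`, `lower`, `upper` for the constrained axes.
#' @export
node_box <- function(tree, id, default = c(0, 1)) {
  nd <- tree$nodes
  lo <- setNames(rep(default[1], length(tree$axes)), tree$axes)
  hi <- setNames(rep(default[2], length(tree$axes)), tree$axes)
  constrained <- character(0)
  cur <- id
  repeat {
    row <- nd[nd$id == cur, ]
    par <- row$parent
    if (is.na(par)) break
    prow <- nd[nd$id == par, ]
    constrained <- union(constrained, prow$axis)
    if (identical(prow$left, row$id)) {
      hi[[prow$axis]] <- min(hi[[prow$axis]], prow$split)
    } else {
      lo[[prow$axis]] <- max(lo[[prow$axis]], prow$split)
    }
    cur <- par
  }
  tibble(axis = constrained, lower = unname(lo[constrained]),
         upper = unname(hi[constrained]))
}

#' @export
print.ri_tree <- function(x, ...) {
  cat(sprintf("<ri_tree> %d nodes (%d leaves), n = %d, alpha = %g, test = %s\n",
              nrow(x$nodes), sum(x$nodes$is_leaf), x$n,
              x$config$alpha, x$config$test))
  nd <- x$nodes
  rec <- function(id, indent) {
    row <- nd[nd$id == id, ]
    pad <- strrep("  ", indent)
    if (row$is_leaf) {
      tag <- if (!is.null(row$robust) && isTRUE(row$robust)) " [robust]" else ""
      cat(sprintf("%s* leaf %d: n=%d, successes=%d (%.1f%%)%s\n", pad, row$id,
                  row$n, row$successes, 100 * row$prop, tag))
    } else {
      cat(sprintf("%s%s <= %.4g (node %d, p=%.3g)\n", pad, row$axis, row$split,
                  row$id, row$p_value))
      rec(row$left, indent + 1)
      rec(row$right, indent + 1)
    }
  }
  rec(nd$id[is.na(nd$parent)], 1)
  invisible(x)
}

#' @export
tidy.ri_tree <- function(x, ...) x$nodes

#' @export
glance.ri_tree <- function(x, ...) {
  tibble(n = x$n, n_nodes = nrow(x$nodes), n_leaves = sum(x$nodes$is_leaf),
         depth = max(x$nodes$depth), alpha = x$config$alpha,
         min_leaf = x$config$min_leaf, test = x$config$test)
}

#' Serialize trees to JSON
#'
#' @param tree An `ri_tree`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(
    list(nodes = tree$nodes, axes = tree$axes, response = tree$response,
         n = tree$n, config = tree$config,
         robust_config = tree$robust_config),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a tree as a DOT graph
#'
#' @param tree An `ri_tree`.
#' @param path Optional file; when `NULL` the DOT source is returned.
#' @return DOT source (invisibly when written to file).
#' @export
tree_to_dot <- function(tree, path = NULL) {
  nd <- tree$nodes
  lab <- ifelse(nd$is_leaf,
                sprintf("leaf %d\\nn=%d p=%.2f", nd$id, nd$n, nd$prop),
                sprintf("%s <= %.3g", nd$axis, nd$split))
  lines <- c("digraph tree {",
             sprintf('  n%d [label="%s", shape=%s];', nd$id, lab,
                     ifelse(nd$is_leaf, "box", "ellipse")))
  inner <- nd[!nd$is_leaf, ]
  lines <- c(lines,
             sprintf("  n%d -> n%d;", inner$id, inner$left),
             sprintf("  n%d -> n%d;", inner$id, inner$right),
             "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}
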