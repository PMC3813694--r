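default_bins <- function(n) max(10, floor(n / 100))

equal_count_bins <- function(x, bins) {
  # equal-count binning by rank; ties share a bin deterministically
  r <- rank(x, ties.method = "first")
  pmin(bins, ceiling(r / (length(x) / bins)))
}

#' First-order variance-decomposition sensitivity index
#'
#' Estimates the first-order Sobol' index `S_i = Var(E[Y|X_i]) / Var(Y)`
#' with the binned correlation-ratio estimator: partition `x` into
#' equal-count bins and compute the between-bin variance of the bin means of
#' `y`, relative to the total variance. Works directly on any
#' (e.g. Latin-hypercube) sample; no paired re-simulation design is needed.
#' The estimate is clipped to \[0, 1\].
#'
#' @param x Input sample (one design column).
#' @param y Output sample.
#' @param bins Number of equal-count bins (default `max(10, n/100)`).
#' @return The estimated first-order index.
#' @export
first_order_index <- function(x, y, bins = default_bins(length(y))) {
  n <- length(y)
  if (n < 50) abort("need at least 50 records")
  vy <- sum((y - mean(y))^2) / n
  if (vy <= 0) abort("degenerate output: Var(Y) = 0")
  b <- equal_count_bins(x, bins)
  mb <- tapply(y, b, mean)
  nb <- tabulate(b, nbins = max(b))
  s <- sum(nb[as.integer(names(mb))] * (mb - mean(y))^2) / (n * vy)
  min(max(s, 0), 1)
}

#' Pairwise interaction index
#'
#' `S_ij = Var(E[Y|X_i, X_j]) / Var(Y) - S_i - S_j`, with the joint
#' conditional expectation estimated on a 2-D equal-count grid. Near zero
#' for additive models.
#'
#' @param xi,xj Input samples.
#' @param y Output sample.
#' @param bins Marginal bins for the first-order terms.
#' @param bins2 Per-axis bins of the 2-D grid
#'   (default `max(5, floor(sqrt(n/50)))`).
#' @return The estimated interaction index.
#' @export
interaction_index <- function(xi, xj, y, bins = default_bins(length(y)),
                              bins2 = max(5, floor(sqrt(length(y) / 50)))) {
  n <- length(y)
  if (n < 50) abort("need at least 50 records")
  vy <- sum((y - mean(y))^2) / n
  if (vy <= 0) abort("degenerate output: Var(Y) = 0")
  bi <- equal_count_bins(xi, bins2)
  bj <- equal_count_bins(xj, bins2)
  cell <- (bi - 1) * bins2 + bj
  mb <- tapply(y, cell, mean)
  nb <- tapply(y, cell, length)
  s_joint <- sum(nb * (mb - mean(y))^2) / (n * vy)
  s_joint - first_order_index(xi, y, bins) - first_order_index(xj, y, bins)
}

#' Sensitivity indices for a whole campaign
#'
#' Computes the first-order index of every axis for every requested output.
#'
#' @param records Campaign records (normalized axis columns + outputs).
#' @param axes Axis names (default: all axis columns found in the attached
#'   space).
#' @param outputs Output column names.
#' @param bins Bins for [first_order_index()].
#' @return An `ri_sensitivity` tibble: `axis`, `output`, `S1`, `rank`
#'   (within output, 1 = most influential).
#' @export
sensitivity_indices <- function(records, outputs,
                                axes = intersect(attr(records, "space")$name,
                                                 names(records)),
                                bins = default_bins(nrow(records))) {
  stopifnot(length(axes) > 0, length(outputs) > 0)
  grid <- tidyr::expand_grid(axis = axes, output = outputs)
  grid$S1 <- purrr::map2_dbl(grid$axis, grid$output, function(a, o) {
    y <- records[[o]]
    ok <- !is.na(y)
    first_order_index(records[[a]][ok], y[ok], bins)
  })
  grid <- grid |>
    group_by(.data$output) |>
    mutate(rank = rank(-.data$S1, ties.method = "first")) |>
    ungroup()
  structure(grid, class = c("ri_sensitivity", class(grid)))
}

#' Rank axes and select the influential set
#'
#' Sorts axes by first-order index for one output and selects by the
#' requested policy: `"elbow"` cuts at the largest relative drop between
#' consecutive sorted indices, `"top_k"` keeps the `k` best, `"threshold"`
#' keeps axes with `S1 >= threshold`. When all indices are (numerically)
#' equal the elbow policy selects every axis with a warning.
#'
#' @param indices An `ri_sensitivity` tibble.
#' @param output The output variable to rank for.
#' @param policy `"elbow"`, `"top_k"` or `"threshold"`.
#' @param k,threshold Policy parameters.
#' @return A list: `selected` (axis names), `explained` (their summed S1),
#'   and the per-axis `ranking` tibble.
#' @export
rank_and_select <- function(indices, output, policy = c("elbow", "top_k", "threshold"),
                            k = 2, threshold = 0.05) {
  policy <- match.arg(policy)
  tab <- indices[indices$output == output, ]
  tab <- tab[order(-tab$S1), ]
  s <- tab$S1
  sel <- switch(policy,
    top_k = seq_len(min(k, nrow(tab))),
    threshold = which(s >= threshold),
    elbow = {
      if (nrow(tab) == 1 || max(s) - min(s) < 1e-12) {
        warn("all indices are equal; elbow policy selects every axis")
        seq_len(nrow(tab))
      } else {
        drops <- (s[-length(s)] - s[-1]) / pmax(s[-length(s)], 1e-12)
        seq_len(which.max(drops))
      }
    }
  )
  list(selected = tab$axis[sel], explained = sum(s[sel]), ranking = tab)
}

#' Pick-freeze Sobol' estimator (cross-check backend)
#'
#' The classic pick-freeze first-order estimator on a paired design: two
#' independent uniform samples `A`, `B` and hybrids `AB_i` (column `i`
#' taken from `A`). Requires its own evaluations of the model; provided as
#' an independent cross-check of the binned estimator on analytic rewards.
#'
#' @param f Vectorised model: takes an `n x d` matrix in \[0,1\], returns `n`
#'   outputs.
#' @param d Number of inputs.
#' @param n Sample size per matrix.
#' @param seed Integer seed.
#' @return Numeric vector of `d` first-order index estimates.
#' @export
sobol_pick_freeze <- function(f, d, n, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  A <- matrix(runif(n * d), n, d)
  B <- matrix(runif(n * d), n, d)
  yA <- f(A)
  yB <- f(B)
  v <- var(yA)
  vapply(seq_len(d), function(i) {
    ABi <- B
    ABi[, i] <- A[, i]
    mean(yA * (f(ABi) - yB)) / v
  }, numeric(1))
}
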