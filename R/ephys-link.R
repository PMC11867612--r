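#' Per-group evoked-response summaries
#'
#' For each group (e.g. brainstem region or section) reports the number of
#' recorded cells, responders, the responding fraction, the mean amplitude
#' over all cells (nonresponders contribute 0 pA, so the all-cell mean
#' equals fraction x responder mean) and the mean amplitude of responders
#' (`NA` when a group has none).
#'
#' @param cells data.frame with logical `responded`, numeric `amplitude_pa`
#'   (0 for nonresponders) and the grouping column.
#' @param grouping column name to group by (default `"region_id"`), or
#'   `NULL` to pool everything into one row.
#' @return data.frame: `group`, `n`, `n_responding`, `fraction`,
#'   `mean_amplitude_all`, `mean_amplitude_responders`.
#' @export
region_response_stats <- function(cells, grouping = "region_id") {
  if (!nrow(cells)) stopf("cell table is empty")
  if (is.null(cells$responded) || is.null(cells$amplitude_pa)) {
    stopf("cell table needs 'responded' and 'amplitude_pa' columns")
  }
  if (any(cells$amplitude_pa[!cells$responded] != 0)) {
    stopf("nonresponding cells must have amplitude 0")
  }
  g <- if (is.null(grouping)) rep("all", nrow(cells)) else cells[[grouping]]
  groups <- sort(unique(g))
  out <- lapply(groups, function(gr) {
    sub <- cells[g == gr, , drop = FALSE]
    nr <- sum(sub$responded)
    data.frame(group = gr, n = nrow(sub), n_responding = nr,
               fraction = nr / nrow(sub),
               mean_amplitude_all = mean(sub$amplitude_pa),
               mean_amplitude_responders = if (nr > 0) {
                 mean(sub$amplitude_pa[sub$responded])
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Local bouton density at each cell's location
#'
#' Looks up the density of the voxel-grid bin containing each cell,
#' following the half-open binning rule (a cell exactly on a bin edge
#' belongs to the higher bin). Cells outside the grid get `NA` and a
#' message is logged.
#'
#' @param cells data.frame with `x_um`, `y_um` (and optionally `z_um`).
#' @param grid a `voxel_grid`, typically section-averaged.
#' @return numeric density per cell (boutons/um^2 of bin area).
#' @export
local_density <- function(cells, grid) {
  P <- as_points3(cells[, intersect(c("x_um", "y_um", "z_um"), names(cells)),
                        drop = FALSE])
  d <- dim(grid$counts)
  idx <- floor(sweep(sweep(P, 2, grid$origin_um), 2, grid$bin_size_um, "/") +
                 1e-9)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
    idx[, 2] >= 0 & idx[, 2] < d[2] &
    idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- rep(NA_real_, nrow(P))
  if (any(ok)) {
    out[ok] <- grid$density[cbind(idx[ok, 1] + 1, idx[ok, 2] + 1,
                                  idx[ok, 3] + 1)]
  }
  if (any(!ok)) {
    message(sprintf("local_density: %d cell(s) outside the grid excluded",
                    sum(!ok)))
  }
  out
}

#' Response probability as a function of local bouton density
#'
#' Bins cells by their local density and reports the responding fraction
#' per bin with a Wilson 95% confidence interval. Default edges are the
#' quantiles of the pooled density distribution (5 bins); empty bins are
#' dropped with a log message.
#'
#' @param cells data.frame with logical `responded`.
#' @param densities per-cell densities from [local_density()]; `NA`s are
#'   excluded.
#' @param bin_edges increasing numeric edges; default density quantiles for
#'   `n_bins` bins. Binning is half-open (lower edge in, upper edge out)
#'   with the last bin closed above.
#' @param n_bins number of quantile bins when `bin_edges` is `NULL`.
#' @return A `density_response_curve`: data.frame with `bin_lo`, `bin_hi`,
#'   `mean_density`, `n_cells`, `n_responding`, `probability`, `ci_lower`,
#'   `ci_upper`.
#' @export
probability_vs_density <- function(cells, densities, bin_edges = NULL,
                                   n_bins = 5) {
  keep <- !is.na(densities)
  responded <- cells$responded[keep]
  densities <- densities[keep]
  if (!length(densities)) stopf("no cells with a defined local density")
  if (is.null(bin_edges)) {
    bin_edges <- unique(stats::quantile(densities, probs = seq(0, 1,
                                                               length.out = n_bins + 1)))
    if (length(bin_edges) < 2L) bin_edges <- c(bin_edges, bin_edges + 1e-12)
  }
  bin <- findInterval(densities, bin_edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  inrange <- bin >= 1 & bin <= length(bin_edges) - 1
  bin <- bin[inrange]; responded <- responded[inrange]
  rows <- lapply(seq_len(length(bin_edges) - 1L), function(b) {
    sel <- bin == b
    n <- sum(sel)
    if (n == 0L) return(NULL)
    k <- sum(responded[sel])
    ci <- wilson_ci(k, n)
    data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1],
               mean_density = mean(densities[inrange][sel]),
               n_cells = n, n_responding = k, probability = k / n,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    message(sprintf("probability_vs_density: %d empty bin(s) dropped", dropped))
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stopf("no non-empty density bins")
  rownames(rows) <- NULL
  class(rows) <- c("density_response_curve", "data.frame")
  rows
}

#' Compare bouton densities of responding vs nonresponding cells
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The default is the
#' normal approximation with tie correction (p capped at 1; p = 1 when the
#' tie-corrected variance vanishes, e.g. identical multisets). With
#' `method = "permutation"` the null distribution of U is enumerated
#' exactly when `choose(n1 + n2, n1) <= max_enumeration`, otherwise sampled
#' with `n_resample` draws.
#'
#' @param densities_responding,densities_nonresponding numeric vectors,
#'   both non-empty.
#' @param method `"normal"` (default) or `"permutation"`.
#' @param n_resample Monte-Carlo permutations when enumeration is infeasible.
#' @param max_enumeration enumeration feasibility cutoff.
#' @param seed RNG seed for the sampled permutation route.
#' @return list: `U` (statistic for the responding group), `p_value`,
#'   `method`, `n1`, `n2`.
#' @export
compare_density_distributions <- function(densities_responding,
                                          densities_nonresponding,
                                          method = c("normal", "permutation"),
                                          n_resample = 10000,
                                          max_enumeration = 200000,
                                          seed = 0L) {
  method <- match.arg(method)
  x <- densities_responding; y <- densities_nonresponding
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "normal") {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    p <- if (sigma2 <= 0) 1 else min(1, 2 * pnorm(-abs(U - mu) / sqrt(sigma2)))
  } else {
    stat_all <- c(x, y)
    u_of <- function(idx) sum(rank(stat_all)[idx]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    if (choose(n1 + n2, n1) <= max_enumeration) {
      combs <- utils::combn(n1 + n2, n1)
      us <- apply(combs, 2, u_of)
      p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    } else {
      p <- with_seed(seed, {
        us <- replicate(n_resample, u_of(sample.int(n1 + n2, n1)))
        (1 + sum(abs(us - mu) >= abs(U - mu) - 1e-9)) / (1 + n_resample)
      })
    }
  }
  list(U = U, p_value = p, method = method, n1 = n1, n2 = n2)
}
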