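#' Copy number states and their LRC means
#'
#' The mixture assigns each segment one of the states `0, 1, ..., max_cn`.
#' The expected LRC of a segment with copy number `c` in a cell with baseline
#' shift `o` is
#' \deqn{\mu_s = \log_2(0.5 c_s) + o.}
#' `o` absorbs the aneuploidy-induced displacement of the LRC baseline: a
#' cell whose genome is dominated by copy number equal to its ploidy has
#' `o = -log2(0.5 * ploidy)` (up to the downward bias the log transform of
#' noisy counts introduces, which `o` absorbs as well).
#'
#' Copy number 0 has no finite log; bins in homozygously deleted regions
#' have zero counts and land exactly at the LRC floor applied by
#' [to_lrc()], a known constant that does not move with the cell baseline.
#' State 0 therefore uses the fixed mean `log2(zero_level)` (no `+ o`),
#' with `zero_level` equal to the floor (default 0.125, mean -3).
#'
#' @param c_s copy number value(s).
#' @param o baseline shift of LRC.
#' @param zero_level normalized-count floor defining the state-0 mean.
#' @return expected LRC mean(s).
#' @export
state_mean <- function(c_s, o, zero_level = 0.125) {
  ifelse(c_s <= 0, log2(zero_level), log2(0.5 * c_s) + o)
}

# log2(0.5*c) for c >= 1; placeholder for state 0 (its mean is fixed)
.log_half_states <- function(states) {
  ifelse(states <= 0, NA_real_, log2(0.5 * states))
}

#' Gaussian log-likelihood of one segment under one state
#'
#' The bins of a segment are conditionally independent given the state, so
#' the segment log-likelihood is the sum of per-bin normal log-densities
#' `sum_i log N(x_ki; mu, sigma^2)`.
#'
#' @param x_k numeric vector of the segment's LRC values.
#' @param mu state mean (see [state_mean()]).
#' @param sigma shared standard deviation, > 0.
#' @return log-likelihood (scalar).
#' @export
segment_loglik <- function(x_k, mu, sigma) {
  stopifnot(sigma > 0, length(x_k) >= 1L)
  L <- length(x_k)
  -L / 2 * log(2 * pi * sigma^2) - sum((x_k - mu)^2) / (2 * sigma^2)
}

#' E-step: posterior state probabilities per segment
#'
#' \deqn{\gamma_{ks} = \pi_s f(x_k|\omega_s) / f(x_k|\theta),} computed in
#' log space with log-sum-exp so long segments cannot underflow to NaN.
#'
#' @param x list of numeric vectors, one per segment (the cell's LRC split
#'   by segment).
#' @param params list with `o`, `sigma`, `pi`, `states` (ascending copy
#'   numbers) and optionally `zero_level`.
#' @return numeric matrix K x S of posteriors; rows sum to 1.
#' @export
em_e_step <- function(x, params) {
  zl <- if (is.null(params$zero_level)) 0.125 else params$zero_level
  mu <- state_mean(params$states, params$o, zl)
  K <- length(x); S <- length(mu)
  stopifnot(length(params$pi) == S)
  logpi <- log(pmax(params$pi, 1e-300))
  g <- matrix(0, K, S)
  for (k in seq_len(K)) {
    lk <- logpi + vapply(mu, function(m)
      segment_loglik(x[[k]], m, params$sigma), numeric(1))
    m0 <- max(lk)
    g[k, ] <- exp(lk - (m0 + log(sum(exp(lk - m0)))))
  }
  g
}

#' M-step: closed-form parameter updates
#'
#' Given posteriors, the objective
#' \deqn{J(\theta) = \sum_k \sum_s \gamma_{ks} (\log \pi_s +
#'   \sum_i \log f(x_{ki}|\omega_s))}
#' is maximized exactly: `o` is the posterior-weighted mean of
#' `x_ki - log2(0.5 c_s)` over the states whose means shift with `o`
#' (state 0 has a fixed mean and does not inform the baseline), `sigma` the
#' posterior-weighted root mean square about the updated means, and
#' `pi_s = sum_k gamma_ks / K`.
#'
#' @param x list of per-segment LRC vectors.
#' @param gamma K x S posterior matrix (rows sum to 1).
#' @param states ascending copy number values.
#' @param zero_level fixed state-0 level, see [state_mean()].
#' @param sigma_floor lower bound applied to the sigma update (default 1e-4);
#'   hitting it triggers a warning since it indicates a degenerate fit.
#' @return list `o`, `sigma`, `pi`, `states`, `zero_level`.
#' @export
em_m_step <- function(x, gamma, states, zero_level = 0.125,
                      sigma_floor = 1e-4) {
  lhs <- .log_half_states(states)
  K <- length(x); S <- length(states)
  L <- lengths(x)
  Sx <- vapply(x, sum, numeric(1))
  shift <- states > 0  # states whose mean moves with o
  gsh <- gamma[, shift, drop = FALSE]
  denom_o <- sum(gsh * outer(L, rep(1, sum(shift))))
  if (denom_o <= 0) stop("no posterior mass on baseline-shifting states")
  o <- sum(gsh * (outer(Sx, rep(1, sum(shift))) -
                    outer(L, lhs[shift]))) / denom_o
  mu <- state_mean(states, o, zero_level)
  Sxx <- vapply(x, function(v) sum(v^2), numeric(1))
  q <- outer(Sxx, rep(1, S)) - 2 * outer(Sx, mu) + outer(L, mu^2)
  sigma <- sqrt(sum(gamma * q) / sum(gamma * outer(L, rep(1, S))))
  if (sigma < sigma_floor) {
    warning("sigma update degenerate; flooring at ", sigma_floor)
    sigma <- sigma_floor
  }
  pi_s <- colSums(gamma) / K
  list(o = o, sigma = sigma, pi = pi_s, states = states,
       zero_level = zero_level)
}

#' Observed-data log-likelihood of a cell
#'
#' `sum_k log sum_s pi_s f(x_k|omega_s)` (the quantity EM increases).
#'
#' @inheritParams em_e_step
#' @return scalar log-likelihood.
#' @export
cell_loglik <- function(x, params) {
  zl <- if (is.null(params$zero_level)) 0.125 else params$zero_level
  mu <- state_mean(params$states, params$o, zl)
  logpi <- log(pmax(params$pi, 1e-300))
  tot <- 0
  for (k in seq_along(x)) {
    lk <- logpi + vapply(mu, function(m)
      segment_loglik(x[[k]], m, params$sigma), numeric(1))
    m0 <- max(lk)
    tot <- tot + m0 + log(sum(exp(lk - m0)))
  }
  tot
}

#' Fit the per-cell copy number mixture by EM with an o grid search
#'
#' For each starting value `o0` on the grid, EM alternates the E and M steps
#' (closed-form updates on per-segment sufficient statistics) from
#' `(o = o0, sigma = sd(x), pi = uniform)` until the relative log-likelihood
#' change falls below `tol` or `max_iter` is reached.
#'
#' Distinct EM solutions ("branches") correspond to different assumed
#' baselines: read depth determines copy number only up to a scale, so a
#' profile and its (near-)proportionally scaled versions explain the data
#' almost equally well, with log-likelihood gaps dominated by how the
#' integer state grid happens to align with segment-mean noise. The fit
#' therefore exposes the whole branch table and selects among branches by
#' goodness of fit of the segment means rather than by raw likelihood:
#' each branch's excess statistic sums, over segments, the part of the
#' squared standardized residual of the segment mean (against a
#' branch-independent noise estimate, plus a small bias floor) beyond its
#' null expectation. Branches whose excess is within `sel_window` of the
#' best are feasible, and the feasible branch whose bin-weighted modal copy
#' number is nearest `prefer_ploidy` (log scale; ties toward the lower
#' ploidy, then the higher likelihood) is returned. Odd-copy-number
#' segments are what make scales distinguishable: a profile with any odd
#' segment excludes its halved version on goodness of fit.
#'
#' @param x the cell's LRC: either a numeric vector of length M together
#'   with `seg`, or a list of per-segment vectors.
#' @param seg a [segmentation()] (required when `x` is a vector).
#' @param max_cn maximum modeled copy number (default 10).
#' @param o_grid starting values for `o` (default `seq(-2, 1, by = 0.05)`,
#'   bracketing ploidies 1 to 8).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per start (default 200).
#' @param zero_level fixed state-0 level, see [state_mean()]; should equal
#'   the [to_lrc()] floor.
#' @param sigma_floor lower bound for sigma.
#' @param prefer_ploidy preferred modal copy number among feasible branches
#'   (default 2; the pipeline re-selects against a dataset-level anchor).
#' @param sel_window feasibility window on the excess statistic (default 15).
#' @param bias_floor residual bias floor (LRC units) added to the segment-
#'   mean noise variance in the excess statistic (default 0.04).
#' @return An object of class `"cn_mixture"`: list with `o`, `sigma`, `pi`,
#'   `states`, `loglik`, `gamma` (K x S), `seg_states` (selected branch's
#'   per-segment copy numbers), `ploidy` (`2^(1 - o)`), `modal_cn`,
#'   `branches` (data.frame: o, sigma, loglik, modal, excess, flat),
#'   `branch_states` (list), `selected` (row index), `loglik_trace`
#'   (winning start), `starts` (per-start diagnostics), `K`.
#' @export
fit_cell_mixture <- function(x, seg = NULL, max_cn = 10L,
                             o_grid = seq(-2, 1, by = 0.05), tol = 1e-6,
                             max_iter = 200L, zero_level = 0.125,
                             sigma_floor = 1e-4, prefer_ploidy = 2,
                             sel_window = 15, bias_floor = 0.04) {
  if (is.list(x)) {
    xs <- x
  } else {
    stopifnot(inherits(seg, "segmentation"), length(x) == seg$M)
    xs <- split(x, segment_of_bin(seg))
  }
  K <- length(xs)
  L <- as.numeric(lengths(xs))
  Sx <- vapply(xs, sum, numeric(1))
  Sxx <- vapply(xs, function(v) sum(v^2), numeric(1))
  M <- sum(L)
  xbar <- Sx / L
  # branch-independent within-segment noise (per bin)
  sw2 <- (sum(Sxx) - sum(L * xbar^2)) / max(M - K, 1)
  # boundary-trimmed segment means for the goodness-of-fit statistic:
  # breakpoints land within a bin or two of the truth, and the mixed bins
  # at segment edges would otherwise penalize exactly the well-scaled
  # branches (dense state grids absorb the contamination, the true scale
  # cannot)
  xt <- lapply(xs, function(v) {
    t <- min(2L, (length(v) - 1L) %/% 2L)
    if (t > 0L) v[(t + 1L):(length(v) - t)] else v
  })
  L_t <- as.numeric(lengths(xt))
  xbar_t <- vapply(xt, mean, numeric(1))
  states <- 0:max_cn
  lhs0 <- log2(0.5 * pmax(states, 1))  # value for state 0 unused (fixed mean)
  sigma0 <- stats::sd(unlist(xs))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- sigma_floor
  fits <- vector("list", length(o_grid))
  for (i in seq_along(o_grid)) {
    fits[[i]] <- .em_fit_cpp(L, Sx, Sxx, lhs0, log2(zero_level), o_grid[i],
                             sigma0, tol, as.integer(max_iter), sigma_floor)
  }
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  starts <- data.frame(o0 = o_grid, o = vapply(fits, `[[`, numeric(1), "o"),
                       loglik = ll, n_iter = vapply(fits, `[[`, numeric(1),
                                                    "n_iter"),
                       converged = conv)
  if (!any(conv & is.finite(ll))) {
    print(starts)
    stop("EM did not converge from any starting value of o")
  }
  cand <- which(conv & is.finite(ll))
  prof <- lapply(fits, function(f) states[apply(f$gamma, 1L, which.max)])
  key <- vapply(prof, paste, character(1), collapse = ",")
  rep_of <- vapply(split(cand, key[cand]), function(ix)
    ix[which.max(ll[ix])], integer(1))
  branch_states <- prof[rep_of]
  branches <- data.frame(
    o = starts$o[rep_of], sigma = vapply(fits[rep_of], `[[`, numeric(1),
                                         "sigma"),
    loglik = ll[rep_of],
    modal = vapply(branch_states, .modal_cn, numeric(1), L = L),
    excess = vapply(seq_along(rep_of), function(j) {
      mu <- state_mean(branch_states[[j]], starts$o[rep_of[j]], zero_level)
      .scale_excess(xbar_t, mu, L_t, sw2, bias_floor)
    }, numeric(1)),
    flat = vapply(branch_states, function(s) length(unique(s)) == 1L,
                  logical(1)),
    row.names = NULL)
  sel <- .select_branch(branches, prefer_ploidy, sel_window)
  f <- fits[[rep_of[sel]]]
  gamma <- f$gamma
  seg_states <- branch_states[[sel]]
  structure(list(o = f$o, sigma = f$sigma, pi = as.numeric(f$pi),
                 states = states, zero_level = zero_level,
                 loglik = f$loglik, gamma = gamma, seg_states = seg_states,
                 ploidy = 2^(1 - f$o),
                 modal_cn = branches$modal[sel],
                 branches = branches, branch_states = branch_states,
                 branch_fits = fits[rep_of], selected = sel,
                 sel_window = sel_window,
                 loglik_trace = f$loglik_trace,
                 starts = starts, K = K, seg_lengths = L),
            class = "cn_mixture")
}

# goodness of fit of segment means under a branch: summed excess of squared
# standardized residuals beyond their null expectation
.scale_excess <- function(xbar, mu, L, sw2, bias_floor = 0.04) {
  z2 <- (xbar - mu)^2 / (sw2 / L + bias_floor^2)
  sum(pmax(z2 - 1, 0))
}

# bin-length-weighted most abundant copy number of a per-segment profile
.modal_cn <- function(seg_cn, L) {
  w <- tapply(L, seg_cn, sum)
  as.numeric(names(w)[which.max(w)])
}

# feasible = excess within window of best; among feasible, modal CN nearest
# the preferred ploidy on log scale, ties toward lower, then max likelihood
.select_branch <- function(branches, prefer, window) {
  feas <- which(branches$excess <= min(branches$excess) + window)
  if (length(feas) == 0L) feas <- which.max(branches$loglik)
  d <- abs(log2(pmax(branches$modal[feas], 0.5) / prefer))
  sel <- feas[d == min(d)]
  sel <- sel[branches$modal[sel] == min(branches$modal[sel])]
  sel[which.max(branches$loglik[sel])]
}

#' Re-select the branch of a fitted cell mixture
#'
#' Re-applies branch selection with a different preferred ploidy (used by
#' the pipeline after estimating the dataset-level ploidy anchor). No EM is
#' re-run; the stored branch table is re-scored.
#'
#' @param fit a [fit_cell_mixture()] result.
#' @param prefer_ploidy new preferred modal copy number.
#' @return the updated `cn_mixture`.
#' @export
reselect_branch <- function(fit, prefer_ploidy) {
  stopifnot(inherits(fit, "cn_mixture"))
  sel <- .select_branch(fit$branches, prefer_ploidy, fit$sel_window)
  if (sel == fit$selected) return(fit)
  f <- fit$branch_fits[[sel]]
  fit$selected <- sel
  fit$o <- f$o; fit$sigma <- f$sigma; fit$pi <- as.numeric(f$pi)
  fit$gamma <- f$gamma
  fit$seg_states <- fit$branch_states[[sel]]
  fit$loglik <- f$loglik
  fit$loglik_trace <- f$loglik_trace
  fit$ploidy <- 2^(1 - f$o)
  fit$modal_cn <- fit$branches$modal[sel]
  fit
}

#' @export
print.cn_mixture <- function(x, ...) {
  cat(sprintf(paste0("cn_mixture: K=%d segments, o=%.4f, modal CN %g, ",
                     "sigma=%.4f, loglik=%.2f (%d branches)\n"),
              x$K, x$o, x$modal_cn, x$sigma, x$loglik, nrow(x$branches)))
  invisible(x)
}

#' Assign each segment its maximum-posterior state
#'
#' Ties are broken toward the lower copy number.
#'
#' @param gamma K x S posterior matrix.
#' @param states ascending copy number values (default `0:(S-1)`).
#' @return integer vector of per-segment copy numbers.
#' @export
assign_states <- function(gamma, states = seq_len(ncol(gamma)) - 1L) {
  states[apply(gamma, 1L, which.max)]
}

#' Re-estimate copy number of segments at the model's amplification ceiling
#'
#' The mixture only models states up to `max_cn`, so the copy number of
#' highly amplified segments is underestimated. For every segment assigned
#' the maximal state, the copy number is recomputed by inverting the state
#' mean relation at the segment's mean LRC, `c = round(2^(xbar - o + 1))`,
#' and substituted when it exceeds `max_cn`.
#'
#' @param seg_cn integer vector of per-segment copy numbers.
#' @param x list of per-segment LRC vectors (or vector + `seg`).
#' @param o fitted baseline shift.
#' @param max_cn the mixture's maximum state.
#' @param seg optional [segmentation()] when `x` is a vector.
#' @return corrected integer vector of per-segment copy numbers.
#' @export
postprocess_amplified <- function(seg_cn, x, o, max_cn = 10L, seg = NULL) {
  if (!is.list(x)) {
    stopifnot(inherits(seg, "segmentation"))
    x <- split(x, segment_of_bin(seg))
  }
  at_max <- which(seg_cn >= max_cn)
  for (k in at_max) {
    c_new <- round(2^(mean(x[[k]]) - o + 1))
    if (c_new > max_cn) seg_cn[k] <- c_new
  }
  seg_cn
}

#' Merge consecutive equal-copy-number segments of one cell
#'
#' Adjacent segments on the same chromosome with equal copy number are
#' merged; per-bin copy numbers are unchanged. This recalibrates the
#' deliberately permissive segmentation.
#'
#' @param seg_cn per-segment copy numbers.
#' @param seg the shared [segmentation()].
#' @param bins the [bin_grid()] (for chromosome assignment and coordinates).
#' @return data.frame with one row per merged segment: `chrom`, `start_bin`,
#'   `end_bin` (1-based inclusive), `start`, `end` (bp, 0-based half-open),
#'   `cn`, `n_bins`.
#' @export
merge_equal_cn <- function(seg_cn, seg, bins) {
  stopifnot(length(seg_cn) == seg$K)
  first <- cumsum(c(1L, seg$lengths[-seg$K]))
  chrom <- bins$chrom[first]
  grp <- cumsum(c(TRUE, seg_cn[-1L] != seg_cn[-seg$K] |
                    chrom[-1L] != chrom[-seg$K]))
  sb <- tapply(first, grp, min)
  eb <- tapply(cumsum(seg$lengths), grp, max)
  data.frame(chrom = bins$chrom[sb],
             start_bin = as.integer(sb), end_bin = as.integer(eb),
             start = bins$start[sb], end = bins$end[eb],
             cn = as.integer(seg_cn[!duplicated(grp)]),
             n_bins = as.integer(eb - sb + 1L),
             row.names = NULL)
}

#' Consensus breakpoints across cells
#'
#' A breakpoint is retained iff at least one cell has different copy numbers
#' on its two sides. Chromosome boundaries are not breakpoints and are
#' excluded.
#'
#' @param cn_matrix integer matrix, cells x bins, of per-bin copy numbers.
#' @param chrom_bounds boundary positions to exclude (see
#'   [chrom_boundaries()]).
#' @return sorted integer breakpoint vector (package convention).
#' @export
consensus_breakpoints <- function(cn_matrix, chrom_bounds = integer(0)) {
  cn_matrix <- rbind(cn_matrix)
  M <- ncol(cn_matrix)
  if (M < 2L) return(integer(0))
  changed <- colSums(abs(cn_matrix[, -1L, drop = FALSE] -
                           cn_matrix[, -M, drop = FALSE])) > 0
  bps <- which(changed)
  sort(setdiff(bps, chrom_bounds))
}

#' Expand per-segment copy numbers to per-bin copy numbers
#'
#' @param seg_cn per-segment copy numbers.
#' @param seg the [segmentation()].
#' @return integer vector of length M.
#' @export
expand_to_bins <- function(seg_cn, seg) {
  rep(as.integer(seg_cn), seg$lengths)
}

#' Estimate the dataset-level ploidy anchor
#'
#' Read depth identifies each cell's copy numbers only up to scale, and for
#' cells without strongly informative (odd-copy-number) segments several
#' scalings remain feasible. Cells of one tumor sample share their ancestral
#' ploidy, so weak per-cell evidence can be aggregated: for each candidate
#' ploidy `P` the per-cell minimum excess over branches with modal copy
#' number `P` (capped when absent) is reduced, over non-normal-like cells,
#' to its median difference from the per-cell best; candidates whose median
#' difference is within `slack` are feasible and the one nearest diploid
#' wins. The median (not the mean) makes the anchor robust to a single
#' clone whose segments are contaminated by missed subclonal breakpoints —
#' such segments sit at half-integer copy numbers that only a doubled state
#' grid absorbs, which would otherwise bias the aggregate toward doubled
#' ploidy — while genuine scale evidence (odd-copy-number segments) is
#' present in every tumor cell. Candidates are restricted to ancestral
#' ploidies 2-5; higher modal values arise as proportional doublings whose
#' excess is contaminated by state-grid noise-chasing.
#'
#' @param mixtures list of [fit_cell_mixture()] results.
#' @param normal_like logical per cell; these cells are excluded from the
#'   aggregation (see [cna_fit()]).
#' @param candidates candidate ancestral ploidies (default `2:5`).
#' @param slack per-cell excess slack for near-ties (default 2).
#' @return the anchor ploidy (numeric scalar).
#' @export
ploidy_anchor <- function(mixtures, normal_like = rep(FALSE,
                                                      length(mixtures)),
                          candidates = 2:5, slack = 2) {
  use <- which(!normal_like)
  if (length(use) == 0L) return(2)
  E <- vapply(candidates, function(P) {
    vapply(use, function(i) {
      br <- mixtures[[i]]$branches
      hit <- which(br$modal == P)
      if (length(hit)) min(br$excess[hit]) else
        min(br$excess) + mixtures[[i]]$sel_window
    }, numeric(1))
  }, numeric(length(use)))
  E <- rbind(E)
  d <- apply(E - apply(E, 1L, min), 2L, stats::median)
  ok <- candidates[d <= slack]
  if (length(ok) == 0L) ok <- candidates[which.min(d)]
  ok[order(abs(log2(ok / 2)), ok)][1L]
}
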