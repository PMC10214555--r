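#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classic split-free PSRF comparing within-chain and between-chain
#' variance: with `m` chains of length `n`, `W` the mean within-chain
#' sample variance and `B/n` the sample variance of the chain means,
#' \deqn{\hat{R} = \sqrt{((n-1)/n \cdot W + B/n) / W}.}
#' When every chain is constant and all agree the factor is 1 by
#' convention; when chains are constant but disagree it is `Inf` (with a
#' warning).
#'
#' @param chains List of equal-length numeric vectors (>= 2 chains of
#'   length >= 2), or a matrix with one column per chain.
#' @return The scalar PSRF.
#' @examples
#' psrf(list(c(1, 2, 3), c(1, 2, 3))) # sqrt(2/3)
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("PSRF requires at least 2 chains", call. = FALSE)
  lens <- vapply(chains, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("chains must have equal lengths", call. = FALSE)
  }
  n <- lens[1L]
  if (n < 2L) stop("chains must have length >= 2", call. = FALSE)
  W <- mean(vapply(chains, stats::var, 0))
  Bn <- stats::var(vapply(chains, mean, 0))
  if (W == 0) {
    if (Bn == 0) return(1)
    warning("zero within-chain variance with non-zero between-chain variance")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Convergence report for posterior samples
#'
#' PSRF for every monitored parameter across chains, with a pass flag at a
#' configurable threshold.
#'
#' @param samples An `nma_samples` object.
#' @param threshold Pass threshold on the maximum PSRF (default 1.05).
#' @param parameters Parameters to monitor; defaults to the basic
#'   parameters and `tau`.
#' @return A `convergence_report`: list with named `psrf`, `max_psrf`,
#'   `pass`, `threshold`, `n_chains`, `n_draws`.
#' @export
convergence_report <- function(samples, threshold = 1.05,
                               parameters = c(samples$d_names, "tau")) {
  stopifnot(inherits(samples, "nma_samples"))
  rhat <- vapply(parameters, function(p) {
    psrf(lapply(samples$chains, function(ch) ch[, p]))
  }, 0)
  structure(
    list(psrf = rhat, max_psrf = max(rhat), pass = max(rhat) < threshold,
         threshold = threshold, n_chains = length(samples$chains),
         n_draws = nrow(samples$chains[[1L]])),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("PSRF over %d chains x %d draws (threshold %.3f): %s\n",
              x$n_chains, x$n_draws, x$threshold,
              if (x$pass) "converged" else "NOT converged"))
  print(round(x$psrf, 4))
  invisible(x)
}

#' Posterior treatment-rank probabilities
#'
#' For every retained draw the treatments are ranked by their relative
#' effect versus the reference (whose effect is identically 0). With
#' `lower_is_better` (the VAS orientation) the largest effect receives
#' rank 1 (worst) and the smallest rank N (best). Ties are broken by
#' treatment order. Cell (t, r) is the fraction of draws in which
#' treatment t occupies rank r; rows and columns each sum to 1.
#'
#' @param samples An `nma_samples` object, or a draws-by-treatments
#'   effect matrix as from [effect_draws()].
#' @param lower_is_better Logical; `TRUE` when smaller outcomes are
#'   better (default, as for pain scores).
#' @return A `rank_table`: T x T probability matrix (rows treatments,
#'   columns ranks) with attribute `lower_is_better`.
#' @export
rank_probabilities <- function(samples, lower_is_better = TRUE) {
  eff <- if (inherits(samples, "nma_samples")) effect_draws(samples) else
    as.matrix(samples)
  stopifnot(nrow(eff) >= 1L)
  T_ <- ncol(eff)
  trts <- colnames(eff)
  ranks <- t(apply(eff, 1L, rank, ties.method = "first"))
  if (lower_is_better) ranks <- T_ + 1L - ranks
  probs <- matrix(0, T_, T_,
                  dimnames = list(trts, paste0("rank", seq_len(T_))))
  for (t in seq_len(T_)) {
    probs[t, ] <- tabulate(ranks[, t], nbins = T_) / nrow(eff)
  }
  structure(probs, class = c("rank_table", "matrix"),
            lower_is_better = lower_is_better)
}

#' Probability of being the best treatment
#'
#' Extracts the last rank column (rank N, the most efficacious rank) of a
#' rank table.
#'
#' @param rank_table A `rank_table` from [rank_probabilities()].
#' @return Named numeric vector of per-treatment probabilities.
#' @export
best_probability <- function(rank_table) {
  stopifnot(inherits(rank_table, "rank_table"))
  m <- unclass(rank_table)
  stats::setNames(m[, ncol(m)], rownames(m))
}

#' Compare direct (pairwise) and network estimates
#'
#' One row per treatment pair with the pairwise random-effects estimate,
#' the network (league-table) estimate, and the absolute difference of the
#' point estimates. Pairs without direct evidence are flagged
#' `"indirect only"`.
#'
#' @param pairwise Named list of `pairwise_result` objects (as from
#'   [pairwise_all()]); may be empty.
#' @param league A `league_table`.
#' @param pairs Optional list of length-2 character vectors selecting and
#'   orienting the rows; defaults to the pairs present in `pairwise`, or
#'   to all unordered league pairs when `pairwise` is empty.
#' @return data.frame with columns `treatment`, `comparator`, `k`,
#'   `direct_md`, `direct_low`, `direct_high`, `nma_md`, `nma_low`,
#'   `nma_high`, `abs_diff`, `evidence`.
#' @export
direct_vs_network_report <- function(pairwise, league, pairs = NULL) {
  stopifnot(inherits(league, "league_table"))
  if (is.null(pairs)) {
    if (length(pairwise) > 0L) {
      pairs <- lapply(pairwise, `[[`, "pair")
    } else {
      trts <- league$treatments
      pairs <- list()
      for (i in seq_len(length(trts) - 1L)) {
        for (j in seq(i + 1L, length(trts))) {
          pairs[[length(pairs) + 1L]] <- c(trts[i], trts[j])
        }
      }
    }
  }
  direct_of <- function(pair) {
    for (pw in pairwise) {
      if (identical(pw$pair, pair)) return(pw)
      if (identical(rev(pw$pair), pair)) {
        out <- pw
        out$pair <- pair
        out$pooled_md <- -pw$pooled_md
        out$ci_low <- -pw$ci_high
        out$ci_high <- -pw$ci_low
        return(out)
      }
    }
    NULL
  }
  rows <- lapply(pairs, function(pair) {
    stopifnot(all(pair %in% league$treatments))
    nma_md <- league$median[pair[2L], pair[1L]]
    nma_lo <- league$lower[pair[2L], pair[1L]]
    nma_hi <- league$upper[pair[2L], pair[1L]]
    pw <- direct_of(pair)
    if (is.null(pw)) {
      data.frame(treatment = pair[1L], comparator = pair[2L], k = 0L,
                 direct_md = NA_real_, direct_low = NA_real_,
                 direct_high = NA_real_, nma_md = nma_md, nma_low = nma_lo,
                 nma_high = nma_hi, abs_diff = NA_real_,
                 evidence = "indirect only", stringsAsFactors = FALSE)
    } else {
      data.frame(treatment = pair[1L], comparator = pair[2L], k = pw$k,
                 direct_md = pw$pooled_md, direct_low = pw$ci_low,
                 direct_high = pw$ci_high, nma_md = nma_md, nma_low = nma_lo,
                 nma_high = nma_hi, abs_diff = abs(pw$pooled_md - nma_md),
                 evidence = "direct + network", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
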