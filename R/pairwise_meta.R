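#' Study-level mean-difference contrast between two arms
#'
#' Computes the unadjusted mean difference (treatment minus comparator) and
#' its sampling variance from two arms of the same study,
#' \eqn{y = \bar{x}_t - \bar{x}_c}, \eqn{v = s_t^2/n_t + s_c^2/n_c}.
#'
#' @param arm_t,arm_c One-row data.frames (or lists) with fields
#'   `study_id`, `treatment`, `n`, `mean`, `sd`, and optionally
#'   `outcome_label`. Both arms must belong to the same study and outcome
#'   condition.
#' @return A `contrast` object: list with `study_id`, `pair`
#'   (c(treatment, comparator)), `outcome_label`, `y`, `v`.
#' @export
compute_contrast <- function(arm_t, arm_c) {
  arm_t <- as.list(arm_t)
  arm_c <- as.list(arm_c)
  if (!identical(arm_t$study_id, arm_c$study_id)) {
    stop(sprintf("arms belong to different studies (%s vs %s)",
                 arm_t$study_id, arm_c$study_id), call. = FALSE)
  }
  lab_t <- arm_t$outcome_label %||% NA_character_
  lab_c <- arm_c$outcome_label %||% NA_character_
  if (!identical(is.na(lab_t), is.na(lab_c)) ||
      (!is.na(lab_t) && !identical(lab_t, lab_c))) {
    stop("arms report different outcome conditions", call. = FALSE)
  }
  y <- arm_t$mean - arm_c$mean
  v <- arm_t$sd^2 / arm_t$n + arm_c$sd^2 / arm_c$n
  new_contrast(arm_t$study_id, c(arm_t$treatment, arm_c$treatment),
               y, v, lab_t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a study-level contrast from its summary statistics
#'
#' Low-level constructor for a mean-difference contrast when `y` and `v`
#' are already known (e.g. simulated or transcribed values).
#'
#' @param study_id Study label.
#' @param pair Length-2 character vector `c(treatment, comparator)`.
#' @param y Mean difference, treatment minus comparator.
#' @param v Sampling variance of `y` (> 0).
#' @param outcome_label Optional outcome-condition label.
#' @return A `contrast` object.
#' @export
new_contrast <- function(study_id, pair, y, v, outcome_label = NA_character_) {
  stopifnot(is.finite(y), is.finite(v), v > 0)
  structure(list(study_id = study_id, pair = pair, y = y, v = v,
                 outcome_label = outcome_label),
            class = "contrast")
}

#' Reverse the orientation of a contrast
#'
#' Negates the mean difference and swaps the pair; the variance is
#' orientation-free.
#'
#' @param contrast A `contrast` object.
#' @return The reversed `contrast`.
#' @export
reverse_contrast <- function(contrast) {
  new_contrast(contrast$study_id, rev(contrast$pair),
               -contrast$y, contrast$v, contrast$outcome_label)
}

#' Merge several outcome conditions of one study into one contrast
#'
#' A study may report the same comparison on the same scale under several
#' conditions (e.g. VAS at rest and with activity). The rows are combined
#' by fixed-effect inverse-variance weighting, treating them as
#' independent: \eqn{y = \sum(y_j/v_j)/\sum(1/v_j)}, \eqn{v = 1/\sum(1/v_j)}.
#' A single input is returned unchanged.
#'
#' @param contrasts List of `contrast` objects sharing `study_id` and pair.
#' @return One merged `contrast`.
#' @export
pool_within_study <- function(contrasts) {
  if (length(contrasts) == 0L) {
    stop("no contrasts to merge", call. = FALSE)
  }
  if (length(contrasts) == 1L) return(contrasts[[1L]])
  sid <- unique(vapply(contrasts, `[[`, "", "study_id"))
  pairs <- unique(vapply(contrasts, function(ct) paste(ct$pair, collapse = "\r"), ""))
  if (length(sid) != 1L || length(pairs) != 1L) {
    stop("within-study merge requires one study and one pair orientation",
         call. = FALSE)
  }
  y <- vapply(contrasts, `[[`, 0, "y")
  v <- vapply(contrasts, `[[`, 0, "v")
  w <- 1 / v
  new_contrast(sid, contrasts[[1L]]$pair, sum(w * y) / sum(w), 1 / sum(w))
}

#' DerSimonian-Laird random-effects pooling of mean differences
#'
#' Pools study-level contrasts under the random-effects model with the
#' DerSimonian-Laird moment estimator of the between-study variance:
#' fixed weights \eqn{w_i = 1/v_i}, Cochran's
#' \eqn{Q = \sum w_i (y_i - \bar{y}_{FE})^2} on \eqn{k-1} df,
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w_i - \sum w_i^2/\sum w_i))},
#' \eqn{I^2 = \max(0, (Q - df)/Q)}, random-effects weights
#' \eqn{w_i^* = 1/(v_i + \tau^2)}, and a normal (Wald) confidence interval
#' `pooled_md +/- z * se`.
#'
#' @param contrasts List of `contrast` objects, all oriented the same way
#'   (same treatment pair), one per study.
#' @param z Normal quantile for the confidence interval (default 1.96, a
#'   two-sided 95\% interval).
#' @return A `pairwise_result`: list with `pair`, `k`, `pooled_md`, `se`,
#'   `ci_low`, `ci_high`, `Q`, `df`, `tau2`, `i2`, `weights` (normalized
#'   random-effects weights, named by study), `studies`, `y`, `v`, `z`.
#' @export
pool_dersimonian_laird <- function(contrasts, z = 1.96) {
  if (length(contrasts) == 0L) {
    stop("no contrasts to pool", call. = FALSE)
  }
  pairs <- unique(vapply(contrasts, function(ct) paste(ct$pair, collapse = "\r"), ""))
  if (length(pairs) != 1L) {
    stop("all contrasts must share one pair orientation", call. = FALSE)
  }
  y <- vapply(contrasts, `[[`, 0, "y")
  v <- vapply(contrasts, `[[`, 0, "v")
  studies <- vapply(contrasts, `[[`, "", "study_id")
  k <- length(y)

  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  df <- k - 1L
  if (Q > df) {
    tau2 <- (Q - df) / (sum(w) - sum(w^2) / sum(w))
    i2 <- (Q - df) / Q
  } else {
    tau2 <- 0
    i2 <- 0
  }
  w_re <- 1 / (v + tau2)
  pooled <- sum(w_re * y) / sum(w_re)
  se <- 1 / sqrt(sum(w_re))

  structure(
    list(pair = contrasts[[1L]]$pair, k = k,
         pooled_md = pooled, se = se,
         ci_low = pooled - z * se, ci_high = pooled + z * se,
         Q = Q, df = df, tau2 = tau2, i2 = i2,
         weights = stats::setNames(w_re / sum(w_re), studies),
         studies = studies, y = y, v = v, z = z),
    class = "pairwise_result"
  )
}

#' @export
print.pairwise_result <- function(x, digits = 2, ...) {
  cat(sprintf("Random-effects (DL) meta-analysis: %s vs %s (k = %d)\n",
              x$pair[1L], x$pair[2L], x$k))
  cat(sprintf("  MD %s (95%% CI %s to %s)\n",
              formatC(x$pooled_md, format = "f", digits = digits),
              formatC(x$ci_low, format = "f", digits = digits),
              formatC(x$ci_high, format = "f", digits = digits)))
  cat(sprintf("  Q = %.3f (df = %d), tau^2 = %.4f, I^2 = %.1f%%\n",
              x$Q, x$df, x$tau2, 100 * x$i2))
  invisible(x)
}

# One merged contrast per study directly comparing `pair`, oriented
# pair[1] minus pair[2]; studies reporting several outcome labels are
# merged by pool_within_study.
edge_contrasts <- function(network, pair) {
  stopifnot(inherits(network, "treatment_network"), length(pair) == 2L)
  out <- list()
  for (sid in names(network$studies)) {
    st <- network$studies[[sid]]
    if (!all(pair %in% st$treatment)) next
    labs <- unique(st$outcome_label)
    per_label <- lapply(labs, function(lab) {
      sel <- if (is.na(lab)) is.na(st$outcome_label) else
        !is.na(st$outcome_label) & st$outcome_label == lab
      sub <- st[sel, , drop = FALSE]
      if (!all(pair %in% sub$treatment)) return(NULL)
      compute_contrast(sub[sub$treatment == pair[1L], ][1L, ],
                       sub[sub$treatment == pair[2L], ][1L, ])
    })
    per_label <- Filter(Negate(is.null), per_label)
    if (length(per_label) > 0L) {
      out[[sid]] <- pool_within_study(per_label)
    }
  }
  unname(out)
}

#' Pairwise meta-analysis of one treatment comparison
#'
#' Collects every study in the network that directly compares the two
#' treatments (merging multi-condition outcome rows within a study) and
#' pools them with [pool_dersimonian_laird()].
#'
#' @param network A `treatment_network`.
#' @param pair Length-2 character vector `c(treatment, comparator)`; the
#'   pooled MD is oriented treatment minus comparator.
#' @param z Normal quantile for the CI (default 1.96).
#' @return A `pairwise_result`.
#' @examples
#' net <- load_gtps_fixture()
#' pairwise_meta(net, c("ESWT", "EX"))
#' @export
pairwise_meta <- function(network, pair, z = 1.96) {
  cts <- edge_contrasts(network, pair)
  if (length(cts) == 0L) {
    stop(sprintf("no study directly compares %s and %s", pair[1L], pair[2L]),
         call. = FALSE)
  }
  pool_dersimonian_laird(cts, z = z)
}

#' Pairwise meta-analyses of every direct comparison in a network
#'
#' One [pairwise_meta()] result per network edge. Each edge is oriented as
#' in its first contributing study (first-listed arm minus second), which
#' for the packaged fixture matches the treatment-vs-comparator
#' orientation of the source trials.
#'
#' @param network A `treatment_network`.
#' @param z Normal quantile for the CI.
#' @return Named list of `pairwise_result` objects, keyed "T1 vs T2".
#' @export
pairwise_all <- function(network, z = 1.96) {
  out <- list()
  for (i in seq_len(nrow(network$edges))) {
    pair <- c(network$edges$treat1[i], network$edges$treat2[i])
    first_study <- network$studies[[network$edges$studies[[i]][1L]]]
    arm_trts <- unique(first_study$treatment)
    # orient by arm order in the first study on this edge
    if (match(pair[1L], arm_trts) > match(pair[2L], arm_trts)) {
      pair <- rev(pair)
    }
    out[[paste(pair, collapse = " vs ")]] <- pairwise_meta(network, pair, z = z)
  }
  out
}
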