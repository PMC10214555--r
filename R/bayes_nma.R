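#' MCMC settings for the consistency-model sampler
#'
#' Defaults follow the long-run analysis protocol: 4 over-dispersed chains
#' of 50000 iterations each, a burn-in of 20000 and a thinning interval of
#' 10, retaining 3000 draws per chain (12000 in total). [desk_settings()]
#' gives a lighter configuration for interactive work and tests.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Discarded initial iterations per chain.
#' @param thin Thinning interval; every `thin`-th post-burn-in draw is kept.
#' @param seed Integer seed; identical (seed, settings, data) give
#'   bit-identical draws.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_chains = 4, n_iter = 50000, burn_in = 20000,
                          thin = 10, seed = 1) {
  stopifnot(n_chains >= 1, n_iter >= 1, burn_in >= 0, thin >= 1)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 retained = (as.integer(n_iter) - as.integer(burn_in)) %/%
                   as.integer(thin)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
desk_settings <- function(seed = 1) {
  mcmc_settings(n_chains = 4, n_iter = 6000, burn_in = 1000, thin = 5,
                seed = seed)
}

#' @rdname mcmc_settings
#' @export
paper_settings <- function(seed = 1) {
  mcmc_settings(seed = seed)
}

#' Build the Bayesian random-effects consistency model for a network
#'
#' Assembles the arm-level network into contrast-level likelihood data and
#' prior hyperparameters. For a two-arm study \eqn{i} comparing treatment
#' \eqn{k} to baseline \eqn{b}: \eqn{y_i \sim N(\delta_i, v_i)} with
#' \eqn{\delta_i \sim N(d_k - d_b, \tau^2)}. A study with \eqn{a} arms
#' contributes the vector of \eqn{a-1} baseline contrasts with
#' random-effects covariance \eqn{\tau^2} on the diagonal and
#' \eqn{\tau^2/2} off it, and likelihood covariance carrying
#' \eqn{s_b^2/n_b} off-diagonal from the shared baseline arm. The
#' reference treatment's basic parameter is fixed at 0. A study reporting
#' the same two-arm comparison under several outcome labels is first
#' merged by [pool_within_study()].
#'
#' Priors are vague on an automatic outcome scale `S` (the largest
#' \eqn{|y_i| + z \sqrt{v_i}} over contrasts): basic parameters
#' \eqn{d_k \sim N(0, (c_d S)^2)} and heterogeneity
#' \eqn{\tau \sim U(0, c_\tau S)}.
#'
#' @param network A connected `treatment_network`.
#' @param reference Reference treatment (defaults to the network's).
#' @param prior_scale Override for the automatic outcome scale `S`.
#' @param c_d Multiplier for the basic-parameter prior SD (default 15).
#' @param c_tau Multiplier for the upper bound of the uniform tau prior
#'   (default 5).
#' @return An `nma_model` object.
#' @export
build_model <- function(network, reference = network$reference,
                        prior_scale = NULL, c_d = 15, c_tau = 5) {
  stopifnot(inherits(network, "treatment_network"))
  if (!reference %in% network$treatments) {
    stop(sprintf("unknown reference treatment %s", dQuote(reference)),
         call. = FALSE)
  }
  treatments <- network$treatments
  free <- setdiff(treatments, reference)
  K <- length(free)

  studies <- list()
  for (sid in names(network$studies)) {
    st <- network$studies[[sid]]
    labs <- unique(st$outcome_label)
    trts <- unique(st$treatment)
    base <- st$treatment[1L]
    others <- setdiff(trts, base)
    if (length(labs) > 1L) {
      if (length(trts) != 2L) {
        stop(sprintf("study %s: multiple outcome labels supported for two-arm studies only",
                     sid), call. = FALSE)
      }
      cts <- lapply(labs, function(lab) {
        sel <- if (is.na(lab)) is.na(st$outcome_label) else
          !is.na(st$outcome_label) & st$outcome_label == lab
        sub <- st[sel, , drop = FALSE]
        compute_contrast(sub[sub$treatment == others, ][1L, ],
                         sub[sub$treatment == base, ][1L, ])
      })
      ct <- pool_within_study(cts)
      y <- ct$y
      V <- matrix(ct$v, 1L, 1L)
    } else {
      arm_b <- st[st$treatment == base, ][1L, ]
      y <- vapply(others, function(tr) {
        st$mean[st$treatment == tr][1L] - arm_b$mean
      }, 0)
      a1 <- length(others)
      V <- matrix(arm_b$sd^2 / arm_b$n, a1, a1)
      diag(V) <- vapply(others, function(tr) {
        row <- st[st$treatment == tr, ][1L, ]
        row$sd^2 / row$n + arm_b$sd^2 / arm_b$n
      }, 0)
    }
    studies[[sid]] <- list(study_id = sid, baseline = base,
                           treatments = others, y = unname(y), V = V)
  }

  z <- 1.96
  s_auto <- max(vapply(studies, function(s) {
    max(abs(s$y) + z * sqrt(diag(s$V)))
  }, 0))
  S <- if (is.null(prior_scale)) s_auto else prior_scale
  stopifnot(S > 0)

  structure(
    list(network = network, treatments = treatments, reference = reference,
         free = free, K = K, studies = studies,
         prior = list(scale = S, sigma_d = c_d * S, tau_max = c_tau * S,
                      c_d = c_d, c_tau = c_tau)),
    class = "nma_model"
  )
}

#' @export
print.nma_model <- function(x, ...) {
  cat(sprintf("Consistency model: %d treatments (%d basic parameters), %d studies\n",
              length(x$treatments), x$K, length(x$studies)))
  cat(sprintf("Reference: %s; priors d ~ N(0, %.1f^2), tau ~ U(0, %.1f)\n",
              x$reference, x$prior$sigma_d, x$prior$tau_max))
  invisible(x)
}

# Precompute the fixed pieces of the Gibbs sweep. Two-arm studies are
# batched into vectors; multi-arm studies keep per-study matrices.
# P = (I + J)/2 is the exchangeable random-effects correlation structure
# of a multi-arm study's baseline contrasts (unit tau), with
# P^{-1} = 2(I - J/a) for a arms.
prepare_sampler <- function(model) {
  trt_index <- stats::setNames(seq_along(model$treatments), model$treatments)
  free_index <- stats::setNames(seq_len(model$K), model$free)
  col_of <- function(tr) if (tr == model$reference) 0L else free_index[[tr]]

  two <- list(y = numeric(0), v = numeric(0), t = integer(0), b = integer(0),
              sid = character(0))
  multi <- list()
  X2 <- NULL
  rowsX2 <- list()
  for (s in model$studies) {
    a1 <- length(s$y)
    if (a1 == 1L) {
      two$y <- c(two$y, s$y)
      two$v <- c(two$v, s$V[1L, 1L])
      two$t <- c(two$t, col_of(s$treatments[1L]))
      two$b <- c(two$b, col_of(s$baseline))
      two$sid <- c(two$sid, s$study_id)
      xr <- numeric(model$K)
      ct <- col_of(s$treatments[1L]); cb <- col_of(s$baseline)
      if (ct > 0L) xr[ct] <- 1
      if (cb > 0L) xr[cb] <- xr[cb] - 1
      rowsX2[[length(rowsX2) + 1L]] <- xr
    } else {
      a <- a1 + 1L
      P <- (diag(a1) + matrix(1, a1, a1)) / 2
      Pinv <- 2 * (diag(a1) - matrix(1 / a, a1, a1))
      Xs <- matrix(0, a1, model$K)
      cb <- col_of(s$baseline)
      for (j in seq_len(a1)) {
        ct <- col_of(s$treatments[j])
        if (ct > 0L) Xs[j, ct] <- 1
        if (cb > 0L) Xs[j, cb] <- Xs[j, cb] - 1
      }
      multi[[length(multi) + 1L]] <-
        list(sid = s$study_id, y = s$y, Vinv = solve(s$V), P = P, Pinv = Pinv,
             X = Xs, a1 = a1, logdetP = determinant(P)$modulus[1L])
    }
  }
  X2 <- if (length(rowsX2) > 0L) do.call(rbind, rowsX2) else
    matrix(0, 0L, model$K)

  # d-precision contribution per unit 1/tau^2
  M0 <- crossprod(X2)
  for (ms in multi) M0 <- M0 + crossprod(ms$X, ms$Pinv %*% ms$X)

  nu <- length(two$y) + sum(vapply(multi, `[[`, 0L, "a1"))
  delta_names <- c(
    if (length(two$sid) > 0L) paste0("delta[", two$sid, "]"),
    unlist(lapply(multi, function(ms)
      paste0("delta[", ms$sid, ":", seq_len(ms$a1), "]")))
  )
  list(two = two, multi = multi, X2 = X2, M0 = M0, nu = nu,
       delta_names = delta_names)
}

# Slice sampler for tau on (0, tau_max): target
# log f(tau) = -nu log(tau) - S_r / (2 tau^2). Shrinkage from the full
# bounded prior support (a valid slice update on a bounded domain).
slice_tau <- function(tau0, nu, S_r, tau_max) {
  logf <- function(tau) -nu * log(tau) - S_r / (2 * tau * tau)
  logy <- logf(tau0) - stats::rexp(1)
  L <- 0
  R <- tau_max
  repeat {
    prop <- stats::runif(1, L, R)
    if (logf(prop) >= logy) return(prop)
    if (prop < tau0) L <- prop else R <- prop
    if (R - L < 1e-300) return(tau0)
  }
}

#' Sample the posterior of a consistency model by MCMC
#'
#' Blocked Gibbs sampler: study-level random effects \eqn{\delta_i} and the
#' basic-parameter vector `d` have normal full conditionals and are drawn
#' exactly; the heterogeneity SD \eqn{\tau} is updated by slice sampling on
#' its bounded prior support. Chains are initialized over-dispersed: chain
#' `j` starts `d` at alternating offsets of up to \eqn{\pm 2 \sigma_d / 10}
#' and \eqn{\tau} at spread quantiles of its uniform prior. Identical
#' (seed, settings, data) give bit-identical draws; chains are run
#' sequentially from one seeded stream.
#'
#' @param model An `nma_model` from [build_model()].
#' @param settings An `mcmc_settings` object.
#' @return An `nma_samples` object: per-chain draw matrices (columns
#'   `d[k]` for non-reference treatments, `tau`, and the study effects
#'   `delta[...]`), plus the model and a settings echo.
#' @export
sample_posterior <- function(model, settings = mcmc_settings()) {
  stopifnot(inherits(model, "nma_model"), inherits(settings, "mcmc_settings"))
  prep <- prepare_sampler(model)
  K <- model$K
  sigma_d <- model$prior$sigma_d
  tau_max <- model$prior$tau_max
  m <- settings$n_chains

  two <- prep$two
  multi <- prep$multi
  n2 <- length(two$y)
  X2t <- t(prep$X2)
  prior_prec <- diag(1 / sigma_d^2, K)

  # over-dispersed starting points
  sign_j <- rep_len(c(-1, 1), m)
  mag_j <- ceiling(seq_len(m) / 2) / max(1, ceiling(m / 2))
  d_starts <- lapply(seq_len(m), function(j) {
    rep(sign_j[j] * mag_j[j] * 2 * sigma_d / 10, K)
  })
  tau_probs <- if (m == 1L) 0.5 else seq(0.1, 0.9, length.out = m)
  tau_starts <- tau_probs * tau_max

  set.seed(settings$seed)
  param_names <- c(paste0("d[", model$free, "]"), "tau", prep$delta_names)
  chains <- vector("list", m)

  for (j in seq_len(m)) {
    d <- d_starts[[j]]
    tau <- tau_starts[j]
    delta2 <- two$y
    deltam <- lapply(multi, `[[`, "y")
    draws <- matrix(NA_real_, settings$retained, length(param_names),
                    dimnames = list(NULL, param_names))
    kept <- 0L

    for (it in seq_len(settings$n_iter)) {
      tau2 <- tau * tau

      # delta | d, tau, y
      if (n2 > 0L) {
        mean_d2 <- ifelse(two$t > 0L, d[pmax(two$t, 1L)], 0) -
          ifelse(two$b > 0L, d[pmax(two$b, 1L)], 0)
        prec <- 1 / two$v + 1 / tau2
        mu <- (two$y / two$v + mean_d2 / tau2) / prec
        delta2 <- stats::rnorm(n2, mu, sqrt(1 / prec))
      }
      if (length(multi) > 0L) {
        for (q in seq_along(multi)) {
          ms <- multi[[q]]
          Prec <- ms$Vinv + ms$Pinv / tau2
          bvec <- ms$Vinv %*% ms$y + (ms$Pinv %*% (ms$X %*% d)) / tau2
          U <- chol(Prec)
          mu_q <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
          deltam[[q]] <- drop(mu_q + backsolve(U, stats::rnorm(ms$a1)))
        }
      }

      # d | delta, tau
      if (K > 0L) {
        bvec <- X2t %*% delta2
        for (q in seq_along(multi)) {
          ms <- multi[[q]]
          bvec <- bvec + crossprod(ms$X, ms$Pinv %*% deltam[[q]])
        }
        A <- prep$M0 / tau2 + prior_prec
        U <- chol(A)
        mu <- backsolve(U, backsolve(U, bvec / tau2, transpose = TRUE))
        d <- drop(mu + backsolve(U, stats::rnorm(K)))
      }

      # tau | delta, d  (slice)
      S_r <- 0
      if (n2 > 0L) {
        mean_d2 <- ifelse(two$t > 0L, d[pmax(two$t, 1L)], 0) -
          ifelse(two$b > 0L, d[pmax(two$b, 1L)], 0)
        S_r <- S_r + sum((delta2 - mean_d2)^2)
      }
      for (q in seq_along(multi)) {
        ms <- multi[[q]]
        r <- deltam[[q]] - drop(ms$X %*% d)
        S_r <- S_r + drop(crossprod(r, ms$Pinv %*% r))
      }
      tau <- slice_tau(tau, prep$nu, S_r, tau_max)

      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L) {
        kept <- kept + 1L
        row <- c(d, tau, delta2, unlist(deltam))
        if (any(!is.finite(row))) {
          stop(sprintf("non-finite state in chain %d at iteration %d: %s",
                       j, it,
                       paste(param_names[!is.finite(row)], collapse = ", ")),
               call. = FALSE)
        }
        draws[kept, ] <- row
      }
    }
    chains[[j]] <- draws
  }

  structure(
    list(model = model, settings = settings, chains = chains,
         parameters = param_names,
         d_names = paste0("d[", model$free, "]"),
         treatments = model$treatments, reference = model$reference),
    class = "nma_samples"
  )
}

#' @export
print.nma_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: %d chains x %d retained draws, %d parameters\n",
              length(x$chains), nrow(x$chains[[1L]]), length(x$parameters)))
  cat(sprintf("Reference: %s; seed %d\n", x$reference, x$settings$seed))
  invisible(x)
}

#' Pooled posterior draws of the treatment effects
#'
#' Stacks all chains and returns one column per treatment (reference
#' column identically 0), each row one retained draw of the basic
#' parameters, in network treatment order.
#'
#' @param samples An `nma_samples` object.
#' @return Numeric matrix, draws x treatments.
#' @export
effect_draws <- function(samples) {
  stopifnot(inherits(samples, "nma_samples"))
  all_draws <- do.call(rbind, samples$chains)
  out <- matrix(0, nrow(all_draws), length(samples$treatments),
                dimnames = list(NULL, samples$treatments))
  free <- setdiff(samples$treatments, samples$reference)
  out[, free] <- all_draws[, paste0("d[", free, "]"), drop = FALSE]
  out
}

#' League table of all pairwise relative effects
#'
#' For every ordered treatment pair the per-draw contrast
#' \eqn{d_c - d_r} (column treatment relative to row treatment; negative
#' favors the column treatment when lower outcomes are better) is
#' summarized by its posterior median and equal-tail 95\% interval.
#' Consistency holds by construction: every functional contrast is formed
#' from the same draw of the basic parameters.
#'
#' @param samples An `nma_samples` object.
#' @param probs Lower and upper interval probabilities.
#' @return A `league_table`: list of `treatments` and T x T matrices
#'   `median`, `lower`, `upper` (diagonal 0).
#' @export
league_table <- function(samples, probs = c(0.025, 0.975)) {
  eff <- effect_draws(samples)
  trts <- colnames(eff)
  T_ <- length(trts)
  med <- lo <- hi <- matrix(0, T_, T_, dimnames = list(trts, trts))
  for (r in seq_len(T_)) {
    for (cc in seq_len(T_)) {
      if (r == cc) next
      diff <- eff[, cc] - eff[, r]
      med[r, cc] <- stats::median(diff)
      qs <- stats::quantile(diff, probs, names = FALSE)
      lo[r, cc] <- qs[1L]
      hi[r, cc] <- qs[2L]
    }
  }
  structure(list(treatments = trts, median = med, lower = lo, upper = hi),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  T_ <- length(x$treatments)
  out <- matrix("", T_, T_, dimnames = list(x$treatments, x$treatments))
  for (r in seq_len(T_)) {
    for (cc in seq_len(T_)) {
      out[r, cc] <- if (r == cc) x$treatments[r] else
        sprintf("%.*f (%.*f, %.*f)", digits, x$median[r, cc],
                digits, x$lower[r, cc], digits, x$upper[r, cc])
    }
  }
  print(out, quote = FALSE)
  invisible(x)
}

#' Posterior summary of the heterogeneity SD
#'
#' @param samples An `nma_samples` object.
#' @param probs Lower and upper interval probabilities.
#' @return Named numeric vector: `median`, `lower`, `upper`.
#' @export
tau_summary <- function(samples, probs = c(0.025, 0.975)) {
  tau <- unlist(lapply(samples$chains, function(ch) ch[, "tau"]))
  c(median = stats::median(tau),
    lower = stats::quantile(tau, probs[1L], names = FALSE),
    upper = stats::quantile(tau, probs[2L], names = FALSE))
}

#' Posterior draws of one relative effect
#'
#' @param samples An `nma_samples` object.
#' @param treatment,vs Treatment codes; returns draws of
#'   `d[treatment] - d[vs]` (treatment relative to `vs`).
#' @return Numeric vector of draws.
#' @export
relative_effect_draws <- function(samples, treatment, vs) {
  eff <- effect_draws(samples)
  stopifnot(treatment %in% colnames(eff), vs %in% colnames(eff))
  eff[, treatment] - eff[, vs]
}
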