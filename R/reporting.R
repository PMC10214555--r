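#' Format a point estimate with its interval for presentation
#'
#' Renders `"-0.82 (-1.81, 0.17)"`-style cells: fixed decimals, ASCII
#' hyphen-minus. Presentation only; canonical CSV outputs keep full
#' precision.
#'
#' @param x,lo,hi Point estimate and interval bounds.
#' @param digits Decimals (default 2).
#' @return Character vector.
#' @export
format_estimate <- function(x, lo, hi, digits = 2) {
  sprintf("%.*f (%.*f, %.*f)", digits, x, digits, lo, digits, hi)
}

pairwise_frame <- function(pairwise) {
  if (length(pairwise) == 0L) {
    return(data.frame(treatment = character(), comparator = character(),
                      k = integer(), pooled_md = double(), se = double(),
                      ci_low = double(), ci_high = double(), Q = double(),
                      df = integer(), tau2 = double(), i2 = double(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(pairwise, function(pw) {
    data.frame(treatment = pw$pair[1L], comparator = pw$pair[2L], k = pw$k,
               pooled_md = pw$pooled_md, se = pw$se, ci_low = pw$ci_low,
               ci_high = pw$ci_high, Q = pw$Q, df = pw$df, tau2 = pw$tau2,
               i2 = pw$i2, stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

league_grid <- function(league, cell = function(m, l, u) {
  sprintf("%.17g|%.17g|%.17g", m, l, u)
}) {
  trts <- league$treatments
  T_ <- length(trts)
  grid <- matrix("", T_, T_, dimnames = list(trts, trts))
  for (r in seq_len(T_)) {
    for (cc in seq_len(T_)) {
      grid[r, cc] <- if (r == cc) trts[r] else
        cell(league$median[r, cc], league$lower[r, cc], league$upper[r, cc])
    }
  }
  grid
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write analysis tables to disk
#'
#' Writes the pairwise, league, and rank tables as canonical
#' full-precision CSV and optionally as 2-decimal Markdown presentation
#' tables. League CSV cells hold `median|lower|upper` (pipe-separated,
#' full precision) with treatment names on the diagonal.
#'
#' @param results Named list with any of `pairwise` (list of
#'   `pairwise_result`), `league` (`league_table`), `ranks`
#'   (`rank_table`).
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
write_tables <- function(results, dir, formats = c("csv", "markdown")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, lines_or_df, kind) {
    path <- file.path(dir, name)
    if (kind == "df") {
      utils::write.csv(lines_or_df, path, row.names = FALSE, quote = FALSE)
    } else if (kind == "mat") {
      utils::write.csv(as.data.frame(lines_or_df), path, quote = FALSE)
    } else {
      writeLines(lines_or_df, path)
    }
    written <<- c(written, path)
  }

  if (!is.null(results$pairwise)) {
    pf <- pairwise_frame(results$pairwise)
    if ("csv" %in% formats) emit("pairwise.csv", pf, "df")
    if ("markdown" %in% formats) {
      md <- data.frame(
        comparison = if (nrow(pf)) paste(pf$treatment, "vs", pf$comparator)
                     else character(),
        k = pf$k,
        `MD (95% CI)` = if (nrow(pf))
          format_estimate(pf$pooled_md, pf$ci_low, pf$ci_high)
          else character(),
        `I2 (%)` = sprintf("%.1f", 100 * pf$i2),
        check.names = FALSE, stringsAsFactors = FALSE
      )
      emit("pairwise.md", md_table(md), "lines")
    }
  }
  if (!is.null(results$league)) {
    if ("csv" %in% formats) emit("league.csv", league_grid(results$league), "mat")
    if ("markdown" %in% formats) {
      grid <- league_grid(results$league, cell = format_estimate)
      emit("league.md", md_table(cbind(
        data.frame(treatment = rownames(grid), stringsAsFactors = FALSE),
        as.data.frame(grid, stringsAsFactors = FALSE))), "lines")
    }
  }
  if (!is.null(results$ranks)) {
    m <- unclass(results$ranks)
    if ("csv" %in% formats) emit("ranks.csv", m, "mat")
    if ("markdown" %in% formats) {
      df <- as.data.frame(round(m, 4))
      emit("ranks.md", md_table(cbind(
        data.frame(treatment = rownames(m), stringsAsFactors = FALSE), df)),
        "lines")
    }
  }
  invisible(written)
}

#' Write posterior draws as plain columnar text
#'
#' Long format with columns `chain`, `iteration`, `parameter`, `value`
#' (full precision), plus a JSON metadata sidecar (`<path>.meta.json`)
#' carrying treatments, reference, and the settings echo so the draws can
#' be reloaded standalone.
#'
#' @param samples An `nma_samples` object.
#' @param path Output CSV path (a `.gz` suffix gzip-compresses).
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path) {
  stopifnot(inherits(samples, "nma_samples"))
  rows <- do.call(rbind, lapply(seq_along(samples$chains), function(j) {
    ch <- samples$chains[[j]]
    data.frame(chain = j, iteration = rep(seq_len(nrow(ch)), ncol(ch)),
               parameter = rep(colnames(ch), each = nrow(ch)),
               value = as.vector(ch), stringsAsFactors = FALSE)
  }))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("chain,iteration,parameter,value",
               sprintf("%d,%d,%s,%.17g", rows$chain, rows$iteration,
                       rows$parameter, rows$value)), con)
  meta <- list(treatments = samples$treatments,
               reference = samples$reference,
               d_names = samples$d_names,
               parameters = samples$parameters,
               settings = unclass(samples$settings))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path Path to the columnar draws file.
#' @return An `nma_samples`-compatible object (without the fitted model).
#' @export
read_draws <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("draws metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  chains <- lapply(sort(unique(long$chain)), function(j) {
    sub <- long[long$chain == j, , drop = FALSE]
    n <- max(sub$iteration)
    m <- matrix(NA_real_, n, length(meta$parameters),
                dimnames = list(NULL, meta$parameters))
    m[cbind(sub$iteration, match(sub$parameter, meta$parameters))] <- sub$value
    m
  })
  settings <- do.call(mcmc_settings, meta$settings[c("n_chains", "n_iter",
                                                     "burn_in", "thin", "seed")])
  structure(
    list(model = NULL, settings = settings, chains = chains,
         parameters = meta$parameters, d_names = meta$d_names,
         treatments = meta$treatments, reference = meta$reference),
    class = "nma_samples"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the complete VAS network meta-analysis
#'
#' End-to-end driver: reads and validates arm-level data, builds the
#' treatment network, runs every pairwise DerSimonian-Laird meta-analysis,
#' fits the Bayesian consistency model, and writes `pairwise.csv`,
#' `league.csv`, `ranks.csv`, `edges.csv`, `diagnostics.json` and a
#' reproducibility `manifest.json` to the output directory. Identical
#' inputs and seed reproduce byte-identical numeric outputs. On a stage
#' failure all partial outputs are removed and the error names the stage.
#'
#' @param arms Path to an arm-level CSV, or an arm-level data.frame.
#' @param out_dir Output directory.
#' @param reference Reference treatment code.
#' @param settings `mcmc_settings`; defaults to [desk_settings()] with
#'   `seed`.
#' @param seed Seed used when `settings` is not supplied.
#' @param z Normal quantile for pairwise CIs.
#' @param psrf_threshold Convergence pass threshold.
#' @param lower_is_better Outcome orientation for ranking.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `pairwise`, `samples`, `league`, `ranks`, `convergence`, `files`).
#' @export
run_full_analysis <- function(arms, out_dir, reference = "CSI-U",
                              settings = NULL, seed = 1L, z = 1.96,
                              psrf_threshold = 1.05, lower_is_better = TRUE,
                              verbose = TRUE) {
  if (is.null(settings)) settings <- desk_settings(seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "input"
  input_path <- if (is.character(arms)) arms else "<in-memory data.frame>"

  result <- tryCatch({
    arm_tab <- if (is.character(arms)) read_arm_table(arms) else
      validate_arm_table(arms)
    if (nrow(arm_tab) == 0L) stop("input contains no arms", call. = FALSE)
    say("input: %d arms, %d studies", nrow(arm_tab),
        length(unique(arm_tab$study_id)))

    stage <- "network"
    network <- build_network(arm_tab, reference = reference)
    say("network: %d treatments, %d edges", length(network$treatments),
        nrow(network$edges))

    stage <- "pairwise"
    pairwise <- pairwise_all(network, z = z)

    stage <- "nma"
    model <- build_model(network)
    samples <- sample_posterior(model, settings)
    say("nma: %d chains x %d retained draws", length(samples$chains),
        nrow(samples$chains[[1L]]))

    stage <- "summaries"
    league <- league_table(samples)
    ranks <- rank_probabilities(samples, lower_is_better = lower_is_better)
    conv <- convergence_report(samples, threshold = psrf_threshold)
    tau <- tau_summary(samples)

    stage <- "write"
    written <- write_tables(list(pairwise = pairwise, league = league,
                                 ranks = ranks), out_dir, formats = "csv")
    edges_path <- file.path(out_dir, "edges.csv")
    utils::write.csv(network_edge_list(network), edges_path,
                     row.names = FALSE, quote = FALSE)
    written <- c(written, edges_path)

    diag_path <- file.path(out_dir, "diagnostics.json")
    jsonlite::write_json(
      list(psrf = as.list(conv$psrf), max_psrf = conv$max_psrf,
           pass = conv$pass, threshold = conv$threshold,
           n_chains = conv$n_chains, retained_per_chain = conv$n_draws,
           tau = as.list(tau)),
      diag_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, diag_path)

    config <- list(reference = reference, z = z,
                   psrf_threshold = psrf_threshold,
                   lower_is_better = lower_is_better,
                   settings = unclass(settings))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(input = input_path, config = config,
           config_hash = config_hash(config), seed = settings$seed,
           tool = paste0("vasnma ",
                         as.character(utils::packageVersion("vasnma"))),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           outputs = basename(written)),
      manifest_path, auto_unbox = TRUE)
    written <- c(written, manifest_path)

    list(network = network, pairwise = pairwise, samples = samples,
         league = league, ranks = ranks, convergence = conv, tau = tau,
         files = written)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("analysis failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
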