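#' Read an arm-level trial table from CSV
#'
#' Reads one row per treatment arm with columns `study_id`, `treatment`,
#' `n`, `mean`, `sd` and optionally `outcome_label` and `follow_up`.
#' Numbers are parsed in the C locale ("." decimal); row order is preserved.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param aliases Named character vector mapping treatment-code aliases to
#'   canonical codes (applied after reading). The default folds the
#'   occasional misspelling "CIS-U" into "CSI-U".
#' @return A validated `data.frame` with columns `study_id`, `treatment`,
#'   `n` (integer), `mean`, `sd` (double), `outcome_label`, `follow_up`
#'   (character, `NA` when absent), one row per arm.
#' @seealso [write_arm_table()], [build_network()], [load_gtps_fixture()]
#' @export
read_arm_table <- function(path, aliases = c("CIS-U" = "CSI-U")) {
  if (!file.exists(path)) {
    stop("arm table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         strip.white = TRUE, fileEncoding = "UTF-8")
  required <- c("study_id", "treatment", "n", "mean", "sd")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("arm table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("outcome_label", "follow_up")) {
    if (!opt %in% names(raw)) raw[[opt]] <- rep(NA_character_, nrow(raw))
  }
  if (nrow(raw) == 0L) {
    return(empty_arm_table())
  }

  parse_num <- function(col, what) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) | !nzchar(raw[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s %s on line %d: %s",
                   what, col, bad[1L] + 1L, dQuote(raw[[col]][bad[1L]])),
           call. = FALSE)
    }
    x
  }
  arms <- data.frame(
    study_id = raw$study_id,
    treatment = raw$treatment,
    n = parse_num("n", "value for"),
    mean = parse_num("mean", "value for"),
    sd = parse_num("sd", "value for"),
    outcome_label = ifelse(nzchar(raw$outcome_label) & !is.na(raw$outcome_label),
                           raw$outcome_label, NA_character_),
    follow_up = ifelse(nzchar(raw$follow_up) & !is.na(raw$follow_up),
                       raw$follow_up, NA_character_),
    stringsAsFactors = FALSE
  )
  if (length(aliases) > 0L) {
    hit <- arms$treatment %in% names(aliases)
    arms$treatment[hit] <- unname(aliases[arms$treatment[hit]])
  }
  validate_arm_table(arms)
}

empty_arm_table <- function() {
  data.frame(study_id = character(), treatment = character(),
             n = integer(), mean = double(), sd = double(),
             outcome_label = character(), follow_up = character(),
             stringsAsFactors = FALSE)
}

#' Validate an arm-level table
#'
#' Enforces the arm-record invariants: `n >= 2` and whole-valued (a sample
#' SD must be definable), `sd > 0`, finite means, and uniqueness of
#' (`study_id`, `treatment`, `outcome_label`).
#'
#' @param arms A data.frame as returned by [read_arm_table()].
#' @return The validated data.frame (with `n` coerced to integer),
#'   invisibly usable in pipelines.
#' @export
validate_arm_table <- function(arms) {
  required <- c("study_id", "treatment", "n", "mean", "sd")
  missing_cols <- setdiff(required, names(arms))
  if (length(missing_cols) > 0L) {
    stop("arm table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(arms) == 0L) return(empty_arm_table())
  if (any(arms$n != round(arms$n))) {
    stop("per-arm n must be a whole number of patients", call. = FALSE)
  }
  if (any(arms$n < 2)) {
    bad <- which(arms$n < 2)[1L]
    stop(sprintf("arm %s/%s has n = %s; at least 2 patients per arm required",
                 arms$study_id[bad], arms$treatment[bad], arms$n[bad]),
         call. = FALSE)
  }
  if (any(!is.finite(arms$mean))) {
    stop("arm means must be finite", call. = FALSE)
  }
  if (any(!is.finite(arms$sd) | arms$sd <= 0)) {
    bad <- which(!is.finite(arms$sd) | arms$sd <= 0)[1L]
    stop(sprintf("arm %s/%s has sd = %s; sd must be > 0",
                 arms$study_id[bad], arms$treatment[bad], arms$sd[bad]),
         call. = FALSE)
  }
  key <- paste(arms$study_id, arms$treatment, arms$outcome_label, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- arms[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate arm: study %s, treatment %s, outcome_label %s",
                 dup$study_id, dup$treatment, dup$outcome_label),
         call. = FALSE)
  }
  arms$n <- as.integer(arms$n)
  rownames(arms) <- NULL
  arms
}

#' Write an arm-level table to CSV
#'
#' Inverse of [read_arm_table()]: the written file round-trips
#' field-for-field.
#'
#' @param arms Arm-level data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arm_table <- function(arms, path) {
  out <- arms[, c("study_id", "treatment", "n", "mean", "sd",
                  "outcome_label", "follow_up")]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a published total sample size into per-arm sizes
#'
#' Trial reports often print only the total number randomized. The split is
#' as equal as possible; when the total is not divisible, the first-listed
#' (treatment) arm receives the larger share.
#'
#' @param total Total number of patients (>= 2 per arm).
#' @param n_arms Number of arms.
#' @return Integer vector of length `n_arms`, summing to `total`, entries
#'   differing by at most 1.
#' @examples
#' split_total_n(104, 2) # 52 52
#' split_total_n(53, 2)  # 27 26
#' @export
split_total_n <- function(total, n_arms) {
  stopifnot(length(total) == 1L, length(n_arms) == 1L,
            total == round(total), n_arms == round(n_arms), n_arms >= 1)
  if (total < 2 * n_arms) {
    stop(sprintf("total %d cannot supply >= 2 patients to each of %d arms",
                 as.integer(total), as.integer(n_arms)), call. = FALSE)
  }
  base <- total %/% n_arms
  extra <- total - base * n_arms
  as.integer(base + as.integer(seq_len(n_arms) <= extra))
}

#' Build a treatment network from arm-level data
#'
#' Groups arms into studies, enumerates the direct-comparison edges, and
#' verifies the comparison graph is connected. Arms of a study that differ
#' only in `outcome_label` describe the same patients under two outcome
#' conditions and count once toward network geometry.
#'
#' @param arms Arm-level data.frame (see [read_arm_table()]).
#' @param reference Treatment code whose basic parameter is fixed at 0.
#' @param treatment_order Optional explicit ordering of treatment codes;
#'   defaults to lexicographic.
#' @return A `treatment_network` object: list with `treatments`,
#'   `reference`, `arms`, `studies` (named list of per-study arm tables),
#'   and `edges` (data.frame with `treat1`, `treat2`, `n_studies`,
#'   and a list column `studies` of study ids).
#' @export
build_network <- function(arms, reference, treatment_order = NULL) {
  arms <- validate_arm_table(arms)
  if (nrow(arms) == 0L) stop("no arms supplied", call. = FALSE)

  studies <- split(arms, factor(arms$study_id, levels = unique(arms$study_id)))
  for (sid in names(studies)) {
    if (length(unique(studies[[sid]]$treatment)) < 2L) {
      stop(sprintf("study %s has fewer than two distinct treatments", sid),
           call. = FALSE)
    }
  }

  treatments <- sort(unique(arms$treatment))
  if (!is.null(treatment_order)) {
    if (!setequal(treatment_order, treatments)) {
      stop("treatment_order must be a permutation of the observed codes",
           call. = FALSE)
    }
    treatments <- treatment_order
  }
  if (!reference %in% treatments) {
    stop(sprintf("reference treatment %s does not appear in any study",
                 dQuote(reference)), call. = FALSE)
  }

  # one edge row per unordered treatment pair with >= 1 direct study
  edge_map <- list()
  for (sid in names(studies)) {
    trts <- unique(studies[[sid]]$treatment)
    trts <- trts[order(match(trts, treatments))]
    for (i in seq_len(length(trts) - 1L)) {
      for (j in seq(i + 1L, length(trts))) {
        key <- paste(trts[i], trts[j], sep = "\r")
        edge_map[[key]] <- c(edge_map[[key]], sid)
      }
    }
  }
  keys <- names(edge_map)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    treat1 = vapply(parts, `[[`, "", 1L),
    treat2 = vapply(parts, `[[`, "", 2L),
    n_studies = vapply(edge_map, length, 0L),
    stringsAsFactors = FALSE
  )
  ord <- order(match(edges$treat1, treatments), match(edges$treat2, treatments))
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  edges$studies <- I(unname(edge_map[keys[ord]]))

  g <- igraph::graph_from_data_frame(edges[, c("treat1", "treat2")],
                                     directed = FALSE,
                                     vertices = treatments)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    groups <- split(names(comp$membership), comp$membership)
    stop("treatment network is disconnected; components: ",
         paste(vapply(groups, function(x) paste0("{", paste(x, collapse = ", "), "}"),
                      ""), collapse = " "),
         call. = FALSE)
  }

  structure(
    list(treatments = treatments, reference = reference,
         arms = arms, studies = studies, edges = edges),
    class = "treatment_network"
  )
}

#' @export
print.treatment_network <- function(x, ...) {
  cat(sprintf("Treatment network: %d treatments, %d studies, %d direct edges\n",
              length(x$treatments), length(x$studies), nrow(x$edges)))
  cat("Treatments:", paste(x$treatments, collapse = ", "),
      sprintf("(reference: %s)\n", x$reference))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s vs %s: %d stud%s (%s)\n",
                x$edges$treat1[i], x$edges$treat2[i], x$edges$n_studies[i],
                if (x$edges$n_studies[i] == 1L) "y" else "ies",
                paste(x$edges$studies[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Export the direct-comparison edges of a network
#'
#' Edge list of the network map (one row per directly compared treatment
#' pair, with the number of contributing studies), suitable for CSV export.
#'
#' @param network A `treatment_network`.
#' @return data.frame with columns `treat1`, `treat2`, `n_studies`,
#'   `studies` (semicolon-joined ids).
#' @export
network_edge_list <- function(network) {
  stopifnot(inherits(network, "treatment_network"))
  data.frame(
    treat1 = network$edges$treat1,
    treat2 = network$edges$treat2,
    n_studies = network$edges$n_studies,
    studies = vapply(network$edges$studies, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Total number of patients in a network
#'
#' Sums per-arm sample sizes, counting each (study, treatment) arm once
#' even when a study reports the same arms under several outcome labels.
#'
#' @param network A `treatment_network`.
#' @return Integer patient total.
#' @export
network_patient_total <- function(network) {
  a <- network$arms
  first <- !duplicated(paste(a$study_id, a$treatment, sep = "\r"))
  sum(a$n[first])
}

#' Load the packaged GTPS trial network
#'
#' The packaged fixture: eight randomized/controlled trials of conservative
#' management for greater trochanteric pain syndrome (GTPS) reporting VAS
#' pain (0-10 cm), forming a connected six-treatment network (PRP-U, CSI-U,
#' CSI-B, ESWT, EX, UC). Arm means and SDs are transcribed from the trial
#' reports; per-arm sample sizes derive from published totals via
#' [split_total_n()] (see the provenance sidecar
#' `inst/extdata/gtps_provenance.json`). The Brinks 2011 trial reports VAS
#' both at rest and with activity; the two rows are stored under distinct
#' `outcome_label`s and merged by the meta-analysis stages.
#'
#' @param reference Reference treatment code (default `"CSI-U"`).
#' @return A `treatment_network` with 8 studies and 6 treatments.
#' @examples
#' net <- load_gtps_fixture()
#' net$edges
#' @export
load_gtps_fixture <- function(reference = "CSI-U") {
  path <- system.file("extdata", "gtps_arms.csv", package = "vasnma",
                      mustWork = TRUE)
  build_network(read_arm_table(path), reference = reference)
}
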