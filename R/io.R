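# Tab-separated file round-trips, protocol-catalog serialization, the
# drug-usage report, and the end-to-end pipeline.

#' Read a tab-separated matrix file
#'
#' Expected layout: a header row of column names, then one row per sample
#' with the sample ID in the first column. Binary matrices accept only
#' "0"/"1"; real matrices accept decimals with "NA" for missing.
#'
#' @param path file path.
#' @param kind `"binary"` or `"real"`.
#' @return Numeric matrix with sample IDs as rownames.
#' @export
read_matrix <- function(path, kind = c("binary", "real")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop(sprintf("%s: expected an ID column plus data columns", path),
                          call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicated sample ID '%s'", path, ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  rownames(raw) <- ids
  if (kind == "binary") {
    bad <- which(!(raw %in% c("0", "1")))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(raw))
      stop(sprintf("%s: non-binary value '%s' at row '%s' (line %d), column '%s'",
                   path, raw[bad[1L]], ids[rc[1]], rc[1] + 1L,
                   colnames(raw)[rc[2]]), call. = FALSE)
    }
    mat <- matrix(as.integer(raw), nrow(raw), ncol(raw), dimnames = dimnames(raw))
  } else {
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & raw != "NA")
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(raw))
      stop(sprintf("%s: unparseable value '%s' at row '%s' (line %d), column '%s'",
                   path, raw[bad[1L]], ids[rc[1]], rc[1] + 1L,
                   colnames(raw)[rc[2]]), call. = FALSE)
    }
    mat <- matrix(vals, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  }
  mat
}

#' Write a matrix in the tab-separated exchange format
#'
#' @param mat matrix with rownames (sample IDs) and colnames.
#' @param path output path.
#' @param id_header header of the ID column (default "sample").
#' @export
write_matrix <- function(mat, path, id_header = "sample") {
  df <- data.frame(rownames(mat) %||% seq_len(nrow(mat)), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Serialize drug protocols to a tab-separated catalog file
#'
#' Columns: drug ID, K, function index b, comma-separated marker names, and
#' the truth table as a 0/1 string (the truth table is authoritative; b is
#' informational). Empty protocols have K = 0 and empty fields.
#'
#' @param protocols list of `drug_protocol`.
#' @param drug_ids drug identifiers.
#' @param marker_names cohort marker names (to resolve indices).
#' @param path output path.
#' @export
write_protocols <- function(protocols, drug_ids, marker_names, path) {
  rows <- lapply(seq_along(protocols), function(j) {
    p <- protocols[[j]]
    K <- length(p$markers)
    data.frame(drug = drug_ids[j], K = K,
               b = if (K) p$fn$b else NA_integer_,
               markers = paste(marker_names[p$markers], collapse = ","),
               truth_table = if (K) paste(p$fn$outputs, collapse = "") else "",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a protocol catalog file
#'
#' @param path file written by [write_protocols()].
#' @param marker_names cohort marker names used to resolve marker columns.
#' @return Named list of `drug_protocol` (names = drug IDs).
#' @export
read_protocols <- function(path, marker_names) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  out <- lapply(seq_len(nrow(df)), function(r) {
    if (as.integer(df$K[r]) == 0L) return(drug_protocol())
    mk <- match(strsplit(df$markers[r], ",", fixed = TRUE)[[1L]], marker_names)
    if (anyNA(mk)) stop(sprintf("unknown marker name in row %d", r), call. = FALSE)
    outputs <- as.integer(strsplit(df$truth_table[r], "")[[1L]])
    drug_protocol(mk, boolfun(outputs))
  })
  names(out) <- df$drug
  out
}

#' Write a treatment plan
#'
#' One row per sample: ID, comma-separated chosen drug IDs, and the
#' combination response probability.
#'
#' @param eval an `assignment_eval`.
#' @param drug_ids drug identifiers.
#' @param path output path.
#' @export
write_plan <- function(eval, drug_ids, path) {
  stopifnot(inherits(eval, "assignment_eval"))
  df <- data.frame(
    sample = rownames(eval$plan$e),
    drugs = vapply(eval$plan$chosen,
                   function(ch) paste(drug_ids[ch], collapse = ","), ""),
    P = eval$P, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a group-rate table
#'
#' One row per drug and marker group: drug ID, group index s, group size
#' and estimated response rate q.
#'
#' @param table a `group_rate_table`.
#' @param drug_ids drug identifiers.
#' @param path output path.
#' @export
write_group_rates <- function(table, drug_ids, path) {
  rows <- list()
  for (j in seq_along(table$drugs)) {
    entry <- table$drugs[[j]]
    if (!length(entry$q)) next
    rows[[length(rows) + 1L]] <- data.frame(
      drug = drug_ids[j], s = seq_along(entry$q) - 1L,
      n = entry$n, q = entry$q, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(0), s = integer(0), n = integer(0),
               q = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Catalog report of drug usage across combination sizes
#'
#' For each drug used at the largest combination size: the percentage of
#' samples whose personalized therapy includes it at every requested `c`
#' (`NA`, printed as "-", when unused at that size), and the drug's marker
#' count, truth table and markers from the largest-`c` assignment. Rows are
#' ordered by decreasing usage at the largest `c`.
#'
#' @param evals list of `assignment_eval` objects for the same cohort at
#'   increasing combination sizes.
#' @param drug_ids drug identifiers.
#' @param marker_names cohort marker names.
#' @return A data frame of class `catalog_report` with one `pct_c<k>`
#'   column per requested size.
#' @export
report_catalog <- function(evals, drug_ids, marker_names) {
  stopifnot(length(evals) >= 1L)
  ns <- vapply(evals, function(ev) nrow(ev$plan$e), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all evaluations must come from the same cohort", call. = FALSE)
  }
  cs <- vapply(evals, function(ev) ev$c, integer(1))
  evals <- evals[order(cs)]
  cs <- sort(cs)
  s <- ns[1L]
  last <- evals[[length(evals)]]
  pct <- vapply(evals, function(ev) 100 * colSums(ev$plan$e) / s,
                numeric(length(drug_ids)))
  pct <- matrix(pct, ncol = length(evals))
  pct[pct == 0] <- NA_real_
  keep <- which(!is.na(pct[, ncol(pct)]))
  keep <- keep[order(-pct[keep, ncol(pct)])]
  out <- data.frame(drug = drug_ids[keep], stringsAsFactors = FALSE)
  for (k in seq_along(cs)) out[[sprintf("pct_c%d", cs[k])]] <- pct[keep, k]
  out$K <- vapply(last$protocols[keep], function(p) length(p$markers), integer(1))
  out$f <- vapply(last$protocols[keep], function(p) {
    if (length(p$markers)) paste(p$fn$outputs, collapse = "") else ""
  }, "")
  out$markers <- vapply(last$protocols[keep], function(p) {
    paste(marker_names[p$markers], collapse = ",")
  }, "")
  class(out) <- c("catalog_report", class(out))
  out
}

#' @export
print.catalog_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in grep("^pct_c", names(y))) {
    y[[cl]] <- ifelse(is.na(y[[cl]]), "-", sprintf("%.1f", y[[cl]]))
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a catalog report to a tab-separated file
#'
#' Percentages are formatted to one decimal place; "-" marks sizes at which
#' the drug is unused.
#'
#' @param report a `catalog_report`.
#' @param path output path.
#' @export
write_catalog <- function(report, path) {
  y <- as.data.frame(report)
  for (cl in grep("^pct_c", names(y))) {
    y[[cl]] <- ifelse(is.na(y[[cl]]), "-", sprintf("%.1f", y[[cl]]))
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full optimization pipeline
#'
#' Reads the marker and logIC50 (or response-probability) matrices, imputes
#' missing logIC50 values if needed, builds the response matrix under the
#' pharmacokinetic model, optimizes marker assignments at each requested
#' combination size, and writes the protocol catalogs, treatment plans,
#' restart traces and the usage report to `outdir`. Fully deterministic
#' given the input files and configuration.
#'
#' @param config a named list or the path of a YAML file. Required fields:
#'   `markers_file` and one of `ic50_file`/`response_file`, plus `outdir`.
#'   Optional fields (defaults in parentheses): `min_marker_count` (10),
#'   `h` (2), `sigma` (1), `alpha_sample` (1), `alpha_drug` (1),
#'   `c_values` (1), `k_max` (2), `steps_per_drug` (10000), `beta0` (0),
#'   `dbeta` (0.01), `restarts` (100), `base_seed` (1),
#'   `min_group_size` (10).
#' @return Invisibly, a list with the per-size `anneal_result`s, the
#'   catalog report and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(field) {
    if (is.null(config[[field]])) {
      stop(sprintf("pipeline config is missing required field '%s'", field),
           call. = FALSE)
    }
    config[[field]]
  }
  get_opt <- function(field, default) config[[field]] %||% default

  markers_file <- need("markers_file")
  outdir <- need("outdir")
  if (is.null(config$ic50_file) && is.null(config$response_file)) {
    stop("pipeline config is missing required field 'ic50_file' (or 'response_file')",
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  coh <- cohort(read_matrix(markers_file, "binary"))
  coh <- filter_markers(coh, get_opt("min_marker_count", 10L))

  if (!is.null(config$response_file)) {
    responses <- read_matrix(config$response_file, "real")
    if (anyNA(responses) || any(responses < 0 | responses > 1)) {
      stop("response matrix stage failed: probabilities must lie in [0,1]",
           call. = FALSE)
    }
  } else {
    ic50 <- read_matrix(config$ic50_file, "real")
    if (anyNA(ic50)) {
      ic50 <- impute_ic50(ic50, get_opt("alpha_sample", 1),
                          get_opt("alpha_drug", 1))
      write_matrix(ic50, file.path(outdir, "ic50_completed.tsv"))
    }
    responses <- build_response_matrix(ic50, h = get_opt("h", 2),
                                       sigma = get_opt("sigma", 1))
  }
  if (nrow(responses) != coh$s) {
    stop("optimize stage failed: sample counts of markers and responses differ",
         call. = FALSE)
  }
  drug_ids <- colnames(responses) %||% sprintf("D%02d", seq_len(ncol(responses)))

  c_values <- sort(unique(as.integer(get_opt("c_values", 1L))))
  results <- list()
  evals <- list()
  for (cc in c_values) {
    cfg <- anneal_config(
      c = cc, k_max = get_opt("k_max", 2L),
      steps_per_drug = get_opt("steps_per_drug", 10000L),
      beta0 = get_opt("beta0", 0), dbeta = get_opt("dbeta", 0.01),
      restarts = get_opt("restarts", 100L),
      base_seed = get_opt("base_seed", 1L),
      min_group_size = get_opt("min_group_size", 10L))
    res <- multi_start(coh, responses, cfg)
    results[[as.character(cc)]] <- res
    evals[[as.character(cc)]] <- res$eval
    write_protocols(res$best$protocols, drug_ids, coh$marker_names,
                    file.path(outdir, sprintf("protocols_c%d.tsv", cc)))
    write_plan(res$eval, drug_ids, file.path(outdir, sprintf("plan_c%d.tsv", cc)))
    utils::write.table(res$trace, file.path(outdir, sprintf("trace_c%d.tsv", cc)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- report_catalog(evals, drug_ids, coh$marker_names)
  write_catalog(report, file.path(outdir, "catalog.tsv"))
  yaml::write_yaml(config, file.path(outdir, "config_echo.yaml"))
  invisible(list(results = results, report = report, outdir = outdir,
                 cohort = coh, responses = responses))
}
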