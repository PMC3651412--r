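# Cohort, drug catalog and response-matrix containers with validation.

#' Construct a cohort of binary marker profiles
#'
#' @param profiles s x m matrix with entries 0/1; rows are samples, columns
#'   are markers. Marker identity is an opaque string label (a tissue type,
#'   a mutation call such as "TP53:wt", or a copy-number state are all just
#'   binary features here).
#' @param sample_ids,marker_names optional identifiers; default to the
#'   matrix dimnames or generated labels.
#' @return An object of class `cohort` with fields `profiles`, `sample_ids`,
#'   `marker_names`, `s`, `m`.
#' @export
cohort <- function(profiles, sample_ids = NULL, marker_names = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L || ncol(profiles) < 1L) {
    stop("cohort needs at least one sample and one marker", call. = FALSE)
  }
  if (anyNA(profiles) || !all(profiles %in% c(0, 1))) {
    stop("marker profiles must be binary 0/1", call. = FALSE)
  }
  storage.mode(profiles) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(profiles)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(profiles)))
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(profiles)
    if (is.null(marker_names)) marker_names <- sprintf("M%03d", seq_len(ncol(profiles)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(marker_names)) stop("duplicate marker names", call. = FALSE)
  dimnames(profiles) <- list(sample_ids, marker_names)
  structure(
    list(profiles = profiles,
         sample_ids = as.character(sample_ids),
         marker_names = as.character(marker_names),
         s = nrow(profiles), m = ncol(profiles)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d samples x %d binary markers\n", x$s, x$m))
  cat(sprintf("  marker prevalence: %d markers present in >= 10 samples\n",
              sum(colSums(x$profiles) >= 10)))
  invisible(x)
}

#' Construct a drug catalog
#'
#' @param drug_ids character vector of unique drug identifiers.
#' @param annotation optional character vector (e.g. nominal target) of the
#'   same length.
#' @return An object of class `drug_catalog`.
#' @export
drug_catalog <- function(drug_ids, annotation = NULL) {
  drug_ids <- as.character(drug_ids)
  if (length(drug_ids) < 1L) stop("catalog needs at least one drug", call. = FALSE)
  if (anyDuplicated(drug_ids)) stop("duplicate drug IDs", call. = FALSE)
  if (!is.null(annotation) && length(annotation) != length(drug_ids)) {
    stop("annotation length must match drug_ids", call. = FALSE)
  }
  structure(list(drug_ids = drug_ids, annotation = annotation,
                 d = length(drug_ids)),
            class = "drug_catalog")
}

#' Restrict a cohort to markers observed in enough samples
#'
#' Markers present in fewer than `min_count` samples are dropped; sample set
#' and marker order are unchanged. Rare-marker filtering stabilizes the
#' by-marker response estimates downstream.
#'
#' @param x a `cohort`.
#' @param min_count minimum number of samples carrying the marker
#'   (default 10).
#' @return A `cohort` with the retained markers.
#' @export
filter_markers <- function(x, min_count = 10L) {
  stopifnot(inherits(x, "cohort"))
  if (length(min_count) != 1L || is.na(min_count) || min_count < 1L) {
    stop("min_count must be a positive integer", call. = FALSE)
  }
  keep <- colSums(x$profiles) >= min_count
  if (!any(keep)) {
    stop("no marker is observed in at least min_count samples; cohort unusable",
         call. = FALSE)
  }
  cohort(x$profiles[, keep, drop = FALSE])
}

#' Validate cohort, catalog and response-probability inputs
#'
#' Collects structural problems (dimension mismatches, non-binary profile
#' entries, probabilities outside \[0,1\], duplicated identifiers) into a
#' report instead of stopping, so a caller can display everything at once.
#'
#' @param profiles a `cohort` or a raw samples-by-markers matrix.
#' @param catalog optional `drug_catalog`.
#' @param responses optional samples-by-drugs probability matrix.
#' @return A data frame of class `validation_report` with columns
#'   `component` and `issue`; zero rows when everything is clean.
#' @export
validate_cohort <- function(profiles, catalog = NULL, responses = NULL) {
  issues <- list()
  add <- function(component, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      component = component, issue = issue, stringsAsFactors = FALSE)
  }

  mat <- if (inherits(profiles, "cohort")) profiles$profiles else as.matrix(profiles)
  bad <- which(!(mat %in% c(0, 1)) | is.na(mat))
  for (cell in bad) {
    rc <- arrayInd(cell, dim(mat))
    add("profiles", sprintf("non-binary entry at row %d ('%s'), column %d ('%s')",
                            rc[1], rownames(mat)[rc[1]] %||% rc[1],
                            rc[2], colnames(mat)[rc[2]] %||% rc[2]))
  }
  rn <- rownames(mat)
  if (!is.null(rn) && anyDuplicated(rn)) {
    add("profiles", sprintf("duplicated sample ID(s): %s",
                            paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  }
  cn <- colnames(mat)
  if (!is.null(cn) && anyDuplicated(cn)) {
    add("profiles", sprintf("duplicated marker name(s): %s",
                            paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  }

  if (!is.null(responses)) {
    responses <- as.matrix(responses)
    if (nrow(responses) != nrow(mat)) {
      add("responses", sprintf("sample count mismatch: %d profiles vs %d response rows",
                               nrow(mat), nrow(responses)))
    }
    if (!is.null(catalog) && ncol(responses) != catalog$d) {
      add("responses", sprintf("drug count mismatch: %d catalog drugs vs %d response columns",
                               catalog$d, ncol(responses)))
    }
    bad <- which(is.na(responses) | responses < 0 | responses > 1)
    for (cell in bad) {
      rc <- arrayInd(cell, dim(responses))
      add("responses", sprintf("probability outside [0,1] at row %d ('%s'), column %d ('%s'): %s",
                               rc[1], rownames(responses)[rc[1]] %||% rc[1],
                               rc[2], colnames(responses)[rc[2]] %||% rc[2],
                               format(responses[cell])))
    }
  }

  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(component = character(0), issue = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Validation passed: no issues found\n")
  } else {
    cat(sprintf("Validation found %d issue(s):\n", nrow(x)))
    for (i in seq_len(nrow(x))) cat(sprintf("  [%s] %s\n", x$component[i], x$issue[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
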