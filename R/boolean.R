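# Boolean drug-to-sample protocols.
#
# A drug's decision rule is a Boolean function on the K markers assigned to
# it. Input states a = sum_k x_k 2^(k-1) index the truth table; only
# non-degenerate functions (output depends on every input) are kept, because
# a function ignoring an input is equivalent to a simpler rule on fewer
# markers. Marker removal/addition moves map a function to the set of
# compatible functions one input away; these sets drive the annealer's moves.

# cache for enumerations and removal/addition sets, keyed by (K) or (K,b,pos)
.bf_cache <- new.env(parent = emptyenv())

state_bits <- function(a, K) {
  as.integer(bitwAnd(bitwShiftR(as.integer(a), 0:(K - 1L)), 1L))
}

state_index <- function(bits) {
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' Construct a Boolean decision function from its truth table
#'
#' @param outputs 0/1 vector of length `2^K`, entry `a + 1` giving the output
#'   for input state `a = sum_k x_k 2^(k-1)`.
#' @return An object of class `boolfun` with fields `K` (number of inputs),
#'   `outputs`, and the integer index `b = sum_a o_a 2^a`.
#' @examples
#' boolfun(c(0, 0, 0, 1)) # AND of two markers
#' @export
boolfun <- function(outputs) {
  outputs <- as.integer(outputs)
  n <- length(outputs)
  K <- as.integer(round(log2(n)))
  if (n < 2L || 2^K != n) {
    stop("truth table length must be 2^K for some K >= 1", call. = FALSE)
  }
  if (anyNA(outputs) || !all(outputs %in% c(0L, 1L))) {
    stop("truth-table outputs must be 0 or 1", call. = FALSE)
  }
  structure(
    list(K = K, outputs = outputs,
         b = sum(outputs * 2^(seq_len(n) - 1L))),
    class = "boolfun"
  )
}

#' @export
print.boolfun <- function(x, ...) {
  cat(sprintf("Boolean function (K=%d, b=%d): %s\n",
              x$K, x$b, paste(x$outputs, collapse = "")))
  invisible(x)
}

#' Test whether a truth table depends on every input
#'
#' A function is degenerate when some input can be flipped in every state
#' without changing the output; such rules reduce to fewer markers and are
#' excluded from the protocol space.
#'
#' @param outputs 0/1 vector of length `2^K`.
#' @return `TRUE` if every input matters.
#' @export
depends_on_all_inputs <- function(outputs) {
  K <- as.integer(round(log2(length(outputs))))
  a <- 0:(length(outputs) - 1L)
  for (k in seq_len(K)) {
    partner <- bitwXor(a, bitwShiftL(1L, k - 1L))
    if (all(outputs[a + 1L] == outputs[partner + 1L])) return(FALSE)
  }
  TRUE
}

#' Enumerate all non-degenerate Boolean functions with K inputs
#'
#' @param K number of inputs (markers).
#' @param k_max upper bound on K; enumeration is exponential in `2^K`, so a
#'   hard cap is enforced.
#' @return List of `boolfun` objects in increasing order of index `b`.
#'   There are 2 functions at K=1 (identity, negation), 10 at K=2 and 218
#'   at K=3.
#' @export
enumerate_functions <- function(K, k_max = 4L) {
  if (length(K) != 1L || is.na(K) || K < 1L) {
    stop("K must be a positive integer", call. = FALSE)
  }
  if (K > k_max) {
    stop(sprintf("K = %d exceeds k_max = %d", K, k_max), call. = FALSE)
  }
  key <- sprintf("enum:%d", K)
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  n_states <- 2L^as.integer(K)
  fns <- vector("list", 0L)
  shift <- 0:(n_states - 1L)
  for (b in 0:(2^n_states - 1L)) {
    outputs <- as.integer(bitwAnd(bitwShiftR(as.integer(b), shift), 1L))
    if (depends_on_all_inputs(outputs)) {
      fns[[length(fns) + 1L]] <- boolfun(outputs)
    }
  }
  .bf_cache[[key]] <- fns
  fns
}

#' Evaluate a Boolean function on a marker-status vector
#'
#' @param fn a `boolfun`.
#' @param inputs 0/1 vector of length `fn$K` (the sample's status on the
#'   drug's markers, in assignment order).
#' @return 0 or 1.
#' @export
bf_evaluate <- function(fn, inputs) {
  stopifnot(inherits(fn, "boolfun"))
  if (length(inputs) != fn$K) {
    stop(sprintf("expected %d inputs, got %d", fn$K, length(inputs)),
         call. = FALSE)
  }
  if (anyNA(inputs) || !all(inputs %in% c(0, 1))) {
    stop("inputs must be 0 or 1", call. = FALSE)
  }
  fn$outputs[state_index(inputs) + 1L]
}

insert_bit <- function(bits, position, value) {
  n <- length(bits)
  if (position == 1L) c(value, bits)
  else if (position == n + 1L) c(bits, value)
  else c(bits[seq_len(position - 1L)], value, bits[position:n])
}

#' Compatible functions after removing one marker
#'
#' Restricting a K-input rule to K-1 inputs: for every reduced input state
#' the surviving rule must output one of the values the original rule takes
#' over the two extensions at the removed position. Degenerate candidates
#' are excluded. Removing the only marker of a one-input rule is not handled
#' here; that transition empties the protocol.
#'
#' @param fn a `boolfun` with `K >= 2` inputs.
#' @param position input position to drop (1-based).
#' @return List of compatible `boolfun` objects on K-1 inputs, ordered by
#'   index `b`. Callers pick one uniformly when several are compatible.
#' @export
remove_marker <- function(fn, position) {
  stopifnot(inherits(fn, "boolfun"))
  if (fn$K < 2L) {
    stop("removal from a one-input function empties the protocol", call. = FALSE)
  }
  if (position < 1L || position > fn$K) {
    stop("position out of range", call. = FALSE)
  }
  key <- sprintf("rm:%d:%d:%d", fn$K, fn$b, position)
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  Kr <- fn$K - 1L
  red_states <- 0:(2^Kr - 1L)
  allowed <- lapply(red_states, function(u) {
    bits <- state_bits(u, Kr)
    unique(c(fn$outputs[state_index(insert_bit(bits, position, 0L)) + 1L],
             fn$outputs[state_index(insert_bit(bits, position, 1L)) + 1L]))
  })
  out <- Filter(function(g) {
    all(vapply(red_states, function(u) {
      g$outputs[u + 1L] %in% allowed[[u + 1L]]
    }, logical(1)))
  }, enumerate_functions(Kr))
  .bf_cache[[key]] <- out
  out
}

#' Compatible functions after adding a marker
#'
#' The reverse of last-position removal: all non-degenerate (K+1)-input
#' functions whose restriction set at the last (new) input contains `fn`.
#'
#' @param fn a `boolfun`.
#' @param k_max maximum allowed number of inputs.
#' @return List of `boolfun` objects on K+1 inputs, ordered by index `b`.
#' @export
add_marker <- function(fn, k_max = 4L) {
  stopifnot(inherits(fn, "boolfun"))
  if (fn$K + 1L > k_max) {
    stop(sprintf("adding a marker would exceed k_max = %d", k_max),
         call. = FALSE)
  }
  key <- sprintf("add:%d:%d", fn$K, fn$b)
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  Kp <- fn$K + 1L
  out <- Filter(function(g) {
    any(vapply(remove_marker(g, Kp), function(h) h$b == fn$b, logical(1)))
  }, enumerate_functions(Kp, k_max = k_max))
  .bf_cache[[key]] <- out
  out
}

#' Draw a different Boolean function with the same number of inputs
#'
#' Uniform over all non-degenerate K-input functions other than `fn` itself,
#' so every proposed change is a real change.
#'
#' @param fn a `boolfun`.
#' @return A `boolfun` with the same `K` and a different truth table.
#' @export
change_function <- function(fn) {
  stopifnot(inherits(fn, "boolfun"))
  pool <- Filter(function(g) g$b != fn$b, enumerate_functions(fn$K))
  if (!length(pool)) stop("no alternative function exists", call. = FALSE)
  pool[[sample.int(length(pool), 1L)]]
}

#' Construct a drug-to-sample protocol
#'
#' A protocol is an ordered list of distinct marker indices plus a Boolean
#' function with one input per marker. An empty protocol (no markers) means
#' the drug is never suggested.
#'
#' @param markers integer vector of marker column indices (possibly empty).
#' @param fn a `boolfun` with `K = length(markers)` inputs, or `NULL` for an
#'   empty protocol.
#' @return An object of class `drug_protocol`.
#' @export
drug_protocol <- function(markers = integer(0), fn = NULL) {
  markers <- as.integer(markers)
  if (anyDuplicated(markers)) {
    stop("duplicate marker in protocol", call. = FALSE)
  }
  if (length(markers) == 0L) {
    if (!is.null(fn)) stop("empty protocol cannot carry a function", call. = FALSE)
  } else {
    if (!inherits(fn, "boolfun")) {
      stop("a protocol with markers needs a boolfun", call. = FALSE)
    }
    if (fn$K != length(markers)) {
      stop("function input count must equal marker count", call. = FALSE)
    }
  }
  structure(list(markers = markers, fn = fn), class = "drug_protocol")
}

#' @export
print.drug_protocol <- function(x, ...) {
  if (length(x$markers) == 0L) {
    cat("Drug protocol: no markers (never suggested)\n")
  } else {
    cat(sprintf("Drug protocol: markers [%s], f = %s (K=%d, b=%d)\n",
                paste(x$markers, collapse = ","),
                paste(x$fn$outputs, collapse = ""), x$fn$K, x$fn$b))
  }
  invisible(x)
}

#' Decide whether a drug is suggested for one sample
#'
#' Evaluates the protocol's Boolean function on the sample's status for the
#' drug's markers. A drug with no markers assigned is never suggested.
#'
#' @param protocol a `drug_protocol`.
#' @param profile full binary marker profile of one sample (length m).
#' @return 0 or 1.
#' @export
suggest <- function(protocol, profile) {
  stopifnot(inherits(protocol, "drug_protocol"))
  if (length(protocol$markers) == 0L) return(0L)
  if (any(protocol$markers < 1L | protocol$markers > length(profile))) {
    stop("marker index out of range for this profile", call. = FALSE)
  }
  bf_evaluate(protocol$fn, profile[protocol$markers])
}
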